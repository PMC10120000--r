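#' Giant-cluster fraction of an Erdos-Renyi random graph
#'
#' Closed form for the infinite-size limit, via the principal branch of
#' the Lambert W function:
#' \deqn{P(\langle k\rangle) = 1 + W_0(-\langle k\rangle e^{-\langle k\rangle}) / \langle k\rangle.}
#' Below the percolation critical point at mean degree 1 the giant
#' cluster vanishes and P = 0. The value agrees with the fixed point of
#' \eqn{P = 1 - e^{-\langle k\rangle P}} to better than 1e-10.
#'
#' @param mean_degree numeric vector of mean degrees, all >= 0.
#' @return numeric vector of P values in \[0, 1\].
#' @examples
#' random_graph_P(c(0.5, 1, 2, 10))
#' @export
random_graph_P <- function(mean_degree) {
  if (any(mean_degree < 0)) stop("mean_degree must be >= 0")
  P <- numeric(length(mean_degree))
  above <- mean_degree > 1
  if (any(above)) {
    k <- mean_degree[above]
    P[above] <- 1 + lambert_w0(-k * exp(-k)) / k
  }
  P
}

# Principal-branch Lambert W on [-1/e, Inf), vectorised. Halley iteration
# seeded by the branch-point series near -1/e (where generic Newton-type
# starts stall: the theory curves evaluate W arbitrarily close to the
# branch point as alpha grows and kappa -> 0) and by log-based asymptotics
# elsewhere. Accuracy ~1e-14; cross-checked against pracma::lambertWp on
# interior arguments in the test suite.
lambert_w0 <- function(z) {
  lo <- -exp(-1)
  if (any(z < lo - 1e-12)) stop("Lambert W argument below -1/e")
  z <- pmax(z, lo)
  w <- numeric(length(z))
  # initial guess
  p <- sqrt(pmax(2 * (1 + exp(1) * z), 0))
  near <- z < -0.25
  w[near] <- -1 + p[near] - p[near]^2 / 3 + 11 / 72 * p[near]^3
  mid <- !near & z < exp(1)
  w[mid] <- z[mid] * exp(-z[mid] * 0.4)       # crude but in basin
  big <- !near & !mid
  lz <- log(z[big])
  w[big] <- lz - log(lz)
  # Halley refinement
  for (i in 1:100) {
    ew <- exp(w)
    f <- w * ew - z
    wp1 <- w + 1
    d <- ew * wp1 - (w + 2) * f / (2 * wp1)
    step <- ifelse(abs(d) > 0, f / d, 0)
    # at the branch point wp1 -> 0; the series guess is already exact there
    step[!is.finite(step)] <- 0
    w <- w - step
    if (all(abs(step) <= 1e-15 * (1 + abs(w)))) break
  }
  w[z == lo] <- -1
  w
}

#' Giant Cluster Self Preference growth curve
#'
#' Closed-form fraction of nodes recruited into the (single) growing
#' cluster as a function of mean degree \eqn{\kappa = 2E/N}, for a network
#' grown under giant-cluster self preference: each new edge is
#' \eqn{\alpha} times more likely to land on an open pair inside the
#' cluster than to branch out and recruit a new node. In the
#' infinite-size limit the recruited fraction is deterministic:
#' \deqn{P(\kappa) = 1 + \frac{1}{1 - 2/\alpha}
#'       W_0\!\left[\left(\tfrac{2}{\alpha}-1\right)
#'       e^{2/\alpha - 1} e^{-\kappa/\alpha}\right],}
#' the solution of the characteristic equation [ode_rhs()] with P(0) = 0.
#' At \eqn{\alpha = 2} the prefactor degenerates and the limit is
#' \eqn{P = 1 - e^{-\kappa/2}}. Unlike [random_graph_P()], the curve has
#' no critical point: P > 0 for every \eqn{\kappa > 0}.
#'
#' Brain fits give \eqn{\alpha} well above 2 (typically 10-16); values
#' \eqn{\alpha \le 2} are still valid mathematically and evaluated by the
#' same formula (the W argument stays in the principal branch's real
#' domain for every \eqn{\alpha > 0}).
#'
#' @param mean_degree numeric vector of mean degrees, all >= 0.
#' @param alpha self-preference parameter, > 0.
#' @return numeric vector of P values in \[0, 1\].
#' @examples
#' gcsp_P(c(1, 5, 20), alpha = 11)
#' @export
gcsp_P <- function(mean_degree, alpha) {
  stopifnot(length(alpha) == 1L, is.finite(alpha), alpha > 0)
  if (any(mean_degree < 0)) stop("mean_degree must be >= 0")
  if (abs(alpha - 2) < 1e-8)
    return(1 - exp(-mean_degree / 2))
  x <- 2 / alpha - 1
  w <- lambert_w0(x * exp(x) * exp(-mean_degree / alpha))
  pmin(pmax(1 + w / (1 - 2 / alpha), 0), 1)
}

#' Branching probability of the self-preference growth process
#'
#' For a single cluster of `n` nodes and `E` edges inside a network that
#' will eventually have `N` nodes, the probability that the next edge
#' recruits a new node (rather than filling one of the
#' \eqn{n(n-1)/2 - E} open pairs inside the cluster) is
#' \deqn{p(n \to n+1 \mid E \to E+1) =
#'   \frac{\frac{1}{\alpha} n (N - n)}
#'        {\frac{1}{2} n (n-1) - E + \frac{1}{\alpha} n (N - n)}.}
#' The complement is the probability of an internal placement.
#'
#' @param n current cluster size(s), 1 <= n <= N (vectorised).
#' @param E current edge count, 0 <= E <= n(n-1)/2.
#' @param alpha self-preference parameter, > 0.
#' @param N final node count.
#' @return branching probability in \[0, 1\].
#' @export
transition_probability <- function(n, E, alpha, N) {
  stopifnot(alpha > 0, N >= 1)
  if (any(n < 1 | n > N)) stop("n must satisfy 1 <= n <= N")
  if (any(E < 0) || any(E > n * (n - 1) / 2))
    stop("E exceeds the capacity n(n-1)/2 of a cluster of size n")
  w <- n * (N - n) / alpha
  spots <- n * (n - 1) / 2 - E
  p <- ifelse(w == 0, 0, w / (spots + w))
  as.numeric(p)
}

#' Evolve the finite-size master equation for cluster growth
#'
#' Exact forward recursion for the distribution \eqn{p(n \mid E)} of the
#' cluster size after `E` edges, starting from a single node
#' (\eqn{p(n \mid 0) = \delta_{n,1}}):
#' \deqn{p(n \mid E+1) = p(n \mid E)\,[1 - T(n, E)] + p(n-1 \mid E)\,T(n-1, E),}
#' with \eqn{T} the branching probability of [transition_probability()].
#' Total probability is checked at every step and must stay within `tol`
#' of 1. For large `N` the mean trajectory converges to the closed form
#' [gcsp_P()].
#'
#' @param alpha self-preference parameter, > 0.
#' @param N final node count (finite).
#' @param E_max number of edge-addition steps to evolve.
#' @param record_at integer vector of E values at which to keep the full
#'   distribution (default: none; the mean is always kept).
#' @param tol allowed deviation of total probability from 1.
#' @return object of class `master_evolution`: list with `E` (0:E_max),
#'   `mean_size` (E[n] at every E), `kappa` (2E/N), `states` (named list
#'   of kept distributions), `alpha`, `N`.
#' @export
master_evolve <- function(alpha, N, E_max, record_at = integer(), tol = 1e-12) {
  stopifnot(alpha > 0, N >= 2, E_max >= 0)
  N <- as.integer(N)
  E_max <- as.integer(E_max)
  nn <- seq_len(N)
  p <- numeric(N); p[1L] <- 1
  mean_size <- numeric(E_max + 1L); mean_size[1L] <- 1
  states <- list()
  if (0L %in% record_at) states[["0"]] <- p
  w_all <- nn * (N - nn) / alpha          # recruitment weight, fixed in E
  for (E in seq_len(E_max)) {
    spots <- pmax(nn * (nn - 1) / 2 - (E - 1L), 0)
    Tn <- ifelse(w_all == 0, 0, w_all / (spots + w_all))
    p <- p * (1 - Tn) + c(0, (p * Tn)[-N])
    s <- sum(p)
    if (abs(s - 1) > tol)
      stop("probability mass leakage at E = ", E, ": |1 - sum(p)| = ",
           format(abs(s - 1)))
    p <- p / s
    mean_size[E + 1L] <- sum(nn * p)
    if (E %in% record_at) states[[as.character(E)]] <- p
  }
  structure(list(E = 0:E_max, kappa = 2 * (0:E_max) / N,
                 mean_size = mean_size, states = states,
                 alpha = alpha, N = N),
            class = "master_evolution")
}

#' @export
print.master_evolution <- function(x, ...) {
  cat(sprintf(
    "master_evolution: N = %d, alpha = %.4g, E = 0..%d, final E[n]/N = %.4f\n",
    x$N, x$alpha, max(x$E), x$mean_size[length(x$mean_size)] / x$N))
  invisible(x)
}

#' Growth-rate right-hand side of the self-preference characteristic ODE
#'
#' The infinite-size limit of the master equation concentrates on a
#' deterministic trajectory \eqn{f(\kappa)} obeying
#' \deqn{f'(\kappa) = \frac{1 - f}{2 - (2 - \alpha) f},}
#' with f(0) = 0; [gcsp_P()] is its closed-form solution. Exposed so the
#' closed form can be validated against direct numerical integration.
#'
#' @param f current recruited fraction, 0 <= f < 1 (vectorised).
#' @param alpha self-preference parameter, > 0.
#' @return df/dkappa.
#' @export
ode_rhs <- function(f, alpha) {
  stopifnot(alpha > 0)
  if (any(f < 0 | f >= 1 + 1e-12)) stop("f must lie in [0, 1)")
  (1 - f) / (2 - (2 - alpha) * f)
}

#' Evaluate a theory curve on a mean-degree grid
#'
#' @param mean_degree numeric grid of mean degrees.
#' @param model `"gcsp"` or `"random"`.
#' @param alpha self-preference parameter (gcsp model only).
#' @return data frame with columns `kappa` and `P`, plus attribute `model`.
#' @export
theory_curve <- function(mean_degree, model = c("gcsp", "random"), alpha = NULL) {
  model <- match.arg(model)
  P <- if (model == "gcsp") {
    if (is.null(alpha)) stop("gcsp model requires `alpha`")
    gcsp_P(mean_degree, alpha)
  } else random_graph_P(mean_degree)
  structure(data.frame(kappa = mean_degree, P = P), model = model)
}

#' Write a theory curve as TSV
#' @param curve result of [theory_curve()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_theory_curve <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
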