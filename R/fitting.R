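# Normalise the many curve-like inputs (attack_curve, growth trajectory,
# plain data frame) to a data frame with columns mean_degree, giant_fraction.
as_curve_points <- function(curve) {
  if (inherits(curve, "attack_curve")) return(curve$points)
  if (is.data.frame(curve)) {
    nm <- names(curve)
    if (all(c("mean_degree", "giant_fraction") %in% nm)) return(curve)
    if (all(c("kappa", "rho") %in% nm))
      return(data.frame(mean_degree = curve$kappa, giant_fraction = curve$rho))
  }
  stop("`curve` must be an attack_curve or a data frame with columns ",
       "mean_degree/giant_fraction (or kappa/rho)")
}

#' Resample a P curve on an equidistant mean-degree grid
#'
#' Attack curves record one point per removal; for fitting they are
#' resampled on `n_points` equidistant mean degrees spanning \[0, k_max\].
#' The curve is a step function of mean degree: each grid point takes the
#' P value of the recorded step whose mean degree is the smallest recorded
#' value >= the grid point (no interpolation).
#'
#' @param curve an `attack_curve`, a growth trajectory, or a data frame
#'   with columns `mean_degree` and `giant_fraction` (or `kappa`, `rho`).
#' @param n_points number of grid points, >= 4.
#' @param k_max upper end of the grid; defaults to the curve's largest
#'   recorded mean degree (the intact network).
#' @return data frame with columns `mean_degree` (the grid) and
#'   `giant_fraction`.
#' @export
resample_curve <- function(curve, n_points = 20L, k_max = NULL) {
  pts <- as_curve_points(curve)
  if (nrow(pts) < 2L) stop("curve has fewer than 2 points")
  if (n_points < 4L) stop("n_points must be >= 4")
  o <- order(pts$mean_degree)
  k <- pts$mean_degree[o]
  P <- pts$giant_fraction[o]
  k_max <- k_max %||% k[length(k)]
  grid <- seq(0, k_max, length.out = n_points)
  # smallest recorded k >= grid value; beyond the range, take the top step
  idx <- length(k) - findInterval(-grid, rev(-k)) + 1L
  idx[idx > length(k)] <- length(k)
  idx[idx < 1L] <- 1L
  data.frame(mean_degree = grid, giant_fraction = P[idx])
}

#' Fit the self-preference parameter to a P curve
#'
#' Least-squares fit of the closed-form curve [gcsp_P()] to an empirical
#' attack curve: the curve is resampled on `n_points` equidistant mean
#' degrees ([resample_curve()]) and
#' \deqn{SSE(\alpha) = \sum_i (P_i - P_{gcsp}(\kappa_i, \alpha))^2}
#' is minimised over `bounds`. The objective is scanned on a coarse
#' alpha grid (step 0.05) — which makes no unimodality assumption — and
#' the best cell is then refined by golden-section search. Deterministic
#' given the curve and settings.
#'
#' @param curve an `attack_curve`, growth trajectory, or plain curve data
#'   frame (see [resample_curve()]).
#' @param n_points number of resampled points (default 20).
#' @param bounds numeric length-2 search interval for alpha.
#' @param property label recorded in the fit (defaults to the attack
#'   property when `curve` is an `attack_curve`, else `"simulated"`).
#' @return object of class `gcsp_fit`: list with `alpha_hat`, `sse`,
#'   `n_points`, `k_max`, `property`.
#' @examples
#' k <- seq(0, 60, length.out = 40)
#' fit <- fit_alpha(data.frame(mean_degree = k, giant_fraction = gcsp_P(k, 11)))
#' fit$alpha_hat
#' @export
fit_alpha <- function(curve, n_points = 20L, bounds = c(2.05, 60),
                      property = NULL) {
  stopifnot(length(bounds) == 2L, bounds[1L] > 0, bounds[2L] > bounds[1L])
  if (is.null(property))
    property <- if (inherits(curve, "attack_curve"))
      curve$ordering$property else "simulated"
  rs <- resample_curve(curve, n_points = n_points)
  kk <- rs$mean_degree
  PP <- rs$giant_fraction
  if (diff(range(PP)) < 1e-12)
    stop("degenerate curve: all P values equal; alpha is unidentifiable")
  sse <- function(a) sum((PP - gcsp_P(kk, a))^2)
  grid <- seq(bounds[1L], bounds[2L], by = 0.05)
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(sse, lower = lo, upper = hi, tol = 1e-8)
  structure(list(alpha_hat = opt$minimum, sse = opt$objective,
                 n_points = as.integer(n_points),
                 k_max = max(kk), property = property),
            class = "gcsp_fit")
}

#' @export
print.gcsp_fit <- function(x, ...) {
  cat(sprintf("gcsp_fit (%s): alpha_hat = %.3f, sse = %.3g (%d points, k_max %.4g)\n",
              x$property, x$alpha_hat, x$sse, x$n_points, x$k_max))
  invisible(x)
}

#' Spearman rank correlation with p-value
#'
#' Thin wrapper around [stats::cor.test()] (method `"spearman"`, ranks
#' tie-corrected, asymptotic t approximation for the p-value) used for
#' covariate-versus-alpha cohort summaries.
#'
#' @param values_a,values_b numeric vectors of equal length >= 3.
#' @return list with `rho` in \[-1, 1\] and `p_value`.
#' @export
rank_correlation <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("inputs must have equal length")
  if (length(values_a) < 3L) stop("need at least 3 observations")
  if (diff(range(values_a)) == 0 || diff(range(values_b)) == 0)
    stop("constant input vector: rank correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(values_a, values_b, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
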