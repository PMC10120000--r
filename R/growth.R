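# Shared topology engine: grow a single cluster from one node under
# giant-cluster self preference. At each of E_max steps one edge is added;
# it either recruits a new node (probability given by
# transition_probability) attached to a uniformly chosen cluster node, or
# fills a uniformly chosen open pair inside the cluster (rejection
# sampling over pairs; acceptance stays high at brain-like densities).
# Returns endpoints in creation order plus the cluster size after each
# step. Nodes are indexed in recruitment order.
grow_gcsp_topology <- function(N, alpha, E_max) {
  N <- as.integer(N)
  E_max <- as.integer(E_max)
  if (E_max > N * (N - 1) / 2)
    stop("requested edge count exceeds the complete graph on N nodes")
  eu <- integer(E_max); ev <- integer(E_max)
  n_after <- integer(E_max)
  present <- logical(N * N)   # (a-1)*N + b, a < b
  n <- 1L
  for (i in seq_len(E_max)) {
    p_branch <- transition_probability(n, i - 1L, alpha, N)
    if (n < N && stats::runif(1) < p_branch) {
      u <- sample.int(n, 1L)
      n <- n + 1L
      v <- n
    } else {
      repeat {
        u <- sample.int(n, 1L)
        v <- sample.int(n, 1L)
        if (u != v && !present[(min(u, v) - 1L) * N + max(u, v)]) break
      }
    }
    a <- min(u, v); b <- max(u, v)
    present[(a - 1L) * N + b] <- TRUE
    eu[i] <- a; ev[i] <- b
    n_after[i] <- n
  }
  list(eu = eu, ev = ev, n_after = n_after, N = N)
}

#' Grow a network under Giant Cluster Self Preference
#'
#' Stochastic finite-size realisation of the self-preference growth
#' process: starting from a single node, each step adds one edge that
#' either recruits a new node or reinforces the existing cluster (see
#' [transition_probability()]). The network is a single connected cluster
#' at every step — secondary clusters cannot arise by construction. The
#' recorded growth trajectory \eqn{(\kappa, \rho) = (2E/N, n/N)} uses the
#' final node count N in both denominators; over many seeds its mean
#' converges to the closed form [gcsp_P()].
#'
#' @param alpha self-preference parameter, > 0.
#' @param N final node count, >= 2.
#' @param k_final target final mean degree; `N * k_final / 2` edges are
#'   added (must not exceed the complete graph).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return list with `edges` (two-column integer matrix in creation
#'   order), `N`, `alpha`, and `trajectory` (data frame `kappa`, `rho`).
#' @export
simulate_gcsp_growth <- function(alpha, N = 727L, k_final = 100, seed = NULL) {
  E_max <- as.integer(round(N * k_final / 2))
  top <- with_seed_(seed, grow_gcsp_topology(N, alpha, E_max))
  traj <- data.frame(kappa = 2 * seq_len(E_max) / N,
                     rho = top$n_after / N)
  list(edges = cbind(from = top$eu, to = top$ev), N = as.integer(N),
       alpha = alpha, trajectory = traj)
}

#' Simulate the Early Path Dominance model
#'
#' Grows a spatially embedded connectome under giant-cluster self
#' preference while the tissue itself grows, so that the earliest edges
#' end up longest and densest:
#' \itemize{
#'   \item nodes originate uniformly inside the unit ball at the moment
#'     they are recruited;
#'   \item after every edge addition all existing coordinates are
#'     multiplied by `coord_scale`, so early edges lengthen;
#'   \item every edge starts with tract density 1 and is multiplied by
#'     `density_scale` at each subsequent edge addition, so early edges
#'     densify (the i-th created edge ends at `density_scale^(E - i)`).
#' }
#' Edge tract lengths are Euclidean distances between the final (fully
#' inflated) coordinates. Inflation is applied lazily as one global
#' factor per node-creation epoch, identical to step-by-step
#' multiplication to within 1e-9. The defaults are the reference
#' parameter set: 727 nodes (Talairach parcellation count), alpha = 11,
#' growth to mean degree 100 (which makes the final network fully
#' connected, P = 1), inflation factors 1.0001 (coordinates) and 1.001
#' (density) per added edge.
#'
#' @param N final node count.
#' @param alpha self-preference parameter.
#' @param k_final final mean degree.
#' @param coord_scale per-step coordinate inflation factor.
#' @param density_scale per-step density multiplication factor.
#' @param seed optional integer seed; caller's RNG state is restored.
#' @return list with `connectome` (the recruited nodes — labels `n0001`...
#'   in recruitment order — with final coordinates and per-edge
#'   tract_length and tract_density; a label that was never recruited by
#'   the end of growth formed zero edges and is not part of the network,
#'   so the final network is always a single cluster with P = 1),
#'   `trajectory` (data frame `kappa`, `rho`), `creation_order` (edge
#'   indices in creation order; edges are stored in creation order so
#'   this is `1:E`), and `config`.
#' @examples
#' sim <- simulate_epd(N = 60, k_final = 10, seed = 1)
#' giant_fraction(sim$connectome)
#' @export
simulate_epd <- function(N = 727L, alpha = 11, k_final = 100,
                         coord_scale = 1.0001, density_scale = 1.001,
                         seed = NULL) {
  E_max <- as.integer(round(N * k_final / 2))
  sim <- with_seed_(seed, {
    top <- grow_gcsp_topology(N, alpha, E_max)
    coords0 <- runif_ball(N)   # drawn lazily in recruitment order
    list(top = top, coords0 = coords0)
  })
  top <- sim$top
  # birth step of node j: the step whose addition recruited it. A node is
  # not inflated by its own birth step (fresh unit-ball draw), so its
  # final scale factor is coord_scale^(E - birth). The seed node exists
  # before any edge and collects all E inflation steps.
  birth <- integer(N)
  birth[1L] <- 0L
  prev_n <- 1L
  for (i in seq_len(E_max)) {
    if (top$n_after[i] > prev_n) {
      birth[top$n_after[i]] <- i
      prev_n <- top$n_after[i]
    }
  }
  # Only recruited nodes exist in the final network. Growth occasionally
  # ends with a label never recruited (the branching probability decays
  # once the cluster nears full size); such a region formed zero edges
  # and is excluded, which is what keeps P = 1 with all edges present.
  n_final <- top$n_after[E_max]
  coords <- sim$coords0[seq_len(n_final), , drop = FALSE] *
    coord_scale^(E_max - birth[seq_len(n_final)])
  dl <- coords[top$eu, , drop = FALSE] - coords[top$ev, , drop = FALSE]
  tract_length <- sqrt(rowSums(dl^2))
  tract_density <- density_scale^(E_max - seq_len(E_max))
  labels <- sprintf("n%04d", seq_len(n_final))
  ed <- data.frame(node_u = labels[top$eu], node_v = labels[top$ev],
                   tract_length = tract_length,
                   tract_density = tract_density)
  con <- connectome(ed, nodes = labels, coords = coords)
  list(connectome = con,
       trajectory = data.frame(kappa = 2 * seq_len(E_max) / N,
                               rho = top$n_after / N),
       creation_order = seq_len(E_max),
       config = list(N = as.integer(N), alpha = alpha, k_final = k_final,
                     coord_scale = coord_scale, density_scale = density_scale,
                     seed = seed))
}

#' Erdos-Renyi G(N, M) random graph
#'
#' Uniform simple graph with exactly `M` edges (igraph's `sample_gnm`).
#'
#' @param N node count.
#' @param M edge count, <= N(N-1)/2.
#' @param seed optional integer seed; caller's RNG state is restored.
#' @return an `igraph` graph.
#' @export
erdos_renyi_gnm <- function(N, M, seed = NULL) {
  if (M > N * (N - 1) / 2) stop("M exceeds the complete graph on N nodes")
  with_seed_(seed, igraph::sample_gnm(N, M, directed = FALSE))
}

#' Preferential-attachment growth (linear and nonlinear)
#'
#' Each arriving node attaches `m` edges to existing nodes with
#' probability proportional to degree^`exponent` (igraph's `sample_pa`;
#' `exponent = 1` is the scale-free Barabasi-Albert model, `exponent = 0`
#' uniform attachment). The growth trajectory is reconstructed from the
#' creation-ordered edge list: after edge i the network holds the nodes
#' seen so far.
#'
#' @param N final node count.
#' @param m edges added per arriving node, >= 1.
#' @param exponent attachment kernel power, >= 0.
#' @param seed optional integer seed; caller's RNG state is restored.
#' @return list with `graph` (igraph), `trajectory` (data frame `kappa`,
#'   `rho`, one row per edge addition).
#' @export
preferential_attachment <- function(N, m = 1L, exponent = 1, seed = NULL) {
  stopifnot(m >= 1L, m < N, exponent >= 0)
  g <- with_seed_(seed,
    igraph::sample_pa(N, power = exponent, m = m, directed = FALSE))
  el <- igraph::as_edgelist(g, names = FALSE)
  n_seen <- cummax(pmax(el[, 1L], el[, 2L]))
  traj <- data.frame(kappa = 2 * seq_len(nrow(el)) / N, rho = n_seen / N)
  list(graph = g, trajectory = traj)
}

#' Watts-Strogatz small-world connectome
#'
#' Ring lattice of `N` nodes each joined to its `k_ring` nearest
#' neighbours, with each edge rewired with probability `p_rewire`
#' (igraph's `sample_smallworld`, simplified to remove any multi-edges).
#' Nodes sit at equal angles on the unit circle; each edge's
#' `tract_length` is the chord distance between its endpoints, so
#' distance-targeted attack is meaningful. All densities are 1.
#'
#' @param N node count.
#' @param k_ring even neighbourhood size, < N.
#' @param p_rewire rewiring probability in \[0, 1\].
#' @param seed optional integer seed; caller's RNG state is restored.
#' @return a `connectome` with 3-d coordinates on the unit circle (z = 0).
#' @export
watts_strogatz <- function(N, k_ring, p_rewire, seed = NULL) {
  if (k_ring %% 2L != 0L || k_ring >= N || k_ring < 2L)
    stop("k_ring must be even, >= 2 and < N")
  if (p_rewire < 0 || p_rewire > 1) stop("p_rewire must be in [0, 1]")
  g <- with_seed_(seed,
    igraph::sample_smallworld(1L, N, k_ring / 2L, p_rewire))
  g <- igraph::simplify(g)
  theta <- 2 * pi * (seq_len(N) - 1L) / N
  coords <- cbind(cos(theta), sin(theta), 0)
  el <- igraph::as_edgelist(g, names = FALSE)
  d <- sqrt(rowSums((coords[el[, 1L], , drop = FALSE] -
                     coords[el[, 2L], , drop = FALSE])^2))
  labels <- sprintf("n%04d", seq_len(N))
  connectome(data.frame(node_u = labels[el[, 1L]], node_v = labels[el[, 2L]],
                        tract_length = d, tract_density = 1),
             nodes = labels, coords = coords)
}

#' Spatially embedded random connectome
#'
#' `N` nodes placed uniformly in the unit ball; `M` distinct node pairs
#' chosen uniformly at random; each edge's `tract_length` is the
#' Euclidean distance between its endpoints (all densities 1). A null
#' model for distance-targeted attack with realistic edge-length
#' geometry but no growth structure.
#'
#' @param N node count.
#' @param M edge count, <= N(N-1)/2.
#' @param seed optional integer seed; caller's RNG state is restored.
#' @return a `connectome` with 3-d coordinates.
#' @export
spatial_random <- function(N, M, seed = NULL) {
  npairs <- N * (N - 1) / 2
  if (M > npairs) stop("M exceeds the complete graph on N nodes")
  sim <- with_seed_(seed, {
    list(coords = runif_ball(N), pick = sample.int(npairs, M))
  })
  # linear index over pairs (u < v), column-major in v
  v <- ceiling((1 + sqrt(1 + 8 * sim$pick)) / 2)
  u <- sim$pick - (v - 1) * (v - 2) / 2
  d <- sqrt(rowSums((sim$coords[u, , drop = FALSE] -
                     sim$coords[v, , drop = FALSE])^2))
  labels <- sprintf("n%04d", seq_len(N))
  connectome(data.frame(node_u = labels[u], node_v = labels[v],
                        tract_length = d, tract_density = 1),
             nodes = labels, coords = sim$coords)
}

#' Average clustering coefficient and shortest path length
#'
#' Standard unweighted small-world summary: the mean over nodes of the
#' local clustering coefficient (degree-0/1 nodes contribute 0) and the
#' mean shortest-path length over reachable pairs. On a disconnected
#' graph the path length is computed on the giant cluster and flagged.
#'
#' @param graph an `igraph` graph or a `connectome`.
#' @return list with `mean_clustering`, `mean_shortest_path`, and
#'   `on_giant_cluster` (TRUE when the path length had to be restricted).
#' @export
clustering_and_pathlength <- function(graph) {
  g <- if (inherits(graph, "connectome")) as.igraph.connectome(graph) else graph
  cc <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  comp <- igraph::components(g)
  restricted <- comp$no > 1L
  if (restricted) {
    giant <- which.max(comp$csize)
    g <- igraph::induced_subgraph(g, which(comp$membership == giant))
  }
  list(mean_clustering = cc,
       mean_shortest_path = igraph::mean_distance(g, directed = FALSE),
       on_giant_cluster = restricted)
}
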