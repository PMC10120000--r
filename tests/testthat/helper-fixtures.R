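# Four-region toy connectome: node c starts with degree 2, and
# increasing-length attack walks P through 1, 1, 3/4, 2/4, 1/4.
fixture_f4 <- function() {
  connectome(data.frame(
    node_u = c("a", "b", "a", "b"),
    node_v = c("c", "c", "b", "d"),
    tract_length = c(1, 2, 3, 4),
    tract_density = c(2, 1, 3, 1)))
}

# Forward brute-force attack oracle: rebuild the residual graph after
# every removal and recompute components from scratch with igraph.
# Defines the semantics the union-find implementation must reproduce.
brute_force_curve <- function(con, removal_order) {
  N <- length(con$nodes)
  E <- nrow(con$edges)
  rows <- lapply(0:E, function(step) {
    keep <- if (step < E) removal_order[(step + 1):E] else integer()
    g <- igraph::make_empty_graph(n = N, directed = FALSE)
    if (length(keep))
      g <- igraph::add_edges(g, rbind(con$edges$from[keep], con$edges$to[keep]))
    cs <- sort(igraph::components(g)$csize, decreasing = TRUE)
    data.frame(step = step, mean_degree = 2 * (E - step) / N,
               giant_fraction = cs[1] / N,
               n_secondary = sum(cs[-1] > 1))
  })
  do.call(rbind, rows)
}

# Largest P drop within any mean-degree window of width `w`: large for
# curves with a percolation-like collapse, small for gradual curves.
max_drop_in_window <- function(pts, w = 0.5) {
  k <- pts$mean_degree
  P <- pts$giant_fraction
  mx <- 0
  for (i in seq_along(k)) {
    j <- which(k >= k[i] & k <= k[i] + w)
    mx <- max(mx, max(P[j]) - P[i])
  }
  mx
}

# Largest absolute residual between a curve and its fitted theory curve,
# measured on a dense resampling grid.
max_fit_residual <- function(curve, fit, n_points = 60) {
  rs <- resample_curve(curve, n_points)
  max(abs(rs$giant_fraction - gcsp_P(rs$mean_degree, fit$alpha_hat)))
}
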