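test_that("self-preference growth keeps a single cluster from the first step", {
  sim <- simulate_gcsp_growth(11, N = 200, k_final = 30, seed = 1)
  expect_equal(sim$edges[1, ], c(from = 1L, to = 2L))   # first edge must branch
  tr <- sim$trajectory
  expect_equal(tr$kappa, 2 * seq_len(nrow(tr)) / 200)
  n_after <- round(tr$rho * 200)
  expect_true(all(diff(n_after) %in% c(0L, 1L)))
  # replaying creation in reverse (newest edge removed first) is an
  # attack that never leaves a secondary cluster: one cluster throughout
  E <- nrow(sim$edges)
  con <- connectome(data.frame(node_u = paste0("n", sim$edges[, 1]),
                               node_v = paste0("n", sim$edges[, 2]),
                               tract_length = 1,
                               tract_density = E + 1 - seq_len(E)))
  atk <- targeted_attack(con, edge_ordering("tract_density", "increasing"))
  expect_true(all(atk$points$n_secondary == 0))
  expect_error(simulate_gcsp_growth(11, N = 10, k_final = 20), "complete graph")
})

test_that("mean growth trajectory approaches the closed form as N grows", {
  mean_dev <- vapply(c(60, 240), function(N) {
    devs <- vapply(1:12, function(s) {
      tr <- simulate_gcsp_growth(11, N, k_final = 30, seed = 100 + s)$trajectory
      mean(abs(tr$rho - gcsp_P(tr$kappa, 11)))
    }, numeric(1))
    mean(devs)
  }, numeric(1))
  expect_lt(mean_dev[2], mean_dev[1])
  expect_lt(mean_dev[2], 0.05)
})

test_that("growth-in-a-growing-brain weights follow the stated update rules", {
  sim <- simulate_epd(N = 80, k_final = 12, seed = 3)
  con <- sim$connectome
  E <- nrow(con$edges)
  # i-th created edge is multiplied by the density factor E - i times
  expect_equal(con$edges$tract_density, 1.001^(E - seq_len(E)))
  # generators are reproducible given the seed
  sim2 <- simulate_epd(N = 80, k_final = 12, seed = 3)
  expect_identical(sim2$connectome$edges, con$edges)
  expect_identical(sim2$connectome$coords, con$coords)
})

test_that("lazy coordinate inflation equals step-by-step multiplication", {
  scale <- 1.01   # exaggerated so drift would be visible
  sim <- simulate_epd(N = 25, k_final = 6, seed = 9, coord_scale = scale)
  E <- nrow(sim$connectome$edges)
  # naive replay: recover birth steps from the trajectory, then multiply
  # every existing node's coordinate after each edge addition
  rho <- round(sim$trajectory$rho * 25)
  birth <- c(0, vapply(2:max(rho), function(j) which(rho >= j)[1], numeric(1)))
  final0 <- sim$connectome$coords / scale^(E - birth[seq_len(nrow(sim$connectome$coords))])
  naive <- final0
  for (step in seq_len(E)) {
    alive <- which(birth < step)
    naive[alive, ] <- naive[alive, ] * scale
  }
  expect_equal(naive, sim$connectome$coords, tolerance = 1e-9)
})

test_that("density attack on a grown connectome replays growth in reverse", {
  # general case: the attack normalises by the recruited node count
  sim <- simulate_epd(N = 50, k_final = 8, seed = 6)
  con <- sim$connectome
  nfin <- length(con$nodes)
  atk <- targeted_attack(con, edge_ordering("tract_density", "increasing"))
  E <- nrow(con$edges)
  n_after <- round(sim$trajectory$rho * 50)   # cluster size after each edge
  # attack step i (0-based) corresponds to creation step E - i
  expect_equal(atk$points$giant_fraction[1:E], rev(n_after) / nfin)
  expect_equal(atk$points$mean_degree[1:E], 2 * rev(seq_len(E)) / nfin)
  expect_true(all(atk$points$n_secondary == 0))

  # fully recruited case: attack curve and trajectory coincide exactly
  sim2 <- simulate_epd(N = 50, k_final = 20, seed = 8)
  expect_equal(length(sim2$connectome$nodes), 50L)
  atk2 <- targeted_attack(sim2$connectome,
                          edge_ordering("tract_density", "increasing"))
  E2 <- nrow(sim2$connectome$edges)
  expect_equal(atk2$points$giant_fraction[1:E2], rev(sim2$trajectory$rho))
  expect_equal(atk2$points$mean_degree[1:E2], rev(sim2$trajectory$kappa))
})

test_that("length attack approximately replays growth; density replays it exactly", {
  sim <- simulate_epd(N = 300, k_final = 60, seed = 3)
  ad <- targeted_attack(sim$connectome, edge_ordering("tract_density", "increasing"))
  al <- targeted_attack(sim$connectome, edge_ordering("tract_length", "increasing"))
  rd <- resample_curve(ad, 40)
  rl <- resample_curve(al, 40)
  expect_lt(mean(abs(rd$giant_fraction - rl$giant_fraction)), 0.05)
})

test_that("G(N, M) sampler hits exact edge counts and the complete graph", {
  g <- erdos_renyi_gnm(4, 6, seed = 1)
  expect_equal(igraph::ecount(g), 6)
  expect_true(all(igraph::degree(g) == 3))
  expect_error(erdos_renyi_gnm(4, 7), "complete graph")
})

test_that("preferential attachment builds trees at m = 1 and the 1/(2m) growth slope", {
  pa1 <- preferential_attachment(200, m = 1, seed = 1)
  expect_equal(igraph::ecount(pa1$graph), 199)
  expect_true(igraph::is_connected(pa1$graph))
  pa0 <- preferential_attachment(200, m = 1, exponent = 0, seed = 1)
  expect_equal(igraph::ecount(pa0$graph), 199)

  pa <- preferential_attachment(500, m = 3, seed = 1)
  tr <- pa$trajectory
  n <- nrow(tr)
  slope <- stats::coef(stats::lm(rho ~ kappa, tr[(n %/% 5):n, ]))[["kappa"]]
  expect_equal(slope, 1 / 6, tolerance = 1e-3)
  expect_error(preferential_attachment(10, m = 10), "m")
})

test_that("ring-lattice rewiring matches known clustering limits", {
  ws0 <- watts_strogatz(400, 6, 0, seed = 1)
  cp <- clustering_and_pathlength(ws0)
  expect_equal(cp$mean_clustering, 3 * (6 - 2) / (4 * (6 - 1)))  # 0.6
  ws1 <- watts_strogatz(2000, 8, 1, seed = 1)
  expect_lt(clustering_and_pathlength(ws1)$mean_clustering, 0.02)
  expect_error(watts_strogatz(10, 5, 0), "even")
})

test_that("lattice distance attack collapses abruptly, unlike self-preference growth", {
  ws0 <- watts_strogatz(400, 6, 0, seed = 1)
  aw <- targeted_attack(ws0, edge_ordering("tract_length", "increasing", tie_seed = 7))
  expect_gt(max_drop_in_window(aw$points, w = 0.5), 0.5)
  tr <- simulate_gcsp_growth(11, 400, 6, seed = 1)$trajectory
  gcurve <- data.frame(mean_degree = rev(tr$kappa), giant_fraction = rev(tr$rho))
  expect_lt(max_drop_in_window(gcurve, w = 0.5), 0.3)
})

test_that("spatial random graphs live in the unit ball and mismatch the theory", {
  sp <- spatial_random(100, 300, seed = 1)
  expect_true(all(sp$edges$tract_length <= 2))
  expect_true(all(sqrt(rowSums(sp$coords^2)) <= 1))
  expect_equal(nrow(sp$edges), 300L)
  full <- spatial_random(12, 66, seed = 1)
  expect_true(all(degrees(full) == 11L))
  expect_error(spatial_random(10, 50), "complete graph")

  # distance attack has a transition the one-parameter curve cannot track
  sp2 <- spatial_random(300, 3000, seed = 2)
  asp <- targeted_attack(sp2, edge_ordering("tract_length", "increasing"))
  fsp <- fit_alpha(asp)
  expect_gt(max_fit_residual(asp, fsp), 0.06)
  sim <- simulate_epd(N = 300, k_final = 60, seed = 3)
  ad <- targeted_attack(sim$connectome, edge_ordering("tract_density", "increasing"))
  expect_lt(max_fit_residual(ad, fit_alpha(ad)), 0.05)
})

test_that("clustering and path length summaries match hand-computable graphs", {
  tri <- connectome(data.frame(node_u = c("a", "b", "c"),
                               node_v = c("b", "c", "a"),
                               tract_length = 1, tract_density = 1))
  cp <- clustering_and_pathlength(tri)
  expect_equal(cp$mean_clustering, 1)
  expect_equal(cp$mean_shortest_path, 1)
  star <- connectome(data.frame(node_u = "h", node_v = c("a", "b", "c", "d"),
                                tract_length = 1, tract_density = 1))
  cps <- clustering_and_pathlength(star)
  expect_equal(cps$mean_clustering, 0)
  expect_equal(cps$mean_shortest_path, 1.6)
  # disconnected input: path length restricted to the giant cluster, flagged
  g <- igraph::graph_from_edgelist(rbind(c(1, 2), c(2, 3), c(4, 5)),
                                   directed = FALSE)
  cpd <- clustering_and_pathlength(g)
  expect_true(cpd$on_giant_cluster)
  expect_equal(cpd$mean_shortest_path, 4 / 3)
})
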