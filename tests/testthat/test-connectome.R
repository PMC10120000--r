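test_that("edge-list parsing builds the expected graph", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node_u\tnode_v\ttract_length\ttract_density",
               "a\tb\t10.0\t2", "b\tc\t5.0\t1", "c\td\t7.5\t4"), p)
  con <- read_connectome(p, "edge_list")
  s <- summary(con)
  expect_equal(s$N, 4L)
  expect_equal(s$E, 3L)
  expect_equal(con$nodes, c("a", "b", "c", "d"))
  expect_equal(con$edges$tract_length, c(10, 5, 7.5))
})

test_that("matrix-pair dialect reads the upper triangle, zeros mean no edge", {
  labels <- c("r1", "r2", "r3", "r4")
  len <- den <- matrix(0, 4, 4, dimnames = list(labels, labels))
  set_edge <- function(m, i, j, v) { m[i, j] <- v; m[j, i] <- v; m }
  len <- set_edge(len, 1, 2, 10); den <- set_edge(den, 1, 2, 2)
  len <- set_edge(len, 1, 3, 4);  den <- set_edge(den, 1, 3, 1)
  len <- set_edge(len, 2, 4, 7);  den <- set_edge(den, 2, 4, 5)
  len <- set_edge(len, 3, 4, 2);  den <- set_edge(den, 3, 4, 1)
  pl <- withr::local_tempfile(fileext = ".csv")
  pd <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(len, pl); utils::write.csv(den, pd)
  con <- read_connectome(c(pl, pd), "matrix_pair")
  expect_equal(summary(con)$E, 4L)
  expect_equal(con$nodes, labels)

  # asymmetric density -> dialect error
  den2 <- den; den2[2, 1] <- 0
  utils::write.csv(den2, pd)
  expect_error(read_connectome(c(pl, pd), "matrix_pair"), "not symmetric")
})

test_that("validation rejects bad weights, duplicates and self-loops", {
  base <- data.frame(node_u = "a", node_v = "b",
                     tract_length = 1, tract_density = 1)
  expect_error(connectome(transform(base, tract_length = -1)), "positive")
  expect_error(connectome(transform(base, tract_density = 0.5)), ">= 1")
  expect_error(connectome(transform(base, node_v = "a")), "self-loop")
  dup <- rbind(base, data.frame(node_u = "b", node_v = "a",
                                tract_length = 2, tract_density = 1))
  expect_error(connectome(dup), "duplicate")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_connectome(connectome(base), p)
  txt <- readLines(p)
  writeLines(c(txt, txt[2]), p)
  expect_error(read_connectome(p), "duplicate")
})

test_that("write/read round-trips nodes, edges and weights exactly", {
  sim <- simulate_epd(N = 120, k_final = 16, seed = 11)
  con <- sim$connectome
  p <- withr::local_tempfile(fileext = ".tsv")
  write_connectome(con, p, "edge_list")
  back <- read_connectome(p, "edge_list")
  expect_identical(back$nodes, con$nodes)
  expect_identical(back$edges[c("from", "to")], con$edges[c("from", "to")])
  expect_equal(back$edges$tract_length, con$edges$tract_length,
               tolerance = 1e-12)
  expect_equal(back$edges$tract_density, con$edges$tract_density,
               tolerance = 1e-12)

  # matrix_pair encoding of the same graph yields an equal connectome
  pl <- withr::local_tempfile(fileext = ".csv")
  pd <- withr::local_tempfile(fileext = ".csv")
  write_connectome(con, c(pl, pd), "matrix_pair")
  back2 <- read_connectome(c(pl, pd), "matrix_pair")
  reorder <- function(x) {
    o <- order(x$edges$from, x$edges$to)
    list(nodes = x$nodes, edges = x$edges[o, ])
  }
  a <- reorder(back2); b <- reorder(con)
  expect_identical(a$nodes, b$nodes)
  expect_equal(a$edges$tract_length, b$edges$tract_length, tolerance = 1e-12)
  expect_equal(a$edges$tract_density, b$edges$tract_density, tolerance = 1e-12)

  # empty-edge write is a header-only file (header survives a round trip)
  con0 <- con; con0$edges <- con$edges[0, ]
  p0 <- withr::local_tempfile(fileext = ".tsv")
  write_connectome(con0, p0, "edge_list")
  expect_equal(length(readLines(p0)), 1L)
})

test_that("pruning removes isolates, warns on fragments, and is idempotent", {
  ed <- data.frame(node_u = c("a", "b", "c"), node_v = c("b", "c", "d"),
                   tract_length = 1:3, tract_density = 1)
  con <- connectome(ed, nodes = c("a", "b", "c", "d", "e"))
  pr <- prune_isolates(con)
  expect_equal(pr$nodes, c("a", "b", "c", "d"))
  expect_identical(prune_isolates(pr), pr)

  # fully connected input is unchanged
  con2 <- connectome(ed)
  expect_identical(prune_isolates(con2), con2)

  # two disjoint triangles: kept, but flagged
  tri2 <- connectome(data.frame(
    node_u = c("a", "b", "c", "x", "y", "z"),
    node_v = c("b", "c", "a", "y", "z", "x"),
    tract_length = 1, tract_density = 1))
  expect_warning(pr2 <- prune_isolates(tri2), "not a single connected")
  expect_equal(summary(pr2)$N, 6L)
})

test_that("summary reports N, E and mean degree 2E/N", {
  tri <- connectome(data.frame(node_u = c("a", "b", "c"),
                               node_v = c("b", "c", "a"),
                               tract_length = 1, tract_density = 1))
  expect_equal(summary(tri), list(N = 3L, E = 3L, mean_degree = 2))
  star <- connectome(data.frame(node_u = "hub", node_v = c("a", "b", "c", "d"),
                                tract_length = 1, tract_density = 1))
  expect_equal(summary(star)$mean_degree, 8 / 5)
})
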