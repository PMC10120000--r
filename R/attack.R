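#' Specify how edges are ranked for a targeted attack
#'
#' The attack removes edges in rank order of a physical property. Ranks
#' are frozen before the attack starts: edge properties do not change
#' while edges are removed, so removing "the currently smallest" edge at
#' every step is equivalent to one static sort. Edges with exactly equal
#' property values have no defined order; within each tie group the order
#' is a uniform random shuffle driven by `tie_seed`, so tie handling is
#' explicit and reproducible rather than an accident of sort stability.
#'
#' @param property `"tract_length"`, `"tract_density"`, or
#'   `"external_rank"` (rank by a caller-supplied numeric vector).
#' @param direction `"increasing"` removes smallest first (the main
#'   analysis), `"decreasing"` largest first.
#' @param tie_seed integer seed for the tie-breaking shuffle.
#' @param values numeric vector of per-edge values, required when
#'   `property = "external_rank"` (one value per edge, in edge-table order).
#' @return an object of class `edge_ordering`.
#' @export
edge_ordering <- function(property = c("tract_length", "tract_density",
                                       "external_rank"),
                          direction = c("increasing", "decreasing"),
                          tie_seed = 1L, values = NULL) {
  property <- match.arg(property)
  direction <- match.arg(direction)
  if (property == "external_rank" && is.null(values))
    stop("external_rank ordering requires `values`")
  structure(list(property = property, direction = direction,
                 tie_seed = as.integer(tie_seed), values = values),
            class = "edge_ordering")
}

#' Rank the edges of a connectome for removal
#'
#' @param x a `connectome`.
#' @param ordering an [edge_ordering()].
#' @return integer permutation of `seq_len(nrow(x$edges))`: the removal
#'   order, deterministic for a fixed `tie_seed`.
#' @export
order_edges <- function(x, ordering) {
  stopifnot(inherits(ordering, "edge_ordering"))
  m <- nrow(x$edges)
  vals <- switch(ordering$property,
    tract_length  = x$edges$tract_length,
    tract_density = x$edges$tract_density,
    external_rank = as.numeric(ordering$values))
  if (length(vals) != m)
    stop("property values missing for some edges (expected ", m, " values)")
  if (any(!is.finite(vals)))
    stop("edge property contains non-finite values")
  tie_key <- with_seed_(ordering$tie_seed, sample.int(m))
  if (ordering$direction == "increasing") order(vals, tie_key)
  else order(-vals, tie_key)
}

#' Fraction of nodes in the giant cluster
#'
#' P is the probability that an arbitrary node lies in the largest
#' connected component: its size divided by the total node count. Under
#' an exact size tie any maximal component may be called "giant"; P is
#' unaffected.
#'
#' @param x a `connectome` or an `igraph` graph with at least one node.
#' @return P in (0, 1].
#' @export
giant_fraction <- function(x) {
  g <- if (inherits(x, "connectome")) as.igraph.connectome(x) else x
  n <- igraph::vcount(g)
  if (n < 1L) stop("giant_fraction needs at least one node")
  max(igraph::components(g)$csize) / n
}

#' Run a targeted edge-removal attack
#'
#' Edges are removed one at a time in the order given by `ordering`; after
#' every removal the giant-cluster fraction P and the number of secondary
#' clusters (non-giant components of size > 1) are recorded against the
#' current mean degree 2E/N. N is the (post-pruning) node count and is held
#' fixed for the whole curve, so P is comparable across steps.
#'
#' The curve is computed by adding edges in reverse removal order while
#' maintaining a disjoint-set forest, which is equivalent to recomputing
#' components after every forward removal but runs in near-linear time.
#' The forward recomputation remains the defining semantics (and the test
#' oracle).
#'
#' @param x a `connectome`, normally pruned with [prune_isolates()].
#' @param ordering an [edge_ordering()].
#' @return an object of class `attack_curve`: list with `points` (data
#'   frame `step`, `mean_degree`, `giant_fraction`, `n_secondary`, one row
#'   for the intact network and one per removal), `removal_order` (edge
#'   indices), `ordering`, and the attacked `connectome`.
#' @examples
#' ed <- data.frame(node_u = c("a","b","a","b"), node_v = c("c","c","b","d"),
#'                  tract_length = 1:4, tract_density = 1)
#' con <- connectome(ed)
#' atk <- targeted_attack(con, edge_ordering("tract_length", "increasing"))
#' atk$points$giant_fraction   # 1, 1, 3/4, 2/4, 1/4
#' @export
targeted_attack <- function(x, ordering = edge_ordering()) {
  stopifnot(inherits(x, "connectome"))
  N <- length(x$nodes)
  E <- nrow(x$edges)
  if (E == 0L) {
    pts <- data.frame(step = 0L, mean_degree = 0,
                      giant_fraction = 1 / N, n_secondary = 0L)
    return(structure(list(points = pts, removal_order = integer(),
                          ordering = ordering, connectome = x),
                     class = "attack_curve"))
  }
  ord <- order_edges(x, ordering)
  eu <- x$edges$from[ord]
  ev <- x$edges$to[ord]

  # reverse union-find: state after adding j edges (j = E - step)
  parent <- seq_len(N)
  sz <- rep(1L, N)
  gmax <- 1L          # giant size
  cnt2 <- 0L          # number of components of size > 1
  giant <- integer(E + 1L); giant[1L] <- 1L
  sec   <- integer(E + 1L); sec[1L]   <- 0L
  for (j in seq_len(E)) {
    i <- E - j + 1L   # edge removed at forward step i is added j-th
    ra <- eu[i]; rb <- ev[i]
    while (parent[ra] != ra) { parent[ra] <- parent[parent[ra]]; ra <- parent[ra] }
    while (parent[rb] != rb) { parent[rb] <- parent[parent[rb]]; rb <- parent[rb] }
    if (ra != rb) {
      if (sz[ra] < sz[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
      was2 <- (sz[ra] > 1L) + (sz[rb] > 1L)
      parent[rb] <- ra
      sz[ra] <- sz[ra] + sz[rb]
      cnt2 <- cnt2 - was2 + 1L
      if (sz[ra] > gmax) gmax <- sz[ra]
    }
    giant[j + 1L] <- gmax
    sec[j + 1L] <- cnt2 - (gmax > 1L)
  }

  steps <- 0:E
  pts <- data.frame(
    step = steps,
    mean_degree = 2 * (E - steps) / N,
    giant_fraction = giant[E - steps + 1L] / N,
    n_secondary = sec[E - steps + 1L]
  )
  structure(list(points = pts, removal_order = ord,
                 ordering = ordering, connectome = x),
            class = "attack_curve")
}

#' @export
print.attack_curve <- function(x, ...) {
  p <- x$points
  cat(sprintf("attack_curve: %d steps, <k> %.4g -> %.4g, P %.4g -> %.4g\n",
              nrow(p) - 1L, p$mean_degree[1L], p$mean_degree[nrow(p)],
              p$giant_fraction[1L], p$giant_fraction[nrow(p)]))
  invisible(x)
}

#' @export
as.data.frame.attack_curve <- function(x, ...) x$points

#' Census of secondary clusters at a given mean degree
#'
#' Secondary clusters are components other than the giant cluster with
#' more than one node. The census is taken at the recorded attack step
#' whose mean degree is closest to `at_mean_degree` from above, by
#' rebuilding the residual graph at that step.
#'
#' @param curve an `attack_curve`.
#' @param at_mean_degree target mean degree, within the curve's range.
#' @return list with `step`, `mean_degree`, `n_secondary`, and `sizes`
#'   (integer vector of secondary-cluster sizes, decreasing).
#' @export
secondary_cluster_census <- function(curve, at_mean_degree) {
  stopifnot(inherits(curve, "attack_curve"))
  k <- curve$points$mean_degree
  if (at_mean_degree > max(k) || at_mean_degree < min(k))
    stop("at_mean_degree outside the curve's range [",
         min(k), ", ", max(k), "]")
  step <- max(which(k >= at_mean_degree)) - 1L   # k is decreasing in step
  x <- curve$connectome
  E <- nrow(x$edges)
  keep <- if (step < E) curve$removal_order[(step + 1L):E] else integer()
  g <- igraph::make_empty_graph(n = length(x$nodes), directed = FALSE)
  if (length(keep))
    g <- igraph::add_edges(g, rbind(x$edges$from[keep], x$edges$to[keep]))
  cs <- sort(igraph::components(g)$csize, decreasing = TRUE)
  sizes <- cs[-1L][cs[-1L] > 1L]
  list(step = step, mean_degree = k[step + 1L],
       n_secondary = length(sizes), sizes = as.integer(sizes))
}

#' Write an attack curve to disk
#'
#' @param curve an `attack_curve`.
#' @param path destination file.
#' @param format `"tsv"` (step, mean_degree, giant_fraction, n_secondary)
#'   or `"json"`.
#' @return `path`, invisibly.
#' @export
write_attack_curve <- function(curve, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(curve$points, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(list(points = curve$points,
                              removal_order = curve$removal_order,
                              property = curve$ordering$property,
                              direction = curve$ordering$direction),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
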