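#' Construct a weighted connectome
#'
#' A connectome is an undirected simple graph whose nodes are gray-matter
#' regions and whose edges are white-matter connections carrying two
#' weights: `tract_length`, the average streamline length in millimetres,
#' and `tract_density`, the streamline count connecting the two regions.
#' Node labels are opaque strings; internally nodes get dense 0-based
#' indices in first-appearance order so that all downstream computations
#' are reproducible.
#'
#' @param edges data frame with columns `node_u`, `node_v`, `tract_length`,
#'   `tract_density` (one row per undirected edge).
#' @param nodes optional character vector of node labels. Labels appearing
#'   in `edges` but not listed here are appended in first-appearance order;
#'   listing extra labels creates isolated nodes.
#' @param coords optional numeric matrix (one row per node, 3 columns) of
#'   node coordinates, in mm or simulation units, ordered as `nodes`.
#' @return An object of class `connectome`: a list with elements `nodes`
#'   (character labels), `edges` (data frame `from`, `to`, `tract_length`,
#'   `tract_density` with integer endpoint indices, `from < to`) and
#'   `coords` (matrix or `NULL`).
#' @examples
#' ed <- data.frame(node_u = c("a", "b"), node_v = c("b", "c"),
#'                  tract_length = c(10, 5), tract_density = c(2, 1))
#' con <- connectome(ed)
#' summary(con)
#' @export
connectome <- function(edges, nodes = NULL, coords = NULL) {
  req <- c("node_u", "node_v", "tract_length", "tract_density")
  if (!all(req %in% names(edges)))
    stop("`edges` must have columns ", paste(req, collapse = ", "))
  u <- as.character(edges$node_u)
  v <- as.character(edges$node_v)
  labels <- unique(c(as.character(nodes %||% character()),
                     as.vector(rbind(u, v))))
  from <- match(u, labels)
  to   <- match(v, labels)
  ed <- data.frame(
    from = pmin(from, to), to = pmax(from, to),
    tract_length  = as.numeric(edges$tract_length),
    tract_density = as.numeric(edges$tract_density)
  )
  x <- structure(list(nodes = labels, edges = ed, coords = coords),
                 class = "connectome")
  validate_connectome(x)
}

validate_connectome <- function(x) {
  ed <- x$edges
  n  <- length(x$nodes)
  if (anyDuplicated(x$nodes))
    stop("duplicate node labels")
  if (nrow(ed)) {
    if (any(ed$from == ed$to))
      stop("self-loops are not allowed")
    if (anyDuplicated(ed[c("from", "to")]))
      stop("duplicate edges: each node pair may appear at most once")
    if (any(!is.finite(ed$tract_length)) || any(ed$tract_length <= 0))
      stop("every tract_length must be a positive finite number")
    if (any(!is.finite(ed$tract_density)) || any(ed$tract_density < 0))
      stop("tract_density must be non-negative and finite")
    if (any(ed$tract_density < 1))
      stop("tract_density must be >= 1 on every existing edge")
    if (any(ed$from < 1L) || any(ed$to > n))
      stop("edge endpoint out of range")
  }
  if (!is.null(x$coords)) {
    x$coords <- as.matrix(x$coords)
    if (nrow(x$coords) != n || ncol(x$coords) != 3L)
      stop("`coords` must be an n x 3 matrix matching the node set")
  }
  x
}

#' @export
print.connectome <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("connectome: %d nodes, %d edges, mean degree %.4g\n",
              s$N, s$E, s$mean_degree))
  if (!is.null(x$coords)) cat("  with 3-d node coordinates\n")
  invisible(x)
}

#' Summarize a connectome
#'
#' @param object a `connectome`.
#' @param ... unused.
#' @return list with `N` (nodes), `E` (edges) and `mean_degree` = 2E/N.
#' @export
summary.connectome <- function(object, ...) {
  N <- length(object$nodes)
  E <- nrow(object$edges)
  list(N = N, E = E, mean_degree = if (N > 0) 2 * E / N else NA_real_)
}

#' Node degrees of a connectome
#' @param x a `connectome`.
#' @return integer vector of degrees, ordered as `x$nodes`.
#' @export
degrees <- function(x) {
  tabulate(c(x$edges$from, x$edges$to), nbins = length(x$nodes))
}

#' Remove isolated nodes
#'
#' Zero-degree regions (typically regions for which tractography found no
#' streamlines) are dropped so that the giant-cluster fraction P equals 1
#' when all edges are present — provided the remaining graph is connected.
#' If it is not, the connectome is returned as-is (the attack is still
#' well defined) with a warning, since P = 1 cannot hold for it.
#' Idempotent.
#'
#' @param x a `connectome`.
#' @return a `connectome` without isolated nodes.
#' @export
prune_isolates <- function(x) {
  deg <- degrees(x)
  keep <- which(deg > 0L)
  if (length(keep) == 0L) stop("connectome has no edges; nothing to keep")
  if (length(keep) < length(x$nodes)) {
    idx <- match(seq_along(x$nodes), keep)
    ed <- x$edges
    ed$from <- idx[ed$from]
    ed$to   <- idx[ed$to]
    x <- structure(
      list(nodes = x$nodes[keep], edges = ed,
           coords = if (is.null(x$coords)) NULL else x$coords[keep, , drop = FALSE]),
      class = "connectome")
  }
  if (giant_fraction(x) < 1)
    warning("connectome is not a single connected component after pruning; ",
            "P < 1 with all edges present")
  x
}

#' Convert a connectome to an igraph graph
#'
#' Edge attributes `tract_length` and `tract_density` are carried over.
#' @param x a `connectome`.
#' @param ... unused.
#' @return an undirected `igraph` graph.
#' @exportS3Method igraph::as.igraph
as.igraph.connectome <- function(x, ...) {
  g <- igraph::make_empty_graph(n = length(x$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = x$nodes)
  if (nrow(x$edges)) {
    g <- igraph::add_edges(g, rbind(x$edges$from, x$edges$to))
    g <- igraph::set_edge_attr(g, "tract_length", value = x$edges$tract_length)
    g <- igraph::set_edge_attr(g, "tract_density", value = x$edges$tract_density)
  }
  g
}

#' Read a connectome from disk
#'
#' Two dialects are supported.
#' \describe{
#'   \item{`edge_list`}{A UTF-8 TSV with header
#'     `node_u  node_v  tract_length  tract_density`, one row per edge.
#'     Duplicate `(u,v)` / `(v,u)` rows are an error, never merged.}
#'   \item{`matrix_pair`}{Two square CSV matrices of identical shape with
#'     node labels as both header and row names: a tract-length matrix and
#'     a tract-density matrix (in that order in `path`). Matrices must be
#'     symmetric to 1e-9; only the upper triangle is read; a zero entry in
#'     the density matrix means "no edge".}
#' }
#'
#' @param path file path (`edge_list`) or a character vector of two paths,
#'   length matrix then density matrix (`matrix_pair`).
#' @param format `"edge_list"` or `"matrix_pair"`.
#' @return a validated `connectome`.
#' @export
read_connectome <- function(path, format = c("edge_list", "matrix_pair")) {
  format <- match.arg(format)
  if (format == "edge_list") {
    if (!file.exists(path)) stop("file not found: ", path)
    ed <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c("character", "character",
                                           "numeric", "numeric"),
                            quote = "", comment.char = "")
    key <- paste(pmin(ed$node_u, ed$node_v), pmax(ed$node_u, ed$node_v))
    if (anyDuplicated(key))
      stop("duplicate edge rows in edge list (merging is never implicit)")
    connectome(ed)
  } else {
    if (length(path) != 2L)
      stop("matrix_pair needs two paths: length matrix, density matrix")
    if (!all(file.exists(path))) stop("file not found: ",
                                      paste(path[!file.exists(path)], collapse = ", "))
    len <- read_square_matrix(path[1L])
    den <- read_square_matrix(path[2L])
    if (!identical(dim(len), dim(den)) ||
        !identical(rownames(len), rownames(den)))
      stop("length and density matrices must have identical shape and labels")
    check_symmetric(len, path[1L])
    check_symmetric(den, path[2L])
    ut <- which(upper.tri(den) & den != 0, arr.ind = TRUE)
    labels <- rownames(den)
    ed <- data.frame(node_u = labels[ut[, 1L]], node_v = labels[ut[, 2L]],
                     tract_length = len[ut], tract_density = den[ut])
    if (any(len[ut] == 0))
      stop("edge present in density matrix but tract length is zero")
    connectome(ed, nodes = labels)
  }
}

read_square_matrix <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1L, check.names = FALSE))
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix in ", path, " must carry node labels as header and row names")
  if (!identical(rownames(m), colnames(m)))
    stop("row and column labels disagree in ", path)
  storage.mode(m) <- "double"
  m
}

check_symmetric <- function(m, path, tol = 1e-9) {
  if (max(abs(m - t(m))) > tol)
    stop("matrix in ", path, " is not symmetric (tolerance 1e-9)")
  if (any(m < 0)) stop("negative weight in ", path)
  invisible(m)
}

#' Write a connectome to disk
#'
#' Inverse of [read_connectome()]: `read(write(x))` reproduces node set,
#' edge set and weights to 1e-12. The `graphml` format exports via igraph
#' with both weights as edge attributes (export only).
#'
#' @param x a `connectome`.
#' @param path destination path (`edge_list`, `graphml`) or two paths
#'   (`matrix_pair`: length matrix, density matrix).
#' @param format one of `"edge_list"`, `"matrix_pair"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(x, path,
                             format = c("edge_list", "matrix_pair", "graphml")) {
  format <- match.arg(format)
  if (format == "edge_list") {
    ed <- data.frame(node_u = x$nodes[x$edges$from],
                     node_v = x$nodes[x$edges$to],
                     tract_length = format(x$edges$tract_length, digits = 17),
                     tract_density = format(x$edges$tract_density, digits = 17))
    utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  } else if (format == "matrix_pair") {
    if (length(path) != 2L)
      stop("matrix_pair needs two paths: length matrix, density matrix")
    n <- length(x$nodes)
    len <- den <- matrix(0, n, n, dimnames = list(x$nodes, x$nodes))
    ij <- cbind(x$edges$from, x$edges$to)
    len[ij] <- x$edges$tract_length;  len[ij[, 2:1, drop = FALSE]] <- x$edges$tract_length
    den[ij] <- x$edges$tract_density; den[ij[, 2:1, drop = FALSE]] <- x$edges$tract_density
    utils::write.csv(format(len, digits = 17), path[1L], quote = FALSE)
    utils::write.csv(format(den, digits = 17), path[2L], quote = FALSE)
  } else {
    igraph::write_graph(as.igraph.connectome(x), path, format = "graphml")
  }
  invisible(path)
}
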