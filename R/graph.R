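#' Build the spot adjacency graph from centre distances
#'
#' Two spots are connected when their centre distance is at most `radius_px`.
#' The default radius is 1.05 pitch units, which on a regular honeycomb
#' lattice connects each interior spot to exactly its six nearest
#' neighbours (the radius used on real slides corresponds to just over one
#' spot pitch at the scanning magnification).
#'
#' @param grid a `spot_grid`, or any data frame with `px_x`/`px_y` columns.
#' @param radius_px connection radius in pixels; if `NULL`, 1.05 times the
#'   grid pitch (or, lacking a pitch attribute, 1.05 times the minimum
#'   pairwise distance).
#' @return A `spot_graph`: list with `spot_id`, `edges` (two-column integer
#'   matrix of undirected edges, `u < v`, no self loops), `radius_px`, `n`.
#' @export
build_spot_graph <- function(grid, radius_px = NULL) {
  n <- nrow(grid)
  xy <- cbind(grid$px_x, grid$px_y)
  if (is.null(radius_px)) {
    p <- attr(grid, "pitch_px")
    if (is.null(p)) {
      d <- stats::dist(xy)
      p <- min(d)
    }
    radius_px <- 1.05 * p
  }
  if (!is.numeric(radius_px) || radius_px <= 0)
    stop_invalid("'radius_px' must be positive")
  d <- pair_dist(xy)
  sel <- which(upper.tri(d) & d <= radius_px, arr.ind = TRUE)
  edges <- cbind(u = as.integer(sel[, 1]), v = as.integer(sel[, 2]))
  structure(
    list(spot_id = grid$spot_id, edges = edges, radius_px = radius_px, n = n),
    class = "spot_graph"
  )
}

#' Adjacency matrix of a spot graph
#'
#' @param graph a `spot_graph`.
#' @param row_normalize divide each row by its degree (rows of isolated
#'   spots stay zero).
#' @return A sparse `dgCMatrix`, symmetric when `row_normalize = FALSE`.
#' @export
graph_adjacency <- function(graph, row_normalize = FALSE) {
  n <- graph$n
  e <- graph$edges
  A <- Matrix::sparseMatrix(
    i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
    x = 1, dims = c(n, n)
  )
  if (row_normalize) {
    deg <- Matrix::rowSums(A)
    deg[deg == 0] <- 1
    A <- A / deg
  }
  methods::as(A, "CsparseMatrix")
}

## degrees of each node
graph_degree <- function(graph) {
  tabulate(c(graph$edges[, 1], graph$edges[, 2]), nbins = graph$n)
}

## mean of each node's neighbours (excluding self) for a vector or matrix
neighbor_mean <- function(graph, x) {
  A <- graph_adjacency(graph, row_normalize = TRUE)
  as.matrix(A %*% cbind(x))
}
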