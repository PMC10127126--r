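#' Extract square image patches centred on each Visium spot
#'
#' For spot `s` the patch spans pixels `[px_x - p/2, px_x + p/2)` by
#' `[px_y - p/2, px_y + p/2)` (0-based, centres rounded to whole pixels).
#' Pixels falling outside the image are filled by reflection, so corner
#' spots yield patches of the same size as interior spots without
#' introducing a constant-colour edge. Expression of other spots that happen
#' to fall inside the patch plays no role: each patch is labelled only by
#' its centre spot.
#'
#' @param bundle a `slide_bundle` with a non-`NULL` image.
#' @param patch_size_px even positive patch side length in pixels.
#' @return A `patch_set`: list with `x` (matrix, spots x `p*p*3`, each row a
#'   column-major flattened `p x p x 3` patch), `patch_size_px`, `spot_id`.
#' @export
extract_patches <- function(bundle, patch_size_px = 64) {
  p <- patch_size_px
  if (!is.numeric(p) || p <= 0 || p %% 2 != 0)
    stop_invalid("'patch_size_px' must be a positive even integer")
  img <- bundle$image
  if (is.null(img)) stop_invalid("bundle has no image")
  H <- dim(img)[1]; W <- dim(img)[2]
  if (p > H || p > W) stop_invalid("patch larger than image (%dx%d)", H, W)
  g <- bundle$grid
  n <- nrow(g)
  x <- matrix(0, n, p * p * 3)
  offs <- seq.int(-p / 2, p / 2 - 1L)
  for (s in seq_len(n)) {
    rows <- reflect_index(round(g$px_y[s]) + offs, H)
    cols <- reflect_index(round(g$px_x[s]) + offs, W)
    x[s, ] <- img[rows + 1L, cols + 1L, ]
  }
  structure(list(x = x, patch_size_px = p, spot_id = g$spot_id),
            class = "patch_set")
}

## reflect 0-based indices into [0, n-1] (mirror about the boundary pixels)
reflect_index <- function(q, n) {
  q <- abs(q)
  over <- q > n - 1L
  q[over] <- 2L * (n - 1L) - q[over]
  q
}

#' Rank genes by mean fraction of spatial variance across slides
#'
#' Genes are scored by the mean, across slides, of the fraction of spatial
#' variance (FSV) of their variance-stabilised expression, ranked in
#' descending order (ties broken lexicographically by gene id), and the top
#' `k` are returned. The default estimator is the package's smoothing-based
#' [estimate_fsv()]; any function with the same signature (for example one
#' wrapping externally computed values) can be substituted.
#'
#' @param slides list of `slide_bundle`s sharing the same genes.
#' @param k number of genes to return.
#' @param fsv_fn FSV estimator `function(values, coords, lengthscale_px)`.
#' @param lengthscale_px smoothing lengthscale; default one pitch.
#' @return Character vector of `k` gene ids, best first.
#' @export
select_genes <- function(slides, k, fsv_fn = estimate_fsv,
                         lengthscale_px = NULL) {
  if (k <= 0) stop_invalid("'k' must be positive")
  genes <- colnames(slides[[1]]$counts)
  if (k > length(genes)) stop_invalid("'k' exceeds the number of genes")
  for (b in slides)
    if (!identical(colnames(b$counts), genes))
      stop_invalid("slides do not share gene identifiers")
  fsv <- sapply(slides, function(b) {
    ls <- if (is.null(lengthscale_px)) grid_pitch(b$grid) else lengthscale_px
    coords <- cbind(b$grid$px_x, b$grid$px_y)
    v <- anscombe(b$counts)
    vapply(seq_along(genes), function(j) fsv_fn(v[, j], coords, ls), 0)
  })
  mean_fsv <- rowMeans(cbind(fsv))
  ord <- order(-mean_fsv, genes)
  genes[ord][seq_len(k)]
}

#' Dichotomize expression at the per-slide gene median
#'
#' A spot is labelled 1 for a gene iff its count is strictly greater than
#' that gene's median across the slide's spots; ties at the median fall in
#' the negative class. Genes that are constant on the slide get all-zero
#' labels and are flagged degenerate so downstream metrics can exclude them.
#'
#' @param counts spots x genes count matrix for one slide.
#' @return A `binary_targets`: list with `labels` (integer 0/1 matrix),
#'   `medians` (per gene), `degenerate` (logical per gene).
#' @export
dichotomize <- function(counts) {
  if (length(counts) == 0) stop_invalid("'counts' is empty")
  med <- apply(counts, 2, stats::median)
  labels <- sweep(counts, 2, med, ">") * 1L
  dimnames(labels) <- dimnames(counts)
  degenerate <- apply(counts, 2, function(v) max(v) == min(v))
  structure(list(labels = labels, medians = med, degenerate = degenerate),
            class = "binary_targets")
}
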