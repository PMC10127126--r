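## Spatial statistics: coverage filtering, variance stabilisation, lattice
## pooling, a permutation Moran's I test for spatially variable genes, a
## smoothing-based fraction-of-spatial-variance estimator, and spatial
## co-expression grouping. The Moran's I test and the smoothing FSV are
## deliberate stand-ins for the Gaussian-process machinery of dedicated SV
## tools: downstream code only consumes (statistic, p, FSV) triplets, and
## externally computed triplets can be substituted anywhere they are used.

#' Filter genes by slide coverage
#'
#' Retains a gene iff the fraction of spots with a non-zero count is at
#' least `min_fraction` (the boundary value is retained).
#'
#' @param counts spots x genes count matrix.
#' @param min_fraction minimum fraction of covered spots, in `(0, 1]`.
#' @return Character vector of retained gene names (or retained column
#'   indices when the matrix has no column names).
#' @export
coverage_filter <- function(counts, min_fraction = 0.30) {
  if (min_fraction <= 0 || min_fraction > 1)
    stop_invalid("'min_fraction' must lie in (0, 1]")
  frac <- colMeans(counts > 0)
  keep <- frac >= min_fraction
  if (is.null(colnames(counts))) which(keep) else colnames(counts)[keep]
}

#' Anscombe variance-stabilising transform
#'
#' `x -> 2 * sqrt(x + 3/8)`, mapping approximately negative-binomial counts
#' towards normality; strictly increasing.
#'
#' @param x non-negative counts (vector, matrix or array).
#' @return Transformed values, same shape.
#' @export
anscombe <- function(x) {
  if (any(x < 0)) stop_invalid("anscombe transform requires non-negative input")
  2 * sqrt(x + 3 / 8)
}

#' 2 x 2 median pooling on the spot lattice
#'
#' Spots are partitioned into blocks by integer-halved array indices
#' `(array_row %/% 2, array_col %/% 2)` (the closest well-defined analogue
#' of square 2 x 2 neighbourhoods on a hexagonal lattice); each block's
#' pooled value is the median of its members and its pooled coordinate the
#' mean of their pixel coordinates.
#'
#' @param grid a `spot_grid` (needs array indices).
#' @param values per-spot vector or spots x genes matrix.
#' @return List with `coords` (blocks x 2 matrix), `values` (pooled vector
#'   or matrix), `block` (block label per input spot).
#' @export
median_pool <- function(grid, values) {
  block <- paste(grid$array_row %/% 2L, grid$array_col %/% 2L, sep = "_")
  ub <- unique(block)
  bi <- match(block, ub)
  v <- cbind(values)
  pooled <- apply(v, 2, function(col)
    vapply(seq_along(ub), function(b) stats::median(col[bi == b]), 0))
  coords <- cbind(
    x = vapply(seq_along(ub), function(b) mean(grid$px_x[bi == b]), 0),
    y = vapply(seq_along(ub), function(b) mean(grid$px_y[bi == b]), 0))
  if (is.null(dim(values))) pooled <- as.vector(pooled)
  list(coords = coords, values = pooled, block = block)
}

## row-normalised neighbour weights from coordinates; radius defaults to
## 1.05 x the minimum pairwise distance (6-neighbour graph on a honeycomb)
sv_weights <- function(coords, radius = NULL) {
  d <- pair_dist(coords)
  diag(d) <- Inf
  if (is.null(radius)) radius <- 1.05 * min(d)
  W <- (d <= radius) * 1
  rs <- rowSums(W)
  rs[rs == 0] <- 1
  Matrix::Matrix(W / rs, sparse = TRUE)
}

#' Moran's I spatial autocorrelation statistic
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centred
#' values and `S0` the total weight.
#'
#' @param values per-spot values.
#' @param W spatial weight matrix (e.g. from centred coordinates via the
#'   row-normalised 6-neighbour graph).
#' @return Moran's I (scalar).
#' @export
morans_i <- function(values, W) {
  z <- values - mean(values)
  s0 <- sum(W)
  n <- length(z)
  (n / s0) * sum(z * as.vector(W %*% z)) / sum(z^2)
}

#' Permutation test for spatial variability (Moran's I)
#'
#' Tests for positive spatial autocorrelation of a gene's values over the
#' spot positions: the statistic is Moran's I under row-normalised weights
#' of the 6-neighbour spot graph, and the p-value is
#' `(1 + #{permuted I >= observed I}) / (n_perm + 1)` with values shuffled
#' over spots (one-sided: spatially variable means clustered, not
#' repulsive). Constant input yields a degenerate result with `p = 1`.
#'
#' @param values per-spot values (length >= 10).
#' @param coords spots x 2 coordinate matrix (ignored when `W` is given).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param radius neighbour radius (default 1.05 x minimum spacing).
#' @param W optional precomputed weight matrix (reuse across genes).
#' @return List: `statistic`, `p_value`, `n_perm`, `degenerate`.
#' @export
sv_test <- function(values, coords = NULL, n_perm = 999L, seed = 1L,
                    radius = NULL, W = NULL) {
  n <- length(values)
  if (n < 10) stop_invalid("need at least 10 spots")
  if (stats::sd(values) == 0)
    return(list(statistic = NA_real_, p_value = 1, n_perm = n_perm,
                degenerate = TRUE))
  if (is.null(W)) W <- sv_weights(coords, radius)
  z <- values - mean(values)
  s0 <- sum(W)
  denom <- sum(z^2)
  i_obs <- (n / s0) * sum(z * as.vector(W %*% z)) / denom
  i_perm <- with_seed(seed, {
    P <- matrix(0, n, n_perm)
    for (b in seq_len(n_perm)) P[, b] <- z[sample.int(n)]
    (n / s0) * Matrix::colSums((W %*% P) * P) / denom
  })
  p <- (1 + sum(i_perm >= i_obs)) / (n_perm + 1)
  list(statistic = i_obs, p_value = p, n_perm = n_perm, degenerate = FALSE)
}

#' Spatial-variability test for every gene of a slide
#'
#' Applies the pipeline in the canonical order: coverage filter, Anscombe
#' transform, optional 2 x 2 median pooling, then the permutation Moran's I
#' test per gene (weights computed once and shared).
#'
#' @param counts spots x genes matrix (counts, or already-transformed
#'   values with `transform = "none"`).
#' @param grid the slide's `spot_grid`.
#' @param n_perm permutations per gene.
#' @param seed base seed (per-gene seeds are derived from it).
#' @param min_fraction coverage threshold; `NULL` skips filtering.
#' @param pool apply median pooling before testing.
#' @param transform `"anscombe"` or `"none"`.
#' @return Data frame: `gene`, `statistic`, `p_value`, `fsv`, `degenerate`.
#' @export
sv_test_genes <- function(counts, grid, n_perm = 999L, seed = 1L,
                          min_fraction = 0.30, pool = FALSE,
                          transform = c("anscombe", "none")) {
  transform <- match.arg(transform)
  genes <- colnames(counts)
  if (!is.null(min_fraction) && transform == "anscombe") {
    keep <- coverage_filter(counts, min_fraction)
    counts <- counts[, keep, drop = FALSE]
    genes <- keep
  }
  v <- if (transform == "anscombe") anscombe(counts) else as.matrix(counts)
  coords <- cbind(grid$px_x, grid$px_y)
  if (pool) {
    pooled <- median_pool(grid, v)
    v <- cbind(pooled$values)
    coords <- pooled$coords
  }
  W <- sv_weights(coords)
  ls <- if (!is.null(grid_pitch(grid))) grid_pitch(grid)
        else min(stats::dist(coords))
  res <- lapply(seq_along(genes), function(j) {
    t <- sv_test(v[, j], n_perm = n_perm, seed = child_seed(seed, j), W = W)
    f <- estimate_fsv(v[, j], coords, ls)
    data.frame(gene = genes[j], statistic = t$statistic, p_value = t$p_value,
               fsv = f, degenerate = t$degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Fraction of spatial variance by kernel smoothing
#'
#' Decomposes a gene's variance into a spatially smooth component and a
#' residual: the smooth component is a Gaussian-kernel weighted
#' neighbourhood average at the given lengthscale, and
#' `FSV = var(smoothed) / var(values)`, clipped to `[0, 1]`. Invariant to
#' affine rescaling of the values. Zero-variance input returns 0 with a
#' `degenerate` attribute.
#'
#' @param values per-spot values (length >= 10).
#' @param coords spots x 2 coordinates.
#' @param lengthscale_px Gaussian kernel lengthscale in pixels.
#' @return FSV in `[0, 1]`.
#' @export
estimate_fsv <- function(values, coords, lengthscale_px) {
  if (length(values) < 10) stop_invalid("need at least 10 spots")
  if (lengthscale_px <= 0) stop_invalid("'lengthscale_px' must be positive")
  if (stats::sd(values) == 0)
    return(structure(0, degenerate = TRUE))
  K <- exp(-pair_dist(coords)^2 / (2 * lengthscale_px^2))
  K <- K / rowSums(K)
  sm <- as.vector(K %*% values)
  clamp(stats::var(sm) / stats::var(values), 0, 1)
}

#' Spatially co-expressed gene groups
#'
#' Clusters genes on their smoothed, z-scored spatial expression patterns
#' with k-means (a clustering stand-in for model-based expression
#' histology): genes sharing a spatial pattern land in the same group.
#'
#' @param expr spots x genes expression matrix (variance-stabilised values
#'   recommended).
#' @param coords spots x 2 coordinates.
#' @param k number of groups (default 5).
#' @param seed RNG seed (k-means initialisation).
#' @param lengthscale_px smoothing lengthscale; default 2 x the minimum
#'   spot spacing.
#' @return Named integer vector: group label in `1..k` per gene.
#' @export
coexpression_groups <- function(expr, coords, k = 5L, seed = 1L,
                                lengthscale_px = NULL) {
  G <- ncol(expr)
  if (G < k) stop_invalid("fewer genes (%d) than groups (%d)", G, k)
  if (is.null(lengthscale_px)) {
    d <- pair_dist(coords); diag(d) <- Inf
    lengthscale_px <- 2 * min(d)
  }
  K <- exp(-pair_dist(coords)^2 / (2 * lengthscale_px^2))
  K <- K / rowSums(K)
  sm <- K %*% expr
  z <- apply(sm, 2, function(v) {
    s <- stats::sd(v)
    if (s < 1e-12) rep(0, length(v)) else (v - mean(v)) / s
  })
  if (k == 1L) {
    labels <- rep(1L, G)
  } else {
    km <- with_seed(seed, stats::kmeans(t(z), centers = k, nstart = 10L,
                                        iter.max = 100L))
    labels <- km$cluster
    if (length(unique(labels)) < k)
      warning("fewer than k non-empty co-expression groups")
  }
  names(labels) <- colnames(expr)
  labels
}
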