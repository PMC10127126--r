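## Synthetic expression generator: latent spatial factor fields, a gene
## design that ties genes to those factors, and zero-inflated negative
## binomial count sampling.

#' Smoothed Gaussian random field on a set of spot coordinates
#'
#' Draws i.i.d. standard normals on the spots and smooths them with a
#' Gaussian kernel of the given lengthscale, then standardises the result to
#' zero mean and unit variance. A non-positive lengthscale returns the
#' unsmoothed (spatially independent) field.
#'
#' @param coords two-column matrix of spot centres (pixels).
#' @param lengthscale_px kernel lengthscale in pixels.
#' @return Numeric vector, one value per spot, mean 0 and sd 1.
#' @keywords internal
grf_field <- function(coords, lengthscale_px, kernel = NULL) {
  n <- nrow(coords)
  z <- stats::rnorm(n)
  if (lengthscale_px > 0) {
    if (is.null(kernel))
      kernel <- exp(-pair_dist(coords)^2 / (2 * lengthscale_px^2))
    z <- as.vector(kernel %*% z)
  }
  as.vector(scale(z))
}

#' Gene design for a simulated cohort
#'
#' Fixes, once per cohort, which genes are spatially variable (SV), which of
#' those carry their signal in the local spot texture versus the surrounding
#' neighbourhood, which are SV only in one slide group, and each gene's
#' baseline mean, dispersion, zero-inflation and loading on a latent factor.
#' Sharing the design across slides is what makes a gene learnable across
#' slides in cross-validation.
#'
#' Latent factors: `f1` and `f2` are smooth fields read out by the red and
#' green image channels; `fctx` is a per-spot texture field read out by the
#' blue channel, whose *neighbour average* drives contextual genes; `fmet`
#' is a smooth field read out by the speckle density of the spot discs, and
#' only exists on slides of the `met` group.
#'
#' @param n_genes total number of genes.
#' @param sv_fraction fraction of genes that are spatially variable.
#' @param contextual_fraction fraction of SV genes whose signal is the
#'   1-ring neighbour mean of the local texture field.
#' @param group_differential_fraction fraction of SV genes that are SV only
#'   on `met` slides.
#' @param mean_range range of per-gene baseline means (counts).
#' @param dispersion_range range of per-gene negative binomial dispersions.
#' @param pi_range range of per-gene zero-inflation probabilities.
#' @param loading_range range of absolute log-scale factor loadings.
#' @param seed RNG seed.
#' @return A data frame with one row per gene: `gene_id`, `gene_class`
#'   (`local`/`contextual`/`noise`), `sv_flag`, `group_differential_flag`,
#'   `factor` (`f1`, `f2`, `fctx`, `fmet` or `NA`), `loading`, `base_mean`,
#'   `sigma`, `pi`.
#' @export
make_gene_design <- function(n_genes = 60, sv_fraction = 2 / 3,
                             contextual_fraction = 0.25,
                             group_differential_fraction = 0.25,
                             mean_range = c(2, 8),
                             dispersion_range = c(1, 4),
                             pi_range = c(0.05, 0.3),
                             loading_range = c(0.6, 1.0),
                             seed = 1L) {
  if (sv_fraction < 0 || sv_fraction > 1 ||
      contextual_fraction < 0 || contextual_fraction > 1 ||
      group_differential_fraction < 0 || group_differential_fraction > 1)
    stop_invalid("fractions must lie in [0, 1]")
  n_sv <- round(n_genes * sv_fraction)
  n_ctx <- round(n_sv * contextual_fraction)
  n_gd <- round(n_sv * group_differential_fraction)
  n_local <- n_sv - n_ctx - n_gd
  if (n_local < 0) stop_invalid("contextual and group-differential fractions exceed the SV budget")

  with_seed(seed, {
    gene_id <- sprintf("gene_%03d", seq_len(n_genes))
    cls <- rep("noise", n_genes)
    fac <- rep(NA_character_, n_genes)
    if (n_local > 0) {
      cls[seq_len(n_local)] <- "local"
      fac[seq_len(n_local)] <- rep(c("f1", "f2"), length.out = n_local)
    }
    if (n_ctx > 0) {
      idx <- n_local + seq_len(n_ctx)
      cls[idx] <- "contextual"
      fac[idx] <- "fctx"
    }
    gd <- rep(FALSE, n_genes)
    if (n_gd > 0) {
      idx <- n_local + n_ctx + seq_len(n_gd)
      cls[idx] <- "local"      # image-encoded (speckle density), own-spot signal
      fac[idx] <- "fmet"
      gd[idx] <- TRUE
    }
    sv <- cls != "noise"
    loading <- ifelse(sv,
                      sample(c(-1, 1), n_genes, replace = TRUE) *
                        stats::runif(n_genes, loading_range[1], loading_range[2]),
                      0)
    data.frame(
      gene_id = gene_id, gene_class = cls, sv_flag = sv,
      group_differential_flag = gd, factor = fac, loading = loading,
      base_mean = stats::runif(n_genes, mean_range[1], mean_range[2]),
      sigma = stats::runif(n_genes, dispersion_range[1], dispersion_range[2]),
      pi = stats::runif(n_genes, pi_range[1], pi_range[2]),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate zero-inflated negative binomial expression on a spot grid
#'
#' Draws the latent factor fields for one slide, builds each gene's mean
#' field from the cohort gene design, and samples counts. Spatially variable
#' genes have `mu_g(spot) = base_mean * exp(loading * field)` with the field
#' a standardised smoothed Gaussian random field; contextual genes use the
#' 1-ring hexagonal neighbour mean of the per-spot texture field, so their
#' signal is only recoverable from a patch's surroundings; genes flagged
#' group-differential have a constant mean unless `group = "met"`. Counts
#' are drawn per spot and gene as 0 with probability `pi`, else negative
#' binomial with mean `mu` and dispersion `sigma`
#' (variance `mu + mu^2 / sigma`).
#'
#' @param grid a `spot_grid`.
#' @param n_genes,sv_fraction,contextual_fraction passed to
#'   [make_gene_design()] when `design` is not supplied.
#' @param lengthscale_px lengthscale of the smooth factor fields (`f1`,
#'   `f2`, `fmet`); default 3 pitches.
#' @param ctx_lengthscale_px lengthscale of the local texture field `fctx`;
#'   the default 0 makes it spatially independent, so the neighbour-mean
#'   signal of contextual genes cannot be read off the spot's own disc.
#' @param dispersion_range,pi_range per-gene parameter ranges (used when
#'   `design` is not supplied).
#' @param group slide group, `"met"` or `"nonmet"`.
#' @param seed RNG seed for this slide.
#' @param design optional precomputed [make_gene_design()] table shared
#'   across the slides of a cohort.
#' @return A list of class `latent_fields`: `design`, `factors` (spots x 4
#'   matrix; `fmet` is all zero on non-met slides), `mu` (spots x genes),
#'   `group`, plus the sampled `counts` matrix (spots x genes, integer,
#'   dimnames barcode x gene).
#' @export
simulate_expression <- function(grid, n_genes = 60, sv_fraction = 2 / 3,
                                contextual_fraction = 0.25,
                                lengthscale_px = NULL,
                                ctx_lengthscale_px = 0,
                                dispersion_range = c(1, 4),
                                pi_range = c(0.05, 0.3),
                                group = c("met", "nonmet"),
                                seed = 1L, design = NULL) {
  group <- match.arg(group)
  if (is.null(lengthscale_px)) lengthscale_px <- 3 * grid_pitch(grid)
  if (lengthscale_px <= 0) stop_invalid("'lengthscale_px' must be positive")
  if (is.null(design))
    design <- make_gene_design(n_genes = n_genes, sv_fraction = sv_fraction,
                               contextual_fraction = contextual_fraction,
                               dispersion_range = dispersion_range,
                               pi_range = pi_range, seed = seed)
  n <- nrow(grid)
  G <- nrow(design)
  coords <- cbind(grid$px_x, grid$px_y)
  has_ctx <- "fctx" %in% design$factor[design$sv_flag]
  graph <- if (has_ctx) build_spot_graph(grid) else NULL

  ## factors no gene loads on are not part of the slide's morphology: they
  ## are left flat (zero) so the image encodes nothing for them
  used <- unique(design$factor[design$sv_flag])
  need_smooth <- any(c("f1", "f2") %in% used) ||
    ("fmet" %in% used && group == "met")
  with_seed(seed, {
    kern <- if (need_smooth)
      exp(-pair_dist(coords)^2 / (2 * lengthscale_px^2)) else NULL
    draw <- function(name, ls, k) {
      f <- grf_field(coords, ls, k)   # always consume RNG for reproducibility
      if (name %in% used) f else rep(0, n)
    }
    f1 <- draw("f1", if ("f1" %in% used) lengthscale_px else 0, kern)
    f2 <- draw("f2", if ("f2" %in% used) lengthscale_px else 0, kern)
    fctx <- draw("fctx", ctx_lengthscale_px, NULL)
    fmet <- if (group == "met")
      draw("fmet", if ("fmet" %in% used) lengthscale_px else 0, kern)
    else rep(0, n)
    factors <- cbind(f1 = f1, f2 = f2, fctx = fctx, fmet = fmet)
    fctx_ring <- if (has_ctx) {
      ## neighbour means of a standardised field shrink; restandardise so
      ## the contextual genes' dynamic range matches the local ones
      as.vector(scale(as.vector(neighbor_mean(graph, fctx))))
    } else rep(0, n)

    logmu <- matrix(log(design$base_mean), n, G, byrow = TRUE)
    for (g in seq_len(G)) {
      if (!design$sv_flag[g]) next
      fld <- switch(design$factor[g],
                    f1 = f1, f2 = f2, fctx = fctx_ring, fmet = fmet)
      if (design$factor[g] == "fmet" && group != "met") next
      logmu[, g] <- logmu[, g] + design$loading[g] * fld
    }
    mu <- exp(logmu)

    y <- stats::rnbinom(n * G, size = rep(design$sigma, each = n), mu = as.vector(mu))
    zero <- stats::rbinom(n * G, 1L, prob = rep(design$pi, each = n)) == 1L
    y[zero] <- 0L
    counts <- matrix(as.integer(y), n, G,
                     dimnames = list(grid$spot_id, design$gene_id))

    structure(
      list(design = design, factors = factors, mu = mu, group = group,
           counts = counts),
      class = "latent_fields"
    )
  })
}
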