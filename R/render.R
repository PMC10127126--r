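#' Render a synthetic slide image encoding the latent factors
#'
#' Draws each spot's circular capture area as a textured disc on a noisy
#' off-white background. Channel statistics of a disc are monotone readouts
#' of the slide's latent factors at that spot: the red channel mean encodes
#' `f1`, the green channel mean `f2`, the blue channel mean the per-spot
#' texture field `fctx`, and the density of dark speckles inside the disc
#' encodes `fmet` (constant on non-met slides). Contextual genes are driven
#' by the *neighbour average* of `fctx`, so their signal is present only in
#' the neighbouring discs, never in the spot's own disc.
#'
#' @param grid a `spot_grid`.
#' @param latents a `latent_fields` object from [simulate_expression()]
#'   for the same grid.
#' @param image_cfg optional list overriding texture parameters:
#'   `background` (default 0.92), `background_sd` (0.02), `base` (0.55),
#'   `gain` (0.16), `pixel_sd` (0.03), `speckle_max` (0.25),
#'   `speckle_dim` (0.45).
#' @param seed RNG seed; the same seed yields a byte-identical image.
#' @return Numeric array `height x width x 3` with values in `[0, 1]`.
#' @export
render_slide <- function(grid, latents, image_cfg = list(), seed = 1L) {
  if (!inherits(latents, "latent_fields"))
    stop_invalid("'latents' must come from simulate_expression()")
  if (nrow(latents$factors) != nrow(grid))
    stop_invalid("grid and latents describe different numbers of spots")
  cfg <- utils::modifyList(
    list(background = 0.92, background_sd = 0.02, base = 0.55, gain = 0.16,
         pixel_sd = 0.03, speckle_max = 0.25, speckle_dim = 0.45),
    image_cfg
  )
  hw <- grid_image_dim(grid)
  H <- hw[1]; W <- hw[2]
  r <- grid_diameter(grid) / 2
  if (any(grid$px_x < r) || any(grid$px_y < r) ||
      any(grid$px_x > W - 1 - r) || any(grid$px_y > H - 1 - r))
    stop_invalid("image too small for grid and margin")

  fac <- latents$factors
  with_seed(seed, {
    img <- array(clamp(cfg$background + stats::rnorm(H * W * 3, sd = cfg$background_sd),
                       0, 1), dim = c(H, W, 3))
    ## disc template: pixel offsets within radius of the centre
    off <- seq(-ceiling(r), ceiling(r))
    dmask <- outer(off, off, function(dy, dx) dy^2 + dx^2 <= r^2)
    dy <- row(dmask)[dmask] - ceiling(r) - 1L
    dx <- col(dmask)[dmask] - ceiling(r) - 1L
    npx <- length(dy)
    speckle_on <- any(fac[, "fmet"] != 0)
    for (s in seq_len(nrow(grid))) {
      cy <- round(grid$px_y[s]) + 1L   # 1-based image row
      cx <- round(grid$px_x[s]) + 1L
      rows <- cy + dy; cols <- cx + dx
      base_rgb <- clamp(cfg$base + cfg$gain * fac[s, c("f1", "f2", "fctx")],
                        0.05, 0.95)
      px <- clamp(rep(base_rgb, each = npx) +
                    stats::rnorm(npx * 3, sd = cfg$pixel_sd), 0, 1)
      p_speckle <- cfg$speckle_max *
        (if (speckle_on) stats::plogis(fac[s, "fmet"]) else 0.5)
      spk <- stats::runif(npx) < p_speckle
      if (any(spk)) px[rep(spk, 3)] <- px[rep(spk, 3)] * cfg$speckle_dim
      idx <- cbind(rep(rows, 3), rep(cols, 3), rep(1:3, each = npx))
      img[idx] <- px
    }
    img
  })
}
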