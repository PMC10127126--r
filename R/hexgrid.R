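#' Build a honeycomb (hexagonal) Visium-like spot lattice
#'
#' Spots are laid out in "pointy-top" offset rows: row `r` sits at vertical
#' position `r * pitch_px * sqrt(3)/2` and odd rows are shifted right by half
#' a pitch, so every interior spot has six equidistant neighbours at exactly
#' `pitch_px`. Coordinates are in the image pixel frame (x = column,
#' y = row, 0-based) and carry a margin so that image patches centred on any
#' spot stay inside the rendered slide.
#'
#' @param n_rows,n_cols lattice dimensions (positive integers).
#' @param pitch_px centre-to-centre distance of adjacent spots, in pixels.
#' @param spot_diameter_px diameter of the circular capture area; must be
#'   smaller than `pitch_px`.
#' @param margin_px blank border between the outermost spot centres and the
#'   image edge.
#' @param seed unused (the lattice is deterministic); accepted so that all
#'   generator operations share a uniform signature.
#' @return A `spot_grid`: a data frame with columns `spot_id`, `array_row`,
#'   `array_col`, `px_x`, `px_y`, `in_tissue`, and attributes `pitch_px`,
#'   `spot_diameter_px`, `margin_px`.
#' @examples
#' g <- make_hex_grid(4, 4, pitch_px = 100, spot_diameter_px = 55)
#' nrow(g)
#' @export
make_hex_grid <- function(n_rows, n_cols, pitch_px = 64, spot_diameter_px = 36,
                          margin_px = 48, seed = NULL) {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) || n_rows < 1 || n_cols < 1)
    stop_invalid("'n_rows' and 'n_cols' must be >= 1")
  if (!is.numeric(pitch_px) || pitch_px <= 0)
    stop_invalid("'pitch_px' must be positive")
  if (!is.numeric(spot_diameter_px) || spot_diameter_px <= 0 ||
      spot_diameter_px >= pitch_px)
    stop_invalid("'spot_diameter_px' must satisfy 0 < diameter < pitch")
  if (margin_px < 0) stop_invalid("'margin_px' must be non-negative")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)

  ar <- rep(seq_len(n_rows) - 1L, each = n_cols)
  ac <- rep(seq_len(n_cols) - 1L, times = n_rows)
  px_x <- margin_px + ac * pitch_px + (ar %% 2L) * pitch_px / 2
  px_y <- margin_px + ar * pitch_px * sqrt(3) / 2
  grid <- data.frame(
    spot_id = sprintf("spot_r%03d_c%03d", ar, ac),
    array_row = ar, array_col = ac,
    px_x = px_x, px_y = px_y,
    in_tissue = 1L,
    stringsAsFactors = FALSE
  )
  attr(grid, "pitch_px") <- pitch_px
  attr(grid, "spot_diameter_px") <- spot_diameter_px
  attr(grid, "margin_px") <- margin_px
  class(grid) <- c("spot_grid", "data.frame")
  grid
}

grid_pitch <- function(grid) attr(grid, "pitch_px")
grid_diameter <- function(grid) attr(grid, "spot_diameter_px")
grid_margin <- function(grid) attr(grid, "margin_px")

#' Image dimensions implied by a spot grid
#'
#' Height and width (pixels) of the smallest slide image that contains all
#' spot centres plus the grid margin on every side.
#'
#' @param grid a `spot_grid`.
#' @return Integer vector `c(height, width)`.
#' @keywords internal
grid_image_dim <- function(grid) {
  h <- ceiling(max(grid$px_y) + grid_margin(grid)) + 1L
  w <- ceiling(max(grid$px_x) + grid_margin(grid)) + 1L
  c(as.integer(h), as.integer(w))
}
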