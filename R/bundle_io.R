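#' Assemble a slide bundle
#'
#' A slide bundle groups everything belonging to one slide: the spot grid,
#' the raster image, the spot x gene count matrix, the (simulation-only)
#' latent fields, and a slide-group label standing for metastasis status.
#'
#' @param grid a `spot_grid`.
#' @param image `H x W x 3` array in `[0, 1]`, or `NULL`.
#' @param counts integer matrix, in-tissue spots x genes, with barcode row
#'   names and gene column names.
#' @param latents optional `latent_fields` (simulated slides only).
#' @param slide_group `"met"` or `"nonmet"`.
#' @param slide_id identifier for the slide.
#' @return A `slide_bundle` list.
#' @export
slide_bundle <- function(grid, image, counts, latents = NULL,
                         slide_group = c("met", "nonmet"), slide_id = "slide") {
  slide_group <- match.arg(slide_group)
  keep <- grid$in_tissue == 1L
  if (sum(keep) != nrow(counts))
    stop_invalid("counts has %d rows but grid has %d in-tissue spots",
                 nrow(counts), sum(keep))
  if (!all(rownames(counts) == grid$spot_id[keep]))
    stop_invalid("counts row names do not match in-tissue spot barcodes")
  if (any(counts < 0)) stop_invalid("counts must be non-negative")
  structure(
    list(grid = grid, image = image, counts = counts, latents = latents,
         slide_group = slide_group, slide_id = slide_id),
    class = "slide_bundle"
  )
}

#' @export
print.slide_bundle <- function(x, ...) {
  cat(sprintf("slide_bundle '%s' (%s): %d spots x %d genes%s\n",
              x$slide_id, x$slide_group, nrow(x$counts), ncol(x$counts),
              if (is.null(x$image)) "" else
                sprintf(", image %dx%d", dim(x$image)[1], dim(x$image)[2])))
  invisible(x)
}

positions_columns <- c("barcode", "in_tissue", "array_row", "array_col",
                       "pxl_row_in_fullres", "pxl_col_in_fullres")

#' Write a slide bundle to disk
#'
#' Produces the on-disk dialect used throughout the package: a
#' `tissue_positions.csv` table (columns `barcode`, `in_tissue`,
#' `array_row`, `array_col`, `pxl_row_in_fullres`, `pxl_col_in_fullres`;
#' pixel coordinates rounded to integers, image frame, 0-based), a
#' MatrixMarket `counts.mtx` with 1-based indices and spots as rows, plain
#' text `genes.txt` and `barcodes.txt` sidecars, an 8-bit RGB `image.png`,
#' and a `metadata.json` with pitch, spot diameter, margin, slide group and
#' id. Re-reading with [read_slide_bundle()] reproduces counts exactly and
#' coordinates as written (i.e. rounded to whole pixels).
#'
#' @param bundle a `slide_bundle`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_slide_bundle <- function(bundle, out_dir) {
  if (!inherits(bundle, "slide_bundle")) stop_invalid("not a slide_bundle")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  g <- bundle$grid
  pos <- data.frame(
    barcode = g$spot_id,
    in_tissue = g$in_tissue,
    array_row = g$array_row,
    array_col = g$array_col,
    pxl_row_in_fullres = as.integer(round(g$px_y)),
    pxl_col_in_fullres = as.integer(round(g$px_x)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(pos, file.path(out_dir, "tissue_positions.csv"),
                   row.names = FALSE, quote = FALSE)
  m <- Matrix::Matrix(bundle$counts, sparse = TRUE)
  Matrix::writeMM(methods::as(m, "generalMatrix"),
                  file.path(out_dir, "counts.mtx"))
  writeLines(colnames(bundle$counts), file.path(out_dir, "genes.txt"))
  writeLines(rownames(bundle$counts), file.path(out_dir, "barcodes.txt"))
  if (!is.null(bundle$image))
    png::writePNG(bundle$image, file.path(out_dir, "image.png"))
  meta <- list(
    pitch_px = grid_pitch(g), spot_diameter_px = grid_diameter(g),
    margin_px = grid_margin(g), slide_group = bundle$slide_group,
    slide_id = bundle$slide_id
  )
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a slide bundle from disk
#'
#' Reads the files written by [write_slide_bundle()]. Spots with
#' `in_tissue = 0` are dropped; count rows are reordered to match the
#' positions order; all bundle invariants are validated.
#'
#' @param dir directory containing the bundle files.
#' @return A `slide_bundle` (with `latents = NULL`).
#' @export
read_slide_bundle <- function(dir) {
  need <- c("tissue_positions.csv", "counts.mtx", "genes.txt", "barcodes.txt",
            "metadata.json")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("missing file: ", file.path(dir, f))
  pos <- utils::read.csv(file.path(dir, "tissue_positions.csv"),
                         stringsAsFactors = FALSE)
  if (!identical(names(pos), positions_columns))
    stop("positions file must have columns: ",
         paste(positions_columns, collapse = ","))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  m <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  genes <- readLines(file.path(dir, "genes.txt"))
  barcodes <- readLines(file.path(dir, "barcodes.txt"))
  if (nrow(m) != length(barcodes) || ncol(m) != length(genes))
    stop("counts dimensions do not match sidecar identifier lists")
  if (anyDuplicated(genes)) stop("format error: duplicated gene identifier")
  if (anyDuplicated(barcodes)) stop("format error: duplicated barcode")
  if (any(m < 0))
    stop(sprintf("format error: negative count for barcode '%s'",
                 barcodes[which(rowSums(m < 0) > 0)[1]]))
  dimnames(m) <- list(barcodes, genes)

  pos <- pos[pos$in_tissue == 1L, , drop = FALSE]
  missing_bc <- setdiff(pos$barcode, barcodes)
  if (length(missing_bc) > 0)
    stop(sprintf("format error: barcode '%s' present in positions but not in counts",
                 missing_bc[1]))
  m <- m[pos$barcode, , drop = FALSE]
  storage.mode(m) <- "integer"

  grid <- data.frame(
    spot_id = pos$barcode, array_row = pos$array_row,
    array_col = pos$array_col,
    px_x = as.numeric(pos$pxl_col_in_fullres),
    px_y = as.numeric(pos$pxl_row_in_fullres),
    in_tissue = pos$in_tissue, stringsAsFactors = FALSE
  )
  attr(grid, "pitch_px") <- meta$pitch_px
  attr(grid, "spot_diameter_px") <- meta$spot_diameter_px
  attr(grid, "margin_px") <- meta$margin_px
  class(grid) <- c("spot_grid", "data.frame")

  img_path <- file.path(dir, "image.png")
  img <- if (file.exists(img_path)) png::readPNG(img_path) else NULL

  slide_bundle(grid, img, m, latents = NULL,
               slide_group = meta$slide_group, slide_id = meta$slide_id)
}

#' Simulate a full Visium-like cohort of slide bundles
#'
#' Generates `n_slides` slides sharing one gene design (so genes behave
#' consistently across slides), the first half labelled `met` and the rest
#' `nonmet`. Group-differential genes are spatially variable only on the
#' `met` slides.
#'
#' @param n_slides number of slides.
#' @param n_rows,n_cols lattice dimensions per slide.
#' @param n_genes number of genes.
#' @param seed cohort seed; per-slide seeds are derived from it.
#' @param pitch_px,spot_diameter_px,margin_px lattice geometry.
#' @param render render the slide images (needed for patch models).
#' @param design optional gene design; defaults to [make_gene_design()]
#'   under the cohort seed.
#' @param ... further arguments passed to [simulate_expression()].
#' @return List of `slide_bundle`s, named by slide id.
#' @export
simulate_cohort <- function(n_slides = 4, n_rows = 32, n_cols = 32,
                            n_genes = 60, seed = 1L, pitch_px = 64,
                            spot_diameter_px = 36, margin_px = 48,
                            render = TRUE, design = NULL, ...) {
  if (n_slides < 1) stop_invalid("'n_slides' must be >= 1")
  if (is.null(design))
    design <- make_gene_design(n_genes = n_genes, seed = child_seed(seed, 0L))
  groups <- rep(c("met", "nonmet"), each = ceiling(n_slides / 2))[seq_len(n_slides)]
  bundles <- vector("list", n_slides)
  for (i in seq_len(n_slides)) {
    grid <- make_hex_grid(n_rows, n_cols, pitch_px = pitch_px,
                          spot_diameter_px = spot_diameter_px,
                          margin_px = margin_px)
    lat <- simulate_expression(grid, group = groups[i],
                               seed = child_seed(seed, i), design = design, ...)
    img <- if (render) render_slide(grid, lat, seed = child_seed(seed, 100L + i))
           else NULL
    bundles[[i]] <- slide_bundle(grid, img, lat$counts, latents = lat,
                                 slide_group = groups[i],
                                 slide_id = sprintf("slide%02d", i))
  }
  names(bundles) <- vapply(bundles, `[[`, "", "slide_id")
  bundles
}
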