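#' Field geometry for the synthetic renderer
#'
#' @param width,height image size in pixels.
#' @param nucleus_radius,cell_radius disc radii in pixels; the cytoplasm disc
#'   must leave room for the quantification ring
#'   (`cell_radius >= nucleus_radius + ring width + 1`).
#' @param spacing centre-to-centre spacing of the cell grid, px.
#' @return list of class `field_geometry`.
#' @export
field_geometry <- function(width = 512, height = 512, nucleus_radius = 8,
                           cell_radius = 15, spacing = 36) {
  stopifnot(width > 0, height > 0, nucleus_radius >= 2,
            cell_radius > nucleus_radius, spacing > 0)
  structure(list(width = width, height = height,
                 nucleus_radius = nucleus_radius, cell_radius = cell_radius,
                 spacing = spacing), class = "field_geometry")
}

#' Render a snapshot population as a multi-channel image with ground truth
#'
#' Draws each cell as a disc nucleus inside a disc cytoplasm on a regular
#' grid. Channel intensities are constructed so the programmed quantities are
#' exactly recoverable by [measure_cells()] in the noise-free case: the FOXO1
#' channel puts `scale * foxo1_nf` in the nucleus and `scale * (1 -
#' foxo1_nf)` in the cytoplasm (so nuclear/(nuclear+ring) equals the
#' programmed nuclear fraction), the p53 channel puts `p53_nuc` in the nucleus,
#' and the gamma-H2AX channel puts `gh2ax` in the nucleus. The label mask
#' assigns every nucleus pixel the (integer) index of its cell.
#'
#' @param cells `snapshot_cells` data frame (see [generate_snapshot()]).
#' @param geometry [field_geometry()].
#' @param noise `"none"` or `"poisson"` (intensities treated as photon
#'   counts; uses the current RNG stream).
#' @param scale photon scale of the FOXO1 channel.
#' @return list of class `rendered_field`: `image` (array `height x width x
#'   3`, channels `foxo1`, `p53`, `gh2ax`), `mask` (integer matrix),
#'   `cells`, `geometry`, `scale`.
#' @export
#' @examples
#' snap <- generate_snapshot(9, dose_preset(100), seed = 1)
#' fld <- render_field(snap, field_geometry(160, 160))
#' m <- measure_cells(fld$image, fld$mask)
render_field <- function(cells, geometry = field_geometry(),
                         noise = c("none", "poisson"), scale = 2000) {
  noise <- match.arg(noise)
  g <- geometry
  n <- nrow(cells)
  if (g$spacing < 2 * g$cell_radius + 1) {
    stop("geometry error: spacing too small, cytoplasm discs would overlap")
  }
  per_row <- floor((g$width - g$spacing / 2) / g$spacing)
  per_col <- floor((g$height - g$spacing / 2) / g$spacing)
  if (per_row < 1 || per_col < 1 || n > per_row * per_col) {
    stop("geometry error: ", n, " cells do not fit a ", g$width, "x",
         g$height, " field at spacing ", g$spacing)
  }
  img <- array(0, c(g$height, g$width, 3L),
               dimnames = list(NULL, NULL, c("foxo1", "p53", "gh2ax")))
  mask <- matrix(0L, g$height, g$width)
  xs <- seq_len(g$height); ys <- seq_len(g$width)
  for (i in seq_len(n)) {
    cx <- g$spacing / 2 + ((i - 1L) %% per_row) * g$spacing + g$spacing / 2
    cy <- g$spacing / 2 + ((i - 1L) %/% per_row) * g$spacing + g$spacing / 2
    d2 <- outer((xs - cy)^2, (ys - cx)^2, `+`)
    nuc <- d2 <= g$nucleus_radius^2
    cyto <- d2 <= g$cell_radius^2 & !nuc
    nf <- cells$foxo1_nf[i]
    img[, , "foxo1"][nuc] <- scale * nf
    img[, , "foxo1"][cyto] <- scale * (1 - nf)
    img[, , "p53"][nuc] <- cells$p53_nuc[i]
    img[, , "p53"][cyto] <- 0.2 * cells$p53_nuc[i]
    img[, , "gh2ax"][nuc] <- cells$gh2ax[i]
    mask[nuc] <- i
  }
  if (noise == "poisson") {
    img[] <- stats::rpois(length(img), img)
  }
  structure(list(image = img, mask = mask, cells = cells, geometry = g,
                 scale = scale), class = "rendered_field")
}

#' Write a rendered field as 16-bit TIFF images
#'
#' Writes the multi-channel image and the label mask as 16-bit TIFFs
#' (requires the `tiff` package). Intensities are clipped to `[0, 65535]`.
#'
#' @param field [render_field()] result.
#' @param image_path,mask_path output paths.
#' @return invisibly, the two paths.
#' @export
write_field_tiff <- function(field, image_path, mask_path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export")
  }
  img <- field$image
  img <- pmin(pmax(img, 0), 65535) / 65535
  tiff::writeTIFF(lapply(seq_len(dim(img)[3L]), function(ci) img[, , ci]),
                  image_path, bits.per.sample = 16L)
  tiff::writeTIFF(field$mask / 65535, mask_path, bits.per.sample = 16L)
  invisible(c(image_path, mask_path))
}
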