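# ECD and per-cell morphometry on the central analysis disc.

#' Crop the central analysis disc of an en-face image
#'
#' Rasterizes a circular analysis region (default 0.5 mm diameter, centred on
#' the image) by centre-of-pixel inclusion. Cells at the corneal periphery
#' are dimmer and harder to segment, so analysis is restricted to this
#' central disc.
#'
#' @param img an [enface_image()] (or any object with `lateral_pitch`; only
#'   geometry is used).
#' @param diameter_mm disc diameter in millimetres.
#' @param center optional `(row, col)` centre in px; defaults to the image
#'   centre.
#' @return An object of class `analysis_disc`: `center`, `diameter_mm`,
#'   `lateral_pitch`, `mask` (logical matrix), `area_mm2` (mask pixel area),
#'   `nominal_area_mm2` (pi (d/2)^2).
#' @export
crop_central_disc <- function(img, diameter_mm = 0.5, center = NULL) {
  h <- nrow(img$intensities); w <- ncol(img$intensities)
  pitch <- img$lateral_pitch
  r_px <- diameter_mm * 1000 / (2 * pitch)
  if (is.null(center)) center <- c((h + 1) / 2, (w + 1) / 2)
  if (center[1] - r_px < 0.5 || center[1] + r_px > h + 0.5 ||
      center[2] - r_px < 0.5 || center[2] + r_px > w + 0.5)
    stop_precondition(sprintf(
      "analysis disc (radius %.1f px) exceeds the %d x %d image bounds", r_px, h, w))
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  mask <- (rows - center[1])^2 + (cols - center[2])^2 <= r_px^2
  structure(list(center = center, diameter_mm = diameter_mm,
                 lateral_pitch = pitch, mask = mask,
                 area_mm2 = sum(mask) * pitch^2 * 1e-6,
                 nominal_area_mm2 = pi * (diameter_mm / 2)^2),
            class = "analysis_disc")
}

#' @export
print.analysis_disc <- function(x, ...) {
  cat(sprintf("<analysis_disc> %.3g mm diameter at (%.1f, %.1f), area %.4f mm^2 (nominal %.4f)\n",
              x$diameter_mm, x$center[1], x$center[2], x$area_mm2,
              x$nominal_area_mm2))
  invisible(x)
}

#' Compute endothelial cell density on an analysis disc
#'
#' Counts retained cells whose centroid lies inside the disc and divides by
#' the analysis area, so that `ecd * analysis_area = n_cells` holds exactly.
#' By default the area is the disc mask's true pixel area; `area = "nominal"`
#' uses pi (d/2)^2 instead (the textbook worked relation: 600 cells in a
#' 0.2-mm^2 area give 3000 cells/mm^2). Morphometry (mean cell area and its
#' coefficient of variation) is computed over the counted cells only.
#'
#' @param cells a `cell_label_map` from [postprocess_to_cells()].
#' @param disc an [crop_central_disc()] result; must share the lateral pitch.
#' @param area `"mask"` (pixel-count area, default) or `"nominal"`.
#' @param include `"centroid"` (cells whose centroid falls inside, default)
#'   or `"interior"` (cells entirely inside the disc).
#' @return An object of class `ecd_report`: `n_cells`, `analysis_area_mm2`,
#'   `ecd_cells_mm2`, `mean_cell_area_um2`, `cell_area_cv`,
#'   `morphometry_defined`.
#' @export
compute_ecd <- function(cells, disc, area = c("mask", "nominal"),
                        include = c("centroid", "interior")) {
  area <- match.arg(area)
  include <- match.arg(include)
  pitch <- attr(cells, "lateral_pitch")
  if (!isTRUE(all.equal(pitch, disc$lateral_pitch)))
    stop_precondition("cells and disc have different lateral pitches")
  if (!all(dim(cells) == dim(disc$mask)))
    stop_precondition("cells and disc have different shapes")
  tab <- cell_measurements(cells)
  r_px <- disc$diameter_mm * 1000 / (2 * pitch)
  if (nrow(tab) == 0) {
    counted <- tab
  } else if (include == "centroid") {
    inside <- (tab$centroid_row - disc$center[1])^2 +
      (tab$centroid_col - disc$center[2])^2 <= r_px^2
    counted <- tab[inside, , drop = FALSE]
  } else {
    # every pixel of the cell must lie inside the disc
    ok <- vapply(tab$label, function(l) {
      px <- which(unclass(cells) == l)
      all(disc$mask[px])
    }, logical(1))
    counted <- tab[ok, , drop = FALSE]
  }
  a_mm2 <- if (area == "mask") disc$area_mm2 else disc$nominal_area_mm2
  n <- nrow(counted)
  structure(list(n_cells = n,
                 analysis_area_mm2 = a_mm2,
                 ecd_cells_mm2 = n / a_mm2,
                 mean_cell_area_um2 = if (n > 0) mean(counted$area_um2) else NA_real_,
                 cell_area_cv = if (n > 1) sd(counted$area_um2) / mean(counted$area_um2)
                                else NA_real_,
                 morphometry_defined = n > 0,
                 area_mode = area, include_rule = include),
            class = "ecd_report")
}

#' @export
print.ecd_report <- function(x, ...) {
  cat(sprintf("<ecd_report> %d cells / %.4f mm^2 = %.0f cells/mm^2",
              x$n_cells, x$analysis_area_mm2, x$ecd_cells_mm2))
  if (x$morphometry_defined)
    cat(sprintf(" (mean area %.0f um^2, CV %.2f)", x$mean_cell_area_um2,
                x$cell_area_cv))
  cat("\n")
  invisible(x)
}
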