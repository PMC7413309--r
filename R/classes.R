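# Lightweight S3 containers for the pipeline stages.

#' Construct a voxel volume
#'
#' A `voxel_volume` wraps a 3-D intensity array (rows x cols x depth) with its
#' lateral pixel pitch (micrometres per pixel) and axial pitch (micrometres
#' per voxel). Depth index increases towards deeper tissue, so the
#' endothelium is the deepest bright layer.
#'
#' @param intensities nonnegative numeric 3-D array, rows x cols x depth.
#' @param lateral_pitch lateral sampling, um/px (> 0).
#' @param axial_pitch axial sampling, um/voxel (> 0).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(intensities, lateral_pitch = 1, axial_pitch = 1.5) {
  if (length(dim(intensities)) != 3L)
    stop_precondition("intensities must be a 3-D array")
  if (any(intensities < 0)) stop_precondition("intensities must be nonnegative")
  if (lateral_pitch <= 0 || axial_pitch <= 0)
    stop_precondition("pitches must be > 0")
  structure(list(intensities = intensities,
                 lateral_pitch = lateral_pitch,
                 axial_pitch = axial_pitch),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<voxel_volume> %d x %d x %d, %.3g um/px lateral, %.3g um/voxel axial\n",
              d[1], d[2], d[3], x$lateral_pitch, x$axial_pitch))
  invisible(x)
}

#' Construct a binary volume
#'
#' Boolean mask with the same shape as its source volume (the result of
#' thresholding / median filtering).
#'
#' @param mask logical 3-D array.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(mask) {
  if (length(dim(mask)) != 3L || !is.logical(mask))
    stop_precondition("mask must be a logical 3-D array")
  structure(list(mask = mask), class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<binary_volume> %d x %d x %d, %.1f%% foreground\n",
              d[1], d[2], d[3], 100 * mean(x$mask)))
  invisible(x)
}

#' Construct an en-face image
#'
#' A 2-D planar view of the (flattened) endothelium with its lateral pitch.
#'
#' @param intensities numeric matrix.
#' @param lateral_pitch lateral sampling, um/px.
#' @return An object of class `enface_image`.
#' @export
enface_image <- function(intensities, lateral_pitch = 1) {
  if (!is.matrix(intensities)) stop_precondition("intensities must be a matrix")
  if (lateral_pitch <= 0) stop_precondition("lateral_pitch must be > 0")
  structure(list(intensities = intensities, lateral_pitch = lateral_pitch),
            class = "enface_image")
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("<enface_image> %d x %d, %.3g um/px\n",
              nrow(x$intensities), ncol(x$intensities), x$lateral_pitch))
  invisible(x)
}

#' Pixel class codes for three-class labelling
#'
#' Integer codes used in a [pixel_label_map()]: cell border, cell interior,
#' and noise.
#'
#' @return Named integer vector `c(border = 1, interior = 2, noise = 3)`.
#' @export
pixel_classes <- function() c(border = 1L, interior = 2L, noise = 3L)

#' Construct a pixel label map
#'
#' Per-pixel three-class labelling (border / interior / noise) of an en-face
#' image, coded with [pixel_classes()].
#'
#' @param labels integer matrix with values in `pixel_classes()`.
#' @return An object of class `pixel_label_map`.
#' @export
pixel_label_map <- function(labels) {
  if (!is.matrix(labels)) stop_precondition("labels must be a matrix")
  storage.mode(labels) <- "integer"
  if (!all(labels %in% pixel_classes()))
    stop_precondition("labels must be in pixel_classes()")
  structure(labels, class = c("pixel_label_map", "matrix", "array"))
}

#' @export
print.pixel_label_map <- function(x, ...) {
  pc <- pixel_classes()
  cat(sprintf("<pixel_label_map> %d x %d (border %.1f%%, interior %.1f%%, noise %.1f%%)\n",
              nrow(x), ncol(x),
              100 * mean(x == pc["border"]), 100 * mean(x == pc["interior"]),
              100 * mean(x == pc["noise"])))
  invisible(x)
}
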