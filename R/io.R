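# Formats, configuration, and the end-to-end pipeline: simulate -> flatten ->
# segment -> count.

#' Read a multi-page TIFF stack as a voxel volume
#'
#' One page per depth slice; pages must share one shape and be 8- or 16-bit
#' grayscale. Intensities are scaled to [0, 1] (divided by the bit-depth
#' maximum).
#'
#' @param path TIFF file.
#' @param lateral_pitch,axial_pitch sampling, um/px and um/voxel (a sidecar
#'   config, if any, takes precedence over these defaults at the CLI level).
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, lateral_pitch = 1, axial_pitch = 1.5) {
  if (!file.exists(path)) stop_format(sprintf("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d1 <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    di <- dim(pages[[i]])
    if (length(di) != 2)
      stop_format(sprintf("page %d is not single-channel grayscale", i))
    if (!all(di == d1))
      stop_format(sprintf("page %d shape (%d x %d) differs from page 1 (%d x %d)",
                          i, di[1], di[2], d1[1], d1[2]))
  }
  mx <- max(vapply(pages, max, numeric(1)))
  denom <- if (mx > 255) 65535 else 255
  vol <- array(0, c(d1, length(pages)))
  for (i in seq_along(pages)) vol[, , i] <- pages[[i]] / denom
  voxel_volume(vol, lateral_pitch, axial_pitch)
}

#' Write a voxel volume as a multi-page 16-bit TIFF
#'
#' Intensities are clamped to [0, 1] and quantized to 16 bits; values on the
#' 16-bit grid round-trip exactly through [read_volume()].
#'
#' @param vol a [voxel_volume()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  x <- pmin(pmax(vol$intensities, 0), 1)
  pages <- lapply(seq_len(dim(x)[3]), function(z) x[, , z])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write an en-face image (or label map) as a 16-bit TIFF
#'
#' @param img an [enface_image()], or an integer matrix (e.g. a cell label
#'   map), written with values divided by `scale`.
#' @param path output file.
#' @param scale divisor mapping values into [0, 1]; defaults to the image
#'   maximum (or 65535 for integer label maps).
#' @return Invisibly, `path`.
#' @export
write_enface <- function(img, path, scale = NULL) {
  m <- if (inherits(img, "enface_image")) img$intensities else unclass(img)
  attributes(m) <- list(dim = dim(m))
  if (is.null(scale)) scale <- if (is.integer(m)) 65535 else max(m, 1e-12)
  tiff::writeTIFF(pmin(pmax(m / scale, 0), 1), path, bits.per.sample = 16L)
  invisible(path)
}

#' Default pipeline run configuration
#'
#' Collects every stage's parameters with provenance flags distinguishing
#' values taken from the published method ("published") from tool-chosen
#' defaults ("tool"). Serializes losslessly through
#' [write_run_config()] / [read_run_config()]. All stage seeds are derived
#' deterministically from the single top-level `seed`.
#'
#' @param ... overrides of any default field.
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    lateral_pitch = 1,            # um/px; 1-mm^2 field at 1000 px
    axial_pitch = 1.5,            # um/voxel axial sectioning
    blur_sigma = 1,               # voxels
    n_levels = 256L,
    median_radius = 1L,
    ransac_threshold = 2,         # voxels
    ransac_iterations = 500L,
    ransac_min_inlier_fraction = 0.35,
    slab_below = 6L,              # ~9 um of endothelial signal below surface
    slab_above = 1L,
    surface_mode = "deepest",
    backend = "classical",
    min_area = 100L,              # px^2, inclusive
    max_area = 750L,              # px^2, inclusive
    dilate_radius = 2L,
    max_noise_fraction = 0.2,
    disc_diameter_mm = 0.5,
    area_mode = "mask",
    include_rule = "centroid"
  )
  prov <- c(seed = "tool", lateral_pitch = "tool", axial_pitch = "published",
            blur_sigma = "tool", n_levels = "tool", median_radius = "tool",
            ransac_threshold = "tool", ransac_iterations = "tool",
            ransac_min_inlier_fraction = "tool", slab_below = "tool",
            slab_above = "tool", surface_mode = "tool",
            backend = "tool", min_area = "published", max_area = "published",
            dilate_radius = "published", max_noise_fraction = "tool",
            disc_diameter_mm = "published", area_mode = "tool",
            include_rule = "tool")
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop_precondition(paste("unknown config fields:",
                                           paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, provenance = prov, class = "run_config")
}

#' Write a run configuration to YAML
#' @param config a [run_config()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(list(config = unclass(config),
                        provenance = as.list(attr(config, "provenance"))),
                   path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file written by [write_run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y$config)
}

#' Run the full analysis pipeline
#'
#' Chains flattening, pixel classification, post-processing into cells, disc
#' cropping, and ECD computation, either on a volume loaded from disk or on
#' a synthetic phantom generated in place. Any stage failure aborts with the
#' stage name and cause. With the classical backend the run is a pure
#' function of (config, input).
#'
#' @param config a [run_config()].
#' @param input a [voxel_volume()], a `phantom_volume`, a path to a
#'   multi-page TIFF, or a phantom specification list (passed to
#'   [generate_mosaic()] / [generate_volume()]: fields `n_cells`, `height`,
#'   `width`, plus any of their other arguments).
#' @param backend optional pre-built classifier backend overriding
#'   `config$backend` (required for `"cnn"`, which needs a trained model).
#' @param out_dir optional directory; when given, the flattened image, label
#'   maps, per-cell table, report, and a reproducible config snapshot are
#'   written there.
#' @return List of class `pipeline_result`: `report` (an `ecd_report`),
#'   `cells`, `pixel_labels`, `enface`, `surface`, `disc`, `config`, and
#'   `truth` (the phantom's ground truth when the input was synthetic).
#' @export
run_pipeline <- function(config = run_config(), input, backend = NULL,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  seeds <- derive_seeds(config$seed, 3L)
  truth <- NULL

  vol <- stage("input", {
    if (is.character(input)) {
      read_volume(input, config$lateral_pitch, config$axial_pitch)
    } else if (inherits(input, "phantom_volume")) {
      truth <- input$mosaic
      input$volume
    } else if (inherits(input, "voxel_volume")) {
      input
    } else if (is.list(input)) {
      spec <- input
      mosaic_args <- spec[intersect(names(spec),
                                    names(formals(generate_mosaic)))]
      if (is.null(mosaic_args$lateral_pitch))
        mosaic_args$lateral_pitch <- config$lateral_pitch
      if (is.null(mosaic_args$rng_seed)) mosaic_args$rng_seed <- seeds[1]
      mosaic <- do.call(generate_mosaic, mosaic_args)
      vol_args <- spec[intersect(names(spec), names(formals(generate_volume)))]
      vol_args$mosaic <- mosaic
      if (is.null(vol_args$surface))
        vol_args$surface <- dome_surface(dim(mosaic$cell_label_map),
                                         apex_depth = 20, sag = 15)
      if (is.null(vol_args$axial_pitch)) vol_args$axial_pitch <- config$axial_pitch
      if (is.null(vol_args$rng_seed)) vol_args$rng_seed <- seeds[2]
      ph <- do.call(generate_volume, vol_args)
      truth <- ph$mosaic
      ph$volume
    } else {
      stop_precondition("unsupported input type")
    }
  })

  flat <- stage("flatten", flatten_endothelium(
    vol, sigma = config$blur_sigma, n_levels = config$n_levels,
    median_radius = config$median_radius,
    inlier_threshold = config$ransac_threshold,
    max_iterations = config$ransac_iterations,
    min_inlier_fraction = config$ransac_min_inlier_fraction,
    slab_below = config$slab_below, slab_above = config$slab_above,
    surface_mode = config$surface_mode, rng_seed = seeds[3]))

  if (is.null(backend)) {
    backend <- stage("backend", switch(config$backend,
      classical = classical_backend(),
      cnn = stop_precondition("cnn backend requires a trained model via `backend`"),
      stop_precondition(sprintf("unknown backend '%s'", config$backend))))
  }
  labels <- stage("classify", classify_pixels(flat$enface, backend))
  cells <- stage("postprocess", postprocess_to_cells(
    labels, min_area = config$min_area, max_area = config$max_area,
    dilate_radius = config$dilate_radius,
    max_noise_fraction = config$max_noise_fraction,
    lateral_pitch = vol$lateral_pitch))
  disc <- stage("crop", crop_central_disc(flat$enface, config$disc_diameter_mm))
  report <- stage("count", compute_ecd(cells, disc, area = config$area_mode,
                                       include = config$include_rule))

  result <- structure(list(report = report, cells = cells,
                           pixel_labels = labels, enface = flat$enface,
                           surface = flat$surface, disc = disc,
                           config = config, truth = truth),
                      class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_enface(flat$enface, file.path(out_dir, "enface.tiff"))
    write_enface(matrix(as.integer(labels), nrow(labels)),
                 file.path(out_dir, "pixel_labels.tiff"), scale = 65535)
    write_enface(cells, file.path(out_dir, "cells.tiff"), scale = 65535)
    write.csv(cell_measurements(cells), file.path(out_dir, "cells.csv"),
              row.names = FALSE)
    write.csv(data.frame(coefficient = names(flat$surface$coefficients),
                         value = as.numeric(flat$surface$coefficients)),
              file.path(out_dir, "surface.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(n_cells = report$n_cells,
           analysis_area_mm2 = report$analysis_area_mm2,
           ecd_cells_mm2 = report$ecd_cells_mm2,
           mean_cell_area_um2 = report$mean_cell_area_um2,
           cell_area_cv = report$cell_area_cv,
           surface_rmse_voxels = flat$surface$rmse,
           surface_inliers = length(flat$surface$inlier_indices),
           huang_threshold = flat$threshold),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    write_run_config(config, file.path(out_dir, "config.yml"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$report)
  if (!is.null(x$truth))
    cat(sprintf("  phantom truth: %.0f cells/mm^2\n", x$truth$true_ecd))
  invisible(x)
}

#' Write a phantom volume and its ground truth to a directory
#'
#' Writes the volume (multi-page 16-bit TIFF), the cell label map (16-bit
#' TIFF), the ground truth (seed points and per-cell areas as CSV), and a
#' sidecar YAML capturing all generation parameters and the seed.
#'
#' @param phantom a `phantom_volume` from [generate_volume()].
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(phantom$volume, file.path(dir, "volume.tiff"))
  write_enface(phantom$mosaic$cell_label_map, file.path(dir, "cell_labels.tiff"),
               scale = 65535)
  write.csv(data.frame(cell = seq_len(nrow(phantom$mosaic$seed_points)),
                       seed_row = phantom$mosaic$seed_points[, 1],
                       seed_col = phantom$mosaic$seed_points[, 2]),
            file.path(dir, "seed_points.csv"), row.names = FALSE)
  areas <- tabulate(phantom$mosaic$cell_label_map[phantom$mosaic$cell_label_map > 0])
  write.csv(data.frame(cell = seq_along(areas), area_px2 = areas),
            file.path(dir, "cell_areas.csv"), row.names = FALSE)
  p <- phantom$params
  yaml::write_yaml(list(
    n_cells = phantom$mosaic$n_cells,
    height = nrow(phantom$mosaic$cell_label_map),
    width = ncol(phantom$mosaic$cell_label_map),
    lateral_pitch = phantom$mosaic$lateral_pitch,
    border_width = phantom$mosaic$border_width,
    relax = phantom$mosaic$relax,
    mosaic_seed = phantom$mosaic$rng_seed,
    true_ecd = phantom$mosaic$true_ecd,
    depth = p$depth, axial_pitch = p$axial_pitch, noise_sd = p$noise_sd,
    vignette_strength = p$vignette_strength,
    fold_spec = if (is.null(p$fold_spec)) NULL else as.list(p$fold_spec),
    volume_seed = p$rng_seed,
    surface = as.list(p$surface)),
    file.path(dir, "phantom.yml"))
  invisible(dir)
}
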