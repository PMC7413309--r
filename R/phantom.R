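# Synthetic corneal phantoms: Voronoi cell mosaics and curved volumes with
# exact ground truth, so every downstream stage is testable without real data.

# Exact nearest-seed assignment for every pixel centre (Voronoi
# rasterization), chunked to bound memory.
assign_nearest_seed <- function(seeds, height, width, chunk = 250000L) {
  n_px <- height * width
  lab <- integer(n_px)
  cl <- factor(seq_len(nrow(seeds)))
  rows <- rep(seq_len(height), times = width)
  cols <- rep(seq_len(width), each = height)
  for (start in seq(1L, n_px, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_px)
    lab[idx] <- as.integer(class::knn1(seeds, cbind(rows[idx], cols[idx]), cl))
  }
  matrix(lab, height, width)
}

# Per-label centroids as an n-row matrix; labels with no pixels yield NA rows.
region_centroids <- function(label_map, n) {
  idx <- which(label_map > 0L)
  lab <- label_map[idx]
  h <- nrow(label_map)
  r <- ((idx - 1L) %% h) + 1L
  c <- ((idx - 1L) %/% h) + 1L
  cnt <- tabulate(lab, n)
  present <- sort(unique(lab))
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("row", "col")))
  out[present, 1] <- as.numeric(rowsum(r, lab, reorder = TRUE)) / cnt[present]
  out[present, 2] <- as.numeric(rowsum(c, lab, reorder = TRUE)) / cnt[present]
  out
}

# Pixels having a 4-neighbour with a different label: a 2-px band straddling
# every Voronoi edge.
label_edges4 <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  e <- matrix(FALSE, h, w)
  dif <- lab[-h, ] != lab[-1, ]
  e[-h, ][dif] <- TRUE; e[-1, ][dif] <- TRUE
  dif <- lab[, -w] != lab[, -1]
  e[, -w][dif] <- TRUE; e[, -1][dif] <- TRUE
  e
}

#' Generate a synthetic endothelial cell mosaic with ground truth
#'
#' Builds a Voronoi tessellation of randomly placed seed points on a pixel
#' grid, marks pixels near inter-cell boundaries as border, and records exact
#' ground truth: the integer cell label map, the border mask, the seed
#' points, and the true endothelial cell density (ECD) on a central analysis
#' disc.
#'
#' Seeds are drawn uniformly and then regularized by `relax` Lloyd
#' (centroidal-Voronoi) iterations. Healthy corneal endothelium is a
#' near-hexagonal mosaic with a cell-area coefficient of variation around
#' 0.3-0.4; two relaxation steps reproduce that regularity, while `relax = 0`
#' keeps the raw uniform (Poisson-Voronoi) tessellation with its much heavier
#' area tails.
#'
#' @param n_cells number of cells (seed points), >= 1.
#' @param height,width image size in pixels, >= 32.
#' @param lateral_pitch lateral sampling, um/px.
#' @param border_width width of the dark border band between cells, px (>= 1).
#' @param relax number of Lloyd relaxation iterations (0 = uniform seeds).
#' @param rng_seed integer seed; identical inputs reproduce the mosaic
#'   bit-for-bit.
#' @param ecd_disc_mm diameter (mm) of the central disc on which `true_ecd`
#'   is computed; shrunk automatically if the field is smaller.
#' @return An object of class `mosaic_truth` with fields `cell_label_map`
#'   (0 = border, k >= 1 = cell k), `border_map`, `seed_points`, `true_ecd`
#'   (cells/mm^2), `true_ecd_disc_mm`, `lateral_pitch`, `n_cells`,
#'   `border_width`, `rng_seed`.
#' @examples
#' m <- generate_mosaic(60, 128, 128, rng_seed = 1)
#' table(m$cell_label_map > 0)
#' @export
generate_mosaic <- function(n_cells, height, width, lateral_pitch = 1,
                            border_width = 2, relax = 2, rng_seed = 1,
                            ecd_disc_mm = 0.5) {
  if (n_cells < 1) stop_precondition("n_cells must be >= 1")
  if (height < 32 || width < 32) stop_precondition("height and width must be >= 32")
  if (border_width < 1) stop_precondition("border_width must be >= 1")
  if (n_cells > height * width)
    stop_precondition(sprintf("n_cells (%d) exceeds the pixel grid (%d x %d)",
                              n_cells, height, width))

  # the whole construction runs under one seeded RNG state: knn1 breaks
  # near-ties randomly, so the assignment itself must be seeded too
  gen <- withr::with_seed(as.integer(rng_seed), {
    seeds <- cbind(runif(n_cells) * height, runif(n_cells) * width)
    while (anyDuplicated(seeds)) {
      dup <- duplicated(seeds)
      seeds[dup, ] <- cbind(runif(sum(dup)) * height,
                            runif(sum(dup)) * width)
    }
    if (n_cells == 1L) {
      lab <- matrix(1L, height, width)
      border <- matrix(FALSE, height, width)
    } else {
      lab <- assign_nearest_seed(seeds, height, width)
      for (i in seq_len(relax)) {
        cents <- region_centroids(lab, n_cells)
        keep <- !is.na(cents[, 1])
        seeds[keep, ] <- cents[keep, ]
        lab <- assign_nearest_seed(seeds, height, width)
      }
      border <- label_edges4(lab)
      if (border_width > 2) {
        # grow the 2-px edge band out to the requested width
        d <- EBImage::distmap(1 - border)
        border <- d <= (border_width - 2) / 2
      }
    }
    list(seeds = seeds, lab = lab, border = border)
  })
  seeds <- gen$seeds
  lab <- gen$lab
  border <- gen$border

  cells <- lab
  cells[border] <- 0L

  out <- structure(list(cell_label_map = cells,
                        border_map = border,
                        seed_points = seeds,
                        true_ecd = NA_real_,
                        true_ecd_disc_mm = NA_real_,
                        lateral_pitch = lateral_pitch,
                        n_cells = n_cells,
                        border_width = border_width,
                        relax = relax,
                        rng_seed = as.integer(rng_seed)),
                   class = "mosaic_truth")
  ecd <- mosaic_true_ecd(out, disc_diameter_mm = ecd_disc_mm)
  out$true_ecd <- ecd$ecd
  out$true_ecd_disc_mm <- ecd$disc_mm
  out
}

#' Recompute the true ECD of a mosaic on a central disc
#'
#' Counts ground-truth cells whose centroid lies inside a centred analysis
#' disc and divides by the disc mask area in mm^2. Used both to populate
#' `true_ecd` at generation time and to verify it later.
#'
#' @param mosaic a `mosaic_truth`.
#' @param disc_diameter_mm requested disc diameter (mm); shrunk to fit the
#'   field if necessary.
#' @return List with `ecd` (cells/mm^2), `n_cells`, `area_mm2`, `disc_mm`.
#' @export
mosaic_true_ecd <- function(mosaic, disc_diameter_mm = 0.5) {
  h <- nrow(mosaic$cell_label_map); w <- ncol(mosaic$cell_label_map)
  pitch <- mosaic$lateral_pitch
  max_mm <- (min(h, w) - 1) * pitch / 1000
  disc_mm <- min(disc_diameter_mm, max_mm)
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  r_px <- disc_mm * 1000 / (2 * pitch)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  mask <- (rows - ctr[1])^2 + (cols - ctr[2])^2 <= r_px^2
  area_mm2 <- sum(mask) * pitch^2 * 1e-6
  cents <- region_centroids(mosaic$cell_label_map, mosaic$n_cells)
  inside <- (cents[, 1] - ctr[1])^2 + (cents[, 2] - ctr[2])^2 <= r_px^2
  n_in <- sum(inside, na.rm = TRUE)
  list(ecd = n_in / area_mm2, n_cells = n_in, area_mm2 = area_mm2,
       disc_mm = disc_mm)
}

#' @export
print.mosaic_truth <- function(x, ...) {
  cat(sprintf("<mosaic_truth> %d x %d px, %d cells, true ECD %.0f cells/mm^2 (%.2g-mm disc)\n",
              nrow(x$cell_label_map), ncol(x$cell_label_map), x$n_cells,
              x$true_ecd, x$true_ecd_disc_mm))
  invisible(x)
}

#' Quadric surface coefficients
#'
#' Convenience constructor for the height function
#' `z(x, y) = c0 + c1 x + c2 y + c3 x^2 + c4 x y + c5 y^2` (x = column,
#' y = row, in px; z in voxels) used by the phantom generator and the RANSAC
#' fitter.
#'
#' @param c0,c1,c2,c3,c4,c5 coefficients.
#' @return Named numeric vector of length 6.
#' @export
quadric_coefficients <- function(c0, c1 = 0, c2 = 0, c3 = 0, c4 = 0, c5 = 0) {
  c(c0 = c0, c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5)
}

#' Dome (paraboloid) surface coefficients for a field of given size
#'
#' Builds quadric coefficients for a rotationally symmetric paraboloid with
#' its apex at the field centre at depth `apex_depth` voxels and sagging by
#' `sag` voxels at the field corners -- the second-order approximation of the
#' curved corneal endothelium over a small field.
#'
#' @param dims `c(rows, cols)` of the lateral field.
#' @param apex_depth depth of the apex at the field centre, voxels.
#' @param sag additional depth at the field corners, voxels.
#' @return Quadric coefficients (see [quadric_coefficients()]).
#' @export
dome_surface <- function(dims, apex_depth = 20, sag = 15) {
  cy <- (dims[1] + 1) / 2
  cx <- (dims[2] + 1) / 2
  a <- sag / ((cx - 1)^2 + (cy - 1)^2)
  quadric_coefficients(c0 = apex_depth + a * (cx^2 + cy^2),
                       c1 = -2 * a * cx, c2 = -2 * a * cy,
                       c3 = a, c4 = 0, c5 = a)
}

eval_quadric <- function(coef, x, y) {
  coef[1] + coef[2] * x + coef[3] * y + coef[4] * x^2 + coef[5] * x * y +
    coef[6] * y^2
}

#' Generate a phantom corneal volume around a mosaic
#'
#' Paints a bright, thin endothelial shell (hyper-reflective cell interiors,
#' dimmer borders) onto a curved height surface inside a voxel volume, with
#' dimmer stroma above, a dark posterior chamber below, additive Gaussian
#' noise, radial peripheral intensity falloff (vignetting), and optional dark
#' fold bands. All intensities are relative (cell interior = 1 at the field
#' centre).
#'
#' @param mosaic a `mosaic_truth` supplying the cell pattern and pitch.
#' @param surface quadric coefficients (see [quadric_coefficients()]) giving
#'   the endothelial depth in voxels as a function of (x = col, y = row), or
#'   a precomputed height matrix.
#' @param depth volume depth in voxels.
#' @param axial_pitch axial sampling, um/voxel.
#' @param noise_sd additive Gaussian noise standard deviation (relative
#'   intensity units; the shell signal-to-noise ratio is `1 / noise_sd`).
#' @param vignette_strength 0-1; corner attenuation factor is
#'   `1 - vignette_strength`.
#' @param fold_spec optional data frame of dark fold bands with columns
#'   `center` (px along the band normal), `width` (px), `attenuation` (0-1),
#'   and optionally `angle_deg` (band normal direction; 0 = bands of constant
#'   column).
#' @param rng_seed integer seed; identical parameters and seed reproduce the
#'   volume bit-for-bit.
#' @param intensity relative intensities of the tissue compartments.
#' @param shell_profile axial intensity profile of the shell over depths
#'   `h - 1, h, h + 1`; the centre value must be the unique maximum so the
#'   noiseless per-column argmax equals the stored surface height.
#' @return An object of class `phantom_volume` with fields `volume`
#'   (a [voxel_volume()]), `surface_height` (integer matrix of painted shell
#'   depths), `mosaic`, and `params`.
#' @export
generate_volume <- function(mosaic, surface, depth = 48, axial_pitch = 1.5,
                            noise_sd = 0.1, vignette_strength = 0.3,
                            fold_spec = NULL, rng_seed = 1,
                            intensity = list(interior = 1, border = 0.45,
                                             stroma = 0.25, posterior = 0.05),
                            shell_profile = c(0.85, 1, 0.85)) {
  h <- nrow(mosaic$cell_label_map); w <- ncol(mosaic$cell_label_map)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  if (is.matrix(surface)) {
    H <- round(surface)
  } else {
    H <- round(eval_quadric(surface, x = cols, y = rows))
  }
  storage.mode(H) <- "integer"
  if (min(H) < 2L || max(H) > depth - 1L)
    stop(structure(class = c("ecdquant_geometry_error", "error", "condition"),
                   list(message = sprintf(
                     "surface height range [%d, %d] exits the paintable depth range [2, %d]",
                     min(H), max(H), depth - 1L), call = sys.call())))

  cell_int <- matrix(intensity$interior, h, w)
  cell_int[mosaic$border_map] <- intensity$border

  # lateral attenuation: vignetting (quadratic radial falloff) and folds
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  d2 <- (rows - ctr[1])^2 + (cols - ctr[2])^2
  atten <- 1 - vignette_strength * d2 / max(d2)
  if (!is.null(fold_spec) && nrow(fold_spec) > 0) {
    for (i in seq_len(nrow(fold_spec))) {
      ang <- if ("angle_deg" %in% names(fold_spec)) fold_spec$angle_deg[i] else 0
      u <- cols * cos(ang * pi / 180) + rows * sin(ang * pi / 180)
      inband <- abs(u - fold_spec$center[i]) <= fold_spec$width[i] / 2
      atten[inband] <- atten[inband] * (1 - fold_spec$attenuation[i])
    }
  }

  vol <- array(0, c(h, w, depth))
  for (z in seq_len(depth)) {
    slice <- matrix(0, h, w)
    slice[z < H - 1L] <- intensity$stroma
    slice[z > H + 1L] <- intensity$posterior
    for (k in -1:1) {
      sel <- H == z - k   # this z sits k voxels from the shell centre
      if (any(sel)) slice[sel] <- shell_profile[k + 2] * cell_int[sel]
    }
    vol[, , z] <- slice * atten
  }

  if (noise_sd > 0) {
    vol <- vol + withr::with_seed(as.integer(rng_seed),
                                  array(rnorm(length(vol), sd = noise_sd), dim(vol)))
    vol[vol < 0] <- 0
  }

  structure(list(volume = voxel_volume(vol, mosaic$lateral_pitch, axial_pitch),
                 surface_height = H,
                 mosaic = mosaic,
                 params = list(depth = depth, axial_pitch = axial_pitch,
                               noise_sd = noise_sd,
                               vignette_strength = vignette_strength,
                               fold_spec = fold_spec,
                               rng_seed = as.integer(rng_seed),
                               intensity = intensity,
                               shell_profile = shell_profile,
                               surface = if (is.matrix(surface)) NULL else surface)),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  d <- dim(x$volume$intensities)
  cat(sprintf("<phantom_volume> %d x %d x %d, shell depth %d-%d, noise sd %.3g, vignette %.2g\n",
              d[1], d[2], d[3], min(x$surface_height), max(x$surface_height),
              x$params$noise_sd, x$params$vignette_strength))
  invisible(x)
}

#' Ground-truth three-class label map of a mosaic
#'
#' Converts a mosaic's exact geometry into a [pixel_label_map()] (border
#' pixels -> border class, cell pixels -> interior class), e.g. for training
#' or scoring pixel classifiers.
#'
#' @param mosaic a `mosaic_truth`.
#' @return A `pixel_label_map`.
#' @export
mosaic_label_map <- function(mosaic) {
  pc <- pixel_classes()
  lab <- matrix(pc[["interior"]], nrow(mosaic$cell_label_map),
                ncol(mosaic$cell_label_map))
  lab[mosaic$border_map] <- pc[["border"]]
  pixel_label_map(lab)
}

#' Noise-free en-face view of a mosaic
#'
#' Renders the mosaic as a flat en-face image using the phantom's relative
#' intensities (no curvature, noise, or vignetting) -- the idealized product
#' of a perfect flattening stage.
#'
#' @param mosaic a `mosaic_truth`.
#' @param interior,border relative intensities.
#' @return An [enface_image()].
#' @export
mosaic_enface <- function(mosaic, interior = 1, border = 0.45) {
  img <- matrix(interior, nrow(mosaic$cell_label_map), ncol(mosaic$cell_label_map))
  img[mosaic$border_map] <- border
  enface_image(img, mosaic$lateral_pitch)
}
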