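# Digital flattening of the curved endothelial layer inside a 3-D volume:
# blur -> Huang binarization -> majority (median) filtering -> RANSAC quadric
# surface fit -> max-intensity projection of a thin slab below the surface.

#' 3-D Gaussian blur of a voxel volume
#'
#' Separable Gaussian smoothing along all three axes with replicate boundary
#' handling; the sampled kernel is truncated at `ceiling(4 * sigma)` samples.
#' `sigma = 0` returns the input unchanged.
#'
#' @param vol a [voxel_volume()].
#' @param sigma standard deviation in voxels (>= 0).
#' @return A smoothed `voxel_volume` of identical shape.
#' @export
gaussian_blur <- function(vol, sigma = 1) {
  if (sigma < 0) stop_precondition("sigma must be >= 0")
  if (sigma == 0) return(vol)
  voxel_volume(blur_array(vol$intensities, sigma), vol$lateral_pitch,
               vol$axial_pitch)
}

#' Huang fuzzy threshold of a gray-level histogram
#'
#' Finds the gray level `t` minimizing the total fuzziness
#' `S(t) = sum_g h(g) * Hf(mu_t(g))`, where the membership
#' `mu_t(g) = 1 / (1 + |g - m(g, t)| / C)` measures how close `g` lies to the
#' mean `m(g, t)` of its side of the threshold (levels `<= t` vs `> t`),
#' `C = g_max - g_min`, and `Hf` is the Shannon binary entropy (natural log,
#' with `Hf(0) = Hf(1) = 0`). The smallest minimizer wins ties. The paired
#' binarization rule is `intensity > t` (see [binarize()]).
#'
#' @param counts histogram counts per gray level.
#' @param levels gray-level values (increasing), same length as `counts`.
#' @return The threshold as an element of `levels`.
#' @export
huang_threshold <- function(counts, levels = seq_along(counts) - 1) {
  if (length(counts) != length(levels))
    stop_precondition("counts and levels must have equal length")
  if (is.unsorted(levels, strictly = TRUE))
    stop_precondition("levels must be strictly increasing")
  nz <- which(counts > 0)
  if (length(nz) < 2)
    stop_precondition("histogram must have at least 2 nonempty levels")
  C <- levels[max(nz)] - levels[min(nz)]
  csum <- cumsum(counts)
  cwsum <- cumsum(counts * levels)
  n_tot <- csum[length(csum)]
  w_tot <- cwsum[length(cwsum)]

  hf <- function(mu) {
    e <- numeric(length(mu))
    inner <- mu > 0 & mu < 1
    m <- mu[inner]
    e[inner] <- -m * log(m) - (1 - m) * log1p(-m)
    e
  }

  best_s <- Inf
  best_t <- NA_real_
  for (ti in min(nz):(max(nz) - 1L)) {
    m0 <- cwsum[ti] / csum[ti]
    m1 <- (w_tot - cwsum[ti]) / (n_tot - csum[ti])
    lo <- seq_len(ti)
    hi <- (ti + 1L):length(levels)
    mu <- c(1 / (1 + abs(levels[lo] - m0) / C),
            1 / (1 + abs(levels[hi] - m1) / C))
    s <- sum(counts * hf(mu))
    if (s < best_s) {
      best_s <- s
      best_t <- levels[ti]
    }
  }
  best_t
}

#' Huang threshold of a volume's intensity histogram
#'
#' Quantizes the volume's intensities into `n_levels` equal-width bins over
#' their range (matching the native bit depth when intensities are already
#' integer-coded) and applies [huang_threshold()]; the returned threshold is
#' on the intensity scale.
#'
#' @param vol a [voxel_volume()].
#' @param n_levels number of histogram levels.
#' @return Intensity threshold (a bin centre).
#' @export
huang_threshold_volume <- function(vol, n_levels = 256) {
  x <- vol$intensities
  rng <- range(x)
  if (rng[1] == rng[2])
    stop_precondition("volume has a single intensity level; no threshold exists")
  width <- diff(rng) / n_levels
  bin <- pmin(floor((x - rng[1]) / width), n_levels - 1)
  counts <- tabulate(bin + 1L, n_levels)
  centers <- rng[1] + (seq_len(n_levels) - 0.5) * width
  huang_threshold(counts, centers)
}

#' Binarize a volume at a threshold
#'
#' @param vol a [voxel_volume()].
#' @param t gray-level threshold; the mask is `intensity > t`.
#' @return A [binary_volume()].
#' @export
binarize <- function(vol, t) {
  binary_volume(vol$intensities > t)
}

#' Majority (median) filter of a binary volume
#'
#' Replaces each voxel by the majority value in its `(2r+1)^3` neighbourhood
#' (nearest-edge replication at boundaries), removing salt-and-pepper
#' singletons introduced by binarization. The neighbourhood has odd size, so
#' no ties occur.
#'
#' @param bin a [binary_volume()].
#' @param radius neighbourhood radius in voxels (>= 1).
#' @return A filtered `binary_volume`.
#' @export
median_filter <- function(bin, radius = 1) {
  if (radius < 1) stop_precondition("radius must be >= 1")
  m <- bin$mask
  d <- dim(m)
  acc <- array(0L, d)
  offs <- -radius:radius
  cnt <- array(0, d)
  storage.mode(m) <- "integer"
  # separable running sums with replicate padding
  for (ax in 1:3) {
    acc <- array(0L, d)
    n <- d[ax]
    base <- seq_len(n)
    for (o in offs) {
      idx <- pmin(pmax(base + o, 1L), n)
      acc <- acc + switch(ax, m[idx, , , drop = FALSE],
                          m[, idx, , drop = FALSE], m[, , idx, drop = FALSE])
    }
    m <- acc
  }
  k <- (2 * radius + 1)^3
  binary_volume(m > k / 2)
}

#' Extract endothelial surface candidate points from a binary volume
#'
#' For each lateral position with at least one foreground voxel, emits the
#' deepest (largest z) foreground voxel -- the endothelium is the
#' posterior-most bright layer. Positions with no foreground voxel are
#' omitted. `mode = "shallowest"` selects the anterior surface instead.
#'
#' @param bin a [binary_volume()].
#' @param mode `"deepest"` (endothelium, default) or `"shallowest"`.
#' @return Data frame with columns `x` (column, px), `y` (row, px),
#'   `z` (depth, voxels); zero rows if the mask is empty.
#' @export
extract_surface_candidates <- function(bin, mode = c("deepest", "shallowest")) {
  mode <- match.arg(mode)
  m <- bin$mask
  d <- dim(m)
  zbest <- matrix(NA_integer_, d[1], d[2])
  zs <- if (mode == "deepest") seq_len(d[3]) else rev(seq_len(d[3]))
  for (z in zs) {
    sel <- m[, , z]
    zbest[sel] <- z
  }
  idx <- which(!is.na(zbest))
  if (length(idx) == 0)
    return(data.frame(x = integer(), y = integer(), z = integer()))
  y <- ((idx - 1L) %% d[1]) + 1L
  x <- ((idx - 1L) %/% d[1]) + 1L
  data.frame(x = x, y = y, z = zbest[idx])
}

quadric_design <- function(x, y) cbind(1, x, y, x^2, x * y, y^2)

#' Robust RANSAC fit of a quadric height surface
#'
#' Repeatedly samples 6 candidate points (the minimal set for the bivariate
#' quadric `z(x, y) = c0 + c1 x + c2 y + c3 x^2 + c4 x y + c5 y^2`), solves
#' the least-squares system, and counts candidates within `inlier_threshold`
#' voxels of the model. The consensus-maximal model is refit by least squares
#' on its inliers. Degenerate (rank-deficient) samples are skipped. Fails
#' with a fit-failure condition if the best consensus falls below
#' `min_inlier_fraction`.
#'
#' @param points data frame with columns `x`, `y` (px) and `z` (voxels), as
#'   produced by [extract_surface_candidates()]; at least 6 rows.
#' @param inlier_threshold absolute residual bound for inliers, voxels.
#' @param max_iterations number of random minimal samples.
#' @param min_inlier_fraction minimum acceptable inlier fraction.
#' @param rng_seed integer seed; the fit is deterministic given the seed.
#' @return An object of class `surface_model`: `coefficients` (c0..c5),
#'   `inlier_threshold`, `inlier_indices` (rows of `points` within threshold
#'   of the refit model), `n_points`, `rmse` (over inliers), `rng_seed`.
#' @export
ransac_fit_surface <- function(points, inlier_threshold = 2,
                               max_iterations = 500,
                               min_inlier_fraction = 0.35, rng_seed = 1) {
  n <- nrow(points)
  if (is.null(n) || n < 6)
    stop_precondition("at least 6 candidate points are required for a quadric fit")
  X <- quadric_design(points$x, points$y)
  z <- points$z

  best_count <- -1L
  best_beta <- NULL
  withr::with_seed(as.integer(rng_seed), {
    for (it in seq_len(max_iterations)) {
      s <- sample.int(n, 6L)
      qr_s <- qr(X[s, , drop = FALSE])
      if (qr_s$rank < 6L) next
      beta <- qr.coef(qr_s, z[s])
      resid <- abs(X %*% beta - z)
      cnt <- sum(resid <= inlier_threshold)
      if (cnt > best_count) {
        best_count <- cnt
        best_beta <- beta
      }
    }
  })

  if (is.null(best_beta) || best_count / n < min_inlier_fraction)
    stop_fit_failure(sprintf(
      "surface consensus too low: best inlier fraction %.3f < %.3f",
      max(best_count, 0) / n, min_inlier_fraction))

  # final refit on the consensus set
  inl <- which(abs(X %*% best_beta - z) <= inlier_threshold)
  beta <- qr.coef(qr(X[inl, , drop = FALSE]), z[inl])
  resid <- X %*% beta - z
  inl <- which(abs(resid) <= inlier_threshold)
  names(beta) <- paste0("c", 0:5)
  structure(list(coefficients = beta,
                 inlier_threshold = inlier_threshold,
                 inlier_indices = inl,
                 n_points = n,
                 rmse = sqrt(mean(resid[inl]^2)),
                 rng_seed = as.integer(rng_seed)),
            class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("<surface_model> z(x,y) quadric, %d/%d inliers (thr %.2g voxels), RMSE %.3g\n",
              length(x$inlier_indices), x$n_points, x$inlier_threshold, x$rmse))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Evaluate a fitted surface over a pixel grid
#'
#' @param object a `surface_model`.
#' @param x,y vectors or matrices of column / row coordinates (px). If both
#'   are missing, supply `dims = c(rows, cols)` to evaluate on the full grid.
#' @param dims optional `c(rows, cols)` for full-grid evaluation.
#' @param ... unused.
#' @return Predicted depths (voxels), matching the shape of `x`/`y` or a
#'   `dims` matrix.
#' @export
predict.surface_model <- function(object, x, y, dims = NULL, ...) {
  if (!is.null(dims)) {
    y <- matrix(seq_len(dims[1]), dims[1], dims[2])
    x <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  }
  z <- eval_quadric(object$coefficients, x, y)
  if (is.matrix(x)) matrix(z, nrow(x), ncol(x)) else as.numeric(z)
}

#' Flatten a volume to an en-face image by slab max-intensity projection
#'
#' For each lateral position, takes the maximum intensity over the depth
#' interval from `slab_above` voxels above to `slab_below` voxels below the
#' fitted surface (clipped to the volume). The one-voxel margin above and the
#' slab below absorb residual surface-estimation error while capturing the
#' full axial extent of the endothelial signal.
#'
#' @param vol a [voxel_volume()].
#' @param surface a `surface_model`, or a height matrix (voxels) matching the
#'   lateral shape.
#' @param slab_below voxels below the surface included in the projection
#'   (>= 1).
#' @param slab_above voxels above the surface included (default 1).
#' @return An [enface_image()]; attribute `source_depth` holds the depth at
#'   which each pixel's maximum was found (NA where the slab misses the
#'   volume entirely).
#' @export
flatten_to_enface <- function(vol, surface, slab_below = 6, slab_above = 1) {
  if (slab_below < 1) stop_precondition("slab_below must be >= 1")
  d <- dim(vol$intensities)
  zhat <- if (is.matrix(surface)) surface
          else predict(surface, dims = d[1:2])
  zc <- round(zhat)
  lo <- zc - slab_above
  hi <- zc + slab_below
  if (all(hi < 1) || all(lo > d[3]))
    stop(structure(class = c("ecdquant_geometry_error", "error", "condition"),
                   list(message = "fitted surface lies entirely outside the depth range",
                        call = sys.call())))
  img <- matrix(-Inf, d[1], d[2])
  src <- matrix(NA_integer_, d[1], d[2])
  for (z in seq_len(d[3])) {
    in_slab <- lo <= z & z <= hi
    if (!any(in_slab)) next
    slice <- vol$intensities[, , z]
    upd <- in_slab & slice > img
    img[upd] <- slice[upd]
    src[upd] <- z
  }
  img[!is.finite(img)] <- 0
  out <- enface_image(img, vol$lateral_pitch)
  attr(out, "source_depth") <- src
  out
}

#' Per-column argmax flattening (1-D baseline)
#'
#' The historical 1-D approach: each lateral position is assigned the depth
#' of its own intensity maximum, with no spatial model. Provided as a
#' baseline; on volumes with folds or noise it produces line discontinuities
#' that the 3-D surface-fit approach avoids.
#'
#' @param vol a [voxel_volume()].
#' @return An [enface_image()] of per-column maxima; attribute
#'   `source_depth` holds the per-column argmax depths.
#' @export
flatten_argmax <- function(vol) {
  d <- dim(vol$intensities)
  img <- matrix(-Inf, d[1], d[2])
  src <- matrix(NA_integer_, d[1], d[2])
  for (z in seq_len(d[3])) {
    slice <- vol$intensities[, , z]
    upd <- slice > img
    img[upd] <- slice[upd]
    src[upd] <- z
  }
  out <- enface_image(img, vol$lateral_pitch)
  attr(out, "source_depth") <- src
  out
}

#' Count depth discontinuities in a flattened image's source-depth map
#'
#' Counts 4-neighbour pixel pairs whose projection source depths differ by
#' more than `min_jump` voxels -- the quantitative signature of the line
#' artifacts produced by 1-D flattening.
#'
#' @param depth integer matrix of source depths (attribute `source_depth` of
#'   a flattened image), NAs ignored.
#' @param min_jump discontinuity threshold in voxels.
#' @return Number of discontinuous 4-neighbour pairs.
#' @export
count_depth_discontinuities <- function(depth, min_jump = 2) {
  h <- nrow(depth); w <- ncol(depth)
  dv <- abs(depth[-h, ] - depth[-1, ])
  dh <- abs(depth[, -w] - depth[, -1])
  sum(dv > min_jump, na.rm = TRUE) + sum(dh > min_jump, na.rm = TRUE)
}

#' Full endothelium flattening pipeline
#'
#' Chains the five flattening steps: Gaussian blur, Huang binarization,
#' majority filtering, deepest-voxel candidate extraction with RANSAC quadric
#' fitting, and slab max-intensity projection. The projection reads from the
#' original (unblurred) volume so the en-face cell contrast is not degraded;
#' the blurred copy drives only the surface estimation.
#'
#' @param vol a [voxel_volume()].
#' @param sigma Gaussian blur standard deviation, voxels.
#' @param n_levels histogram levels for the Huang threshold.
#' @param median_radius majority-filter radius, voxels.
#' @param inlier_threshold,max_iterations,min_inlier_fraction RANSAC
#'   parameters (see [ransac_fit_surface()]).
#' @param slab_below,slab_above projection slab, voxels.
#' @param surface_mode candidate rule, `"deepest"` (endothelium) or
#'   `"shallowest"`.
#' @param recenter when `TRUE` (default), the fitted surface is shifted by
#'   the median per-column offset between it and the local axial intensity
#'   peak (searched within `recenter_range` voxels), so the projection slab
#'   is centred on the endothelial signal rather than on the binarized
#'   layer's boundary, which sits a few voxels deep of the intensity peak
#'   after blurring.
#' @param recenter_range half-width of the peak search, voxels.
#' @param rng_seed seed for the RANSAC sampling.
#' @return List of class `flatten_result`: `enface` (an [enface_image()]),
#'   `surface` (a `surface_model`), `threshold`, `n_candidates`.
#' @export
flatten_endothelium <- function(vol, sigma = 1, n_levels = 256,
                                median_radius = 1, inlier_threshold = 2,
                                max_iterations = 500,
                                min_inlier_fraction = 0.35, slab_below = 6,
                                slab_above = 1,
                                surface_mode = c("deepest", "shallowest"),
                                recenter = TRUE, recenter_range = 5,
                                rng_seed = 1) {
  surface_mode <- match.arg(surface_mode)
  blurred <- gaussian_blur(vol, sigma)
  t <- huang_threshold_volume(blurred, n_levels)
  mask <- binarize(blurred, t)
  mask <- median_filter(mask, median_radius)
  cand <- extract_surface_candidates(mask, mode = surface_mode)
  if (nrow(cand) < 6)
    stop_fit_failure("binarized volume yielded fewer than 6 surface candidates")
  surf <- ransac_fit_surface(cand, inlier_threshold = inlier_threshold,
                             max_iterations = max_iterations,
                             min_inlier_fraction = min_inlier_fraction,
                             rng_seed = rng_seed)
  offset <- 0
  if (recenter) {
    offset <- surface_peak_offset(blurred, surf, recenter_range)
    surf$coefficients["c0"] <- surf$coefficients["c0"] + offset
  }
  surf$peak_offset <- offset
  enface <- flatten_to_enface(vol, surf, slab_below = slab_below,
                              slab_above = slab_above)
  structure(list(enface = enface, surface = surf, threshold = t,
                 n_candidates = nrow(cand)),
            class = "flatten_result")
}

# Median per-column offset between the fitted surface and the depth of the
# local intensity maximum within +/- `range` voxels of it.
surface_peak_offset <- function(vol, surface, range = 5) {
  d <- dim(vol$intensities)
  zc <- round(predict(surface, dims = d[1:2]))
  best_val <- matrix(-Inf, d[1], d[2])
  best_off <- matrix(NA_real_, d[1], d[2])
  for (z in seq_len(d[3])) {
    off <- z - zc
    in_win <- abs(off) <= range
    if (!any(in_win)) next
    slice <- vol$intensities[, , z]
    upd <- in_win & slice > best_val
    best_val[upd] <- slice[upd]
    best_off[upd] <- off[upd]
  }
  med <- median(best_off, na.rm = TRUE)
  if (is.na(med)) 0 else med
}
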