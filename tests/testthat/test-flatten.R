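# Flattening stages: blur, Huang threshold, binarize, majority filter,
# candidate extraction, RANSAC surface fit, slab projection.

test_that("gaussian blur preserves constants, is identity at sigma 0, matches brute-force convolution", {
  const <- voxel_volume(array(0.7, c(8, 8, 8)))
  expect_equal(gaussian_blur(const, 2)$intensities, const$intensities,
               tolerance = 1e-12)

  v <- voxel_volume(array(runif(6^3), c(6, 6, 6)))
  expect_identical(gaussian_blur(v, 0), v)
  expect_error(gaussian_blur(v, -1), class = "ecdquant_precondition")

  # unit impulse at the centre vs direct spatial convolution
  imp <- array(0, c(11, 11, 11)); imp[6, 6, 6] <- 1
  got <- gaussian_blur(voxel_volume(imp), 1)$intensities
  want <- oracle_gauss3d(imp, 1)
  expect_lt(max(abs(got - want)) / max(want), 1e-6)
})

test_that("huang threshold matches the exhaustive fuzziness scan", {
  # two-level histogram: any separating t gives zero fuzziness; smallest wins
  counts <- numeric(256); counts[11] <- 50; counts[201] <- 50
  expect_equal(huang_threshold(counts, 0:255), 10)

  # random histograms vs the independent oracle
  withr::with_seed(123, {
    for (i in 1:25) {
      counts <- rpois(64, lambda = sample(c(2, 20, 80), 64, TRUE))
      if (sum(counts > 0) < 2) next
      expect_equal(huang_threshold(counts, 0:63), oracle_huang(counts, 0:63))
    }
  })

  # bimodal mixture: threshold falls strictly between the modes
  withr::with_seed(7, {
    x <- round(c(rnorm(5000, 60, 12), rnorm(5000, 180, 12)))
    x <- pmin(pmax(x, 0), 255)
    counts <- tabulate(x + 1L, 256)
  })
  t <- huang_threshold(counts, 0:255)
  expect_gt(t, 60); expect_lt(t, 180)
  expect_equal(t, oracle_huang(counts, 0:255))

  counts1 <- numeric(16); counts1[4] <- 99
  expect_error(huang_threshold(counts1, 0:15), class = "ecdquant_precondition")
})

test_that("binarize is the voxelwise comparison intensity > t", {
  v <- voxel_volume(array(runif(5^3), c(5, 5, 5)))
  expect_false(any(binarize(v, 1)$mask))
  expect_true(all(binarize(v, -1)$mask))
  t <- 0.4
  want <- array(FALSE, dim(v$intensities))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    want[i, j, k] <- v$intensities[i, j, k] > t
  expect_identical(binarize(v, t)$mask, want)
})

test_that("majority filter removes singletons and matches the naive neighbourhood count", {
  all_true <- binary_volume(array(TRUE, c(6, 6, 6)))
  expect_true(all(median_filter(all_true, 1)$mask))

  lone <- array(FALSE, c(7, 7, 7)); lone[4, 4, 4] <- TRUE
  expect_false(any(median_filter(binary_volume(lone), 1)$mask))

  withr::with_seed(42, m <- array(runif(12^3) < 0.5, c(12, 12, 12)))
  expect_identical(median_filter(binary_volume(m), 1)$mask,
                   oracle_majority3d(m, 1))
  expect_error(median_filter(binary_volume(m), 0),
               class = "ecdquant_precondition")
})

test_that("surface candidates are the deepest foreground voxel per column", {
  # plane mask
  m <- array(FALSE, c(5, 6, 10)); m[, , 4] <- TRUE
  cand <- extract_surface_candidates(binary_volume(m))
  expect_equal(nrow(cand), 30)
  expect_true(all(cand$z == 4))

  # two foreground depths in one column: deepest wins
  m <- array(FALSE, c(3, 3, 50)); m[2, 2, c(10, 40)] <- TRUE
  cand <- extract_surface_candidates(binary_volume(m))
  expect_equal(cand$z, 40)
  # anterior mode picks the shallowest instead
  expect_equal(extract_surface_candidates(binary_volume(m), "shallowest")$z, 10)

  # random mask vs reverse-scan oracle
  withr::with_seed(5, m <- array(runif(8 * 7 * 9) < 0.2, c(8, 7, 9)))
  cand <- extract_surface_candidates(binary_volume(m))
  want <- as.data.frame(oracle_deepest(m))
  got <- cand[order(cand$x, cand$y), ]
  want <- want[order(want$x, want$y), ]
  expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))

  empty <- extract_surface_candidates(binary_volume(array(FALSE, c(4, 4, 4))))
  expect_equal(nrow(empty), 0)
})

test_that("RANSAC recovers exact quadrics, planes, and survives 30% outliers", {
  grid <- expand.grid(x = seq(5, 100, by = 5), y = seq(5, 100, by = 5))
  z_true <- 50 + 0.001 * grid$x^2 + 0.001 * grid$y^2
  pts <- data.frame(x = grid$x, y = grid$y, z = z_true)

  fit <- ransac_fit_surface(pts, inlier_threshold = 2, rng_seed = 1)
  expect_equal(unname(fit$coefficients),
               c(50, 0, 0, 0.001, 0, 0.001), tolerance = 1e-6)
  expect_length(fit$inlier_indices, nrow(pts))

  # plane: quadratic terms recovered as zero
  plane <- data.frame(x = grid$x, y = grid$y, z = 100)
  pfit <- ransac_fit_surface(plane, rng_seed = 2)
  expect_equal(unname(pfit$coefficients[4:6]), c(0, 0, 0), tolerance = 1e-6)

  # 30% uniform-depth outliers
  withr::with_seed(9, {
    out_idx <- sample(nrow(pts), round(0.3 * nrow(pts)))
    noisy <- pts
    noisy$z[out_idx] <- runif(length(out_idx), 1, 100)
  })
  rfit <- ransac_fit_surface(noisy, inlier_threshold = 2, rng_seed = 3)
  zhat <- predict(rfit, x = grid$x, y = grid$y)
  expect_lt(max(abs(zhat - z_true)), 1)

  # determinism
  rfit2 <- ransac_fit_surface(noisy, inlier_threshold = 2, rng_seed = 3)
  expect_identical(rfit$coefficients, rfit2$coefficients)

  # error taxonomy: too few points vs consensus failure
  expect_error(ransac_fit_surface(pts[1:5, ]), class = "ecdquant_precondition")
  withr::with_seed(1, junk <- data.frame(x = runif(60, 0, 100),
                                         y = runif(60, 0, 100),
                                         z = runif(60, 0, 100)))
  expect_error(ransac_fit_surface(junk, inlier_threshold = 0.5,
                                  min_inlier_fraction = 0.9, rng_seed = 4),
               class = "ecdquant_fit_failure")
})

test_that("slab projection reproduces a painted shell and handles degenerate inputs", {
  # value 1 exactly on the true surface, 0 elsewhere, perfect fit
  h <- 20; w <- 20; depth <- 30
  coef <- quadric_coefficients(c0 = 10, c1 = 0.2)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  zs <- matrix(as.integer(round(10 + 0.2 * cols)), h, w)
  vol <- array(0, c(h, w, depth))
  for (j in seq_len(w)) vol[, j, zs[1, j]] <- 1
  surf <- structure(list(coefficients = coef), class = "surface_model")
  ef <- flatten_to_enface(voxel_volume(vol), surf, slab_below = 6)
  expect_true(all(ef$intensities == 1))
  expect_identical(attr(ef, "source_depth"), zs)

  zero <- voxel_volume(array(0, c(8, 8, 8)))
  flat0 <- structure(list(coefficients = quadric_coefficients(4)),
                     class = "surface_model")
  expect_true(all(flatten_to_enface(zero, flat0)$intensities == 0))

  far <- structure(list(coefficients = quadric_coefficients(500)),
                   class = "surface_model")
  expect_error(flatten_to_enface(zero, far), class = "ecdquant_geometry_error")
  expect_error(flatten_to_enface(zero, flat0, slab_below = 0),
               class = "ecdquant_precondition")
})

test_that("noiseless phantom flattening reproduces the mosaic classes in the disc", {
  m <- generate_mosaic(170, 240, 240, rng_seed = 21)
  ph <- generate_volume(m, dome_surface(c(240, 240), apex_depth = 14, sag = 10),
                        depth = 36, noise_sd = 0, vignette_strength = 0,
                        rng_seed = 22)
  fl <- flatten_endothelium(ph$volume, rng_seed = 23)
  img <- fl$enface$intensities
  mid <- (max(img) + min(img)) / 2
  disc <- crop_central_disc(fl$enface, diameter_mm = 0.2)
  in_disc <- disc$mask
  agree <- (img > mid) == (m$cell_label_map > 0L)
  expect_gte(mean(agree[in_disc]), 0.99)
})

test_that("flat phantoms keep lateral geometry through the pipeline (idempotence)", {
  m <- generate_mosaic(80, 128, 128, rng_seed = 31)
  ph <- generate_volume(m, quadric_coefficients(c0 = 15), depth = 30,
                        noise_sd = 0, vignette_strength = 0)
  fl <- flatten_endothelium(ph$volume, rng_seed = 32)
  img <- fl$enface$intensities
  mid <- (max(img) + min(img)) / 2
  # no lateral displacement: interior pixels stay interior pixel-for-pixel
  expect_gte(mean((img > mid) == (m$cell_label_map > 0L)), 0.99)
})

test_that("surface recovery across seeded curvatures with 30% outliers stays under 1 voxel RMSE", {
  sags <- round(seq(0, 60, length.out = 10))
  errs <- numeric(length(sags))
  for (i in seq_along(sags)) {
    coef <- dome_surface(c(200, 200), apex_depth = 30, sag = sags[i])
    grid <- expand.grid(x = seq(2, 200, by = 6), y = seq(2, 200, by = 6))
    z <- coef[1] + coef[2] * grid$x + coef[3] * grid$y + coef[4] * grid$x^2 +
      coef[5] * grid$x * grid$y + coef[6] * grid$y^2
    withr::with_seed(100 + i, {
      zn <- z + rnorm(length(z), sd = 0.3)
      out_idx <- sample(length(z), round(0.3 * length(z)))
      zn[out_idx] <- runif(length(out_idx), 1, 90)
    })
    fit <- ransac_fit_surface(data.frame(x = grid$x, y = grid$y, z = zn),
                              inlier_threshold = 2, rng_seed = i)
    zhat <- predict(fit, x = grid$x, y = grid$y)
    errs[i] <- sqrt(mean((zhat - z)^2))
  }
  expect_lt(max(errs), 1)
})

test_that("3-D flattening yields fewer depth discontinuities than 1-D argmax on folded phantoms", {
  folds <- data.frame(center = c(70, 160), width = c(16, 10),
                      attenuation = c(0.75, 0.6))
  ph <- make_small_phantom(61, fold_spec = folds)
  fl <- flatten_endothelium(ph$volume, rng_seed = 62)
  d3 <- count_depth_discontinuities(attr(fl$enface, "source_depth"), 2)
  d1 <- count_depth_discontinuities(attr(flatten_argmax(ph$volume),
                                         "source_depth"), 2)
  expect_lt(d3, d1)
})
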