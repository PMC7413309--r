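# Synthetic mosaic and volume generator: ground-truth invariants.

test_that("mosaic generation: label structure, determinism, sizing errors", {
  m <- generate_mosaic(n_cells = 300, height = 1000, width = 1000,
                       lateral_pitch = 1, rng_seed = 7)
  labs <- setdiff(unique(as.integer(m$cell_label_map)), 0L)
  expect_length(labs, 300)

  # border_map is exactly the label-0 set
  expect_identical(m$border_map, m$cell_label_map == 0L)

  # conservation: cell areas + border area = image area
  expect_identical(sum(m$cell_label_map > 0L) + sum(m$border_map), 1000L * 1000L)

  # determinism
  m2 <- generate_mosaic(300, 1000, 1000, lateral_pitch = 1, rng_seed = 7)
  expect_identical(m$cell_label_map, m2$cell_label_map)
  expect_identical(m$seed_points, m2$seed_points)

  # single-seed mosaic: one region, no borders
  m1 <- generate_mosaic(1, 128, 128, rng_seed = 1)
  expect_identical(unique(as.integer(m1$cell_label_map)), 1L)
  expect_false(any(m1$border_map))

  expect_error(generate_mosaic(33 * 33, 32, 32), class = "ecdquant_precondition")
  expect_error(generate_mosaic(0, 64, 64), class = "ecdquant_precondition")
  expect_error(generate_mosaic(5, 16, 64), class = "ecdquant_precondition")
})

test_that("every cell label is a single 4-connected region", {
  m <- generate_mosaic(120, 256, 256, rng_seed = 11)
  for (k in sample(seq_len(120), 25)) {
    comp <- label_components4(m$cell_label_map == k)
    expect_equal(max(comp), 1L, info = sprintf("cell %d", k))
  }
})

test_that("true ECD is recomputable from the label map and matches the density", {
  m <- generate_mosaic(3000, 1000, 1000, lateral_pitch = 1, rng_seed = 3)
  re <- mosaic_true_ecd(m, disc_diameter_mm = 0.5)
  expect_identical(re$ecd, m$true_ecd)
  # 3000 cells on 1 mm^2: central-disc density within 15% of 3000
  expect_lt(abs(m$true_ecd - 3000) / 3000, 0.15)
})

test_that("volume painting: argmax at the stored surface, vignette, folds, determinism", {
  m <- generate_mosaic(40, 96, 96, rng_seed = 5)

  # flat noiseless surface: per-column argmax equals the painted depth
  flat <- generate_volume(m, quadric_coefficients(c0 = 12), depth = 24,
                          noise_sd = 0, vignette_strength = 0)
  am <- apply(flat$volume$intensities, c(1, 2), which.max)
  interior <- m$cell_label_map > 0L
  expect_true(all(am[interior] == 12L))

  # curved noiseless surface: argmax reproduces surface_height exactly
  dome <- generate_volume(m, dome_surface(c(96, 96), apex_depth = 6, sag = 14),
                          depth = 24, noise_sd = 0, vignette_strength = 0)
  am <- apply(dome$volume$intensities, c(1, 2), which.max)
  expect_identical(as.integer(am), as.integer(dome$surface_height))
  expect_gte(min(dome$surface_height), 2L)

  # full vignette: corner shell dimmer than centre shell
  vig <- generate_volume(m, quadric_coefficients(c0 = 12), depth = 24,
                         noise_sd = 0, vignette_strength = 1)
  v <- vig$volume$intensities
  expect_lt(v[1, 1, vig$surface_height[1, 1]],
            v[48, 48, vig$surface_height[48, 48]])

  # fold band attenuates the shell inside the band
  fold <- generate_volume(m, quadric_coefficients(c0 = 12), depth = 24,
                          noise_sd = 0, vignette_strength = 0,
                          fold_spec = data.frame(center = 48, width = 10,
                                                 attenuation = 0.7))
  vf <- fold$volume$intensities
  expect_equal(vf[10, 48, 12], 0.3 * flat$volume$intensities[10, 48, 12],
               tolerance = 1e-12)
  expect_equal(vf[10, 90, 12], flat$volume$intensities[10, 90, 12],
               tolerance = 1e-12)

  # determinism with noise
  a <- generate_volume(m, quadric_coefficients(c0 = 12), depth = 24,
                       noise_sd = 0.1, rng_seed = 42)
  b <- generate_volume(m, quadric_coefficients(c0 = 12), depth = 24,
                       noise_sd = 0.1, rng_seed = 42)
  expect_identical(a$volume$intensities, b$volume$intensities)

  # surface exiting the depth range is a geometry error
  expect_error(generate_volume(m, quadric_coefficients(c0 = 30), depth = 24),
               class = "ecdquant_geometry_error")
})

test_that("ground-truth label map and en-face rendering agree with the mosaic", {
  m <- generate_mosaic(50, 128, 128, rng_seed = 9)
  lab <- mosaic_label_map(m)
  pc <- pixel_classes()
  expect_identical(lab == pc[["border"]], m$border_map)
  img <- mosaic_enface(m, interior = 1, border = 0.4)
  expect_identical(img$intensities == 0.4, m$border_map)
})
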