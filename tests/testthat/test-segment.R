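# Pixel classification (classical backend) and morphological post-processing.

test_that("classical backend: contract shape, constant image, noiseless mosaic accuracy", {
  pc <- pixel_classes()

  const <- enface_image(matrix(0.5, 48, 48))
  lab <- classify_pixels(const, classical_backend())
  expect_identical(dim(lab), c(48L, 48L))
  expect_true(all(lab %in% pc))
  expect_equal(sum(lab == pc[["border"]]), 0L)

  m <- generate_mosaic(300, 320, 320, rng_seed = 7)
  img <- mosaic_enface(m)
  lab <- classify_pixels(img, classical_backend())
  # >= 95% of true border pixels labelled border (1-px tolerance), and
  # >= 95% of interior pixels labelled interior
  border_lab <- lab == pc[["border"]]
  near_border <- EBImage::dilate(m$border_map * 1L, matrix(1L, 3, 3)) > 0
  expect_gte(mean(border_lab[m$border_map]), 0.95)
  expect_gte(mean((lab == pc[["interior"]])[m$cell_label_map > 0L]), 0.95)
  # border calls stay within 1 px of a true border
  expect_gte(mean(near_border[border_lab]), 0.95)
})

test_that("skeletons are thin: no 2x2 all-foreground block survives", {
  withr::with_seed(13, {
    for (rep in 1:5) {
      blob <- matrix(runif(60 * 60) < 0.45, 60, 60)
      blob <- EBImage::dilate(blob * 1L, matrix(1L, 3, 3)) > 0
      sk <- skeletonize(blob)
      two_by_two <- sk[-1, -1] & sk[-nrow(sk), -1] & sk[-1, -ncol(sk)] &
        sk[-nrow(sk), -ncol(sk)]
      expect_false(any(two_by_two))
    }
  })
})

test_that("postprocessing a perfect square lattice keeps every interior cell", {
  # 20-px lattice: interiors are 19x19 boxes; dilation + skeletonization
  # returns a 1-px net, so each retained cell is 19^2 = 361 px^2
  lab <- lattice_label_map(401, 401, 20)
  cells <- postprocess_to_cells(lab)
  tab <- cell_measurements(cells)
  expect_equal(nrow(tab), 400)
  # interiors are 19x19 = 361 px^2; skeleton junction pixels may shave a few
  # pixels off cells on the lattice crossings, never below the filter floor
  expect_true(all(tab$area_px2 <= 361 & tab$area_px2 >= 323))
  expect_gte(mean(tab$area_px2 == 361), 0.8)
  # labels are one 4-connected region each, numbered in raster order
  expect_identical(sort(unique(tab$label)), seq_len(400))
  expect_equal(max(label_components4(unclass(cells) == 1L)), 1L)
})

test_that("area bounds are inclusive: 100 and 750 retained, 99 and 751 excluded", {
  pc <- pixel_classes()
  # enclose exact-area regions in one-pixel border outlines (skeleton-stable)
  raw <- matrix(pc[["interior"]], 160, 160)
  add_region <- function(mask) {
    ring <- (EBImage::dilate(mask * 1L, matrix(1L, 3, 3)) > 0) & !mask
    raw[ring] <<- pc[["border"]]
    mask
  }
  region <- function(rows, cols, extra = NULL) {
    m <- matrix(FALSE, 160, 160)
    m[rows, cols] <- TRUE
    if (!is.null(extra)) m[extra] <- TRUE
    m
  }
  r100 <- add_region(region(10:19, 10:19))                    # 100 px^2
  r99  <- add_region(region(10:12, 40:72))                    # 99 px^2
  r750 <- add_region(region(40:69, 10:34))                    # 750 px^2
  r751 <- add_region(region(80:89, 50:124, cbind(90L, 50L)))  # 751 px^2
  stopifnot(sum(r100) == 100, sum(r99) == 99, sum(r750) == 750,
            sum(r751) == 751)
  cells <- postprocess_to_cells(pixel_label_map(raw), dilate_radius = 0)
  areas <- sort(cell_measurements(cells)$area_px2)
  expect_identical(areas, c(100L, 750L))

  # all-noise map has no cells
  noise <- pixel_label_map(matrix(pc[["noise"]], 64, 64))
  expect_equal(nrow(cell_measurements(postprocess_to_cells(noise))), 0)

  # empty border map: the whole frame is one region, excluded when larger
  # than max_area but retained when it fits the window
  blank <- pixel_label_map(matrix(pc[["interior"]], 64, 64))
  expect_equal(nrow(cell_measurements(postprocess_to_cells(blank))), 0)
  small <- pixel_label_map(matrix(pc[["interior"]], 20, 20))
  expect_equal(nrow(cell_measurements(postprocess_to_cells(small))), 1)
})

test_that("raising min_area never increases the retained-cell count", {
  m <- generate_mosaic(250, 300, 300, rng_seed = 17)
  lab <- classify_pixels(mosaic_enface(m), classical_backend())
  counts <- vapply(c(50, 100, 200, 300, 400),
                   function(a) nrow(cell_measurements(
                     postprocess_to_cells(lab, min_area = a))),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("size filter covers >= 95% of ground-truth cells at 3000 cells/mm^2", {
  m <- generate_mosaic(1500, 707, 707, lateral_pitch = 1, rng_seed = 19)
  areas <- tabulate(m$cell_label_map[m$cell_label_map > 0L], 1500)
  areas <- areas[areas > 0]
  expect_gte(mean(areas >= 100 & areas <= 750), 0.95)
})

test_that("noisy-region exclusion drops cells dominated by the noise class", {
  pc <- pixel_classes()
  lab <- lattice_label_map(41, 41, 20)
  raw <- unclass(lab); attributes(raw) <- list(dim = dim(lab))
  # first cell: 40% noise pixels; second: clean
  raw[2:9, 2:19] <- pc[["noise"]]
  lab <- pixel_label_map(raw)
  cells <- postprocess_to_cells(lab, min_area = 50)
  tab <- cell_measurements(cells)
  # the noisy top-left cell is gone; clean cells remain
  expect_false(any(tab$centroid_row < 20 & tab$centroid_col < 20))
  expect_gte(nrow(tab), 2)
})

test_that("merge corrections split cells, drop small fragments, and keep other labels", {
  lab <- lattice_label_map(61, 81, 20)
  # remove one interior wall -> two 19x19 cells merge into a 19x39 region
  raw <- unclass(lab); attributes(raw) <- list(dim = dim(lab))
  pc <- pixel_classes()
  raw[22:40, 41] <- pc[["interior"]]
  lab <- pixel_label_map(raw)
  cells <- postprocess_to_cells(lab, dilate_radius = 0)
  tab0 <- cell_measurements(cells)
  merged <- tab0$label[tab0$area_px2 > 700]
  expect_length(merged, 1)

  # no instructions: identical output
  expect_identical(unclass(merge_correct(cells, list())), unclass(cells))

  # bisect the merged region -> two retained cells where one was
  stroke <- cbind(22:40, 41L)
  fixed <- merge_correct(cells, list(stroke))
  tabf <- cell_measurements(fixed)
  expect_equal(nrow(tabf), nrow(tab0) + 1)
  expect_true(all(tabf$area_px2 <= 400))
  # untouched labels survive with identical areas
  untouched <- setdiff(tab0$label, merged)
  expect_true(all(untouched %in% tabf$label))

  # a stroke that carves off a fragment below min_area drops the fragment
  stroke2 <- cbind(rep(24L, 19), 42:60)
  fixed2 <- merge_correct(cells, list(stroke2))
  areas2 <- cell_measurements(fixed2)$area_px2
  expect_false(any(areas2 < 100))

  # strokes outside the image are rejected
  expect_error(merge_correct(cells, list(cbind(999L, 1L))),
               class = "ecdquant_precondition")
})
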