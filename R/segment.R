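# Three-class pixel labelling of the flattened en-face image (cell border /
# cell interior / noise) and post-processing of the border class into
# individual cells: dilation, skeletonization, 4-connected components,
# size filtering.

#' Classical (deterministic) pixel-classification backend
#'
#' Rule-based three-class labelling: the image is contrast-normalized by
#' dividing out a heavily smoothed copy (removing vignetting and fold
#' attenuation), lightly smoothed, and split at a Huang threshold -- dark
#' ridges between the hyper-reflective cell interiors become the border
#' class. Pixels whose local background falls below an intensity floor are
#' labelled noise. A constant (contrast-free) image yields no border pixels.
#'
#' @param smooth_sigma pre-classification Gaussian smoothing, px.
#' @param bg_sigma background (illumination) smoothing scale, px.
#' @param noise_floor fraction of the median background below which pixels
#'   are labelled noise.
#' @param min_contrast minimum 2-98 percentile spread of the normalized
#'   image for border detection; below it the field is labelled interior.
#' @param n_levels histogram levels for the Huang threshold.
#' @return An object of classes `classical_backend`, `pixel_backend`.
#' @export
classical_backend <- function(smooth_sigma = 0.5, bg_sigma = 40,
                              noise_floor = 0.25, min_contrast = 0.05,
                              n_levels = 256) {
  structure(list(smooth_sigma = smooth_sigma, bg_sigma = bg_sigma,
                 noise_floor = noise_floor, min_contrast = min_contrast,
                 n_levels = n_levels),
            class = c("classical_backend", "pixel_backend"))
}

#' Classify pixels of an en-face image into border / interior / noise
#'
#' Backends are interchangeable behind this contract: the output is one
#' class code per pixel (see [pixel_classes()]), same shape as the input.
#'
#' @param img an [enface_image()].
#' @param backend a `classical_backend` or a trained [cnn_backend()].
#' @param ... passed to backend methods.
#' @return A [pixel_label_map()].
#' @export
classify_pixels <- function(img, backend, ...) {
  if (!inherits(img, "enface_image"))
    stop_precondition("img must be an enface_image")
  UseMethod("classify_pixels", backend)
}

#' @export
classify_pixels.classical_backend <- function(img, backend, ...) {
  pc <- pixel_classes()
  I <- img$intensities
  bg <- blur_array(I, backend$bg_sigma)
  norm <- I / pmax(bg, 1e-12)
  sm <- blur_array(norm, backend$smooth_sigma)

  noise <- bg < backend$noise_floor * median(bg)
  lab <- matrix(pc[["interior"]], nrow(I), ncol(I))
  lab[noise] <- pc[["noise"]]

  vals <- sm[!noise]
  if (length(vals) > 1) {
    q <- quantile(vals, c(0.02, 0.98), names = FALSE)
    if (q[2] - q[1] >= backend$min_contrast) {
      width <- (q[2] - q[1]) / backend$n_levels
      bin <- pmin(pmax(floor((vals - q[1]) / width), 0), backend$n_levels - 1)
      counts <- tabulate(bin + 1L, backend$n_levels)
      centers <- q[1] + (seq_len(backend$n_levels) - 0.5) * width
      if (sum(counts > 0) >= 2) {
        t <- huang_threshold(counts, centers)
        lab[sm <= t & !noise] <- pc[["border"]]
      }
    }
  }
  pixel_label_map(lab)
}

# ---------------------------------------------------------------------------
# Morphological post-processing

zs_neighbours <- function(p) {
  # clockwise from north: P2..P9
  list(n  = shift_matrix(p,  1,  0), ne = shift_matrix(p,  1, -1),
       e  = shift_matrix(p,  0, -1), se = shift_matrix(p, -1, -1),
       s  = shift_matrix(p, -1,  0), sw = shift_matrix(p, -1,  1),
       w  = shift_matrix(p,  0,  1), nw = shift_matrix(p,  1,  1))
}

#' Topological skeletonization (Zhang-Suen thinning)
#'
#' Iteratively peels border pixels from a binary mask until a one-pixel-wide,
#' 8-connected skeleton remains; connectivity and line endpoints are
#' preserved. No 2x2 all-foreground block survives.
#'
#' @param mask logical matrix.
#' @return Logical matrix of the skeleton.
#' @export
skeletonize <- function(mask) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  p <- mask
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      nb <- zs_neighbours(p)
      b <- Reduce(`+`, nb)
      seq8 <- nb[c("n", "ne", "e", "se", "s", "sw", "w", "nw", "n")]
      a <- matrix(0L, nrow(p), ncol(p))
      for (i in 1:8) a <- a + (!seq8[[i]] & seq8[[i + 1]])
      if (phase == 1) {
        cond <- p & b >= 2 & b <= 6 & a == 1 &
          !(nb$n & nb$e & nb$s) & !(nb$e & nb$s & nb$w)
      } else {
        cond <- p & b >= 2 & b <= 6 & a == 1 &
          !(nb$n & nb$e & nb$w) & !(nb$n & nb$s & nb$w)
      }
      if (any(cond)) {
        p[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  thin_2x2_blocks(p)
}

# Zhang-Suen can leave staircase 2x2 blocks; remove their redundant pixels
# sequentially, deleting only simple points so that 8-connectivity of the
# skeleton and 4-connectivity of its complement are preserved.
thin_2x2_blocks <- function(p) {
  # ring positions N NE E SE S SW W NW; adjacency = Chebyshev distance <= 1
  offs <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  adj <- matrix(FALSE, 8, 8)
  for (a in 1:8) for (b in 1:8)
    adj[a, b] <- a != b && max(abs(offs[a, ] - offs[b, ])) <= 1L
  one_fg_component <- function(nb) {
    fg <- which(nb)
    if (length(fg) == 0L) return(FALSE)
    seen <- fg[1]
    repeat {
      grow <- union(seen, fg[apply(adj[seen, fg, drop = FALSE], 2, any)])
      if (length(grow) == length(seen)) break
      seen <- grow
    }
    length(seen) == length(fg)
  }
  h <- nrow(p); w <- ncol(p)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  repeat {
    blocks <- p[-h, -w] & p[-1, -w] & p[-h, -1] & p[-1, -1]
    if (!any(blocks)) break
    pad[2:(h + 1L), 2:(w + 1L)] <- p
    bidx <- which(blocks)
    br <- ((bidx - 1L) %% (h - 1L)) + 1L
    bc <- ((bidx - 1L) %/% (h - 1L)) + 1L
    removed <- FALSE
    for (b in seq_along(bidx)) {
      for (off in list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))) {
        i <- br[b] + off[1]; j <- bc[b] + off[2]
        if (!pad[i + 1L, j + 1L]) next
        nb <- logical(8)
        for (q in 1:8) nb[q] <- pad[i + 1L + offs[q, 1], j + 1L + offs[q, 2]]
        if (any(!nb[c(1L, 3L, 5L, 7L)]) && one_fg_component(nb)) {
          pad[i + 1L, j + 1L] <- FALSE
          removed <- TRUE
        }
      }
    }
    p <- pad[2:(h + 1L), 2:(w + 1L)]
    if (!removed) break                          # no simple point: give up
  }
  p
}

#' Label 4-connected components of a binary mask
#'
#' @param mask logical matrix.
#' @return Integer matrix; 0 = background, components numbered from 1 in
#'   raster (row-major) order of their first pixel.
#' @export
label_components4 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  idx <- which(mask)
  if (length(idx) == 0) return(out)
  vid <- matrix(0L, h, w)
  vid[idx] <- seq_along(idx)
  # vertical and horizontal adjacencies among foreground pixels
  vpair <- which(mask[-h, ] & mask[-1, ])
  vr <- ((vpair - 1L) %% (h - 1L)) + 1L
  vc <- ((vpair - 1L) %/% (h - 1L)) + 1L
  hpair <- which(mask[, -w] & mask[, -1])
  hr <- ((hpair - 1L) %% h) + 1L
  hc <- ((hpair - 1L) %/% h) + 1L
  edges <- rbind(cbind(vid[cbind(vr, vc)], vid[cbind(vr + 1L, vc)]),
                 cbind(vid[cbind(hr, hc)], vid[cbind(hr, hc + 1L)]))
  g <- igraph::make_graph(t(edges), n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber in raster (row-major) order of each component's first pixel
  r <- ((idx - 1L) %% h) + 1L
  c <- ((idx - 1L) %/% h) + 1L
  raster_pos <- (r - 1L) * w + c
  first_pos <- tapply(raster_pos, memb, min)
  new_id <- integer(length(first_pos))
  new_id[order(first_pos)] <- seq_along(first_pos)
  out[idx] <- new_id[memb]
  out
}

disc_brush <- function(radius) {
  k <- 2L * radius + 1L
  offs <- seq(-radius, radius)
  b <- outer(offs^2, offs^2, `+`) <= radius^2
  storage.mode(b) <- "integer"
  b
}

cell_table <- function(labels, lateral_pitch) {
  idx <- which(labels > 0L)
  if (length(idx) == 0)
    return(data.frame(label = integer(), area_px2 = integer(),
                      area_um2 = numeric(), centroid_row = numeric(),
                      centroid_col = numeric()))
  lab <- labels[idx]
  h <- nrow(labels)
  r <- ((idx - 1L) %% h) + 1L
  c <- ((idx - 1L) %/% h) + 1L
  ids <- sort(unique(lab))
  cnt <- tabulate(lab, max(ids))[ids]
  data.frame(label = ids,
             area_px2 = cnt,
             area_um2 = cnt * lateral_pitch^2,
             centroid_row = as.numeric(rowsum(r, lab)) / cnt,
             centroid_col = as.numeric(rowsum(c, lab)) / cnt)
}

new_cell_label_map <- function(labels, lateral_pitch, min_area, max_area) {
  structure(labels,
            class = c("cell_label_map", "matrix", "array"),
            lateral_pitch = lateral_pitch,
            min_area = min_area, max_area = max_area,
            cells = cell_table(labels, lateral_pitch))
}

#' @export
print.cell_label_map <- function(x, ...) {
  cells <- attr(x, "cells")
  cat(sprintf("<cell_label_map> %d x %d, %d cells (areas %s-%s px^2)\n",
              nrow(x), ncol(x), nrow(cells),
              if (nrow(cells)) min(cells$area_px2) else "-",
              if (nrow(cells)) max(cells$area_px2) else "-"))
  invisible(x)
}

#' Per-cell measurements of a cell label map
#'
#' @param cells a `cell_label_map`.
#' @return Data frame with one row per retained cell: `label`, `area_px2`,
#'   `area_um2`, `centroid_row`, `centroid_col`.
#' @export
cell_measurements <- function(cells) attr(cells, "cells")

#' Post-process a pixel label map into individual cells
#'
#' Extracts the border-class mask, closes small gaps by a morphological
#' dilation (disc element), thins the result to a one-pixel skeleton, takes
#' 4-connected components of the complement as candidate cells, and filters
#' them: regions smaller than `min_area` or larger than `max_area` square
#' pixels are excluded (the bounds themselves are retained), as are regions
#' whose noise-class fraction exceeds `max_noise_fraction`. Survivors are
#' relabelled 1..N in raster order of their first pixel. Noise-class pixels
#' never count towards cell area.
#'
#' @param labels a [pixel_label_map()].
#' @param min_area,max_area retained region area bounds, px^2 (inclusive).
#' @param dilate_radius border dilation radius, px.
#' @param max_noise_fraction regions with a larger fraction of noise-class
#'   pixels are discarded as noisy areas.
#' @param lateral_pitch um/px, for the per-cell um^2 areas.
#' @return A `cell_label_map` (0 = background/skeleton, k >= 1 = cell k)
#'   with a per-cell measurement table (see [cell_measurements()]).
#' @export
postprocess_to_cells <- function(labels, min_area = 100, max_area = 750,
                                 dilate_radius = 2, max_noise_fraction = 0.2,
                                 lateral_pitch = 1) {
  pc <- pixel_classes()
  border <- labels == pc[["border"]]
  noise <- labels == pc[["noise"]]
  if (any(border)) {
    dil <- EBImage::dilate(border * 1L, disc_brush(dilate_radius)) > 0
    skel <- skeletonize(dil)
  } else {
    skel <- matrix(FALSE, nrow(labels), ncol(labels))
  }
  comp <- label_components4(!skel)
  ids <- seq_len(max(comp, 0L))
  if (length(ids) == 0)
    return(new_cell_label_map(comp, lateral_pitch, min_area, max_area))
  tot <- tabulate(comp[comp > 0L], length(ids))
  nz <- tabulate(comp[comp > 0L & noise], length(ids))
  area <- tot - nz                       # noise pixels do not count
  keep <- area >= min_area & area <= max_area & nz / tot <= max_noise_fraction
  remap <- integer(length(ids))
  remap[keep] <- seq_len(sum(keep))      # comp ids already in raster order
  out <- matrix(0L, nrow(labels), ncol(labels))
  sel <- comp > 0L
  out[sel] <- remap[comp[sel]]
  out[noise] <- 0L
  new_cell_label_map(out, lateral_pitch, min_area, max_area)
}

#' Split under-segmented cells with user-drawn border strokes
#'
#' Adds each stroke (a pixel path) to the border set of the regions it
#' touches and re-runs component labelling and the size filter on those
#' regions only; untouched regions keep their labels. Fragments falling
#' below the minimum area are dropped, reproducing manual correction of
#' merged cells.
#'
#' @param cells a `cell_label_map` from [postprocess_to_cells()].
#' @param split_instructions list of two-column matrices of (row, col) pixel
#'   coordinates; each matrix is one stroke.
#' @return A corrected `cell_label_map`.
#' @export
merge_correct <- function(cells, split_instructions) {
  if (length(split_instructions) == 0) return(cells)
  h <- nrow(cells); w <- ncol(cells)
  pitch <- attr(cells, "lateral_pitch")
  min_area <- attr(cells, "min_area"); max_area <- attr(cells, "max_area")
  labels <- unclass(cells)
  attributes(labels) <- list(dim = dim(cells))

  stroke_px <- do.call(rbind, split_instructions)
  if (any(stroke_px[, 1] < 1 | stroke_px[, 1] > h |
          stroke_px[, 2] < 1 | stroke_px[, 2] > w))
    stop_precondition("stroke coordinates fall outside the image")

  touched <- setdiff(unique(labels[stroke_px]), 0L)
  if (length(touched) == 0) return(cells)
  region <- labels %in% touched
  dim(region) <- dim(labels)
  region[stroke_px] <- FALSE
  sub <- label_components4(region)
  next_id <- max(labels)
  area <- tabulate(sub[sub > 0L])
  keep <- which(area >= min_area & area <= max_area)
  # untouched regions keep their labels; fragments get fresh labels appended
  labels[labels %in% touched] <- 0L
  for (i in seq_along(keep)) {
    labels[sub == keep[i]] <- next_id + i
  }
  new_cell_label_map(labels, pitch, min_area, max_area)
}
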