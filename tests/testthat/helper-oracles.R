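# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles are deliberately naive (loops, exhaustive scans) and
# share no code with the package internals they check.

# Exhaustive Huang fuzziness scan: for every candidate threshold, compute
# the total fuzziness directly from its definition.
oracle_huang <- function(counts, levels = seq_along(counts) - 1) {
  nz <- which(counts > 0)
  C <- levels[max(nz)] - levels[min(nz)]
  entropy <- function(mu) {
    if (mu <= 0 || mu >= 1) return(0)
    -mu * log(mu) - (1 - mu) * log(1 - mu)
  }
  best_s <- Inf; best_t <- NA
  for (ti in min(nz):(max(nz) - 1)) {
    lo <- 1:ti; hi <- (ti + 1):length(levels)
    m0 <- sum(counts[lo] * levels[lo]) / sum(counts[lo])
    m1 <- sum(counts[hi] * levels[hi]) / sum(counts[hi])
    s <- 0
    for (g in seq_along(levels)) {
      if (counts[g] == 0) next
      m <- if (g <= ti) m0 else m1
      mu <- 1 / (1 + abs(levels[g] - m) / C)
      s <- s + counts[g] * entropy(mu)
    }
    if (s < best_s) { best_s <- s; best_t <- levels[ti] }
  }
  best_t
}

# Naive per-voxel majority vote with nearest-edge replication.
oracle_majority3d <- function(mask, radius) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    ii <- pmin(pmax((i - radius):(i + radius), 1), d[1])
    jj <- pmin(pmax((j - radius):(j + radius), 1), d[2])
    kk <- pmin(pmax((k - radius):(k + radius), 1), d[3])
    votes <- 0L
    for (a in ii) for (b in jj) for (cc in kk) votes <- votes + mask[a, b, cc]
    out[i, j, k] <- votes > (2 * radius + 1)^3 / 2
  }
  out
}

# Brute-force 3-D convolution with the sampled Gaussian kernel (same
# sampling rule as documented: radius ceiling(4 sigma), normalized),
# replicate padding.
oracle_gauss3d <- function(vol, sigma) {
  r <- max(1, ceiling(4 * sigma))
  w <- dnorm(-r:r, sd = sigma); w <- w / sum(w)
  k3 <- outer(outer(w, w), w)    # separable => full 3-D kernel
  d <- dim(vol)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (a in -r:r) for (b in -r:r) for (cc in -r:r) {
      ii <- min(max(i + a, 1), d[1])
      jj <- min(max(j + b, 1), d[2])
      kk <- min(max(k + cc, 1), d[3])
      acc <- acc + vol[ii, jj, kk] * k3[a + r + 1, b + r + 1, cc + r + 1]
    }
    out[i, j, k] <- acc
  }
  out
}

# Per-column reverse scan for the deepest foreground voxel.
oracle_deepest <- function(mask) {
  d <- dim(mask)
  res <- NULL
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    for (k in rev(seq_len(d[3]))) {
      if (mask[i, j, k]) {
        res <- rbind(res, c(x = j, y = i, z = k))
        break
      }
    }
  }
  res
}

# Square-lattice border mask: vertical/horizontal grid lines `period` px
# apart, 1 px wide. Interiors are (period-1)^2 boxes before morphology.
lattice_border_mask <- function(h, w, period) {
  m <- matrix(FALSE, h, w)
  m[seq(1, h, by = period), ] <- TRUE
  m[, seq(1, w, by = period)] <- TRUE
  m
}

lattice_label_map <- function(h, w, period) {
  pc <- pixel_classes()
  lab <- matrix(pc[["interior"]], h, w)
  lab[lattice_border_mask(h, w, period)] <- pc[["border"]]
  pixel_label_map(lab)
}

# Small noisy phantom used by several end-to-end tests.
make_small_phantom <- function(seed, n_cells = 170, size = 240, depth = 36,
                               noise_sd = 0.1, vignette = 0.3,
                               fold_spec = NULL, sag = 10) {
  m <- generate_mosaic(n_cells, size, size, rng_seed = seed)
  generate_volume(m, dome_surface(c(size, size), apex_depth = 14, sag = sag),
                  depth = depth, noise_sd = noise_sd,
                  vignette_strength = vignette, fold_spec = fold_spec,
                  rng_seed = seed + 1000L)
}
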