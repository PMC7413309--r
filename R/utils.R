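# Internal helpers shared across modules.

#' @importFrom stats dnorm median quantile sd rnorm runif
#' @importFrom utils read.csv write.csv
NULL

# Error constructors: precondition violations vs runtime fit failures get
# distinct condition classes so callers can tell them apart.
stop_precondition <- function(msg) {
  stop(structure(class = c("ecdquant_precondition", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_fit_failure <- function(msg) {
  stop(structure(class = c("ecdquant_fit_failure", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_format <- function(msg) {
  stop(structure(class = c("ecdquant_format_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Sampled, normalized 1-D Gaussian kernel; radius ceil(4*sigma) keeps the
# truncation error below 1e-6 of the peak.
gaussian_kernel_1d <- function(sigma) {
  if (sigma == 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  w <- dnorm(seq(-r, r), sd = sigma)
  w / sum(w)
}

# Convolve an array (2-D or 3-D) along one axis with a centred odd kernel,
# replicating edge values.
conv_axis <- function(a, kernel, axis) {
  if (length(kernel) == 1L) return(a * kernel)
  d <- dim(a)
  n <- d[axis]
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, d)
  base <- seq_len(n)
  for (j in seq_along(kernel)) {
    idx <- pmin(pmax(base + (j - r - 1L), 1L), n)
    shifted <- switch(length(d) - 1L,
      # 2-D
      if (axis == 1L) a[idx, , drop = FALSE] else a[, idx, drop = FALSE],
      # 3-D
      switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
             a[, , idx, drop = FALSE])
    )
    out <- out + kernel[j] * shifted
  }
  out
}

# Separable Gaussian smoothing of a 2-D or 3-D array (replicate boundary).
blur_array <- function(a, sigma) {
  if (sigma < 0) stop_precondition("sigma must be >= 0")
  if (sigma == 0) return(a)
  k <- gaussian_kernel_1d(sigma)
  for (ax in seq_along(dim(a))) a <- conv_axis(a, k, ax)
  a
}

# Shift a logical/numeric matrix by (dr, dc), filling vacated cells with
# `fill`. Used by the skeletonization and phantom code.
shift_matrix <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- seq_len(h) - dr
  cs <- seq_len(w) - dc
  ok_r <- rs >= 1L & rs <= h
  ok_c <- cs >= 1L & cs <= w
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# Derive per-stage RNG seeds (< 2^31) from one top-level seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}
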