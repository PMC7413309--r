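# Trainable pixel-classification backend: a patch-centred neural network
# (odd-sized intensity window in, centre-pixel class out) trained with
# minibatch stochastic gradient descent with momentum.

#' Training configuration for the neural pixel classifier
#'
#' Defaults follow the published recipe for this segmentation task:
#' stochastic gradient descent with momentum 0.9, initial learning rate
#' 1e-3, L2 regularization 5e-4, minibatch size 16, at most 400 epochs.
#' Augmentation comprises random translations of up to +/-10 px in both
#' directions, specular reflections, and right-angle rotations; scaling and
#' skewing are structurally impossible (no such fields exist), preserving
#' the morphology and sizes of the cells.
#'
#' @param momentum SGD momentum coefficient.
#' @param learning_rate initial learning rate.
#' @param l2 L2 weight-decay coefficient.
#' @param batch_size minibatch size.
#' @param max_epochs maximum number of training epochs.
#' @param translate_px maximum augmentation translation, px, each axis.
#' @param reflect,rotate enable specular reflections / right-angle rotations.
#' @return An object of class `training_config`.
#' @export
training_config <- function(momentum = 0.9, learning_rate = 1e-3, l2 = 5e-4,
                            batch_size = 16, max_epochs = 400,
                            translate_px = 10, reflect = TRUE, rotate = TRUE) {
  if (momentum < 0 || momentum >= 1) stop_precondition("momentum must be in [0, 1)")
  if (learning_rate <= 0) stop_precondition("learning_rate must be > 0")
  if (batch_size < 1 || max_epochs < 1)
    stop_precondition("batch_size and max_epochs must be >= 1")
  structure(list(momentum = momentum, learning_rate = learning_rate, l2 = l2,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 translate_px = as.integer(translate_px),
                 reflect = isTRUE(reflect), rotate = isTRUE(rotate)),
            class = "training_config")
}

#' Geometry-preserving augmentation of an image or label map
#'
#' Applies the augmentation transforms available to the trainer -- circular
#' translation, specular reflection, right-angle rotation -- to a full
#' matrix. None of them resamples scale, so the multiset of per-cell pixel
#' counts of a label map is preserved exactly (translation wraps circularly).
#'
#' @param m matrix (image or integer label map).
#' @param translate integer `c(dr, dc)` circular shift.
#' @param reflect one of `"none"`, `"horizontal"`, `"vertical"`.
#' @param rotate_k number of 90-degree counterclockwise rotations (0-3).
#' @return The transformed matrix.
#' @export
augment_image <- function(m, translate = c(0L, 0L), reflect = "none",
                          rotate_k = 0L) {
  h <- nrow(m); w <- ncol(m)
  dr <- ((translate[1] %% h) + h) %% h
  dc <- ((translate[2] %% w) + w) %% w
  if (dr > 0) m <- m[c((h - dr + 1L):h, 1L:(h - dr)), , drop = FALSE]
  if (dc > 0) m <- m[, c((w - dc + 1L):w, 1L:(w - dc)), drop = FALSE]
  if (reflect == "horizontal") m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  if (reflect == "vertical") m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  k <- rotate_k %% 4L
  while (k > 0L) {
    m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
    k <- k - 1L
  }
  m
}

#' Untrained neural pixel-classifier backend
#'
#' Constructs the patch-classifier skeleton; it must be fitted with
#' [train_cnn_backend()] before use -- classifying with an untrained backend
#' raises a not-ready error.
#'
#' @param patch_size odd patch window side, px.
#' @param hidden_units hidden-layer width.
#' @return An object of classes `cnn_backend`, `pixel_backend`.
#' @export
cnn_backend <- function(patch_size = 9, hidden_units = 24) {
  if (patch_size %% 2 != 1) stop_precondition("patch_size must be odd")
  structure(list(patch_size = as.integer(patch_size),
                 hidden_units = as.integer(hidden_units),
                 weights = NULL, trained = FALSE),
            class = c("cnn_backend", "pixel_backend"))
}

# illumination-normalized intensities, patch features centred at 0
normalize_for_patches <- function(I, bg_sigma = 40) {
  bg <- blur_array(I, bg_sigma)
  I / pmax(bg, 1e-12) - 1
}

pad_replicate <- function(m, r) {
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci]
}

# rows = patches (row-major over the window) centred at (rows, cols)
extract_patches <- function(padded, rows, cols, patch_size) {
  r <- (patch_size - 1L) %/% 2L
  offs <- seq(-r, r)
  n <- length(rows)
  out <- matrix(0, n, patch_size^2)
  k <- 0L
  for (dc in offs) for (dr in offs) {
    k <- k + 1L
    out[, k] <- padded[cbind(rows + dr + r, cols + dc + r)]
  }
  out
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train the neural pixel-classification backend
#'
#' Fits the patch-centred classifier on annotated en-face images with
#' seeded minibatch SGD with momentum, L2 weight decay, and the
#' geometry-preserving augmentations of the [training_config()]: each
#' sampled patch centre is jittered by up to the configured translation and
#' the patch is randomly reflected / rotated by right angles. Training is
#' fully reproducible given the seed.
#'
#' @param images list of [enface_image()]s.
#' @param labels list of matching [pixel_label_map()]s.
#' @param config a [training_config()].
#' @param rng_seed integer seed.
#' @param backend an untrained [cnn_backend()] (architecture).
#' @param patches_per_image patch samples drawn per image per epoch plan.
#' @param epochs epochs to run (capped at `config$max_epochs`).
#' @return The fitted `cnn_backend` (field `trained = TRUE`), with a
#'   `history` of mean minibatch losses per epoch.
#' @export
train_cnn_backend <- function(images, labels, config = training_config(),
                              rng_seed = 1, backend = cnn_backend(),
                              patches_per_image = 1500,
                              epochs = min(30L, config$max_epochs)) {
  if (length(images) == 0) stop_precondition("at least one annotated image is required")
  if (length(images) != length(labels))
    stop_precondition("images and labels must have equal length")
  if (!inherits(config, "training_config"))
    stop_precondition("config must be a training_config")
  epochs <- min(as.integer(epochs), config$max_epochs)
  ps <- backend$patch_size
  r <- (ps - 1L) %/% 2L
  n_class <- 3L

  norm <- lapply(images, function(im) normalize_for_patches(im$intensities))
  padded <- lapply(norm, pad_replicate, r = r)

  withr::with_seed(as.integer(rng_seed), {
    # balanced patch sampling across the classes present in each image
    feats <- list(); targs <- list()
    for (i in seq_along(images)) {
      lab <- labels[[i]]
      h <- nrow(lab); w <- ncol(lab)
      present <- sort(unique(as.integer(lab)))
      per_class <- ceiling(patches_per_image / length(present))
      rows <- integer(0); cols <- integer(0)
      for (cl in present) {
        px <- which(lab == cl)
        px <- px[sample.int(length(px), min(per_class, length(px)))]
        rows <- c(rows, ((px - 1L) %% h) + 1L)
        cols <- c(cols, ((px - 1L) %/% h) + 1L)
      }
      # translation augmentation: jitter the sampling centre; the label is
      # the class at the jittered centre, so scale is never resampled
      if (config$translate_px > 0) {
        rows <- pmin(pmax(rows + sample(-config$translate_px:config$translate_px,
                                        length(rows), TRUE), 1L), h)
        cols <- pmin(pmax(cols + sample(-config$translate_px:config$translate_px,
                                        length(cols), TRUE), 1L), w)
      }
      X <- extract_patches(padded[[i]], rows, cols, ps)
      feats[[i]] <- X
      targs[[i]] <- as.integer(lab[cbind(rows, cols)])
    }
    X <- do.call(rbind, feats)
    yy <- do.call(c, targs)
    n <- nrow(X)

    # reflection / right-angle rotation augmentation as patch index
    # permutations (the window is square, so these are exact)
    perm_grid <- matrix(seq_len(ps^2), ps, ps)
    perms <- list(seq_len(ps^2))
    if (config$reflect) {
      perms <- c(perms, list(as.integer(perm_grid[, rev(seq_len(ps))]),
                             as.integer(perm_grid[rev(seq_len(ps)), ])))
    }
    if (config$rotate) {
      rot <- perm_grid
      for (k in 1:3) {
        rot <- t(rot)[rev(seq_len(ncol(rot))), , drop = FALSE]
        perms <- c(perms, list(as.integer(rot)))
      }
    }

    p2 <- ps^2
    hsz <- backend$hidden_units
    W1 <- matrix(rnorm(p2 * hsz, sd = sqrt(2 / p2)), p2, hsz)
    b1 <- numeric(hsz)
    W2 <- matrix(rnorm(hsz * n_class, sd = sqrt(2 / hsz)), hsz, n_class)
    b2 <- numeric(n_class)
    vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- b2 * 0
    lr <- config$learning_rate; mom <- config$momentum; l2 <- config$l2
    bs <- config$batch_size
    history <- numeric(epochs)

    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n - bs + 1L, by = bs)) {
        take <- ord[start:(start + bs - 1L)]
        xb <- X[take, , drop = FALSE]
        prm <- perms[[sample.int(length(perms), 1L)]]
        xb <- xb[, prm, drop = FALSE]
        yb <- yy[take]

        hpre <- sweep(xb %*% W1, 2, b1, `+`)
        hact <- pmax(hpre, 0)                       # ReLU
        out <- sweep(hact %*% W2, 2, b2, `+`)
        prob <- softmax_rows(out)
        losses <- c(losses, -mean(log(pmax(prob[cbind(seq_len(bs), yb)], 1e-12))))

        dout <- prob
        dout[cbind(seq_len(bs), yb)] <- dout[cbind(seq_len(bs), yb)] - 1
        dout <- dout / bs
        gW2 <- crossprod(hact, dout) + l2 * W2
        gb2 <- colSums(dout)
        dh <- (dout %*% t(W2)) * (hpre > 0)
        gW1 <- crossprod(xb, dh) + l2 * W1
        gb1 <- colSums(dh)

        vW2 <- mom * vW2 - lr * gW2; W2 <- W2 + vW2
        vb2 <- mom * vb2 - lr * gb2; b2 <- b2 + vb2
        vW1 <- mom * vW1 - lr * gW1; W1 <- W1 + vW1
        vb1 <- mom * vb1 - lr * gb1; b1 <- b1 + vb1
      }
      history[ep] <- mean(losses)
    }

    backend$weights <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    backend$trained <- TRUE
    backend$history <- history
    backend$config <- config
    backend$rng_seed <- as.integer(rng_seed)
  })
  backend
}

#' @export
classify_pixels.cnn_backend <- function(img, backend, chunk = 20000L, ...) {
  if (!isTRUE(backend$trained))
    stop(structure(class = c("ecdquant_not_ready", "error", "condition"),
                   list(message = "cnn backend has not been trained; call train_cnn_backend() first",
                        call = sys.call())))
  ps <- backend$patch_size
  r <- (ps - 1L) %/% 2L
  I <- normalize_for_patches(img$intensities)
  padded <- pad_replicate(I, r)
  h <- nrow(I); w <- ncol(I)
  n <- h * w
  wts <- backend$weights
  lab <- integer(n)
  all_rows <- rep(seq_len(h), times = w)
  all_cols <- rep(seq_len(w), each = h)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    X <- extract_patches(padded, all_rows[idx], all_cols[idx], ps)
    hact <- pmax(sweep(X %*% wts$W1, 2, wts$b1, `+`), 0)
    out <- sweep(hact %*% wts$W2, 2, wts$b2, `+`)
    lab[idx] <- max.col(out, ties.method = "first")
  }
  pixel_label_map(matrix(lab, h, w))
}
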