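# Independent reference implementations used as oracles.  These are written
# as straightforward per-pixel / exhaustive computations and must stay
# independent of the package's own code paths.

# Per-pixel target-mask pipeline: min-max normalize, circular-boundary
# Gaussian convolution (kernel truncated at ceiling(3*sigma), normalized),
# strict threshold, disc dilation (outside = background), block-max resize.
oracle_target_mask <- function(img, threshold = 0.3, sigma = 0, rad = 0,
                               out_side) {
  n <- nrow(img)
  rngv <- range(img)
  x <- if (diff(rngv) > 0) (img - rngv[1]) / diff(rngv) else (img > 0) * 1
  if (sigma > 0) {
    r <- max(1L, as.integer(ceiling(3 * sigma)))
    g1 <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    kern <- outer(g1, g1)
    kern <- kern / sum(kern)
    sm <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      acc <- 0
      for (di in -r:r) for (dj in -r:r) {
        ii <- ((i - 1 + di) %% n) + 1
        jj <- ((j - 1 + dj) %% n) + 1
        acc <- acc + kern[di + r + 1, dj + r + 1] * x[ii, jj]
      }
      sm[i, j] <- acc
    }
    x <- sm
  }
  b <- (x > threshold) * 1
  if (rad >= 1 && any(b > 0)) {
    rr <- as.integer(ceiling(rad))
    d <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      hit <- 0
      for (di in -rr:rr) for (dj in -rr:rr) {
        if (di^2 + dj^2 > rad^2) next
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= n && jj >= 1 && jj <= n && b[ii, jj] > 0) hit <- 1
      }
      d[i, j] <- hit
    }
    b <- d
  }
  out <- matrix(0, out_side, out_side)
  blk <- n / out_side
  for (i in 1:out_side) for (j in 1:out_side) {
    rows <- ((i - 1) * blk + 1):(i * blk)
    cols <- ((j - 1) * blk + 1):(j * blk)
    out[i, j] <- as.numeric(any(b[rows, cols] > 0))
  }
  out
}

# Exhaustive grid search for threshold calibration: tries every grid value
# and records dice computed from first principles.
oracle_calibrate <- function(confidences, truths, grid_step = 0.01) {
  grid <- seq(0, 1, by = grid_step)
  vapply(seq_len(ncol(confidences)), function(ci) {
    best_t <- 0; best_d <- -1
    for (t0 in grid) {
      pred <- as.integer(confidences[, ci] >= t0)
      tru <- truths[, ci]
      tp <- sum(pred & tru); fp <- sum(pred & !tru); fn <- sum(!pred & tru)
      d <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
      if (d > best_d + 1e-12) { best_d <- d; best_t <- t0 }
    }
    best_t
  }, numeric(1))
}

# Literal transcription of the multi-label confusion attribution rule.
oracle_confusion_counts <- function(true_sets, predicted_sets, classes) {
  counts <- matrix(0, length(classes), length(classes),
                   dimnames = list(classes, classes))
  for (i in seq_along(true_sets)) {
    T0 <- true_sets[[i]]; P0 <- predicted_sets[[i]]
    for (c0 in T0) {
      if (c0 %in% P0) counts[c0, c0] <- counts[c0, c0] + 1
      else for (c1 in setdiff(P0, T0)) counts[c0, c1] <- counts[c0, c1] + 1
    }
  }
  counts
}

# Small deterministic random multi-channel image batch.
random_images <- function(n, side = 16, channels = 4, seed = 1) {
  set.seed(seed)
  array(runif(side * side * channels * n), dim = c(side, side, channels, n))
}
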