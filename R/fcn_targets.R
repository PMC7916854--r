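# Binary FCN training targets derived from the green fluorescence channel.
# Pipeline order is fixed: normalize -> Gaussian smooth -> threshold ->
# binary dilate -> max-pool downsample to the FCN output grid.

# Truncated, normalized 2-D Gaussian kernel (odd side, cut at ~3 sigma).
gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  g <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

# Disc structuring element: offsets with dx^2 + dy^2 <= radius^2.
disc_kernel <- function(radius) {
  r <- as.integer(ceiling(radius))
  d <- outer((-r:r)^2, (-r:r)^2, "+") <= radius^2
  storage.mode(d) <- "double"
  d
}

#' Max-pool downsample a binary mask
#'
#' Output pixel is 1 iff any input pixel in its receptive block is 1, so
#' small positive regions (e.g. a centrosome dot) survive the resize.
#'
#' @param mask Binary matrix.
#' @param out_side Output side; must not exceed the input side.
#' @return Binary `out_side` x `out_side` matrix.
#' @export
downsample_mask <- function(mask, out_side) {
  n <- nrow(mask)
  if (out_side > n) stop("out_side exceeds input side")
  if (out_side == n) return((mask > 0) * 1)
  # receptive block of output pixel i covers input rows/cols mapped by
  # the ceiling partition; exact blocks when n %% out_side == 0
  breaks <- ceiling(seq_len(n) * out_side / n)
  out <- matrix(0, out_side, out_side)
  for (i in seq_len(out_side)) {
    ri <- which(breaks == i)
    for (j in seq_len(out_side)) {
      cj <- which(breaks == j)
      out[i, j] <- as.numeric(any(mask[ri, cj] > 0))
    }
  }
  out
}

#' Build the binary FCN target mask from a green channel
#'
#' Implements the automatic target generation for the fully convolutional
#' head: the image is min-max normalized, smoothed with a Gaussian kernel,
#' thresholded at a fixed fraction (default 0.3), binary-dilated with a disc
#' and finally max-pool resized to the FCN output grid.  Min-max
#' normalization makes the result invariant to positive rescaling of the
#' input, so the 0.3 cutoff is scale-free.
#'
#' @param green_channel Nonnegative 2-D intensity matrix.
#' @param threshold Fraction of the normalized range (default 0.3).
#' @param smooth_sigma Gaussian sigma in pixels at a 256 px image; scaled
#'   proportionally for other sizes.  0 disables smoothing.
#' @param dilate_radius Disc radius in pixels at 256 px, scaled likewise;
#'   0 disables dilation.
#' @param out_side Side of the output mask (FCN output resolution).
#' @return Binary `out_side` x `out_side` matrix.
#' @export
#' @examples
#' g <- matrix(0, 256, 256); g[65:128, 65:128] <- 1
#' m <- make_target_mask(g, smooth_sigma = 0, dilate_radius = 0, out_side = 16)
#' which(m == 1, arr.ind = TRUE)  # rows/cols 5..8
make_target_mask <- function(green_channel, threshold = 0.3,
                             smooth_sigma = 2, dilate_radius = 3,
                             out_side = 16) {
  if (any(green_channel < 0)) stop("green channel must be nonnegative")
  if (out_side < 1) stop("out_side must be >= 1")
  side <- nrow(green_channel)
  if (all(green_channel == 0))
    return(matrix(0, out_side, out_side))
  # 1. normalize (min-max to [0,1]); constant images map positives to 1
  rng <- range(green_channel)
  x <- if (diff(rng) > 0) (green_channel - rng[1]) / diff(rng)
       else (green_channel > 0) * 1
  # 2. Gaussian smooth (sigma stated at 256 px, scaled to the actual size)
  sc <- side / 256
  sigma <- smooth_sigma * sc
  if (sigma > 0)
    x <- EBImage::filter2(x, gaussian_kernel(sigma), boundary = "circular")
  # 3. threshold
  b <- (x > threshold) * 1
  # 4. dilate
  rad <- dilate_radius * sc
  if (rad >= 1 && any(b > 0))
    b <- EBImage::dilate(b, disc_kernel(rad))
  # 5. resize to the FCN output grid
  downsample_mask(b, out_side)
}

#' Per-class FCN target stack for one sample
#'
#' One shared spatial mask is derived from the green channel and replicated
#' for every present class; absent classes get an all-zero target.
#'
#' @param green_channel 2-D green-channel intensity matrix.
#' @param labels Binary 13-vector with at least one present class.
#' @param fcn_out_side FCN output side.
#' @param ... Passed to [make_target_mask()].
#' @return Array `fcn_out_side` x `fcn_out_side` x 13 in canonical class
#'   order.
#' @export
build_training_targets <- function(green_channel, labels, fcn_out_side, ...) {
  stopifnot(length(labels) == n_classes())
  if (!any(labels > 0)) stop("labels must contain at least one present class")
  mask <- make_target_mask(green_channel, out_side = fcn_out_side, ...)
  out <- array(0, dim = c(fcn_out_side, fcn_out_side, n_classes()))
  for (ci in which(labels > 0)) out[, , ci] <- mask
  out
}

#' Write a per-class target stack as a multi-page TIFF
#' @param targets Array out x out x 13 from [build_training_targets()].
#' @param path Output file path.
#' @export
write_target_stack <- function(targets, path) {
  pages <- lapply(seq_len(dim(targets)[3]), function(i) targets[, , i])
  tiff::writeTIFF(pages, path)
  invisible(path)
}

#' Read a per-class target stack from a multi-page TIFF
#' @param path File written by [write_target_stack()].
#' @return Array out x out x 13.
#' @export
read_target_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  arr
}
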