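# Network construction: a shared convolutional trunk (blocks of two 3x3
# convolutions + batch normalization + 2x2 max pooling, kernel count
# doubling per block) specialized into
#   * CNN: trunk + flatten + three fully connected layers, 13 sigmoid
#     confidences;
#   * FCN: trunk with the last max pool removed + one convolutional layer
#     with 13 kernels, 13 sigmoid heat maps of side input_side / 2^(blocks-1).
# Models are plain R lists of layers evaluated by the compiled engine.

#' Network architecture specification
#'
#' @param input_side Input image side in pixels (default 256).
#' @param in_channels Input channels (4: green, blue, red, yellow).
#' @param base_kernels Kernel count of the first block; doubles after every
#'   max pool.  16 at 256 px; 8 is a sensible test-size choice at 64 px.
#' @param kernel_size Odd convolution kernel side (default 3).
#' @param convs_per_block Convolutions per block (default 2).
#' @param pool_blocks Number of conv-conv-batchnorm-pool blocks in the base
#'   trunk (default 5, giving 10 convolutional layers in total).
#' @param variant `"CNN"` or `"FCN"`.
#' @param n_classes Number of output classes (13).
#' @param fc_widths Widths of the three fully connected CNN layers; the last
#'   must equal `n_classes`.
#' @param dropout_rate Dropout fraction (between the fully connected layers
#'   for CNN, before the final convolution for FCN).
#' @return Object of class `protloc_spec`.
#' @export
network_spec <- function(input_side = 256, in_channels = 4,
                         base_kernels = 16, kernel_size = 3,
                         convs_per_block = 2, pool_blocks = 5,
                         variant = c("CNN", "FCN"), n_classes = 13,
                         fc_widths = c(128, 64, n_classes),
                         dropout_rate = 0.2) {
  variant <- match.arg(variant)
  if (kernel_size %% 2 != 1) stop("kernel_size must be odd")
  if (input_side %% 2^pool_blocks != 0)
    stop("input_side must be divisible by 2^pool_blocks")
  if (variant == "FCN" && input_side < 2^(pool_blocks - 1))
    stop("input_side too small for the FCN pooling depth")
  if (fc_widths[length(fc_widths)] != n_classes)
    stop("last fully connected width must equal n_classes")
  structure(list(input_side = input_side, in_channels = in_channels,
                 base_kernels = base_kernels, kernel_size = kernel_size,
                 convs_per_block = convs_per_block, pool_blocks = pool_blocks,
                 conv_layers_total = convs_per_block * pool_blocks,
                 variant = variant, n_classes = n_classes,
                 fc_widths = fc_widths, dropout_rate = dropout_rate),
            class = "protloc_spec")
}

# Glorot (uniform) initialization
.glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

.conv_layer <- function(k, c_in, c_out, relu = TRUE, sigmoid = FALSE) {
  list(type = "conv",
       W = .glorot(k * k * c_in, k * k * c_out, c(k, k, c_in, c_out)),
       b = numeric(c_out), relu = relu, sigmoid = sigmoid)
}

.bnorm_layer <- function(c_out) {
  list(type = "bnorm", gamma = rep(1, c_out), beta = numeric(c_out),
       running_mean = numeric(c_out), running_var = rep(1, c_out),
       momentum = 0.9, eps = 1e-5)
}

.dense_layer <- function(d_in, d_out, relu = TRUE, sigmoid = FALSE) {
  list(type = "dense", W = matrix(.glorot(d_in, d_out, c(d_in, d_out)),
                                  d_in, d_out),
       b = numeric(d_out), relu = relu, sigmoid = sigmoid)
}

#' Build the base convolutional trunk
#'
#' `pool_blocks` repetitions of two same-padded convolutions (each followed
#' by a rectified-linear activation), batch normalization, then 2x2 max
#' pooling; kernel counts double after each pooling stage.  Weights are
#' Glorot-initialized from the current RNG state (seed it for reproducible
#' models).
#'
#' @param spec A [network_spec()].
#' @return List of layer objects.
#' @export
build_base_trunk <- function(spec) {
  layers <- list()
  c_in <- spec$in_channels
  width <- spec$base_kernels
  for (b in seq_len(spec$pool_blocks)) {
    for (j in seq_len(spec$convs_per_block)) {
      layers[[length(layers) + 1]] <-
        .conv_layer(spec$kernel_size, c_in, width)
      c_in <- width
    }
    layers[[length(layers) + 1]] <- .bnorm_layer(width)
    layers[[length(layers) + 1]] <- list(type = "pool")
    if (b < spec$pool_blocks) width <- width * 2
  }
  layers
}

#' Build the CNN classifier
#'
#' Trunk + flatten + three fully connected layers with dropout in between;
#' the final layer has 13 sigmoid outputs, one confidence per class.
#'
#' @param spec A [network_spec()] with `variant = "CNN"`.
#' @return Object of class `protloc_model`.
#' @export
build_cnn <- function(spec) {
  if (spec$variant != "CNN") stop("spec$variant must be 'CNN'")
  layers <- build_base_trunk(spec)
  layers[[length(layers) + 1]] <- list(type = "flatten")
  side_out <- spec$input_side / 2^spec$pool_blocks
  d_in <- side_out^2 * spec$base_kernels * 2^(spec$pool_blocks - 1)
  nw <- length(spec$fc_widths)
  for (i in seq_len(nw)) {
    last <- i == nw
    layers[[length(layers) + 1]] <-
      .dense_layer(d_in, spec$fc_widths[i], relu = !last, sigmoid = last)
    d_in <- spec$fc_widths[i]
    if (!last)
      layers[[length(layers) + 1]] <- list(type = "dropout",
                                           rate = spec$dropout_rate)
  }
  structure(list(spec = spec, layers = layers), class = "protloc_model")
}

#' Build the FCN heat-map model
#'
#' Trunk with the final max pooling removed (keeping a larger spatial
#' output), dropout, then one convolutional layer with 13 kernels and
#' sigmoid activation: 13 heat maps of side `input_side / 2^(pool_blocks-1)`
#' (16x16 for a 256 px input with the default 5 blocks).
#'
#' @param spec A [network_spec()] with `variant = "FCN"`.
#' @return Object of class `protloc_model`.
#' @export
build_fcn <- function(spec) {
  if (spec$variant != "FCN") stop("spec$variant must be 'FCN'")
  layers <- build_base_trunk(spec)
  layers[[length(layers)]] <- NULL   # drop the last max pool
  width <- spec$base_kernels * 2^(spec$pool_blocks - 1)
  layers[[length(layers) + 1]] <- list(type = "dropout",
                                       rate = spec$dropout_rate)
  layers[[length(layers) + 1]] <-
    .conv_layer(spec$kernel_size, width, spec$n_classes,
                relu = FALSE, sigmoid = TRUE)
  structure(list(spec = spec, layers = layers), class = "protloc_model")
}

#' Side of the FCN output heat maps for a spec
#' @param spec A [network_spec()].
#' @return Integer heat-map side.
#' @export
fcn_output_side <- function(spec) spec$input_side / 2^(spec$pool_blocks - 1)

#' Count convolutional layers in a model or layer list
#' @param model A `protloc_model` or list of layers.
#' @return Integer count.
#' @export
count_conv_layers <- function(model) {
  layers <- if (inherits(model, "protloc_model")) model$layers else model
  sum(vapply(layers, function(l) l$type == "conv", TRUE))
}

#' Count trainable parameters
#' @param model A `protloc_model` or list of layers.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  layers <- if (inherits(model, "protloc_model")) model$layers else model
  sum(vapply(layers, function(l) {
    switch(l$type,
           conv = length(l$W) + length(l$b),
           dense = length(l$W) + length(l$b),
           bnorm = length(l$gamma) + length(l$beta),
           0L)
  }, numeric(1)))
}

# Nearest-neighbour resize of (H, W, C) or (H, W) arrays.
resize_nearest <- function(img, side) {
  d <- dim(img)
  if (length(d) == 2) img <- array(img, dim = c(d, 1))
  d <- dim(img)
  if (d[1] == side && d[2] == side) return(img)
  ri <- pmin(d[1], floor((seq_len(side) - 0.5) * d[1] / side) + 1)
  ci <- pmin(d[2], floor((seq_len(side) - 0.5) * d[2] / side) + 1)
  img[ri, ci, , drop = FALSE]
}

# Raw forward pass over a batch array (H, W, C, N); eval mode.
.forward_batch <- function(model, x) {
  .nn_batch(model$layers, x, NULL, FALSE, FALSE)$output
}

#' Predict confidences (and FCN heat maps) for images
#'
#' Images are nearest-neighbour resized to the spec input side.  For the
#' CNN the 13 sigmoid outputs are the confidences directly; for the FCN the
#' confidence of each class is the maximum of its predicted heat map.
#'
#' @param model A trained (or freshly built) `protloc_model`.
#' @param images One image (H x W x 4) or a batch (H x W x 4 x N).
#' @param batch_size Forward-pass batch size.
#' @return List with `confidences` (N x 13 matrix) and, for FCN,
#'   `heatmaps` (out x out x 13 x N array).
#' @export
predict_samples <- function(model, images, batch_size = 16) {
  d <- dim(images)
  if (length(d) == 3) { images <- array(images, dim = c(d, 1)); d <- dim(images) }
  if (d[3] != model$spec$in_channels)
    stop("expected ", model$spec$in_channels, " channels, got ", d[3])
  n <- d[4]
  side <- model$spec$input_side
  conf <- matrix(NA_real_, n, n_classes(),
                 dimnames = list(NULL, organelle_classes()))
  heat <- NULL
  if (model$spec$variant == "FCN") {
    hs <- fcn_output_side(model$spec)
    heat <- array(0, dim = c(hs, hs, n_classes(), n))
  }
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1)
    xb <- array(0, dim = c(side, side, d[3], length(idx)))
    for (j in seq_along(idx))
      xb[, , , j] <- resize_nearest(images[, , , idx[j]], side)
    out <- .forward_batch(model, xb)
    if (model$spec$variant == "CNN") {
      conf[idx, ] <- t(out)
    } else {
      heat[, , , idx] <- out
      conf[idx, ] <- t(apply(out, c(3, 4), max))
    }
  }
  list(confidences = conf, heatmaps = heat)
}

#' Save a model checkpoint with a YAML sidecar describing the architecture
#' @param model A `protloc_model`.
#' @param path Checkpoint path (`.rds`); `<path>.yaml` records the spec.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  yaml::write_yaml(unclass(model$spec), paste0(path, ".yaml"))
  invisible(path)
}

#' Load a model checkpoint
#' @param path Path written by [save_checkpoint()].
#' @return A `protloc_model`.
#' @export
load_checkpoint <- function(path) readRDS(path)
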