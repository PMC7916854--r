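# Training protocol: index-based train/validation/test split, mean binary
# cross-entropy, Adam (lr 0.001, beta1 0.9, beta2 0.999, eps 1e-8),
# divide-learning-rate-by-3 after 8 epochs without validation improvement,
# early stopping after 20, best-validation checkpointing.

#' Training configuration
#'
#' Defaults follow the standard Adam parameters (learning rate 0.001,
#' beta1 0.9, beta2 0.999, epsilon 1e-8) with plateau decay (divide by 3
#' after 8 stagnant epochs) and a 20-epoch early-stopping limit.
#'
#' @param learning_rate Initial Adam learning rate.
#' @param beta1,beta2,epsilon Adam moment parameters.
#' @param batch_size Minibatch size (64 at full scale; 8-16 for tests).
#' @param max_epochs Maximum training epochs.
#' @param plateau_patience Stagnant epochs before a learning-rate drop.
#' @param plateau_factor Learning-rate divisor at a plateau.
#' @param early_stop_patience Stagnant epochs before training stops.
#' @param val_fraction Fraction of the training block held out for
#'   validation.
#' @param seed Seed controlling shuffling and dropout.
#' @return Object of class `protloc_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, batch_size = 64, max_epochs = 100,
                         plateau_patience = 8, plateau_factor = 3,
                         early_stop_patience = 20, val_fraction = 0.10,
                         seed = 1) {
  stopifnot(val_fraction > 0, val_fraction < 1,
            plateau_patience >= 1, early_stop_patience >= 1)
  structure(as.list(environment()), class = "protloc_train_config")
}

#' Deterministic index-based dataset split
#'
#' The first `train_count` indices form the training block; its last
#' `val_fraction` becomes the validation set, and all remaining indices are
#' the test set.  (E.g. 20,000 samples with `train_count` 16,000 and 10%
#' validation give 14,400 / 1,600 / 4,000.)
#'
#' @param n_total Total sample count.
#' @param train_count Size of the training block (train + validation).
#' @param val_fraction Fraction of the block used for validation.
#' @return List with integer vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n_total, train_count, val_fraction = 0.10) {
  if (train_count > n_total) stop("train_count exceeds n_total")
  n_val <- round(train_count * val_fraction)
  if (n_val < 1) stop("val_fraction yields an empty validation set")
  if (n_val >= train_count) stop("val_fraction leaves no training samples")
  block <- seq_len(train_count)
  val <- block[(train_count - n_val + 1):train_count]
  train <- block[seq_len(train_count - n_val)]
  test <- if (train_count < n_total) (train_count + 1):n_total else integer(0)
  list(train = train, val = val, test = test)
}

#' Mean binary cross-entropy
#'
#' Averaged over every output element (13 scalars per sample for the CNN;
#' 13 x out x out heat-map pixels for the FCN).  Predictions are clipped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param predictions Numeric array/matrix of probabilities.
#' @param targets Binary array of the same shape.
#' @return Scalar loss.
#' @export
bce_loss <- function(predictions, targets) {
  if (length(predictions) != length(targets) ||
      !identical(dim(predictions), dim(targets)))
    stop("prediction and target shapes differ")
  p <- pmin(pmax(predictions, 1e-7), 1 - 1e-7)
  -mean(targets * log(p) + (1 - targets) * log1p(-p))
}

#' Fresh training state
#' @param config A [train_config()].
#' @return Object of class `protloc_train_state` with the current learning
#'   rate, running best validation loss, stagnation counters and an empty
#'   history data frame.
#' @export
train_state <- function(config = train_config()) {
  structure(list(epoch = 0L, current_lr = config$learning_rate,
                 best_val_loss = Inf, epochs_since_improvement = 0L,
                 plateau_wait = 0L, config = config,
                 history = data.frame(epoch = integer(), train_loss = numeric(),
                                      val_loss = numeric(), lr = numeric())),
            class = "protloc_train_state")
}

#' Advance the learning-rate schedule by one epoch
#'
#' "Improvement" means strictly beating the running best validation loss.
#' After `plateau_patience` (8) consecutive epochs without improvement the
#' learning rate is divided by `plateau_factor` (3) and the plateau counter
#' resets; the early-stopping counter keeps running across drops.
#'
#' @param state A `protloc_train_state`.
#' @param new_val_loss Validation loss of the epoch just finished.
#' @return Updated state.
#' @export
lr_schedule_step <- function(state, new_val_loss) {
  cfg <- state$config
  if (new_val_loss < state$best_val_loss) {
    state$best_val_loss <- new_val_loss
    state$epochs_since_improvement <- 0L
    state$plateau_wait <- 0L
  } else {
    state$epochs_since_improvement <- state$epochs_since_improvement + 1L
    state$plateau_wait <- state$plateau_wait + 1L
    if (state$plateau_wait >= cfg$plateau_patience) {
      state$current_lr <- state$current_lr / cfg$plateau_factor
      state$plateau_wait <- 0L
    }
  }
  state
}

#' Early-stopping decision
#' @param state A `protloc_train_state`.
#' @return `TRUE` iff the validation loss has not improved for
#'   `early_stop_patience` (20) consecutive epochs.
#' @export
early_stop_check <- function(state) {
  state$epochs_since_improvement >= state$config$early_stop_patience
}

# ---- Adam ----------------------------------------------------------------

.adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (l$type %in% c("conv", "dense"))
      list(mW = array(0, dim = dim(l$W) %||% length(l$W)), vW = array(0, dim = dim(l$W) %||% length(l$W)),
           mb = numeric(length(l$b)), vb = numeric(length(l$b)))
    else if (l$type == "bnorm")
      list(mg = numeric(length(l$gamma)), vg = numeric(length(l$gamma)),
           mb = numeric(length(l$beta)), vb = numeric(length(l$beta)))
    else NULL
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adam_update <- function(val, grad, m, v, lr, cfg, t) {
  m <- cfg$beta1 * m + (1 - cfg$beta1) * grad
  v <- cfg$beta2 * v + (1 - cfg$beta2) * grad^2
  mhat <- m / (1 - cfg$beta1^t)
  vhat <- v / (1 - cfg$beta2^t)
  list(val = val - lr * mhat / (sqrt(vhat) + cfg$epsilon), m = m, v = v)
}

# One optimizer step over all layers, given the grads list from .nn_batch.
.apply_grads <- function(layers, grads, opt, lr, cfg, t) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    l <- layers[[i]]
    if (l$type %in% c("conv", "dense")) {
      u <- .adam_update(l$W, g$W, opt[[i]]$mW, opt[[i]]$vW, lr, cfg, t)
      l$W <- u$val; opt[[i]]$mW <- u$m; opt[[i]]$vW <- u$v
      u <- .adam_update(l$b, g$b, opt[[i]]$mb, opt[[i]]$vb, lr, cfg, t)
      l$b <- u$val; opt[[i]]$mb <- u$m; opt[[i]]$vb <- u$v
    } else if (l$type == "bnorm") {
      u <- .adam_update(l$gamma, g$gamma, opt[[i]]$mg, opt[[i]]$vg, lr, cfg, t)
      l$gamma <- u$val; opt[[i]]$mg <- u$m; opt[[i]]$vg <- u$v
      u <- .adam_update(l$beta, g$beta, opt[[i]]$mb, opt[[i]]$vb, lr, cfg, t)
      l$beta <- u$val; opt[[i]]$mb <- u$m; opt[[i]]$vb <- u$v
      if (!is.null(g$running_mean)) {
        l$running_mean <- g$running_mean
        l$running_var <- g$running_var
      }
    }
    layers[[i]] <- l
  }
  list(layers = layers, opt = opt)
}

# Targets for a batch: matrix (13 x n) for CNN, array (out, out, 13, n) for
# FCN.  `targets` is the full-dataset structure; idx selects columns/slices.
.batch_targets <- function(targets, idx) {
  if (is.matrix(targets)) targets[, idx, drop = FALSE]
  else targets[, , , idx, drop = FALSE]
}

.eval_loss <- function(layers, x, targets, idx, batch_size) {
  tot <- 0; nn <- 0
  for (start in seq(1, length(idx), by = batch_size)) {
    sel <- idx[start:min(length(idx), start + batch_size - 1)]
    xb <- x[, , , sel, drop = FALSE]
    yb <- .batch_targets(targets, sel)
    r <- .nn_batch(layers, xb, as.numeric(yb), FALSE, FALSE)
    tot <- tot + r$loss * length(sel); nn <- nn + length(sel)
  }
  tot / nn
}

#' Train a model
#'
#' Minibatch Adam with the plateau learning-rate schedule and early
#' stopping; the returned model carries the weights of the epoch with the
#' lowest validation loss.  Fully reproducible from `config$seed` (epoch
#' shuffling and dropout both draw from R's RNG).
#'
#' @param model A `protloc_model` from [build_cnn()] or [build_fcn()].
#' @param x Input batch array (side x side x 4 x N) at the spec input side.
#' @param targets CNN: 13 x N binary matrix (i.e. `t(labels)`); FCN: out x
#'   out x 13 x N target array from [build_training_targets()].
#' @param train_idx,val_idx Integer index vectors (see [split_dataset()]).
#' @param config A [train_config()].
#' @param verbose Print one line per epoch to stderr.
#' @return List with `model` (best weights), `state` (history etc.).
#' @export
train_model <- function(model, x, targets, train_idx, val_idx,
                        config = train_config(), verbose = FALSE) {
  if (!length(train_idx)) stop("empty training set")
  state <- train_state(config)
  if (config$max_epochs == 0)
    return(list(model = model, state = state))
  layers <- model$layers
  opt <- .adam_init(layers)
  best_layers <- layers
  t_step <- 0
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(train_idx)
      tr_tot <- 0
      for (start in seq(1, length(ord), by = config$batch_size)) {
        sel <- ord[start:min(length(ord), start + config$batch_size - 1)]
        xb <- x[, , , sel, drop = FALSE]
        yb <- .batch_targets(targets, sel)
        r <- .nn_batch(layers, xb, as.numeric(yb), TRUE, TRUE)
        t_step <- t_step + 1
        up <- .apply_grads(layers, r$grads, opt, state$current_lr,
                           config, t_step)
        layers <- up$layers; opt <- up$opt
        tr_tot <- tr_tot + r$loss * length(sel)
      }
      train_loss <- tr_tot / length(ord)
      val_loss <- .eval_loss(layers, x, targets, val_idx, config$batch_size)
      improved <- val_loss < state$best_val_loss
      state <- lr_schedule_step(state, val_loss)
      state$epoch <- epoch
      state$history <- rbind(state$history,
                             data.frame(epoch = epoch, train_loss = train_loss,
                                        val_loss = val_loss,
                                        lr = state$current_lr))
      if (improved) best_layers <- layers
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2e",
                        epoch, train_loss, val_loss, state$current_lr))
      if (early_stop_check(state)) break
    }
  })
  model$layers <- best_layers
  list(model = model, state = state)
}

#' Write a training history as CSV (epoch, train_loss, val_loss, lr)
#' @param state A `protloc_train_state` returned by [train_model()].
#' @param path Output CSV path.
#' @export
write_history <- function(state, path) {
  write.csv(state$history, path, row.names = FALSE)
  invisible(path)
}
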