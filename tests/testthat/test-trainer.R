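# A tiny linearly separable task: class CY bright lower half, class NU
# bright upper half of the green channel; other channels noise.
toy_dataset <- function(n = 24, side = 32, seed = 1) {
  set.seed(seed)
  x <- array(runif(side * side * 4 * n, 0, 0.1), dim = c(side, side, 4, n))
  y <- matrix(0, 13, n)
  for (i in seq_len(n)) {
    if (i %% 2 == 0) { x[1:(side / 2), , 1, i] <- 0.9; y[11, i] <- 1 }
    else             { x[(side / 2 + 1):side, , 1, i] <- 0.9; y[3, i] <- 1 }
  }
  list(x = x, y = y)
}

toy_model <- function(seed = 2) {
  set.seed(seed)
  build_cnn(network_spec(input_side = 32, base_kernels = 4,
                         fc_widths = c(16, 8, 13), dropout_rate = 0.1))
}

test_that("index-based splitting reproduces the canonical 20k partition", {
  s <- split_dataset(20000, 16000, 0.10)
  expect_length(s$train, 14400)
  expect_length(s$val, 1600)
  expect_length(s$test, 4000)
  expect_equal(s$train, 1:14400)
  expect_equal(s$val, 14401:16000)
  expect_equal(s$test, 16001:20000)
})

test_that("splits partition the index range for arbitrary sizes", {
  for (case in list(c(100, 100), c(57, 40), c(251, 200))) {
    s <- split_dataset(case[1], case[2], 0.10)
    all_idx <- c(s$train, s$val, s$test)
    expect_equal(sort(all_idx), seq_len(case[1]))
    expect_false(any(duplicated(all_idx)))
  }
  expect_length(split_dataset(100, 100, 0.10)$test, 0)
  expect_error(split_dataset(10, 20, 0.1), "exceeds")
  expect_error(split_dataset(100, 5, 0.01), "empty validation")
})

test_that("binary cross-entropy matches its closed forms", {
  y <- matrix(rbinom(26, 1, 0.5), 13, 2)
  expect_equal(bce_loss(matrix(0.5, 13, 2), y), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(y * 0.9999999 + 0.0000001 * (1 - y), y), 1e-5)
  # all-zero targets at constant prediction p: loss = -log(1 - p)
  z <- array(0, dim = c(4, 4, 13))
  expect_equal(bce_loss(array(0.1, dim = c(4, 4, 13)), z), -log(0.9),
               tolerance = 1e-12)
  expect_equal(-log(0.9), 0.10536, tolerance = 1e-4)
  expect_error(bce_loss(matrix(0.5, 13, 2), matrix(1, 13, 3)), "shapes")
})

test_that("learning rate drops by 3 exactly at the 8th stagnant epoch", {
  st <- train_state(train_config())
  st <- lr_schedule_step(st, 0.5)      # improvement: best = 0.5
  for (i in 1:7) st <- lr_schedule_step(st, 0.6)
  expect_equal(st$current_lr, 0.001)   # 7 stagnant: unchanged
  st <- lr_schedule_step(st, 0.6)      # 8th stagnant
  expect_equal(st$current_lr, 0.001 / 3, tolerance = 1e-12)
  expect_equal(st$plateau_wait, 0L)    # counter reset after the drop
})

test_that("improvement resets the plateau counter without touching lr", {
  st <- train_state(train_config())
  st <- lr_schedule_step(st, 0.5)
  for (i in 1:7) st <- lr_schedule_step(st, 0.6)
  st <- lr_schedule_step(st, 0.4)      # improvement on the 8th
  expect_equal(st$current_lr, 0.001)
  expect_equal(st$plateau_wait, 0L)
  expect_equal(st$best_val_loss, 0.4)
})

test_that("strictly decreasing losses never change the learning rate", {
  st <- train_state(train_config())
  for (v in seq(1, 0.1, by = -0.05)) st <- lr_schedule_step(st, v)
  expect_equal(st$current_lr, 0.001)
  expect_equal(st$epochs_since_improvement, 0L)
})

test_that("the lr sequence follows 0.001 / 3^k", {
  st <- train_state(train_config())
  st <- lr_schedule_step(st, 1)
  lrs <- st$current_lr
  for (i in 1:40) {
    st <- lr_schedule_step(st, 2)      # never improves
    lrs <- c(lrs, st$current_lr)
  }
  ks <- log(0.001 / lrs) / log(3)
  expect_equal(ks, round(ks), tolerance = 1e-9)
  expect_true(all(diff(lrs) <= 0))
})

test_that("early stopping fires at 20 stagnant epochs, not 19", {
  st <- train_state(train_config())
  st <- lr_schedule_step(st, 0.5)
  for (i in 1:19) st <- lr_schedule_step(st, 0.6)
  expect_false(early_stop_check(st))
  st <- lr_schedule_step(st, 0.6)
  expect_true(early_stop_check(st))
  # an improvement resets the early-stop counter
  st2 <- train_state(train_config())
  st2 <- lr_schedule_step(st2, 0.5)
  for (i in 1:19) st2 <- lr_schedule_step(st2, 0.6)
  st2 <- lr_schedule_step(st2, 0.3)
  expect_equal(st2$epochs_since_improvement, 0L)
  expect_false(early_stop_check(st2))
})

test_that("training reduces the loss on separable toy data", {
  ds <- toy_dataset()
  m <- toy_model()
  cfg <- train_config(batch_size = 8, max_epochs = 6, seed = 9)
  fit <- train_model(m, ds$x, ds$y, train_idx = 1:20, val_idx = 21:24, cfg)
  h <- fit$state$history
  expect_equal(nrow(h), 6)
  expect_lt(h$train_loss[6], h$train_loss[1])
  expect_lt(h$val_loss[6], h$val_loss[1])
})

test_that("max_epochs = 0 returns the untrained model with empty history", {
  ds <- toy_dataset(n = 8)
  m <- toy_model()
  fit <- train_model(m, ds$x, ds$y, 1:6, 7:8,
                     train_config(max_epochs = 0, batch_size = 4))
  expect_identical(fit$model$layers, m$layers)
  expect_equal(nrow(fit$state$history), 0)
})

test_that("training is reproducible from the seed and rejects empty sets", {
  ds <- toy_dataset(n = 12)
  cfg <- train_config(batch_size = 4, max_epochs = 3, seed = 31)
  f1 <- train_model(toy_model(), ds$x, ds$y, 1:10, 11:12, cfg)
  f2 <- train_model(toy_model(), ds$x, ds$y, 1:10, 11:12, cfg)
  expect_identical(f1$state$history, f2$state$history)
  expect_identical(f1$model$layers, f2$model$layers)
  expect_error(train_model(toy_model(), ds$x, ds$y, integer(0), 1:2, cfg),
               "empty training set")
})

test_that("the returned model carries the best-validation weights", {
  ds <- toy_dataset(n = 16)
  cfg <- train_config(batch_size = 4, max_epochs = 5, seed = 13)
  fit <- train_model(toy_model(), ds$x, ds$y, 1:12, 13:16, cfg)
  h <- fit$state$history
  # recompute validation loss of the returned weights: equals the minimum
  pr <- protlocnet:::.nn_batch(fit$model$layers,
                               ds$x[, , , 13:16, drop = FALSE],
                               as.numeric(ds$y[, 13:16]), FALSE, FALSE)
  expect_equal(pr$loss, min(h$val_loss), tolerance = 1e-10)
})

test_that("history CSV has the Fig-9-style columns", {
  ds <- toy_dataset(n = 8)
  fit <- train_model(toy_model(), ds$x, ds$y, 1:6, 7:8,
                     train_config(batch_size = 4, max_epochs = 2, seed = 1))
  p <- file.path(withr::local_tempdir(), "h.csv")
  write_history(fit$state, p)
  h <- read.csv(p)
  expect_equal(names(h), c("epoch", "train_loss", "val_loss", "lr"))
  expect_equal(nrow(h), 2)
})
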