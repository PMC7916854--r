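test_that("dice coefficient matches its closed form and conventions", {
  expect_equal(dice_for_class(c(1, 1, 1, 0, 0, 0), c(1, 1, 0, 1, 0, 0)),
               4 / 6)
  expect_equal(dice_for_class(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(dice_for_class(c(0, 0), c(0, 0)), 0)  # zero-denominator rule
  expect_error(dice_for_class(c(1, 0), c(1, 0, 1)), "length")
})

test_that("dice equals the per-class F1 score", {
  set.seed(21)
  for (i in 1:100) {
    pred <- rbinom(40, 1, runif(1, 0.1, 0.9))
    tru <- rbinom(40, 1, runif(1, 0.1, 0.9))
    tp <- sum(pred & tru)
    prec <- if (sum(pred)) tp / sum(pred) else 0
    rec <- if (sum(tru)) tp / sum(tru) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    expect_equal(dice_for_class(pred, tru), f1, tolerance = 1e-12)
  }
})

test_that("threshold calibration picks the smallest dice-maximizing value", {
  conf <- matrix(c(0.2, 0.4, 0.6, 0.8), 4, 1)
  tru <- matrix(c(0, 0, 1, 1), 4, 1)
  expect_equal(unname(calibrate_thresholds(conf, tru)[1]), 0.41)
  # already perfect at 0: tie-break returns 0
  expect_equal(unname(calibrate_thresholds(matrix(0.9, 5, 1),
                                           matrix(1, 5, 1))[1]), 0)
  # constructed tie: thresholds in (0.3, 0.7] all give dice 1
  conf2 <- matrix(c(0.1, 0.3, 0.7, 0.9), 4, 1)
  tru2 <- matrix(c(0, 0, 1, 1), 4, 1)
  expect_equal(unname(calibrate_thresholds(conf2, tru2)[1]), 0.31)
})

test_that("calibration is invariant to sample order", {
  set.seed(5)
  conf <- matrix(runif(50 * 13), 50, 13)
  tru <- matrix(rbinom(50 * 13, 1, 0.3), 50, 13)
  perm <- sample(50)
  expect_equal(calibrate_thresholds(conf, tru),
               calibrate_thresholds(conf[perm, ], tru[perm, ]))
})

test_that("calibration equals exhaustive grid search on random instances", {
  for (rep in 1:10) {
    set.seed(rep)
    conf <- matrix(round(runif(50 * 13), 3), 50, 13)
    tru <- matrix(rbinom(50 * 13, 1, runif(1, 0.1, 0.5)), 50, 13)
    expect_equal(unname(calibrate_thresholds(conf, tru)),
                 oracle_calibrate(conf, tru), tolerance = 1e-12)
  }
})

test_that("thresholding uses the inclusive >= rule", {
  conf <- matrix(c(0.5, 0.49), 2, 1)
  expect_equal(as.vector(apply_thresholds(conf, 0.5)), c(1, 0))
  expect_equal(sum(apply_thresholds(matrix(0, 3, 13), rep(0.01, 13))), 0)
  expect_equal(sum(apply_thresholds(matrix(0, 3, 13), rep(0, 13))), 39)
})

test_that("the multi-label attribution rule fills the confusion matrix", {
  cm <- multilabel_confusion(list(c("NU", "NI")), list(c("NU", "CY")))
  expect_equal(cm$counts["NU", "NU"], 1)
  expect_equal(cm$counts["NI", "CY"], 1)
  expect_equal(sum(cm$counts), 2)
  expect_equal(unname(cm$row_totals[c("NU", "NI")]), c(1, 1))
  # exact single-label match: diagonal only
  cm2 <- multilabel_confusion(list("NU"), list("NU"))
  expect_equal(sum(cm2$counts), 1)
  expect_equal(cm2$counts["NU", "NU"], 1)
  # missed label without false positives: row total grows, no counts
  cm3 <- multilabel_confusion(list("AF"), list(character(0)))
  expect_equal(sum(cm3$counts), 0)
  expect_equal(unname(cm3$row_totals["AF"]), 1)
  expect_equal(unname(cm3$normalized["AF", "AF"]), 0)
  expect_error(multilabel_confusion(list(), list()), "empty")
})

test_that("single-label samples reduce to the classical confusion matrix", {
  # enumerate all (T, P) with |T| = 1, |P| <= 2 over 3 classes
  cls <- c("NU", "CY", "VE")
  preds <- c(list(character(0)), as.list(cls),
             utils::combn(cls, 2, simplify = FALSE))
  for (t0 in cls) for (P0 in preds) {
    cm <- multilabel_confusion(list(t0), list(P0))
    if (t0 %in% P0) {
      expect_equal(sum(cm$counts), 1)
      expect_equal(cm$counts[t0, t0], 1)
    } else {
      # every false positive hits the missed true row
      expect_equal(sum(cm$counts), length(P0))
      for (c1 in P0) expect_equal(cm$counts[t0, c1], 1)
    }
  }
})

test_that("diagonal counts total the per-sample true-label hits", {
  set.seed(31)
  cls <- organelle_classes()
  tru <- lapply(1:60, function(i) sample(cls, sample(1:3, 1)))
  pred <- lapply(1:60, function(i) sample(cls, sample(0:3, 1)))
  cm <- multilabel_confusion(tru, pred)
  hits <- sum(vapply(1:60, function(i)
    length(intersect(tru[[i]], pred[[i]])), numeric(1)))
  expect_equal(sum(diag(cm$counts)), hits)
})

test_that("mean diagonal accuracy averages only represented classes", {
  cm <- multilabel_confusion(list("NU", "NU", "CY"), list("NU", "CY", "CY"))
  # NU found 1/2, CY 1/1
  expect_warning(acc <- mean_diag_accuracy(cm), "excluded")
  expect_equal(acc, mean(c(0.5, 1)))
  perfect <- multilabel_confusion(list("NU", "CY"), list("NU", "CY"))
  expect_equal(suppressWarnings(mean_diag_accuracy(perfect)), 1)
})

test_that("multilocalization strata score exact and all-found rules", {
  tru <- list("NU", c("NU", "CY", "VE"), c("NU", "CY"))
  pred <- list("NU", c("NU", "CY"), c("NU", "CY", "VE"))
  ex <- accuracy_by_multiloc(tru, pred)
  expect_equal(ex$fraction[1], 1)            # exact match
  expect_equal(ex$fraction[3], 0)            # subset is not exact
  expect_equal(ex$fraction[2], 0)            # superset is not exact
  expect_true(is.na(ex$fraction[4]))         # empty stratum
  af <- accuracy_by_multiloc(tru, pred, rule = "all_found")
  expect_equal(af$fraction[2], 1)            # extra prediction allowed
  expect_equal(af$fraction[3], 0)            # VE still missed
})

test_that("co-occurrence fractions count shared-sample rates", {
  co <- cooccurrence_matrix(list("NU", c("NU", "NI"), c("NI", "CY")))
  expect_equal(co["NU", "NI"], 1 / 2)
  expect_equal(co["NI", "NU"], 1 / 2)
  expect_equal(co["NI", "CY"], 1 / 2)
  expect_equal(co["NU", "NU"], 1)
  expect_equal(co["NI", "NI"], 1)
  single <- cooccurrence_matrix(list("NU", "CY", "NU"))
  offdiag <- single[c("NU", "CY"), c("NU", "CY")]
  expect_equal(offdiag, diag(2), ignore_attr = TRUE)
})

test_that("group-stratified dice degenerates to the global mean", {
  set.seed(41)
  conf <- matrix(runif(30 * 13), 30, 13,
                 dimnames = list(NULL, organelle_classes()))
  tru <- matrix(rbinom(30 * 13, 1, 0.4), 30, 13)
  th <- rep(0.5, 13)
  g1 <- groupwise_dice(conf, tru, th, rep("U2OS", 30))
  pred <- apply_thresholds(conf, th)
  global <- mean(vapply(1:13, function(ci)
    dice_for_class(pred[, ci], tru[, ci]), numeric(1)))
  expect_equal(unname(g1["U2OS"]), global)
  expect_error(groupwise_dice(conf, tru, th, rep("a", 5)), "align")
})

test_that("minority tags pool into an 'other' group", {
  set.seed(42)
  conf <- matrix(runif(40 * 13), 40, 13)
  tru <- matrix(rbinom(40 * 13, 1, 0.4), 40, 13)
  tags <- c(rep("A", 15), rep("B", 12), rep("C", 9), "d1", "d2", "d3", "d4")
  g <- groupwise_dice(conf, tru, rep(0.5, 13), tags)
  expect_equal(names(g), c("A", "B", "C", "other"))
  # perfect vs hopeless groups
  conf2 <- rbind(tru[1:20, ], 1 - tru[21:40, ])
  g2 <- groupwise_dice(conf2, tru, rep(0.5, 13),
                       c(rep("good", 20), rep("bad", 20)), n_major = 2)
  expect_equal(unname(g2["good"]), 1)
  expect_equal(unname(g2["bad"]), 0)
})

test_that("evaluation metrics are invariant to class permutation", {
  set.seed(43)
  conf <- matrix(runif(25 * 13), 25, 13,
                 dimnames = list(NULL, organelle_classes()))
  tru <- matrix(rbinom(25 * 13, 1, 0.4), 25, 13,
                dimnames = list(NULL, organelle_classes()))
  th <- calibrate_thresholds(conf, tru)
  r1 <- evaluate_predictions(conf, tru, th)
  perm <- sample(13)
  r2 <- evaluate_predictions(conf[, perm], tru[, perm], th[perm])
  expect_equal(r1$mean_dice, r2$mean_dice)
  expect_equal(r1$mean_diag_accuracy, r2$mean_diag_accuracy)
  expect_true(r1$mean_dice >= 0 && r1$mean_dice <= 1)
})

test_that("a near-perfect classifier evaluates near 1 end to end", {
  set.seed(44)
  tru <- matrix(0, 60, 13, dimnames = list(NULL, organelle_classes()))
  for (i in 1:60) tru[i, sample(13, 1)] <- 1
  conf <- tru * matrix(runif(60 * 13, 0.85, 1), 60, 13) +
    (1 - tru) * matrix(runif(60 * 13, 0, 0.1), 60, 13)
  th <- calibrate_thresholds(conf, tru)
  r <- evaluate_predictions(conf, tru, th)
  expect_gte(r$mean_diag_accuracy, 0.99)
  expect_gte(r$mean_dice, 0.99)
})

test_that("evaluation reports serialize to JSON and CSV", {
  set.seed(45)
  tru <- matrix(rbinom(20 * 13, 1, 0.3), 20, 13,
                dimnames = list(NULL, organelle_classes()))
  conf <- matrix(pmin(1, pmax(0, tru + rnorm(20 * 13, 0, 0.2))), 20, 13,
                 dimnames = dimnames(tru))
  th <- calibrate_thresholds(conf, tru)
  r <- evaluate_predictions(conf, tru, th, rep(c("A", "B"), 10))
  d <- withr::local_tempdir()
  write_eval_report(r, d)
  j <- jsonlite::read_json(file.path(d, "eval_report.json"))
  expect_equal(j$mean_dice, r$mean_dice, tolerance = 1e-12)
  expect_length(j$thresholds, 13)
  cm <- read.csv(file.path(d, "confusion_normalized.csv"), row.names = 1)
  expect_equal(dim(cm), c(13, 13))
})
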