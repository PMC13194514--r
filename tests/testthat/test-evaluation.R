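# Independent reference implementations used as oracles in this file: the
# confusion tally is recomputed element-by-element, and kappa is
# cross-checked against e1071::classAgreement.

brute_confusion <- function(y_true, y_pred, positive = 0L) {
  tp <- fn <- tn <- fp <- 0L
  for (i in seq_along(y_true)) {
    if (y_true[i] == positive) {
      if (y_pred[i] == y_true[i]) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (y_pred[i] == y_true[i]) tn <- tn + 1L else fp <- fp + 1L
    }
  }
  c(tp = tp, fn = fn, tn = tn, fp = fp)
}

counts_from <- function(tp, fn, tn, fp, positive = 0L) {
  y_true <- c(rep(0L, tp + fn), rep(1L, tn + fp))
  y_pred <- c(rep(0L, tp), rep(1L, fn), rep(1L, tn), rep(0L, fp))
  confusion_counts(y_true, y_pred, positive_label = positive)
}

test_that("confusion counts follow the normal-as-positive convention", {
  cc <- confusion_counts(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(unlist(cc[c("tp", "fn", "tn", "fp")]),
               c(tp = 2L, fn = 0L, tn = 2L, fp = 0L))
  cc2 <- confusion_counts(c(0, 1), c(1, 0))
  expect_equal(unlist(cc2[c("tp", "fn", "tn", "fp")]),
               c(tp = 0L, fn = 1L, tn = 0L, fp = 1L))

  set.seed(20)
  yt <- sample(0:1, 200, replace = TRUE)
  yp <- sample(0:1, 200, replace = TRUE)
  cc3 <- confusion_counts(yt, yp)
  expect_equal(unlist(cc3[c("tp", "fn", "tn", "fp")]), brute_confusion(yt, yp))

  expect_error(confusion_counts(c(0, 2), c(0, 1)), "binary")
  expect_error(confusion_counts(c(0, 1), c(0, 1, 1)), "lengths")
})

test_that("classification metrics reproduce the worked example", {
  cc <- counts_from(tp = 40L, fn = 10L, tn = 30L, fp = 20L)
  m <- classification_metrics(cc)
  expect_equal(m$accuracy, 0.70, tolerance = 1e-12)
  expect_equal(m$precision, 2 / 3, tolerance = 1e-12)
  expect_equal(m$recall, 0.80, tolerance = 1e-12)
  expect_equal(m$f1, 2 * (2 / 3) * 0.8 / (2 / 3 + 0.8), tolerance = 1e-12)
  expect_equal(round(m$f1, 4), 0.7273)

  perfect <- counts_from(tp = 5L, fn = 0L, tn = 7L, fp = 0L)
  mp <- classification_metrics(perfect)
  expect_equal(unlist(mp), c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  # degenerate denominators come back as flagged zeros, not errors
  deg <- counts_from(tp = 0L, fn = 3L, tn = 4L, fp = 0L)
  expect_warning(md <- classification_metrics(deg), "precision undefined")
  expect_equal(md$precision, 0)
  expect_equal(md$recall, 0)
})

test_that("kappa reproduces the worked example and its chance structure", {
  cc <- counts_from(tp = 40L, fn = 10L, tn = 30L, fp = 20L)
  expect_equal(kappa(cc), 0.40, tolerance = 1e-12)
  # observed agreement equals accuracy by construction
  expect_equal(classification_metrics(cc)$accuracy, 0.70)

  perfect <- counts_from(tp = 6L, fn = 0L, tn = 4L, fp = 0L)
  expect_equal(kappa(perfect), 1)

  # constant labels on both sides: chance agreement 1, kappa undefined
  allpos <- confusion_counts(rep(0L, 5), rep(0L, 5))
  expect_error(kappa(allpos), "undefined")

  # permutation null: independent predictions give kappa ~ 0
  set.seed(21)
  yt <- sample(0:1, 200, replace = TRUE)
  ks <- replicate(1000, {
    kappa(confusion_counts(yt, sample(yt)))
  })
  expect_lt(abs(mean(ks)), 0.05)
})

test_that("metrics agree with independent references on random inputs", {
  set.seed(22)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    yt <- sample(0:1, n, replace = TRUE)
    yp <- if (runif(1) < 0.5) sample(0:1, n, replace = TRUE) else {
      ifelse(runif(n) < 0.3, 1L - yt, yt)
    }
    if (length(unique(yt)) < 2 || length(unique(yp)) < 2) next
    cc <- confusion_counts(yt, yp)
    m <- classification_metrics(cc)
    ca <- e1071::classAgreement(table(yp, yt))
    expect_equal(m$accuracy, ca$diag, tolerance = 1e-9)
    expect_equal(kappa(cc), ca$kappa, tolerance = 1e-9)
    # regression metrics vs direct formulas on the same draws
    s_true <- runif(n, 0, 27)
    s_pred <- s_true + rnorm(n, sd = 3)
    rm <- regression_metrics(s_true, s_pred)
    expect_equal(rm$mse, mean((s_true - s_pred)^2), tolerance = 1e-9)
    expect_equal(rm$rmse, sqrt(rm$mse), tolerance = 1e-9)
    expect_equal(rm$mae, mean(abs(s_true - s_pred)), tolerance = 1e-9)
    expect_equal(rm$medae, median(abs(s_true - s_pred)), tolerance = 1e-9)
    expect_lte(rm$mae, rm$rmse + 1e-12)                 # Jensen
    expect_lte(rm$medae, max(abs(s_true - s_pred)) + 1e-12)
  }
})

test_that("regression metrics reproduce the worked example and robustness", {
  m <- regression_metrics(c(20, 5, 10), c(18, 5, 13))
  expect_equal(m$mse, 13 / 3, tolerance = 1e-12)
  expect_equal(m$rmse, sqrt(13 / 3), tolerance = 1e-12)
  expect_equal(round(m$rmse, 4), 2.0817)
  expect_equal(m$mae, 5 / 3, tolerance = 1e-12)
  expect_equal(m$medae, 2)

  z <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(z), c(mse = 0, rmse = 0, mae = 0, medae = 0))

  # the median error ignores a single large outlier that dominates the mean
  o <- regression_metrics(c(0, 0, 0, 20), c(0, 0, 0, 0))
  expect_equal(o$medae, 0)
  expect_equal(o$mae, 5)
})

test_that("swapping the positive label swaps precision/recall but not accuracy/kappa", {
  set.seed(23)
  yt <- sample(0:1, 150, replace = TRUE)
  yp <- ifelse(runif(150) < 0.25, 1L - yt, yt)
  c0 <- confusion_counts(yt, yp, positive_label = 0L)
  c1 <- confusion_counts(yt, yp, positive_label = 1L)
  m0 <- classification_metrics(c0)
  m1 <- classification_metrics(c1)
  expect_equal(m0$accuracy, m1$accuracy)
  expect_equal(kappa(c0), kappa(c1), tolerance = 1e-12)
  expect_equal(c0$tp, c1$tn)
  expect_equal(c0$fp, c1$fn)
})

test_that("the per-subject report recomputes each subject's errors", {
  records <- data.frame(subject_id = 1:3, group = c("MDD", "HC", "HC"),
                        phq9 = c(15L, 2L, 4L))
  folds <- list(
    list(held_out_subject = 1L, trial_predictions = rep(15, 4),
         trial_truth = rep(15, 4)),
    list(held_out_subject = 2L, trial_predictions = rep(4, 4),
         trial_truth = rep(2, 4)),
    list(held_out_subject = 3L, trial_predictions = c(3, 5, 4, 4),
         trial_truth = rep(4, 4))
  )
  rep <- subject_level_report(folds, records)
  expect_equal(rep$rmse[1L], 0)
  expect_equal(rep$mae[2L], 2)     # constant +2 offset
  expect_equal(rep$medae[2L], 2)
  expect_equal(rep$rmse[3L], sqrt(mean(c(1, 1, 0, 0))))
  folds[[1L]]$held_out_subject <- 99L
  expect_error(subject_level_report(folds, records), "missing")
})
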