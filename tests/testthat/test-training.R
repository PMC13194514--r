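test_that("label normalisation maps the score range onto [0, 1] and back", {
  tab <- load_subject_table(cohort_table_path())
  p <- fit_label_normalizer(tab, "train_minmax")
  expect_equal(c(p$ymin, p$ymax), c(0, 24))   # observed cohort range
  pb <- fit_label_normalizer(tab, "scale_bounds")
  expect_equal(c(pb$ymin, pb$ymax), c(0, 27))

  expect_equal(normalize_labels(27, pb), 1)
  expect_equal(normalize_labels(0, pb), 0)
  expect_equal(normalize_labels(23, pb), 23 / 27, tolerance = 1e-12)
  expect_equal(round(normalize_labels(23, pb), 4), 0.8519)
  expect_equal(denormalize_predictions(1, pb), 27)
  expect_equal(denormalize_predictions(0.5, p), 12)

  y <- c(0, 5, 23, 27)
  expect_equal(denormalize_predictions(normalize_labels(y, pb), pb), y,
               tolerance = 1e-9)
  # the map is strictly monotone affine
  expect_true(all(diff(normalize_labels(0:27, pb)) > 0))

  same <- data.frame(phq9 = c(7L, 7L, 7L))
  expect_error(fit_label_normalizer(same, "train_minmax"),
               "degenerate.*scale_bounds")
  expect_warning(normalize_labels(30, pb), "outside")
})

test_that("metrics after denormalisation are invariant to the (ymin, ymax) choice", {
  # closed-form check on a fixed prediction vector
  yhat <- c(3.2, 17.9, 8.4, 25.0)
  y <- c(4, 18, 7, 23)
  for (p in list(fit_label_normalizer(data.frame(phq9 = c(0L, 24L))),
                 fit_label_normalizer(data.frame(phq9 = c(2L, 20L))),
                 structure(list(ymin = 0, ymax = 27),
                           class = "normalization_params"))) {
    m <- regression_metrics(y, denormalize_predictions(normalize_labels(yhat, p), p))
    m0 <- regression_metrics(y, yhat)
    expect_equal(m, m0, tolerance = 1e-12)
  }
})

test_that("cue triplets pair per-cue trials with the min-count policy", {
  h <- random_epoch_set(n = 8L, C = 2L, T = 40L, seed = 1L, cue = "hcue",
                        subject_id = 4L)
  f <- random_epoch_set(n = 6L, C = 2L, T = 40L, seed = 2L, cue = "fcue",
                        subject_id = 4L)
  s <- random_epoch_set(n = 8L, C = 2L, T = 40L, seed = 3L, cue = "scue",
                        subject_id = 4L)
  expect_message(bt <- make_cue_triplets(h, f, s), "dropping 4 excess")
  expect_equal(dim(bt$x_happy)[1L], 6L)
  expect_equal(bt$x_happy[3L, , ], h$data[3L, , ])   # by-index pairing

  # equal counts keep everything
  f8 <- random_epoch_set(n = 8L, C = 2L, T = 40L, seed = 2L, cue = "fcue",
                         subject_id = 4L)
  bt8 <- make_cue_triplets(h, f8, s)
  expect_equal(dim(bt8$x_happy)[1L], 8L)

  # shuffled pairing is deterministic under the seed and permutes trials
  b1 <- make_cue_triplets(h, f8, s, policy = "shuffled", seed = 5L)
  b2 <- make_cue_triplets(h, f8, s, policy = "shuffled", seed = 5L)
  expect_identical(b1$x_fear, b2$x_fear)
  expect_false(identical(b1$x_fear, bt8$x_fear))

  other <- random_epoch_set(n = 8L, C = 2L, T = 40L, seed = 9L, cue = "scue",
                            subject_id = 5L)
  expect_error(make_cue_triplets(h, f8, other), "same subject")

  rec <- data.frame(subject_id = 4L, phq9 = 17L, label = 1L)
  btl <- make_cue_triplets(h, f8, s, record = rec)
  expect_equal(btl$labels_class, rep(1L, 8L))
  expect_equal(btl$labels_score, rep(17, 8L))
})

test_that("training respects the epoch budget and keeps the best-validation weights", {
  co <- tiny_cohort(n_per_group = 2L, seed = 3L)
  batch <- mceegnet:::triplet_rbind(lapply(co$subjects, `[[`, "triplets"))
  cfg <- mceegnet_config(branch_config(4L, 125L, f1 = 2L, temporal_kernel = 15L,
                                       sep_kernel = 5L),
                         mode = "classify")
  tc <- train_config(epochs = 4L, batch_size = 16L, seed = 1L)
  fit <- train_model(build_model(cfg, seed = 1L), batch, tc)
  expect_lte(nrow(fit$history), 4L)
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
  expect_true(all(is.finite(fit$history$train_loss)))

  # reproducibility: same seeds, same data -> identical weights
  fit2 <- train_model(build_model(cfg, seed = 1L), batch, tc)
  expect_identical(fit$model$params, fit2$model$params)
  expect_equal(fit$history, fit2$history)

  expect_error(train_model(build_model(cfg, seed = 1L), batch,
                           train_config(val_fraction = 0.01, seed = 1L)),
               "validation split would be empty")
})

test_that("a high-separation synthetic set is learnable to high training accuracy", {
  cfg <- sim_config(n_channels = 8L, n_trials_per_cue = 34L,
                    severity_slope = c(hcue = -0.5, fcue = 0.4, scue = 0.4),
                    noise = c(pink = 0.4, white = 0.3))
  co <- simulate_cohort(cfg, n_mdd = 6L, n_hc = 6L, seed = 0L)
  batch <- mceegnet:::triplet_rbind(lapply(co$subjects, `[[`, "triplets"))
  mcfg <- mceegnet_config(branch_config(8L, 125L), mode = "classify")
  fit <- train_model(build_model(mcfg, seed = 0L), batch,
                     train_config(epochs = 10L, seed = 0L))
  pred <- forward(fit$model, batch)
  acc <- mean((max.col(pred$class_probs) - 1L) == batch$labels_class)
  expect_gte(acc, 0.95)
})

test_that("LOSOCV builds one leakage-free fold per subject", {
  co <- tiny_cohort(n_per_group = 3L, seed = 2L)
  res <- run_losocv(co, fast_train_cfg(seed = 1L, epochs = 1L),
                    task = "classify")
  expect_s3_class(res, "losocv_result")
  expect_length(res$folds, 6L)
  for (f in res$folds) {
    expect_length(f$train_subjects, 5L)
    expect_false(f$held_out_subject %in% f$train_subjects)
    expect_length(intersect(f$heldout_trial_ids, f$train_trial_ids), 0L)
    expect_length(f$trial_predictions, 8L)
  }
  expect_error(run_losocv(co$subjects[1:2], fast_train_cfg()), "at least 3")

  # single-class cohorts cannot be classified
  cfg <- sim_config(n_channels = 4L, n_trials_per_cue = 4L)
  mono <- simulate_cohort(cfg, n_mdd = 3L, n_hc = 1L, seed = 1L)
  mono$subjects <- mono$subjects[1:3]
  expect_error(run_losocv(mono$subjects, fast_train_cfg(), task = "classify"),
               "both classes")
})

test_that("regression folds fit their normaliser on training subjects only", {
  co <- tiny_cohort(n_per_group = 3L, seed = 4L)
  res <- run_losocv(co, fast_train_cfg(seed = 2L, epochs = 1L),
                    task = "regress")
  recs <- co$records
  for (f in res$folds) {
    train_scores <- recs$phq9[recs$subject_id %in% f$train_subjects]
    expect_equal(f$normalizer$ymin, min(train_scores))
    expect_equal(f$normalizer$ymax, max(train_scores))
    # predictions come back on the PHQ-9 scale
    expect_true(all(f$trial_truth == recs$phq9[recs$subject_id == f$held_out_subject]))
  }
  expect_s3_class(res$per_subject, "data.frame")
  expect_equal(nrow(res$per_subject), 6L)
})
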