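# Label normalisation, cue-triplet pairing, minibatch optimisation with
# early stopping, and the leave-one-subject-out cross-validation harness.

#' Training configuration
#'
#' @param epochs Maximum number of training epochs (default 20).
#' @param optimizer Only `"adam"` is provided.
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Minibatch size (default 64).
#' @param val_fraction Fraction of the training data held out as a
#'   validation set for early stopping (default 0.10).
#' @param seed Integer seed controlling the split, shuffling and dropout.
#' @param class_weights `"balanced"` (default) weights the cross-entropy
#'   by inverse class frequency of the training split, compensating the
#'   majority-class bias of imbalanced (and leave-one-subject-out) folds;
#'   `"none"` uses the plain mean.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 20L, optimizer = c("adam"),
                         learning_rate = 1e-3, batch_size = 64L,
                         val_fraction = 0.10, seed = 0L,
                         class_weights = c("balanced", "none")) {
  optimizer <- match.arg(optimizer)
  class_weights <- match.arg(class_weights)
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop_contract("val_fraction must lie in (0, 1)")
  }
  if (epochs < 1L) stop_contract("epochs must be >= 1")
  structure(list(epochs = as.integer(epochs), optimizer = optimizer,
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 class_weights = class_weights),
            class = "train_config")
}

# ---- label normalisation --------------------------------------------------

#' Fit min-max label normalisation parameters
#'
#' `"train_minmax"` maps the training subjects' score range to `[0, 1]`
#' (fitted per cross-validation fold, on training subjects only, to avoid
#' label leakage); `"scale_bounds"` uses the full PHQ-9 scale `(0, 27)`.
#'
#' @param train_records A `subject_table` (or data frame with a `phq9`
#'   column) of the training subjects.
#' @param strategy `"train_minmax"` or `"scale_bounds"`.
#' @return An object of class `normalization_params` with fields `ymin`,
#'   `ymax`.
#' @export
fit_label_normalizer <- function(train_records,
                                 strategy = c("train_minmax", "scale_bounds")) {
  strategy <- match.arg(strategy)
  if (strategy == "scale_bounds") {
    return(structure(list(ymin = 0, ymax = 27), class = "normalization_params"))
  }
  y <- train_records$phq9
  if (length(unique(y)) < 2L) {
    stop_contract(paste0("degenerate score range (all training scores equal %s); ",
                         "use strategy = 'scale_bounds'"), unique(y)[1L])
  }
  structure(list(ymin = min(y), ymax = max(y)), class = "normalization_params")
}

#' Map PHQ-9 scores to the normalised [0, 1] training scale
#'
#' Affine map `y* = (y - ymin) / (ymax - ymin)`. Scores outside
#' `[ymin, ymax]` map outside `[0, 1]` by design (a warning is emitted).
#'
#' @param y Numeric scores.
#' @param p A `normalization_params` object.
#' @return Normalised scores.
#' @export
normalize_labels <- function(y, p) {
  stopifnot(inherits(p, "normalization_params"))
  out <- (y - p$ymin) / (p$ymax - p$ymin)
  if (any(out < 0 | out > 1)) {
    warning("some scores fall outside the fitted [ymin, ymax] range", call. = FALSE)
  }
  out
}

#' Map normalised predictions back to the PHQ-9 scale
#'
#' Inverse of [normalize_labels()]: `y = y* (ymax - ymin) + ymin`.
#'
#' @param y_star Numeric predictions on the normalised scale.
#' @param p A `normalization_params` object.
#' @return Scores on the PHQ-9 scale.
#' @export
denormalize_predictions <- function(y_star, p) {
  stopifnot(inherits(p, "normalization_params"))
  y_star * (p$ymax - p$ymin) + p$ymin
}

# ---- triplet pairing ------------------------------------------------------

#' Pair per-cue trials into model input triplets
#'
#' The three cue conditions are recorded as separate trial sets; the model
#' consumes aligned (happy, fear, sad) triplets. `"by_index"` pairs the
#' i-th trial of each condition; `"shuffled"` permutes trials within each
#' condition under `seed` before pairing. The triplet count is the minimum
#' of the three trial counts; excess trials are dropped with a message.
#'
#' @param hcue,fcue,scue [epoch_set()] objects from the same subject.
#' @param policy `"by_index"` or `"shuffled"`.
#' @param seed Seed for the `"shuffled"` policy.
#' @param record Optional one-row subject record used to attach
#'   `labels_class` (group) and `labels_score` (PHQ-9) to every triplet.
#' @return A [cue_triplet_batch()].
#' @export
make_cue_triplets <- function(hcue, fcue, scue, policy = c("by_index", "shuffled"),
                              seed = 0L, record = NULL) {
  policy <- match.arg(policy)
  sets <- list(hcue = hcue, fcue = fcue, scue = scue)
  for (nm in names(sets)) {
    stopifnot(inherits(sets[[nm]], "epoch_set"))
    if (sets[[nm]]$cue != nm) {
      stop_contract("argument %s holds cue '%s'", nm, sets[[nm]]$cue)
    }
  }
  sid <- unique(vapply(sets, `[[`, 0L, "subject_id"))
  if (length(sid) != 1L) {
    stop_contract("all three epoch sets must come from the same subject (got %s)",
                  paste(sid, collapse = ", "))
  }
  counts <- vapply(sets, function(s) dim(s$data)[1L], 0L)
  if (any(counts == 0L)) stop_contract("empty epoch set for cue %s",
                                       names(counts)[counts == 0L][1L])
  n <- min(counts)
  if (any(counts > n)) {
    message(sprintf("dropping %d excess trial(s) beyond the common count %d",
                    sum(counts - n), n))
  }
  pick <- lapply(counts, function(cnt) {
    idx <- seq_len(cnt)
    if (policy == "shuffled") idx <- with_seed(seed, sample(idx))
    idx[seq_len(n)]
  })
  lab <- score <- NULL
  if (!is.null(record)) {
    lab <- rep(as.integer(record$label), n)
    score <- rep(as.numeric(record$phq9), n)
  }
  cue_triplet_batch(
    sets$hcue$data[pick$hcue, , , drop = FALSE],
    sets$fcue$data[pick$fcue, , , drop = FALSE],
    sets$scue$data[pick$scue, , , drop = FALSE],
    labels_class = lab, labels_score = score, subject_id = sid
  )
}

# ---- optimisation ---------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(t = 0L, m = zeros, v = zeros)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) stop_contract("missing gradient for parameter '%s'", nm)
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] - lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(params = params, st = st)
}

# loss + head gradients for one forward pass
head_loss <- function(model, full, batch, cw = NULL) {
  mode <- model$cfg$mode
  loss <- 0
  dh <- list()
  if (mode %in% c("classify", "joint")) {
    ycls <- batch$labels_class + 1L
    loss <- loss + cross_entropy_loss(full$class_probs, ycls, cw)
    dh$dlogits <- cross_entropy_grad(full$class_probs, ycls, cw)
  }
  if (mode %in% c("regress", "joint")) {
    loss <- loss + mse_loss(full$scores, batch$labels_score)
    dh$dscores <- mse_grad(full$scores, batch$labels_score)
  }
  list(loss = loss, dh = dh)
}

eval_loss <- function(model, batch, cw = NULL) {
  full <- mceegnet_forward_full(model, batch, train = FALSE)
  head_loss(model, full, batch, cw)$loss
}

#' Train a multi-cue network with early stopping
#'
#' Splits off a validation fraction (stratified by class for
#' classification), runs at most `cfg$epochs` epochs of Adam on shuffled
#' minibatches, and returns the weights of the epoch with the lowest
#' validation loss. Classification uses mean cross-entropy on the 0/1 group
#' labels; regression uses mean squared error on `labels_score` (pass
#' normalised scores for severity training). Fully reproducible under
#' `cfg$seed` on a fixed device.
#'
#' @param model An `mceegnet_model` from [build_model()].
#' @param train A [cue_triplet_batch()] with the labels the mode requires.
#' @param cfg A [train_config()].
#' @return A list with `model` (best-epoch weights), `history` (data frame
#'   of per-epoch train/val losses) and `best_epoch`.
#' @export
train_model <- function(model, train, cfg = train_config()) {
  stopifnot(inherits(model, "mceegnet_model"), inherits(train, "cue_triplet_batch"),
            inherits(cfg, "train_config"))
  n <- n_triplets(train)
  if (n < 2L) stop_contract("need at least 2 training triplets")
  mode <- model$cfg$mode
  if (mode %in% c("classify", "joint") && is.null(train$labels_class)) {
    stop_contract("labels_class required for classification training")
  }
  if (mode %in% c("regress", "joint") && is.null(train$labels_score)) {
    stop_contract("labels_score required for regression training")
  }
  n_val <- floor(cfg$val_fraction * n)
  if (n_val < 1L) {
    stop_contract("validation split would be empty (n = %d, val_fraction = %g)",
                  n, cfg$val_fraction)
  }
  with_seed(cfg$seed, {
    if (mode %in% c("classify", "joint")) {
      # stratified: sample validation trials within each class
      val_idx <- unlist(lapply(split(seq_len(n), train$labels_class), function(ix) {
        k <- max(1L, round(cfg$val_fraction * length(ix)))
        sample(ix, min(k, length(ix) - 1L))
      }), use.names = FALSE)
    } else {
      val_idx <- sample(n, n_val)
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    tr <- triplet_subset(train, tr_idx)
    va <- triplet_subset(train, val_idx)
    ntr <- length(tr_idx)

    cw <- NULL
    if (mode %in% c("classify", "joint") && cfg$class_weights == "balanced") {
      # inverse-frequency weights from the training split (classes 0, 1)
      freq <- tabulate(tr$labels_class + 1L, nbins = model$cfg$n_classes)
      cw <- ifelse(freq > 0, ntr / (model$cfg$n_classes * freq), 0)
    }

    opt <- adam_init(model$params)
    best <- list(loss = Inf, params = model$params, bn = model$bn, epoch = 0L)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric())
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(ntr)
      ep_loss <- 0
      nb <- 0L
      for (b0 in seq(1L, ntr, by = cfg$batch_size)) {
        bi <- ord[b0:min(b0 + cfg$batch_size - 1L, ntr)]
        bt <- triplet_subset(tr, bi)
        full <- mceegnet_forward_full(model, bt, train = TRUE)
        model$bn <- full$states
        hl <- head_loss(model, full, bt, cw)
        grads <- mceegnet_backward(model, full, hl$dh, train = TRUE)
        upd <- adam_step(model$params, grads, opt, cfg$learning_rate)
        model$params <- upd$params
        opt <- upd$st
        ep_loss <- ep_loss + hl$loss
        nb <- nb + 1L
      }
      vl <- eval_loss(model, va, cw)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                     val_loss = vl))
      if (vl < best$loss) {
        best <- list(loss = vl, params = model$params, bn = model$bn, epoch = ep)
      }
    }
    model$params <- best$params
    model$bn <- best$bn
  })
  list(model = model, history = hist, best_epoch = best$epoch)
}

# ---- leave-one-subject-out cross-validation -------------------------------

# global trial identifiers (subject:index) used for leakage accounting
trial_ids <- function(subject_id, n) paste(subject_id, seq_len(n), sep = ":")

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: all trials of that subject are held out; the model
#' is trained on the remaining subjects (with the validation split for
#' early stopping drawn from training subjects' trials only) and evaluated
#' on the held-out subject's trials. For regression, the label normaliser
#' is fitted on each fold's training subjects only and predictions are
#' mapped back to the PHQ-9 scale before any metric is computed. Pooled
#' trial-level metrics are primary; a per-subject table and (for
#' classification) majority-vote subject-level accuracy are also returned.
#'
#' @param cohort A `cue_cohort` (see [simulate_cohort()]) or a list of
#'   subjects, each a list with `record` (one-row subject data frame) and
#'   `triplets` (a [cue_triplet_batch()]).
#' @param train_cfg A [train_config()]; its seed drives every fold.
#' @param task `"classify"` or `"regress"`.
#' @param model_cfg Optional [mceegnet_config()]; derived from the data
#'   dimensions when `NULL`.
#' @param normalizer Normalisation strategy for regression labels
#'   (see [fit_label_normalizer()]).
#' @param positive_label Positive class for pooled classification metrics.
#' @return An object of class `losocv_result`: `folds` (per-fold
#'   predictions, truths, ids and training history), `pooled` (a
#'   [metric_report()]), `per_subject` (data frame), and for classification
#'   `subject_votes` with majority-vote accuracy.
#' @export
run_losocv <- function(cohort, train_cfg = train_config(),
                       task = c("classify", "regress"), model_cfg = NULL,
                       normalizer = c("train_minmax", "scale_bounds"),
                       positive_label = 0L) {
  task <- match.arg(task)
  normalizer <- match.arg(normalizer)
  subjects <- if (inherits(cohort, "cue_cohort")) cohort$subjects else cohort
  ns <- length(subjects)
  if (ns < 3L) stop_contract("leave-one-subject-out needs at least 3 subjects")
  recs <- do.call(rbind, lapply(subjects, function(s) as.data.frame(s$record)))
  if (task == "classify" && length(unique(recs$label)) < 2L) {
    stop_contract("both classes must be present for classification")
  }
  dims <- dim(subjects[[1L]]$triplets$x_happy)
  if (is.null(model_cfg)) {
    model_cfg <- mceegnet_config(branch_config(dims[2L], dims[3L]),
                                 mode = task)
  }

  folds <- vector("list", ns)
  for (k in seq_len(ns)) {
    held <- subjects[[k]]
    train_subj <- subjects[-k]
    train_recs <- recs[-k, , drop = FALSE]
    if (task == "classify" && length(unique(train_recs$label)) < 2L) {
      stop_contract("degenerate fold: training set for held-out subject %s lacks a class",
                    held$record$subject_id)
    }
    train_batch <- triplet_rbind(lapply(train_subj, `[[`, "triplets"))
    norm <- NULL
    if (task == "regress") {
      norm <- fit_label_normalizer(train_recs, normalizer)
      train_batch$labels_score <- normalize_labels(train_batch$labels_score, norm)
    }
    fold_train_cfg <- train_cfg
    fold_train_cfg$seed <- as.integer(child_seed(train_cfg$seed, 2L * k))
    model <- build_model(model_cfg, seed = child_seed(train_cfg$seed, 2L * k + 1L))
    fit <- train_model(model, train_batch, fold_train_cfg)

    pred <- forward(fit$model, held$triplets, train_mode = FALSE)
    n_held <- n_triplets(held$triplets)
    if (task == "classify") {
      p <- pred$class_probs
      yhat <- max.col(p, ties.method = "first") - 1L
      truth <- rep(as.integer(held$record$label), n_held)
    } else {
      yhat <- denormalize_predictions(pred$scores, norm)
      truth <- rep(as.numeric(held$record$phq9), n_held)
    }
    folds[[k]] <- list(
      held_out_subject = as.integer(held$record$subject_id),
      trial_predictions = yhat,
      trial_truth = truth,
      history = fit$history,
      best_epoch = fit$best_epoch,
      normalizer = norm,
      train_subjects = as.integer(train_recs$subject_id),
      heldout_trial_ids = trial_ids(held$record$subject_id, n_held),
      train_trial_ids = unlist(lapply(train_subj, function(s) {
        trial_ids(s$record$subject_id, n_triplets(s$triplets))
      }), use.names = FALSE)
    )
  }

  all_pred <- unlist(lapply(folds, `[[`, "trial_predictions"))
  all_truth <- unlist(lapply(folds, `[[`, "trial_truth"))
  if (task == "classify") {
    pooled <- metric_report(all_truth, all_pred, "classify", positive_label)
    votes <- data.frame(
      subject_id = vapply(folds, `[[`, 0L, "held_out_subject"),
      truth = vapply(folds, function(f) f$trial_truth[1L], 0),
      vote = vapply(folds, function(f) {
        as.integer(mean(f$trial_predictions) >= 0.5)
      }, 0L)
    )
    votes$correct <- votes$vote == votes$truth
    per_subject <- data.frame(
      subject_id = votes$subject_id,
      accuracy = vapply(folds, function(f) {
        mean(f$trial_predictions == f$trial_truth)
      }, 0)
    )
    res <- list(folds = folds, pooled = pooled, per_subject = per_subject,
                subject_votes = votes,
                subject_accuracy = mean(votes$correct), task = task)
  } else {
    pooled <- metric_report(all_truth, all_pred, "regress")
    per_subject <- subject_level_report(folds, recs)
    res <- list(folds = folds, pooled = pooled, per_subject = per_subject,
                task = task)
  }
  structure(res, class = "losocv_result")
}

#' @export
print.losocv_result <- function(x, ...) {
  cat(sprintf("LOSOCV (%s), %d folds, %d pooled trials\n", x$task,
              length(x$folds), length(unlist(lapply(x$folds, `[[`, "trial_truth")))))
  print(x$pooled)
  if (!is.null(x$subject_accuracy)) {
    cat(sprintf("subject-level majority-vote accuracy: %.4f\n", x$subject_accuracy))
  }
  invisible(x)
}
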