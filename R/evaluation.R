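# Classification and regression metrics.
#
# The classification scores follow the study convention that the positive
# class is the *normal* (healthy control, label 0) group: a control
# classified as control is a true positive. This is the opposite of the
# usual clinical convention; `positive_label` can be set to 1 to obtain
# the depressed-positive variant. Accuracy and Cohen's kappa are invariant
# to that choice.

#' Confusion counts for binary labels
#'
#' @param y_true,y_pred Equal-length binary label vectors (values 0/1).
#' @param positive_label Which label counts as positive; defaults to 0
#'   ("normal"), the convention used throughout this package's reports.
#' @return An object of class `confusion_counts` with fields `tp`, `fn`,
#'   `tn`, `fp`.
#' @export
confusion_counts <- function(y_true, y_pred, positive_label = 0L) {
  if (length(y_true) != length(y_pred)) {
    stop_contract("y_true and y_pred have different lengths (%d vs %d)",
                  length(y_true), length(y_pred))
  }
  if (length(y_true) < 1L) stop_contract("need at least one label pair")
  labs <- unique(c(y_true, y_pred))
  if (!all(labs %in% c(0, 1))) {
    stop_contract("labels must be binary 0/1; found: %s",
                  paste(sort(labs), collapse = ", "))
  }
  if (!positive_label %in% c(0, 1)) stop_contract("positive_label must be 0 or 1")
  pos <- y_true == positive_label
  hit <- y_true == y_pred
  structure(list(
    tp = sum(pos & hit), fn = sum(pos & !hit),
    tn = sum(!pos & hit), fp = sum(!pos & !hit),
    positive_label = positive_label
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts (positive = label %d): TP=%d FN=%d TN=%d FP=%d\n",
              x$positive_label, x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

# 0 with a warning when a ratio denominator is empty, so pooled
# cross-validation reports never abort on a degenerate fold.
safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (empty denominator); reporting 0", what),
            call. = FALSE)
    return(0)
  }
  num / den
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Accuracy is the fraction of correctly classified samples; precision and
#' recall are taken with respect to the positive class of `c`; F1 is their
#' harmonic mean. Undefined ratios (empty denominators) are reported as 0
#' with a warning rather than an error.
#'
#' @param c A [confusion_counts()] object.
#' @return A list with `accuracy`, `precision`, `recall`, `f1`, all in
#'   `[0, 1]`.
#' @export
classification_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  n <- c$tp + c$tn + c$fp + c$fn
  if (n == 0) stop_contract("all confusion counts are zero")
  precision <- safe_ratio(c$tp, c$tp + c$fp, "precision")
  recall <- safe_ratio(c$tp, c$tp + c$fn, "recall")
  f1 <- if (precision + recall == 0) {
    warning("F1 undefined (precision + recall = 0); reporting 0", call. = FALSE)
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(accuracy = (c$tp + c$tn) / n, precision = precision,
       recall = recall, f1 = f1)
}

#' Cohen's kappa from confusion counts
#'
#' `kappa = (Pa - Pe) / (1 - Pe)` with observed agreement `Pa` equal to
#' accuracy and chance agreement `Pe` computed from the marginal label
#' frequencies of truth and prediction.
#'
#' @param c A [confusion_counts()] object.
#' @return Kappa in `[-1, 1]`; 1 only for perfect agreement with both
#'   classes present.
#' @export
kappa <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  n <- c$tp + c$tn + c$fp + c$fn
  if (n == 0) stop_contract("all confusion counts are zero")
  pa <- (c$tp + c$tn) / n
  pe <- ((c$tp + c$fp) * (c$tp + c$fn) + (c$fn + c$tn) * (c$fp + c$tn)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    stop_contract("kappa undefined: chance agreement Pe = 1 (constant labels)")
  }
  (pa - pe) / (1 - pe)
}

#' Regression error metrics on the PHQ-9 scale
#'
#' Mean squared error, its square root, mean absolute error and median
#' absolute error between true and predicted severity scores. All four are
#' reported on the original (denormalised) PHQ-9 scale.
#'
#' @param y_true,y_pred Equal-length numeric vectors of scores.
#' @return A list with `mse`, `rmse`, `mae`, `medae`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop_contract("y_true and y_pred have different lengths (%d vs %d)",
                  length(y_true), length(y_pred))
  }
  if (length(y_true) < 1L) stop_contract("need at least one pair")
  err <- y_true - y_pred
  mse <- mean(err^2)
  list(mse = mse, rmse = sqrt(mse), mae = mean(abs(err)),
       medae = stats::median(abs(err)))
}

#' Full metric report for one set of predictions
#'
#' Convenience wrapper combining [confusion_counts()],
#' [classification_metrics()] and [kappa()] (classification) or
#' [regression_metrics()] (regression).
#'
#' @param y_true True labels (0/1) or PHQ-9 scores.
#' @param y_pred Predicted labels or scores.
#' @param task `"classify"` or `"regress"`.
#' @param positive_label Positive class for classification metrics.
#' @return A list of class `metric_report`.
#' @export
metric_report <- function(y_true, y_pred, task = c("classify", "regress"),
                          positive_label = 0L) {
  task <- match.arg(task)
  if (task == "classify") {
    cc <- confusion_counts(y_true, y_pred, positive_label)
    rep <- c(list(counts = cc), classification_metrics(cc),
             list(kappa = kappa(cc)))
  } else {
    rep <- regression_metrics(y_true, y_pred)
    rep$pearson_r <- if (stats::sd(y_true) > 0 && stats::sd(y_pred) > 0) {
      stats::cor(y_true, y_pred)
    } else {
      NA_real_
    }
  }
  structure(rep, class = "metric_report", task = task)
}

#' @export
print.metric_report <- function(x, ...) {
  if (attr(x, "task") == "classify") {
    cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f  kappa %.4f\n",
                x$accuracy, x$precision, x$recall, x$f1, x$kappa))
  } else {
    cat(sprintf("MSE %.4f  RMSE %.4f  MAE %.4f  MEDAE %.4f  r %.4f\n",
                x$mse, x$rmse, x$mae, x$medae, x$pearson_r))
  }
  invisible(x)
}

#' Per-subject regression report over cross-validation folds
#'
#' For each held-out subject, compares that subject's trial-level predicted
#' scores with the subject's single true PHQ-9 score and reports RMSE, MAE
#' and MEDAE (plus MSE) per subject.
#'
#' @param folds A list of fold results from [run_losocv()].
#' @param records A subject table as returned by [load_subject_table()].
#' @return A data frame with one row per subject.
#' @export
subject_level_report <- function(folds, records) {
  rows <- lapply(folds, function(f) {
    rec <- records[records$subject_id == f$held_out_subject, , drop = FALSE]
    if (nrow(rec) != 1L) {
      stop_contract("subject %s missing from the subject table", f$held_out_subject)
    }
    m <- regression_metrics(f$trial_truth, f$trial_predictions)
    data.frame(subject_id = rec$subject_id, group = as.character(rec$group),
               phq9 = rec$phq9, n_trials = length(f$trial_predictions),
               mse = m$mse, rmse = m$rmse, mae = m$mae, medae = m$medae)
  })
  do.call(rbind, rows)
}
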