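# Typed containers for subject metadata and epoched EEG, and the reader for
# the packaged cohort table (53 subjects: 24 MDD, 29 HC, with PHQ-9 scores).

#' Load a subject metadata table
#'
#' Reads a CSV/TSV table with columns `id`, `type`, `gender`, `PHQ-9`
#' (case-insensitive, `-`/`_`/`.` interchangeable) describing one subject
#' per row: identifier, diagnostic group (`MDD` or `HC`), sex (`F`/`M`) and
#' PHQ-9 depression severity score. Rows are validated: scores must lie in
#' the PHQ-9 range 0-27.
#'
#' The binary class label used by the classifier follows the group: `HC`
#' maps to label 0 ("normal"), `MDD` to label 1.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"tsv"`.
#' @return A data frame of class `subject_table` with columns
#'   `subject_id` (integer), `group` (factor MDD/HC), `sex` (factor F/M),
#'   `phq9` (integer) and `label` (0/1 integer).
#' @export
load_subject_table <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_contract("subject table not found: %s", path)
  sep <- if (format == "csv") "," else "\t"
  # read everything as character: a sex column of all "F" would otherwise
  # be parsed as logical FALSE
  raw <- utils::read.csv(path, sep = sep, check.names = FALSE,
                         colClasses = "character")
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  cols <- norm(names(raw))
  want <- c(id = "id", type = "type", gender = "gender", phq9 = "phq9")
  idx <- stats::setNames(match(want, cols), names(want))
  if (anyNA(idx)) {
    stop_contract("missing column(s) in subject table: %s",
                  paste(names(want)[is.na(idx)], collapse = ", "))
  }
  id <- as.integer(raw[[idx[["id"]]]])
  group <- toupper(trimws(raw[[idx[["type"]]]]))
  sex <- toupper(trimws(raw[[idx[["gender"]]]]))
  phq9 <- suppressWarnings(as.integer(raw[[idx[["phq9"]]]]))
  for (i in seq_along(id)) {
    if (is.na(id[i]) || id[i] < 1L) {
      stop_contract("row %d: subject id must be a positive integer", i)
    }
    if (!group[i] %in% c("MDD", "HC")) {
      stop_contract("row %d (id %s): group must be MDD or HC, got '%s'",
                    i, id[i], group[i])
    }
    if (!sex[i] %in% c("F", "M")) {
      stop_contract("row %d (id %s): sex must be F or M, got '%s'", i, id[i], sex[i])
    }
    if (is.na(phq9[i]) || phq9[i] < 0L || phq9[i] > 27L) {
      stop_contract("row %d (id %s): PHQ-9 score %s outside the scale range [0, 27]",
                    i, id[i], raw[[idx[["phq9"]]]][i])
    }
  }
  if (anyDuplicated(id)) stop_contract("duplicate subject ids in table")
  out <- data.frame(
    subject_id = id,
    group = factor(group, levels = c("HC", "MDD")),
    sex = factor(sex, levels = c("F", "M")),
    phq9 = phq9,
    label = ifelse(group == "MDD", 1L, 0L)
  )
  class(out) <- c("subject_table", "data.frame")
  out
}

#' Path of the packaged cohort subject table
#'
#' The package ships the 53-subject cohort table (24 depressed patients,
#' 29 healthy controls, with sex and PHQ-9 score) as a CSV fixture; this
#' returns its installed path.
#'
#' @return File path of the CSV.
#' @export
cohort_table_path <- function() {
  system.file("extdata", "modma_subjects.csv", package = "mceegnet",
              mustWork = TRUE)
}

#' Construct an epoch set
#'
#' An `epoch_set` holds cue-locked epochs for one subject and one cue
#' condition: a `[trials x channels x samples]` array in microvolts plus
#' sampling metadata.
#'
#' @param data Numeric array `[n_trials x n_channels x n_samples]`.
#' @param fs Sampling rate in Hz.
#' @param cue One of `"hcue"`, `"fcue"`, `"scue"` (happy / fear / sad).
#' @param subject_id Positive integer subject identifier.
#' @param t0 Epoch start time in seconds relative to the stimulus event
#'   (negative = pre-stimulus).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, cue = c("hcue", "fcue", "scue"),
                      subject_id = 1L, t0 = -0.1) {
  cue <- match.arg(cue)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_contract("data must be a 3-d [trials x channels x samples] array")
  }
  if (!all(is.finite(data))) stop_contract("epoch data contains non-finite values")
  assert_scalar_number(fs, "fs")
  if (fs <= 0) stop_contract("fs must be positive")
  assert_scalar_number(t0, "t0")
  subject_id <- as.integer(subject_id)
  if (is.na(subject_id) || subject_id < 1L) {
    stop_contract("subject_id must be a positive integer")
  }
  structure(list(data = data, fs = fs, cue = cue, subject_id = subject_id,
                 t0 = t0), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoch_set: subject %d, cue %s, %d trials x %d channels x %d samples @ %g Hz, t0 = %g s\n",
              x$subject_id, x$cue, d[1L], d[2L], d[3L], x$fs, x$t0))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Aligned happy/fear/sad trial triplets for the model
#'
#' One model input sample is a triplet of single trials, one per cue
#' condition, all from the same subject. `labels_class` carries the 0/1
#' group label and `labels_score` the (possibly normalised) PHQ-9 score per
#' triplet.
#'
#' @param x_happy,x_fear,x_sad `[n x channels x samples]` arrays with
#'   identical dimensions.
#' @param labels_class Integer 0/1 vector of length `n` (optional).
#' @param labels_score Numeric vector of length `n` (optional).
#' @param subject_id Integer vector (length 1 or `n`) of source subjects.
#' @return An object of class `cue_triplet_batch`.
#' @export
cue_triplet_batch <- function(x_happy, x_fear, x_sad, labels_class = NULL,
                              labels_score = NULL, subject_id = NULL) {
  dims <- list(dim(x_happy), dim(x_fear), dim(x_sad))
  if (any(vapply(dims, length, 0L) != 3L)) {
    stop_contract("cue arrays must be 3-d [trials x channels x samples]")
  }
  if (!all(vapply(dims, identical, TRUE, dims[[1L]]))) {
    stop_contract("the three cue arrays must have identical dimensions")
  }
  n <- dims[[1L]][1L]
  if (!is.null(labels_class)) {
    if (length(labels_class) != n) stop_contract("labels_class must have length n")
    if (!all(labels_class %in% c(0L, 1L))) stop_contract("labels_class must be 0/1")
  }
  if (!is.null(labels_score) && length(labels_score) != n) {
    stop_contract("labels_score must have length n")
  }
  if (!is.null(subject_id)) {
    if (!length(subject_id) %in% c(1L, n)) {
      stop_contract("subject_id must have length 1 or n")
    }
    subject_id <- as.integer(rep_len(subject_id, n))
  }
  structure(list(x_happy = x_happy, x_fear = x_fear, x_sad = x_sad,
                 labels_class = labels_class, labels_score = labels_score,
                 subject_id = subject_id),
            class = "cue_triplet_batch")
}

n_triplets <- function(batch) dim(batch$x_happy)[1L]

# subset a batch by trial indices
triplet_subset <- function(batch, idx) {
  cue_triplet_batch(
    batch$x_happy[idx, , , drop = FALSE],
    batch$x_fear[idx, , , drop = FALSE],
    batch$x_sad[idx, , , drop = FALSE],
    labels_class = batch$labels_class[idx],
    labels_score = batch$labels_score[idx],
    subject_id = if (is.null(batch$subject_id)) NULL else batch$subject_id[idx]
  )
}

# concatenate batches along the trial axis
triplet_rbind <- function(batches) {
  bind3 <- function(field) {
    arrs <- lapply(batches, `[[`, field)
    d <- dim(arrs[[1L]])
    ns <- vapply(arrs, function(a) dim(a)[1L], 0L)
    out <- array(0, c(sum(ns), d[2L], d[3L]))
    at <- 0L
    for (a in arrs) {
      out[at + seq_len(dim(a)[1L]), , ] <- a
      at <- at + dim(a)[1L]
    }
    out
  }
  cat_or_null <- function(field) {
    vals <- lapply(batches, `[[`, field)
    if (any(vapply(vals, is.null, TRUE))) NULL else do.call(c, vals)
  }
  cue_triplet_batch(bind3("x_happy"), bind3("x_fear"), bind3("x_sad"),
                    labels_class = cat_or_null("labels_class"),
                    labels_score = cat_or_null("labels_score"),
                    subject_id = cat_or_null("subject_id"))
}
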