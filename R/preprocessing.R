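# The ERP preprocessing pipeline: average reference, zero-phase band-pass
# filtering, cue-locked epoch extraction, baseline correction and pluggable
# artifact rejection. ICA-based component subtraction is deliberately out of
# scope; the rejection step exposes a strategy interface with a per-trial
# peak-to-peak amplitude threshold as the built-in default.

#' Construct a continuous EEG recording
#'
#' @param data Numeric matrix `[n_channels x n_samples]`, microvolts.
#' @param fs Sampling rate in Hz.
#' @param events Data frame with columns `sample` (1-based sample index of
#'   the stimulus event) and `cue` (`"hcue"`, `"fcue"`, `"scue"`).
#' @return An object of class `continuous_eeg`.
#' @export
continuous_eeg <- function(data, fs, events = NULL) {
  if (!is.matrix(data)) stop_contract("data must be a [channels x samples] matrix")
  assert_scalar_number(fs, "fs")
  if (is.null(events)) {
    events <- data.frame(sample = integer(), cue = character())
  }
  stopifnot(all(c("sample", "cue") %in% names(events)))
  if (nrow(events)) {
    if (is.unsorted(events$sample, strictly = TRUE)) {
      stop_contract("event samples must be strictly increasing")
    }
    if (any(events$sample < 1L) || any(events$sample > ncol(data))) {
      stop_contract("event sample indices must lie within the recording")
    }
    if (!all(events$cue %in% c("hcue", "fcue", "scue"))) {
      stop_contract("event cues must be hcue/fcue/scue")
    }
  }
  structure(list(data = data, fs = fs, events = events), class = "continuous_eeg")
}

#' Re-reference to the channel average
#'
#' Subtracts, at every time sample, the mean across channels, so the
#' channel mean is zero everywhere afterwards. Idempotent and linear.
#'
#' @param x A [continuous_eeg()] or [epoch_set()].
#' @return The same type, re-referenced.
#' @export
average_reference <- function(x) UseMethod("average_reference")

#' @export
average_reference.continuous_eeg <- function(x) {
  if (nrow(x$data) < 2L) {
    stop_contract("average reference needs at least 2 channels")
  }
  x$data <- sweep(x$data, 2L, colMeans(x$data))
  x
}

#' @export
average_reference.epoch_set <- function(x) {
  d <- dim(x$data)
  if (d[2L] < 2L) stop_contract("average reference needs at least 2 channels")
  m <- colSums(aperm(x$data, c(2L, 1L, 3L))) / d[2L]   # [trials x samples]
  x$data <- sweep(x$data, c(1L, 3L), m)
  x
}

#' Band-pass filter specification
#'
#' @param low_hz,high_hz Pass-band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @param order Butterworth order of each (high-pass and low-pass) section.
#' @param zero_phase Apply forward-backward for zero phase distortion.
#' @param notch_hz Optional mains notch frequency (e.g. 50); `NULL` disables.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.3, high_hz = 100, order = 4L,
                        zero_phase = TRUE, notch_hz = NULL) {
  if (low_hz <= 0 || high_hz <= low_hz) {
    stop_contract("need 0 < low_hz < high_hz")
  }
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 zero_phase = zero_phase, notch_hz = notch_hz),
            class = "filter_spec")
}

# Forward(-backward) IIR filtering with odd (reflect-and-negate) edge
# extension, applied row-wise. The extension length covers ~3 periods of
# the slowest dynamics (`settle_hz`), so start-up transients of the
# zero-initial-state filter decay inside the discarded padding.
apply_iir <- function(mat, flt, zero_phase, fs, settle_hz) {
  b <- flt$b
  a <- flt$a
  n <- ncol(mat)
  if (n < 4L) stop_contract("signal too short to filter")
  npad <- max(3L * max(length(a), length(b)),
              as.integer(ceiling(3 * fs / settle_hz)))
  npad <- min(npad, n - 1L)
  run <- function(x) {
    pre <- 2 * x[1L] - x[(npad + 1L):2L]
    post <- 2 * x[n] - x[(n - 1L):(n - npad)]
    ext <- c(pre, x, post)
    y <- if (zero_phase) {
      rev(signal::filter(b, a, rev(signal::filter(b, a, ext))))
    } else {
      signal::filter(b, a, ext)
    }
    as.numeric(y[(npad + 1L):(npad + n)])
  }
  t(apply(mat, 1L, run))
}

#' Band-pass filter a continuous recording
#'
#' Butterworth filtering realised as a high-pass section at `low_hz`
#' cascaded with a low-pass section at `high_hz` (each of the given order),
#' applied forward-backward for zero phase when `zero_phase` is set, with
#' odd edge extension. An optional narrow band-stop notch can be enabled
#' via `notch_hz`.
#'
#' @param x A [continuous_eeg()].
#' @param spec A [filter_spec()].
#' @return The filtered recording, same length as the input.
#' @export
bandpass_filter <- function(x, spec = filter_spec()) {
  stopifnot(inherits(x, "continuous_eeg"), inherits(spec, "filter_spec"))
  nyq <- x$fs / 2
  if (spec$high_hz >= nyq) {
    stop_contract("high_hz = %g must be below the Nyquist frequency %g", spec$high_hz, nyq)
  }
  hp <- signal::butter(spec$order, spec$low_hz / nyq, type = "high")
  lp <- signal::butter(spec$order, spec$high_hz / nyq, type = "low")
  x$data <- apply_iir(x$data, hp, spec$zero_phase, x$fs, spec$low_hz)
  x$data <- apply_iir(x$data, lp, spec$zero_phase, x$fs, spec$high_hz)
  if (!is.null(spec$notch_hz)) {
    if (spec$notch_hz >= nyq) stop_contract("notch_hz must be below Nyquist")
    bs <- signal::butter(2L, c(spec$notch_hz - 2, spec$notch_hz + 2) / nyq,
                         type = "stop")
    x$data <- apply_iir(x$data, bs, spec$zero_phase, x$fs, 2)
  }
  x
}

#' Cut cue-locked epochs out of a continuous recording
#'
#' Epoch windows are half-open `[t_start, t_end)` in seconds relative to
#' each event; each epoch has `round((t_end - t_start) * fs)` samples.
#' Events whose window would fall outside the recording are dropped with a
#' warning. Epochs are grouped into one [epoch_set()] per cue condition, in
#' event order; no filtering happens here, so the samples equal the
#' corresponding continuous segment exactly.
#'
#' @param x A [continuous_eeg()] with events.
#' @param window Numeric length-2 vector `(t_start, t_end)` in seconds,
#'   default `c(-0.1, 0.4)`.
#' @param subject_id Subject id to record on the resulting epoch sets.
#' @return Named list of [epoch_set()] objects, one per cue present.
#' @export
extract_epochs <- function(x, window = c(-0.1, 0.4), subject_id = 1L) {
  stopifnot(inherits(x, "continuous_eeg"))
  if (nrow(x$events) == 0L) stop_contract("recording has no events")
  n_samp <- round((window[2L] - window[1L]) * x$fs)
  if (n_samp < 1L) stop_contract("window is empty at fs = %g", x$fs)
  off0 <- round(window[1L] * x$fs)
  starts <- x$events$sample + off0
  ends <- starts + n_samp - 1L
  ok <- starts >= 1L & ends <= ncol(x$data)
  if (!all(ok)) {
    warning(sprintf("dropped %d event(s) too close to the recording edge (indices: %s)",
                    sum(!ok), paste(which(!ok), collapse = ", ")), call. = FALSE)
  }
  ev <- x$events[ok, , drop = FALSE]
  if (nrow(ev) == 0L) stop_contract("no events with a complete epoch window")
  out <- list()
  for (cue in intersect(c("hcue", "fcue", "scue"), unique(ev$cue))) {
    sel <- which(ev$cue == cue)
    arr <- array(0, c(length(sel), nrow(x$data), n_samp))
    for (i in seq_along(sel)) {
      s0 <- ev$sample[sel[i]] + off0
      arr[i, , ] <- x$data[, s0:(s0 + n_samp - 1L)]
    }
    out[[cue]] <- epoch_set(arr, fs = x$fs, cue = cue, subject_id = subject_id,
                            t0 = window[1L])
  }
  out
}

#' Remove the mean pre-stimulus baseline from each epoch
#'
#' For every trial and channel, subtracts the mean over the baseline
#' interval (half-open, in seconds relative to the event), so the baseline
#' mean is zero afterwards. Idempotent and linear.
#'
#' @param es An [epoch_set()].
#' @param interval Length-2 vector, default `c(-0.1, 0)` (the 100 ms before
#'   stimulus onset).
#' @return The corrected [epoch_set()].
#' @export
baseline_correct <- function(es, interval = c(-0.1, 0)) {
  stopifnot(inherits(es, "epoch_set"))
  d <- dim(es$data)
  i0 <- round((interval[1L] - es$t0) * es$fs) + 1L
  i1 <- round((interval[2L] - es$t0) * es$fs)
  if (i0 < 1L || i1 > d[3L] || i1 < i0) {
    stop_contract("baseline interval [%g, %g) lies outside the epoch window",
                  interval[1L], interval[2L])
  }
  k <- i1 - i0 + 1L
  m <- rowMeans(matrix(es$data[, , i0:i1], d[1L] * d[2L], k))
  es$data <- es$data - c(m)   # recycles over the time axis
  es
}

# ---- artifact rejection ---------------------------------------------------

.rejection_strategies <- new.env(parent = emptyenv())

#' Register an artifact-rejection strategy
#'
#' A strategy is a function `function(es, ...)` returning an integer vector
#' of trial indices to reject (possibly with a `reason` character attribute
#' or vector of the same length).
#'
#' @param name Strategy name.
#' @param fun The strategy function.
#' @return Invisibly, `name`.
#' @export
register_rejection_strategy <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .rejection_strategies)
  invisible(name)
}

#' Reject artifact trials from an epoch set
#'
#' Applies a registered rejection strategy (or a strategy function passed
#' directly) and returns the retained trials together with a report of what
#' was rejected and why. The built-in `"ptp"` strategy rejects any trial
#' whose peak-to-peak amplitude on any channel exceeds `threshold`
#' microvolts.
#'
#' @param es An [epoch_set()].
#' @param method Strategy name (default `"ptp"`) or a strategy function.
#' @param ... Passed to the strategy (for `"ptp"`: `threshold`, default 100).
#' @return A list with `epochs` (the retained [epoch_set()]) and `report`
#'   (data frame of rejected trial indices and reasons).
#' @export
reject_artifacts <- function(es, method = "ptp", ...) {
  stopifnot(inherits(es, "epoch_set"))
  fun <- if (is.function(method)) {
    method
  } else {
    if (!exists(method, envir = .rejection_strategies, inherits = FALSE)) {
      stop_contract("unknown rejection strategy '%s'; registered: %s", method,
                    paste(ls(.rejection_strategies), collapse = ", "))
    }
    get(method, envir = .rejection_strategies, inherits = FALSE)
  }
  rejected <- fun(es, ...)
  reasons <- attr(rejected, "reason") %||% rep("rejected", length(rejected))
  rejected <- as.integer(rejected)
  n <- dim(es$data)[1L]
  if (length(rejected) >= n) {
    stop_contract("rejection strategy removed every trial (empty epoch set)")
  }
  keep <- setdiff(seq_len(n), rejected)
  out <- es
  out$data <- es$data[keep, , , drop = FALSE]
  list(epochs = out,
       report = data.frame(trial = rejected,
                           reason = rep_len(reasons, length(rejected))))
}

ptp_strategy <- function(es, threshold = 100) {
  d <- dim(es$data)
  flat <- matrix(aperm(es$data, c(3L, 1L, 2L)), d[3L], d[1L] * d[2L])
  ptp <- matrix(apply(flat, 2L, function(v) max(v) - min(v)), d[1L], d[2L])
  bad <- which(apply(ptp, 1L, max) > threshold)
  attr(bad, "reason") <- sprintf("peak-to-peak > %g uV", threshold)
  bad
}

register_rejection_strategy("ptp", ptp_strategy)
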