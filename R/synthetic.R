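# Synthetic dot-probe ERP cohorts.
#
# Each subject contributes three cue conditions (happy / fear / sad face
# pairs). A cue's noiseless template is a sum of Gaussian-envelope ERP
# components, each with a fixed scalp topography; component amplitude
# varies linearly with the subject's PHQ-9 severity with a cue-specific
# slope, on top of 1/f (pink) plus white background noise. This gives the
# pipeline, model and cross-validation harness a ground-truth cohort with
# a recoverable severity effect.

default_topography <- function(n_channels, j) {
  v <- cos(2 * pi * j * (seq_len(n_channels) - 1) / n_channels + (j - 1) * pi / 4)
  v / sqrt(sum(v^2))
}

default_erp_components <- function() {
  # latencies/widths in seconds, base amplitudes in microvolts: an early
  # visual P1, a face-sensitive N170-like deflection, and a late P3
  list(
    list(latency = 0.10, width = 0.030, amplitude = 4),
    list(latency = 0.17, width = 0.040, amplitude = -5),
    list(latency = 0.30, width = 0.080, amplitude = 6)
  )
}

#' Configuration of the synthetic ERP cohort generator
#'
#' @param n_channels Number of EEG channels (default 16; the full-montage
#'   analogue is 128).
#' @param fs Sampling rate in Hz (default 250).
#' @param n_trials_per_cue Trials per cue condition (default 160, one third
#'   of a 480-trial session).
#' @param window Epoch window in seconds relative to the stimulus,
#'   default `c(-0.1, 0.4)` (125 samples at 250 Hz).
#' @param erp_components List of components, each a list with `latency`
#'   (s), `width` (s), `amplitude` (microvolts) and optionally a unit-norm
#'   `topography` vector of length `n_channels` (a smooth deterministic
#'   topography is generated when absent).
#' @param severity_slope Named numeric vector (`hcue`, `fcue`, `scue`):
#'   microvolts of component amplitude per PHQ-9 point. The default
#'   emulates a blunted response to happy faces and a heightened response
#'   to fearful/sad faces with increasing severity.
#' @param noise Named numeric vector with `pink` and `white` standard
#'   deviations in microvolts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 16L, fs = 250, n_trials_per_cue = 160L,
                       window = c(-0.1, 0.4),
                       erp_components = default_erp_components(),
                       severity_slope = c(hcue = -0.20, fcue = 0.15, scue = 0.15),
                       noise = c(pink = 0.5, white = 0.4)) {
  n_samples <- (window[2L] - window[1L]) * fs
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop_contract("fs * window length must give an integer sample count")
  }
  stopifnot(all(c("hcue", "fcue", "scue") %in% names(severity_slope)),
            all(c("pink", "white") %in% names(noise)))
  for (comp in erp_components) {
    if (!is.null(comp$topography)) {
      if (length(comp$topography) != n_channels) {
        stop_contract("topography length must equal n_channels")
      }
      if (abs(sum(comp$topography^2) - 1) > 1e-8) {
        stop_contract("topographies must be unit-norm")
      }
    }
  }
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 n_trials_per_cue = as.integer(n_trials_per_cue),
                 window = window, n_samples = as.integer(round(n_samples)),
                 erp_components = erp_components,
                 severity_slope = severity_slope, noise = noise),
            class = "sim_config")
}

#' Noiseless ERP template for one cue and severity
#'
#' `template = sum_j topography_j x gaussian(latency_j, width_j) *
#' (amplitude_j + slope[cue] * severity)` - deterministic, no noise.
#'
#' @param cfg A [sim_config()].
#' @param cue `"hcue"`, `"fcue"` or `"scue"`.
#' @param severity PHQ-9 severity in `[0, 27]`.
#' @return A `[channels x samples]` matrix in microvolts.
#' @export
make_erp_template <- function(cfg, cue = c("hcue", "fcue", "scue"), severity) {
  cue <- match.arg(cue)
  stopifnot(inherits(cfg, "sim_config"))
  if (severity < 0 || severity > 27) stop_contract("severity must lie in [0, 27]")
  tgrid <- cfg$window[1L] + (seq_len(cfg$n_samples) - 1L) / cfg$fs
  tpl <- matrix(0, cfg$n_channels, cfg$n_samples)
  slope <- cfg$severity_slope[[cue]]
  for (j in seq_along(cfg$erp_components)) {
    comp <- cfg$erp_components[[j]]
    topo <- comp$topography %||% default_topography(cfg$n_channels, j)
    env <- exp(-0.5 * ((tgrid - comp$latency) / comp$width)^2)
    amp <- comp$amplitude + slope * severity
    tpl <- tpl + amp * outer(topo, env)
  }
  tpl
}

# 1/f-amplitude (pink) noise by spectral shaping of white noise; each
# column is one independent series with expected standard deviation 1.
pink_noise <- function(n_samples, n_series, fs) {
  freqs <- (seq_len(n_samples) - 1L) * fs / n_samples
  # two-sided amplitude response, symmetric so the inverse transform is real
  f_fold <- pmin(freqs, fs - freqs)
  g <- ifelse(f_fold > 0, 1 / sqrt(f_fold), 0)
  g <- g / sqrt(mean(g^2))
  w <- matrix(stats::rnorm(n_samples * n_series), n_samples, n_series)
  Re(stats::mvfft(stats::mvfft(w) * g, inverse = TRUE)) / n_samples
}

#' Simulate all epochs of one subject
#'
#' Every trial is the subject's cue template (from the subject's PHQ-9
#' score) plus independent pink and white noise; reproducible under `seed`.
#'
#' @param cfg A [sim_config()].
#' @param record One-row subject record (needs `subject_id`, `phq9`,
#'   `label`).
#' @param seed Integer seed.
#' @return A list with `record`, `epochs` (named list of three
#'   [epoch_set()]s), `triplets` (a [cue_triplet_batch()], index-paired)
#'   and `ground_truth` (the noiseless templates).
#' @export
simulate_subject <- function(cfg, record, seed = 0L) {
  stopifnot(inherits(cfg, "sim_config"))
  C <- cfg$n_channels
  Tn <- cfg$n_samples
  ntr <- cfg$n_trials_per_cue
  epochs <- list()
  truth <- list()
  with_seed(seed, {
    for (cue in c("hcue", "fcue", "scue")) {
      tpl <- make_erp_template(cfg, cue, record$phq9)
      truth[[cue]] <- tpl
      arr <- array(0, c(ntr, C, Tn))
      if (cfg$noise[["pink"]] > 0) {
        pk <- pink_noise(Tn, ntr * C, cfg$fs) * cfg$noise[["pink"]]
        arr <- arr + aperm(array(pk, c(Tn, ntr, C)), c(2L, 3L, 1L))
      }
      if (cfg$noise[["white"]] > 0) {
        arr <- arr + array(stats::rnorm(ntr * C * Tn, sd = cfg$noise[["white"]]),
                           c(ntr, C, Tn))
      }
      arr <- sweep(arr, c(2L, 3L), tpl, `+`)
      epochs[[cue]] <- epoch_set(arr, fs = cfg$fs, cue = cue,
                                 subject_id = record$subject_id,
                                 t0 = cfg$window[1L])
    }
  })
  triplets <- make_cue_triplets(epochs$hcue, epochs$fcue, epochs$scue,
                                policy = "by_index", record = record)
  list(record = record, epochs = epochs, triplets = triplets,
       ground_truth = truth)
}

#' Simulate a full two-group cohort
#'
#' PHQ-9 scores are drawn uniformly (integers) from each group's range;
#' depressed subjects get ids 1..n_mdd, controls follow. Each subject's
#' data are generated with a seed derived from `seed` and the subject id,
#' so the whole cohort is reproducible.
#'
#' @param cfg A [sim_config()].
#' @param n_mdd,n_hc Group sizes (cohort analogue: 24 and 29).
#' @param score_ranges List with integer ranges for `HC` and `MDD`;
#'   defaults to the observed cohort ranges (controls 0-5, patients 11-24).
#'   Overlapping ranges are allowed but warned about (label noise).
#' @param seed Integer seed.
#' @return An object of class `cue_cohort`: `subjects` (list of
#'   [simulate_subject()] results), `records` (subject data frame) and
#'   `cfg`.
#' @export
simulate_cohort <- function(cfg = sim_config(), n_mdd = 24L, n_hc = 29L,
                            score_ranges = list(HC = c(0L, 5L), MDD = c(11L, 24L)),
                            seed = 0L) {
  if (n_mdd < 1L || n_hc < 1L) stop_contract("need at least one subject per group")
  if (score_ranges$HC[2L] >= score_ranges$MDD[1L]) {
    warning("HC and MDD score ranges overlap: groups are label-noisy by construction",
            call. = FALSE)
  }
  n <- n_mdd + n_hc
  groups <- c(rep("MDD", n_mdd), rep("HC", n_hc))
  scores <- with_seed(seed, {
    vapply(groups, function(g) {
      r <- score_ranges[[g]]
      as.integer(sample(seq(r[1L], r[2L]), 1L))
    }, 0L)
  })
  records <- data.frame(
    subject_id = seq_len(n),
    group = factor(groups, levels = c("HC", "MDD")),
    sex = factor(rep_len(c("F", "M"), n), levels = c("F", "M")),
    phq9 = scores,
    label = ifelse(groups == "MDD", 1L, 0L)
  )
  subjects <- lapply(seq_len(n), function(i) {
    simulate_subject(cfg, records[i, , drop = FALSE],
                     seed = child_seed(seed, 1000L + i))
  })
  structure(list(subjects = subjects, records = records, cfg = cfg),
            class = "cue_cohort")
}

#' @export
print.cue_cohort <- function(x, ...) {
  cat(sprintf("synthetic cue cohort: %d subjects (%d MDD, %d HC), %d ch x %d samples, %d trials/cue\n",
              nrow(x$records), sum(x$records$group == "MDD"),
              sum(x$records$group == "HC"), x$cfg$n_channels,
              x$cfg$n_samples, x$cfg$n_trials_per_cue))
  invisible(x)
}
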