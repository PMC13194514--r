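# Shared fixture builders; everything is generated in code under fixed seeds.

tiny_branch <- function(C = 3L, T = 40L) {
  branch_config(n_channels = C, n_samples = T, f1 = 2L, temporal_kernel = 7L,
                depth_multiplier = 2L, sep_kernel = 5L, pool1 = 2L, pool2 = 4L,
                dropout_p = 0)
}

tiny_batch <- function(n = 5L, C = 3L, T = 40L, seed = 1L) {
  set.seed(seed)
  cue_triplet_batch(
    array(rnorm(n * C * T), c(n, C, T)),
    array(rnorm(n * C * T), c(n, C, T)),
    array(rnorm(n * C * T), c(n, C, T)),
    labels_class = rep_len(c(0L, 1L), n),
    labels_score = runif(n)
  )
}

random_epoch_set <- function(n = 4L, C = 3L, T = 125L, seed = 1L, cue = "hcue",
                             subject_id = 1L, fs = 250, t0 = -0.1) {
  set.seed(seed)
  epoch_set(array(rnorm(n * C * T), c(n, C, T)), fs = fs, cue = cue,
            subject_id = subject_id, t0 = t0)
}

# a quick low-noise cohort for cross-validation plumbing tests
tiny_cohort <- function(n_per_group = 3L, seed = 1L, slope = c(hcue = -0.5,
                                                               fcue = 0.4,
                                                               scue = 0.4)) {
  cfg <- sim_config(n_channels = 4L, n_trials_per_cue = 8L,
                    severity_slope = slope,
                    noise = c(pink = 0.3, white = 0.3))
  simulate_cohort(cfg, n_mdd = n_per_group, n_hc = n_per_group, seed = seed)
}

fast_train_cfg <- function(seed = 0L, epochs = 2L) {
  train_config(epochs = epochs, batch_size = 16L, seed = seed)
}
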