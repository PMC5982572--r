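# Shared fixtures, all generated in code.  Heavier objects are memoized so
# several test files can reuse one simulated experiment.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

# deterministic ERP: zero SDs, zero noise
erp_fixed <- function() {
  erp_model(amplitude_sd = c(0, 0, 0), latency_sd = c(0, 0, 0))
}

table1_values <- function() {
  list(amplitude_mean = c(P1 = -6.29, P2 = 5.62, P3 = 8.72),
       amplitude_sd = c(P1 = 4.03, P2 = 3.26, P3 = 4.17),
       latency_mean = c(P1 = 159.26, P2 = 266.17, P3 = 478.65),
       latency_sd = c(P1 = 45.98, P2 = 63.03, P3 = 76.53))
}

# default-world experiment at the paper noise preset, seed 1
default_recording <- function() {
  memo("rec_default", {
    synthesize_recording(simulate_paradigm(seed = 1),
                         noise = noise_preset("paper"), seed = 1)
  })
}

default_epochs <- function() {
  memo("epochs_default", extract_epochs(default_recording()))
}

# zero-noise zero-SD experiment (every target epoch identical)
noiseless_recording <- function() {
  memo("rec_noiseless", {
    synthesize_recording(simulate_paradigm(seed = 1), erp = erp_fixed(),
                         noise = noise_model(noise_rms = 0), seed = 1)
  })
}

# one raw (not demeaned) target epoch straight from a recording
raw_target_epoch <- function(rec, which_target = 1) {
  fs <- rec$sampling_rate
  onset <- rec$schedule$onset_s[rec$schedule$is_target][which_target]
  i0 <- as.integer(round(onset * fs)) + 1L
  rowMeans(rec$samples[i0:(i0 + as.integer(floor(0.7 * fs)) - 1L), ,
                       drop = FALSE])
}

# an all-target schedule with non-overlapping events, for parameter recovery
spaced_target_schedule <- function(n_events, spacing = 1) {
  sched <- data.frame(onset_s = (seq_len(n_events) - 1) * spacing,
                      image_index = 1L, is_target = TRUE, trial = 1L)
  attr(sched, "soa") <- spacing
  class(sched) <- c("stimulus_schedule", "data.frame")
  sched
}

# single-subject pipeline accuracy at given noise / amplitude scaling
subject_accuracy <- function(seed, noise = noise_preset("paper"),
                             amplitude_scale = 1) {
  cfg <- pipeline_config(seeds = seed, noise = noise,
                         subject_amplitude_sd = 0)
  run_subject(cfg, seed, amplitude_scale = amplitude_scale)$results$accuracy
}

# 2-D Gaussian clusters for classifier tests
gaussian_clusters <- function(n, mu_t, mu_n, sd = 1, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    window_start_s = seq_len(2 * n) * 0.25,
    label = rep(c("target", "nontarget"), each = n),
    x = c(rnorm(n, mu_t[1], sd), rnorm(n, mu_n[1], sd)),
    y = c(rnorm(n, mu_t[2], sd), rnorm(n, mu_n[2], sd)))
  attr(df, "feature_pair") <- c("skewness", "std")
  class(df) <- c("feature_set", "data.frame")
  df
}
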