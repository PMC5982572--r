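# Mean subtraction, band-pass, epoching, averaging, component detection.

test_that("subtract_mean centers any signal", {
  expect_equal(subtract_mean(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(subtract_mean(rep(7.5, 10)), rep(0, 10))
  set.seed(1)
  x <- rnorm(1000, 50, 10)
  expect_lt(abs(mean(subtract_mean(x))), 1e-12 * sqrt(mean(x^2)))
  expect_error(subtract_mean(numeric(0)), "empty")
})

test_that("band-pass gain matches the analog Butterworth oracle", {
  # |H| values frozen from scipy.signal.butter(4, 2*pi*c(1,8), analog=TRUE)
  f <- c(0.5, 1, 2.8284271247461903, 4, 8, 16, 30)
  g_oracle <- c(4.156137949678e-02, 7.071067811865e-01, 1.0,
                9.999777970242e-01, 7.071067811865e-01,
                4.156137949678e-02, 3.071961101820e-03)
  expect_equal(stp300:::butterworth_bp_gain(f, 1, 8, 4), g_oracle,
               tolerance = 1e-9)
})

test_that("band-pass preserves in-band tones and rejects out-of-band energy", {
  fs <- 128
  t <- (0:(20 * fs - 1)) / fs
  mid <- (5 * fs):(15 * fs)   # ignore edges
  in_band <- bandpass(sin(2 * pi * 4 * t), fs, 1, 8)
  expect_equal(max(abs(in_band[mid])), 1, tolerance = 0.05)
  out_band <- bandpass(sin(2 * pi * 30 * t), fs, 1, 8)
  expect_lt(max(abs(out_band[mid])), 0.1)
  dc <- bandpass(rep(3, length(t)), fs, 1, 8)
  expect_lt(abs(mean(dc)), 1e-8)
  # zero phase: a 4 Hz tone keeps its zero crossings
  expect_lt(abs(in_band[5 * fs + 1] - sin(2 * pi * 4 * t[5 * fs + 1])), 0.05)
  expect_error(bandpass(t, fs, 8, 1), "invalid band")
  expect_error(bandpass(t, fs, 1, 70), "invalid band")
})

test_that("epoch extraction yields 72 target epochs of 89 samples", {
  ep <- default_epochs()
  expect_equal(sum(ep$label == "target"), 72)
  expect_equal(ncol(ep$epochs), 89)        # floor(0.7 * 128)
  expect_gt(sum(ep$label == "nontarget"), 72)
})

test_that("target and non-target epochs never share a sample", {
  ep <- default_epochs()
  fs <- ep$sampling_rate
  len <- ncol(ep$epochs)
  idx_of <- function(onset) {
    i0 <- as.integer(round(onset * fs)) + 1L
    i0:(i0 + len - 1L)
  }
  t_idx <- unlist(lapply(ep$onset_s[ep$label == "target"], idx_of))
  n_idx <- unlist(lapply(ep$onset_s[ep$label == "nontarget"], idx_of))
  expect_length(intersect(unique(t_idx), unique(n_idx)), 0)
  # non-target epochs are mutually non-overlapping
  expect_equal(length(n_idx), length(unique(n_idx)))
})

test_that("a target too close to the recording end is dropped with a warning", {
  sched <- spaced_target_schedule(5, spacing = 1)
  attr(sched, "soa") <- 0.3   # recording ends 0.5 s after the last onset
  rec <- synthesize_recording(sched, erp = erp_fixed(),
                              noise = noise_model(noise_rms = 0), seed = 1,
                              padding = 0.2)
  expect_warning(ep <- extract_epochs(rec), "dropped")
  expect_equal(sum(ep$label == "target"), 4)
})

test_that("zero-target recordings put all material in the non-target group", {
  sched <- spaced_target_schedule(10, spacing = 1)
  sched$is_target <- FALSE
  rec <- synthesize_recording(sched, noise = noise_preset("clean"), seed = 1)
  ep <- extract_epochs(rec)
  expect_equal(sum(ep$label == "target"), 0)
  expect_equal(sum(ep$label == "nontarget"),
               floor(nrow(rec$samples) / 89))
})

test_that("ERP averaging is the pointwise mean and shrinks noise as 1/sqrt(n)", {
  # identical epochs: average equals any one of them
  ep <- list(epochs = matrix(rep(sin(1:89 / 7), 5), 5, 89, byrow = TRUE),
             label = rep("target", 5), onset_s = 1:5,
             epoch_duration = 0.7, sampling_rate = 128)
  class(ep) <- "epoch_set"
  av <- average_erp(ep, "target")
  expect_equal(av$samples, sin(1:89 / 7))
  expect_equal(av$n_epochs_averaged, 5)
  expect_error(average_erp(ep, "nontarget"), "no epochs")
  # noise-only epochs: RMS of the average scales as 1/sqrt(n)
  set.seed(42)
  rms_at <- function(n) {
    e <- list(epochs = matrix(rnorm(n * 89), n, 89), label = rep("target", n),
              onset_s = seq_len(n), epoch_duration = 0.7, sampling_rate = 128)
    class(e) <- "epoch_set"
    sqrt(mean(average_erp(e, "target")$samples^2))
  }
  ratio <- mean(replicate(20, rms_at(10))) / mean(replicate(20, rms_at(100)))
  expect_equal(ratio, sqrt(10), tolerance = 0.25)
})

test_that("component detection rejects epochs without the three components", {
  # all-zero epoch: P1 sign constraint fails
  expect_true(detect_components(numeric(89), 128)$rejected)
  # single positive bump at 480 ms: P3 present but P1 constraint fails
  t <- (0:88) / 128
  bump <- 5 * exp(-(t - 0.48)^2 / (2 * 0.04^2))
  pk <- detect_components(bump, 128)
  expect_true(pk$rejected)
  expect_match(pk$reason, "P1")
  # window outside the 89-sample epoch (0..687.5 ms) is an error
  expect_error(
    detect_components(bump, 128, windows = list(P1 = c(100, 210),
                                                P2 = c(200, 330),
                                                P3 = c(400, 700))),
    "outside the epoch")
})

test_that("detection recovers injected peaks within noise and one sample", {
  # resolved, well-separated peaks at low noise: the one-sample latency
  # guarantee needs the peak curvature to dominate the noise
  set.seed(9)
  fs <- 128
  t <- (0:88) / fs
  noise_rms <- 0.05
  for (i in 1:10) {
    a <- c(-runif(1, 4, 8), runif(1, 4, 7), runif(1, 5, 9))
    l <- c(runif(1, 0.12, 0.17), runif(1, 0.24, 0.30), runif(1, 0.43, 0.53))
    x <- a[1] * exp(-(t - l[1])^2 / (2 * 0.02^2)) +
      a[2] * exp(-(t - l[2])^2 / (2 * 0.025^2)) +
      a[3] * exp(-(t - l[3])^2 / (2 * 0.04^2)) +
      rnorm(89, 0, noise_rms)
    pk <- detect_components(x, fs)
    expect_false(pk$rejected)
    expect_true(all(abs(pk$peaks$amplitude - a) < 3 * noise_rms + 0.2))
    expect_true(all(abs(pk$peaks$latency_ms - l * 1000) <= 1000 / fs + 1e-9))
  }
})

test_that("component statistics give mean/SD and mean +/- SD windows", {
  mk <- function(a, l) {
    structure(list(peaks = data.frame(component = c("P1", "P2", "P3"),
                                      amplitude = a, latency_ms = l),
                   rejected = FALSE, reason = NULL,
                   windows = erp_component_windows()),
              class = "component_peaks")
  }
  # two identical peak sets: SD 0, window collapses to a point
  st <- component_stats(list(mk(c(-5, 4, 8), c(150, 260, 470)),
                             mk(c(-5, 4, 8), c(150, 260, 470))))
  expect_equal(st$stats$latency_sd, c(0, 0, 0))
  expect_equal(st$stats$window_low_ms, st$stats$window_high_ms)
  expect_equal(st$n_retained, 2)
  # rejected sets count as discarded; < 2 retained is an error
  rej <- mk(c(-5, 4, 8), c(150, 260, 470)); rej$rejected <- TRUE
  st2 <- component_stats(list(mk(c(-4, 3, 7), c(140, 250, 460)),
                              mk(c(-6, 5, 9), c(160, 270, 480)), rej))
  expect_equal(st2$n_discarded, 1)
  expect_equal(st2$stats$latency_mean, c(150, 260, 470))
  expect_error(component_stats(list(mk(c(-5, 4, 8), c(150, 260, 470)), rej)),
               "at least 2")
})
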