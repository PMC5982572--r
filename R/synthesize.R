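# Synthetic two-channel occipital EEG.  Target flashes evoke three ERP
# components (negative P1, positive P2 and P3) modelled as Gaussian-windowed
# bumps whose peak amplitude and latency are drawn per event from the
# published component statistics; 1/f^alpha colored noise is added to both
# channels independently.

.ERP_COMPONENTS <- c("P1", "P2", "P3")

#' ERP component model
#'
#' Per-component peak statistics for the three occipital ERP components of a
#' target (oddball) flash: a negative deflection around 160 ms (P1) and two
#' positive deflections around 266 ms (P2) and 479 ms (P3, the P300 proper).
#' Defaults are the published component means and standard deviations
#' (amplitudes in microvolts, latencies in ms after flash onset).
#'
#' Each component is synthesized as a Gaussian bump
#' `a * exp(-(t - l)^2 / (2 w^2))`; the width `w` (`width_ms`) is a morphology
#' parameter chosen so the summed waveform's energy falls in the 1-8 Hz ERP
#' band and the components stay resolved within a 700 ms epoch.
#'
#' @param amplitude_mean,amplitude_sd peak amplitude mean/SD per component
#'   (microvolts); P1 mean must be negative, P2/P3 positive.
#' @param latency_mean,latency_sd peak latency mean/SD per component (ms);
#'   means must be ordered P1 < P2 < P3.
#' @param width_ms Gaussian width per component (ms), all > 0.
#' @return An object of class `erp_model`.
#' @export
erp_model <- function(amplitude_mean = c(P1 = -6.29, P2 = 5.62, P3 = 8.72),
                      amplitude_sd = c(P1 = 4.03, P2 = 3.26, P3 = 4.17),
                      latency_mean = c(P1 = 159.26, P2 = 266.17, P3 = 478.65),
                      latency_sd = c(P1 = 45.98, P2 = 63.03, P3 = 76.53),
                      width_ms = c(P1 = 20, P2 = 25, P3 = 40)) {
  for (nm in c("amplitude_mean", "amplitude_sd", "latency_mean",
               "latency_sd", "width_ms")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 3L || !all(is.finite(v))) {
      stopf("'%s' must be a numeric vector of 3 finite values (P1, P2, P3)", nm)
    }
  }
  if (any(amplitude_sd < 0) || any(latency_sd < 0)) {
    stopf("standard deviations must be >= 0")
  }
  if (any(width_ms <= 0)) stopf("'width_ms' must be > 0")
  if (amplitude_mean[[1]] >= 0) stopf("P1 amplitude_mean must be negative")
  if (amplitude_mean[[2]] <= 0 || amplitude_mean[[3]] <= 0) {
    stopf("P2 and P3 amplitude_mean must be positive")
  }
  if (is.unsorted(latency_mean, strictly = TRUE)) {
    stopf("latency means must be strictly increasing P1 < P2 < P3")
  }
  structure(
    list(amplitude_mean = stats::setNames(as.numeric(amplitude_mean), .ERP_COMPONENTS),
         amplitude_sd = stats::setNames(as.numeric(amplitude_sd), .ERP_COMPONENTS),
         latency_mean = stats::setNames(as.numeric(latency_mean), .ERP_COMPONENTS),
         latency_sd = stats::setNames(as.numeric(latency_sd), .ERP_COMPONENTS),
         width_ms = stats::setNames(as.numeric(width_ms), .ERP_COMPONENTS)),
    class = "erp_model")
}

#' Background noise model
#'
#' `1/f^alpha` colored Gaussian noise added independently to each channel,
#' optionally with a 10 Hz idle-rhythm (alpha) sinusoid.  `noise_rms` presets
#' reflect a low-SNR consumer headset: `"clean"` 1, `"paper"` 4, `"hard"`
#' 8 microvolts RMS.
#'
#' @param spectral_exponent slope alpha of the 1/f^alpha power spectrum
#'   (>= 0, default 1).
#' @param noise_rms RMS noise amplitude in microvolts (>= 0, default 4).
#' @param alpha_bump_amplitude amplitude of an optional 10 Hz sinusoidal idle
#'   rhythm (microvolts, default 0).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(spectral_exponent = 1, noise_rms = 4,
                        alpha_bump_amplitude = 0) {
  if (spectral_exponent < 0) stopf("'spectral_exponent' must be >= 0")
  if (noise_rms < 0) stopf("'noise_rms' must be >= 0")
  if (alpha_bump_amplitude < 0) stopf("'alpha_bump_amplitude' must be >= 0")
  structure(list(spectral_exponent = spectral_exponent, noise_rms = noise_rms,
                 alpha_bump_amplitude = alpha_bump_amplitude),
            class = "noise_model")
}

#' Noise presets
#'
#' @param preset one of `"clean"` (1 uV RMS), `"paper"` (4 uV RMS, the
#'   default synthetic world), `"hard"` (8 uV RMS).
#' @return A [noise_model()].
#' @export
noise_preset <- function(preset = c("paper", "clean", "hard")) {
  preset <- match.arg(preset)
  noise_model(noise_rms = c(clean = 1, paper = 4, hard = 8)[[preset]])
}

#' Generate 1/f^alpha colored Gaussian noise
#'
#' White Gaussian noise is shaped in the frequency domain by `f^(-alpha/2)`
#' (DC removed) and rescaled to the requested RMS, so the average periodogram
#' falls off as `1/f^alpha`.
#'
#' @param n number of samples.
#' @param spectral_exponent alpha.
#' @param rms target RMS in microvolts.
#' @param sampling_rate Hz (sets the frequency axis only).
#' @return Numeric vector of length `n`.
#' @export
colored_noise <- function(n, spectral_exponent = 1, rms = 4,
                          sampling_rate = 128) {
  n <- as.integer(n)
  if (n <= 0 || rms == 0) return(numeric(max(n, 0)))
  w <- stats::rnorm(n)
  if (spectral_exponent == 0) {
    x <- w - mean(w)
  } else {
    k <- 0:(n - 1)
    f <- pmin(k, n - k) * sampling_rate / n
    shape <- ifelse(f > 0, f^(-spectral_exponent / 2), 0)
    x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
    x <- x - mean(x)
  }
  x * rms / sqrt(mean(x^2))
}

#' Synthesize a two-channel EEG recording from a stimulus schedule
#'
#' For every target flash, both channels receive the sum of the three ERP
#' component bumps, with peak amplitude and latency drawn independently per
#' event from `Normal(mean, sd^2)` of the [erp_model()].  Non-target flashes
#' receive no component (optionally a scaled mean-parameter template via
#' `nontarget_scale`, as a stress test for the physiological small visual
#' response).  Colored noise of the stated RMS is added to every sample,
#' independently per channel.  The recording starts at t = 0 at the first
#' flash onset and extends `padding` seconds past the end of the last
#' stimulus-onset asynchrony so the final epoch is complete.
#'
#' A drawn latency that would place a component peak outside the
#' `epoch_duration` epoch is redrawn up to `max_latency_redraws` times, then
#' clipped to the epoch bounds with a warning.
#'
#' The per-event draws are attached as attribute `"draws"` (a data frame with
#' `event`, `component`, `amplitude`, `latency_ms`) for parameter-recovery
#' checks.
#'
#' @param schedule a [simulate_paradigm()] schedule (or any data frame with
#'   `onset_s`, `image_index`, `is_target`, `trial`).
#' @param erp an [erp_model()].
#' @param noise a [noise_model()].
#' @param sampling_rate Hz (default 128).
#' @param seed master integer seed; expands into independent substreams for
#'   amplitudes, latencies and per-channel noise.
#' @param epoch_duration epoch length in seconds used for the latency bound
#'   (default 0.7).
#' @param padding seconds of recording appended after the last flash's SOA
#'   (default 1).
#' @param nontarget_scale scale factor for a deterministic mean-parameter
#'   response added at non-target flashes (default 0 = none).
#' @param amplitude_scale global multiplicative factor on all drawn
#'   amplitudes (used for subject-level variability; default 1).
#' @param max_latency_redraws bounded retry count for out-of-epoch latencies.
#' @return An `eeg_recording`: list with `samples` (time x channel matrix,
#'   microvolts), `sampling_rate`, `channel_names`, `schedule`.
#' @export
synthesize_recording <- function(schedule, erp = erp_model(),
                                 noise = noise_model(), sampling_rate = 128,
                                 seed = 1, epoch_duration = 0.7, padding = 1,
                                 nontarget_scale = 0, amplitude_scale = 1,
                                 max_latency_redraws = 10) {
  if (is.null(schedule) || nrow(schedule) == 0L) {
    stopf("'schedule' must contain at least one flash event")
  }
  check_scalar(sampling_rate, "sampling_rate")
  fs <- sampling_rate
  soa <- attr(schedule, "soa") %||%
    (if (nrow(schedule) > 1) min(diff(schedule$onset_s)) else 0.3)
  duration <- max(schedule$onset_s) + soa + padding
  n <- as.integer(ceiling(duration * fs))
  epoch_ms <- epoch_duration * 1000

  targets <- which(schedule$is_target)
  nt <- length(targets)
  base <- numeric(n)
  draws <- NULL

  if (nt > 0) {
    amps <- with_seed(substream(seed, 2L), {
      matrix(stats::rnorm(nt * 3, mean = rep(erp$amplitude_mean, each = nt),
                          sd = rep(erp$amplitude_sd, each = nt)), nt, 3)
    })
    lats <- with_seed(substream(seed, 3L), {
      l <- matrix(stats::rnorm(nt * 3, mean = rep(erp$latency_mean, each = nt),
                               sd = rep(erp$latency_sd, each = nt)), nt, 3)
      bad <- which(l < 0 | l > epoch_ms)
      tries <- 0L
      while (length(bad) > 0 && tries < max_latency_redraws) {
        l[bad] <- stats::rnorm(length(bad),
                               mean = rep(erp$latency_mean, each = nt)[bad],
                               sd = rep(erp$latency_sd, each = nt)[bad])
        bad <- which(l < 0 | l > epoch_ms)
        tries <- tries + 1L
      }
      if (length(bad) > 0) {
        warnf("%d component latencies still outside the %.0f ms epoch after %d redraws; clipped",
              length(bad), epoch_ms, max_latency_redraws)
        l[bad] <- pmin(pmax(l[bad], 0), epoch_ms)
      }
      l
    })
    amps <- amps * amplitude_scale
    widths <- erp$width_ms / 1000
    for (e in seq_len(nt)) {
      onset <- schedule$onset_s[targets[e]]
      for (c in 1:3) {
        base <- add_bump(base, fs, onset + lats[e, c] / 1000,
                         amps[e, c], widths[c])
      }
    }
    draws <- data.frame(
      event = rep(seq_len(nt), times = 3),
      component = rep(.ERP_COMPONENTS, each = nt),
      amplitude = as.vector(amps),
      latency_ms = as.vector(lats)
    )
  }

  if (nontarget_scale > 0) {
    nontargets <- which(!schedule$is_target)
    widths <- erp$width_ms / 1000
    for (i in nontargets) {
      onset <- schedule$onset_s[i]
      for (c in 1:3) {
        base <- add_bump(base, fs, onset + erp$latency_mean[c] / 1000,
                         nontarget_scale * erp$amplitude_mean[c] *
                           amplitude_scale, widths[c])
      }
    }
  }

  samples <- matrix(0, n, 2, dimnames = list(NULL, c("O1", "O2")))
  tgrid <- (seq_len(n) - 1) / fs
  for (ch in 1:2) {
    chan_noise <- with_seed(substream(seed, 4L + ch), {
      x <- colored_noise(n, noise$spectral_exponent, noise$noise_rms, fs)
      if (noise$alpha_bump_amplitude > 0) {
        x <- x + noise$alpha_bump_amplitude *
          sin(2 * pi * 10 * tgrid + stats::runif(1, 0, 2 * pi))
      }
      x
    })
    samples[, ch] <- base + chan_noise
  }

  rec <- structure(
    list(samples = samples, sampling_rate = fs,
         channel_names = c("O1", "O2"), schedule = schedule),
    class = "eeg_recording")
  attr(rec, "draws") <- draws
  rec
}

# add a Gaussian bump a*exp(-(t-t_peak)^2/(2 w^2)) into x (w in seconds)
add_bump <- function(x, fs, t_peak, a, w) {
  n <- length(x)
  i0 <- max(1L, as.integer(floor((t_peak - 5 * w) * fs)) + 1L)
  i1 <- min(n, as.integer(ceiling((t_peak + 5 * w) * fs)) + 1L)
  if (i0 > i1) return(x)
  idx <- i0:i1
  t <- (idx - 1) / fs
  x[idx] <- x[idx] + a * exp(-(t - t_peak)^2 / (2 * w^2))
  x
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("eeg_recording: %d samples x %d channels (%s) @ %g Hz, %.1f s, %d events (%d targets)\n",
              nrow(x$samples), ncol(x$samples),
              paste(x$channel_names, collapse = ", "), x$sampling_rate,
              nrow(x$samples) / x$sampling_rate, nrow(x$schedule),
              sum(x$schedule$is_target)))
  invisible(x)
}

#' Channel-averaged occipital trace
#'
#' O1 and O2 are averaged into a single occipital signal before ERP and
#' feature analysis (the two channels carry the same ERP template with
#' independent noise).
#'
#' @param recording an `eeg_recording`.
#' @return Numeric vector, microvolts.
#' @export
occipital_trace <- function(recording) {
  rowMeans(recording$samples)
}
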