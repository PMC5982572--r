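# Preprocessing: mean subtraction, zero-phase 1-8 Hz ERP-band filtering,
# epoch extraction into target (P300) / non-target groups, grand averaging,
# and P1/P2/P3 component peak statistics.

#' Subtract the mean of a signal
#'
#' @param signal non-empty numeric vector (microvolts).
#' @return `signal - mean(signal)`.
#' @export
subtract_mean <- function(signal) {
  if (length(signal) == 0L) stopf("cannot subtract the mean of an empty signal")
  signal - mean(signal)
}

#' Zero-phase band-pass filter
#'
#' Filters with the squared magnitude response of an `order`-th Butterworth
#' band-pass, applied in the frequency domain; this is the amplitude response
#' of forward-backward (filtfilt) filtering but has exactly zero phase and no
#' start-up transient, so component latencies are preserved.  Edges are
#' handled by odd-reflection padding.  One octave outside the passband the
#' attenuation exceeds 20 dB (it is about 55 dB for the default 4th order).
#'
#' @param signal numeric vector.
#' @param sampling_rate Hz.
#' @param low,high passband edges in Hz, `0 <= low < high < sampling_rate/2`.
#' @param order Butterworth prototype order (default 4).
#' @return Filtered signal, same length.
#' @export
bandpass <- function(signal, sampling_rate, low = 1, high = 8, order = 4) {
  fs <- sampling_rate
  if (!(low >= 0 && low < high && high < fs / 2)) {
    stopf("invalid band: need 0 <= low < high < sampling_rate/2 (got %g-%g Hz at %g Hz)",
          low, high, fs)
  }
  n <- length(signal)
  if (n < 4) stopf("signal too short to filter")
  # odd reflection padding to suppress wrap-around ringing
  p <- min(n - 1, as.integer(round(2 * fs)))
  head_pad <- 2 * signal[1] - signal[(p + 1):2]
  tail_pad <- 2 * signal[n] - signal[(n - 1):(n - p)]
  xp <- c(head_pad, signal, tail_pad)
  m <- length(xp)
  k <- 0:(m - 1)
  f <- pmin(k, m - k) * fs / m
  g <- butterworth_bp_gain(f, low, high, order)^2
  out <- Re(stats::fft(stats::fft(xp) * g, inverse = TRUE)) / m
  out[(p + 1):(p + n)]
}

# |H(f)| of an analog Butterworth band-pass prototype
butterworth_bp_gain <- function(f, low, high, order) {
  omega <- ifelse(f > 0, (f^2 - low * high) / (f * (high - low)), Inf)
  ifelse(is.infinite(omega), 0, 1 / sqrt(1 + omega^(2 * order)))
}

#' Extract target / non-target epochs from a recording
#'
#' One target epoch of `epoch_duration` seconds starts at each target-flash
#' onset (epochs whose end would fall past the recording end are dropped with
#' a warning).  Non-target ("Group 2") epochs are consecutive non-overlapping
#' slices of the remaining signal, excluding every sample within
#' `epoch_duration` after any target onset, so no sample belongs to both
#' groups.  O1 and O2 are averaged into a single occipital trace first and
#' the trace mean is subtracted when `demean = TRUE`.
#'
#' @param recording an `eeg_recording` with stimulus markers.
#' @param epoch_duration epoch length in seconds (default 0.7; 89 samples at
#'   128 Hz).
#' @param demean subtract the whole-trace mean first (default TRUE).
#' @return An `epoch_set`: list with `epochs` (matrix, one epoch per row),
#'   `label` (`"target"`/`"nontarget"`), `onset_s`, `epoch_duration`,
#'   `sampling_rate`.
#' @export
extract_epochs <- function(recording, epoch_duration = 0.7, demean = TRUE) {
  sched <- recording$schedule
  if (is.null(sched) || nrow(sched) == 0L) {
    stopf("recording has no stimulus markers")
  }
  fs <- recording$sampling_rate
  trace <- occipital_trace(recording)
  if (demean) trace <- subtract_mean(trace)
  n <- length(trace)
  len <- as.integer(floor(epoch_duration * fs))

  t_onsets <- sched$onset_s[sched$is_target]
  starts <- as.integer(round(t_onsets * fs)) + 1L
  complete <- starts + len - 1L <= n
  if (any(!complete)) {
    warnf("%d target epoch(s) extend past the recording end and were dropped",
          sum(!complete))
  }
  t_starts <- starts[complete]
  t_onsets <- t_onsets[complete]

  epochs <- list()
  labels <- character(0)
  onsets <- numeric(0)
  for (i in seq_along(t_starts)) {
    epochs[[length(epochs) + 1]] <- trace[t_starts[i]:(t_starts[i] + len - 1L)]
    labels <- c(labels, "target")
    onsets <- c(onsets, t_onsets[i])
  }

  # exclusion mask: every sample within epoch_duration after any target onset
  excluded <- logical(n)
  for (s in starts) {
    excluded[s:min(n, s + len - 1L)] <- TRUE
  }
  free <- rle(!excluded)
  pos <- cumsum(c(1L, free$lengths))
  for (j in seq_along(free$values)) {
    if (!free$values[j]) next
    run_start <- pos[j]
    run_len <- free$lengths[j]
    k <- 0L
    while ((k + 1L) * len <= run_len) {
      s <- run_start + k * len
      epochs[[length(epochs) + 1]] <- trace[s:(s + len - 1L)]
      labels <- c(labels, "nontarget")
      onsets <- c(onsets, (s - 1) / fs)
      k <- k + 1L
    }
  }

  mat <- if (length(epochs)) do.call(rbind, epochs) else
    matrix(numeric(0), 0, len)
  structure(
    list(epochs = mat, label = labels, onset_s = onsets,
         epoch_duration = epoch_duration, sampling_rate = fs),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set: %d epochs (%d target, %d non-target) of %d samples @ %g Hz\n",
              nrow(x$epochs), sum(x$label == "target"),
              sum(x$label == "nontarget"), ncol(x$epochs), x$sampling_rate))
  invisible(x)
}

#' Export an epoch set as long-format CSV
#'
#' Columns `epoch_id,label,sample_index,value_uV` (sample_index 0-based
#' within the epoch).
#'
#' @param epochs an `epoch_set`.
#' @param path CSV output path.
#' @return Invisibly, `path`.
#' @export
write_epochs <- function(epochs, path) {
  n <- nrow(epochs$epochs)
  len <- ncol(epochs$epochs)
  utils::write.csv(
    data.frame(epoch_id = rep(seq_len(n), each = len),
               label = rep(epochs$label, each = len),
               sample_index = rep(0:(len - 1), n),
               value_uV = as.vector(t(epochs$epochs))),
    path, row.names = FALSE)
  invisible(path)
}

#' Grand-average ERP waveform
#'
#' Pointwise mean across all epochs with the given label.
#'
#' @param epochs an `epoch_set`.
#' @param label `"target"` or `"nontarget"`.
#' @return An `erp_waveform`: list with `samples`, `sampling_rate`,
#'   `n_epochs_averaged`.
#' @export
average_erp <- function(epochs, label = c("target", "nontarget")) {
  label <- match.arg(label)
  sel <- epochs$label == label
  if (!any(sel)) stopf("no epochs with label '%s'", label)
  structure(
    list(samples = colMeans(epochs$epochs[sel, , drop = FALSE]),
         sampling_rate = epochs$sampling_rate,
         n_epochs_averaged = sum(sel)),
    class = "erp_waveform")
}

#' Default component search windows
#'
#' P1 (minimum) 100-210 ms, P2 (maximum) 200-330 ms, P3 (maximum) 400-560 ms:
#' the published mean +/- 1 SD latency ranges rounded outward.
#'
#' @return Named list of `c(low_ms, high_ms)` windows.
#' @export
erp_component_windows <- function() {
  list(P1 = c(100, 210), P2 = c(200, 330), P3 = c(400, 560))
}

#' Detect P1/P2/P3 component peaks in one epoch or ERP
#'
#' P1 is the minimum sample in its window; P2 and P3 the maxima in theirs.
#' An epoch that does not clearly present the components (P1 >= 0, or P2 or
#' P3 <= 0) is *rejected*, not an error, mirroring the discard rule used in
#' the component statistics.
#'
#' @param epoch_or_erp numeric vector or `erp_waveform`.
#' @param sampling_rate Hz (taken from the waveform if omitted).
#' @param windows per-component `(low_ms, high_ms)` search windows; must lie
#'   inside the epoch.
#' @return A `component_peaks` object: `peaks` data frame (component,
#'   amplitude, latency_ms), `rejected` flag, `reason`, `windows`.
#' @export
detect_components <- function(epoch_or_erp, sampling_rate = NULL,
                              windows = erp_component_windows()) {
  if (inherits(epoch_or_erp, "erp_waveform")) {
    x <- epoch_or_erp$samples
    sampling_rate <- sampling_rate %||% epoch_or_erp$sampling_rate
  } else {
    x <- as.numeric(epoch_or_erp)
  }
  if (is.null(sampling_rate)) stopf("'sampling_rate' is required")
  fs <- sampling_rate
  t_ms <- (seq_along(x) - 1) * 1000 / fs
  epoch_ms <- t_ms[length(t_ms)]
  peaks <- data.frame(component = names(windows), amplitude = NA_real_,
                      latency_ms = NA_real_)
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    if (w[1] < 0 || w[2] > epoch_ms) {
      stopf("window %s (%g-%g ms) lies outside the epoch (0-%.1f ms)",
            names(windows)[i], w[1], w[2], epoch_ms)
    }
    idx <- which(t_ms >= w[1] & t_ms <= w[2])
    pick <- if (names(windows)[i] == "P1") idx[which.min(x[idx])] else
      idx[which.max(x[idx])]
    peaks$amplitude[i] <- x[pick]
    peaks$latency_ms[i] <- t_ms[pick]
  }
  rejected <- FALSE
  reason <- NULL
  if (peaks$amplitude[peaks$component == "P1"] >= 0) {
    rejected <- TRUE; reason <- "P1 not negative"
  } else if (any(peaks$amplitude[peaks$component %in% c("P2", "P3")] <= 0)) {
    rejected <- TRUE; reason <- "P2/P3 not positive"
  }
  structure(list(peaks = peaks, rejected = rejected, reason = reason,
                 windows = windows),
            class = "component_peaks")
}

#' Component peak statistics across epochs
#'
#' Sample mean and SD of the detected amplitudes and latencies per component,
#' plus the mean +/- 1 SD latency window used to characterize each
#' component's time range.  Rejected epochs are counted as discarded.
#'
#' @param peaks list of [detect_components()] results.
#' @return An `erp_component_stats` object: `stats` data frame with columns
#'   component, amplitude_mean, amplitude_sd, latency_mean, latency_sd,
#'   window_low_ms, window_high_ms; plus `n_retained`, `n_discarded`.
#' @export
component_stats <- function(peaks) {
  if (!length(peaks) || !all(vapply(peaks, inherits, TRUE, "component_peaks"))) {
    stopf("'peaks' must be a list of component_peaks objects")
  }
  keep <- !vapply(peaks, `[[`, TRUE, "rejected")
  if (sum(keep) < 2) {
    stopf("need at least 2 retained epochs to compute statistics (got %d)",
          sum(keep))
  }
  kept <- peaks[keep]
  comps <- kept[[1]]$peaks$component
  amp <- sapply(kept, function(p) p$peaks$amplitude)
  lat <- sapply(kept, function(p) p$peaks$latency_ms)
  stats_df <- data.frame(
    component = comps,
    amplitude_mean = rowMeans(amp),
    amplitude_sd = apply(amp, 1, stats::sd),
    latency_mean = rowMeans(lat),
    latency_sd = apply(lat, 1, stats::sd)
  )
  stats_df$window_low_ms <- stats_df$latency_mean - stats_df$latency_sd
  stats_df$window_high_ms <- stats_df$latency_mean + stats_df$latency_sd
  structure(list(stats = stats_df, n_retained = sum(keep),
                 n_discarded = sum(!keep)),
            class = "erp_component_stats")
}

#' @export
print.erp_component_stats <- function(x, ...) {
  cat(sprintf("erp_component_stats (%d epochs retained, %d discarded)\n",
              x$n_retained, x$n_discarded))
  print(format(x$stats, digits = 5), row.names = FALSE)
  invisible(x)
}

#' Latency windows from stated component statistics
#'
#' Convenience: mean +/- 1 SD windows from given latency means/SDs, e.g. to
#' reproduce published time ranges.
#'
#' @param latency_mean,latency_sd numeric vectors (ms).
#' @return Data frame with `low_ms`, `high_ms`.
#' @export
latency_windows <- function(latency_mean, latency_sd) {
  data.frame(low_ms = latency_mean - latency_sd,
             high_ms = latency_mean + latency_sd)
}
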