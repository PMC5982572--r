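# Band-averaged rhythm signals and sliding-window statistical features.
#
# The S-transform magnitude is partitioned into the five canonical EEG bands
# (delta 1-5, theta 5-8, alpha 8-15, beta 15-30, gamma 30-64 Hz; half-open
# [low, high) so shared edges are not double counted), each band is averaged
# over frequency into one representative rhythm amplitude signal, and the
# signal is sliced into 2 s windows advanced by 0.25 s.  Five statistical
# functions turn each window into scalars; pairs of them form the 2-D feature
# points used by the classifiers.

.FEATURE_KINDS <- c("std", "kurtosis", "skewness", "auc", "avg_power")

#' Canonical EEG band definitions
#'
#' @return Data frame with columns `name`, `low`, `high` (Hz): delta 1-5,
#'   theta 5-8, alpha 8-15, beta 15-30, gamma 30-64.
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low = c(1, 5, 8, 15, 30),
             high = c(5, 8, 15, 30, 64))
}

#' Look up one band definition
#'
#' @param name band name or a `list(name=, low=, high=)` definition.
#' @return A one-row band definition list.
#' @export
band_definition <- function(name) {
  if (is.list(name)) {
    if (!(name$low > 0 && name$low < name$high)) {
      stopf("invalid band: need 0 < low < high")
    }
    return(name)
  }
  b <- eeg_bands()
  i <- match(name, b$name)
  if (is.na(i)) stopf("unknown band '%s'; known bands: %s", name,
                      paste(b$name, collapse = ", "))
  as.list(b[i, ])
}

#' Average spectrogram magnitude over one frequency band
#'
#' Per time sample, the mean of the magnitude rows whose voice frequency lies
#' in `[low, high)` (the zero-frequency voice is excluded).
#'
#' @param spec an `st_spectrogram`, or a magnitude matrix (then supply
#'   `freqs` and `sampling_rate`).
#' @param band a band name or definition (see [band_definition()]).
#' @param freqs,sampling_rate row frequencies (Hz) and sampling rate, needed
#'   only when `spec` is a bare matrix.
#' @return A `band_signal`: list with non-negative `samples` (mean in-band
#'   instantaneous amplitude, microvolts), `band`, `sampling_rate`.
#' @export
band_average <- function(spec, band, freqs = NULL, sampling_rate = NULL) {
  band <- band_definition(band)
  if (inherits(spec, "st_spectrogram")) {
    mag <- Mod(spec$values)
    freqs <- spec$freqs
    sampling_rate <- spec$sampling_rate
  } else {
    mag <- spec
    if (is.null(freqs) || is.null(sampling_rate)) {
      stopf("'freqs' and 'sampling_rate' are required for a bare matrix")
    }
  }
  rows <- which(freqs >= band$low & freqs < band$high & freqs > 0)
  if (!length(rows)) {
    stopf("band %s (%g-%g Hz) contains no voices; available 0-%g Hz at %g Hz resolution",
          band$name %||% "?", band$low, band$high, max(freqs),
          if (length(freqs) > 1) freqs[2] - freqs[1] else NA)
  }
  structure(
    list(samples = colMeans(mag[rows, , drop = FALSE]),
         band = band, sampling_rate = sampling_rate),
    class = "band_signal")
}

#' Sliding-window configuration
#'
#' @param width window duration in seconds (default 2).
#' @param step window displacement in seconds (default 0.25).
#' @return A `windowing_config`.
#' @export
windowing_config <- function(width = 2, step = 0.25) {
  check_scalar(width, "width")
  check_scalar(step, "step")
  if (step > width) stopf("'step' must be <= 'width'")
  structure(list(width = width, step = step), class = "windowing_config")
}

#' Slice a signal into sliding windows
#'
#' Windows of `round(width * fs)` samples advanced by `round(step * fs)`
#' samples; the count is `floor((duration - width) / step) + 1`.
#'
#' @param signal numeric vector, at least one window long.
#' @param sampling_rate Hz.
#' @param cfg a [windowing_config()].
#' @return List of numeric windows, with attribute `start_s` (window start
#'   times in seconds).
#' @export
sliding_windows <- function(signal, sampling_rate, cfg = windowing_config()) {
  fs <- sampling_rate
  wl <- as.integer(round(cfg$width * fs))
  st <- as.integer(round(cfg$step * fs))
  n <- length(signal)
  if (n < wl) {
    stopf("signal (%g s) shorter than the window width (%g s)", n / fs,
          cfg$width)
  }
  starts <- seq.int(1L, n - wl + 1L, by = st)
  out <- lapply(starts, function(s) signal[s:(s + wl - 1L)])
  attr(out, "start_s") <- (starts - 1) / fs
  out
}

#' Compute one statistical feature of a window
#'
#' * `std`: sample standard deviation (n-1 denominator).
#' * `skewness`: `m3 / m2^1.5` (biased moment form; the asymmetry
#'   coefficient).
#' * `kurtosis`: `m4 / m2^2` (Pearson form; 3 for a Gaussian, not excess).
#' * `auc`: trapezoidal integral of the window, microvolt-seconds.
#' * `avg_power`: mean squared value, microvolts squared.
#'
#' For a zero-variance window, skewness and kurtosis are undefined and
#' `NA` is returned (the point is then dropped by
#' [build_feature_vectors()]).
#'
#' @param window numeric vector, length >= 4.
#' @param kind one of `"std"`, `"kurtosis"`, `"skewness"`, `"auc"`,
#'   `"avg_power"`.
#' @param sampling_rate Hz (used by `auc`).
#' @return A scalar.
#' @export
compute_feature <- function(window, kind = .FEATURE_KINDS, sampling_rate) {
  kind <- match.arg(kind)
  n <- length(window)
  if (n < 4) stopf("window must have at least 4 samples (got %d)", n)
  m <- mean(window)
  d <- window - m
  m2 <- mean(d^2)
  switch(kind,
         std = stats::sd(window),
         skewness = if (m2 <= 0) NA_real_ else mean(d^3) / m2^1.5,
         kurtosis = if (m2 <= 0) NA_real_ else mean(d^4) / m2^2,
         auc = sum((window[-1] + window[-n]) / 2) / sampling_rate,
         avg_power = mean(window^2))
}

#' Build 2-D feature vectors from a band signal
#'
#' Slices the band signal into sliding windows and computes the chosen pair
#' of feature functions per window.  Windows with undefined features
#' (zero variance, for skewness/kurtosis) are dropped with a warning.
#'
#' @param band_signal a [band_average()] result (or a plain numeric vector
#'   plus `sampling_rate`).
#' @param labels `"target"`/`"nontarget"` per window, or a single label
#'   recycled to all windows.
#' @param pair character pair of feature names, e.g. `c("skewness", "std")`.
#' @param cfg a [windowing_config()].
#' @param sampling_rate Hz, required only for a bare vector.
#' @param t0 time offset added to window starts (seconds, default 0).
#' @return A `feature_set`: data frame with `window_start_s`, `label`, `x`,
#'   `y`; attribute `feature_pair`.
#' @export
build_feature_vectors <- function(band_signal, labels, pair,
                                  cfg = windowing_config(),
                                  sampling_rate = NULL, t0 = 0) {
  if (inherits(band_signal, "band_signal")) {
    x <- band_signal$samples
    sampling_rate <- band_signal$sampling_rate
  } else {
    x <- as.numeric(band_signal)
    if (is.null(sampling_rate)) stopf("'sampling_rate' is required")
  }
  if (length(pair) != 2L || !all(pair %in% .FEATURE_KINDS)) {
    stopf("'pair' must be two of: %s", paste(.FEATURE_KINDS, collapse = ", "))
  }
  wins <- sliding_windows(x, sampling_rate, cfg)
  nw <- length(wins)
  if (length(labels) == 1L) labels <- rep(labels, nw)
  if (length(labels) != nw) {
    stopf("got %d labels for %d windows", length(labels), nw)
  }
  fx <- vapply(wins, compute_feature, 0.0, kind = pair[1],
               sampling_rate = sampling_rate)
  fy <- vapply(wins, compute_feature, 0.0, kind = pair[2],
               sampling_rate = sampling_rate)
  ok <- is.finite(fx) & is.finite(fy)
  if (any(!ok)) {
    warnf("%d window(s) with undefined %s/%s dropped", sum(!ok), pair[1],
          pair[2])
  }
  out <- data.frame(window_start_s = attr(wins, "start_s")[ok] + t0,
                    label = labels[ok], x = fx[ok], y = fy[ok])
  attr(out, "feature_pair") <- pair
  class(out) <- c("feature_set", "data.frame")
  out
}

#' Combine feature sets
#'
#' @param ... `feature_set` objects with identical feature pairs.
#' @return One combined `feature_set`.
#' @export
bind_feature_sets <- function(...) {
  sets <- list(...)
  pairs <- lapply(sets, attr, "feature_pair")
  if (length(unique(lapply(pairs, paste, collapse = "+"))) != 1L) {
    stopf("feature sets use different feature pairs")
  }
  out <- do.call(rbind, lapply(sets, as.data.frame))
  attr(out, "feature_pair") <- pairs[[1]]
  class(out) <- c("feature_set", "data.frame")
  out
}

#' Write / read a feature set as CSV
#'
#' Columns `window_start_s,label,feature_x_name,feature_x,feature_y_name,feature_y`.
#'
#' @param fs_set a `feature_set`.
#' @param path CSV path.
#' @return `write_feature_set`: invisibly `path`; `read_feature_set`: a
#'   `feature_set`.
#' @export
write_feature_set <- function(fs_set, path) {
  pair <- attr(fs_set, "feature_pair")
  utils::write.csv(
    data.frame(window_start_s = fs_set$window_start_s, label = fs_set$label,
               feature_x_name = pair[1], feature_x = fs_set$x,
               feature_y_name = pair[2], feature_y = fs_set$y),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  df <- utils::read.csv(path)
  out <- data.frame(window_start_s = df$window_start_s, label = df$label,
                    x = df$feature_x, y = df$feature_y)
  attr(out, "feature_pair") <- c(df$feature_x_name[1], df$feature_y_name[1])
  class(out) <- c("feature_set", "data.frame")
  out
}
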