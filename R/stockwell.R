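# Discrete 1-D Stockwell (S-) transform.
#
# The S-transform of h(t) is a short-time Fourier analysis whose Gaussian
# window scales inversely with frequency,
#     S(tau, f) = Int h(t) (|f|/(sqrt(2*pi)*ws)) exp(-(tau-t)^2 f^2 / (2 ws^2))
#                 exp(-i 2 pi f t) dt,
# giving wavelet-like multiresolution with absolutely referenced phase.  The
# discrete implementation works voice by voice in the frequency domain:
#     S[n, j] = sum_m H[(m+n) mod N] G_n[m] exp(+i 2 pi m j / N),
# where H is the DFT of the signal divided by N and G_n is the (alias-summed)
# spectrum of the unit-area Gaussian window, G_n[m] = exp(-2 pi^2 m^2 ws^2/n^2).
# Averaging S[n, ] over time leaves only the m = 0 term, i.e. the Fourier
# coefficient H[n]: the time average of the S-transform is the Fourier
# spectrum.  The zero-frequency voice, where the window degenerates, is
# defined as the constant signal mean.
#
# `stransform()` is the fast FFT path; `stransform_direct()` is the O(N^2)
# direct summation of the defining integral (sampled, circularly periodized
# window) kept as an independent reference oracle.

#' Discrete Stockwell transform
#'
#' Computes the one-sided discrete S-transform of a real signal: one row
#' ("voice") per frequency `n * sampling_rate / N` for
#' `n = 0..floor(N/2)`, one column per time sample.  Row 0 is the signal
#' mean (the Gaussian window is degenerate at f = 0).
#'
#' @param signal finite numeric vector, length `N >= 4`.
#' @param sampling_rate Hz.
#' @param window_scale multiplier on the Gaussian window width in time
#'   (default 1 = the classical window).
#' @param freq_range optional `c(low, high)` in Hz: compute only voices in
#'   this closed range (saves time when only one band is needed).
#' @return An `st_spectrogram`: list with complex matrix `values`
#'   (voices x time), `freqs` (Hz), `times` (s), `sampling_rate`,
#'   `window_scale`.
#' @seealso [stransform_direct()], [time_average_spectrum()], [st_magnitude()]
#' @export
stransform <- function(signal, sampling_rate, window_scale = 1,
                       freq_range = NULL) {
  if (!all(is.finite(signal))) stopf("'signal' must be finite")
  n_samp <- length(signal)
  if (n_samp < 4) stopf("'signal' must have at least 4 samples (got %d)", n_samp)
  check_scalar(sampling_rate, "sampling_rate")
  check_scalar(window_scale, "window_scale")
  fs <- sampling_rate

  voices <- 0:(n_samp %/% 2)
  freqs_all <- voices * fs / n_samp
  if (!is.null(freq_range)) {
    keep <- freqs_all >= freq_range[1] & freqs_all <= freq_range[2]
    if (!any(keep)) {
      stopf("no voices in %g-%g Hz; resolution is %g Hz up to %g Hz",
            freq_range[1], freq_range[2], fs / n_samp, max(freqs_all))
    }
    voices <- voices[keep]
    freqs_all <- freqs_all[keep]
  }

  H <- stats::fft(signal) / n_samp
  m <- 0:(n_samp - 1)
  mw <- ifelse(m <= n_samp / 2, m, m - n_samp)
  values <- matrix(0i, length(voices), n_samp)
  for (r in seq_along(voices)) {
    nv <- voices[r]
    if (nv == 0) {
      values[r, ] <- complex(real = mean(signal))
      next
    }
    c0 <- 2 * pi^2 * window_scale^2 / nv^2
    gau <- exp(-c0 * mw^2) + exp(-c0 * (mw + n_samp)^2) +
      exp(-c0 * (mw - n_samp)^2)
    hs <- H[((m + nv) %% n_samp) + 1]
    values[r, ] <- stats::fft(hs * gau, inverse = TRUE)
  }
  structure(
    list(values = values, freqs = freqs_all, times = (m) / fs,
         sampling_rate = fs, window_scale = window_scale),
    class = "st_spectrogram")
}

#' Direct-summation Stockwell transform (reference oracle)
#'
#' Evaluates the defining time-domain sum of the S-transform with the
#' sampled, circularly periodized Gaussian window.  O(N^2) per voice; meant
#' for verification on short signals, not production use.
#'
#' @inheritParams stransform
#' @param wraps number of +/- periodizations of the Gaussian window summed
#'   (default `8 * window_scale`; the lowest voice's window has a sigma of
#'   `window_scale * N` samples, so its tails die off slowly in units of
#'   the period).
#' @return An `st_spectrogram` (same layout as [stransform()]).
#' @export
stransform_direct <- function(signal, sampling_rate, window_scale = 1,
                              wraps = ceiling(8 * window_scale)) {
  if (!all(is.finite(signal))) stopf("'signal' must be finite")
  n_samp <- length(signal)
  if (n_samp < 4) stopf("'signal' must have at least 4 samples (got %d)", n_samp)
  fs <- sampling_rate
  voices <- 0:(n_samp %/% 2)
  k <- 0:(n_samp - 1)
  values <- matrix(0i, length(voices), n_samp)
  for (r in seq_along(voices)) {
    nv <- voices[r]
    if (nv == 0) {
      values[r, ] <- complex(real = mean(signal))
      next
    }
    # circularly periodized sampled window, unit area
    p <- 0:(n_samp - 1)
    w <- numeric(n_samp)
    for (s in -wraps:wraps) {
      w <- w + exp(-((p + s * n_samp) * nv / n_samp)^2 / (2 * window_scale^2))
    }
    w <- w * nv / (n_samp * window_scale * sqrt(2 * pi))
    phase <- exp(-2i * pi * nv * k / n_samp)
    for (j in k) {
      values[r, j + 1] <- sum(signal * phase * w[((j - k) %% n_samp) + 1])
    }
  }
  structure(
    list(values = values, freqs = voices * fs / n_samp, times = k / fs,
         sampling_rate = fs, window_scale = window_scale),
    class = "st_spectrogram")
}

#' Time-averaged S-transform spectrum
#'
#' The column-wise mean over time of each voice.  By construction this equals
#' the signal's (1/N-normalized) DFT coefficients at the voice frequencies:
#' the Fourier-spectrum identity of the S-transform.
#'
#' @param spec an `st_spectrogram`.
#' @return Complex vector named by frequency (Hz).
#' @export
time_average_spectrum <- function(spec) {
  if (!inherits(spec, "st_spectrogram")) stopf("'spec' must be an st_spectrogram")
  stats::setNames(rowMeans(spec$values), format(spec$freqs))
}

#' S-transform magnitude (instantaneous amplitude)
#'
#' @param spec an `st_spectrogram`.
#' @return Non-negative real matrix of elementwise complex moduli.
#' @export
st_magnitude <- function(spec) {
  if (!inherits(spec, "st_spectrogram")) stopf("'spec' must be an st_spectrogram")
  Mod(spec$values)
}

#' @export
print.st_spectrogram <- function(x, ...) {
  cat(sprintf("st_spectrogram: %d voices (%.3g-%.3g Hz) x %d samples @ %g Hz\n",
              nrow(x$values), min(x$freqs), max(x$freqs), ncol(x$values),
              x$sampling_rate))
  invisible(x)
}

#' Export a spectrogram as long-format CSV
#'
#' Columns `freq_hz,time_s,real,imag`.
#'
#' @param spec an `st_spectrogram`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_spectrogram <- function(spec, path) {
  df <- data.frame(
    freq_hz = rep(spec$freqs, times = length(spec$times)),
    time_s = rep(spec$times, each = length(spec$freqs)),
    real = as.vector(Re(spec$values)),
    imag = as.vector(Im(spec$values)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
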