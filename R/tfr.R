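#' Continuous neural signal
#'
#' Container for a uniformly sampled single-channel time course (for example
#' the beta-band ICA component time course burst detection operates on).
#'
#' @param samples Numeric vector of samples, arbitrary physical units. Must
#'   be finite throughout.
#' @param fs Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample in seconds (default 0).
#'
#' @return An object of class `bb_signal`: a list with elements `samples`,
#'   `fs` and `start_time`.
#' @examples
#' sig <- continuous_signal(sin(2 * pi * 20 * seq(0, 2, by = 1 / 250)), fs = 250)
#' sig
#' @export
continuous_signal <- function(samples, fs, start_time = 0) {
  assert_scalar_num(fs, "fs", positive = TRUE)
  assert_scalar_num(start_time, "start_time")
  samples <- as.numeric(samples)
  if (length(samples) < 1L) abort("`samples` must be non-empty.")
  if (!all(is.finite(samples))) {
    abort("`samples` must be finite (no NA/NaN/Inf).")
  }
  structure(
    list(samples = samples, fs = fs, start_time = start_time),
    class = "bb_signal"
  )
}

#' @export
print.bb_signal <- function(x, ...) {
  cat(sprintf(
    "<bb_signal> %d samples @ %g Hz (%.2f s), start %.3f s\n",
    length(x$samples), x$fs, length(x$samples) / x$fs, x$start_time
  ))
  invisible(x)
}

#' @export
format.bb_signal <- function(x, ...) {
  sprintf("<bb_signal: %d samples @ %g Hz>", length(x$samples), x$fs)
}

signal_duration <- function(signal) length(signal$samples) / signal$fs

signal_times <- function(signal) {
  signal$start_time + (seq_along(signal$samples) - 1) / signal$fs
}

new_spectrogram <- function(power, freqs, times, fs, smoothed, edge_margin) {
  structure(
    list(
      power = power, freqs = freqs, times = times, fs = fs,
      smoothed = smoothed, edge_margin = edge_margin
    ),
    class = "bb_spectrogram"
  )
}

#' @export
print.bb_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<bb_spectrogram> %d freqs (%g-%g Hz) x %d times @ %g Hz%s\n",
    length(x$freqs), min(x$freqs), max(x$freqs), length(x$times), x$fs,
    if (x$smoothed) ", smoothed" else ""
  ))
  invisible(x)
}

# Complex Morlet wavelet at frequency f, sampled at fs, truncated at +-5
# temporal SDs. The Gaussian envelope SD is n_cycles/(2*pi*f).
# Per-frequency scaling trades off where peak frequencies land, because the
# wavelet bandwidth grows with f (sigma_f = f / n_cycles):
#   "peak"      unit time-domain peak, i.e. unit-area frequency response;
#               unbiased peak frequency for broadband transients (bursts).
#   "energy"    unit L2 norm; unbiased-ish for tones, biases transient
#               peaks upward by roughly sigma_f^2 / (2 f).
#   "amplitude" unit peak frequency response; equal tone magnitude across
#               frequencies, largest upward transient bias.
morlet_wavelet <- function(f, fs, n_cycles, n_sd = 5,
                           norm = c("energy", "peak", "amplitude")) {
  norm <- match.arg(norm)
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(n_sd * sigma_t * fs)
  t <- (-half:half) / fs
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t)
  switch(norm,
    peak = w,
    energy = w / sqrt(sum(Mod(w)^2)),
    amplitude = w / sum(Mod(w))
  )
}

#' Morlet wavelet time-frequency decomposition
#'
#' Computes the power spectrogram of a continuous signal by convolution with
#' complex Morlet wavelets, by default 5-cycle wavelets at 1-Hz intervals
#' from 1 to 40 Hz. Power is the squared magnitude of the complex wavelet
#' coefficient at every sample; the time axis is kept at the signal sampling
#' rate. Wavelets are truncated at five envelope standard deviations and
#' normalised to unit energy, so absolute power scales are arbitrary; the
#' downstream burst threshold is a ratio to the per-frequency median and is
#' invariant to this normalisation.
#'
#' Samples closer to either recording edge than half the wavelet support at a
#' given frequency are unreliable (the wavelet overhangs the recording); the
#' per-frequency margin in seconds is stored as `edge_margin` and used by
#' [detect_bursts()] to drop edge events.
#'
#' @param signal A [continuous_signal()].
#' @param freqs Analysis frequencies in Hz, strictly increasing, all below
#'   the Nyquist frequency. Default `1:40`.
#' @param n_cycles Number of wavelet cycles (default 5).
#' @param norm Per-frequency wavelet normalisation: `"energy"` (default;
#'   unit L2 norm), `"peak"` (unit time-domain peak, i.e. unit-area
#'   frequency response) or `"amplitude"` (unit peak frequency response).
#'   The median-ratio burst threshold is invariant to this choice (it
#'   rescales whole frequency rows), but the frequency assigned to a peak
#'   is not, because the wavelet bandwidth grows with frequency: energy
#'   normalisation localises sustained tones exactly but biases the peak
#'   frequency of brief transients upward by roughly 1-2 Hz in the beta
#'   band; `"peak"` removes most of that transient bias at the cost of a
#'   small downward tone bias. See the methods vignette.
#'
#' @return A `bb_spectrogram`: power matrix (`n_freqs x n_times`), `freqs`,
#'   `times`, `fs`, a `smoothed` flag (FALSE) and `edge_margin` (seconds per
#'   frequency).
#' @examples
#' sig <- continuous_signal(sin(2 * pi * 20 * seq(0, 5, by = 1 / 250)), fs = 250)
#' spec <- morlet_tfr(sig)
#' spec$freqs[which.max(rowMeans(spec$power))] # 20
#' @export
morlet_tfr <- function(signal, freqs = 1:40, n_cycles = 5,
                       norm = c("energy", "peak", "amplitude")) {
  norm <- match.arg(norm)
  stopifnot(inherits(signal, "bb_signal"))
  if (n_cycles < 1) abort("`n_cycles` must be >= 1.")
  freqs <- as.numeric(freqs)
  if (length(freqs) < 1L || any(diff(freqs) <= 0)) {
    abort("`freqs` must be strictly increasing.")
  }
  nyq <- signal$fs / 2
  if (any(freqs >= nyq)) {
    abort(sprintf(
      "All frequencies must be below the Nyquist frequency (%g Hz).", nyq
    ))
  }
  x <- signal$samples
  n <- length(x)
  # longest wavelet is at the lowest frequency
  max_half <- ceiling(5 * n_cycles / (2 * pi * min(freqs)) * signal$fs)
  if (n <= 2L * max_half + 1L) {
    abort(sprintf(
      "Signal (%d samples) is shorter than the longest wavelet (%d samples).",
      n, 2L * max_half + 1L
    ))
  }
  power <- matrix(0, nrow = length(freqs), ncol = n)
  edge_margin <- numeric(length(freqs))
  nfft <- 2^ceiling(log2(n + 2L * max_half + 1L))
  fx <- fft(c(x, rep(0, nfft - n)))
  for (i in seq_along(freqs)) {
    w <- morlet_wavelet(freqs[i], signal$fs, n_cycles, norm = norm)
    half <- (length(w) - 1L) %/% 2L
    fw <- fft(c(w, rep(0 + 0i, nfft - length(w))))
    full <- fft(fx * fw, inverse = TRUE) / nfft
    # 'same' alignment: coefficient at sample t is the full convolution at
    # index t + half (the wavelet envelope is symmetric, so convolution
    # equals correlation with the conjugate wavelet)
    power[i, ] <- Mod(full[(half + 1L):(half + n)])^2
    edge_margin[i] <- half / signal$fs
  }
  new_spectrogram(
    power = power, freqs = freqs, times = signal_times(signal),
    fs = signal$fs, smoothed = FALSE, edge_margin = edge_margin
  )
}

# Truncated, unit-sum 1D Gaussian kernel with SD in bin units.
gaussian_kernel_1d <- function(sd_bins, n_sd = 4) {
  r <- max(1L, ceiling(n_sd * sd_bins))
  k <- exp(-((-r:r)^2) / (2 * sd_bins^2))
  k / sum(k)
}

# Convolve each row (dim = 2, along time) or each column (dim = 1, along
# frequency) of `mat` with kernel `k`, using mirror-reflected boundaries.
conv_dim_reflect <- function(mat, k, dim) {
  r <- (length(k) - 1L) %/% 2L
  out <- matrix(0, nrow(mat), ncol(mat))
  if (dim == 2L) {
    n <- ncol(mat)
    idx <- reflect_index(seq.int(1L - r, n + r), n)
    padded <- mat[, idx, drop = FALSE]
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[, j:(j + n - 1L), drop = FALSE]
    }
  } else {
    n <- nrow(mat)
    idx <- reflect_index(seq.int(1L - r, n + r), n)
    padded <- mat[idx, , drop = FALSE]
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[j:(j + n - 1L), , drop = FALSE]
    }
  }
  out
}

#' Smooth a spectrogram with a 2D Gaussian filter
#'
#' Applies a separable two-dimensional Gaussian filter to an unsmoothed
#' power spectrogram, with standard deviations of 1 Hz along the frequency
#' axis and 6 ms along the time axis by default. The SDs are converted to
#' bin units (`sd_f / frequency step`, `sd_t * fs`); the kernel is truncated
#' at four standard deviations, renormalised to unit sum, and applied with
#' mirror-reflected boundaries, so a constant spectrogram is unchanged and
#' the interior sum is preserved.
#'
#' @param spec An unsmoothed `bb_spectrogram` from [morlet_tfr()].
#' @param sd_f Frequency-axis SD in Hz (default 1).
#' @param sd_t Time-axis SD in seconds (default 0.006).
#'
#' @return The smoothed `bb_spectrogram` (flagged `smoothed = TRUE`).
#' @export
smooth_spectrogram <- function(spec, sd_f = 1, sd_t = 0.006) {
  stopifnot(inherits(spec, "bb_spectrogram"))
  if (isTRUE(spec$smoothed)) {
    abort("Spectrogram is already smoothed.", class = "bb_invalid_state")
  }
  assert_scalar_num(sd_f, "sd_f", positive = TRUE)
  assert_scalar_num(sd_t, "sd_t", positive = TRUE)
  df <- if (length(spec$freqs) > 1L) diff(spec$freqs)[1] else 1
  if (length(spec$freqs) > 2L && any(abs(diff(spec$freqs) - df) > 1e-9)) {
    abort("Frequency axis must be uniformly spaced for bin-based smoothing.")
  }
  kf <- gaussian_kernel_1d(sd_f / df)
  kt <- gaussian_kernel_1d(sd_t * spec$fs)
  sm <- conv_dim_reflect(conv_dim_reflect(spec$power, kt, dim = 2L), kf, dim = 1L)
  out <- spec
  out$power <- sm
  out$smoothed <- TRUE
  out
}

#' @describeIn morlet_tfr Tidy a spectrogram into a long tibble with columns
#'   `time`, `freq`, `power`.
#' @param x A `bb_spectrogram`.
#' @param ... Unused.
#' @export
as_tibble.bb_spectrogram <- function(x, ...) {
  tibble(
    time = rep(x$times, each = length(x$freqs)),
    freq = rep(x$freqs, times = length(x$times)),
    power = as.vector(x$power)
  )
}

#' Plot a spectrogram
#'
#' @param object A `bb_spectrogram`.
#' @param max_times Downsample the time axis to at most this many columns
#'   before plotting (default 2000).
#' @param ... Unused.
#' @return A ggplot object (time-frequency raster of power).
#' @export
autoplot.bb_spectrogram <- function(object, max_times = 2000, ...) {
  keep <- unique(round(seq(1, length(object$times), length.out =
    min(max_times, length(object$times)))))
  sub <- object
  sub$power <- object$power[, keep, drop = FALSE]
  sub$times <- object$times[keep]
  ggplot2::ggplot(as_tibble(sub), ggplot2::aes(.data$time, .data$freq,
    fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "Time (s)", y = "Frequency (Hz)",
      fill = "Power",
      title = if (object$smoothed) "Smoothed spectrogram" else "Spectrogram"
    )
}
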