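#' Burst-detection configuration
#'
#' Bundles the parameters of the beta-burst detector: the analysis
#' frequencies and wavelet cycles of the time-frequency decomposition, the
#' 2D Gaussian smoothing SDs, the beta band, and the median-ratio threshold.
#'
#' @param beta_band Two-element Hz interval defining the beta band; detected
#'   events are restricted to peak frequencies inside it. Default
#'   `c(13, 30)`, the conventional beta-band definition.
#' @param threshold_factor Peaks below `threshold_factor` times the median
#'   power across all time points at the peak frequency are excluded.
#'   Default 6.
#' @param freqs Analysis frequencies (default 1-40 Hz at 1-Hz steps).
#' @param n_cycles Morlet wavelet cycles (default 5).
#' @param norm Wavelet normalisation; see [morlet_tfr()].
#' @param sd_f,sd_t Smoothing SDs in Hz and seconds (defaults 1 Hz, 6 ms).
#' @param median_on Whether the per-frequency median is taken on the
#'   `"smoothed"` (default) or `"raw"` spectrogram.
#' @param min_separation Optional minimum time separation between retained
#'   events in seconds; 0 (default) keeps every suprathreshold local
#'   maximum. When positive, events are kept greedily in decreasing order of
#'   power.
#' @param drop_edges Drop events within half a wavelet support of either
#'   recording edge (default TRUE).
#'
#' @return A list of class `bb_detection_config`.
#' @export
detection_config <- function(beta_band = c(13, 30), threshold_factor = 6,
                             freqs = 1:40, n_cycles = 5,
                             norm = c("energy", "peak", "amplitude"),
                             sd_f = 1, sd_t = 0.006,
                             median_on = c("smoothed", "raw"),
                             min_separation = 0, drop_edges = TRUE) {
  median_on <- match.arg(median_on)
  norm <- match.arg(norm)
  if (length(beta_band) != 2L || beta_band[1] >= beta_band[2]) {
    abort("`beta_band` must be an increasing Hz interval.")
  }
  assert_scalar_num(threshold_factor, "threshold_factor", positive = TRUE)
  if (min_separation < 0) abort("`min_separation` must be >= 0.")
  structure(
    list(
      beta_band = as.numeric(beta_band),
      threshold_factor = threshold_factor,
      freqs = as.numeric(freqs), n_cycles = n_cycles, norm = norm,
      sd_f = sd_f, sd_t = sd_t, median_on = median_on,
      min_separation = min_separation, drop_edges = isTRUE(drop_edges)
    ),
    class = "bb_detection_config"
  )
}

#' Center-excluded 5x5 image dilation
#'
#' Morphological dilation of a matrix with a 5-by-5 structuring element
#' consisting of ones with a center value of zero: each output cell is the
#' maximum of the input over the 5x5 neighborhood excluding the cell itself.
#' Out-of-bounds neighbors are ignored, so border cells take the maximum
#' over their in-bounds neighbors only. A cell strictly exceeding its
#' dilated value is a strict local maximum.
#'
#' @param power A numeric matrix (at least 1x1).
#' @return A matrix of the same dimensions.
#' @examples
#' m <- matrix(0, 9, 9); m[5, 5] <- 10
#' d <- dilate(m)
#' d[5, 5] # 0: the center is excluded
#' @export
dilate <- function(power) {
  if (!is.matrix(power) || length(power) == 0L) {
    abort("`power` must be a non-empty matrix.")
  }
  nr <- nrow(power)
  nc <- ncol(power)
  padded <- matrix(-Inf, nr + 4L, nc + 4L)
  padded[3:(nr + 2L), 3:(nc + 2L)] <- power
  out <- matrix(-Inf, nr, nc)
  for (di in -2:2) {
    for (dj in -2:2) {
      if (di == 0L && dj == 0L) next
      out <- pmax(out, padded[(3L + di):(nr + 2L + di),
                              (3L + dj):(nc + 2L + dj), drop = FALSE])
    }
  }
  out
}

#' Find spectrogram peaks by center-excluded dilation
#'
#' A cell of the smoothed spectrogram is a peak iff its power strictly
#' exceeds the center-excluded 5x5 dilation at that cell, i.e. it is
#' strictly greater than all of its (up to 24) in-bounds neighbors. Plateaus
#' of exactly tied values yield no peaks.
#'
#' @param smoothed A smoothed `bb_spectrogram`.
#' @return A tibble with columns `freq_bin`, `time_bin` (1-based indices),
#'   `freq` (Hz), `time` (s) and `power`, sorted by time.
#' @export
find_peaks <- function(smoothed) {
  stopifnot(inherits(smoothed, "bb_spectrogram"))
  if (!isTRUE(smoothed$smoothed)) {
    abort("`find_peaks()` requires a smoothed spectrogram.",
          class = "bb_invalid_state")
  }
  hit <- which(smoothed$power > dilate(smoothed$power), arr.ind = TRUE)
  out <- tibble(
    freq_bin = as.integer(hit[, 1]),
    time_bin = as.integer(hit[, 2]),
    freq = smoothed$freqs[hit[, 1]],
    time = smoothed$times[hit[, 2]],
    power = smoothed$power[hit]
  )
  dplyr::arrange(out, .data$time, .data$freq)
}

#' Threshold peaks against the per-frequency median power
#'
#' Retains a candidate peak iff its power is at least `factor` times the
#' median power across all time points at the peak frequency (median over
#' the full recording, including edge-flagged samples). Peaks below the
#' threshold are excluded.
#'
#' @param candidates Peak tibble from [find_peaks()].
#' @param smoothed The spectrogram the candidates came from (used for the
#'   row medians).
#' @param factor Threshold factor (> 0, default 6).
#' @return The retained candidates with `row_median` and `median_ratio`
#'   columns appended.
#' @export
threshold_peaks <- function(candidates, smoothed, factor = 6) {
  stopifnot(inherits(smoothed, "bb_spectrogram"))
  assert_scalar_num(factor, "factor", positive = TRUE)
  row_med <- apply(smoothed$power, 1L, median)
  out <- candidates |>
    dplyr::mutate(
      row_median = row_med[.data$freq_bin],
      median_ratio = .data$power / .data$row_median
    )
  dplyr::filter(out, .data$power >= factor * .data$row_median)
}

#' Detect transient beta bursts in a continuous signal
#'
#' The full single-trial burst detector: Morlet wavelet time-frequency
#' decomposition, 2D Gaussian smoothing, strict local-maximum picking via
#' center-excluded 5x5 dilation, exclusion of peaks below `threshold_factor`
#' times the per-frequency median power, and restriction to peaks whose
#' frequency lies in the configured beta band. Events within half a wavelet
#' support of either recording edge are dropped (the TFR is unreliable
#' there). The peak times are the burst event times used by the rate
#' statistics and the BOLD model.
#'
#' Detection is deterministic, and — because the threshold is a ratio to the
#' per-frequency median — invariant to rescaling the signal by any positive
#' constant.
#'
#' @param signal A [continuous_signal()].
#' @param config A [detection_config()].
#' @return A tibble of class `bb_bursts` with columns `time` (s), `freq`
#'   (Hz), `peak_power` and `median_ratio`, sorted by time.
#' @examples
#' sig <- synthesize_eeg(make_nback_schedule(1, seed = 1), seed = 2)
#' bursts <- detect_bursts(sig$signal)
#' @export
detect_bursts <- function(signal, config = detection_config()) {
  stopifnot(inherits(signal, "bb_signal"),
            inherits(config, "bb_detection_config"))
  spec_raw <- morlet_tfr(signal, freqs = config$freqs,
                         n_cycles = config$n_cycles, norm = config$norm)
  spec <- smooth_spectrogram(spec_raw, sd_f = config$sd_f, sd_t = config$sd_t)
  peaks <- find_peaks(spec)
  med_spec <- if (config$median_on == "raw") {
    tmp <- spec
    tmp$power <- spec_raw$power
    tmp
  } else {
    spec
  }
  kept <- threshold_peaks(peaks, med_spec, factor = config$threshold_factor)
  kept <- dplyr::filter(
    kept,
    .data$freq >= config$beta_band[1], .data$freq <= config$beta_band[2]
  )
  if (config$drop_edges && nrow(kept) > 0L) {
    t0 <- min(spec$times)
    t1 <- max(spec$times)
    margin <- spec$edge_margin[kept$freq_bin]
    kept <- kept[kept$time >= t0 + margin & kept$time <= t1 - margin, ]
  }
  if (config$min_separation > 0 && nrow(kept) > 1L) {
    ord <- order(kept$power, decreasing = TRUE)
    keep <- logical(nrow(kept))
    kept_times <- numeric(0)
    for (i in ord) {
      if (!length(kept_times) ||
          min(abs(kept_times - kept$time[i])) >= config$min_separation) {
        keep[i] <- TRUE
        kept_times <- c(kept_times, kept$time[i])
      }
    }
    kept <- kept[keep, ]
  }
  out <- kept |>
    dplyr::transmute(
      time = .data$time, freq = .data$freq,
      peak_power = .data$power, median_ratio = .data$median_ratio
    ) |>
    dplyr::arrange(.data$time)
  class(out) <- c("bb_bursts", class(out))
  out
}

#' Surrogate ("fake") event times
#'
#' Draws `n` event times uniformly over `[0, duration)` subject to a
#' minimum inter-event gap, for use as a null control in place of detected
#' bursts (event-related regressors built from surrogate times should show
#' no effect). Times are generated by uniform placement in the feasible
#' reduced interval plus cumulative gaps, so the marginal rate is
#' `n / duration`.
#'
#' @param n Number of events (>= 0).
#' @param duration Recording duration in seconds.
#' @param min_gap Minimum separation between consecutive events (default 0).
#' @param seed Optional integer seed for reproducibility.
#' @return A sorted numeric vector of `n` event times.
#' @export
surrogate_events <- function(n, duration, min_gap = 0, seed = NULL) {
  if (n < 0) abort("`n` must be >= 0.")
  if (n == 0L) return(numeric(0))
  assert_scalar_num(duration, "duration", positive = TRUE)
  if (min_gap < 0) abort("`min_gap` must be >= 0.")
  slack <- duration - n * min_gap
  if (slack <= 0) {
    abort(sprintf(
      "Cannot place %d events with min_gap %g s in %g s.", n, min_gap, duration
    ), class = "bb_infeasible")
  }
  with_seed(seed, {
    base <- sort(runif(n, 0, slack))
    base + (seq_len(n) - 1) * min_gap
  })
}

#' Score detected events against ground truth
#'
#' Matches detected bursts to ground-truth bursts within a time and
#' frequency tolerance. Recall is the fraction of true bursts with at least
#' one detected event within tolerance; precision is the fraction of
#' detected events within tolerance of at least one true burst.
#'
#' @param detected Tibble with `time` and `freq` columns (e.g. from
#'   [detect_bursts()]).
#' @param truth Tibble with `time` and `freq` columns (e.g. the ground
#'   truth from [synthesize_eeg()]).
#' @param tol_time Time tolerance in seconds (default 0.025).
#' @param tol_freq Frequency tolerance in Hz (default 2).
#' @return A one-row tibble: `recall`, `precision`, `n_true`, `n_detected`.
#' @export
score_detection <- function(detected, truth, tol_time = 0.025, tol_freq = 2) {
  if (nrow(truth) == 0L) {
    return(tibble(recall = NA_real_,
                  precision = if (nrow(detected)) 0 else NA_real_,
                  n_true = 0L, n_detected = nrow(detected)))
  }
  match_any <- function(t1, f1, t2, f2) {
    vapply(seq_along(t1), function(i) {
      any(abs(t2 - t1[i]) <= tol_time & abs(f2 - f1[i]) <= tol_freq)
    }, logical(1))
  }
  hit_true <- match_any(truth$time, truth$freq, detected$time, detected$freq)
  hit_det <- match_any(detected$time, detected$freq, truth$time, truth$freq)
  tibble(
    recall = mean(hit_true),
    precision = if (nrow(detected)) mean(hit_det) else NA_real_,
    n_true = nrow(truth), n_detected = nrow(detected)
  )
}
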