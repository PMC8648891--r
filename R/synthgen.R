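# Synthetic-data generators: n-back task schedules, behavioural responses,
# burst-structured EEG, and BOLD series with known ground truth.

SUBBLOCK_N_STIM <- 15L
SUBBLOCK_N_TARGET <- 4L
STIM_INTERVAL <- 2
INTER_BLOCK_REST <- 30
INTER_SUBBLOCK_REST <- 10
BLOCKS_PER_RUN <- 7L
N_LETTERS <- 10L # letter ids 0-9; id 0 is 'X'

# Letters for one sub-block: choose target positions, then fill letters so
# the n-back match rule holds exactly at the chosen targets and nowhere else.
subblock_letters <- function(condition) {
  n_back <- switch(condition, "0back" = 0L, "1back" = 1L, "2back" = 2L)
  pos <- sort(sample((n_back + 1L):SUBBLOCK_N_STIM, SUBBLOCK_N_TARGET))
  is_target <- seq_len(SUBBLOCK_N_STIM) %in% pos
  letters <- integer(SUBBLOCK_N_STIM)
  for (i in seq_len(SUBBLOCK_N_STIM)) {
    if (n_back == 0L) {
      letters[i] <- if (is_target[i]) 0L else sample(1:9, 1L)
    } else {
      ref <- if (i > n_back) letters[i - n_back] else NA_integer_
      if (is_target[i]) {
        letters[i] <- ref
      } else {
        pool <- setdiff(0:(N_LETTERS - 1L), ref)
        letters[i] <- sample(pool, 1L)
      }
    }
  }
  list(letters = letters, is_target = is_target)
}

#' Generate an n-back task schedule
#'
#' Builds the working-memory task schedule the generators and rate
#' statistics operate on: each run contains seven task blocks interspersed
#' with 30-second rest intervals; each block consists of 0-back, 1-back and
#' 2-back sub-blocks in random order, separated by 10-second rest intervals;
#' each sub-block presents 15 letters at 2-second intervals, exactly 4 of
#' which are targets. Ten letter ids (0-9) are used, with id 0 playing the
#' role of the letter 'X': in the 0-back condition the target is 'X', in the
#' 1-back (2-back) condition the target is any letter matching the one
#' presented one (two) trials earlier. Letter sequences are constructed so
#' the match rule holds at exactly the four designated target positions of
#' every sub-block.
#'
#' @param runs Number of task runs (>= 1).
#' @param seed Optional integer seed; the schedule is deterministic given
#'   the seed.
#' @return An object of class `bb_schedule`: a list with tibbles `stimuli`
#'   (run, block, subblock, trial, onset, letter, condition, is_target),
#'   `subblocks` (onset, duration, condition, run, block) and `rests`
#'   (onset, duration, kind), plus `runs` and total `duration` in seconds.
#' @examples
#' sched <- make_nback_schedule(1, seed = 1)
#' nrow(sched$stimuli) # 315
#' sum(sched$stimuli$is_target) # 84
#' @export
make_nback_schedule <- function(runs = 2, seed = NULL) {
  if (!is.numeric(runs) || runs < 1) {
    abort("`runs` must be >= 1.")
  }
  runs <- as.integer(runs)
  with_seed(seed, {
    stim <- list()
    sub <- list()
    rest <- list()
    t <- 0
    for (run in seq_len(runs)) {
      for (block in seq_len(BLOCKS_PER_RUN)) {
        conds <- sample(c("0back", "1back", "2back"))
        for (sb in 1:3) {
          cond <- conds[sb]
          ls <- subblock_letters(cond)
          onsets <- t + (seq_len(SUBBLOCK_N_STIM) - 1L) * STIM_INTERVAL
          stim[[length(stim) + 1L]] <- tibble(
            run = run, block = block, subblock = sb,
            trial = seq_len(SUBBLOCK_N_STIM), onset = onsets,
            letter = ls$letters, condition = cond, is_target = ls$is_target
          )
          sub[[length(sub) + 1L]] <- tibble(
            onset = t, duration = SUBBLOCK_N_STIM * STIM_INTERVAL,
            condition = cond, run = run, block = block
          )
          t <- t + SUBBLOCK_N_STIM * STIM_INTERVAL
          if (sb < 3L) {
            rest[[length(rest) + 1L]] <- tibble(
              onset = t, duration = INTER_SUBBLOCK_REST,
              kind = "inter_subblock"
            )
            t <- t + INTER_SUBBLOCK_REST
          }
        }
        if (block < BLOCKS_PER_RUN || run < runs) {
          rest[[length(rest) + 1L]] <- tibble(
            onset = t, duration = INTER_BLOCK_REST, kind = "inter_block"
          )
          t <- t + INTER_BLOCK_REST
        }
      }
    }
    structure(
      list(
        stimuli = dplyr::bind_rows(stim),
        subblocks = dplyr::bind_rows(sub),
        rests = dplyr::bind_rows(rest),
        runs = runs, duration = t
      ),
      class = "bb_schedule"
    )
  })
}

#' @export
print.bb_schedule <- function(x, ...) {
  cat(sprintf(
    "<bb_schedule> %d run(s), %.0f s, %d stimuli (%d targets)\n",
    x$runs, x$duration, nrow(x$stimuli), sum(x$stimuli$is_target)
  ))
  invisible(x)
}

#' Rest-only schedule
#'
#' A degenerate schedule consisting of a single rest interval, convenient
#' for simulation studies of the burst point process (e.g. rate calibration
#' or PMBR recovery with an artificial response train).
#'
#' @param duration Rest duration in seconds.
#' @return A `bb_schedule` with one rest interval and no stimuli.
#' @export
rest_schedule <- function(duration) {
  assert_scalar_num(duration, "duration", positive = TRUE)
  structure(
    list(
      stimuli = tibble(
        run = integer(), block = integer(), subblock = integer(),
        trial = integer(), onset = numeric(), letter = integer(),
        condition = character(), is_target = logical()
      ),
      subblocks = tibble(
        onset = numeric(), duration = numeric(), condition = character(),
        run = integer(), block = integer()
      ),
      rests = tibble(onset = 0, duration = duration, kind = "inter_block"),
      runs = 0L, duration = duration
    ),
    class = "bb_schedule"
  )
}

#' Simulate behavioural responses to an n-back schedule
#'
#' Draws one button-press response per detected ("hit") target, with
#' reaction times from a shifted lognormal distribution; non-targets never
#' elicit responses (no errors of commission). Hit rates and RT medians may
#' be given per condition; the defaults emulate near-ceiling accuracy that
#' declines with load and RTs that lengthen with load.
#'
#' @param schedule A `bb_schedule`.
#' @param hit_rate Probability of responding to a target, scalar or named
#'   per condition (`0back`, `1back`, `2back`); each in (0, 1].
#' @param rt_median Median reaction time in seconds, scalar or named per
#'   condition; must exceed `rt_shift`.
#' @param rt_shift Lognormal shift (minimum possible RT) in seconds.
#' @param rt_sdlog Lognormal log-scale SD; 0 gives fixed RTs at the median.
#' @param seed Optional integer seed.
#' @return A tibble of responses: `onset` (s), `stimulus_onset`,
#'   `condition`, `correct` (all TRUE), sorted by onset.
#' @export
simulate_behavior <- function(schedule,
                              hit_rate = c("0back" = 1.0, "1back" = 0.99,
                                           "2back" = 0.96),
                              rt_median = c("0back" = 0.45, "1back" = 0.50,
                                            "2back" = 0.58),
                              rt_shift = 0.2, rt_sdlog = 0.25, seed = NULL) {
  stopifnot(inherits(schedule, "bb_schedule"))
  conds <- c("0back", "1back", "2back")
  expand <- function(x, name) {
    if (length(x) == 1L && is.null(names(x))) x <- stats::setNames(rep(x, 3), conds)
    if (!all(conds %in% names(x))) {
      abort(sprintf("`%s` must be a scalar or named per condition.", name))
    }
    x[conds]
  }
  hit_rate <- expand(hit_rate, "hit_rate")
  rt_median <- expand(rt_median, "rt_median")
  if (any(hit_rate <= 0) || any(hit_rate > 1)) {
    abort("`hit_rate` must be in (0, 1].")
  }
  if (rt_shift < 0 || any(rt_median <= rt_shift)) {
    abort("`rt_median` must exceed `rt_shift` (>= 0).")
  }
  if (rt_sdlog < 0) abort("`rt_sdlog` must be >= 0.")
  targets <- dplyr::filter(schedule$stimuli, .data$is_target)
  if (nrow(targets) == 0L) {
    return(tibble(onset = numeric(), stimulus_onset = numeric(),
                  condition = character(), correct = logical()))
  }
  with_seed(seed, {
    hit <- rbinom(nrow(targets), 1L, hit_rate[targets$condition]) == 1L
    hits <- targets[hit, ]
    rt <- rt_shift +
      unname(rt_median[hits$condition] - rt_shift) *
        exp(rnorm(nrow(hits), 0, rt_sdlog))
    tibble(
      onset = hits$onset + rt,
      stimulus_onset = hits$onset,
      condition = hits$condition,
      correct = TRUE
    ) |>
      dplyr::arrange(.data$onset)
  })
}

#' Beta-burst generative model
#'
#' Parameters of the inhomogeneous point process and waveform used to inject
#' transient beta bursts into synthetic EEG. Bursts are Hann-enveloped
#' sinusoids of duration under 150 ms; their occurrence rate is the tonic
#' condition rate, multiplicatively suppressed in a window after every
#' stimulus, plus an additive post-movement rebound boost in a window after
#' every response, scaled by a group attenuation factor (1 = full rebound,
#' smaller values emulate the attenuated rebound observed in psychosis).
#'
#' @param center_freq_range Burst center-frequency interval in Hz, inside
#'   the beta band (default 15-28 Hz).
#' @param duration_range Burst duration interval in seconds; the upper bound
#'   must stay below 0.150 s (default 0.05-0.145 s).
#' @param amplitude Burst peak amplitude in units of the background-noise SD
#'   (default 6).
#' @param tonic_rate Named bursts/s per condition (`rest`, `0back`, `1back`,
#'   `2back`); defaults decrease monotonically with working-memory load
#'   (0.50, 0.42, 0.34, 0.26), sized so that the load effect is resolvable
#'   from a few hundred seconds of recording per condition (see the methods
#'   vignette for the power analysis behind these values).
#' @param pmbr_boost Additive rate (bursts/s) in the post-response window
#'   (default 0.6).
#' @param pmbr_window Post-response window in seconds (default 0.5-1.0 s
#'   after the button press).
#' @param poststim_suppression Multiplicative rate factor in the
#'   post-stimulus window (default 0.5).
#' @param poststim_window Post-stimulus window (default 0-0.5 s).
#' @param group_attenuation Scalar in \[0, 1\] multiplying `pmbr_boost`
#'   (default 1).
#' @return A list of class `bb_burst_model`.
#' @export
burst_model <- function(center_freq_range = c(15, 28),
                        duration_range = c(0.05, 0.145),
                        amplitude = 6,
                        tonic_rate = c(rest = 0.50, "0back" = 0.42,
                                       "1back" = 0.34, "2back" = 0.26),
                        pmbr_boost = 0.6, pmbr_window = c(0.5, 1.0),
                        poststim_suppression = 0.5,
                        poststim_window = c(0, 0.5),
                        group_attenuation = 1.0) {
  if (any(tonic_rate < 0)) abort("All tonic rates must be >= 0.")
  needed <- c("rest", "0back", "1back", "2back")
  if (!all(needed %in% names(tonic_rate))) {
    abort("`tonic_rate` must be named per condition: rest, 0back, 1back, 2back.")
  }
  if (duration_range[2] >= 0.150) {
    abort("Burst durations must stay below 0.150 s.")
  }
  if (pmbr_boost < 0) abort("`pmbr_boost` must be >= 0.")
  if (group_attenuation < 0 || group_attenuation > 1) {
    abort("`group_attenuation` must be in [0, 1].")
  }
  if (poststim_suppression < 0) {
    abort("`poststim_suppression` must be >= 0.")
  }
  structure(
    list(
      center_freq_range = center_freq_range,
      duration_range = duration_range,
      amplitude = amplitude,
      tonic_rate = tonic_rate[needed],
      pmbr_boost = pmbr_boost, pmbr_window = pmbr_window,
      poststim_suppression = poststim_suppression,
      poststim_window = poststim_window,
      group_attenuation = group_attenuation
    ),
    class = "bb_burst_model"
  )
}

# Condition intervals (rest + sub-blocks) as a sorted tibble(onset, end,
# condition).
schedule_condition_intervals <- function(schedule) {
  dplyr::bind_rows(
    schedule$rests |>
      dplyr::transmute(onset = .data$onset, end = .data$onset + .data$duration,
                       condition = "rest"),
    schedule$subblocks |>
      dplyr::transmute(onset = .data$onset, end = .data$onset + .data$duration,
                       condition = .data$condition)
  ) |>
    dplyr::arrange(.data$onset)
}

#' Instantaneous burst rate of the generative model
#'
#' Evaluates the inhomogeneous Poisson rate
#' `tonic_rate(condition) * poststim_factor + pmbr_boost * group_attenuation`
#' at arbitrary times: the tonic rate of the condition active at each time,
#' halved (by default) within the post-stimulus window of the most recent
#' stimulus, plus the attenuated rebound boost when the time falls in the
#' post-response window of a recent response. Overlapping response windows
#' do not stack.
#'
#' @param times Numeric vector of times in seconds.
#' @param schedule A `bb_schedule`.
#' @param model A [burst_model()].
#' @param responses Optional response tibble (from [simulate_behavior()]) or
#'   numeric vector of response onsets.
#' @return Numeric vector of rates (bursts/s) at `times`.
#' @export
burst_rate_at <- function(times, schedule, model = burst_model(),
                          responses = NULL) {
  stopifnot(inherits(schedule, "bb_schedule"),
            inherits(model, "bb_burst_model"))
  intervals <- schedule_condition_intervals(schedule)
  idx <- findInterval(times, intervals$onset)
  rate <- numeric(length(times))
  inside <- idx > 0L
  inside[inside] <- times[inside] < intervals$end[idx[inside]]
  rate[inside] <- model$tonic_rate[intervals$condition[idx[inside]]]
  stim <- sort(schedule$stimuli$onset)
  if (length(stim)) {
    si <- findInterval(times, stim)
    dt <- times - ifelse(si > 0L, stim[pmax(si, 1L)], -Inf)
    supp <- si > 0L & dt >= model$poststim_window[1] &
      dt < model$poststim_window[2]
    rate[supp] <- rate[supp] * model$poststim_suppression
  }
  resp <- if (is.data.frame(responses)) responses$onset else responses
  resp <- sort(as.numeric(resp))
  if (length(resp)) {
    in_window <- function(k) {
      ok <- k > 0L
      d <- times - ifelse(ok, resp[pmax(k, 1L)], -Inf)
      ok & d >= model$pmbr_window[1] & d < model$pmbr_window[2]
    }
    ri <- findInterval(times, resp)
    boosted <- in_window(ri) | in_window(ri - 1L)
    rate[boosted] <- rate[boosted] + model$pmbr_boost * model$group_attenuation
  }
  rate
}

#' Draw burst event times from the generative point process
#'
#' Samples burst times over the schedule duration from the thinned
#' inhomogeneous Poisson process whose rate is [burst_rate_at()]. This is
#' the point-process core of [synthesize_eeg()], exposed directly so that
#' rate and rebound statistics can be simulated at scale without
#' synthesising and re-detecting full EEG.
#'
#' @inheritParams burst_rate_at
#' @param seed Optional integer seed.
#' @return Sorted numeric vector of burst times in seconds.
#' @export
simulate_burst_times <- function(schedule, model = burst_model(),
                                 responses = NULL, seed = NULL) {
  stopifnot(inherits(schedule, "bb_schedule"))
  rate_max <- max(model$tonic_rate) * max(1, model$poststim_suppression) +
    model$pmbr_boost * model$group_attenuation
  if (rate_max <= 0) return(numeric(0))
  with_seed(seed, {
    n_cand <- rpois(1L, rate_max * schedule$duration)
    if (n_cand == 0L) return(numeric(0))
    cand <- runif(n_cand, 0, schedule$duration)
    keep <- runif(n_cand) * rate_max <
      burst_rate_at(cand, schedule, model, responses)
    sort(cand[keep])
  })
}

# 1/f^alpha Gaussian noise via spectral shaping, rescaled to SD `amp`.
one_over_f_noise <- function(n, fs, alpha = 1, amp = 1) {
  if (alpha == 0) return(rnorm(n, 0, amp))
  white <- rnorm(n)
  xf <- fft(white)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n # two-sided frequency magnitude
  scale <- c(0, f[-1]^(-alpha / 2)) # zero out DC
  x <- Re(fft(xf * scale, inverse = TRUE) / n)
  x / sd(x) * amp
}

#' Synthesize burst-structured EEG with ground truth
#'
#' Generates a continuous single-channel time course consisting of 1/f^alpha
#' Gaussian background noise plus Hann-enveloped sinusoidal beta bursts
#' injected at times drawn from the model's inhomogeneous Poisson process
#' (tonic condition rates, post-stimulus suppression, attenuated
#' post-response rebound). Every injected burst is recorded in the returned
#' ground-truth table, so detector recall and precision can be measured
#' exactly.
#'
#' @inheritParams burst_rate_at
#' @param fs Sampling rate in Hz; must be at least four times the highest
#'   burst center frequency (default 250).
#' @param noise_alpha Spectral exponent of the 1/f^alpha background
#'   (default 1).
#' @param noise_amp Background noise SD in signal units (default 1).
#' @param seed Optional integer seed.
#' @return A list with `signal` (a [continuous_signal()]) and `truth` (a
#'   tibble `time`, `freq`, `amplitude`, `duration`, sorted by time).
#' @export
synthesize_eeg <- function(schedule, model = burst_model(), fs = 250,
                           noise_alpha = 1, noise_amp = 1, responses = NULL,
                           seed = NULL) {
  stopifnot(inherits(schedule, "bb_schedule"),
            inherits(model, "bb_burst_model"))
  f_hi <- max(model$center_freq_range)
  if (fs < 4 * f_hi) {
    abort(sprintf(
      paste0("`fs` = %g Hz is too low: bursts up to %g Hz need fs >= %g Hz ",
             "(4x the highest burst frequency; Nyquist is fs/2)."),
      fs, f_hi, 4 * f_hi
    ))
  }
  n <- round(schedule$duration * fs)
  with_seed(seed, {
    times <- simulate_burst_times(schedule, model, responses, seed = NULL)
    max_half <- model$duration_range[2] / 2
    times <- times[times >= max_half & times <= schedule$duration - max_half]
    k <- length(times)
    truth <- tibble(
      time = times,
      freq = runif(k, model$center_freq_range[1], model$center_freq_range[2]),
      amplitude = rep(model$amplitude, k),
      duration = runif(k, model$duration_range[1], model$duration_range[2])
    )
    x <- one_over_f_noise(n, fs, noise_alpha, noise_amp)
    if (k > 0L) {
      phase <- runif(k, 0, 2 * pi)
      for (i in seq_len(k)) {
        len <- max(3L, round(truth$duration[i] * fs))
        center <- round(truth$time[i] * fs) + 1L
        idx <- (center - (len %/% 2L)) + 0:(len - 1L)
        ok <- idx >= 1L & idx <= n
        u <- (0:(len - 1L)) / (len - 1L)
        env <- 0.5 * (1 - cos(2 * pi * u))
        tt <- (idx - 1L) / fs
        wave <- truth$amplitude[i] * env *
          cos(2 * pi * truth$freq[i] * (tt - truth$time[i]) + phase[i])
        x[idx[ok]] <- x[idx[ok]] + wave[ok]
      }
    }
    list(signal = continuous_signal(x, fs), truth = truth)
  })
}

#' Synthesize a BOLD series from burst and task events
#'
#' Forward model mirroring the analysis model: the design matrix is built by
#' [build_design_matrix()] (task boxcars, response and burst impulses, all
#' convolved with the canonical HRF), each voxel's series is design x its
#' true coefficients plus Gaussian noise, and the truth is returned for
#' recovery tests.
#'
#' @param burst_times Numeric vector of burst event times in seconds.
#' @param events BIDS-style event tibble (e.g. from [schedule_events()]).
#' @param tr Repetition time in seconds.
#' @param n_scans Number of scans; defaults to covering the last event.
#' @param n_voxels Number of voxels to simulate (default 1).
#' @param true_betas Coefficient vector (length = number of design columns,
#'   shared by all voxels) or matrix (columns x voxels).
#' @param noise_sd Gaussian noise SD (default 1).
#' @param seed Optional integer seed.
#' @param ... Passed to [build_design_matrix()].
#' @return A list with `bold` (scans x voxels matrix), `design` (the
#'   `bb_design` used) and `true_betas` (columns x voxels matrix).
#' @export
synthesize_bold <- function(burst_times, events, tr, n_scans = NULL,
                            n_voxels = 1, true_betas, noise_sd = 1,
                            seed = NULL, ...) {
  assert_scalar_num(tr, "tr", positive = TRUE)
  if (n_voxels < 1) abort("`n_voxels` must be >= 1.")
  if (is.null(n_scans)) {
    t_end <- max(c(events$onset + events$duration, burst_times, 0))
    n_scans <- ceiling(t_end / tr) + 1L
  }
  design <- build_design_matrix(events, burst_times, n_scans = n_scans,
                                tr = tr, ...)
  X <- design$matrix
  p <- ncol(X)
  B <- if (is.matrix(true_betas)) true_betas else
    matrix(rep(as.numeric(true_betas), n_voxels), ncol = n_voxels)
  if (nrow(B) != p || ncol(B) != n_voxels) {
    abort(sprintf(
      "`true_betas` must have %d rows (design columns: %s) and %d voxel column(s).",
      p, paste(colnames(X), collapse = ", "), n_voxels
    ))
  }
  with_seed(seed, {
    Y <- X %*% B
    if (noise_sd > 0) {
      Y <- Y + matrix(rnorm(length(Y), 0, noise_sd), nrow(Y), ncol(Y))
    }
    list(bold = Y, design = design, true_betas = B)
  })
}
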