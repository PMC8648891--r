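# Burst-rate statistics: condition rates, event-locked rate curves, the
# post-movement beta rebound (PMBR) statistic, and group/association tests.

burst_times_of <- function(bursts) {
  t <- if (is.data.frame(bursts)) bursts$time else as.numeric(bursts)
  sort(t)
}

#' Condition-wise burst rates
#'
#' Mean beta burst rate per experimental condition: the number of bursts
#' falling inside the union of a condition's intervals divided by the total
#' duration of those intervals. Bursts outside all condition intervals are
#' ignored. Intervals are half-open `[onset, onset + duration)`.
#'
#' @param bursts Burst times: a numeric vector or a tibble with a `time`
#'   column (e.g. from [detect_bursts()]).
#' @param events BIDS-style event tibble with `onset`, `duration`,
#'   `trial_type`; rows with `trial_type` in `conditions` define the
#'   condition intervals (e.g. from [schedule_events()]).
#' @param conditions Conditions to report (default rest and the three task
#'   loads). A requested condition with zero total duration is an error.
#' @return A tibble: `condition`, `n_bursts`, `duration` (s), `rate`
#'   (bursts/s).
#' @examples
#' ev <- tibble::tibble(onset = c(0, 20), duration = c(20, 20),
#'                      trial_type = c("rest", "0back"))
#' condition_rates(seq(0.5, 19.5, by = 2), ev, conditions = c("rest", "0back"))
#' @export
condition_rates <- function(bursts, events,
                            conditions = c("rest", "0back", "1back", "2back")) {
  t <- burst_times_of(bursts)
  rows <- events[events$trial_type %in% conditions, , drop = FALSE]
  purrr::map_dfr(conditions, function(cond) {
    iv <- rows[rows$trial_type == cond, , drop = FALSE]
    total <- sum(iv$duration)
    if (total <= 0) {
      abort(sprintf("Condition '%s' has zero total duration.", cond),
            class = "bb_undefined_rate")
    }
    n <- sum(count_in_windows(t, iv$onset, iv$onset + iv$duration))
    tibble(condition = cond, n_bursts = n, duration = total, rate = n / total)
  })
}

#' Event-locked burst rate curve
#'
#' Mean bursts per second in sliding windows time-locked to a set of events
#' (motor responses, target stimuli, ...). At lag `l`, the rate is the count
#' of bursts in the half-open window `[t + l - w/2, t + l + w/2)`, averaged
#' over lock times `t`, divided by the window length `w`.
#'
#' @param bursts Burst times (vector or tibble with `time`).
#' @param lock_times Numeric vector of locking event times (>= 1).
#' @param window Window length in seconds (default 0.5).
#' @param lag_range Two-element lag range in seconds (default -3 to 3).
#' @param step Lag step in seconds (default 0.05).
#' @return A tibble of class `bb_rate_curve` with columns `lag` (s, window
#'   centers) and `rate` (bursts/s); attributes `window` and `n_events`.
#' @export
event_locked_rate <- function(bursts, lock_times, window = 0.5,
                              lag_range = c(-3, 3), step = 0.05) {
  if (length(lock_times) < 1L) {
    abort("`lock_times` must contain at least one event.")
  }
  assert_scalar_num(window, "window", positive = TRUE)
  assert_scalar_num(step, "step", positive = TRUE)
  t <- burst_times_of(bursts)
  lags <- seq(lag_range[1], lag_range[2], by = step)
  n_lock <- length(lock_times)
  rate <- vapply(lags, function(l) {
    lo <- lock_times + l - window / 2
    sum(count_in_windows(t, lo, lo + window)) / (n_lock * window)
  }, numeric(1))
  out <- tibble(lag = lags, rate = rate)
  attr(out, "window") <- window
  attr(out, "n_events") <- n_lock
  class(out) <- c("bb_rate_curve", class(out))
  out
}

#' Post-movement beta rebound (PMBR)
#'
#' Quantifies the rebound in burst probability after a motor response: the
#' mean beta burst rate in windows extending from 0.5 to 1 second after
#' button presses minus the rate in baseline windows extending from 3 to 1.5
#' seconds before button presses. Rates are pooled across responses by
#' default (total burst count divided by total window time); set
#' `per_response = TRUE` to average per-response rates instead (equivalent
#' when no windows are dropped). Windows are half-open `[lo, hi)`. Windows
#' extending past the recording edges (when `t_range` is given) are dropped
#' from both numerator and denominator for that response.
#'
#' @param bursts Burst times (vector or tibble with `time`).
#' @param response_times Numeric vector of response onsets (>= 1).
#' @param post Post-response window relative to the response, seconds
#'   (default `c(0.5, 1.0)`).
#' @param baseline Baseline window relative to the response (default
#'   `c(-3.0, -1.5)`).
#' @param t_range Optional recording extent `c(start, end)`; windows not
#'   fully inside it are dropped.
#' @param per_response Average per-response rates instead of pooling.
#' @return A one-row tibble: `pmbr` (bursts/s, post minus baseline),
#'   `post_rate`, `baseline_rate`, `n_responses`, `n_post`, `n_baseline`
#'   (windows actually used).
#' @export
pmbr <- function(bursts, response_times, post = c(0.5, 1.0),
                 baseline = c(-3.0, -1.5), t_range = NULL,
                 per_response = FALSE) {
  if (length(response_times) < 1L) {
    abort("`response_times` must contain at least one response.")
  }
  if (diff(post) <= 0 || diff(baseline) <= 0) {
    abort("PMBR windows must be non-degenerate increasing intervals.")
  }
  t <- burst_times_of(bursts)
  window_rate <- function(rel) {
    lo <- response_times + rel[1]
    hi <- response_times + rel[2]
    if (!is.null(t_range)) {
      ok <- lo >= t_range[1] & hi <= t_range[2]
      lo <- lo[ok]
      hi <- hi[ok]
    }
    if (!length(lo)) {
      abort("No usable PMBR windows inside the recording extent.",
            class = "bb_undefined_rate")
    }
    counts <- count_in_windows(t, lo, hi)
    len <- rel[2] - rel[1]
    rate <- if (per_response) mean(counts / len) else
      sum(counts) / (length(lo) * len)
    list(rate = rate, n = length(lo))
  }
  p <- window_rate(post)
  b <- window_rate(baseline)
  tibble(
    pmbr = p$rate - b$rate, post_rate = p$rate, baseline_rate = b$rate,
    n_responses = length(response_times), n_post = p$n, n_baseline = b$n
  )
}

#' Two-group comparison with effect size
#'
#' Compares two independent groups with either the Mann-Whitney U test
#' (exact p when the pooled sample is at most 20 and untied, otherwise the
#' tie-corrected normal approximation) with effect size `r = |Z| / sqrt(N)`
#' (Z from the tie-corrected normal approximation, no continuity
#' correction), or Welch's t test with Cohen's d using the pooled-SD
#' convention.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param method `"mann_whitney"` (default) or `"t_test"`.
#' @return A one-row tibble: `method`, `statistic` (U or t), `p.value`,
#'   `effect_size`, `effect_type` (`"rank_r"` or `"cohen_d"`), `n_a`, `n_b`
#'   and `df` (Welch df; NA for Mann-Whitney).
#' @examples
#' group_compare(c(1, 2, 3), c(4, 5, 6))
#' @export
group_compare <- function(values_a, values_b,
                          method = c("mann_whitney", "t_test")) {
  method <- match.arg(method)
  a <- as.numeric(values_a)
  b <- as.numeric(values_b)
  if (length(a) < 2L || length(b) < 2L) {
    abort("Each group needs at least 2 values.")
  }
  n1 <- length(a)
  n2 <- length(b)
  if (method == "mann_whitney") {
    pooled <- c(a, b)
    has_ties <- anyDuplicated(pooled) > 0L
    exact <- (n1 + n2) <= 20L && !has_ties
    wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = FALSE))
    U <- unname(wt$statistic)
    # tie-corrected normal approximation for the effect-size Z
    N <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- if (sigma2 > 0) (U - n1 * n2 / 2) / sqrt(sigma2) else 0
    tibble(
      method = "mann_whitney", statistic = U, p.value = wt$p.value,
      effect_size = abs(z) / sqrt(N), effect_type = "rank_r",
      n_a = n1, n_b = n2, df = NA_real_
    )
  } else {
    if (sd(c(a, b)) == 0) {
      abort("All pooled values are identical: t test is degenerate.",
            class = "bb_degenerate_variance")
    }
    tt <- t.test(a, b)
    sp <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2))
    d <- if (sp > 0) (mean(a) - mean(b)) / sp else 0
    tibble(
      method = "t_test", statistic = unname(tt$statistic),
      p.value = tt$p.value, effect_size = d, effect_type = "cohen_d",
      n_a = n1, n_b = n2, df = unname(tt$parameter)
    )
  }
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser adjustment
#'
#' Fits the one-way repeated-measures F test to a complete participants x
#' conditions matrix, computes the Greenhouse-Geisser epsilon from the
#' sample covariance of the conditions, and reports the
#' sphericity-adjusted p value (adjusted dfs `eps * (k - 1)` and
#' `eps * (k - 1) * (n - 1)`) together with partial eta squared
#' `SS_effect / (SS_effect + SS_error)`. The adjustment is applied
#' unconditionally; set `gg = FALSE` for the unadjusted p.
#'
#' @param mat Numeric matrix, participants in rows (>= 3), conditions in
#'   columns (>= 2), no missing cells.
#' @param gg Apply the Greenhouse-Geisser adjustment (default TRUE).
#' @return An object of class `bb_rm_anova`; see [tidy()] and [glance()]
#'   methods. Fields include `F`, `df1`, `df2`, `epsilon`, `p.value`
#'   (adjusted when `gg`), `p.unadjusted` and `partial_eta_sq`.
#' @export
rm_anova_gg <- function(mat, gg = TRUE) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) abort("`mat` must have no missing cells.")
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 3L || k < 2L) {
    abort("Need >= 3 participants and >= 2 conditions.")
  }
  gm <- mean(mat)
  col_m <- colMeans(mat)
  row_m <- rowMeans(mat)
  ss_cond <- n * sum((col_m - gm)^2)
  ss_subj <- k * sum((row_m - gm)^2)
  ss_tot <- sum((mat - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  f_stat <- (ss_cond / df1) / (ss_err / df2)
  # Greenhouse-Geisser epsilon from the double-centered covariance matrix
  S <- cov(mat)
  Sdc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  eps <- sum(diag(Sdc))^2 / ((k - 1) * sum(Sdc^2))
  p_unadj <- pf(f_stat, df1, df2, lower.tail = FALSE)
  p_adj <- pf(f_stat, eps * df1, eps * df2, lower.tail = FALSE)
  structure(
    list(
      F = f_stat, df1 = df1, df2 = df2, epsilon = eps,
      p.value = if (gg) p_adj else p_unadj, p.unadjusted = p_unadj,
      gg = isTRUE(gg),
      partial_eta_sq = ss_cond / (ss_cond + ss_err),
      ss = c(condition = ss_cond, subject = ss_subj, error = ss_err),
      n = n, k = k
    ),
    class = "bb_rm_anova"
  )
}

#' @export
print.bb_rm_anova <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures ANOVA: F(%.3g, %.3g) = %.3f, p = %.4g%s\n",
    if (x$gg) x$epsilon * x$df1 else x$df1,
    if (x$gg) x$epsilon * x$df2 else x$df2,
    x$F, x$p.value,
    if (x$gg) sprintf(" (Greenhouse-Geisser, epsilon = %.3f)", x$epsilon) else ""
  ))
  cat(sprintf("partial eta^2 = %.3f, n = %d, k = %d\n",
              x$partial_eta_sq, x$n, x$k))
  invisible(x)
}

#' @export
tidy.bb_rm_anova <- function(x, ...) {
  tibble(
    term = "condition", statistic = x$F,
    df1 = if (x$gg) x$epsilon * x$df1 else x$df1,
    df2 = if (x$gg) x$epsilon * x$df2 else x$df2,
    p.value = x$p.value, partial_eta_sq = x$partial_eta_sq
  )
}

#' @export
glance.bb_rm_anova <- function(x, ...) {
  tibble(
    n = x$n, k = x$k, epsilon = x$epsilon,
    p.unadjusted = x$p.unadjusted, gg = x$gg
  )
}

#' Spearman association, optionally covariate-adjusted
#'
#' Spearman rank correlation between two variables, with ties handled by
#' midranks. When covariates are supplied, both variables are residualised
#' on the covariates by linear regression and the residuals are
#' rank-correlated (a rank partial-correlation convention).
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param covariates Optional data frame / matrix of covariates.
#' @return A one-row tibble: `rho`, `p.value`, `n`, `adjusted` (logical).
#' @export
associate <- function(x, y, covariates = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 4L) {
    abort("`x` and `y` must have equal length >= 4.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined for constant input.",
          class = "bb_undefined_correlation")
  }
  adjusted <- !is.null(covariates)
  if (adjusted) {
    Z <- as.data.frame(covariates)
    if (nrow(Z) != length(x)) abort("Covariates must match `x` in length.")
    x <- resid(lm(x ~ ., data = Z))
    y <- resid(lm(y ~ ., data = Z))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble(rho = unname(ct$estimate), p.value = ct$p.value,
         n = length(x), adjusted = adjusted)
}

#' Plot an event-locked rate curve
#'
#' @param object A `bb_rate_curve` from [event_locked_rate()].
#' @param pmbr_windows Shade the PMBR post and baseline windows
#'   (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bb_rate_curve <- function(object, pmbr_windows = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$lag, .data$rate))
  if (pmbr_windows) {
    shade <- tibble(lo = c(-3, 0.5), hi = c(-1.5, 1.0),
                    window = c("baseline", "post"))
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                   ymin = -Inf, ymax = Inf, fill = .data$window),
      alpha = 0.15, inherit.aes = FALSE
    )
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(
      x = "Lag from locking event (s)", y = "Burst rate (bursts/s)",
      title = sprintf("Event-locked burst rate (%d events, %.0f-ms windows)",
                      attr(object, "n_events"), 1000 * attr(object, "window"))
    )
}
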