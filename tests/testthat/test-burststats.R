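test_that("condition rates are counts over interval unions", {
  ev <- tibble::tibble(
    onset = c(0, 20, 50, 80, 120),
    duration = c(20, 20, 20, 20, 20),
    trial_type = c("rest", "0back", "1back", "2back", "rest")
  )
  bursts <- seq(0.5, 19.5, by = 2) # 10 bursts inside the first rest block
  r <- condition_rates(bursts, ev)
  expect_equal(r$rate[r$condition == "rest"], 10 / 40)
  expect_equal(r$rate[r$condition == "0back"], 0)
  # bursts outside all intervals are ignored
  r2 <- condition_rates(c(bursts, 45, 110, 200), ev)
  expect_equal(r2$n_bursts[r2$condition == "rest"], 10)
  # no bursts -> all rates zero
  r0 <- condition_rates(numeric(0), ev)
  expect_true(all(r0$rate == 0))
  expect_error(condition_rates(bursts, ev[1:2, ]), class = "bb_undefined_rate")
  # order and time-translation invariance
  shift <- 13.7
  ev_s <- dplyr::mutate(ev, onset = onset + shift)
  r3 <- condition_rates(sample(bursts) + shift, ev_s)
  expect_equal(r3$rate, r$rate)
})

test_that("Poisson bursts recover the condition rate within its 99% band", {
  sched <- make_nback_schedule(3, seed = 30)
  m <- burst_model(poststim_suppression = 1, pmbr_boost = 0)
  t <- simulate_burst_times(sched, m, seed = 31)
  r <- condition_rates(t, schedule_events(sched))
  for (i in seq_len(nrow(r))) {
    lambda <- unname(burst_model()$tonic_rate[r$condition[i]]) * r$duration[i]
    expect_gt(r$n_bursts[i], qpois(0.005, lambda))
    expect_lt(r$n_bursts[i], qpois(0.995, lambda))
  }
})

test_that("event-locked rate curves behave at the extremes", {
  locks <- seq(10, 500, by = 5)
  # one burst exactly at each lock -> rate 1/w at lag 0
  cv <- event_locked_rate(locks, locks, window = 0.5)
  expect_equal(cv$rate[cv$lag == 0], 2.0)
  expect_equal(max(cv$rate), 2.0)
  # no bursts -> zero curve
  cv0 <- event_locked_rate(numeric(0), locks)
  expect_true(all(cv0$rate == 0))
  expect_error(event_locked_rate(locks, numeric(0)), "lock_times")
  # bursts independent of locks -> flat curve near the true rate
  set.seed(32)
  T <- 2000
  bursts <- sort(runif(round(0.8 * T), 0, T))
  locks2 <- sort(runif(1000, 10, T - 10))
  cv2 <- event_locked_rate(bursts, locks2, lag_range = c(-2, 2))
  expect_equal(mean(cv2$rate), 0.8, tolerance = 0.1)
  expect_lt(diff(range(cv2$rate)), 0.8) # no systematic structure
})

test_that("pmbr equals the post-minus-baseline pooled rate", {
  resp <- seq(20, by = 10, length.out = 50)
  # one burst centered in each post window, none in the baselines
  bursts <- resp + 0.75
  p <- pmbr(bursts, resp)
  expect_equal(p$pmbr, 2.0)
  expect_equal(p$post_rate, 2.0)
  expect_equal(p$baseline_rate, 0)
  expect_equal(p$n_responses, 50)
  # windows are half-open: a burst exactly at response+1.0 is excluded
  expect_equal(pmbr(resp + 1.0, resp)$post_rate, 0)
  expect_equal(pmbr(resp + 0.5, resp)$post_rate, 2.0)
  expect_error(pmbr(bursts, numeric(0)), "response")
  # per-response averaging agrees when no windows are dropped
  set.seed(33)
  b2 <- sort(runif(300, 0, 520))
  expect_equal(pmbr(b2, resp)$pmbr,
               pmbr(b2, resp, per_response = TRUE)$pmbr)
})

test_that("pmbr is null-centered for homogeneous bursts", {
  set.seed(34)
  vals <- replicate(300, {
    bursts <- sort(runif(400, 0, 1000))
    resp <- seq(10, 990, by = 10)
    pmbr(bursts, resp)$pmbr
  })
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3.5 * se + 1e-12)
})

test_that("pmbr windows outside the recording are dropped symmetrically", {
  resp <- c(1.0, 50, 99.8) # first baseline and last post window out of range
  bursts <- c(as.numeric(outer(resp, c(0.6, 0.8), "+")), 48, 49)
  p <- pmbr(bursts, resp, t_range = c(0, 100))
  expect_equal(p$n_post, 2)
  expect_equal(p$n_baseline, 2)
  expect_equal(p$post_rate, 4 / (2 * 0.5))
})

test_that("pmbr is consistent with the event-locked rate curve", {
  set.seed(35)
  bursts <- sort(runif(600, 0, 1500))
  resp <- seq(20, 1480, by = 15)
  p <- pmbr(bursts, resp)
  # post window [0.5, 1.0) = one 0.5-s window centered at 0.75
  cv_post <- event_locked_rate(bursts, resp, window = 0.5,
                               lag_range = c(0.75, 0.75), step = 1)
  # baseline [-3, -1.5) tiled by three 0.5-s windows
  cv_base <- event_locked_rate(bursts, resp, window = 0.5,
                               lag_range = c(-2.75, -1.75), step = 0.5)
  expect_equal(p$pmbr, cv_post$rate - mean(cv_base$rate), tolerance = 1e-12)
})

test_that("group comparison matches its references", {
  # identical groups: U = n^2 / 2, d = 0
  g <- as.numeric(1:10)
  mw <- group_compare(g, g)
  expect_equal(mw$statistic, 50)
  expect_equal(mw$effect_size, 0)
  tt <- group_compare(g, g, method = "t_test")
  expect_equal(tt$effect_size, 0)
  expect_equal(tt$p.value, 1)
  # complete separation
  expect_equal(group_compare(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  expect_error(group_compare(rep(1, 5), rep(1, 5), method = "t_test"),
               class = "bb_degenerate_variance")
})

test_that("Mann-Whitney agrees with an exhaustive enumeration oracle", {
  set.seed(36)
  for (rep in 1:20) {
    n1 <- sample(3:5, 1)
    n2 <- sample(3:5, 1)
    a <- round(rnorm(n1), 3)
    b <- round(rnorm(n2, 0.5), 3)
    if (anyDuplicated(c(a, b))) next
    got <- group_compare(a, b)
    ora <- oracle_mann_whitney(a, b)
    expect_equal(got$statistic, ora$U)
    expect_equal(got$p.value, ora$p, tolerance = 1e-12)
  }
})

test_that("repeated-measures ANOVA matches aov and the epsilon formula", {
  set.seed(37)
  mat <- matrix(rnorm(80), 20, 4) +
    outer(rnorm(20), rep(1, 4)) + # subject effects
    outer(rep(1, 20), c(0, 0.2, 0.1, 0.4))
  fit <- rm_anova_gg(mat)
  ora <- oracle_rm_anova(mat)
  expect_equal(fit$F, ora$F, tolerance = 1e-9)
  expect_equal(fit$p.unadjusted, ora$p, tolerance = 1e-9)
  expect_equal(fit$epsilon, ora$epsilon, tolerance = 1e-9)
  expect_equal(fit$partial_eta_sq,
               ora$ss_cond / (ora$ss_cond + ora$ss_err), tolerance = 1e-9)
  # with two conditions sphericity is trivial: epsilon exactly 1
  expect_equal(rm_anova_gg(mat[, 1:2])$epsilon, 1, tolerance = 1e-12)
  # epsilon is bounded by 1 (Cauchy-Schwarz on the eigenvalues)
  expect_lte(fit$epsilon, 1 + 1e-12)
  expect_error(rm_anova_gg(mat[1:2, ]), "participants")
  m2 <- mat
  m2[1, 1] <- NA
  expect_error(rm_anova_gg(m2), "missing")
  expect_s3_class(tidy(fit), "tbl_df")
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("null repeated-measures F averages to about 1", {
  set.seed(38)
  fs <- replicate(200, rm_anova_gg(matrix(rnorm(24), 8, 3))$F)
  # E[F] = df2 / (df2 - 2) for a central F with df2 = 14
  expect_equal(mean(fs), 14 / 12, tolerance = 0.15)
})

test_that("Spearman association matches the direct formula", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5)
  y <- c(2, 0.5, 5, 1, 7, 3, 4.5)
  got <- associate(x, y)
  expect_equal(got$rho, oracle_spearman(x, y), tolerance = 1e-12)
  expect_equal(associate(1:10, (1:10)^3)$rho, 1) # any monotone map
  set.seed(39)
  xn <- rnorm(1000)
  expect_lt(abs(associate(xn, rnorm(1000))$rho), 3 / sqrt(1000))
  expect_error(associate(rep(1, 5), 1:5), class = "bb_undefined_correlation")
})

test_that("covariate adjustment residualises both variables", {
  set.seed(40)
  z <- rnorm(200)
  x <- 2 * z + rnorm(200, sd = 0.1)
  y <- -3 * z + rnorm(200, sd = 0.1)
  raw <- associate(x, y)
  adj <- associate(x, y, covariates = data.frame(z = z))
  expect_lt(raw$rho, -0.9) # spuriously correlated through z
  expect_lt(abs(adj$rho), 0.25) # association vanishes after adjustment
  expect_true(adj$adjusted)
})
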