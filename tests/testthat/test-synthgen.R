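test_that("schedule arithmetic and structure match the task design", {
  s <- make_nback_schedule(1, seed = 42)
  expect_equal(nrow(s$stimuli), 315)
  expect_equal(sum(s$stimuli$is_target), 84)
  # per sub-block: 15 stimuli, 4 targets, 2-s spacing
  by_sb <- split(s$stimuli, interaction(s$stimuli$block, s$stimuli$subblock))
  for (sb in by_sb) {
    expect_equal(nrow(sb), 15)
    expect_equal(sum(sb$is_target), 4)
    expect_equal(diff(sb$onset), rep(2, 14))
  }
  # conditions within each block are a permutation of the three loads
  conds <- tapply(s$subblocks$condition, s$subblocks$block,
                  function(x) sort(x))
  for (cc in conds) expect_equal(cc, c("0back", "1back", "2back"))
  # rest structure: 30-s inter-block, 10-s inter-sub-block
  expect_equal(s$rests$duration[s$rests$kind == "inter_block"],
               rep(30, 6))
  expect_equal(s$rests$duration[s$rests$kind == "inter_subblock"],
               rep(10, 14))
  s2 <- make_nback_schedule(2, seed = 7)
  expect_equal(nrow(s2$stimuli), 630)
  expect_equal(sum(s2$stimuli$is_target), 168)
  expect_error(make_nback_schedule(0), "runs")
})

test_that("target flags agree with an exhaustive re-scan of the match rules", {
  for (seed in c(1, 2, 3)) {
    s <- make_nback_schedule(1, seed = seed)
    expect_equal(s$stimuli$is_target, oracle_targets(s$stimuli))
    zero <- s$stimuli[s$stimuli$condition == "0back", ]
    expect_true(all(zero$letter[zero$is_target] == 0L))
    expect_true(all(zero$letter[!zero$is_target] != 0L))
  }
})

test_that("schedules are deterministic given the seed", {
  expect_identical(make_nback_schedule(2, seed = 11),
                   make_nback_schedule(2, seed = 11))
  s1 <- make_nback_schedule(1, seed = 11)
  s2 <- make_nback_schedule(1, seed = 12)
  expect_false(identical(s1$stimuli$letter, s2$stimuli$letter))
})

test_that("simulated responses follow the hit-rate and RT model", {
  s <- make_nback_schedule(1, seed = 5)
  # certain hits with fixed RT: one response per target, exactly 0.5 s later
  r <- simulate_behavior(s, hit_rate = 1.0, rt_median = 0.5, rt_sdlog = 0,
                         seed = 1)
  expect_equal(nrow(r), 84)
  expect_equal(r$onset - r$stimulus_onset, rep(0.5, 84))
  # hit_rate ~ 0 -> (almost surely) empty; use exact zero via tiny p bound
  r0 <- simulate_behavior(s, hit_rate = 1e-12, seed = 1)
  expect_equal(nrow(r0), 0)
  expect_error(simulate_behavior(s, hit_rate = 0), "hit_rate")
  expect_error(simulate_behavior(s, rt_median = 0.1, rt_shift = 0.2),
               "rt_median")
  # binomial expectation of the response count across seeds
  counts <- vapply(1:200, function(sd) {
    nrow(simulate_behavior(s, hit_rate = 0.9, rt_sdlog = 0, seed = sd))
  }, numeric(1))
  expect_equal(mean(counts), 84 * 0.9,
               tolerance = 3 * sqrt(84 * 0.9 * 0.1 / 200) / (84 * 0.9))
})

test_that("burst point process matches its rate model", {
  # zero-rate model -> no bursts, pure noise
  m0 <- burst_model(tonic_rate = c(rest = 0, "0back" = 0, "1back" = 0,
                                   "2back" = 0), pmbr_boost = 0)
  syn <- synthesize_eeg(rest_schedule(30), m0, seed = 1)
  expect_equal(nrow(syn$truth), 0)
  expect_equal(length(syn$signal$samples), 30 * 250)
  # Poisson expectation: tonic 0.4/s over 1000 s rest
  m <- burst_model(tonic_rate = c(rest = 0.4, "0back" = 0.4, "1back" = 0.4,
                                  "2back" = 0.4), pmbr_boost = 0)
  n <- length(simulate_burst_times(rest_schedule(1000), m, seed = 2))
  expect_gt(n, qpois(0.005, 400))
  expect_lt(n, qpois(0.995, 400))
  # empirical per-condition rate converges to the model rate
  sched <- make_nback_schedule(3, seed = 3)
  t <- simulate_burst_times(sched, burst_model(poststim_suppression = 1,
                                               pmbr_boost = 0), seed = 4)
  r <- condition_rates(t, schedule_events(sched))
  expect_equal(r$rate, unname(burst_model()$tonic_rate[r$condition]),
               tolerance = 0.12)
})

test_that("group attenuation scales the post-response burst-rate excess", {
  resp <- seq(10, by = 4, length.out = 2500)
  sched <- rest_schedule(max(resp) + 10)
  excess <- function(att, seed) {
    m <- burst_model(tonic_rate = c(rest = 0.4, "0back" = 0.4,
                                    "1back" = 0.4, "2back" = 0.4),
                     pmbr_boost = 0.8, group_attenuation = att)
    t <- simulate_burst_times(sched, m, responses = resp, seed = seed)
    p <- pmbr(t, resp)
    p$pmbr
  }
  e1 <- excess(1.0, 11)
  e05 <- excess(0.5, 12)
  se <- sqrt(1.2 / (2500 * 0.5) + 0.4 / (2500 * 1.5)) # Poisson SEs
  expect_equal(e1, 0.8, tolerance = 3 * se / 0.8)
  expect_equal(e05, 0.4, tolerance = 3 * sqrt(2) * se / 0.4)
})

test_that("injected bursts respect the waveform constraints", {
  syn <- synthesize_eeg(rest_schedule(120), burst_model(), seed = 6)
  expect_true(all(diff(syn$truth$time) >= 0))
  expect_true(all(syn$truth$duration < 0.150))
  expect_true(all(syn$truth$freq >= 15 & syn$truth$freq <= 28))
  expect_true(all(syn$truth$time >= 0 & syn$truth$time <= 120))
  expect_identical(syn,
                   synthesize_eeg(rest_schedule(120), burst_model(), seed = 6))
  expect_error(synthesize_eeg(rest_schedule(10), burst_model(), fs = 50),
               "Nyquist")
  expect_error(burst_model(duration_range = c(0.05, 0.2)), "0.150")
  expect_error(burst_model(group_attenuation = 1.5), "attenuation")
})

test_that("synthetic BOLD is the design times the true coefficients", {
  sched <- make_nback_schedule(1, seed = 9)
  resp <- simulate_behavior(sched, seed = 9)
  ev <- schedule_events(sched, resp)
  bursts <- simulate_burst_times(sched, burst_model(), responses = resp,
                                 seed = 10)
  betas <- c(0.3, 0.2, 0.1, 0.5, 0.4, 100)
  sim <- synthesize_bold(bursts, ev, tr = 2, true_betas = betas,
                         noise_sd = 0, seed = 1)
  fit <- fit_glm(sim$bold, sim$design)
  expect_equal(unname(fit$betas[, 1]), betas, tolerance = 1e-8)
  expect_error(
    synthesize_bold(bursts, ev, tr = 2, true_betas = c(1, 2), noise_sd = 0),
    "true_betas"
  )
})
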