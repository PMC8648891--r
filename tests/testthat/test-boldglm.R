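test_that("the canonical HRF has the expected shape", {
  h <- canonical_hrf(0.1)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  # exactly one sign change: positive lobe then undershoot
  signs <- sign(h[h != 0])
  expect_equal(sum(diff(signs) != 0), 1)
  # argmax agrees with a fine-grid maximisation of the closed form
  t_fine <- seq(0, 32, by = 0.001)
  h_fine <- dgamma(t_fine, 6, 1) - dgamma(t_fine, 16, 1) / 6
  t_peak_fine <- t_fine[which.max(h_fine)]
  expect_lte(abs(seq(0, 32, by = 0.1)[which.max(h)] - t_peak_fine), 0.1)
})

simple_events <- function() {
  tibble::tibble(
    onset = c(0, 10, 40, 70, 12, 45, 72),
    duration = c(10, 30, 30, 30, 0, 0, 0),
    trial_type = c("rest", "0back", "1back", "2back",
                   "response", "response", "response")
  )
}

test_that("design matrix columns are HRF convolutions of their events", {
  ev <- simple_events()
  d <- build_design_matrix(ev, burst_times = numeric(0), n_scans = 60, tr = 2)
  expect_named(as.data.frame(d$matrix),
               c("0back", "1back", "2back", "response", "burst", "intercept"))
  expect_true(all(d$matrix[, "burst"] == 0))
  expect_true(all(d$matrix[, "intercept"] == 1))
  # one impulse: the burst column is the HRF sampled at scan times - t0
  t0 <- 16
  d1 <- build_design_matrix(ev[ev$trial_type == "rest", ], t0,
                            n_scans = 60, tr = 2)
  hrf <- canonical_hrf(2 / 16)
  scan_t <- (0:59) * 2
  expected <- numeric(60)
  idx <- (scan_t - t0) >= 0 & (scan_t - t0) <= 32
  expected[idx] <- hrf[round((scan_t[idx] - t0) / (2 / 16)) + 1]
  expect_equal(d1$matrix[, "burst"], expected, tolerance = 1e-9)
  # linearity: overlapping boxcars sum
  ev_a <- tibble::tibble(onset = 10, duration = 30, trial_type = "0back")
  ev_b <- tibble::tibble(onset = 25, duration = 30, trial_type = "0back")
  ev_ab <- dplyr::bind_rows(ev_a, ev_b)
  col_ab <- build_design_matrix(ev_ab, n_scans = 60, tr = 2)$matrix[, "0back"]
  col_sum <- build_design_matrix(ev_a, n_scans = 60, tr = 2)$matrix[, "0back"] +
    build_design_matrix(ev_b, n_scans = 60, tr = 2)$matrix[, "0back"]
  expect_equal(col_ab, col_sum, tolerance = 1e-12)
  expect_error(build_design_matrix(ev, 500, n_scans = 60, tr = 2), "outside")
})

test_that("OLS recovers noiseless coefficients and calibrated p values", {
  ev <- simple_events()
  d <- build_design_matrix(ev, c(5, 30, 55, 80), n_scans = 60, tr = 2)
  beta <- c(1, -0.5, 0.3, 0.8, 0.6, 10)
  y <- d$matrix %*% beta
  fit <- fit_glm(y, d)
  expect_equal(unname(fit$betas[, 1]), beta, tolerance = 1e-8)
  # pure-noise voxels: burst-contrast p values are uniform
  set.seed(50)
  Y <- matrix(rnorm(60 * 1000), 60, 1000)
  fit0 <- fit_glm(Y, d)
  ks <- suppressWarnings(ks.test(fit0$p.value, "punif"))
  expect_gt(ks$p.value, 0.01)
  # adding a constant to Y changes only the intercept
  fit_c <- fit_glm(Y + 7, d)
  expect_equal(fit_c$betas["intercept", ], fit0$betas["intercept", ] + 7,
               tolerance = 1e-8)
  expect_equal(fit_c$estimate, fit0$estimate, tolerance = 1e-10)
  # OLS unbiasedness of the burst coefficient
  sim <- synthesize_bold(c(5, 30, 55, 80), ev, tr = 2, n_scans = 60,
                         n_voxels = 800,
                         true_betas = c(0, 0, 0, 0, 0.5, 0), noise_sd = 1,
                         seed = 51)
  fit1 <- fit_glm(sim$bold, sim$design)
  mc_se <- sd(fit1$estimate) / sqrt(800)
  expect_lt(abs(mean(fit1$estimate) - 0.5), 3.5 * mc_se)
})

test_that("rank-deficient designs warn and fall back to a pseudo-inverse", {
  X <- cbind(a = rep(1, 20), b = rep(1, 20), burst = rnorm(20),
             intercept = 1)
  expect_warning(fit <- fit_glm(rnorm(20), X), "rank deficient")
  expect_true(fit$rank_deficient)
})

test_that("BH rejection matches the brute-force step-up scan", {
  expect_equal(fdr_bh(numeric(0)), logical(0))
  expect_true(all(fdr_bh(rep(0.001, 30))))
  expect_false(any(fdr_bh(rep(0.9, 30))))
  set.seed(52)
  for (rep in 1:25) {
    p <- runif(100)^sample(c(1, 2, 3), 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(fdr_bh(p, q), oracle_bh(p, q))
  }
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("cluster filtering matches a flood-fill oracle", {
  # single 3x3x3 cube survives at k_min = 20
  cube <- array(FALSE, c(10, 10, 10))
  cube[4:6, 4:6, 4:6] <- TRUE
  cf <- cluster_filter(cube, k_min = 20)
  expect_equal(cf$sizes$n_voxels, 27)
  expect_true(all(cf$labels[4:6, 4:6, 4:6] == 1))
  # scattered isolated voxels all removed
  scat <- array(FALSE, c(9, 9, 9))
  scat[cbind(c(1, 5, 9), c(1, 5, 9), c(1, 5, 9))] <- TRUE
  expect_equal(nrow(cluster_filter(scat, k_min = 20)$sizes), 0)
  # random masks vs oracle, several connectivities
  set.seed(53)
  for (conn in c(6, 18, 26)) {
    mask <- array(runif(12^3) < 0.25, c(12, 12, 12))
    cf <- cluster_filter(mask, k_min = 1, connectivity = conn)
    ora <- oracle_components(mask, connectivity = conn)
    # same partition: labels must be a relabelling of each other
    pairs <- unique(cbind(cf$labels[mask], ora[mask]))
    expect_equal(nrow(pairs), length(unique(ora[mask])))
    expect_equal(length(unique(pairs[, 1])), nrow(pairs))
    # and the retained sizes agree after thresholding
    sizes_o <- sort(as.integer(table(ora[mask])), decreasing = TRUE)
    cf20 <- cluster_filter(mask, k_min = 20, connectivity = conn)
    expect_equal(cf20$sizes$n_voxels,
                 sizes_o[sizes_o >= 20])
  }
})

test_that("spherical ROI extraction counts lattice voxels correctly", {
  affine <- diag(c(3, 3, 3, 1)) # 3-mm isotropic, origin at voxel (0,0,0)
  map <- array(2.5, c(21, 21, 21))
  center <- c(30, 30, 30)
  roi <- roi_extract(map, affine, center, radius_mm = 10)
  expect_equal(roi$mean_coef, 2.5)
  # lattice-count oracle: 3-mm grid offsets with norm <= 10 mm
  offs <- expand.grid(x = -4:4, y = -4:4, z = -4:4) * 3
  n_expected <- sum(sqrt(rowSums(offs^2)) <= 10)
  expect_equal(roi$n_voxels, n_expected)
  # radius below half a voxel: only the center voxel
  roi1 <- roi_extract(map, affine, center, radius_mm = 1.4)
  expect_equal(roi1$n_voxels, 1)
  expect_error(roi_extract(map, affine, c(500, 500, 500), 5),
               class = "bb_empty_roi")
})
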