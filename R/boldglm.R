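# EEG-informed first-level BOLD model: canonical HRF, design construction,
# per-voxel OLS, FDR thresholding, cluster-extent filtering, spherical ROIs.

#' Canonical double-gamma hemodynamic response function
#'
#' The conventional canonical HRF: a difference of two gamma densities with
#' a response peak at 6 s and an undershoot at 16 s (unit dispersions,
#' peak-to-undershoot ratio 6), sampled on `[0, length]` at `dt` and
#' normalised to unit peak. The value at t = 0 is 0, there is a single
#' positive lobe followed by a single undershoot.
#'
#' @param dt Sampling interval in seconds (> 0).
#' @param length Kernel length in seconds (default 32).
#' @param peak_delay,undershoot_delay Gamma delays in seconds (6, 16).
#' @param peak_disp,undershoot_disp Gamma dispersions (1, 1).
#' @param ratio Peak-to-undershoot amplitude ratio (6).
#' @return Numeric vector of kernel values at `seq(0, length, by = dt)`.
#' @examples
#' h <- canonical_hrf(0.1)
#' seq(0, 32, by = 0.1)[which.max(h)] # ~5 s (mode of the 6-s gamma)
#' @export
canonical_hrf <- function(dt, length = 32, peak_delay = 6,
                          undershoot_delay = 16, peak_disp = 1,
                          undershoot_disp = 1, ratio = 6) {
  assert_scalar_num(dt, "dt", positive = TRUE)
  t <- seq(0, length, by = dt)
  h <- dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    dgamma(t, shape = undershoot_delay / undershoot_disp,
           scale = undershoot_disp) / ratio
  h / max(h)
}

#' Build the EEG-informed first-level design matrix
#'
#' Constructs the BOLD design: 0-back, 1-back and 2-back sub-blocks modelled
#' as boxcars convolved with the canonical hemodynamic response function,
#' and motor responses and beta bursts modelled as impulses convolved with
#' the same function. Regressors are built on a microtime grid of
#' `tr / microtime_factor` seconds (so impulses falling between scan times
#' are not lost), convolved at that resolution, then sampled at scan
#' acquisition times `0, tr, 2 tr, ...`. Boxcar convolutions are scaled by
#' the grid step (approximating the convolution integral); an impulse
#' regressor therefore equals the HRF itself shifted to the event time. An
#' intercept is appended, plus an optional cosine high-pass drift basis.
#'
#' @param events BIDS-style event tibble (`onset`, `duration`,
#'   `trial_type`); rows with `trial_type` `0back`/`1back`/`2back` become
#'   boxcars, rows with `trial_type` `"response"` become impulses. Other
#'   rows (rest, stimuli) are not modelled.
#' @param burst_times Numeric vector of burst event times (may be empty:
#'   the burst column is then all zero).
#' @param n_scans Number of scans.
#' @param tr Repetition time in seconds (> 0).
#' @param microtime_factor Microtime upsampling factor (default 16).
#' @param drift_cutoff Optional high-pass cutoff in seconds for a cosine
#'   drift basis (e.g. 128); NULL (default) adds no drift terms.
#' @return An object of class `bb_design`: list with `matrix` (scans x
#'   regressors, named columns including `intercept`), `tr`,
#'   `microtime_factor` and `frame_times`.
#' @export
build_design_matrix <- function(events, burst_times = numeric(0), n_scans,
                                tr, microtime_factor = 16,
                                drift_cutoff = NULL) {
  assert_scalar_num(tr, "tr", positive = TRUE)
  if (n_scans < 2) abort("`n_scans` must be >= 2.")
  n_scans <- as.integer(n_scans)
  t_end <- n_scans * tr
  burst_times <- as.numeric(burst_times)
  bad <- burst_times[burst_times < 0 | burst_times >= t_end]
  ev_bad <- events$onset[events$onset < 0 | events$onset >= t_end]
  if (length(bad) || length(ev_bad)) {
    abort(sprintf(
      "Events outside the scan window [0, %g): %s",
      t_end,
      paste(signif(utils::head(c(ev_bad, bad), 5), 4), collapse = ", ")
    ))
  }
  dt <- tr / microtime_factor
  hrf <- canonical_hrf(dt)
  n_grid <- n_scans * microtime_factor
  grid_conv <- function(x, impulse) {
    full <- stats::convolve(x, rev(hrf), type = "open")[seq_len(n_grid)]
    if (!impulse) full <- full * dt
    full
  }
  to_bin <- function(t) pmin(n_grid, pmax(1L, round(t / dt) + 1L))
  boxcar_col <- function(rows) {
    x <- numeric(n_grid)
    for (i in seq_len(nrow(rows))) {
      a <- to_bin(rows$onset[i])
      b <- to_bin(rows$onset[i] + rows$duration[i]) - 1L
      if (b >= a) x[a:b] <- x[a:b] + 1 # overlapping epochs accumulate
    }
    grid_conv(x, impulse = FALSE)
  }
  impulse_col <- function(times) {
    x <- numeric(n_grid)
    if (length(times)) {
      bins <- to_bin(times)
      for (b in bins) x[b] <- x[b] + 1
    }
    grid_conv(x, impulse = TRUE)
  }
  scan_bins <- to_bin((seq_len(n_scans) - 1L) * tr)
  cols <- list()
  for (cond in c("0back", "1back", "2back")) {
    rows <- events[events$trial_type == cond, , drop = FALSE]
    cols[[cond]] <- if (nrow(rows)) boxcar_col(rows)[scan_bins] else
      numeric(n_scans)
  }
  resp <- events$onset[events$trial_type == "response"]
  cols[["response"]] <- impulse_col(resp)[scan_bins]
  cols[["burst"]] <- impulse_col(burst_times)[scan_bins]
  X <- do.call(cbind, cols)
  if (!is.null(drift_cutoff)) {
    ts <- (seq_len(n_scans) - 1L) * tr
    n_basis <- max(0L, floor(2 * n_scans * tr / drift_cutoff))
    if (n_basis > 0L) {
      drift <- sapply(seq_len(n_basis), function(k) {
        cos(pi * k * (2 * ts + tr) / (2 * n_scans * tr))
      })
      colnames(drift) <- paste0("drift", seq_len(n_basis))
      X <- cbind(X, drift)
    }
  }
  X <- cbind(X, intercept = 1)
  structure(
    list(matrix = X, tr = tr, microtime_factor = microtime_factor,
         frame_times = (seq_len(n_scans) - 1L) * tr),
    class = "bb_design"
  )
}

#' @export
print.bb_design <- function(x, ...) {
  cat(sprintf("<bb_design> %d scans x %d regressors (tr = %g s): %s\n",
              nrow(x$matrix), ncol(x$matrix), x$tr,
              paste(colnames(x$matrix), collapse = ", ")))
  invisible(x)
}

#' Plot design-matrix regressors
#'
#' @param object A `bb_design`.
#' @param ... Unused.
#' @return A ggplot object with one facet per regressor.
#' @export
autoplot.bb_design <- function(object, ...) {
  df <- as_tibble(object$matrix) |>
    dplyr::mutate(time = object$frame_times) |>
    tidyr::pivot_longer(-"time", names_to = "regressor",
                        values_to = "value") |>
    dplyr::mutate(regressor = factor(.data$regressor,
                                     levels = colnames(object$matrix)))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~regressor, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Time (s)", y = "Regressor value",
                  title = "First-level design matrix")
}

#' Fit the first-level GLM voxelwise
#'
#' Ordinary least squares of each voxel's BOLD series on the design matrix,
#' with a t statistic and two-sided p value for a contrast (by default the
#' burst-above-baseline contrast, i.e. the `burst` column). With a
#' rank-deficient design a pseudo-inverse is used and the fit flagged.
#'
#' @param Y Numeric matrix, scans x voxels (a vector is treated as one
#'   voxel).
#' @param design A `bb_design` from [build_design_matrix()], or a plain
#'   numeric design matrix with named columns.
#' @param contrast Contrast vector of length = number of regressors, or the
#'   name of a single regressor (default `"burst"`).
#' @return An object of class `bb_glm`: `betas` (regressors x voxels),
#'   `sigma2`, `df`, `contrast`, and per-voxel `estimate`, `statistic`,
#'   `p.value`. See [tidy()] / [glance()].
#' @export
fit_glm <- function(Y, design, contrast = "burst") {
  X <- if (inherits(design, "bb_design")) design$matrix else as.matrix(design)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L)
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X)) {
    abort("`Y` and the design must have the same number of scans.")
  }
  if (is.character(contrast)) {
    if (!contrast %in% colnames(X)) {
      abort(sprintf("No regressor named '%s' in the design.", contrast))
    }
    cvec <- as.numeric(colnames(X) == contrast)
  } else {
    cvec <- as.numeric(contrast)
    if (length(cvec) != ncol(X)) {
      abort("`contrast` length must match the number of regressors.")
    }
  }
  qr_x <- qr(X)
  rank_deficient <- qr_x$rank < ncol(X)
  if (rank_deficient) {
    warn("Design is rank deficient; using the Moore-Penrose pseudo-inverse.")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    xtx_inv <- sv$v[, pos, drop = FALSE] %*%
      diag(1 / sv$d[pos]^2, sum(pos)) %*% t(sv$v[, pos, drop = FALSE])
    betas <- xtx_inv %*% t(X) %*% Y
  } else {
    betas <- qr.coef(qr_x, Y)
    xtx_inv <- chol2inv(qr.R(qr_x))
  }
  fitted <- X %*% betas
  res <- Y - fitted
  df <- nrow(X) - qr_x$rank
  if (df <= 0) abort("Non-positive residual degrees of freedom.")
  sigma2 <- colSums(res^2) / df
  est <- as.numeric(crossprod(cvec, betas))
  c_var <- as.numeric(crossprod(cvec, xtx_inv %*% cvec))
  se <- sqrt(sigma2 * c_var)
  tstat <- ifelse(se > 0, est / se, NA_real_)
  pval <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  rownames(betas) <- colnames(X)
  structure(
    list(
      betas = betas, sigma2 = sigma2, df = df, contrast = cvec,
      estimate = est, se = se, statistic = tstat, p.value = pval,
      rank_deficient = rank_deficient, n_scans = nrow(X),
      regressors = colnames(X)
    ),
    class = "bb_glm"
  )
}

#' @export
print.bb_glm <- function(x, ...) {
  cat(sprintf(
    "<bb_glm> %d voxel(s), %d scans, df = %d%s\n",
    length(x$estimate), x$n_scans, x$df,
    if (x$rank_deficient) " (rank deficient)" else ""
  ))
  cat(sprintf("contrast estimate: mean %.4g, median t %.3f\n",
              mean(x$estimate), median(x$statistic, na.rm = TRUE)))
  invisible(x)
}

#' @export
tidy.bb_glm <- function(x, ...) {
  tibble(
    voxel = seq_along(x$estimate),
    estimate = x$estimate, std.error = x$se,
    statistic = x$statistic, p.value = x$p.value
  )
}

#' @export
glance.bb_glm <- function(x, ...) {
  tibble(
    n_scans = x$n_scans, n_voxels = length(x$estimate), df = x$df,
    n_regressors = length(x$regressors),
    rank_deficient = x$rank_deficient
  )
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up false discovery rate control at level `q`: reject the hypotheses
#' with the `k` smallest p values, where `k` is the largest index with
#' `p_(k) <= k q / m`.
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Logical rejection mask of the same length (empty for empty
#'   input).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (!length(p_values)) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH") <= q
}

# 3D neighbor offsets for a given connectivity.
connectivity_offsets <- function(connectivity = 26) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  manh <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
    "6" = manh == 1,
    "18" = manh <= 2,
    "26" = rep(TRUE, nrow(g)),
    abort("`connectivity` must be 6, 18 or 26.")
  )
  g[keep, , drop = FALSE]
}

#' Cluster-extent filtering of a 3D mask
#'
#' Labels connected components of a 3D binary mask (26-neighbor
#' connectivity by default, as is conventional for voxel clusters) and
#' removes components smaller than the minimum cluster size.
#'
#' @param mask 3D logical/numeric array (nonzero = in mask).
#' @param k_min Minimum cluster size in voxels (default 20).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return A list: `labels` (integer array, 0 outside retained clusters,
#'   1..K for retained clusters ordered by decreasing size) and `sizes`
#'   (tibble `cluster`, `n_voxels`).
#' @export
cluster_filter <- function(mask, k_min = 20, connectivity = 26) {
  if (length(dim(mask)) != 3L) abort("`mask` must be a 3D array.")
  dims <- dim(mask)
  idx <- which(mask != 0)
  labels <- array(0L, dims)
  if (!length(idx)) {
    return(list(labels = labels,
                sizes = tibble(cluster = integer(), n_voxels = integer())))
  }
  coords <- arrayInd(idx, dims)
  vox_id <- integer(prod(dims))
  vox_id[idx] <- seq_along(idx)
  offs <- connectivity_offsets(connectivity)
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2L, as.numeric(offs[r, ]), "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1L) * dims[1] * dims[2] +
      (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    nb_id <- vox_id[nb_lin]
    src <- which(ok)[nb_id > 0L]
    edges[[length(edges) + 1L]] <- cbind(src, nb_id[nb_id > 0L])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(em[em[, 1] < em[, 2], , drop = FALSE]))
  }
  comp <- igraph::components(g)
  keep_comp <- which(comp$csize >= k_min)
  ord <- keep_comp[order(comp$csize[keep_comp], decreasing = TRUE)]
  relabel <- integer(comp$no)
  relabel[ord] <- seq_along(ord)
  lab <- relabel[comp$membership]
  labels[idx] <- lab
  list(
    labels = labels,
    sizes = tibble(cluster = seq_along(ord),
                   n_voxels = as.integer(comp$csize[ord]))
  )
}

#' Spherical ROI summary of a coefficient map
#'
#' Mean of a 3D coefficient map over the voxels whose center lies within a
#' given radius (default 1 cm) of a point in mm space; the NIfTI-style
#' affine maps 0-based voxel indices to mm coordinates.
#'
#' @param beta_map 3D numeric array.
#' @param affine 4x4 voxel-to-mm affine.
#' @param center_mm Sphere center, length-3 mm coordinates.
#' @param radius_mm Sphere radius in mm (default 10).
#' @return A one-row tibble: `center_x/y/z`, `radius`, `mean_coef`,
#'   `n_voxels`.
#' @export
roi_extract <- function(beta_map, affine, center_mm, radius_mm = 10) {
  if (length(dim(beta_map)) != 3L) abort("`beta_map` must be a 3D array.")
  assert_scalar_num(radius_mm, "radius_mm", positive = TRUE)
  dims <- dim(beta_map)
  grid <- as.matrix(expand.grid(i = 0:(dims[1] - 1L), j = 0:(dims[2] - 1L),
                                k = 0:(dims[3] - 1L)))
  mm <- grid %*% t(affine[1:3, 1:3]) +
    matrix(affine[1:3, 4], nrow(grid), 3, byrow = TRUE)
  d2 <- rowSums(sweep(mm, 2L, center_mm)^2)
  inside <- d2 <= radius_mm^2
  if (!any(inside)) {
    abort("The sphere contains no voxel centers.", class = "bb_empty_roi")
  }
  tibble(
    center_x = center_mm[1], center_y = center_mm[2], center_z = center_mm[3],
    radius = radius_mm,
    mean_coef = mean(beta_map[inside]),
    n_voxels = sum(inside)
  )
}
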