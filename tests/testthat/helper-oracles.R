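# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# Per-pixel 5x5 center-excluded neighborhood maximum.
oracle_dilate <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(-Inf, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      best <- -Inf
      for (di in -2:2) {
        for (dj in -2:2) {
          if (di == 0 && dj == 0) next
          ii <- i + di
          jj <- j + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
            best <- max(best, m[ii, jj])
          }
        }
      }
      out[i, j] <- best
    }
  }
  out
}

# Cells strictly greater than every in-bounds neighbor in the 5x5 window.
oracle_peaks <- function(m) {
  d <- oracle_dilate(m)
  which(m > d, arr.ind = TRUE)
}

# Full (non-separable) 2D convolution with mirror-reflected boundaries.
oracle_conv2_reflect <- function(m, kf, kt) {
  rf <- (length(kf) - 1L) %/% 2L
  rt <- (length(kt) - 1L) %/% 2L
  refl <- function(i, n) {
    if (n == 1L) return(rep(1L, length(i)))
    p <- (i - 1L) %% (2L * n - 2L)
    ifelse(p < n, p + 1L, 2L * n - 1L - p)
  }
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (a in -rf:rf) {
        for (b in -rt:rt) {
          acc <- acc + kf[a + rf + 1L] * kt[b + rt + 1L] *
            m[refl(i + a, nr), refl(j + b, nc)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Direct time-domain Morlet coefficient power at selected samples.
oracle_morlet_power <- function(x, fs, f, n_cycles, at, norm = "energy") {
  sigma <- n_cycles / (2 * pi * f)
  half <- ceiling(5 * sigma * fs)
  tw <- (-half:half) / fs
  w <- exp(-tw^2 / (2 * sigma^2)) * exp(2i * pi * f * tw)
  w <- switch(norm,
    energy = w / sqrt(sum(Mod(w)^2)),
    peak = w,
    amplitude = w / sum(Mod(w))
  )
  n <- length(x)
  vapply(at, function(t0) {
    acc <- 0 + 0i
    for (k in -half:half) {
      j <- t0 - k # convolution: sum_j x[j] w[t - j]
      if (j >= 1 && j <= n) acc <- acc + x[j] * w[k + half + 1L]
    }
    Mod(acc)^2
  }, numeric(1))
}

# Benjamini-Hochberg step-up by explicit scan over all k.
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  kmax <- 0L
  for (k in seq_len(m)) {
    if (ps[k] <= k * q / m) kmax <- k
  }
  out <- logical(m)
  if (kmax > 0L) out[ord[seq_len(kmax)]] <- TRUE
  out
}

# Connected components of a 3D mask by flood fill (stack-based).
oracle_components <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  current <- 0L
  for (start in which(mask != 0)) {
    if (lab[start] != 0L) next
    current <- current + 1L
    stack <- start
    lab[start] <- current
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      co <- arrayInd(v, dims)
      for (r in seq_len(nrow(offs))) {
        ii <- co[1] + offs[r, 1]
        jj <- co[2] + offs[r, 2]
        kk <- co[3] + offs[r, 3]
        if (ii < 1 || ii > dims[1] || jj < 1 || jj > dims[2] ||
            kk < 1 || kk > dims[3]) next
        lin <- (kk - 1L) * dims[1] * dims[2] + (jj - 1L) * dims[1] + ii
        if (mask[lin] != 0 && lab[lin] == 0L) {
          lab[lin] <- current
          stack <- c(stack, lin)
        }
      }
    }
  }
  lab
}

# Exact Mann-Whitney U and two-sided p by enumeration of all group
# assignments of the pooled sample (no ties assumed).
oracle_mann_whitney <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  N <- length(pooled)
  u_of <- function(xa, xb) sum(outer(xa, xb, ">")) # U for sample a
  u_obs <- u_of(a, b)
  combs <- utils::combn(N, n1)
  us <- apply(combs, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Spearman rho by the direct no-ties formula.
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# One-way repeated-measures ANOVA via aov(), plus Greenhouse-Geisser
# epsilon from eigenvalues of the covariance projected on orthonormal
# contrasts (an independent route to the epsilon formula).
oracle_rm_anova <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  df <- data.frame(
    y = as.vector(mat),
    subj = factor(rep(seq_len(n), times = k)),
    cond = factor(rep(seq_len(k), each = n))
  )
  fit <- summary(aov(y ~ cond + Error(subj), data = df))
  tab <- fit[["Error: Within"]][[1]]
  C <- contr.helmert(k)
  C <- qr.Q(qr(C)) # orthonormal contrasts
  lam <- eigen(t(C) %*% cov(mat) %*% C, symmetric = TRUE)$values
  list(
    F = tab["cond", "F value"],
    p = tab["cond", "Pr(>F)"],
    ss_cond = tab["cond", "Sum Sq"],
    ss_err = tab["Residuals", "Sum Sq"],
    epsilon = sum(lam)^2 / ((k - 1) * sum(lam^2))
  )
}

# Minimal n-back schedule checker: recomputes target flags from the letter
# sequence and the match rules.
oracle_targets <- function(stimuli) {
  out <- logical(nrow(stimuli))
  key <- interaction(stimuli$run, stimuli$block, stimuli$subblock,
                     drop = TRUE)
  for (g in levels(key)) {
    rows <- which(key == g)
    letters <- stimuli$letter[rows]
    cond <- stimuli$condition[rows][1]
    nb <- switch(cond, "0back" = 0L, "1back" = 1L, "2back" = 2L)
    for (i in seq_along(rows)) {
      out[rows[i]] <- if (nb == 0L) letters[i] == 0L else
        (i > nb && letters[i] == letters[i - nb])
    }
  }
  out
}

random_spectrogram <- function(n_freqs, n_times, fs = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(
    list(
      power = matrix(stats::rexp(n_freqs * n_times), n_freqs, n_times),
      freqs = seq_len(n_freqs),
      times = (seq_len(n_times) - 1) / fs,
      fs = fs, smoothed = TRUE,
      edge_margin = rep(0, n_freqs)
    ),
    class = "bb_spectrogram"
  )
}
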