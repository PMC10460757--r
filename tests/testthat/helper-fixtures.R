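# Shared fixtures and independent oracle implementations used across the
# suite. Oracles are deliberately naive re-implementations, kept separate
# from the package code paths they check.

# config with all stochastic parts off unless overridden
quiet_cfg <- function(...) {
  args <- list(...)
  base <- list(duration_s = 600, noise_sd = c(abp = 0, icp = 0, rso2 = 0),
               artifact_rate = 0, gap_rate = 0, resp_amp_mmHg = 0,
               slow_amp_mmHg = 0, autoregulation_gain = 0,
               abp_pulse_amp_mmHg = 0, coupling_delay_s = 0, seed = 1L)
  base[names(args)] <- args
  do.call(sim_config, base)
}

# brute-force windowed Pearson: per-window recomputation from scratch
naive_windowed_pearson <- function(x, y, window_s = 300, update_s = 60,
                                   bin_s = 10, min_pairs = 15) {
  w <- window_s / bin_s
  u <- update_s / bin_s
  ends <- seq(w, length(x), by = u)
  vapply(ends, function(e) {
    xs <- x[(e - w + 1):e]
    ys <- y[(e - w + 1):e]
    keep <- !(is.na(xs) | is.na(ys))
    if (sum(keep) < min_pairs) return(NA_real_)
    xs <- xs[keep]; ys <- ys[keep]
    if (length(unique(xs)) == 1 || length(unique(ys)) == 1)
      return(NA_real_)
    sxy <- sum((xs - mean(xs)) * (ys - mean(ys)))
    sxx <- sum((xs - mean(xs))^2)
    syy <- sum((ys - mean(ys))^2)
    sxy / sqrt(sxx * syy)
  }, numeric(1))
}

# assemble a cvr_decimated frame directly from 10-s mean vectors
make_decimated <- function(abp, icp, amp, rso2, subject_id = "tst") {
  out <- data.frame(t_s = (seq_along(abp) - 1) * 10, abp = abp, icp = icp,
                    amp = amp, cpp = abp - icp, rso2 = rso2)
  attr(out, "subject_id") <- subject_id
  attr(out, "bin_s") <- 10
  class(out) <- c("cvr_decimated", "data.frame")
  out
}

# simulate a VAR process with identity-covariance shocks
sim_var_process <- function(A_list, n, k = 3, intercept = rep(0, k),
                            sd = 1) {
  p <- length(A_list)
  y <- matrix(0, n, k)
  for (t in (p + 1):n) {
    v <- intercept
    for (j in seq_len(p)) v <- v + A_list[[j]] %*% y[t - j, ]
    y[t, ] <- v + stats::rnorm(k, 0, sd)
  }
  colnames(y) <- c("abp", "icp", "rso2")[seq_len(k)]
  y
}

# brute-force orthogonal IRF via companion-matrix powers
companion_irf <- function(A_list, sigma, impulse_col, horizon) {
  k <- nrow(A_list[[1]])
  p <- length(A_list)
  M <- matrix(0, k * p, k * p)
  for (j in seq_len(p)) M[1:k, ((j - 1) * k + 1):(j * k)] <- A_list[[j]]
  if (p > 1) M[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  L <- t(chol(sigma))
  J <- cbind(diag(k), matrix(0, k, k * (p - 1)))
  out <- matrix(NA_real_, k, horizon + 1)
  Mp <- diag(k * p)
  for (h in 0:horizon) {
    psi <- J %*% Mp %*% t(J)
    out[, h + 1] <- (psi %*% L)[, impulse_col]
    Mp <- Mp %*% M
  }
  out
}

# brute-force complete-linkage merge heights: max pairwise distance
# between the members of the two clusters merged at each step
brute_complete_heights <- function(x_cols) {
  d <- as.matrix(stats::dist(t(x_cols)))
  clusters <- as.list(seq_len(ncol(x_cols)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}
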