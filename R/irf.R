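# Orthogonal impulse response functions of a fitted VAR, with residual
# bootstrap confidence bands, and the qualitative similarity judgement of
# two response curves.

# moving-average coefficient matrices Psi_0..Psi_h by recursion
ma_coefficients <- function(A, k, horizon) {
  p <- length(A)
  psi <- vector("list", horizon + 1)
  psi[[1]] <- diag(k)
  for (h in seq_len(horizon)) {
    m <- matrix(0, k, k)
    for (j in seq_len(min(h, p)))
      m <- m + psi[[h - j + 1]] %*% A[[j]]
    psi[[h + 1]] <- m
  }
  psi
}

companion_matrix <- function(A) {
  p <- length(A)
  k <- nrow(A[[1]])
  M <- matrix(0, k * p, k * p)
  for (j in seq_len(p)) M[1:k, ((j - 1) * k + 1):(j * k)] <- A[[j]]
  if (p > 1) M[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  M
}

var_stable <- function(model)
  max(Mod(eigen(companion_matrix(model$A), only.values = TRUE)$values)) < 1

irf_point <- function(model, impulse, horizon) {
  k <- length(model$var_names)
  L <- t(chol(model$sigma))                 # lower triangular
  psi <- ma_coefficients(model$A, k, horizon)
  ii <- match(impulse, model$var_names)
  sapply(psi, function(P) (P %*% L)[, ii])  # k x (horizon+1)
}

# simulate a series from a fitted VAR with bootstrap-resampled residuals
var_simulate <- function(model, y0, n_out, resid_pool) {
  k <- ncol(resid_pool)
  p <- model$order
  y <- matrix(0, n_out + p, k)
  y[seq_len(p), ] <- y0
  pick <- sample.int(nrow(resid_pool), n_out, replace = TRUE)
  for (t in (p + 1):(n_out + p)) {
    v <- model$intercept
    for (j in seq_len(p)) v <- v + model$A[[j]] %*% y[t - j, ]
    y[t, ] <- v + resid_pool[pick[t - p], ]
  }
  y
}

#' Orthogonal impulse response functions with bootstrap confidence bands
#'
#' Computes the responses of all variables to a one-standard-deviation
#' orthogonal impulse in `impulse` over lags 0..`horizon`. Residuals are
#' orthogonalised by the lower-triangular Cholesky factor of the residual
#' covariance in the variable order (ABP, ICP, rSO2), so the ABP shock is
#' the leading one. 95% confidence bands come from a residual bootstrap:
#' each replicate resamples residual rows, simulates every stored series
#' from the fitted model, refits, and recomputes the IRF; percentile
#' intervals are widened, if necessary, to contain the point estimate.
#'
#' @param model A `cvr_var` (stable; positive-definite residual
#'   covariance).
#' @param impulse Impulse variable name (default `"abp"`).
#' @param horizon Number of lags (default 10).
#' @param boot Number of bootstrap replicates (default 100); 0 disables
#'   the bands.
#' @param seed RNG seed for the bootstrap.
#' @param ci Confidence level.
#' @return A `cvr_irf` list with one data frame per response variable
#'   (`lag, point, lower, upper`) plus metadata.
#' @export
orthogonal_irf <- function(model, impulse = "abp", horizon = 10,
                           boot = 100, seed = 42L, ci = 0.95) {
  stopifnot(inherits(model, "cvr_var"))
  if (!impulse %in% model$var_names)
    stop("unknown impulse variable: ", impulse, call. = FALSE)
  if (!var_stable(model))
    stop("VAR model is not stable (companion spectral radius >= 1)",
         call. = FALSE)
  ev <- eigen(model$sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("residual covariance is not positive definite", call. = FALSE)
  point <- irf_point(model, impulse, horizon)   # k x (h+1)
  k <- length(model$var_names)
  lower <- upper <- NULL
  if (boot > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    p <- model$order
    resid_pool <- sweep(model$residuals, 2, colMeans(model$residuals))
    reps <- array(NA_real_, c(k, horizon + 1, boot))
    for (b in seq_len(boot)) {
      ys <- lapply(model$series, function(y)
        var_simulate(model, y[seq_len(p), , drop = FALSE],
                     nrow(y) - p, resid_pool))
      refit <- tryCatch(
        if (length(ys) == 1L) fit_var(ys[[1]], p) else fit_cohort_var(ys, p),
        error = function(e) NULL)
      if (is.null(refit) || !var_stable(refit)) next
      reps[, , b] <- irf_point(refit, impulse, horizon)
    }
    alpha2 <- (1 - ci) / 2
    qs <- apply(reps, c(1, 2), stats::quantile,
                probs = c(alpha2, 1 - alpha2), na.rm = TRUE)
    lower <- pmin(qs[1, , ], point)
    upper <- pmax(qs[2, , ], point)
  }
  out <- lapply(seq_len(k), function(i) {
    data.frame(lag = 0:horizon,
               point = point[i, ],
               lower = if (is.null(lower)) NA_real_ else lower[i, ],
               upper = if (is.null(upper)) NA_real_ else upper[i, ])
  })
  names(out) <- model$var_names
  structure(list(responses = out, impulse = impulse, horizon = horizon,
                 boot = boot, seed = seed, ci = ci),
            class = "cvr_irf")
}

#' @export
print.cvr_irf <- function(x, ...) {
  cat(sprintf("Orthogonal IRF to a %s impulse, lags 0..%d (%d bootstrap reps)\n",
              x$impulse, x$horizon, x$boot))
  for (nm in names(x$responses))
    cat(sprintf("  %-5s lag0 %+7.4f  lag1 %+7.4f\n", nm,
                x$responses[[nm]]$point[1], x$responses[[nm]]$point[2]))
  invisible(x)
}

tri_phasic <- function(resp, settle_lag = 8) {
  pos1 <- resp$point[resp$lag == 1] > 0
  neg_by3 <- any(resp$point[resp$lag >= 1 & resp$lag <= 3] < 0)
  tail_ <- resp[resp$lag >= settle_lag, , drop = FALSE]
  settled <- if (all(is.na(tail_$lower))) {
    max(abs(tail_$point)) < 0.25 * max(abs(resp$point))
  } else any(tail_$lower <= 0 & tail_$upper >= 0)
  isTRUE(pos1 && neg_by3 && settled)
}

#' Judge whether two impulse responses have similar form
#'
#' Summarises the agreement of two response curves to the same impulse:
#' (a) sign agreement over lags 1..5, (b) Pearson correlation of the
#' max-normalised curves, and (c) a "tri-phasic" shape flag per curve
#' (positive response at lag 1, a negative excursion by lag 3, and a
#' return to a confidence band straddling zero by lag `settle_lag`). The
#' pair is declared of similar form when the curve correlation exceeds
#' `cor_threshold` and the two tri-phasic flags agree.
#'
#' @param irf_a,irf_b Data frames `lag, point, lower, upper` (e.g. single
#'   responses out of a `cvr_irf`) on the same horizon.
#' @param cor_threshold Correlation threshold for similarity.
#' @param settle_lag Lag by which the response should have settled.
#' @return List: `sign_agreement`, `curve_correlation`, `tri_phasic_a`,
#'   `tri_phasic_b`, `similar`.
#' @export
irf_similarity <- function(irf_a, irf_b, cor_threshold = 0.7,
                           settle_lag = 8) {
  if (!identical(irf_a$lag, irf_b$lag))
    stop("impulse responses have different horizons", call. = FALSE)
  norm <- function(v) if (max(abs(v)) > 0) v / max(abs(v)) else v
  a <- norm(irf_a$point); b <- norm(irf_b$point)
  sel <- irf_a$lag >= 1 & irf_a$lag <= 5
  sign_agr <- mean(sign(a[sel]) == sign(b[sel]))
  curve_cor <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else
    stats::cor(a, b)
  ta <- tri_phasic(irf_a, settle_lag)
  tb <- tri_phasic(irf_b, settle_lag)
  list(sign_agreement = sign_agr,
       curve_correlation = curve_cor,
       tri_phasic_a = ta, tri_phasic_b = tb,
       similar = isTRUE(!is.na(curve_cor) && curve_cor > cor_threshold &&
                          ta == tb))
}

#' Bivariate Granger causality at lag 1
#'
#' Tests whether `cause` Granger-causes `effect` at lag 1 by comparing
#' the restricted regression (effect on its own first lag) with the
#' unrestricted one (adding the cause's first lag) through the standard
#' nested-model F-statistic.
#'
#' @param ts Differenced `cvr_triseries` (or data frame with the two
#'   channels).
#' @param cause,effect Channel names.
#' @return A `cvr_granger` data frame row: direction, lag, F, p, n_obs.
#' @export
granger_lag1 <- function(ts, cause, effect) {
  stopifnot(all(c(cause, effect) %in% names(ts)))
  x <- as.numeric(ts[[cause]])
  y <- as.numeric(ts[[effect]])
  if (anyNA(x) || anyNA(y))
    stop("series contain missing values; interpolate first", call. = FALSE)
  n <- length(y)
  if (n < 10) stop("series too short for Granger test", call. = FALSE)
  yt <- y[-1]; yl <- y[-n]; xl <- x[-n]
  m <- length(yt)
  r_fit <- stats::lm.fit(cbind(1, yl), yt)
  u_fit <- stats::lm.fit(cbind(1, yl, xl), yt)
  rss_r <- sum(r_fit$residuals^2)
  rss_u <- sum(u_fit$residuals^2)
  f <- (rss_r - rss_u) / (rss_u / (m - 3))
  out <- data.frame(direction = paste(cause, "->", effect), lag = 1L,
                    F = f, p = stats::pf(f, 1, m - 3, lower.tail = FALSE),
                    n_obs = m)
  class(out) <- c("cvr_granger", "data.frame")
  out
}

#' All four directed Granger pairs of the tri-variate system
#'
#' Runs [granger_lag1()] for the four directions of interest:
#' dABP -> drSO2, dABP -> dICP, drSO2 -> dABP and dICP -> dABP.
#'
#' @param ts Differenced `cvr_triseries`.
#' @return A `cvr_granger` data frame with four rows.
#' @export
granger_pairs <- function(ts) {
  dirs <- list(c("abp", "rso2"), c("abp", "icp"),
               c("rso2", "abp"), c("icp", "abp"))
  out <- do.call(rbind, lapply(dirs, function(d)
    granger_lag1(ts, d[1], d[2])))
  attr(out, "subject_id") <- attr(ts, "subject_id")
  class(out) <- c("cvr_granger", "data.frame")
  out
}
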