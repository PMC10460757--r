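# Unit-root and stationarity screening for the 10-s physiologic series.
# The augmented Dickey-Fuller regression (constant, no trend) and the KPSS
# level-stationarity statistic are computed directly; p-values come from
# interpolation in the published critical-value tables, clamped to the
# tabulated range.

# Dickey-Fuller tau distribution, regression with constant, no trend
# (Banerjee, Dolado, Galbraith & Hendry 1993, Table 4.2)
.adf_probs <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
.adf_table <- rbind(
  `25`  = c(-3.75, -3.33, -3.00, -2.62, -0.37, 0.00, 0.34, 0.72),
  `50`  = c(-3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66),
  `100` = c(-3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63),
  `250` = c(-3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62),
  `500` = c(-3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61),
  `1e5` = c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60)
)
.adf_ns <- c(25, 50, 100, 250, 500, 1e5)

# KPSS level-stationarity statistic (Kwiatkowski et al. 1992, Table 1)
.kpss_probs <- c(0.10, 0.05, 0.025, 0.01)
.kpss_crit <- c(0.347, 0.463, 0.574, 0.739)

#' Augmented Dickey-Fuller unit-root test (constant, no trend)
#'
#' Fits the regression
#' \eqn{\Delta y_t = a + b y_{t-1} + \sum_{i=1}^{k} c_i \Delta y_{t-i} + e_t}
#' and tests \eqn{b = 0} (null: unit root) with the Dickey-Fuller tau
#' statistic. The lag order defaults to the Schwert rule
#' \eqn{\lfloor 12 (n/100)^{1/4} \rfloor}. The p-value is interpolated
#' from the published finite-sample tau table and clamped to
#' [0.01, 0.99].
#'
#' @param x Numeric series without missing values.
#' @param lags Number of augmentation lags.
#' @return List: `statistic`, `p_value`, `lags`, `n`.
#' @export
adf_test <- function(x, lags = NULL) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("series contains missing values", call. = FALSE)
  n <- length(x)
  if (is.null(lags)) lags <- floor(12 * (n / 100)^0.25)
  lags <- max(0L, as.integer(lags))
  if (n < lags + 10L) stop("series too short for ADF test", call. = FALSE)
  dx <- diff(x)
  m <- length(dx) - lags
  yy <- dx[(lags + 1L):length(dx)]
  X <- cbind(1, x[(lags + 1L):(n - 1L)])
  if (lags > 0)
    for (i in seq_len(lags))
      X <- cbind(X, dx[(lags + 1L - i):(length(dx) - i)])
  fit <- stats::lm.fit(X, yy)
  res <- fit$residuals
  dof <- m - ncol(X)
  s2 <- sum(res^2) / dof
  XtXinv <- chol2inv(chol(crossprod(X)))
  stat <- fit$coefficients[2] / sqrt(s2 * XtXinv[2, 2])
  # bilinear interpolation over sample size and tail probability
  row <- vapply(seq_along(.adf_probs), function(j)
    stats::approx(.adf_ns, .adf_table[, j], xout = n, rule = 2)$y,
    numeric(1))
  p <- stats::approx(row, .adf_probs, xout = stat, rule = 2)$y
  list(statistic = unname(stat), p_value = unname(p), lags = lags, n = n)
}

#' KPSS test for level stationarity
#'
#' Computes the KPSS statistic for the null of level stationarity:
#' \eqn{\eta = n^{-2} \sum_t S_t^2 / \hat\sigma^2_{LR}} with partial sums
#' of the demeaned series and a Bartlett-kernel long-run variance with
#' truncation lag \eqn{\lfloor 4 (n/100)^{1/4} \rfloor}. The p-value is
#' interpolated from the published table and clamped to [0.01, 0.10].
#'
#' @param x Numeric series without missing values.
#' @param lags Bartlett truncation lag.
#' @return List: `statistic`, `p_value`, `lags`, `n`.
#' @export
kpss_test <- function(x, lags = NULL) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("series contains missing values", call. = FALSE)
  n <- length(x)
  if (n < 10L) stop("series too short for KPSS test", call. = FALSE)
  if (is.null(lags)) lags <- floor(4 * (n / 100)^0.25)
  lags <- max(0L, as.integer(lags))
  e <- x - mean(x)
  s_t <- cumsum(e)
  lrv <- sum(e^2) / n
  if (lags > 0)
    for (h in seq_len(lags)) {
      w <- 1 - h / (lags + 1)
      lrv <- lrv + 2 * w * sum(e[(h + 1):n] * e[1:(n - h)]) / n
    }
  stat <- sum(s_t^2) / (n^2 * lrv)
  p <- stats::approx(.kpss_crit, .kpss_probs, xout = stat, rule = 2)$y
  list(statistic = unname(stat), p_value = unname(p), lags = lags, n = n)
}

#' Stationarity screen for a tri-variate series
#'
#' Runs the ADF and KPSS tests on every channel. A channel is declared
#' stationary only when the two tests agree: ADF rejects its unit-root
#' null (p < alpha) AND KPSS fails to reject its stationarity null
#' (p > alpha).
#'
#' @param ts A `cvr_triseries` (see [tri_series()]) without missing
#'   values, or any data frame of numeric channels.
#' @param alpha Significance level.
#' @return A `cvr_stationarity` data frame: channel, adf_stat, adf_p,
#'   kpss_stat, kpss_p, stationary.
#' @export
test_stationarity <- function(ts, alpha = 0.05) {
  chans <- intersect(c("abp", "icp", "rso2"), names(ts))
  if (!length(chans)) chans <- names(ts)[vapply(ts, is.numeric, logical(1))]
  rows <- lapply(chans, function(ch) {
    x <- ts[[ch]]
    if (length(x) < 50) stop("channel '", ch, "' too short (need >= 50)",
                             call. = FALSE)
    a <- adf_test(x)
    k <- kpss_test(x)
    data.frame(channel = ch, adf_stat = a$statistic, adf_p = a$p_value,
               kpss_stat = k$statistic, kpss_p = k$p_value,
               stationary = a$p_value < alpha && k$p_value > alpha)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cvr_stationarity", "data.frame")
  out
}
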