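# Tri-variate (ABP, ICP, rSO2) dynamics on the 10-s grid: gap
# interpolation, first differencing, VAR estimation by equation-wise least
# squares, AIC order selection on a common sample, and pooled cohort fits.

#' Construct a tri-variate 10-s series
#'
#' Extracts the ABP, ICP and rSO2 columns of a decimated frame (or accepts
#' them directly) as the tri-variate series used for VAR, impulse-response
#' and Granger analysis.
#'
#' @param dec A `cvr_decimated` frame, or a data frame with columns
#'   `abp`, `icp`, `rso2` (and optionally `t_s`).
#' @param subject_id Identifier; defaults to the frame's.
#' @return A `cvr_triseries` data frame with columns `t_10s, abp, icp,
#'   rso2` and attributes `differenced` (logical) and `subject_id`.
#' @export
tri_series <- function(dec, subject_id = NULL) {
  stopifnot(all(c("abp", "icp", "rso2") %in% names(dec)))
  t_10s <- if ("t_10s" %in% names(dec)) dec$t_10s else
    if ("t_s" %in% names(dec)) dec$t_s else (seq_len(nrow(dec)) - 1) * 10
  out <- data.frame(t_10s = t_10s, abp = dec$abp, icp = dec$icp,
                    rso2 = dec$rso2)
  attr(out, "differenced") <- FALSE
  attr(out, "subject_id") <- subject_id %||% attr(dec, "subject_id")
  class(out) <- c("cvr_triseries", "data.frame")
  out
}

ts_channels <- c("abp", "icp", "rso2")

#' Fill gaps by linear interpolation
#'
#' Interior missing runs in each channel are filled by linear
#' interpolation between the flanking observed values (`zoo::na.approx`);
#' rows at the start or end where any channel is still missing are
#' trimmed, so channels remain aligned.
#'
#' @param ts A `cvr_triseries` with missing values.
#' @return The gap-free `cvr_triseries`.
#' @export
interpolate_gaps <- function(ts) {
  stopifnot(inherits(ts, "cvr_triseries"))
  for (ch in ts_channels) {
    if (sum(!is.na(ts[[ch]])) < 2L)
      stop("channel '", ch, "' has fewer than 2 observed points",
           call. = FALSE)
    ts[[ch]] <- zoo::na.approx(ts[[ch]], na.rm = FALSE)
  }
  ok <- stats::complete.cases(ts[, ts_channels])
  first <- which(ok)[1]
  last <- rev(which(ok))[1]
  out <- ts[first:last, , drop = FALSE]
  rownames(out) <- NULL
  if (anyNA(out[, ts_channels]))
    stop("internal: interpolation left missing values", call. = FALSE)
  attributes_keep(out, ts)
}

attributes_keep <- function(new, old) {
  attr(new, "differenced") <- attr(old, "differenced")
  attr(new, "subject_id") <- attr(old, "subject_id")
  class(new) <- class(old)
  new
}

#' First-difference a tri-variate series
#'
#' Replaces each channel by its first differences (yielding dABP, dICP,
#' drSO2), dropping the first row. The initial values are stored so the
#' original series can be reconstructed by cumulative summation.
#'
#' @param ts An undifferenced, gap-free `cvr_triseries`.
#' @return Differenced `cvr_triseries` of length n - 1 with attribute
#'   `initial` (named first observations).
#' @export
difference_series <- function(ts) {
  stopifnot(inherits(ts, "cvr_triseries"))
  if (isTRUE(attr(ts, "differenced")))
    stop("series is already differenced", call. = FALSE)
  init <- vapply(ts_channels, function(ch) ts[[ch]][1], numeric(1))
  out <- data.frame(t_10s = ts$t_10s[-1],
                    abp = diff(ts$abp), icp = diff(ts$icp),
                    rso2 = diff(ts$rso2))
  out <- attributes_keep(out, ts)
  attr(out, "differenced") <- TRUE
  attr(out, "initial") <- init
  out
}

# lagged design matrix for a VAR(p): rows t = (p+1):n,
# columns [1, y_{t-1}, ..., y_{t-p}]
var_design <- function(y, p, from = p + 1L) {
  n <- nrow(y)
  idx <- from:n
  X <- matrix(1, length(idx), 1 + p * ncol(y))
  for (j in seq_len(p))
    X[, (2 + (j - 1) * ncol(y)):(1 + j * ncol(y))] <- y[idx - j, ,
                                                        drop = FALSE]
  list(Y = y[idx, , drop = FALSE], X = X)
}

var_fit_ls <- function(Y, X, p, k) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular VAR design matrix", call. = FALSE)
  B <- qr.coef(qrX, Y)                      # (1 + p k) x k
  res <- Y - X %*% B
  n_eff <- nrow(Y)
  n_par <- ncol(X)
  sigma_ml <- crossprod(res) / n_eff
  sigma <- crossprod(res) / (n_eff - n_par)
  aic <- log(det(sigma_ml)) + 2 * (p * k * k + k) / n_eff
  A <- lapply(seq_len(p), function(j)
    t(B[(2 + (j - 1) * k):(1 + j * k), , drop = FALSE]))
  list(intercept = B[1, ], A = A, sigma = sigma, sigma_ml = sigma_ml,
       residuals = res, n_obs = n_eff, aic = aic, B = B)
}

#' Fit a vector autoregression by equation-wise least squares
#'
#' Estimates \eqn{y_t = c + A_1 y_{t-1} + \dots + A_p y_{t-p} + e_t} with
#' an intercept by multivariate least squares. The residual covariance is
#' degrees-of-freedom adjusted; the reported AIC is
#' \eqn{\log|\hat\Sigma_{ML}| + 2 m / T} with m free regression
#' parameters.
#'
#' @param ts A differenced `cvr_triseries`, or a numeric matrix whose
#'   columns are the variables (order ABP, ICP, rSO2).
#' @param p Autoregressive order.
#' @return A `cvr_var` model: order, intercept, coefficient matrices
#'   `A[[1..p]]` (k x k), residual covariance `sigma`, `n_obs`, `aic`,
#'   and the data for bootstrap resampling.
#' @export
fit_var <- function(ts, p = 5) {
  y <- var_data(ts)
  k <- ncol(y)
  if (nrow(y) <= 3 * p + 10)
    stop("series too short for VAR(", p, ")", call. = FALSE)
  d <- var_design(y, p)
  f <- var_fit_ls(d$Y, d$X, p, k)
  structure(list(order = p, intercept = f$intercept, A = f$A,
                 sigma = f$sigma, n_obs = f$n_obs, aic = f$aic,
                 residuals = f$residuals, series = list(y),
                 var_names = colnames(y)),
            class = "cvr_var")
}

var_data <- function(ts) {
  if (inherits(ts, "cvr_triseries")) {
    if (!isTRUE(attr(ts, "differenced")))
      warning("fitting VAR on an undifferenced series")
    y <- as.matrix(ts[, ts_channels])
  } else y <- as.matrix(ts)
  if (anyNA(y)) stop("series contains missing values; interpolate first",
                     call. = FALSE)
  if (is.null(colnames(y))) colnames(y) <- ts_channels[seq_len(ncol(y))]
  y
}

#' @export
print.cvr_var <- function(x, ...) {
  cat(sprintf("VAR(%d) on %d observations of (%s)\n", x$order, x$n_obs,
              paste(x$var_names, collapse = ", ")))
  cat(sprintf("  AIC: %.4f\n", x$aic))
  invisible(x)
}

#' AIC-based VAR order selection on a common sample
#'
#' Fits VAR(p) for each candidate order on the estimation sample implied
#' by the largest candidate (so the AIC values are comparable) and
#' reports the AIC-minimising order together with an elbow heuristic: the
#' smallest order beyond which the step improvement in AIC falls below
#' `elbow_frac` of the total improvement across the candidate range.
#'
#' @param ts Differenced `cvr_triseries` or numeric matrix.
#' @param orders Candidate orders (default 1..15).
#' @param elbow_frac Fraction of the total AIC improvement below which
#'   further steps are considered negligible.
#' @return List: `aic_table` (data frame order, aic), `order_aic`
#'   (minimiser), `order_elbow`.
#' @export
select_var_order <- function(ts, orders = 1:15, elbow_frac = 0.05) {
  y <- var_data(ts)
  k <- ncol(y)
  pmax_ <- max(orders)
  if (nrow(y) <= pmax_ * k + 10)
    stop("series too short for order selection up to ", pmax_,
         call. = FALSE)
  aics <- vapply(orders, function(p) {
    d <- var_design(y, p, from = pmax_ + 1L)
    var_fit_ls(d$Y, d$X, p, k)$aic
  }, numeric(1))
  tab <- data.frame(order = orders, aic = aics)
  total_impr <- max(aics[1] - min(aics), .Machine$double.eps)
  impr <- -diff(aics)                      # improvement from p to p+1
  below <- c(impr < elbow_frac * total_impr, TRUE)
  elbow <- orders[which(below)[1]]
  list(aic_table = tab, order_aic = orders[which.min(aics)],
       order_elbow = elbow)
}

#' Pooled cohort VAR
#'
#' Fits one VAR by stacking the lagged least-squares design rows of every
#' subject, excluding any row whose lag window would cross a subject
#' boundary. With a single subject this is identical to [fit_var()].
#'
#' @param ts_list List of differenced `cvr_triseries` (or matrices).
#' @param p Autoregressive order.
#' @return A `cvr_var` model; `series` holds the per-subject matrices.
#' @export
fit_cohort_var <- function(ts_list, p = 5) {
  if (!length(ts_list)) stop("empty cohort", call. = FALSE)
  ys <- lapply(ts_list, var_data)
  k <- ncol(ys[[1]])
  ds <- lapply(ys, function(y) {
    if (nrow(y) <= p + 1) return(NULL)
    var_design(y, p)
  })
  ds <- ds[!vapply(ds, is.null, logical(1))]
  Y <- do.call(rbind, lapply(ds, `[[`, "Y"))
  X <- do.call(rbind, lapply(ds, `[[`, "X"))
  if (nrow(Y) <= 3 * p + 10)
    stop("cohort too short for VAR(", p, ")", call. = FALSE)
  f <- var_fit_ls(Y, X, p, k)
  structure(list(order = p, intercept = f$intercept, A = f$A,
                 sigma = f$sigma, n_obs = f$n_obs, aic = f$aic,
                 residuals = f$residuals, series = ys,
                 var_names = colnames(ys[[1]])),
            class = "cvr_var")
}
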