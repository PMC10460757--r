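# Minute-by-minute updating windowed Pearson correlation indices of
# cerebrovascular reactivity over paired 10-s mean values.

#' Minute-updating windowed Pearson correlation of paired 10-s means
#'
#' For each update step (every `update_s` seconds) the Pearson correlation
#' of the paired values inside the trailing `window_s`-second window is
#' computed, using only pairs where both series are present. Windows with
#' fewer than `min_pairs` complete pairs, or in which either series has
#' zero variance, yield `NA` (a correlation there is undefined; emitting 0
#' would bias index means). Windows are right-aligned and timestamped at
#' the window end.
#'
#' @param x,y Aligned numeric vectors of 10-s means (`NA` = missing).
#' @param t_s Bin start times (s), contiguous `bin_s` grid; defaults to
#'   `0, bin_s, ...`.
#' @param window_s Correlation window (s), default 300.
#' @param update_s Update interval (s), default 60; must divide into the
#'   bin grid.
#' @param bin_s Width of the input bins (s).
#' @param min_pairs Minimum complete pairs per window (default 15, i.e.
#'   half of a 300-s window of 10-s bins).
#' @return Data frame with `t_s` (window end times) and `r`.
#' @export
windowed_pearson <- function(x, y, t_s = NULL, window_s = 300,
                             update_s = 60, bin_s = 10, min_pairs = 15) {
  if (length(x) != length(y))
    stop("x and y must be aligned (equal length)", call. = FALSE)
  if (is.null(t_s)) t_s <- (seq_along(x) - 1) * bin_s
  if (length(t_s) != length(x) ||
      (length(t_s) > 1 && any(abs(diff(t_s) - bin_s) > 1e-9)))
    stop("t_s must be a contiguous ", bin_s, "-s grid aligned with x",
         call. = FALSE)
  w_bins <- as.integer(round(window_s / bin_s))
  u_bins <- as.integer(round(update_s / bin_s))
  if (length(x) < w_bins)
    return(data.frame(t_s = numeric(0), r = numeric(0)))
  ends <- seq(w_bins, length(x), by = u_bins)
  r <- vapply(ends, function(e) {
    i <- (e - w_bins + 1L):e
    xs <- x[i]; ys <- y[i]
    ok <- !is.na(xs) & !is.na(ys)
    if (sum(ok) < min_pairs) return(NA_real_)
    xs <- xs[ok]; ys <- ys[ok]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
    stats::cor(xs, ys)
  }, numeric(1))
  data.frame(t_s = t_s[ends] + bin_s, r = r)
}

#' Derive the five cerebrovascular reactivity indices
#'
#' Computes, with identical minute-updating 300-s windows over 10-s means:
#' PRx = corr(ICP, ABP); PAx = corr(AMP, ABP); RAC = corr(AMP, CPP);
#' COx = corr(rSO2, CPP); COx_a = corr(rSO2, ABP). Being Pearson
#' correlations, all values lie in [-1, 1]; higher values indicate greater
#' disruption of cerebrovascular reactivity.
#'
#' @param dec A `cvr_decimated` frame from [decimate_10s()].
#' @param window_s,update_s,min_pairs Passed to [windowed_pearson()].
#' @return A `cvr_indices` data frame with `t_min` (minute timestamps =
#'   window end times, 60-s spacing) and `prx, pax, rac, cox, cox_a`.
#' @export
derive_indices <- function(dec, window_s = 300, update_s = 60,
                           min_pairs = 15) {
  stopifnot(inherits(dec, "cvr_decimated"))
  bin_s <- attr(dec, "bin_s") %||% 10
  wp <- function(a, b) windowed_pearson(a, b, t_s = dec$t_s,
                                        window_s = window_s,
                                        update_s = update_s, bin_s = bin_s,
                                        min_pairs = min_pairs)
  prx <- wp(dec$icp, dec$abp)
  out <- data.frame(
    t_min = prx$t_s,
    prx = prx$r,
    pax = wp(dec$amp, dec$abp)$r,
    rac = wp(dec$amp, dec$cpp)$r,
    cox = wp(dec$rso2, dec$cpp)$r,
    cox_a = wp(dec$rso2, dec$abp)$r
  )
  attr(out, "subject_id") <- attr(dec, "subject_id")
  class(out) <- c("cvr_indices", "data.frame")
  out
}

#' Minute-by-minute export table
#'
#' Joins minute-level means of the decimated physiologic parameters to the
#' five reactivity indices. Each row is one minute; the physiologic
#' columns are means of that minute's 10-s bins (ending at the row's
#' timestamp) and the index columns are the windowed correlations
#' timestamped at the same minute end. Minutes with no data keep their
#' timestamp with missing values.
#'
#' @param dec A `cvr_decimated` frame.
#' @param idx The matching `cvr_indices` frame.
#' @return Data frame with columns
#'   `t_min, abp, icp, cpp, amp, rso2, prx, pax, rac, cox, cox_a`.
#' @export
export_minutely <- function(dec, idx) {
  stopifnot(inherits(dec, "cvr_decimated"), inherits(idx, "cvr_indices"))
  bin_s <- attr(dec, "bin_s") %||% 10
  per_min <- as.integer(round(60 / bin_s))
  n_min <- length(dec$t_s) %/% per_min
  minute_mean <- function(v) {
    vapply(seq_len(n_min), function(i) {
      seg <- v[((i - 1L) * per_min + 1L):(i * per_min)]
      if (all(is.na(seg))) NA_real_ else mean(seg, na.rm = TRUE)
    }, numeric(1))
  }
  out <- data.frame(
    t_min = seq_len(n_min) * 60,
    abp = minute_mean(dec$abp), icp = minute_mean(dec$icp),
    cpp = minute_mean(dec$cpp), amp = minute_mean(dec$amp),
    rso2 = minute_mean(dec$rso2)
  )
  m <- match(out$t_min, idx$t_min)
  for (cn in c("prx", "pax", "rac", "cox", "cox_a"))
    out[[cn]] <- idx[[cn]][m]
  attr(out, "subject_id") <- attr(dec, "subject_id")
  class(out) <- c("cvr_minutely", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
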