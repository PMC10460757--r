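# Raw-signal conditioning: physiologic-range artifact filters, NIRS side
# selection, Fourier-based ICP pulse-amplitude extraction and 10-s
# decimation.

#' Remove physiologically impossible samples
#'
#' Replaces samples outside the physiologic ranges by `NA`: ABP below
#' `abp_min` (0 mmHg) or above `abp_max` (200 mmHg), ICP strictly above
#' `icp_max` (100 mmHg) and rSO2 strictly below `rso2_min` (25%). Boundary
#' values are retained. All other samples pass through unchanged.
#'
#' @param rec A `cvr_recording`.
#' @param abp_min,abp_max,icp_max,rso2_min Filter thresholds.
#' @return List with `recording` (filtered copy) and `removed` (named
#'   integer vector of samples newly set to missing, per channel).
#' @export
apply_artifact_filters <- function(rec, abp_min = 0, abp_max = 200,
                                   icp_max = 100, rso2_min = 25) {
  stopifnot(inherits(rec, "cvr_recording"))
  removed <- integer(0)
  for (nm in names(rec$channels)) {
    x <- rec$channels[[nm]]$x
    bad <- switch(sub("_(left|right)$", "", nm),
                  abp  = x < abp_min | x > abp_max,
                  icp  = x > icp_max,
                  rso2 = x < rso2_min,
                  stop("unknown channel: ", nm, call. = FALSE))
    bad[is.na(bad)] <- FALSE
    rec$channels[[nm]]$x[bad] <- NA_real_
    removed[nm] <- sum(bad)
  }
  list(recording = rec, removed = removed)
}

#' Select the rSO2 channel for analysis
#'
#' The right-sided channel is used unless a right frontal contusion or
#' right scalp hematoma is flagged, in which case the left side is used.
#' If the preferred side is absent from the recording the other side is
#' returned with a warning.
#'
#' @param rec A `cvr_recording`.
#' @return Channel name, `"rso2_right"` or `"rso2_left"`.
#' @export
select_rso2_side <- function(rec) {
  stopifnot(inherits(rec, "cvr_recording"))
  have <- intersect(c("rso2_right", "rso2_left"), names(rec$channels))
  if (!length(have)) stop("recording has no rSO2 channel", call. = FALSE)
  pref <- if (isTRUE(rec$meta$contusion_right) ||
              isTRUE(rec$meta$hematoma_right)) "rso2_left" else "rso2_right"
  if (pref %in% have) return(pref)
  other <- setdiff(c("rso2_right", "rso2_left"), pref)
  warning("preferred rSO2 side '", pref, "' absent; using '", other, "'",
          call. = FALSE)
  other
}

#' ICP pulse amplitude of one waveform window by Fourier analysis
#'
#' AMP is the amplitude of the cardiac-fundamental component of the ICP
#' pulse waveform. The window is de-meaned (missing samples filled by
#' linear interpolation) and discrete-Fourier transformed; the largest
#' spectral magnitude within the cardiac band (0.67-3 Hz, i.e. 40-180 bpm)
#' locates the fundamental. Because the heart rate rarely falls exactly on
#' a DFT bin, the peak frequency is refined by Jacobsen interpolation over
#' the adjacent bins and the amplitude is then measured by a least-squares
#' sinusoid fit at the refined frequency, which is free of the scalloping
#' loss of the raw `2 * |X_k| / N` bin magnitude. Windows with fewer than
#' `min_frac` non-missing samples yield `NA`.
#'
#' @param window Numeric vector of ICP samples at `fs` Hz; length must be
#'   `window_s * fs`.
#' @param fs Sample rate (Hz).
#' @param window_s Window length (s).
#' @param band Cardiac frequency band (Hz).
#' @param min_frac Minimum fraction of non-missing samples.
#' @return AMP in the window's units (mmHg), or `NA`.
#' @export
derive_amp <- function(window, fs = 100, window_s = 10,
                       band = c(0.67, 3.0), min_frac = 0.5) {
  n <- as.integer(round(window_s * fs))
  if (length(window) != n)
    stop("window must contain exactly ", n, " samples", call. = FALSE)
  ok <- !is.na(window)
  if (mean(ok) < min_frac || sum(ok) < 2L) return(NA_real_)
  if (!all(ok))
    window <- zoo::na.approx(window, na.rm = FALSE, rule = 2)
  window <- window - mean(window)
  sp <- stats::fft(window)
  freqs <- (seq_len(n) - 1L) * fs / n
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(in_band)) return(NA_real_)
  k <- in_band[which.max(Mod(sp[in_band]))]
  if (Mod(sp[k]) < n * 1e-12) return(0)
  # Jacobsen bin-offset estimate from the two neighbouring coefficients
  delta <- 0
  if (k > 1L && k < n) {
    den <- 2 * sp[k] - sp[k - 1L] - sp[k + 1L]
    if (Mod(den) > 0)
      delta <- max(-0.5, min(0.5, Re((sp[k - 1L] - sp[k + 1L]) / den)))
  }
  f_hat <- (k - 1L + delta) * fs / n
  tt <- (seq_len(n) - 1L) / fs
  X <- cbind(sin(2 * pi * f_hat * tt), cos(2 * pi * f_hat * tt))
  cf <- stats::lm.fit(X, window)$coefficients
  sqrt(sum(cf^2))
}

# AMP for every consecutive window of a 100 Hz ICP channel
derive_amp_series <- function(x, fs = 100, window_s = 10,
                              band = c(0.67, 3.0), min_frac = 0.5) {
  n_bin <- as.integer(round(window_s * fs))
  n_full <- length(x) %/% n_bin
  vapply(seq_len(n_full), function(i) {
    derive_amp(x[((i - 1L) * n_bin + 1L):(i * n_bin)], fs = fs,
               window_s = window_s, band = band, min_frac = min_frac)
  }, numeric(1))
}

# mean of non-missing samples per non-overlapping bin; NA when fewer than
# min_frac of the expected samples are present
bin_means <- function(x, samples_per_bin, n_bins, min_frac = 0.5) {
  vapply(seq_len(n_bins), function(i) {
    seg <- x[((i - 1L) * samples_per_bin + 1L):(i * samples_per_bin)]
    if (mean(!is.na(seg)) < min_frac) NA_real_ else mean(seg, na.rm = TRUE)
  }, numeric(1))
}

#' Decimate a recording to 10-s means
#'
#' Applies a 10-s non-overlapping moving-average filter to ABP, ICP and the
#' selected rSO2 channel, attaches the per-window ICP pulse amplitude, and
#' derives CPP as the difference of the decimated ABP and ICP. A bin is
#' missing when fewer than `min_frac` of its expected samples are present;
#' CPP is missing wherever ABP or ICP is.
#'
#' @param rec A (filtered) `cvr_recording`.
#' @param amp_series Optional per-bin AMP values (from the same recording);
#'   computed from the ICP channel when omitted.
#' @param rso2_channel rSO2 channel name; defaults to [select_rso2_side()].
#' @param bin_s Bin width in seconds.
#' @param min_frac Minimum per-bin completeness fraction.
#' @return A `cvr_decimated` data frame with columns
#'   `t_s, abp, icp, amp, cpp, rso2` (bin start times).
#' @export
decimate_10s <- function(rec, amp_series = NULL, rso2_channel = NULL,
                         bin_s = 10, min_frac = 0.5) {
  stopifnot(inherits(rec, "cvr_recording"))
  if (is.null(rso2_channel)) rso2_channel <- select_rso2_side(rec)
  abp_ch <- rec$channels$abp
  icp_ch <- rec$channels$icp
  rso_ch <- rec$channels[[rso2_channel]]
  if (is.null(abp_ch) || is.null(icp_ch))
    stop("recording must contain abp and icp channels", call. = FALSE)
  n_bins <- min(length(abp_ch$x) %/% (bin_s * abp_ch$fs),
                length(icp_ch$x) %/% (bin_s * icp_ch$fs),
                length(rso_ch$x) %/% (bin_s * rso_ch$fs))
  abp <- bin_means(abp_ch$x, as.integer(bin_s * abp_ch$fs), n_bins, min_frac)
  icp <- bin_means(icp_ch$x, as.integer(bin_s * icp_ch$fs), n_bins, min_frac)
  rso2 <- bin_means(rso_ch$x, as.integer(bin_s * rso_ch$fs), n_bins,
                    min_frac)
  if (is.null(amp_series))
    amp_series <- derive_amp_series(icp_ch$x, fs = icp_ch$fs,
                                    window_s = bin_s, min_frac = min_frac)
  amp <- amp_series[seq_len(n_bins)]
  out <- data.frame(
    t_s = (seq_len(n_bins) - 1L) * bin_s,
    abp = abp, icp = icp, amp = amp,
    cpp = abp - icp, rso2 = rso2
  )
  attr(out, "subject_id") <- rec$subject_id
  attr(out, "bin_s") <- bin_s
  class(out) <- c("cvr_decimated", "data.frame")
  out
}
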