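# CSV interchange for raw recordings and derived tables, plus the
# configuration object holding every pipeline constant.

#' Pipeline configuration
#'
#' Collects every constant of the analysis pipeline: the physiologic
#' artifact-filter thresholds, the decimation and correlation-window
#' geometry, the VAR candidate orders and chosen order, the IRF horizon,
#' the Granger lag, the test significance level and the bootstrap
#' settings.
#'
#' @param abp_min,abp_max,icp_max,rso2_min Artifact-filter thresholds
#'   (mmHg, mmHg, mmHg, %).
#' @param decimate_s Decimation bin width (s).
#' @param window_s,update_s Correlation window and update interval (s);
#'   `update_s` must divide `window_s`.
#' @param min_pair_frac Minimum fraction of complete pairs per
#'   correlation window (and of samples per decimation bin).
#' @param var_orders Candidate VAR orders for AIC selection.
#' @param chosen_order VAR order used for the IRF/Granger stages.
#' @param irf_horizon IRF horizon in lags.
#' @param granger_lag Granger test lag.
#' @param alpha Significance level.
#' @param boot,boot_seed Bootstrap replicates and seed for IRF bands.
#' @return A validated `cvr_config` list.
#' @export
pipeline_config <- function(abp_min = 0, abp_max = 200, icp_max = 100,
                            rso2_min = 25, decimate_s = 10, window_s = 300,
                            update_s = 60, min_pair_frac = 0.5,
                            var_orders = 1:15, chosen_order = 5,
                            irf_horizon = 10, granger_lag = 1,
                            alpha = 0.05, boot = 100, boot_seed = 42L) {
  cfg <- list(abp_min = abp_min, abp_max = abp_max, icp_max = icp_max,
              rso2_min = rso2_min, decimate_s = decimate_s,
              window_s = window_s, update_s = update_s,
              min_pair_frac = min_pair_frac, var_orders = var_orders,
              chosen_order = chosen_order, irf_horizon = irf_horizon,
              granger_lag = granger_lag, alpha = alpha, boot = boot,
              boot_seed = as.integer(boot_seed))
  if (any(c(cfg$decimate_s, cfg$window_s, cfg$update_s) <= 0))
    stop("durations must be positive", call. = FALSE)
  if (cfg$window_s %% cfg$update_s != 0)
    stop("update_s must divide window_s", call. = FALSE)
  if (cfg$update_s %% cfg$decimate_s != 0 ||
      cfg$window_s %% cfg$decimate_s != 0)
    stop("decimate_s must divide update_s and window_s", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (!cfg$chosen_order %in% cfg$var_orders)
    stop("chosen_order must be among var_orders", call. = FALSE)
  class(cfg) <- "cvr_config"
  cfg
}

#' Write a recording as per-channel CSV plus JSON sidecar
#'
#' One `time_s,value` CSV per channel (6-decimal precision, missing as
#' empty) and a JSON sidecar with the subject id, side flags and, for
#' synthetic subjects, the generator configuration and ground truth.
#'
#' @param sub A `cvr_subject` or bare `cvr_recording`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_waveform_csv <- function(sub, dir) {
  rec <- if (inherits(sub, "cvr_subject")) sub$recording else sub
  stopifnot(inherits(rec, "cvr_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(rec$channels)) {
    ch <- rec$channels[[nm]]
    p <- file.path(dir, paste0(rec$subject_id, "_", nm, ".csv"))
    df <- data.frame(time_s = sprintf("%.6f", channel_times(ch)),
                     value = ifelse(is.na(ch$x), "",
                                    sprintf("%.6f", ch$x)))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  side <- list(subject_id = rec$subject_id, meta = rec$meta,
               channels = lapply(rec$channels, function(ch)
                 list(fs = ch$fs, t0 = ch$t0, n = length(ch$x))))
  if (inherits(sub, "cvr_subject")) {
    tr <- sub$truth
    side$truth <- list(
      autoregulation_gain = tr$autoregulation_gain,
      artifacts = lapply(tr$artifacts, as.integer),
      config = unclass(tr$config)
    )
  }
  jp <- file.path(dir, paste0(rec$subject_id, "_meta.json"))
  jsonlite::write_json(side, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, jp))
}

#' Read one channel CSV written by [write_waveform_csv()]
#'
#' Validates the `time_s,value` header, strictly increasing timestamps
#' and a constant sampling interval consistent with `fs`; empty values
#' become `NA`.
#'
#' @param path CSV path.
#' @param fs Expected sample rate (Hz); `NULL` to infer.
#' @return List `fs`, `t0`, `x` suitable for [waveform_recording()].
#' @export
read_channel_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = c("numeric", "numeric"),
                        na.strings = c("", "NA"))
  if (!identical(names(df), c("time_s", "value")))
    stop(path, ": header must be 'time_s,value'", call. = FALSE)
  t <- df$time_s
  if (anyNA(t)) stop(path, ": missing timestamps", call. = FALSE)
  dt <- diff(t)
  if (length(dt) && any(dt <= 0))
    stop(path, ": time not strictly increasing at row ",
         which(dt <= 0)[1] + 1L, call. = FALSE)
  if (length(dt) && diff(range(dt)) > 1e-6 * stats::median(dt) + 1e-9)
    stop(path, ": irregular sampling interval", call. = FALSE)
  fs_obs <- if (length(dt)) 1 / stats::median(dt) else fs
  if (!is.null(fs) && !is.null(fs_obs) && abs(fs_obs - fs) > 1e-6 * fs)
    stop(path, ": sample rate ", signif(fs_obs, 6), " Hz, expected ", fs,
         call. = FALSE)
  list(fs = if (is.null(fs)) fs_obs else fs, t0 = t[1], x = df$value)
}

#' Read a full recording from a directory of channel CSVs
#'
#' Expects files named `<subject_id>_<channel>.csv` as produced by
#' [write_waveform_csv()], plus the `<subject_id>_meta.json` sidecar for
#' the side flags.
#'
#' @param dir Directory containing the files.
#' @param subject_id Subject identifier (file prefix).
#' @return A `cvr_recording`.
#' @export
read_waveform_csv <- function(dir, subject_id) {
  expected_fs <- c(abp = 100, icp = 100, rso2_left = 1, rso2_right = 1)
  channels <- list()
  for (nm in names(expected_fs)) {
    p <- file.path(dir, paste0(subject_id, "_", nm, ".csv"))
    if (file.exists(p))
      channels[[nm]] <- read_channel_csv(p, fs = expected_fs[[nm]])
  }
  if (!length(channels))
    stop("no channel files for subject '", subject_id, "' in ", dir,
         call. = FALSE)
  meta <- list()
  jp <- file.path(dir, paste0(subject_id, "_meta.json"))
  if (file.exists(jp)) {
    side <- jsonlite::read_json(jp, simplifyVector = TRUE)
    if (!is.null(side$meta)) meta <- side$meta
  }
  waveform_recording(subject_id, channels, meta = meta)
}

write_table_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) ifelse(is.na(v), NA,
                                                sprintf("%.6f", v)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}
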