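#' Construct a raw multichannel waveform recording
#'
#' Container for one subject's raw monitoring record: full-waveform ABP and
#' ICP at 100 Hz and one or two NIRS rSO2 channels at 1 Hz, together with the
#' radiographic side flags used to pick the rSO2 channel. Missing samples are
#' encoded as `NA`, never as zeros.
#'
#' @param subject_id Character scalar identifier.
#' @param channels Named list; each element a list with fields
#'   `fs` (sample rate, Hz), `t0` (start time, s) and `x` (numeric samples,
#'   `NA` = missing). Recognised names: `abp`, `icp`, `rso2_left`,
#'   `rso2_right`.
#' @param meta List of logical side flags: `contusion_left`,
#'   `contusion_right`, `hematoma_left`, `hematoma_right` (defaults `FALSE`).
#'
#' @return Object of class `cvr_recording`.
#' @export
waveform_recording <- function(subject_id, channels, meta = list()) {
  known <- c("abp", "icp", "rso2_left", "rso2_right")
  if (is.null(names(channels)) || !all(nzchar(names(channels))))
    stop("channels must be a named list", call. = FALSE)
  bad <- setdiff(names(channels), known)
  if (length(bad))
    stop("unknown channel name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  expected_fs <- c(abp = 100, icp = 100, rso2_left = 1, rso2_right = 1)
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.list(ch) || !all(c("fs", "x") %in% names(ch)))
      stop("channel '", nm, "' must have fields fs and x", call. = FALSE)
    if (is.null(ch$t0)) channels[[nm]]$t0 <- 0
    if (ch$fs != expected_fs[[nm]])
      stop("channel '", nm, "' must be sampled at ", expected_fs[[nm]],
           " Hz, got ", ch$fs, call. = FALSE)
    if (length(ch$x) == 0L)
      stop("channel '", nm, "' is empty", call. = FALSE)
  }
  flags <- list(contusion_left = FALSE, contusion_right = FALSE,
                hematoma_left = FALSE, hematoma_right = FALSE)
  flags[names(meta)] <- meta
  structure(list(subject_id = as.character(subject_id),
                 channels = channels, meta = flags),
            class = "cvr_recording")
}

#' @export
print.cvr_recording <- function(x, ...) {
  cat("Waveform recording:", x$subject_id, "\n")
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-10s %6g Hz  %8d samples  %6d missing\n",
                nm, ch$fs, length(ch$x), sum(is.na(ch$x))))
  }
  fl <- unlist(x$meta)
  if (any(fl)) cat("  flags:", paste(names(fl)[fl], collapse = ", "), "\n")
  invisible(x)
}

channel_times <- function(ch) ch$t0 + (seq_along(ch$x) - 1L) / ch$fs
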