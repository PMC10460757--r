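# Synthetic multimodal neuromonitoring signals with known autoregulatory
# ground truth. The generator composes each channel from interpretable
# parts so that every downstream stage (artifact filters, AMP extraction,
# decimation, windowed correlation indices, VAR dynamics) has a known
# answer to recover.

# Band-limited Gaussian slow-wave process, unit SD, synthesised in the
# frequency domain at sample rate fs: white-noise spectrum masked to the
# passband, so periodogram mass outside the band is exactly zero at the
# synthesis rate.
slow_wave <- function(n, fs, band) {
  freqs <- (seq_len(n) - 1L) * fs / n
  fold <- pmin(freqs, fs - freqs)              # two-sided frequency axis
  keep <- fold >= band[1] & fold <= band[2]
  if (!any(keep)) return(numeric(n))
  z <- stats::fft(stats::rnorm(n))
  z[!keep] <- 0
  x <- Re(stats::fft(z, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# Arterial pulse: fundamental plus 2nd/3rd harmonics with fixed relative
# amplitudes (1, 0.4, 0.15) and phases, giving a non-sinusoidal waveform
# whose cardiac-fundamental amplitude is exactly `amp`.
cardiac_pulse <- function(t, f0, amp) {
  amp * (sin(2 * pi * f0 * t) +
           0.4 * sin(2 * pi * 2 * f0 * t + 0.9) +
           0.15 * sin(2 * pi * 3 * f0 * t + 1.8))
}

# Poisson-count event starts, uniform over the record
event_starts <- function(rate_per_h, duration_s, fs) {
  n_ev <- stats::rpois(1L, rate_per_h * duration_s / 3600)
  if (n_ev == 0L) return(integer(0))
  sort(sample.int(max(1L, as.integer(duration_s * fs)), n_ev))
}

inject_artifacts <- function(x, starts, values, run_len) {
  idx <- integer(0)
  for (s in starts) {
    run <- s:min(length(x), s + run_len - 1L)
    x[run] <- values[sample.int(length(values), 1L)]
    idx <- c(idx, run)
  }
  list(x = x, idx = idx)
}

inject_gaps <- function(x, starts, fs, min_s = 5, max_s = 30) {
  iv <- NULL
  for (s in starts) {
    len <- as.integer(stats::runif(1L, min_s, max_s) * fs)
    run <- s:min(length(x), s + len - 1L)
    x[run] <- NA_real_
    iv <- rbind(iv, c(start = run[1], end = run[length(run)]))
  }
  list(x = x, intervals = iv)
}

#' Simulate one synthetic neuromonitoring subject
#'
#' Generates raw ABP and ICP waveforms at 100 Hz and left/right rSO2 at
#' 1 Hz from a [sim_config()]. ABP is the sum of its mean, a 3-harmonic
#' cardiac pulse, a respiratory sinusoid, a band-limited Gaussian slow-wave
#' process and white noise. ICP transmits a (slow-wave-modulated) fraction
#' of the arterial pulse, plus the delayed slow wave scaled by the
#' autoregulation gain, plus noise. rSO2 follows the same slow
#' cerebral-blood-volume term at 1 Hz, quantised to integer percent and
#' clipped to [15, 95]. Spike artifacts (values outside the published
#' physiologic filter thresholds) and dropout gaps are injected at the
#' configured hourly rates; their positions are recorded as ground truth.
#'
#' @param config A [sim_config()] object.
#' @param meta Optional list of radiographic side flags passed to
#'   [waveform_recording()].
#' @param subject_id Identifier for the generated recording.
#'
#' @return Object of class `cvr_subject`: a list with elements
#'   `recording` (a `cvr_recording`) and `truth` (autoregulation gain,
#'   artifact sample indices, gap intervals, per-channel clean signals'
#'   slow components).
#' @export
simulate_subject <- function(config, meta = list(), subject_id = "sim01") {
  validate_sim_config(config)
  cfg <- config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  fs_w <- 100
  n_w <- as.integer(round(cfg$duration_s * fs_w))
  n_s <- as.integer(round(cfg$duration_s))      # 1 Hz channel length
  t_w <- (seq_len(n_w) - 1L) / fs_w
  t_s <- seq_len(n_s) - 1L

  # slow vasogenic wave, synthesised at 1 Hz and interpolated to 100 Hz
  slow1 <- slow_wave(n_s, 1, cfg$slow_wave_band_hz)
  slow_w <- stats::approx(t_s, slow1, xout = t_w, rule = 2)$y
  d <- cfg$coupling_delay_s
  slow_del_w <- stats::approx(t_s, slow1, xout = t_w - d, rule = 2)$y
  slow_del_s <- stats::approx(t_s, slow1, xout = t_s - d, rule = 2)$y

  pulse <- cardiac_pulse(t_w, cfg$heart_rate_hz, cfg$abp_pulse_amp_mmHg)
  resp <- cfg$resp_amp_mmHg * sin(2 * pi * cfg$resp_rate_hz * t_w)

  abp <- cfg$mean_abp_mmHg + pulse + resp + cfg$slow_amp_mmHg * slow_w +
    stats::rnorm(n_w, 0, cfg$noise_sd[["abp"]])

  g <- cfg$autoregulation_gain
  cbv_w <- g * cfg$slow_amp_mmHg * slow_del_w   # slow CBV surrogate, mmHg
  cbv_s <- g * cfg$slow_amp_mmHg * slow_del_s
  pulse_mod <- pmax(0, 1 + cfg$amp_slow_mod * g * slow_del_w)
  icp <- cfg$mean_icp_mmHg + cfg$icp_pulse_gain * pulse_mod * pulse +
    cbv_w + stats::rnorm(n_w, 0, cfg$noise_sd[["icp"]])

  rso2_core <- cfg$rso2_baseline_pct + cfg$rso2_cbv_gain * cbv_s
  rso2_l <- rso2_core + stats::rnorm(n_s, 0, cfg$noise_sd[["rso2"]])
  rso2_r <- rso2_core + stats::rnorm(n_s, 0, cfg$noise_sd[["rso2"]])
  clipq <- function(x) pmin(95, pmax(15, round(x)))
  rso2_l <- clipq(rso2_l)
  rso2_r <- clipq(rso2_r)

  # artifacts: values chosen to land outside the stated filter thresholds
  art <- list()
  a <- inject_artifacts(abp, event_starts(cfg$artifact_rate, cfg$duration_s,
                                          fs_w),
                        values = c(-10, 250), run_len = 20L)
  abp <- a$x; art$abp <- a$idx
  a <- inject_artifacts(icp, event_starts(cfg$artifact_rate, cfg$duration_s,
                                          fs_w),
                        values = 120, run_len = 20L)
  icp <- a$x; art$icp <- a$idx
  a <- inject_artifacts(rso2_r, event_starts(cfg$artifact_rate,
                                             cfg$duration_s, 1),
                        values = 20, run_len = 3L)
  rso2_r <- a$x; art$rso2_right <- a$idx
  art$rso2_left <- integer(0)

  gaps <- list()
  gp <- inject_gaps(abp, event_starts(cfg$gap_rate, cfg$duration_s, fs_w),
                    fs_w)
  abp <- gp$x; gaps$abp <- gp$intervals
  gp <- inject_gaps(icp, event_starts(cfg$gap_rate, cfg$duration_s, fs_w),
                    fs_w)
  icp <- gp$x; gaps$icp <- gp$intervals
  gp <- inject_gaps(rso2_r, event_starts(cfg$gap_rate, cfg$duration_s, 1), 1)
  rso2_r <- gp$x; gaps$rso2_right <- gp$intervals

  rec <- waveform_recording(
    subject_id,
    channels = list(
      abp = list(fs = fs_w, t0 = 0, x = abp),
      icp = list(fs = fs_w, t0 = 0, x = icp),
      rso2_left = list(fs = 1, t0 = 0, x = rso2_l),
      rso2_right = list(fs = 1, t0 = 0, x = rso2_r)
    ),
    meta = meta
  )
  structure(list(
    recording = rec,
    truth = list(autoregulation_gain = g,
                 artifacts = art, gaps = gaps,
                 slow_abp = cfg$slow_amp_mmHg * slow1,
                 slow_cbv = cbv_s,
                 config = cfg)
  ), class = "cvr_subject")
}

#' Simulate a synthetic cohort
#'
#' Draws `n_subjects` independent subjects. Per-subject seeds are derived
#' deterministically from the master seed, so a cohort is reproducible as a
#' whole and each subject individually via [simulate_subject()] with its
#' derived seed.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param config_sampler Either a single [sim_config()] used for all
#'   subjects, or a `function(i)` returning the config for subject `i`
#'   (its `seed` field is overridden by the derived per-subject seed).
#' @param seed Master integer seed.
#'
#' @return List with `subjects` (list of `cvr_subject`) and `truth`
#'   (data frame: subject_id, autoregulation_gain, seed).
#' @export
simulate_cohort <- function(n_subjects, config_sampler, seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  ids <- sprintf("sim%03d", seq_len(n_subjects))
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    cfg <- if (is.function(config_sampler)) config_sampler(i) else
      config_sampler
    validate_sim_config(cfg)
    cfg$seed <- sub_seeds[i]
    class(cfg) <- "cvr_sim_config"
    subjects[[i]] <- simulate_subject(cfg, subject_id = ids[i])
  }
  truth <- data.frame(
    subject_id = ids,
    autoregulation_gain = vapply(subjects, function(s)
      s$truth$autoregulation_gain, numeric(1)),
    seed = sub_seeds
  )
  list(subjects = subjects, truth = truth)
}

# save/restore global RNG state so simulation is seed-pure
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
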