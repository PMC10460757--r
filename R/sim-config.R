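#' Configuration for the synthetic neuromonitoring signal generator
#'
#' Bundles every parameter of the synthetic subject generator: signal
#' composition (cardiac pulse, respiratory modulation, band-limited slow
#' waves), the autoregulatory coupling between slow arterial pressure waves
#' and ICP / rSO2, and the artifact/gap injection rates.
#'
#' The autoregulation gain is the key ground-truth parameter: it scales the
#' delayed slow arterial-pressure wave that is passed into ICP (as a slow
#' cerebral-blood-volume surrogate) and into rSO2. A negative gain mimics
#' intact active vasoconstriction (slow ICP/rSO2 waves move against ABP,
#' driving PRx/COx_a negative); a positive gain mimics a pressure-passive,
#' impaired vascular bed (indices positive).
#'
#' @param duration_s Recording length in seconds.
#' @param heart_rate_hz Cardiac fundamental frequency (Hz).
#' @param resp_rate_hz Respiratory frequency (Hz).
#' @param slow_wave_band_hz Length-2 vector, passband (Hz) of the slow
#'   vasogenic wave process (Lundberg-type slow waves).
#' @param mean_abp_mmHg,abp_pulse_amp_mmHg Mean ABP and amplitude of the
#'   cardiac fundamental of the arterial pulse (mmHg).
#' @param resp_amp_mmHg Amplitude of the respiratory ABP modulation (mmHg).
#' @param slow_amp_mmHg Standard deviation of the slow-wave ABP component
#'   (mmHg).
#' @param mean_icp_mmHg Mean ICP (mmHg).
#' @param icp_pulse_gain Dimensionless transmission of the arterial pulse
#'   into the ICP waveform.
#' @param amp_slow_mod Fractional modulation of the ICP pulse amplitude by
#'   the (autoregulation-gain-scaled, unit-variance) slow wave; ties the ICP
#'   pulse amplitude to the autoregulatory state so that AMP-based indices
#'   (PAx, RAC) carry the same latent reactivity factor as PRx.
#' @param autoregulation_gain Real in [-1, 1]; see Details.
#' @param coupling_delay_s Lag (s) of the cerebrovascular response to slow
#'   ABP waves.
#' @param rso2_baseline_pct Baseline regional oxygen saturation (%).
#' @param rso2_cbv_gain Percent rSO2 per mmHg of the slow cerebral
#'   blood-volume surrogate.
#' @param noise_sd Named numeric vector with elements `abp`, `icp`, `rso2`:
#'   white measurement-noise SD per channel (mmHg, mmHg, %).
#' @param artifact_rate Expected artifacts per hour per channel.
#' @param gap_rate Expected dropout gaps per hour per channel.
#' @param seed Integer RNG seed; identical configs give bit-identical
#'   subjects.
#'
#' @return An object of class `cvr_sim_config` (a validated list).
#' @seealso [simulate_subject()], [simulate_cohort()]
#' @export
sim_config <- function(duration_s = 7200,
                       heart_rate_hz = 1.2,
                       resp_rate_hz = 0.25,
                       slow_wave_band_hz = c(0.005, 0.05),
                       mean_abp_mmHg = 90,
                       abp_pulse_amp_mmHg = 20,
                       resp_amp_mmHg = 2,
                       slow_amp_mmHg = 4,
                       mean_icp_mmHg = 12,
                       icp_pulse_gain = 0.2,
                       amp_slow_mod = 0.3,
                       autoregulation_gain = -0.5,
                       coupling_delay_s = 5,
                       rso2_baseline_pct = 65,
                       rso2_cbv_gain = 1.5,
                       noise_sd = c(abp = 2, icp = 1, rso2 = 0.5),
                       artifact_rate = 2,
                       gap_rate = 1,
                       seed = 1L) {
  cfg <- list(
    duration_s = duration_s, heart_rate_hz = heart_rate_hz,
    resp_rate_hz = resp_rate_hz, slow_wave_band_hz = slow_wave_band_hz,
    mean_abp_mmHg = mean_abp_mmHg, abp_pulse_amp_mmHg = abp_pulse_amp_mmHg,
    resp_amp_mmHg = resp_amp_mmHg, slow_amp_mmHg = slow_amp_mmHg,
    mean_icp_mmHg = mean_icp_mmHg, icp_pulse_gain = icp_pulse_gain,
    amp_slow_mod = amp_slow_mod, autoregulation_gain = autoregulation_gain,
    coupling_delay_s = coupling_delay_s,
    rso2_baseline_pct = rso2_baseline_pct, rso2_cbv_gain = rso2_cbv_gain,
    noise_sd = noise_sd, artifact_rate = artifact_rate, gap_rate = gap_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "cvr_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$duration_s) || cfg$duration_s <= 0)
    stop_cfg("duration_s must be a positive number")
  if (!num1(cfg$heart_rate_hz) || cfg$heart_rate_hz <= 0)
    stop_cfg("heart_rate_hz must be positive")
  if (!num1(cfg$resp_rate_hz) || cfg$resp_rate_hz <= 0)
    stop_cfg("resp_rate_hz must be positive")
  b <- cfg$slow_wave_band_hz
  if (!is.numeric(b) || length(b) != 2L || !all(is.finite(b)) ||
      b[1] <= 0 || b[1] >= b[2])
    stop_cfg("slow_wave_band_hz must be (low, high) with 0 < low < high")
  if (!num1(cfg$autoregulation_gain) || abs(cfg$autoregulation_gain) > 1)
    stop_cfg("autoregulation_gain must lie in [-1, 1]")
  if (!num1(cfg$coupling_delay_s) || cfg$coupling_delay_s < 0)
    stop_cfg("coupling_delay_s must be non-negative")
  ns <- cfg$noise_sd
  if (!is.numeric(ns) || !all(c("abp", "icp", "rso2") %in% names(ns)) ||
      any(ns < 0))
    stop_cfg("noise_sd must be a named non-negative vector (abp, icp, rso2)")
  for (f in c("abp_pulse_amp_mmHg", "resp_amp_mmHg", "slow_amp_mmHg",
              "icp_pulse_gain", "amp_slow_mod", "artifact_rate", "gap_rate"))
    if (!num1(cfg[[f]]) || cfg[[f]] < 0)
      stop_cfg(paste(f, "must be non-negative"))
  if (!num1(cfg$seed)) stop_cfg("seed must be a single integer")
  invisible(cfg)
}

#' @export
print.cvr_sim_config <- function(x, ...) {
  cat("Synthetic neuromonitoring subject configuration\n")
  cat(sprintf("  duration: %g s, heart rate: %g Hz, resp: %g Hz\n",
              x$duration_s, x$heart_rate_hz, x$resp_rate_hz))
  cat(sprintf("  slow-wave band: %g-%g Hz (SD %g mmHg)\n",
              x$slow_wave_band_hz[1], x$slow_wave_band_hz[2],
              x$slow_amp_mmHg))
  cat(sprintf("  autoregulation gain: %+g (delay %g s)\n",
              x$autoregulation_gain, x$coupling_delay_s))
  cat(sprintf("  artifacts/h: %g, gaps/h: %g, seed: %d\n",
              x$artifact_rate, x$gap_rate, x$seed))
  invisible(x)
}
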