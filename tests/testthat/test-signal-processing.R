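# Artifact filters, rSO2 side selection, Fourier pulse-amplitude
# extraction and 10-s decimation.

mk_rec <- function(abp = NULL, icp = NULL, rso2_right = NULL,
                   rso2_left = NULL, meta = list()) {
  ch <- list()
  if (!is.null(abp)) ch$abp <- list(fs = 100, t0 = 0, x = abp)
  if (!is.null(icp)) ch$icp <- list(fs = 100, t0 = 0, x = icp)
  if (!is.null(rso2_right))
    ch$rso2_right <- list(fs = 1, t0 = 0, x = rso2_right)
  if (!is.null(rso2_left))
    ch$rso2_left <- list(fs = 1, t0 = 0, x = rso2_left)
  waveform_recording("t", ch, meta = meta)
}

test_that("artifact filters apply the stated thresholds with strict inequalities", {
  rec <- mk_rec(abp = c(-5, 80, 250, 90, 0, 200),
                icp = c(10, 100, 101, 50, -2, 3),
                rso2_right = c(25, 24.9, 60))
  out <- apply_artifact_filters(rec)
  expect_equal(out$recording$channels$abp$x, c(NA, 80, NA, 90, 0, 200))
  expect_equal(out$recording$channels$icp$x, c(10, 100, NA, 50, -2, 3))
  expect_equal(out$recording$channels$rso2_right$x, c(25, NA, 60))
  expect_equal(unname(out$removed[c("abp", "icp", "rso2_right")]),
               c(2L, 1L, 1L))
})

test_that("filtering is idempotent and leaves missing samples missing", {
  rec <- mk_rec(abp = c(NA, 300, 90), icp = c(5, NA, 120))
  once <- apply_artifact_filters(rec)
  twice <- apply_artifact_filters(once$recording)
  expect_identical(once$recording$channels, twice$recording$channels)
  expect_equal(unname(twice$removed[c("abp", "icp")]), c(0L, 0L))
})

test_that("recordings with unknown channel names are rejected at construction", {
  expect_error(waveform_recording("t", list(pressure = list(fs = 100,
                                                            x = 1:5))),
               "unknown channel")
})

test_that("right rSO2 channel is preferred unless right-sided pathology is flagged", {
  both <- c(60, 61, 62)
  expect_equal(select_rso2_side(mk_rec(rso2_right = both,
                                       rso2_left = both)), "rso2_right")
  expect_equal(select_rso2_side(mk_rec(rso2_right = both, rso2_left = both,
                                       meta = list(hematoma_right = TRUE))),
               "rso2_left")
  expect_equal(select_rso2_side(mk_rec(rso2_right = both, rso2_left = both,
                                       meta = list(contusion_right = TRUE))),
               "rso2_left")
  # left-sided pathology does not displace the right channel
  expect_equal(select_rso2_side(mk_rec(rso2_right = both, rso2_left = both,
                                       meta = list(hematoma_left = TRUE))),
               "rso2_right")
  expect_warning(
    side <- select_rso2_side(mk_rec(rso2_right = both,
                                    meta = list(hematoma_right = TRUE))),
    "absent")
  expect_equal(side, "rso2_right")
  expect_error(select_rso2_side(mk_rec(abp = rep(80, 10))), "rSO2")
})

test_that("AMP of a pure cardiac sinusoid equals its amplitude", {
  t <- (0:999) / 100
  expect_equal(derive_amp(10 + 2 * sin(2 * pi * 1.2 * t)), 2,
               tolerance = 0.01)
  expect_equal(derive_amp(rep(10, 1000)), 0, tolerance = 1e-9)
  expect_error(derive_amp(rep(10, 999)), "samples")
})

test_that("AMP recovers the fundamental of a multi-harmonic pulse (least-squares oracle)", {
  t <- (0:999) / 100
  f0 <- 1.0
  pulse <- 1.5 * sin(2 * pi * f0 * t + 0.4) +
    0.6 * sin(2 * pi * 2 * f0 * t + 1.1) +
    0.2 * sin(2 * pi * 3 * f0 * t + 2.0)
  # oracle: least-squares sinusoid fit at the known fundamental
  fit <- lm(pulse ~ sin(2 * pi * f0 * t) + cos(2 * pi * f0 * t))
  oracle <- sqrt(sum(coef(fit)[2:3]^2))
  expect_equal(oracle, 1.5, tolerance = 1e-6)
  expect_equal(derive_amp(12 + pulse), oracle, tolerance = 0.05)
})

test_that("AMP is invariant to constant offsets and tolerates interpolated gaps", {
  t <- (0:999) / 100
  w <- 2 * sin(2 * pi * 1.5 * t)
  expect_equal(derive_amp(w), derive_amp(w + 57), tolerance = 1e-9)
  # a linearly filled 1-s gap removes ~10% of the pulse energy, so the
  # estimate is biased low but stays near the true amplitude
  w_gap <- w
  w_gap[200:299] <- NA
  expect_equal(derive_amp(w_gap), 2, tolerance = 0.25)
  w_gap[1:700] <- NA           # below 50% completeness
  expect_true(is.na(derive_amp(w_gap)))
})

test_that("10-s decimation averages bins, derives CPP and applies the completeness rule", {
  abp <- rep(80, 3000)
  icp <- rep(10, 3000)
  abp[1001:1601] <- NA         # bin 2 keeps 399/1000 samples -> missing
  rec <- mk_rec(abp = abp, icp = icp, rso2_right = rep(60, 30))
  dec <- decimate_10s(rec)
  expect_equal(nrow(dec), 3)
  expect_equal(dec$abp, c(80, NA, 80))
  expect_equal(dec$icp, rep(10, 3))
  expect_equal(dec$cpp, c(70, NA, 70))
  expect_equal(dec$rso2, rep(60, 3))
  expect_true(all(dec$amp < 1e-9, na.rm = TRUE))
})

test_that("decimation commutes with affine rescaling and cpp + icp = abp exactly", {
  set.seed(4)
  abp <- 90 + rnorm(6000)
  icp <- 12 + rnorm(6000)
  rec <- mk_rec(abp = abp, icp = icp, rso2_right = rep(60, 60))
  rec2 <- mk_rec(abp = 2 * abp + 5, icp = icp, rso2_right = rep(60, 60))
  d1 <- decimate_10s(rec)
  d2 <- decimate_10s(rec2)
  expect_equal(d2$abp, 2 * d1$abp + 5, tolerance = 1e-10)
  expect_equal(d1$cpp + d1$icp, d1$abp, tolerance = 1e-12)
})
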