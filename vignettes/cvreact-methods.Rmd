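---
title: "Methods: cerebrovascular reactivity indices and their multivariate structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cerebrovascular reactivity indices and their multivariate structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvreact)
```

## The problem

Cerebrovascular reactivity — the ability of the cerebral vasculature to
buffer changes in driving pressure — is monitored at the bedside of
brain-injured patients through continuously updating correlation indices.
The most established is PRx, the windowed Pearson correlation between
arterial blood pressure (ABP) and intracranial pressure (ICP): when
autoregulation is intact, active vasoconstriction makes slow ICP waves move
*against* slow ABP waves and the correlation is negative; when the vascular
bed is pressure-passive the two move together and the correlation is
positive. ICP enters this construction only as a surrogate for pulsatile
cerebral blood volume (CBV). Near-infrared spectroscopy offers a
non-invasive alternative surrogate, regional oxygen saturation (rSO~2~),
giving the indices COx (rSO~2~ vs CPP) and COx_a (rSO~2~ vs ABP). Two
further ICP-derived indices use the cardiac pulse amplitude of ICP (AMP):
PAx (AMP vs ABP) and RAC (AMP vs CPP).

`cvreact` implements the full analysis chain used to compare these five
indices: signal conditioning and index derivation from raw waveforms;
agglomerative hierarchical clustering and PCA of the pooled 10-parameter
physiologic space; and vector-autoregressive modelling of the differenced
10-second series with orthogonal impulse responses and Granger causality.
Because clinical high-resolution neuromonitoring databases are not publicly
deposited, the package pairs the analysis with a synthetic signal generator
whose ground-truth autoregulatory state is known, so every stage can be
validated by parameter recovery rather than by eye.

## Signal conditioning

Raw inputs are ABP and ICP waveforms at 100 Hz and one or two rSO~2~
channels at 1 Hz. Conditioning proceeds in four steps.

**Artifact filters.** Samples outside physiologic range are removed (set to
missing, never zeroed): ABP below 0 or above 200 mmHg, ICP above 100 mmHg,
rSO~2~ below 25%. All comparisons are strict, so boundary values survive; a
recording is never shortened, and a per-channel removal count is reported.

**rSO~2~ side selection.** The right-sided channel is used unless a right
frontal contusion or right scalp hematoma is flagged, in which case the
left is used; if the preferred side is absent the other is used with a
warning. A fixed, systematic rule avoids selection bias.

**ICP pulse amplitude (AMP).** Per 10-s window the ICP waveform is
de-meaned (interior gaps linearly interpolated) and Fourier transformed;
the largest spectral peak in the cardiac band 0.67–3.0 Hz (40–180 bpm)
locates the fundamental. Because a heart rate rarely coincides with a DFT
bin, the raw bin magnitude `2|X_k|/N` suffers scalloping loss (up to ~36%
at a half-bin offset with a rectangular window), so the peak frequency is
refined by Jacobsen interpolation over the adjacent bins and the amplitude
is then measured by a least-squares sinusoid fit at the refined frequency.
This is exact for on-bin frequencies and accurate to about 1% elsewhere;
the band excludes the respiratory peak by construction. Windows with less
than 50% of samples present yield missing.

**Decimation.** Each channel is reduced to 10-s non-overlapping means — the
standard step that suppresses pulse and respiratory frequencies while
retaining the slow (0.005–0.05 Hz) vasogenic waves the indices rely on. A
bin with less than half its expected samples is missing. CPP is derived
after decimation as ABP − ICP, so `cpp + icp = abp` holds exactly wherever
all are present.

## The reactivity indices

All five indices are the same statistic applied to different parameter
pairs: a Pearson correlation over a trailing 300-s window of paired 10-s
means (30 pairs), updated every 60 s and timestamped at the window end
(a causal convention computable in real time). A window yields a value only
if at least 15 complete pairs are available (the same 50% convention as the
bins) and both series vary; a zero-variance window is reported missing
rather than zero, since a correlation is undefined there and silently
emitting 0 would bias index means toward the "indeterminate" middle.

| index | x | y |
|-------|----|----|
| PRx   | ICP | ABP |
| PAx   | AMP | ABP |
| RAC   | AMP | CPP |
| COx   | rSO~2~ | CPP |
| COx_a | rSO~2~ | ABP |

Minute-by-minute tables join minute means of the decimated parameters to
the index values ending at the same minute.

## Cohort structure: clustering and PCA

Minute observations of the 10 parameters (ABP, ICP, CPP, rSO~2~, PRx, PAx,
RAC, AMP, COx, COx_a) are pooled over all subjects; any row with a missing
entry is dropped to obtain a fully populated matrix, and each column is
z-scaled over the entire cohort (sample SD; the convention of mainstream
statistical software).

Hierarchical clustering operates on the *parameter columns*: Euclidean
distances between scaled column vectors, complete-linkage agglomeration,
and the cophenetic correlation coefficient as goodness of fit. Clustering
columns (not minute rows) is what yields a dendrogram whose leaves are the
10 parameters; for z-scored columns the distance is a monotone transform of
the correlation, `d = sqrt(2(n-1)(1-r))`, so the dendrogram is effectively
a hierarchy of parameter correlations. PCA is performed on the same scaled
matrix via singular-value decomposition (numerically equivalent to an
eigen-decomposition of the parameter correlation matrix but better
conditioned). Eigenvector signs are fixed by making the largest-magnitude
loading of each component positive; biplot coordinates are loadings scaled
by the square root of the eigenvalue. A proximity report flags whether the
five indices co-cluster — merge among themselves at a lower cophenetic
height than any of them joins a raw parameter.

This pooling deliberately ignores the hierarchical (per-subject) structure
of the data; a mixed-effects decomposition is out of scope by design.

## Dynamics: VAR, impulse responses, Granger causality

The tri-variate 10-s series (ABP, ICP, rSO~2~) is prepared by linear
interpolation of interior gaps (edge gaps are trimmed so channels stay
aligned). Stationarity is screened per channel by an augmented
Dickey–Fuller regression with intercept and Schwert-rule lag length (null:
unit root) and the KPSS level statistic with Bartlett long-run variance
(null: stationary); p-values are interpolated from the published
critical-value tables and clamped to their tabulated ranges. A channel is
declared stationary only when the two tests agree (ADF rejects AND KPSS
fails to reject). The pipeline then takes first differences of all three
channels — the differenced series dABP, dICP, drSO~2~ are what the
published impulse-response and Granger analyses are defined on — and
reports both the pre- and post-differencing test tables.

The VAR(p) with intercept is estimated by equation-wise least squares;
residual covariance is degrees-of-freedom adjusted, and the reported AIC is
`log|Sigma_ML| + 2m/T`. Order selection computes the AIC for orders 1–15
**on the common estimation sample implied by the largest candidate** —
otherwise AIC values are not comparable across orders — and reports both
the minimiser and an elbow: the smallest order beyond which the step
improvement falls below 5% of the total improvement. On long clinical
records the minimiser tends to creep upward (AIC is not consistent), which
is precisely why the elbow-plus-parsimony convention selects a small order
such as 5; the package keeps order 5 as the default for the IRF and
comparability.

Orthogonal impulse responses use the moving-average recursion on the fitted
coefficient matrices and a lower-triangular Cholesky factor of the residual
covariance in the variable order (ABP, ICP, rSO~2~), so the orthogonal
shock is the ABP innovation — ABP is the modeled driving pressure, which
motivates placing it first in the ordering. Stability (companion spectral
radius < 1) is checked before the recursion. 95% confidence bands come
from a residual bootstrap (default 100 replicates, seeded): resample
residual rows, simulate each stored series from the fitted model, refit,
recompute; percentile intervals are widened if needed to contain the point
estimate so the band invariant holds even at small replicate counts.
Cohort models pool the per-subject lagged design rows, masking any row
whose lag window would cross a subject boundary.

Two responses are judged "of similar form" by `irf_similarity`: sign
agreement over lags 1–5, the correlation of the max-normalised curves, and
a tri-phasic flag per curve (positive at lag 1, a negative excursion by lag
3, and a confidence band straddling zero by lag 8). The pair is similar
when the curve correlation exceeds 0.7 and the flags agree; both thresholds
are configurable.

Granger causality is tested bivariately at lag 1 for the four directed
pairs (dABP → dICP, dABP → drSO~2~, and the reverses): the standard nested
F-test of adding the cause's first lag to the effect's own-lag regression.
The bivariate formulation (rather than a conditional three-variable test)
matches the four enumerated pairwise directions; direction is judged by
comparing F magnitudes.

## The synthetic generator

`simulate_subject()` composes each channel from interpretable parts:

* **ABP** = mean + cardiac pulse + respiratory sinusoid + slow-wave process
  + white noise, at 100 Hz. The cardiac pulse is a 3-harmonic waveform
  (relative amplitudes 1, 0.4, 0.15) so that AMP extraction at the
  fundamental is tested on a non-sinusoidal pulse. The slow-wave process is
  Gaussian noise synthesised in the frequency domain with support exactly
  inside 0.005–0.05 Hz — the Lundberg-type band the indices target —
  without committing to any particular slow-wave morphology.
* **ICP** = mean + transmitted pulse + `g`·slow_ABP(t − delay) + noise,
  where `g` is the autoregulation gain in [−1, 1]: negative for intact
  (counter-moving) vasoregulation, positive for a pressure-passive bed. The
  transmitted pulse amplitude is additionally modulated by the
  gain-weighted slow wave (`amp_slow_mod`, default 0.3), because in an
  impaired subject slow CBV waves raise the ICP pulse amplitude — without
  this, AMP (hence PAx and RAC) would carry no autoregulatory signal at
  all.
* **rSO~2~** = baseline + gain-scaled slow CBV term + noise at 1 Hz,
  quantised to integer percent and clipped to [15, 95], mimicking oximeter
  export granularity.

Artifacts are spikes whose values (−10/250 mmHg ABP, 120 mmHg ICP, 20%
rSO~2~) land outside the filter thresholds, so filter tests have exact
expected answers; dropout gaps of 5–30 s exercise the missing-data paths.
Both are Poisson events at configurable hourly rates, and every injected
position is recorded as ground truth. The generator is bit-reproducible
under its seed; cohorts derive per-subject seeds deterministically from a
master seed.

Default magnitudes (mean ABP 90 mmHg, pulse 20 mmHg, respiratory 2 mmHg,
slow-wave SD 4 mmHg, mean ICP 12 mmHg, pulse transmission 0.2, rSO~2~
baseline 65%, 1.5% per mmHg slow CBV, noise SDs 2/1/0.5, 2 artifacts and 1
gap per hour) are ordinary adult neuro-ICU magnitudes chosen once for
realism and testability. What the generator does **not** emulate: real
slow-wave spectra and nonstationary drift, biophysical pressure–volume
coupling (no Ursino-type model), baroreflex dynamics, oxygenation
covariates, or clinical deterioration. Passing end-to-end tests therefore
demonstrates that the pipeline recovers a known coupling structure, not
that clinical effect sizes are reproduced.

## Numerical and design choices

* **50% completeness** thresholds (bins, AMP windows, correlation windows)
  are one consistent convention for an automated surrogate of manual
  artifact clearing.
* **Trailing windows** timestamped at the window end: causal and
  real-time-computable.
* **ADF variant**: intercept, no trend; physiologic pressures have a
  nonzero mean but no deterministic trend at these scales.
* **p-value clamping** to the tabulated ranges ([0.01, 0.99] ADF,
  [0.01, 0.10] KPSS) follows the usual table-interpolation practice; only
  the verdict at alpha = 0.05 feeds the pipeline.
* **Unconditional differencing** in the pipeline: the impulse-response and
  Granger analyses are defined on the differenced series. The screening
  tables let a user apply a conditional rule instead.
* **AIC on a common sample**, elbow fraction 0.05.
* **Cholesky order (ABP, ICP, rSO~2~)**: the impulse of interest is the
  ABP innovation.
* **Bootstrap 100 replicates**: matches common tooling defaults for IRF
  bands; intervals are percentile-based and widened to contain the point
  estimate.
* **Problem sizes** used by the shipped analysis scripts and the
  acceptance script — 20–50 subjects of 0.2–2 h — were chosen so the whole
  battery runs in minutes on a laptop while leaving every Monte Carlo
  margin wide (sign recovery and Granger direction are at 100% under the
  defaults).

## Known limitations

The generator's linear, delay-only coupling cannot produce the asymmetric,
state-dependent autoregulation of real patients, and its artifacts are
caricatures (single-valued spikes). The ADF/KPSS p-values are
table-interpolated, not response-surface approximations, so they are
step-wise near the table edges. Bootstrap bands treat the VAR order as
fixed. The cohort VAR assumes shared dynamics across subjects; the
per-subject models quantify how heterogeneous that assumption is.
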