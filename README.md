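# cvreact

Cerebrovascular reactivity indices and multivariate time-series analysis
of multimodal neuromonitoring data.

## The scientific problem

After moderate or severe traumatic brain injury, dysfunctional
cerebrovascular reactivity — the loss of the vasculature's ability to
buffer changes in driving pressure — is a major contributor to secondary
injury. At the bedside it is monitored through continuously updating
correlation indices over slow (0.005–0.05 Hz) vasogenic waves:

* **PRx** = corr(ICP, ABP) — the prevalent, invasive index; ICP acts as a
  surrogate for pulsatile cerebral blood volume (CBV), ABP for driving
  pressure;
* **PAx** = corr(AMP, ABP) and **RAC** = corr(AMP, CPP), where AMP is the
  cardiac pulse amplitude of ICP and CPP = ABP − ICP;
* **COx** = corr(rSO₂, CPP) and **COx_a** = corr(rSO₂, ABP), NIRS-based
  indices that replace ICP by regional cerebral oxygen saturation — COx_a
  being fully non-invasive.

Each is a Pearson correlation over a trailing 300-s window of paired 10-s
mean values, updated minute by minute; positive values indicate a
pressure-passive (impaired) vascular bed. The scientific question this
package's analysis chain addresses: do the NIRS-based indices relate to the
ICP-based ones closely enough — in multivariate parameter space and in
their dynamics — that rSO₂ is a valid CBV surrogate?

`cvreact` implements, for R users in multimodal-neuromonitoring research:

1. **Signal conditioning** — physiologic artifact filters (ABP outside
   [0, 200] mmHg, ICP > 100 mmHg, rSO₂ < 25% removed), rSO₂ side
   selection, ICP pulse-amplitude extraction by Fourier analysis, 10-s
   decimation, CPP derivation.
2. **Index derivation** — the five windowed-correlation indices and
   minute-by-minute export tables.
3. **Multivariate structure** — complete-linkage agglomerative clustering
   of the z-scaled 10-parameter space (ABP, ICP, CPP, rSO₂, AMP + the five
   indices) with cophenetic validation, and PCA with scree/biplot outputs.
4. **Dynamics** — ADF/KPSS stationarity screening, first differencing,
   VAR estimation with AIC order selection over orders 1–15, orthogonal
   impulse responses of dICP and drSO₂ to a dABP shock (Cholesky ordering
   ABP first, residual-bootstrap 95% bands), and lag-1 bivariate Granger
   causality over the four directed ABP pairs.
5. **A synthetic cohort generator** with a known ground-truth
   autoregulation gain, so the whole chain is validated by parameter
   recovery.

## Worked example

```r
library(cvreact)

# one synthetic subject, 1 h, impaired autoregulation (gain +0.8)
cfg <- sim_config(duration_s = 3600, autoregulation_gain = 0.8, seed = 42)
sub <- simulate_subject(cfg)

flt <- apply_artifact_filters(sub$recording)
flt$removed
#>        abp        icp  rso2_left rso2_right
#>         60          0          0          3

dec <- decimate_10s(flt$recording)       # 10-s means + AMP + CPP
idx <- derive_indices(dec)               # PRx, PAx, RAC, COx, COx_a
mean(idx$prx, na.rm = TRUE)              # +0.688
mean(idx$cox_a, na.rm = TRUE)            # +0.633
```

Both indices are strongly positive — the pipeline recovers the impaired
state the generator imposed. The dynamics stage on the same subject:

```r
dts <- difference_series(interpolate_gaps(tri_series(dec)))
granger_pairs(dts)
#>    direction lag         F             p n_obs
#>  abp -> rso2   1 1018.2550 2.545313e-106   358
#>   abp -> icp   1  862.1529  5.220032e-97   358
#>  rso2 -> abp   1  103.2724  1.828441e-21   358
#>   icp -> abp   1  111.1545  8.619846e-23   358

m   <- fit_var(dts, 5)
irf <- orthogonal_irf(m, boot = 100, seed = 1)
irf_similarity(irf$responses$icp, irf$responses$rso2)$curve_correlation
#> 0.995
```

The F-statistics put the direction of temporal causation firmly at
dABP → dICP/drSO₂ (not the reverse), and the dICP and drSO₂ impulse
responses have near-identical form — the behaviour expected if rSO₂ is an
adequate CBV surrogate.

The `analysis/` directory holds the cohort-level drivers, run in order
from the repository root:

```sh
Rscript analysis/01_simulate_derive.R   # 20-subject cohort -> results/cohort/
Rscript analysis/02_cluster_pca.R       # dendrogram, cophenetic, scree, biplot
Rscript analysis/03_var_irf.R           # stationarity, AIC, pooled VAR(5), IRFs
Rscript analysis/04_granger.R           # per-subject Granger table
```

On the default 20-subject cohort the five reactivity indices co-cluster
away from the raw pressures (cophenetic correlation 0.97), the pooled
impulse responses of dICP and drSO₂ to a dABP shock are positive at lag 1
with a negative overcorrection and settle within the band by lag 8, and
the dABP → dICP / dABP → drSO₂ direction dominates in 20/20 subjects.

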