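Package: cvreact
Title: Cerebrovascular Reactivity Indices and Multivariate Time-Series
    Analysis of Multimodal Neuromonitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derivation of intracranial-pressure-based (PRx, PAx, RAC) and
    near-infrared-spectroscopy-based (COx, COx_a) cerebrovascular reactivity
    indices from raw arterial blood pressure, intracranial pressure and
    regional cerebral oxygen saturation recordings, together with the
    cohort-level analyses used to compare them: artifact filtering, ICP pulse
    amplitude extraction by Fourier analysis, 10-second decimation,
    minute-by-minute windowed Pearson correlation indices, agglomerative
    hierarchical clustering with cophenetic validation, principal component
    analysis of the physiologic parameter space, and vector autoregressive
    modelling of differenced signals with orthogonal impulse response
    functions and Granger causality tests. Includes a synthetic multimodal
    neuromonitoring signal generator with a known ground-truth autoregulatory
    state for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    zoo,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lmtest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
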