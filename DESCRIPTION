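Package: bayesddm
Title: Bayesian Observer Models and Their Exact Drift-Diffusion Equivalents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-alternative perceptual decision making built around
    the exact equivalence between a Bayesian sequential-inference observer and
    the pure drift-diffusion model (pDDM). Provides discretized pDDM and
    Bayesian-observer trial simulators with matched-noise reproducibility,
    closed-form first-passage oracles, bidirectional parameter translation
    under two constraint sets (symmetric means; equal means), the prior/bias
    and bound-rescaling maps, decision-variable trajectory recording and
    averaging, synthetic multi-condition experiment generation with trial
    table I/O, and fitting of accuracy and reaction-time quantiles by a
    quantile-weighted pseudo-likelihood with adaptive Metropolis MCMC or the
    closed-form EZ-diffusion inversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
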