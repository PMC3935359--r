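---
title: "Bayesian observers, drift-diffusion equivalence, and fitting behavioral data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian observers, drift-diffusion equivalence, and fitting behavioral data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesddm)
```

## The two models

`bayesddm` is built around two descriptions of how a two-alternative
perceptual decision unfolds within a trial, and the fact that they are the
same process in different coordinates.

**Pure drift-diffusion model (pDDM).** A scalar evidence state follows the
discretized Wiener process with drift,

$$y_t = y_{t-\Delta t} + v\,\Delta t + \sqrt{\Delta t}\, s\, \varepsilon_t,
\qquad \varepsilon_t \sim N(0, 1),$$

started at a bias $y_0$ and absorbed at symmetric bounds $\pm B$; the first
bound crossed selects the alternative, and the reaction time is the crossing
time plus a non-decision time $T_{nd}$ covering transduction and motor
latencies. `ddm_params()` holds $(v, s, B, y_0, \Delta t, T_{nd})$.

**Bayesian observer.** A generative description of the same trial. While
alternative $i$ is presented, the sensory stages deliver a noisy feature
value $x_t \sim N(\mu_i, \Delta t\,\sigma^2)$ (the *input process*; note the
mean does not scale with $\Delta t$ while the variance does). The observer
evaluates each observation under per-alternative *generative models*
$p(x_t \mid A_i) = N(\hat\mu_i, \Delta t\,\hat\sigma^2)$ and updates its
posterior belief recursively,

$$p(A_i \mid X_{1:t}) \propto p(x_t \mid A_i)\, p(A_i \mid X_{1:t-1}),$$

starting from a prior $p(A_i)$. A decision is made when a decision variable
reaches a bound: the posterior itself (bound $\lambda$), the log posterior
(bound $\log\lambda$), or — for two alternatives — the log posterior odds
$q_t = \log p(A_1 \mid X_{1:t}) - \log p(A_2 \mid X_{1:t})$ (bound
$\lambda^* = \log\frac{\lambda}{1-\lambda}$). `bayes_params()` holds
$(\mu_i, \hat\mu_i, \sigma, \hat\sigma, \lambda, p(A_i), \Delta t, T_{nd})$.
The internal uncertainty $\hat\sigma$ is not an extra noise source: it acts
as a gain on how strongly each observation moves the belief.

**Equivalence.** Substituting the Gaussian densities into the recursive
update shows that the log-odds increment is

$$q_t - q_{t-\Delta t} = \hat v + \hat s\, x_t, \qquad
\hat v = \frac{\hat\mu_2^2 - \hat\mu_1^2}{2\Delta t \hat\sigma^2},\quad
\hat s = \frac{\hat\mu_1 - \hat\mu_2}{\Delta t \hat\sigma^2},$$

which, with $x_t$ drawn from the input process, is exactly a pDDM step with

$$v = \frac{\hat\mu_2^2 - \hat\mu_1^2}{2\Delta t^2 \hat\sigma^2}
  + \mu_i\,\frac{\hat\mu_1 - \hat\mu_2}{\Delta t^2 \hat\sigma^2},
\qquad s = \sigma\,\frac{\hat\mu_1 - \hat\mu_2}{\Delta t\,\hat\sigma^2},
\qquad B = \lambda^*, \qquad y_0 = \log\frac{p(A_1)}{p(A_2)}.$$

This identity is exact per noise draw, not merely in distribution: feeding
the same $\varepsilon_t$ sequence to `simulate_bayes_trial()` and to
`simulate_ddm_trial()` with `bayes_to_ddm()` parameters reproduces the same
trajectory, choice and decision step. The package treats this matched-noise
identity as its central invariant and tests it to $10^{-10}$ per step. The
equivalence requires equal generative variances across alternatives;
`bayes_params()` therefore carries a single $\hat\sigma$, and translation of
unequal-variance models is refused rather than approximated. The three
decision policies are behaviorally identical when their bounds are linked by
$\lambda \to \log\lambda \to \log\frac{\lambda}{1-\lambda}$; they differ
only in the quantity a neural recording would have to track.

## Constraint sets and the scaling freedom

The observer has seven parameters against the pDDM's three, so translating a
fitted pDDM into observer language requires four constraints. Two standard
sets are implemented:

* **Symmetric means** (`ddm_to_bayes_symmetric_means()`): input and
  generative means are centered at $\pm\mu$ and $\pm\hat\mu$, and both
  uncertainties are fixed to a common value $\sigma = \hat\sigma = a$. Then
  $\mu = v\,\Delta t\,\sigma / s$ and $\hat\mu = s\,\Delta t\,\hat\sigma^2 /
  (2\sigma)$, and behavior is explained by the feature amplitudes. The
  signal-to-noise identity $v\,\Delta t / s = \mu / \sigma$ holds exactly.
* **Equal means** (`ddm_to_bayes_equal_means()`): the observer is assumed to
  know the feature means perfectly ($\hat\mu_i = \mu_i = \pm\mu$, fixed
  amplitude $\mu = 1$ by default). Then $\hat\sigma^2 = 2\mu^2 / (\Delta t^2
  |v|)$, $\sigma = \mu s / (\Delta t |v|)$, $\lambda = e^B/(1+e^B)$, and
  behavior is explained by input noise versus internal uncertainty. This is
  the set used by the fitting code, because it keeps the stimulus
  description fixed across conditions.

Both translations round-trip through `bayes_to_ddm()` to within $10^{-12}$
relative error, which the test suite checks on random draws.

Accuracy and reaction times constrain the pDDM only up to a common scaling
of $(v, s, B, y_0)$. On the observer side this freedom lives in the pair
(internal uncertainty, posterior bound) while $\sigma$ — a ratio of
diffusion to drift — is untouched. `rescale_to_bound()` applies the scaling
constant $c = \log\frac{\lambda'}{1-\lambda'} / B$ that moves a fit to a new
posterior bound $\lambda'$; $\hat\sigma$ scales as $1/\sqrt{c}$ and all
decisions are bit-identical under matched noise. The package fixes
$\lambda = 0.7$ as its default bound — intermediate between the theoretical
extremes 0.5 and 1, and a region where $\sigma$ and $\hat\sigma$ take
comparable magnitudes — and treats any other choice as a rescaling of the
same fit. The worked number reproduced by `scripts/acceptance.R` is exactly
this map: a fit with $\hat\sigma = 28.6$ at $\lambda = 0.7$ is the same
model as $\hat\sigma = 12.3$ at $\lambda = 0.99$.

## Simulators and numerical choices

* All inference runs in log space with the log-sum-exp construction;
  posteriors are exponentiated only for output. Posterior rows are
  normalized to $10^{-10}$ along entire trajectories.
* Bound crossings are checked after each update and are inclusive
  (`>=`); there is no within-step interpolation of the crossing time, so
  `decision_time = n_steps * dt` exactly. Ties at the bound are therefore
  resolved identically in both models, which the matched-noise identity
  requires.
* The response deadline (default 1.25 s) applies to the total reaction time.
  The simulators run at most `steps_to_deadline(dt, deadline)` updates (45
  at the default $\Delta t = 28.3$ ms); undecided trials and decided trials
  with `rt > deadline` are flagged as outliers and excluded from summaries
  by default (a switch retains them).
* Whole experiments are simulated by the vectorized log-odds recursion
  (`simulate_bayes_experiment()`), which is the observer itself written in
  its log-odds coordinates — identical to the per-trial recursion by the
  exactness above — and runs in step chunks so that very fine grids
  ($\Delta t = 10^{-4}$) stay within memory.
* `ddm_accuracy_closed_form()`, `ddm_mean_dt_closed_form()` and
  `ddm_var_dt_closed_form()` provide continuum-limit first-passage oracles
  (the variance expression solves the standard moment boundary-value
  problem). Discrete-time simulation converges to these as $\Delta t \to 0$,
  but with a known bias: the discrete path overshoots the bound by roughly
  $0.583\, s \sqrt{\Delta t}$ (the standard discrete-monitoring correction),
  which inflates mean decision times by about that amount times
  $\partial E[T] / \partial B$. At $\Delta t = 10^{-4}$, $v = s = B = 1$ this
  bias is $\approx 7$–$10$ ms — larger than the Monte-Carlo standard error
  of the mean at $10^5$ trials ($\approx 1.8$ ms), so the fine-grid
  mean-decision-time check in the test suite resolves the discretization
  bias of the simulator rather than sampling noise, and is expected to
  exceed a 3-standard-error band even though accuracy sits well within it.
  Halving the bias requires quartering $\Delta t$; we document the effect
  rather than interpolate crossings, keeping the simulator faithful to the
  discrete update rule.
* Priors map to the diffusion bias as $y_0 = \log\frac{p_0}{1-p_0}$
  (`prior_to_bias()`); a non-uniform prior reproduces the uniform-prior
  trajectory shifted by $y_0$, exactly.

## Trajectory averaging

`average_trajectories()` mirrors the analysis used to compare decision
variables against neural accumulation signals: per time point it averages a
decision variable over the trials still contributing, with standard errors
of the mean (SEM) for the shading. With `stop_at_bound = TRUE` a trial
contributes only data points strictly before its bound crossing, and the
curve is truncated once fewer than `min_trials` (default 12) trials remain.
Because a neural correlate of a decision variable carries an unknown gain
and offset, `rescale = TRUE` applies the affine map sending each variant's
starting value (from the prior) to 0 and its bound value to 1 — the minimal
map that removes the unknown scaling; any richer normalization would have to
assume more about the neural code than the model supplies.

## Fitting

**Quantile-weighted pseudo-likelihood.** Behavioral data are reduced to the
proportion correct and seven reaction-time quantiles (0.02, 0.05, 0.1, 0.3,
0.5, 0.7, 0.9) for correct and error responses separately
(`summarize_behavior()`, linear interpolation of order statistics — the
common type-7 estimator, a dialect choice). The objective is the Gaussian
pseudo-log-likelihood

$$L(\theta) = -w_{Acc}\,(Acc - Acc(\theta))^2 -
\sum_{e \in \{0,1\}}\sum_{i=1}^{7} w_{q_{e,i}}\,(q_{e,i} - q_{e,i}(\theta))^2,$$

with $\theta = (\sigma, \hat\sigma, T_{nd})$ under the equal-means
constraints at fixed $\lambda$, $\mu$, $\Delta t$. Predictions
$Acc(\theta), q_{e,i}(\theta)$ average 30 simulated experiments of 1100
trials each (`predict_summary()`); both counts are configurable and are
reduced in the package's own calibration checks (10 repetitions, see below).

**Weights.** `estimate_weights()` sets each weight to the inverse variance
of its statistic across 30 simulated repetitions of the experiment at a
reference parameter set chosen to show a generously large spread (default
$\sigma = 18.1$, $\hat\sigma = 28.6$, $T_{nd} = 0.42$ s, which yields
realistic accuracy near 0.9 and a broad RT distribution at the default
settings). Weights are estimated once and never updated during fitting —
they describe the precision of the observations, not of the model. One
numerical guard matters: simulated reaction times live on the lattice
$T_{nd} + k\,\Delta t$, so extreme quantiles can be identical across
repetitions and a raw inverse variance would diverge. The default variance
floor $(\Delta t / 2)^2$ caps every quantile weight at the resolution of the
time grid — differences finer than the grid are not meaningful — while the
accuracy weight, being dimensionless, has a separate (tiny) floor.

**Sampler.** `fit_mcmc()` draws from the pseudo-posterior with an adaptive
Metropolis sampler with delayed rejection (DRAM style): a random-walk
proposal whose covariance is re-estimated from the chain history
($2.38^2/d$ scaling plus a small jitter), a global scale adapted toward the
0.234 acceptance target, and a second-stage proposal shrunk by 0.25 when the
first stage rejects. Priors are wide zero-mean Gaussians (sd 400 on
$\sigma$ and $\hat\sigma$, 10.2 s on $T_{nd}$), restricted to positive
values by proposal rejection. Defaults: 3000 samples initialized at
$\sigma = \hat\sigma = 2$, $T_{nd} = 0.42$ s, burn-in 1000, keep every 10th
sample — 200 retained draws. Because the objective is stochastic, the
current state's log-posterior is re-evaluated each iteration by default; a
stored lucky evaluation would otherwise freeze the chain, and the refresh
folds the objective noise into the reported posterior spread. A
common-random-numbers mode removes objective noise entirely for testing.
Split-half $\hat R$ and an autocorrelation ESS are reported per parameter;
doubling the prior widths moves posterior means by less than a posterior sd
(prior-robustness is cheap to re-run with the `priors` argument).

**EZ closed form.** `fit_ez()` inverts proportion correct, mean and variance
of correct RTs into $(v, a, T_{nd})$ (bound $B = a/2$) under the fixed
diffusion-scale convention $s = 0.1$, using the standard logit-based closed
form; `ddm_summary_closed_form()` supplies the exact forward statistics, so
the inversion round-trips to machine precision. Degenerate accuracies (0,
0.5, 1) are rejected unless the standard $1/(2n)$ edge corrections are
enabled. An optional `lambda` argument chains the fit through
`rescale_to_bound()` and `ddm_to_bayes_equal_means()` into observer
parameters, which is the full pipeline for interpreting a published pDDM fit
in uncertainty terms.

## The synthetic-data generator

`generate_experiment()` emulates the structure of a multi-condition
two-alternative forced-choice study: named conditions with their own
parameter sets, 1100 trials per condition by default matching the modeled
experiment's pooled per-condition count, a balanced stimulus schedule
(randomized by the config seed), a 1.25 s response deadline with outlier
flagging, and lossless CSV trial-table I/O with strict parsing. What it does
*not* emulate matters for interpreting green tests: real data contain
across-trial drift and bias variability, contaminant responses, learning and
fatigue trends, and subject heterogeneity — none of which are in the pure
model. Passing recovery tests therefore show that the fitting machinery is
self-consistent at realistic sizes, not that the pure model suffices for any
particular dataset.

## Calibration checks and problem sizes

The test suite runs (sizes chosen to keep the default suite within a few
minutes while leaving Monte-Carlo error well below the tolerances checked):

* the matched-noise accumulation identity on 1000 random parameter sets
  with 100-step noise sequences, at $10^{-10}$ per step;
* policy agreement on 10^4 trials across 20 random parameter sets;
* translation round-trips on 1000 random draws at $10^{-12}$;
* fine-grid continuum checks at $\Delta t = 10^{-4}$ with $10^5$ trials
  (see the discretization-bias note above);
* a parameter-recovery run at the full 1100-trial experiment size with a
  reduced chain (1000 samples, 10 prediction repetitions per evaluation),
  checking that the generating $(\sigma, \hat\sigma, T_{nd})$ fall inside
  the central 95% of the retained samples.

## Known limitations

* Two alternatives only for translation and the log-odds policy (posterior
  inference itself accepts $M \ge 2$); no race-model generalization.
* No across-trial parameter variability, collapsing bounds, or time-varying
  stimuli; the equivalence as implemented requires equal generative
  variances.
* The pseudo-likelihood is a weighted-moments objective, not a full
  first-passage likelihood; its posterior spread inherits the weight
  choices, and error-response terms are dropped (with a warning) when fewer
  than 10 error trials are observed.
* Mean/variance closed forms assume an unbiased start ($y_0 = 0$); the EZ
  inversion additionally assumes no deadline truncation, so applying it to
  heavily truncated data biases $T_{nd}$.
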