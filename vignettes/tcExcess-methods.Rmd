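---
title: "Methods: counterfactual excess-event estimation and risk prediction for tropical cyclones"
author: "tcExcess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: counterfactual excess-event estimation and risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Tropical cyclones (TCs) cause health events — deaths, respiratory and
cardiovascular hospitalizations — well beyond what post-storm surveillance
attributes to them. tcExcess estimates, for each storm and each exposed
county, the *excess* number of events during the storm period: the observed
count minus the count that would have occurred had the storm not hit. That
counterfactual is never observed for exposed counties, so it is imputed
from the space-time structure of the surrounding panel. A second,
deliberately separated model then relates the estimated excess rates to
storm and community features and predicts impacts of future exposures.

# Panel construction

Each storm is treated as a quasi-experiment on a county-by-interval panel.

* **Exposure.** A county is *treated* for a storm when its maximum
  sustained windspeed at the population mean center reaches gale force,
  17.4 m/s; otherwise it is a *control*.
* **Study period.** Ten contiguous two-week intervals. The final
  (treatment) interval is pinned to begin 2 days before and end 11 days
  after the storm's first US approach. The remaining nine intervals are
  anchored backwards from it, so the window opens 128 days before the
  approach. (Counting 129 days of lead plus 11 days of tail inclusively
  spans 141 days, one more than 10 × 14; we resolve the discrepancy by
  holding the treatment interval — the most consequential definition —
  exact and letting the backward anchoring set the opening day.)
* **Eligibility.** A county is excluded if its at-risk population is
  below 100 or if it has 5 or fewer events of *any* studied outcome over
  the study period (small counts make baseline trends unstable). Controls
  are kept only within 150 miles (great-circle, haversine with Earth
  radius 6371 km) of a retained treated county, because distant controls
  carry non-comparable seasonal trends. The exclusion log records the
  first rule each dropped county triggered; the retained set is invariant
  to the order in which rules are applied. A storm qualifies only with at
  least 1 treated county, 20 analytic counties in total and 5 controls.
* **Event-count minima** are evaluated over the full ten-interval study
  period, across all studied outcomes, and a county failing for any
  outcome is dropped from all analyses of that storm — one analytic set
  per storm.
* **Missing daily counts** inside the study period are a hard error by
  default (a `"zero"` policy exists but silently zero-filling biases
  baselines downward, so it is opt-in).
* **Offsets.** Populations are taken constant over the 20-week window
  (denominators move slowly at this timescale); a full matrix of
  time-varying offsets is accepted when available.

The result is a `StormPanel` (a `SummarizedExperiment`): counts
\(Y_{it}\), a treatment mask \(D_{it}\) that is 1 exactly for treated
counties in the treatment interval(s) \(t \ge T_0\) (here \(T_0 = T\)),
and offsets \(p_{it}\).

# The causal stage: matrix completion for counts

The counterfactual matrix \(\mathbf{Y}(0)\) equals the observed panel
except at masked cells. Those cells are imputed with a low-rank
latent-factor model using the epidemiological log-link convention:

\[
\log E[Y_{it}(0)] \;=\; \alpha + \gamma_i + \psi_t +
\mathbf{U}_i^\top \mathbf{V}_t + \log p_{it},
\qquad Y_{it}(0) \sim \mathrm{NB}(\mu_{it}, \phi),
\]

with \(\mathrm{Var} = \mu + \mu^2/\phi\) (mean–dispersion form). The
two-way effects absorb county levels and common temporal shocks; the
\(K\)-dimensional inner product absorbs space-time structure — including
trends induced by unmeasured time-varying confounders — learned from
control counties at all times and treated counties before treatment.
Masked cells are *excluded from the likelihood*, so observed
storm-period outcomes of treated counties cannot contaminate their own
counterfactuals (verified bit-for-bit in the tests).

Fitting is by MCMC (JAGS), with the negative binomial coded as its exact
Poisson–gamma mixture. Defaults: 2 chains, 1000 post-warmup draws each,
matching the operating point we recommend for real analyses; the test
suite uses shorter chains sized so that Monte Carlo error stays well
below the tolerances being checked.

**Priors.** "Uninformative" is concretized as weakly informative:
\(\alpha, \gamma_i, \psi_t \sim N(0, 5^2)\); factor entries
\(\sim N(0,1)\); and a half-normal(0, 5) prior on \(1/\sqrt{\phi}\), so
the Poisson arises as the small-scale limit. Factor priors of scale 1
stabilize the unidentified factorization while leaving predictions
data-driven.

**Identification and convergence.** The individual factors are not
identifiable and are left unconstrained on purpose: identifiability
constraints (e.g. triangular loadings) slow mixing and can hurt
prediction, while every quantity we report is a function of the
identified cell means. Convergence is therefore gated on the split-R̂ of
the masked cells' predicted means (threshold 1.05), not on raw
parameters; a violation produces a warning carried in the fit's
diagnostics, never a silent pass.

**Choice of K.** `chooseKByPCA()` is advisory: it reports the smallest
\(K\) whose mean cumulative variance explained across the panels' centered
log-rate matrices reaches a target (default 70%). We run the PCA on log
rates, \(\log((Y+0.5)/p)\), because the model is linear on that scale;
raw counts would conflate population size with structure. The package
default is \(K = 4\).

**Counterfactual draws.** For each posterior draw \(m\) and masked cell,
one sample \(Y^{(m)}_{it}(0) \sim \mathrm{NB}(\mu^{(m)}_{it},
\phi^{(m)})\). Posterior-predictive, not plug-in: dispersion and
parameter uncertainty both propagate.

# Estimands

With a single treated interval, the individual excess events (IEE) for
treated county \(i\) are \(\theta_i^{(m)} = Y_{iT} - Y^{(m)}_{iT}(0)\)
per draw (negative values — protective effects — are legitimate), and the
individual excess rate is \(\theta^{*(m)}_i = 100\,000\,
\theta^{(m)}_i/p_{iT}\). Storm-level excess events sum \(\theta\) over
the storm's counties. For the storm-level *rate* two readings exist; the
default pools denominators (\(100\,000 \sum_i \theta_i / \sum_i p_{iT}\)),
which weights counties by population as a single-region rate should, and
`rate = "mean"` exposes the unweighted alternative. Study-wide, the total
excess events (TEE) draw is the grand sum over all storms and counties,
and the average excess rate (AER) draw is the *unweighted* mean of
\(\theta^*\) over all county-level exposures (each storm-county pair
counts once). Intervals are equal-tailed 95% posterior quantiles. Every
summary draw is an exact deterministic function of the \(\theta\) draws,
so summaries recompute bit-for-bit from stored counterfactual draws.

# The predictive stage and Bayesian modularization

The second stage regresses excess rates on exposure features
\(X_{si}\) (windspeed, duration of winds above 20 m/s, year, exposure
count, socioeconomic covariates — the schema is user-defined):

\[\theta^{*}_{si} = g(X_{si};\beta) + \varepsilon_{si}.\]

This model is *associational by design* — it need not correspond to any
true data-generating mechanism — so it is treated as a suspect component
and **modularized**: for each causal draw \(m\), the linear model is
conditioned on \(\{\theta^{*(m)}_{si}\}\) and exactly one posterior
sample \(\beta^{(m)}\) is retained. Draw \(m\) of every storm is paired
by index (equal draw counts are enforced at assembly). Information flows
uni-directionally: first-stage uncertainty reaches \(\beta\), but the
predictive model can never influence the causal fits — the causal
outputs are bit-identical whether or not the second stage runs. Per-storm
causal models share no parameters, so they too are mutually modularized
and can be fit in parallel with per-storm seeds expanded deterministically
from one master seed.

**Exact conjugate update.** Because \(g\) is linear-Gaussian, we use the
normal–inverse-gamma conjugate family and draw each \(\beta^{(m)}\)
*exactly*: \(\sigma^2 \sim \mathrm{IG}(0.01, 0.01)\),
\(\beta \mid \sigma^2 \sim N(0, 100\,\sigma^2 I)\) on standardized
design columns. This replaces a per-draw short MCMC entirely — no warmup
tuning, no convergence question, and refitting the model 2000 times is
instantaneous. The \(\sigma^2\)-scaled coefficient prior is what makes
the update exact while keeping the same weak-information intent as a
fixed-scale normal.

**Splines.** Windspeed (and year) effects are flexibly modeled with
restricted cubic splines in the standard truncated-power form — linear
beyond the boundary knots, with 4 knots at the 5/35/65/95 percentiles of
the training values by default. Knots, column centers and scales are
frozen in a schema at training time and reused at prediction time.

**Plug-in comparator.** `fitPlugin()` fits the same model once to the
posterior-mean excess rates. It exists only to quantify what ignoring
first-stage uncertainty would claim: across simulations with nonzero
first-stage variance, modular intervals are strictly wider on average
(and the two coincide exactly when the first-stage posterior is
degenerate).

**Prediction.** For new feature vectors, one draw
\(\theta^{*(m)}_{\mathrm{new}} = Z_{\mathrm{new}}\beta^{(m)} +
N(0, \sigma^{(m)2})\) per retained draw gives a posterior-predictive
distribution whose spread reflects causal uncertainty, coefficient
uncertainty and residual heterogeneity.

**Model selection.** `crossvalidateModelMenu()` ranks candidate
specifications by K-fold held-out squared error against the
posterior-mean rates (deterministic folds given a seed). Squared error on
the rate scale is a pragmatic default; the menu, not the loss, is the
interface.

# The synthetic-data generator

`simulateStudy()` generates multi-storm panels that are *exact draws from
the causal model class*: populations log-normal (median 50 000,
\(\sigma_{\log} = 0.5\)); \(\alpha = \log(100/10^5)\) — a baseline of 100
events per 100 000 per two-week interval, giving mean cell counts near
50, large enough that discreteness is mild but small enough that NB noise
matters; county and interval effects of SD 0.3 and 0.2; a rank-2 factor
structure of scale 0.3; NB dispersion \(\phi = 25\) (variance ≈ 3× mean
at \(\mu = 50\)). Treated windspeeds are 17.4 m/s plus a gamma(2, scale
6) excess (median ≈ 27 m/s, occasional major hurricanes).

Treatment effects are injected additively on the count scale with
rate-scale targeting: the injected count is
\(\mathrm{round}(X^\top\beta_{\mathrm{true}} \times p/10^5 + N(0, 5))\),
clamped so \(Y(1) \ge 0\) (clamping is logged; the *realized*
\(\theta = Y(1)-Y(0)\) is recorded as truth, so truth stays exact even
when clamped). Default \(\beta_{\mathrm{true}}\): 2 per 100 000 per m/s
of windspeed with intercept −14.8, i.e. an expected excess rate of 20
per 100 000 at the gale-force threshold rising to ≈ 80 at 47 m/s —
magnitudes comparable to the upper range of county-level excess rates
reported for respiratory outcomes in Medicare-scale data.

Because baselines are exact model draws, calibration tests on held-out
cells check the *inference machinery*, not model adequacy. What the
generator deliberately does not emulate: spatial correlation of storm
tracks, population displacement, secular trends longer than the study
window, outcome-to-outcome dependence, and reporting artifacts. Passing
tests therefore demonstrate correctness of the estimator under its own
assumptions, not robustness to their violation.

# Numerical choices and problem sizes

* NB sampling is the exact Poisson–gamma mixture; `phi` is parameterized
  through \(1/\sqrt{\phi}\) truncated at \(10^{-6}\) to keep the Poisson
  limit reachable without overflow.
* Degenerate inputs fail loudly: constant matrices in the PCA, rank
  deficiency and missing features in the design, non-positive offsets
  and denominators everywhere.
* Ties in spline knots (too few distinct values) are an error, not a
  silent collapse.
* Per-storm, per-stage seeds come from a fixed integer congruence
  (`expandSeed`), all below \(2^{31}\), so parallel and serial execution
  give identical results.
* Validation sizes: held-out calibration uses 4 panels of 60 counties
  with a 25 × 5 masked block (500 cells); effect recovery uses 40 storms
  × 10 treated counties (400 cells); end-to-end coefficient recovery uses
  20 replicate studies of 3 storms × 30 counties; the oracle comparison
  uses one 30 × 10 panel against a maximum-likelihood two-way NB fit.
  These sizes keep each check's Monte Carlo error a few times smaller
  than the property being asserted.

# Known limitations

* \(K\) is user-set; the PCA tool is advisory and data-driven selection
  of \(K\) is out of scope.
* A common treatment start \(T_0\) per storm; staggered adoption is not
  supported.
* The predictive stage is linear-Gaussian on the rate scale; heavy-tailed
  or heteroscedastic alternatives would need a different \(g\).
* Exposures are weighted equally in the predictive likelihood; no
  precision weighting by first-stage uncertainty.
* Real-claims features (the full socioeconomic predictor list) are the
  user's to supply; the package fixes only the schema mechanics.

# A minimal session

```{r example}
library(tcExcess)

study <- simulateStudy(simConfig(S = 3, N = 30, nTreated = 10, seed = 1))
res <- runPipeline(study$panels, study$features,
                   mcSpec = mcModelSpec(K = 4, drawsPerChain = 500,
                                        warmup = 800),
                   predSpec = predictiveModelSpec(linear = "windspeed"),
                   seed = 1)
res$study$summary          # TEE / AER with 95% intervals
coefSummary(res$modular)   # windspeed coefficient, uncertainty propagated

## predict a new exposure profile
predictNew(res$modular, data.frame(windspeed = 40))
```
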