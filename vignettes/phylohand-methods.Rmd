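---
title: "Phylogenetic meta-analysis of handedness: models and methods"
author: "phylohand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic meta-analysis of handedness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its statistics: the model
and its assumptions, the parameters that matter and their defaults, what
the synthetic-data generator does and does not emulate, the numerical
choices, and the known limitations. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The scientific problem

Species-level handedness effect sizes — the mean handedness index (MHI,
direction, in $[-1, 1]$) and the mean absolute handedness index (MABSHI,
strength, in $[0, 1]$) from the standardized tube task — come from many
published studies of unequal precision, across species that share
evolutionary history. Treating species means as independent, equally
precise data points both understates uncertainty and conflates
phylogeny with ecology. The package therefore combines a random-effects
meta-analysis (records weighted by their known sampling variance, with
between-study heterogeneity) with a phylogenetic mixed model (species
effects correlated according to shared branch lengths).

## 2. Model

For record $k$ of species $s(k)$ from study $g(k)$:

$$y_k \sim \mathcal N\!\left(x_{s(k)}^\top\beta + a_{s(k)} + u_{s(k)} +
b_{g(k)},\; se_k^2\right)$$

$$a \sim \mathrm{MVN}(0, \sigma_p^2 C), \qquad
u_i \sim \mathcal N(0, \sigma_s^2), \qquad
b_g \sim \mathcal N(0, \tau^2)$$

* $C$ is the **phylogenetic correlation matrix**: shared root-to-MRCA
  path length for each species pair, divided by the maximum root-to-tip
  depth. Under Brownian motion this is the expected trait correlation.
  On fossil-bearing (non-ultrametric) trees the matrix is still scaled
  by the maximum *extant* depth, so extinct tips get diagonal entries
  below one — they had less time to accrue variance, which is exactly
  the Brownian-motion expectation.
* $a$ captures heritable, tree-structured species differences; $u$
  captures species idiosyncrasies (niche, environment) unrelated to the
  tree; $b$ captures study-level heterogeneity (protocol, colony,
  sampling), grouped by publication.
* The measurement variance $se_k^2$ is **known per record**, which is
  what makes the model meta-analytic: precise studies pull harder.

Priors: $\beta_j \sim \mathcal N(0, 1)$ — weakly informative given that
all continuous predictors are standardized and both responses live in
$[-1,1]$ — and half-Cauchy$(0, 0.05)$ on each of
$\sigma_p, \sigma_s, \tau$: non-negative, concentrated near zero but
heavy-tailed enough not to rule out large components.

**Phylogenetic signal** is Lynch's
$h^2 = \sigma_p^2 / (\sigma_p^2 + \sigma_s^2 + \tau^2)$, computed per
posterior draw (`lynch_h2()`). The known $se_k^2$ are excluded from the
denominator because the lambda-equivalence of $h^2$ holds among the
latent components; the alternative denominator without $\tau^2$ is a
function argument (`include_tau = FALSE`). Both conventions are reported
by `summary()` users who want them; the default includes $\tau^2$.

**Bayesian $R^2$** is `Var(pred) / (Var(pred) + resid var)` per draw:
the `fixed_only` variant uses $x^\top\beta$ with residual variance
$\sigma_p^2+\sigma_s^2+\tau^2+\overline{se^2}$; the `conditional`
variant uses the full linear predictor with residual variance
$\overline{se^2}$. Which one a published single number corresponds to is
often ambiguous, so both are computed.

## 3. Sampler

All location parameters $(\beta, a, u, b)$ are jointly Gaussian given
the three SDs, so the package draws the entire block **exactly** in one
Gibbs update per iteration: the data part of the normal equations is
constant and precomputed; only the prior-precision blocks change. This
eliminates the notorious slow mixing between the intercept and the mean
of the species effects. The log SDs are updated by stepping-out slice
sampling, followed by an interweaved non-centered update (effects
whitened, SD redrawn against the data likelihood) that breaks the
funnel-shaped coupling between effects and their SD. The core is
C++ (RcppArmadillo); R's RNG is used throughout, so `set.seed()`
reproducibility holds exactly.

Defaults mirror standard practice for this model class: 2 chains,
12,000 iterations with 4,000 warmup. The test suite and the acceptance
script run reduced chains (2 × 1,500–3,000 retained draws) — all
problem sizes used by the tests are stated in the tests themselves and
were chosen so that each fit takes seconds; results at full settings
differ only in Monte-Carlo error.

Correctness anchors (all in the test suite):

* with all SDs frozen at zero the sampler must reproduce closed-form
  conjugate Gaussian posteriors for $\beta$ to within 3 Monte-Carlo SEs;
* simulation-based calibration: 95% intervals for $\beta, \sigma_p,
  \sigma_s, \tau$ cover the generative values at 85–100% over 40
  replicates of the default synthetic world;
* convergence diagnostics are the rank-normalized split-$\widehat R$ and
  Geyer-type bulk/tail ESS, checked against analytic white-noise and
  AR(1) cases.

One caveat found by the calibration study and worth stating plainly: the
posterior mean of the **per-draw ratio** $h^2$ is pulled toward the
ratio's symmetric prior mean (1/3) whenever the phylogenetic /
non-phylogenetic split is weakly identified, which at 41 species it is.
The individual variance components are recovered essentially without
bias, and the plug-in ratio of their posterior means sits on the
generative value; the per-draw ratio's mean sits 0.1–0.15 below it.
This is a property of ratio posteriors at this design size, not of the
sampler, and it persists at much larger study counts per species. Users
comparing $h^2$ across analyses should compare like with like.

## 4. Data model and transforms

Records are filtered to the tube task; rows lacking an effect or its SE
are dropped with a logged count; duplicated (study, species, response)
rows are rejected as probable double-counting between source
compilations. Species names are whitespace/underscore-normalized and an
alias map (e.g., a genus-level pooled label mapped to the congeneric
tree tip with most data) is applied to both records and covariates.

Covariate transforms, with constants stored for reuse on new species:

* continuous traits (body mass BM, endocranial volume ECV, intermembral
  index IMI, body-mass dimorphism DIM): $\log_{10}$ then z-score
  (sample SD);
* proportions (FRUIT, DIET): clamped to $[\varepsilon, 1-\varepsilon]$
  ($\varepsilon = 5\times10^{-4}$, finite logits for observed 0/1),
  logit, then z-score;
* categoricals: dummies against declared references — arboreal
  (substrate), solitary (social system), absence (binaries), lowest
  level (competition level, kept categorical because no scoring is
  defensible).

Standardization constants are recomputed on the analysis set actually
fitted (e.g., after excluding a species), and **reused unchanged** when
projecting fossils — predictions must live on the fitted scale. A
covariate more than 3 SD outside the training range triggers an
extrapolation warning, not an error.

## 5. Imputation

Missing IMI/DIM values are imputed jointly with body mass under a
multivariate Brownian-motion model: the vectorized species-by-trait
matrix is Gaussian with covariance $R \otimes C_{\mathrm{raw}}$ (trait
rate matrix Kronecker the unscaled shared-path matrix). $R$ and the root
means are estimated by maximum likelihood — $R$ through a log-Cholesky
parameterization so the optimization is unconstrained — and each missing
cell is filled with its conditional expectation given all observed
cells, with the conditional variance recorded. Imputation happens on the
$\log_{10}$ scale (the scale the downstream model uses; the raw/log
choice is not dictated by anything upstream, and the log scale keeps the
Gaussian assumption tenable for ratio-type traits) and on the maximum
clade credibility tree only; the completed table is then reused across
all model trees. Imputed values are treated as known downstream — a
deliberate two-step simplification, listed under limitations.

## 6. Model selection

The hypothesis battery is a YAML file mapping named covariate sets to
responses; the engine treats it purely as data. Each hypothesis is
fitted over every tree in the supplied set; posterior summaries are
averaged **across trees** (averaging summaries, not pooling draws, so a
multimodal tree set cannot masquerade as extra precision; pooling is a
config switch in spirit but summaries-averaging is the implemented
default). PSIS-LOO is computed on the MCC-tree fit.

PSIS-LOO follows the standard recipe: per left-out record, importance
ratios $\propto 1/p(y_k \mid \theta)$, a generalized-Pareto fit to the
largest 20% of ratios (profile-posterior estimator), tail replacement by
expected order statistics truncated at the raw maximum, and an **exact
refit** for any record with shape diagnostic $k > 0.7$. The test suite
pins the implementation to a brute-force exact-LOO oracle (and the
smoothing matches an independent reference implementation to ~0.01 in
pointwise elpd). Model ranking flags "no meaningful winner" when the
top-two difference is below 4 and below twice its SE.

Model reduction removes one predictor at a time — the non-credible
predictor with the smallest $|\mathrm{median}|/\mathrm{sd}$ across its
design columns; a categorical predictor is removable only when every
level is non-credible and is removed as a block — refitting until all
remaining predictors are credible or none remain. The one-at-a-time
order makes the trace reproducible and conservative.

## 7. Outlier test and fossil prediction

For a species held out of the fit, the package draws, per retained
posterior draw, the conditional Brownian-motion effect
$$a^* \mid a \sim \mathcal N\!\left(c^\top C_{oo}^{-1} a,\;
\sigma_p^2 (C_{**} - c^\top C_{oo}^{-1} c)\right),$$
adds the fixed effects at the target's (stored-scale) covariates, a
fresh non-phylogenetic effect $u^* \sim \mathcal N(0, \sigma_s^2)$, and
meta-analytic noise at the supplied `se_target`. The observed value's
percentile in this predictive distribution, and whether it falls outside
the 95% interval, constitute the outlier test: a flagged species has
evolved further than its tree position and covariates can explain. The
study-level effect is not drawn separately — the meta-analytic component
enters through `se_target` (the precision-weighted pooled SE of the
species' records is the natural choice, provided by `pooled_se()`).

Fossil prediction is the same conditional-Gaussian step applied
**jointly** to all fossil tips of a grafted tree (so predictions carry
the fossils' mutual correlation), with fresh $u^*$ per draw — fossils
have no estimable idiosyncratic effect, so it is marginalized — and
measurement noise at a user-supplied (e.g., human-level) SE. Predictions
are *not* truncated to the response bounds: the fitted model is a
Gaussian identity-link model, values slightly outside the bounds are
meaningful model output near boundary species, and truncating would
silently change the estimand; a warning is emitted instead.

Grafting replaces the base clade spanned by the shared taxa with the
calibrated addon subtree, rescaling the addon so shared extant tips keep
their base depths exactly; fossil tips land at proportionally shallower
depths and the result is non-ultrametric by design. Depths of all tips
outside the clade are untouched (asserted exactly in tests). Which
consensus rule the backbone "should" use is genuinely open; the package
uses its own MCC tree (sum of log clade frequencies, ties to the lowest
index) for both imputation and grafting, cross-checked against an
independent MCC implementation.

## 8. Synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the rest of the package is validated under:

* 41 species on birth–death trees (birth 0.1, death 0.05 per lineage)
  rescaled to root depth 40 — the approximate crown age, in Myr, of the
  clade being emulated;
* 1–3 studies per species and 10–40 individuals per study, giving
  roughly 2,000 individuals in expectation, matching the size of the
  empirical corpus;
* per-study SE $= 0.6/\sqrt{n}$ — an individual-level handedness-score
  SD of about 0.6;
* latent SDs $(\sigma_p, \sigma_s, \tau) = (0.25, 0.19, 0.16)$:
  variance shares (0.5, 0.3, 0.2) and $h^2 = 0.5$, in the region
  reported for these traits, with a total species-level SD (~0.35) that
  reproduces the observed spread of species means without violating the
  response bounds;
* continuous covariates are generated as correlated Brownian motion on
  the same tree (so covariates carry realistic phylogenetic structure —
  one consequence, visible in the calibration study, is that per-dataset
  fixed-effect estimates scatter more than naive i.i.d. intuition
  suggests); categorical covariates follow a symmetric Markov switch
  along branches;
* responses are clipped to their bounds, with clip events counted in
  the truth ledger (about 2–3% of records under the defaults; a
  strength-type world centered at 0.66 uses half the latent spread,
  matching the compressed range of strength values near the upper
  bound, to keep clipping negligible);
* an optional outlier species receives a fixed post-hoc shift, recorded
  in the ledger.

The outlier-calibration studies run in an explicitly parameterized world
($\sigma_p = 0.2$, $\sigma_s = 0.1$, $\tau = 0.08$, SE constant 0.5,
2–3 studies of 20–40 individuals): chosen so that a +0.7 shift — the
magnitude separating the human handedness direction from its
phylogenetic expectation — is an unambiguous (>4 SD) outlier under the
generative predictive spread, making "≥90% detection, ~5% false flags"
a sharp, testable property rather than a power lottery.

What the generator does **not** emulate: individual-level trial
sequences, publication bias, correlated missingness, study-level
covariates, multi-species publications (each synthetic study belongs to
one species), or non-Brownian trait evolution. Passing tests therefore
certify the estimation machinery under the stated generative model, not
the field validity of any particular empirical conclusion.

## 9. Numerical choices

* $C$ gets diagonal jitter $10^{-8}$ before inversion (zero-length
  branches make it singular); the imputation and kriging oracles use
  $10^{-10}$.
* MCC ties break to the lowest input index; reduction removes exactly
  one predictor per round; all derived seeds are taken modulo
  $2^{31}-19$ to stay in integer range.
* Proportion clamping $\varepsilon = 5\times10^{-4}$; degenerate inputs
  (all-missing trait, non-positive trait passed to $\log_{10}$,
  non-monophyletic graft, heterogeneous tip sets) are errors that name
  the offending species/trait/tree.
* The BM optimizer starts from pairwise-complete moment estimates
  (eigenvalue-floored to PD), runs Nelder–Mead then BFGS, and restarts
  from jittered starts on non-convergence, carrying the best value.

## 10. Limitations

* Imputed covariates are fixed downstream; their predictive variance is
  reported but not propagated into the regression.
* The hypothesis battery shipped in `inst/extdata/battery.yaml` is a
  configurable reconstruction of the usual eco-evolutionary hypothesis
  sets; it is data, meant to be edited, not a canonical registry.
* The hominin tree and covariates shipped under `inst/extdata/` are
  **synthetic** stand-ins with schematic (though palaeontologically
  plausible) dates and values, for testing the grafting/prediction
  machinery offline; real analyses should substitute a published
  calibrated tree and measured covariates.
* Responses are modeled as unbounded Gaussians; this is a good
  approximation away from the bounds and is exactly the assumption the
  clipping diagnostic monitors.
* The between-study effect is grouped by publication; grouping by
  (publication × species) would be a one-line change in the frame
  builder but is not currently a config switch.
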