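---
title: "Methods: driver attribution for contaminant time series in herring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: driver attribution for contaminant time series in herring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herringdrivers)
```

## Scope and model

The package implements a retrospective attribution workflow for annual
contaminant concentrations in a monitored fish population. The statistical
model underlying the regression stage is a linear driver model on the
detrended, standardized scale:

$$ y_t = \sum_j \beta_j \, x_{j,\,t-\ell_j} + \varepsilon_t $$

where $y_t$ is the z-scored, detrended annual (log) geometric-mean
concentration, $x_j$ are z-scored, detrended annual predictors, $\ell_j
\in \{0,\dots,5\}$ are lags identified by cross-correlation screening, and
$\varepsilon_t$ is treated as independent noise (checked afterwards by a
Ljung–Box test). With ~20–24 annual observations and ~14 candidate
predictors, ordinary least squares is ill-posed; partial least squares
(PLS1 via NIPALS) extracts a small number of latent components and is the
estimator throughout.

Key assumptions, stated plainly:

* concentrations are log-normal-like within a year, so the geometric mean
  is the annual location estimator;
* confounding by body size is linear and removable by the covariate
  adjustment $\mathrm{Var}_{adj} = \mathrm{Var} + A(\bar{TL} - TL)$;
* shared linear time trends are nuisance structure — associations are
  interpreted on departures from trend only;
* driver effects are linear, additive, and at most 5 years lagged;
* residual independence across years (tested, not assumed silently).

## Why the response is modelled on the log scale

The geometric mean equals $\exp(\overline{\log x})$: its logarithm *is*
the mean log-concentration. Additive driver effects on a positive
concentration are multiplicative, i.e. additive in logs, so the pipeline
models `log(geometric mean)` by default (`analysis_config(log_response =
TRUE)`). For series with modest interannual amplitude (±20–30%, which is
what real monitoring series and the generator defaults produce) the
z-scores of the raw and the log series are nearly identical and the choice
is immaterial; for large amplitudes the raw scale distorts a linear latent
model through the curvature of the exponential. During development this
distortion was large enough under early, too-large generator amplitudes to
scramble driver ranking even without noise — which is why both the
amplitudes and the scale convention are now fixed as they are.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `alpha` | 0.05 | — | the only significance level the workflow uses (adjustment gate, segment slopes) |
| `vip_threshold` | 0.7 | — | VIP retention cut in backward elimination |
| `max_lag` | 5 | years | life span of the sampled fish bounds plausible lagged exposure |
| `n_perm` | 199 | — | permutation count; p-values resolve to 1/200 = 0.005 |
| `ncomp_max` | 5 | — | upper bound on latent components (n ≈ 20 supports no more) |
| component rule | PRESS within 5% of min, smallest A | — | parsimony reading of "minimum number of components" under LOO |
| `beta` | 3.4 | permil | producer Glx–Phe offset for trophic position (literature convention; echoed into reports) |
| `tdf` | 7.6 | permil | Glx/Phe trophic discrimination factor (same) |
| collinearity threshold | 0.8 | \|r\| | conventional acceptance cut for PLSR predictor sets |
| quality gate | R²Y > 0.7 and Q² > 0.4 | — | reporting rule for explanatory/predictive adequacy |

All of these sit in `analysis_config()`; the YAML loader
(`read_analysis_config()`) accepts the same keys.

## The synthetic world

`synthetic_config()` defaults describe one fixed stated world, chosen once:

* 24 annual cohorts (1995–2018), 12 fish per year; total length
  truncated-normal, mean 17.7 cm within 15–19 cm; ages 3–5 assigned from
  TL quantile bins with jitter so that an age~TL regression is strongly
  significant (the adjustment pathway is exercised) without simulating
  growth;
* 14 annual predictors named after the field's usual candidate set, each a
  linear trend (optionally with a single continuous slope change) plus
  white noise (AR(1) noise is available as an option because the true
  noise structure of monitoring series is unknown; nothing asserts which
  is real);
* three true drivers with log-scale effects `d15n_range` +0.2, `fca` −0.2
  and `biovolume` +0.2 acting at lag 1 — equal magnitudes, because nothing
  in the stated design privileges one driver — against annual process
  noise of SD 0.05 log-units and individual-fish noise 4× that (which
  averages down by √12 in the annual mean);
* a −0.03/yr log trend (roughly a halving over the series, matching the
  observed declines) and a small age effect (+0.02 log-units per year of
  age);
* per-fish bulk isotopes from a fixed bivariate normal (drives the SEA
  metrics); missing years produce no rows at all.

What the generator does **not** emulate: mechanistic bioaccumulation,
food-web feedbacks, nonlinear or interactive driver effects, drifting
isotope baselines, measurement censoring in the response, or spatial
structure. A green recovery test therefore establishes that the pipeline
recovers linear, additive, possibly-lagged drivers at realistic
monitoring-series dimensions — not that the method is robust to violations
of those assumptions.

## Numerical conventions

* **Breakpoint scan**: candidate splits leave at least
  `max(3, ceil(0.15 n))` observations per segment; the reported
  `breakpoint_year` is the first year of the second segment. A continuous
  noiseless kink at year $b$ is fit exactly by two adjacent splits, so RSS
  ties are resolved toward the earlier year using a relative tolerance
  (`1e-9 · Σv²`), which makes the reported year exactly $b$. The BIC of
  the break model counts 6 parameters (two intercepts, two slopes, the
  break position, the error variance) against 3 — conservative toward the
  null. Under noise, the kink ambiguity makes +1-year errors the most
  common kind; recovery is assessed within ±1 year.
* **Stineman interpolation**: slopes use the squared-chord-length
  weighting of adjacent secants with parabolic endpoint extrapolation, then
  a sign-consistency clamp (a slope disagreeing in sign with an adjoining
  secant is set to zero). Without the clamp the endpoint extrapolation can
  flip sign on convex monotone data and overshoot; with it the rational
  interpolant is shape-preserving and still reproduces straight lines
  exactly. No extrapolation: leading/trailing missing years are an error.
* **LOO Q²**: standardization parameters are recomputed on each training
  fold (no leakage); TSS accumulates deviations of each held-out value
  from its training-fold mean.
* **Backward elimination**: one predictor per iteration (the single lowest
  VIP; alphabetical tie-break), because VIPs renormalize after each refit;
  stops at all-VIP ≥ threshold or two predictors. Lagged columns must
  additionally improve Q² (ΔQ² > 0) or they are removed.
* **Permutation test**: fixed predictor subset, component count
  re-selected per permutation, statistic Q² (R²Y reported alongside),
  add-one p-value $(1 + \#\{Q^2_{null} \ge Q^2_{obs}\})/(1 + n_{perm})$.
* **Bayesian SEA**: exact conjugate sampling — with a vague
  inverse-Wishart prior ($\nu_0 = 3$, scale $10^{-3} I$) the covariance
  posterior is $\mathrm{IW}(\nu_0 + n - 1,\; \Psi_0 + S)$, whose mean is
  the sample covariance; SEA draws are $\pi\sqrt{\det\Sigma}$. No MCMC, no
  convergence diagnostics needed. The fixed prior scale means exact
  scale-equivariance holds only up to ~$10^{-4}$ relative.
* **Cross-correlation bound**: constant $1.96/\sqrt{n}$ at every lag (the
  ccf-plot convention). Because the overlap shrinks with lag, the realized
  false-positive rate drifts from ~5% at lag 0 to ~9% at lag 5 for
  n = 24; the screen is deliberately permissive since final retention is
  decided by ΔQ² downstream.
* **Geometric vs arithmetic aggregation**: geometric only for strictly
  positive variables (concentrations, age); delta-scale isotope values are
  aggregated arithmetically (they cross zero, so a geometric mean is
  undefined). The "inverse" δ¹⁵N-Phe proxy is a negation, not a
  reciprocal, for the same reason.
* **TEQ**: lower bound only — censored congeners contribute zero. The
  packaged TEF table is the WHO-2005 set for the 17 laterally substituted
  congeners.

## Open design choices, resolved

* The covariate adjustment is fitted over the pooled series (all fish, all
  years), not year-by-year — with 12 fish per year a yearly regression is
  too unstable to gate on.
* Interpolation happens after annual aggregation for every variable (gaps
  are whole missing years), before z-scoring.
* VIP uses cumulative explained-variance weights over all fitted
  components (the standard form).
* Only predictor-leading lags (1–5) are screened; response-leading lags
  have no mechanistic reading here.
* Permuted models keep the observed predictor subset; re-running the whole
  selection inside the permutation loop would change the null hypothesis
  being tested and multiply the cost ~10×.

## Limitations

* With ~20 annual observations, chance correlations of irrelevant
  predictors are large (SD ≈ 0.21); the VIP threshold 0.7 then retains a
  pure-noise column in roughly 10–15% of worlds. This is a property of the
  design dimensions, not of the implementation, and is why importance
  claims should rest on the WRC ranking plus the permutation test, not on
  survival of the VIP cut alone.
* Single breakpoint only; gradual or multiple regime changes are
  classified as whatever single-break approximation fits best.
* Linear detrending is a first-order correction; strongly nonlinear trends
  leave structure that can masquerade as driver effects.
* The trophic-position constants β and TDF are not estimable from the data
  the pipeline sees; they are configuration, and every report records the
  values used.
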