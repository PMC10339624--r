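---
title: "Stable CpG selection and compact gestational-age clocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stable CpG selection and compact gestational-age clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabclock)
```

## The problem

Cord-blood DNA methylation predicts gestational age (GA) remarkably well,
and several "epigenetic clocks" exploit this. But clocks built with
penalized regression alone disagree almost completely about *which* CpG
sites matter: methylation is measured with noise, neighbouring CpGs are
correlated, and the lasso picks one arbitrary representative from each
correlated group. The result is clocks of dozens to hundreds of CpGs whose
membership is unstable across cohorts.

`stabclock` separates **feature selection** from **prediction**:

1. **Stability selection.** The lasso is refit on many random
   half-subsamples of the data; a CpG's *selection probability*
   $\hat\pi_j$ is the fraction of runs in which its coefficient is
   nonzero. Features that matter are selected again and again; noise
   features come and go.
2. **A false-discovery budget.** The expected number of false discoveries
   $E(V)$ among features passing a probability threshold $\pi_{thr}$ is
   bounded by
   $$E(V) \le \frac{q^2}{(2\pi_{thr}-1)\,p},$$
   where $p$ is the number of candidate features and $q$ the average
   number of features the selector picks per subsample run. Inverting the
   bound turns a budget into a threshold:
   $\pi_{thr} = \min\!\big(1, \tfrac12(1 + q^2/(E(V)\,p))\big)$.
   `stabclock` estimates $q$ *under outcome permutation*: the whole
   subsampled-lasso procedure is rerun with GA permuted, and $q$ is the
   mean selected-set size. (The original theorem defines $q$ as the
   average selected-set size of the actual procedure; the permutation
   variant calibrates the null selection pressure directly and is what we
   implement.)
3. **Nested GAM clocks.** The stable CpGs — usually a handful — are ranked
   by univariate fit and combined into additive models of penalized cubic
   regression splines, one smooth per CpG. Splines matter because several
   predictive CpGs track GA nonlinearly, flattening in the preterm range;
   a linear clock systematically overestimates preterm GA. The effective
   degrees of freedom (EDF) of each smooth diagnose this: EDF 1 is a
   straight line, larger values indicate genuine curvature.

## Threshold conventions

With $q = 593.8$ and $p = 769{,}139$ the bound gives $\pi_{thr} = 0.729$
at $E(V) = 1$ and $0.764$ at $E(V) = 0.5$ ($q = 450.5$). Published
applications of this calculus describe those same thresholds as allowing
"two" and "one" false discoveries respectively — a factor-2 ambiguity in
how the budget is stated. `compute_threshold()` takes the bound value
verbatim; `pipeline_config()` exposes the user-facing budget with an
`ev_convention` switch (`"half"`, the default, divides the budget by two
before entering the bound, reproducing the published thresholds;
`"stated"` passes it through). We take no position on which reading is
"right" — both are one switch away.

## The synthetic cohort generator

The reference cohorts for GA clocks are access-restricted, so the
package ships a generator that plants known signal in realistic
methylation data. Everything downstream is validated against it.

* **GA distribution**: normal, mean 279.8 d, SD 11.2 d, truncated to
  216–300 d — the moments of a term-dominated ultrasound-dated birth
  cohort. Truncation is by inversion, so no draw ever escapes the range.
  An optional `preterm_boost` reweights the preterm segment (< 259 d) for
  experiments on preterm calibration; it is off by default because the
  realistic condition is preterm scarcity.
* **Signal and noise live on the logit scale** (the M-value scale) and are
  mapped back through the inverse logit, which keeps betas strictly inside
  (0, 1) with no clipping artifacts. For causal CpG $j$,
  $\mathrm{logit}\,E[\beta_{ij}] = a_j + f_j(z_i)$ with $z_i$ standardized
  GA.
* **Link shapes**: besides linear links, two bounded nonlinear families
  mimic the curvature seen in real predictive CpGs — a saturating sigmoid
  (flat in the deep preterm range, steep around term) and a hinge with a
  slope break at the GA mean. The shape amplitudes are scaled so all
  three families inject comparable signal variance.
* **Correlation structure**: CpGs come in blocks (default 5) sharing an
  AR(1) correlation (default 0.6) on the logit scale; causal CpGs head
  their block and leak geometrically attenuated signal to block-mates,
  reproducing the "correlated neighbours tag along" difficulty that
  motivates stability selection.
* **Noise**: per-sample logit-scale SD 0.5, a typical M-value residual
  spread for array data of this kind.
* **Calibration**: `calibrate_effect_scale(r2, config)` converts a target
  univariate R² into an effect amplitude. The closed form
  $b = s\sqrt{r^2/(1-r^2)}$ is refined by a deterministic bisection
  against a large simulated draw because GA truncation (variance of
  standardized GA < 1) and inverse-logit curvature each attenuate the
  realized R² by a few percent. The package's reference planted signal is
  univariate R² ≈ 0.5, matching the strength of the strongest known
  GA-predictive CpG.
* **Sex** is generated (49% male) but unused by the models, matching how
  such clocks are actually built.

What the generator does **not** emulate: probe chemistry and batch
effects, cell-type composition, genome-wide bimodal beta distributions
(null CpGs here are unimodal logit-normal), and any spatial genomic
structure beyond the block layout. Passing tests therefore demonstrate
correctness of the *procedure* under controlled signal, not performance
on any particular real cohort.

## Numerical choices

* **Lasso**: `glmnet`, $\alpha = 1$, penalty chosen once by 10-fold CV on
  the full training data (`lambda.min` rule) and held fixed across all
  subsample fits. Standardization is recomputed inside every subsample
  fit. Convergence threshold is $10^{-12}$: at looser tolerances the
  active set of correlated designs depends on column order, which would
  break the exchangeability of the selection profile; the tight setting
  costs nothing measurable.
* **Subsampling**: simple random half-samples (`floor(n/2)`) without
  replacement. A master seed spawns an independent substream per run, so
  increasing the number of runs extends, rather than reshuffles, the
  earlier ones. Permutation-$q$ uses one fresh permutation per run by
  default (decorrelating runs); a single global permutation is available.
* **GAMs**: `mgcv` cubic regression splines, basis dimension 10 per CpG
  (room for EDF up to ~9, beyond the strongest curvature reported for
  GA-predictive CpGs), penalties selected by GCV (REML available). Each
  nested model re-selects its penalties independently. One caveat worth
  knowing: on *noise-free* input the smoothing criterion is degenerate —
  any EDF reproduces the data — so the "EDF = 1 means linear" calibration
  is defined for noisy data, which is the regime the diagnostic exists
  for.
* **Prediction** beyond the training beta range uses the spline's natural
  linear extension and flags the affected samples, rather than clamping,
  to avoid silent bias for extreme preterm inputs.
* **Train/test split**: test size `round(n * 0.2)`. (For n = 2138 that is
  1710/428; the 1709/429 split quoted in prior work matches no standard
  rounding and is not emulated.)
* **Robust calibration regression**: MM-type (S-estimate initialization,
  bisquare M-step at 95% Gaussian efficiency) via `MASS::rlm`. The
  S-initialization resamples randomly, so `robust_fit()` sorts the input
  canonically and uses a frozen internal RNG stream — results are
  deterministic and invariant to sample order, and the caller's RNG state
  is untouched. When a majority of points fit a line exactly the robust
  scale collapses to zero and the M-iteration is undefined; the
  least-trimmed-squares fit, which is the limiting solution, is returned
  instead.
* **R²** is reported both as squared Pearson correlation (the headline
  metric, affine-invariant) and as variance explained
  ($1 - SS_{res}/SS_{tot}$, floored at 0 with a flag), because the two
  diverge for miscalibrated predictors. MAD is the *paired* median
  absolute prediction error in days, not the scale estimator.

## Validation scale

The test suite and acceptance script exercise the full pipeline at a
reduced reference scale chosen to keep the signal geometry honest while
running on a laptop: cohorts of n = 300 samples and p = 2000 CpGs, B =
100 subsample runs, 20 replicates for Monte-Carlo properties, and
50-replicate batteries for the EDF diagnostics. At this scale the
permutation-calibrated $q$ is large relative to $\sqrt{p}$, so the bound
often caps at $\pi_{thr} = 1$ — a faithful property of the calculus at
small $p$, and the planted CpGs still pass because their selection
probabilities reach 1.0.

## A worked run

```{r example, eval = FALSE}
library(stabclock)

base <- cohort_config(n_samples = 300, n_cpgs = 2000, seed = 11)
cfg <- cohort_config(
  n_samples = 300, n_cpgs = 2000,
  effect_scale = calibrate_effect_scale(0.5, config = base),
  seed = 11
)
res <- run_pipeline(pipeline_config(
  cohort = cfg,
  selection = selection_config(n_subsamples = 100, seed = 3),
  k_max = 5
))

res$bound            # q, p, and the probability threshold
res$stable           # stably selected CpGs
tidy(res$curve)      # R^2 / MAD per clock size + lasso baseline
autoplot(res$profile, pi_thr = res$bound)
autoplot(res$curve)
```

## Limitations

* The generator's realism bounds what the validation can claim; see
  above.
* Stability selection deliberately under-selects groups of highly
  correlated predictive CpGs (each member is selected in only a fraction
  of runs); the block-leakage design reproduces this behaviour but the
  package does not attempt group-aware selection.
* The permutation estimate of $q$ diverges from the cited theorem's
  definition (see "The problem"); both conventions for the budget are
  exposed, neither is silently preferred beyond the documented default.
* No uncertainty intervals accompany clock predictions.
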