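---
title: "Normative reference modeling with normref: models, design choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative reference modeling with normref}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A normative model estimates the covariate-conditional reference distribution
of a brain measurement (cortical thickness, subcortical volume) in a healthy
population, so that any individual can be placed on that distribution as a
percentile or deviation (z) score. How trustworthy those scores are depends on
the reference cohort: its size, and how well its age and sex composition
matches the population the model is applied to. `normref` packages the full
machinery needed to study that question — a warped Bayesian linear regression
(BLR) normative model per region of interest (ROI), controlled subsampling
designs over the training cohort, evaluation and clinical readouts on a fixed
test set, mixed-model summarization, and transfer-learning recalibration —
together with a seeded synthetic multi-site cohort generator so the whole
pipeline can be exercised and validated end to end without access-restricted
data.

## The model

For each ROI, responses $y$ are standardized by the training mean and SD and
warped by the sinh-arcsinh function

$$\phi(y) = \sinh(\delta\,\mathrm{asinh}(y) - \epsilon),$$

where $\epsilon$ controls skew and $\delta > 0$ tail weight; $(0, 1)$ is the
identity. The warped response follows a Bayesian linear regression

$$\phi(y) \sim \mathcal{N}(\mathbf{x}^\top \mathbf{w},\ 1/\beta_n), \qquad
\mathbf{w} \sim \mathcal{N}(\mathbf{0},\ \mathbf{I}/\alpha_w),$$

with design $\mathbf{x}$ = intercept, a cubic B-spline basis on age with three
evenly spaced interior knots over the training age range (7 columns forming a
partition of unity), a male indicator, and dummy-coded site indicators with
the reference site dropped. The four hyperparameters
$(\log\alpha_w, \log\beta_n, \epsilon, \log\delta)$ minimize the negative log
marginal likelihood (BLR evidence plus the warp's log-Jacobian) by Powell's
conjugate-direction method, restarted from the origin and two fixed jittered
points; the best finite optimum wins. Deviation scores are

$$z = \frac{\phi(y) - \mathbf{x}^\top \mathbf{m}}
{\sqrt{1/\beta_n + \mathbf{x}^\top \mathbf{A}^{-1}\mathbf{x}}},$$

combining aleatoric (irreducible noise, $1/\beta_n$) and epistemic (posterior
leverage, $\mathbf{x}^\top\mathbf{A}^{-1}\mathbf{x}$) variance. Centiles
invert the warp: $q$-centile $= \phi^{-1}(\mu + \Phi^{-1}(q)\,\sigma)$ mapped
back through the training standardization.

### Numerical and convention choices

These points were genuinely open and are fixed as follows:

* **Warp parameterization.** The literature names the sinh-arcsinh family but
  not a unique sign convention; we fix $\phi(x)=\sinh(\delta\,\mathrm{asinh}(x)-\epsilon)$
  applied to standardized responses. Standardization stabilizes the Powell
  search; its side effect is that exact $(\epsilon, \delta)$ recovery is only
  identifiable when fitting data already on the model scale, so
  `fit_roi(standardize = FALSE)` exists for recovery studies.
* **Spline covers age only.** Sex and site enter as linear indicator columns:
  a spline on a binary covariate is degenerate, and the smooth basis is read
  as applying to the continuous covariate.
* **Out-of-boundary ages** use linear extension of the spline columns (value
  plus first derivative at the nearest boundary knot). This gives bounded,
  continuous extrapolation where subsamples fail to cover the test age range —
  the regime in which skewed training sets do their damage — instead of
  undefined basis values.
* **Evaluation space.** MSLL, SMSE, EV and Rho are computed in the
  warped/standardized space, where the Gaussian variance decomposition is
  exact. The alternative (data-space) convention exists in the wild; the
  warped-space choice keeps every metric's Gaussian assumptions exact and is
  applied uniformly, so comparisons across sampling conditions are unaffected.
* **Centile variance.** Centiles use total (aleatoric + epistemic) variance by
  default; `centile_variance = "aleatoric"` is the toggle.
* **Tail bounds vs clinical threshold.** Calibration tails use the exact
  Gaussian 2.5/97.5 bounds ($\pm 1.959964$); the clinical outlier rule uses
  the conventional printed $-1.96$ with strict inequality. The two are
  deliberately not unified: calibration is about the nominal interval, the
  clinical rule is a fixed convention.
* **Hyperparameter search.** Powell tolerance $10^{-6}$ on the NLL, box
  constraints $|\log\alpha_w|, |\log\beta_n| \le 20$, $|\epsilon| \le 5$,
  $\delta \in [10^{-2}, 10^2]$; non-finite evidence values are treated as
  $+\infty$ so the line searches back away from degenerate regions. A
  constant response cannot be standardized and is returned flagged (it still
  predicts the constant); flagged fits are excluded from sweep tables and
  logged.

## Subsampling designs

Healthy controls are split 80/20 into train/test within site x sex x 5-year
age-bin strata (largest-remainder allocation: the global 80% count is exact
and every stratum is within one subject of 80%); all patients go to the test
set. Strata with fewer than two controls are merged with the nearest age bin
of the same site and sex — the source material is silent here, and merging
avoids strata that cannot be split.

Training draws follow four strategies: *representative* (10 quantile age
bins, equal counts per bin, sexes balanced within one), *left-* and
*right-skewed* (10 equal-width age bins weighted by Beta(2,5) or Beta(5,2)
mass), and *sex-imbalanced* (representative age procedure per sex at F:M
ratios 1:1 through 10:1). Two further silent corners are fixed as: bin
weights use the integrated Beta CDF mass per bin (exact and well defined at
bins touching 0/1; the pdf-at-center variant is available via
`bin_weighting = "pdf"` for sensitivity checks), and exhausted bins
redistribute their demand proportionally to the remaining bins' weights,
iterating until the draw is filled — this preserves the intended skew as
closely as the pool allows. Remainder units (n not divisible by bins, ratios
not exact) go to bins chosen uniformly at random under the draw's seed, so no
bin is systematically favoured across iterations.

Every draw's seed is a stable hash of (master seed, strategy, n, iteration),
so any cell of a sweep can be replayed in isolation from its manifest.

The age-bin coverage statistic discretizes age into 20 quantile bins defined
on the full training set and reports
$\sum_i \min(n_{\text{train}}(i), n_{\text{test}}(i)) / \sum_i n_{\text{test}}(i)$:
1 when the draw covers the test-set age distribution completely, 0 when it
covers none of it.

## The synthetic cohort generator

`synthetic_config()` states a generative world chosen once:

* ages uniform on 44–82 years by default (a beta-weighted option produces the
  old-age skew typical of aging cohorts);
* per-ROI values are baseline + smooth age decline (linear + mild quadratic
  acceleration) + sex effect + site offset + skewed noise;
* the noise is $\mathrm{scale} \cdot \sinh((\mathrm{asinh}(g) + \epsilon)/\delta)$
  with standard-Gaussian $g$ — the inverse of the model's warp family;
* an AD group receives an additional decrement on a designated
  "medial-temporal-like" ROI subset, multiplied per subject by a
  Gamma(4, 4) severity factor (mean 1), so not every patient is an outlier in
  every region.

The default *realistic-SNR preset*: age trend explaining 20–40% of
healthy-control variance per ROI (cycled deterministically across ROIs), sex
effect 0.3 residual SD, site offsets 0.5 residual SD apart, residual skew
mild ($|\epsilon| = 0.1$, $\delta = 1.03$, sign alternating across ROIs).
The variance explained by age in real ROI data is not publicly tabulated, so
the 20–40% band is a calibration choice — flagged here, fixed once, not
revisited. Site offsets are expressed in residual-SD units (scaled by each
ROI's noise scale) rather than raw measurement units, because a single scalar
cannot be meaningful across thickness (mm) and volume (mm³) regions at once.
Patients draw ages from the same law as controls; the group contrast is
carried entirely by the atrophy term.

Two structural notes matter for interpreting green tests. First, the
generator shifts the mean *outside* the warp while the model warps the whole
standardized response; the two laws coincide exactly only at the identity
warp. With the mild default skew the misspecification is second-order — the
calibration suite (tails near 2.5%) is the empirical check — but warp
*parameter* recovery is only a well-posed test on data generated from the
model's own law, which is how the recovery tests construct it. Second, the
generator produces independent noise across ROIs; real neuroanatomy is
spatially correlated, so multivariate readouts (total outlier counts,
classifier AUC) have less between-ROI dependence here than in real cohorts.
A green calibration or learning-curve test therefore establishes correctness
of the machinery under the stated world, not the real-data effect sizes,
which live on access-restricted cohorts.

## Evaluation, clinical readouts, statistics

* **Fit metrics** on the fixed HC test set: MSLL (model log loss minus the
  trivial predictor built from the training mean/variance), SMSE (mean squared
  error over test variance), EV, Pearson Rho, and the percentage of test
  z-scores outside the nominal 95% interval, split by tail. Variances are
  population (divisor n) throughout.
* **ICC(2,1)** — two-way random effects, absolute agreement, single
  measurement — quantifies the stability of a subject's z-score across the 10
  repeated draws of the same (strategy, n) cell, computed from ANOVA mean
  squares with no imputation (missing cells are an error).
* **Z-score errors** against the full-sample reference model: per-subject MSE
  and MBE over ROIs (negative MBE = overestimated deviations). Before
  cell-level averaging, subject values outside 3 x IQR of their
  (strategy, n, group) cell can be excluded via `iqr_exclude()` — the least
  aggressive grouping that still touches aberrant iterations, since the
  exclusion is meant to damp rare extreme draws, and pooling iterations keeps
  cells large enough for stable quartiles. Cubic age regressions of MSE
  localize where on the age axis errors concentrate.
* **Clinical readouts**: negative outlier flags ($z < -1.96$), per-subject
  total outlier count (tOC), per-ROI outlier percentages by group, and a
  linear support-vector classifier (squared hinge, unit regularization,
  features standardized per fold on training folds only) evaluated by
  stratified 10-fold cross-validated ROC-AUC. No SVM backend is assumed: the
  classifier is fitted in-package by BFGS on the differentiable squared-hinge
  objective, which is deterministic given the fold seed. The linear kernel
  matches the high-dimensional small-n regime of z-score features; kernels
  are out of scope.
* **Mixed models**: `outcome ~ log(n) * strategy + (1 | ROI)` for fit metrics
  and `outcome ~ log(n) * strategy * group + (1 | individual)` for deviation
  outcomes, fitted by REML with outcome and log(n) z-scored over the full
  analysis table (so coefficients compare across terms), representative
  sampling and HC as reference levels, Wald z p-values (the
  degrees-of-freedom method was unspecified; Wald is the stable default at
  these table sizes), and Benjamini–Hochberg FDR for per-ROI model families.

## Transfer-learning adaptation

`adapt()` recalibrates a pre-trained model to a new cohort with a mean-level
offset per target site: the mean warped residual of the adaptation subjects.
Variance, warp, and posterior covariance are untouched, which has the exact
consequence that explained variance and correlation on a fixed test set are
unchanged by adaptation — asserted bit-for-bit in the tests. In the pipeline
arm, pre-training uses all healthy controls of the large reference cohort and
target site labels are namespaced so they can never collide with reference
sites; the adaptation sets reuse the direct arm's draws, and both arms are
evaluated on the identical fixed test set.

## Known limitations

* The generator does not emulate spatial correlation between ROIs, site
  differences in noise scale, or age-by-sex interactions.
* Warped BLR treats site as a fixed effect; hierarchical site pooling
  (random-effect site models, federated updates) is out of scope.
* The support-vector classifier is linear-kernel only.
* LMM p-values are Wald; Satterthwaite/Kenward–Roger corrections are not
  provided.
* Mean ICC of held-out z-scores at n = 50 on the default preset comes out
  near 0.89 — just under the conventional 0.9 "excellent reliability" line
  that real-data analyses reach at that size. The preset was fixed a priori
  from the realistic-SNR band; the shortfall is reported as computed rather
  than tuned away.

## A worked sweep

```{r, eval = FALSE}
library(normref)
cfg <- preset_config(n_hc = 600, n_ad = 80, iterations = 3,
                     master_seed = 42)
res <- run_sweep(cfg)
aggregate(msll ~ n, data = subset(res$fit_metrics, strategy != "full"),
          FUN = median)
write_results(res, "sweep-out")
```

The same experiment is available from the command line via
`inst/cli/normref.R` (subcommands `simulate`, `sweep`, `adapt`, `evaluate`,
`report`).
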