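# normref

Sample-size and covariate effects in neuroanatomical normative models.

`normref` is an R package for researchers who fit normative models of brain
structure — covariate-conditional reference distributions of regional cortical
thickness and subcortical volume — and need to know how much the *reference
cohort* itself (its size, its age profile, its sex balance) shapes the
deviation scores and clinical readouts those models produce. It implements:

* **Warped Bayesian linear regression** per region of interest (ROI): the
  response is standardized and warped by the sinh-arcsinh function
  `phi(y) = sinh(delta * asinh(y) - epsilon)`, then modelled as
  `phi(y) ~ N(x'w, 1/beta_n)` with weight prior `w ~ N(0, I/alpha_w)`. The
  design holds an intercept, a cubic B-spline basis on age (3 evenly spaced
  interior knots), a sex indicator, and dummy-coded site columns. The four
  hyperparameters `(log alpha_w, log beta_n, epsilon, log delta)` minimize
  the negative log marginal likelihood (evidence + warp Jacobian) by Powell's
  conjugate-direction method. Deviation scores are
  `z = (phi(y) - x'm) / sqrt(1/beta_n + x' A^-1 x)` — warped residual over
  total (aleatoric + epistemic) predictive SD.
* **Subsampling designs**: stratified 80/20 train/test splitting
  (site x sex x 5-year age bins), a 5..200-by-5 / 250..600-by-50 sample-size
  grid, representative draws (10 quantile age bins, balanced sexes),
  beta-weighted age-skewed draws (Beta(2,5) young-biased, Beta(5,2)
  old-biased), sex-imbalanced draws (1:1 to 10:1), and an age-bin coverage
  statistic `sum_i min(n_train(i), n_test(i)) / sum_i n_test(i)`.
* **Evaluation**: MSLL, SMSE, EV, Rho, tail calibration at the exact
  2.5/97.5% bounds, ICC(2,1) of z-scores across repeated draws, per-subject
  MSE/MBE of z-scores against the full-sample reference model with 3 x IQR
  screening, and cubic age profiles of the error.
* **Clinical readouts**: negative outlier flags (`z < -1.96`), per-subject
  total outlier counts (tOC), per-ROI outlier percentages by group, and
  HC/AD classification AUC from a linear support-vector classifier under
  stratified 10-fold cross-validation.
* **Statistics**: linear mixed models
  `outcome ~ log(n) * strategy + (1 | ROI)` and
  `outcome ~ log(n) * strategy * group + (1 | individual)` (REML, standardized
  coefficients, Wald p-values) plus Benjamini–Hochberg FDR.
* **Transfer learning**: mean-level recalibration of pre-trained models to a
  new cohort (`adapt()`), leaving variance, warp and posterior covariance —
  and therefore EV/Rho on a fixed test set — exactly unchanged.
* **Synthetic cohorts**: a fully seeded multi-site generator (ages 44–82,
  smooth age decline, sex and site offsets, sinh-arcsinh-skewed noise, an AD
  group with atrophy on designated medial-temporal-like ROIs) with analytic
  `true_centile()` oracles, so every stage of the pipeline is testable
  end to end.

## Worked example

```r
library(normref)

cfg <- preset_config(n_hc = 600, n_ad = 80, iterations = 3, master_seed = 42,
                     grid = c(10L, 25L, 50L, 100L))
res <- run_sweep(cfg)

aggregate(msll ~ n, data = subset(res$fit_metrics, strategy != "full"),
          FUN = median)
#>     n          msll
#> 1  10 -0.0004087869
#> 2  25 -0.0081148090
#> 3  50 -0.0971091294
#> 4 100 -0.1636221711

rt <- res$reference$toc
tapply(rt$toc, rt$group, mean)
#>     AD     HC
#> 3.9375 0.5250
```

Median MSLL (mean standardized log loss; more negative = better than the
trivial training-mean predictor) improves monotonically as the training
subsample grows from 10 to 100 controls — the learning-curve behaviour that
motivates the package. Under the full-sample reference model the synthetic AD
group carries more negative-outlier regions per subject (mean tOC 3.94 of 20
ROIs) than held-out controls (0.53), driven by the atrophy ROIs; with the full
167-ROI configuration the healthy-control mean sits near the binomial
expectation 167 x 2.5% ≈ 4.2 (the `t3` acceptance target).

A command-line front end is in `inst/cli/normref.R`:

```sh
Rscript inst/cli/normref.R sweep --seed 3 --out run1 --preset desk
Rscript inst/cli/normref.R report --out run1
```

## Documentation

The methods vignette (`vignettes/normref-methods.Rmd`) describes the model,
the sampling designs, the synthetic-data world and its limits, and every
numerical convention the package fixes.
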