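test_that("design matrix: partition of unity, layout arithmetic, extension", {
  set.seed(1)
  sub <- data.frame(age = runif(40, 50, 80),
                    sex = sample(c("F", "M"), 40, TRUE),
                    site = sample(c("s1", "s2", "s3"), 40, TRUE))
  bs <- basis_spec(sub$age, site_levels = c("s1", "s2", "s3"))
  X <- build_design(sub, bs)
  # 1 intercept + 7 spline + 1 sex + 2 site dummies
  expect_equal(ncol(X), 11)
  spl <- X[, 2:8]
  expect_equal(rowSums(spl), rep(1, 40), tolerance = 1e-12)

  # single site: no site block
  bs1 <- basis_spec(sub$age, site_levels = "s1")
  expect_equal(ncol(build_design(transform(sub, site = "s1"), bs1)), 9)

  # out-of-boundary ages: finite, continuous linear extension
  lo <- min(sub$age)
  ext <- build_design(data.frame(age = c(lo - 5, lo - 0.001, lo),
                                 sex = "F", site = "s1"), bs)
  expect_true(all(is.finite(ext)))
  expect_equal(ext[2, 2:8], ext[3, 2:8], tolerance = 1e-2)

  expect_error(build_design(transform(sub, site = "nope"), bs), "unknown site")
  expect_error(build_design(transform(sub, age = NA_real_), bs), "finite")
})

test_that("NLL equals a dense marginal-covariance oracle", {
  # 5-point toy set; oracle integrates the weights analytically:
  # t ~ N(0, Phi Phi' / alpha + I / beta), plus the warp Jacobian.
  set.seed(2)
  sub <- data.frame(age = c(50, 55, 60, 70, 80), sex = c("F", "M", "F", "M", "F"),
                    site = "s1")
  bs <- basis_spec(sub$age, site_levels = "s1")
  X <- build_design(sub, bs)
  y <- c(0.3, -0.2, 0.5, 0.1, -0.4)
  for (hyper in list(c(0, 0, 0, 0), c(0.5, -0.3, 0, 0),
                     c(0.2, 0.4, 0.3, log(1.2)))) {
    alpha <- exp(hyper[1]); beta <- exp(hyper[2])
    t <- sinh_arcsinh(y, hyper[3], exp(hyper[4]))
    C <- tcrossprod(X) / alpha + diag(5) / beta
    R <- chol(C)
    logdens <- -0.5 * 5 * log(2 * pi) - sum(log(diag(R))) -
      0.5 * drop(crossprod(backsolve(R, t, transpose = TRUE)))
    oracle <- -logdens - sum(log(sinh_arcsinh_deriv(y, hyper[3], exp(hyper[4]))))
    expect_equal(negative_log_likelihood(hyper, X, y), oracle,
                 tolerance = 1e-8)
  }
})

test_that("NLL: duplication increases it and doubles the Jacobian data term", {
  set.seed(3)
  sub <- data.frame(age = runif(20, 44, 82), sex = "F", site = "s1")
  bs <- basis_spec(sub$age, site_levels = "s1")
  X <- build_design(sub, bs)
  y <- rnorm(20)
  h <- c(0.1, -0.2, 0.3, log(1.1))
  expect_gt(negative_log_likelihood(h, rbind(X, X), c(y, y)),
            negative_log_likelihood(h, X, y))
  jac <- function(yy) sum(log(sinh_arcsinh_deriv(yy, h[3], exp(h[4]))))
  expect_equal(jac(c(y, y)), 2 * jac(y), tolerance = 1e-12)
  # degenerate hyperparameters signal with a non-finite value
  expect_false(is.finite(negative_log_likelihood(c(50, 0, 0, 0), X, y)))
})

test_that("frozen hyperparameters: posterior mean equals the ridge solution", {
  set.seed(4)
  n <- 60
  sub <- data.frame(age = runif(n, 44, 82), sex = sample(c("F", "M"), n, TRUE),
                    site = "s1")
  bs <- basis_spec(sub$age, site_levels = "s1")
  X <- build_design(sub, bs)
  y <- 0.4 * (sub$age - 60) / 10 + rnorm(n, 0, 0.5)
  h <- c(log(2), log(3), 0, 0)  # identity warp, fixed alpha/beta
  mdl <- fit_roi(sub, y, basis = bs, standardize = FALSE, fixed_hyper = h)
  ridge <- solve(crossprod(X) + (2 / 3) * diag(ncol(X)), crossprod(X, y))
  expect_equal(mdl$m, unname(drop(ridge)), tolerance = 1e-8)
  # posterior covariance symmetric positive definite
  expect_equal(mdl$A_inv, t(mdl$A_inv), tolerance = 1e-10)
  expect_true(all(eigen(mdl$A_inv, symmetric = TRUE)$values > 0))
})

test_that("constant response is flagged but still predicts the constant", {
  sub <- data.frame(age = seq(50, 70, length.out = 10), sex = "F", site = "s1")
  mdl <- fit_roi(sub, rep(2.5, 10))
  expect_true(mdl$flagged)
  pr <- predict(mdl, sub, q = 0.5)
  expect_equal(drop(pr$centiles), rep(2.5, 10), tolerance = 1e-4)
})

test_that("prediction: median centile, leverage monotonicity, variance split", {
  dat <- model_law_data(400, eps = 0, delta = 1, sigma = 0.5, seed = 5)
  mdl <- fit_roi(dat$sub, dat$y, basis = dat$basis)
  newd <- data.frame(age = c(60, 95), sex = "F", site = "s01")
  newd$site <- "site01"
  pr <- predict(mdl, newd, q = 0.5)
  # q = 0.5 centile is the unwarped predictive mean
  expect_equal(pr$centiles[, 1],
               normref:::unwarp_response(mdl, pr$mean), tolerance = 1e-12)
  # epistemic variance larger at the extrapolated age
  expect_gt(pr$s2_epistemic[2], pr$s2_epistemic[1])
  expect_true(all(pr$s2_aleatoric > 0))
  expect_error(predict(mdl, newd, q = c(0.5, 1.5)), "q must")
})

test_that("epistemic variance shrinks toward zero as training n grows", {
  s2e <- vapply(c(50, 500, 5000), function(n) {
    dat <- model_law_data(n, eps = 0, delta = 1, sigma = 0.5, w_age = 0.5,
                          seed = 6)
    mdl <- fit_roi(dat$sub, dat$y, basis = dat$basis)
    newd <- data.frame(age = 63, sex = "F", site = "site01")
    predict(mdl, newd)$s2_epistemic
  }, numeric(1))
  expect_true(all(diff(s2e) < 0))
  expect_lt(s2e[3], 1e-3)
})

test_that("z-scores: construction identities and calibration", {
  dat <- model_law_data(3000, eps = 0.2, delta = 1.1, seed = 7)
  mdl <- fit_roi(dat$sub, dat$y, basis = dat$basis)
  zz <- zscores(mdl, dat$sub, dat$y)

  # y on the predicted median has z = 0
  pr <- predict(mdl, dat$sub[1:5, ], q = 0.5)
  z0 <- zscores(mdl, dat$sub[1:5, ], pr$centiles[, 1])
  expect_equal(z0$z, rep(0, 5), tolerance = 1e-10)

  # warped value at mean + 2 sd has z = 2
  tot <- pr$s2_aleatoric + pr$s2_epistemic
  y2 <- normref:::unwarp_response(mdl, pr$mean + 2 * sqrt(tot))
  expect_equal(zscores(mdl, dat$sub[1:5, ], y2)$z, rep(2, 5),
               tolerance = 1e-10)

  # held-out calibration: z approximately standard normal
  hold <- model_law_data(2000, eps = 0.2, delta = 1.1, seed = 8)
  zh <- zscores(mdl, hold$sub, hold$y)$z
  expect_gt(ks.test(zh, "pnorm")$p.value, 0.01)
})

test_that("fitted centiles recover generative centiles on identity-warp data", {
  cfg <- tiny_config(n_hc = 4000, n_roi_c = 1, n_roi_s = 0,
                     noise_eps = 0, noise_delta = 1)
  coh <- generate_cohort(cfg, seed = 9)
  mdl <- fit_roi(coh$subjects, coh$values[, 1])
  newd <- data.frame(age = c(55, 65, 75), sex = "M", site = "site01")
  pr <- predict(mdl, newd, q = 0.975)
  truth <- true_centile(cfg, 1, newd$age, "M", 1, 0.975)
  # agreement within a few percent of the residual scale
  expect_lt(max(abs(pr$centiles[, 1] - truth)), 0.05 * cfg$noise_scale[1] * 3)
})

test_that("warp recovery on model-law data at n = 5000 (eps 0.4, delta 1.3)", {
  dat <- model_law_data(5000, eps = 0.4, delta = 1.3, seed = 1)
  mdl <- fit_roi(dat$sub, dat$y, basis = dat$basis, standardize = FALSE)
  expect_true(mdl$converged)
  expect_lt(abs(mdl$warp$epsilon - 0.4), 0.05)
  expect_lt(abs(mdl$warp$delta - 1.3), 0.05)
})

test_that("adaptation: offset recovery, null adaptation, EV/Rho invariance", {
  dat <- model_law_data(2000, eps = 0, delta = 1, sigma = 0.5, seed = 10)
  mdl <- fit_roi(dat$sub, dat$y, basis = dat$basis)

  # target cohort = reference shifted by c in warped space, new site label
  set.seed(11)
  shift_w <- 0.8
  tgt <- model_law_data(600, eps = 0, delta = 1, sigma = 0.5, seed = 12)
  tgt$sub$site <- "newsite"
  y_t <- normref:::unwarp_response(
    mdl, normref:::warp_response(mdl, tgt$y) + shift_w)
  ad <- adapt(mdl, tgt$sub[1:300, ], y_t[1:300])
  expect_equal(as.numeric(ad$adapt_offsets["newsite"]), shift_w,
               tolerance = 0.1)
  # residuals on fresh target data are centered after adaptation
  zz <- zscores(ad, tgt$sub[301:600, ], y_t[301:600])
  expect_lt(abs(mean(zz$z)), 0.15)

  # adaptation set from the reference itself: offset near zero
  ad0 <- adapt(mdl, dat$sub[1:300, ], dat$y[1:300])
  expect_lt(abs(as.numeric(ad0$adapt_offsets)), 0.1)

  # EV and Rho identical before and after adaptation (fixed test set)
  test_sub <- dat$sub[1001:2000, ]
  test_y <- dat$y[1001:2000]
  fm_before <- fit_metrics_for_model(mdl, test_sub, test_y)
  mdl_shifted <- mdl
  mdl_shifted$adapt_offsets <- c(site01 = 0.37)
  fm_after <- fit_metrics_for_model(mdl_shifted, test_sub, test_y)
  expect_identical(fm_before$ev, fm_after$ev)
  expect_identical(fm_before$rho, fm_after$rho)

  expect_error(adapt(mdl, dat$sub[0, ], numeric(0)), "empty adaptation")
})

test_that("model JSON serialization round-trips", {
  dat <- model_law_data(200, eps = 0.1, delta = 1.05, seed = 13)
  mdl <- fit_roi(dat$sub, dat$y, basis = dat$basis)
  txt <- model_to_json(mdl)
  back <- model_from_json(txt)
  expect_equal(back$m, mdl$m, tolerance = 1e-12)
  expect_equal(back$A_inv, mdl$A_inv, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$warp, mdl$warp, tolerance = 1e-12)
  expect_equal(back$train_summary$var_w, mdl$train_summary$var_w,
               tolerance = 1e-12)
  # predictions from the restored model are identical
  newd <- data.frame(age = c(50, 70), sex = "F", site = "site01")
  expect_equal(predict(back, newd)$mean, predict(mdl, newd)$mean,
               tolerance = 1e-12)
})

test_that("age affine equivariance: z-scores invariant when basis co-transforms", {
  dat <- model_law_data(800, eps = 0, delta = 1, sigma = 0.5, seed = 14)
  mdl <- fit_roi(dat$sub, dat$y, basis = dat$basis)
  z1 <- zscores(mdl, dat$sub, dat$y)$z
  sub2 <- dat$sub
  sub2$age <- 2 * sub2$age + 10
  bs2 <- basis_spec(sub2$age, site_levels = "site01")
  mdl2 <- fit_roi(sub2, dat$y, basis = bs2)
  z2 <- zscores(mdl2, sub2, dat$y)$z
  expect_equal(z1, z2, tolerance = 1e-3)
})
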