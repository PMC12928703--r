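test_that("fit metrics: self-standardization, perfection, hand-computed toy", {
  ts <- list(mean_w = 0.2, var_w = 1.5)

  # predictions = training mean with training variance: MSLL is exactly 0
  t_test <- c(-0.5, 0.1, 0.7, 1.4)
  fm0 <- compute_fit_metrics(rep(ts$mean_w, 4), rep(ts$var_w, 4), t_test, ts)
  expect_equal(fm0$msll, 0, tolerance = 1e-12)

  # perfect predictions
  fm1 <- compute_fit_metrics(t_test, rep(0.01, 4), t_test, ts)
  expect_equal(fm1$smse, 0)
  expect_equal(fm1$ev, 1)
  expect_equal(fm1$rho, 1)

  # constant prediction at the test mean on a printed 4-point toy set:
  # SMSE = mean(resid^2)/var_pop = 1 exactly, EV = 0, Rho undefined
  fm2 <- compute_fit_metrics(rep(mean(t_test), 4), rep(1, 4), t_test, ts)
  expect_equal(fm2$smse, 1, tolerance = 1e-12)
  expect_equal(fm2$ev, 0, tolerance = 1e-12)
  expect_true(is.na(fm2$rho))

  # hand evaluation with a sloped predictor on the same toy set
  pred <- c(-0.4, 0.0, 0.8, 1.2)
  fm3 <- compute_fit_metrics(pred, rep(0.5, 4), t_test, ts)
  resid <- t_test - pred
  expect_equal(fm3$smse, mean(resid^2) / mean((t_test - mean(t_test))^2),
               tolerance = 1e-12)
  expect_equal(fm3$ev, 1 - mean((resid - mean(resid))^2) /
                 mean((t_test - mean(t_test))^2), tolerance = 1e-12)
  expect_equal(fm3$rho, cor(pred, t_test), tolerance = 1e-12)

  # degenerate test variance flagged as NA
  fm4 <- compute_fit_metrics(c(0, 0), c(1, 1), c(0.3, 0.3), ts)
  expect_true(is.na(fm4$smse) && is.na(fm4$ev))
  expect_error(compute_fit_metrics(0, 1, 0.3, ts), "at least 2")

  # tail percentages use the exact gaussian bounds, not 1.96
  z_edge <- c(-1.9599, -1.96, 1.9599, 1.96, 0)  # all inside +-1.959964
  fm5 <- compute_fit_metrics(rep(0, 5), rep(1, 5), z_edge, ts)
  expect_equal(fm5$lower_tail_pct, 100 * 1 / 5)  # only -1.96 is outside
  expect_equal(fm5$upper_tail_pct, 100 * 1 / 5)
})

test_that("ICC(2,1): exact cases and brute-force ANOVA oracle", {
  # identical iterations, distinct subjects: ICC = 1
  M <- matrix(rep(c(1, 2, 3, 5, 8, 13), 3), ncol = 3)
  expect_equal(icc_2_1(M)$icc, 1, tolerance = 1e-12)

  # no subject effect: ICC near 0 on a large simulation
  set.seed(1)
  M0 <- matrix(rnorm(1e4 * 3), ncol = 3)
  expect_lt(abs(icc_2_1(M0)$icc), 0.03)

  # 6 x 3 toy matrix vs an independent ANOVA mean-squares oracle (aov)
  set.seed(2)
  M3 <- matrix(rnorm(18, sd = 1), 6, 3) + rnorm(6, sd = 2)
  d <- data.frame(v = as.vector(M3),
                  s = factor(rep(1:6, 3)),
                  r = factor(rep(1:3, each = 6)))
  ms <- summary(aov(v ~ s + r, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  oracle <- (msr - mse) / (msr + 2 * mse + 3 * (msc - mse) / 6)
  expect_equal(icc_2_1(M3)$icc, oracle, tolerance = 1e-10)

  expect_error(icc_2_1(M3[1, , drop = FALSE]), ">= 2 subjects")
  M3[2, 2] <- NA
  expect_error(icc_2_1(M3), "missing cells")
})

test_that("z_error: identities, sign convention, axis checks", {
  z_full <- matrix(rnorm(40), 8, 5,
                   dimnames = list(paste0("s", 1:8), paste0("r", 1:5)))
  expect_equal(z_error(z_full, z_full)$mse, rep(0, 8), ignore_attr = TRUE)

  # uniform shift of -0.5: MSE 0.25, MBE -0.5 (overestimated deviations)
  ze <- z_error(z_full - 0.5, z_full)
  expect_equal(ze$mse, rep(0.25, 8), ignore_attr = TRUE)
  expect_equal(ze$mbe, rep(-0.5, 8), ignore_attr = TRUE)

  bad <- z_full[, 1:4]
  expect_error(z_error(bad, z_full), "share subjects")
})

test_that("IQR exclusion flags extreme cell values only", {
  df <- data.frame(strategy = "rep", n = 10, group = "HC",
                   mse = c(1, 1, 1, 1, 100))
  out <- iqr_exclude(df, "mse", by = c("strategy", "n", "group"), k = 3)
  expect_identical(out$excluded, c(FALSE, FALSE, FALSE, FALSE, TRUE))

  # cells are independent: a well-spread second cell keeps all its values
  df2 <- rbind(df, data.frame(strategy = "rep", n = 20, group = "HC",
                              mse = c(96, 98, 100, 102, 104)))
  out2 <- iqr_exclude(df2, "mse", by = c("strategy", "n", "group"), k = 3)
  expect_identical(sum(out2$excluded[6:10]), 0L)
  expect_identical(out2$excluded[1:5], out$excluded)

  # a degenerate cell (IQR = 0) keeps only the modal value
  df3 <- data.frame(strategy = "rep", n = 20, group = "HC",
                    mse = c(99, 100, 100, 100, 101))
  out3 <- iqr_exclude(df3, "mse", by = "strategy", k = 3)
  expect_identical(out3$excluded, c(TRUE, FALSE, FALSE, FALSE, TRUE))
})

test_that("cubic age profile: recovery, constant input, vertex location", {
  set.seed(3)
  ages <- runif(400, 44, 82)
  beta <- c(5, -0.3, 0.004, -0.00001)
  mse <- beta[1] + beta[2] * ages + beta[3] * ages^2 + beta[4] * ages^3 +
    rnorm(400, 0, 0.05)
  fit <- mse_age_profile(mse, ages)
  ci <- confint(lm(mse ~ ages + I(ages^2) + I(ages^3)))
  expect_true(all(fit$coefficients >= ci[, 1] & fit$coefficients <= ci[, 2]))

  flat <- mse_age_profile(rep(2, 100), runif(100, 44, 82))
  expect_lt(max(abs(flat$coefficients[-1])), 1e-8)

  # U-shape: fitted minimum strictly inside the age range
  u <- (ages - 63)^2 / 100 + rnorm(400, 0, 0.02)
  fu <- mse_age_profile(u, ages)
  amin <- ages[which.min(fu$fitted)]
  expect_gt(amin, 50)
  expect_lt(amin, 76)

  expect_error(mse_age_profile(1:3, 1:3), "at least 5")
})
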