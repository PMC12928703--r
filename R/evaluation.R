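#' Model-fit metrics on a test set
#'
#' All quantities are computed in the model's warped/standardized space, where
#' the Gaussian variance decomposition is exact:
#' * `msll` — mean Gaussian log loss under the model minus the log loss of the
#'   trivial predictor that uses the training mean/variance (0 = no better
#'   than the trivial predictor; more negative is better);
#' * `smse` — mean squared error divided by the (population) test variance;
#' * `ev` — explained variance `1 - var(residual)/var(y)`;
#' * `rho` — Pearson correlation of predictions with observations;
#' * `lower_tail_pct` / `upper_tail_pct` — percentage of test z-scores below
#'   `-1.959964` / above `+1.959964`, the exact Gaussian 2.5/97.5 centile
#'   bounds of the nominal 95% interval.
#'
#' @param mean_w Predicted warped-space means.
#' @param s2_total Total predictive variances (aleatoric + epistemic).
#' @param t_test Warped test responses (use [fit_metrics_for_model()] to get
#'   them from raw values).
#' @param train_summary The model's `train_summary` (needs `mean_w`, `var_w`).
#' @return An `nm_fit_metrics` one-row data.frame.
#' @export
compute_fit_metrics <- function(mean_w, s2_total, t_test, train_summary) {
  if (length(t_test) < 2) stop("need at least 2 test subjects")
  resid <- t_test - mean_w
  v_test <- var_pop(t_test)
  loss_model <- mean(0.5 * log(2 * pi * s2_total) + resid^2 / (2 * s2_total))
  loss_triv <- mean(0.5 * log(2 * pi * train_summary$var_w) +
                    (t_test - train_summary$mean_w)^2 / (2 * train_summary$var_w))
  z <- resid / sqrt(s2_total)
  qb <- stats::qnorm(0.975)  # 1.959964, the exact nominal bound
  degenerate <- v_test <= 0
  out <- data.frame(
    msll = loss_model - loss_triv,
    smse = if (degenerate) NA_real_ else mean(resid^2) / v_test,
    ev = if (degenerate) NA_real_ else 1 - var_pop(resid) / v_test,
    rho = if (degenerate || stats::sd(mean_w) == 0) NA_real_ else
      stats::cor(mean_w, t_test),
    lower_tail_pct = 100 * mean(z < -qb),
    upper_tail_pct = 100 * mean(z > qb)
  )
  class(out) <- c("nm_fit_metrics", class(out))
  out
}

#' Fit metrics of one model on raw test data
#'
#' Convenience wrapper: predicts, warps the observed responses, and calls
#' [compute_fit_metrics()].
#'
#' @param model A fitted `nm_model`.
#' @param subjects Test subjects (`age`, `sex`, `site`).
#' @param y Observed test responses.
#' @export
fit_metrics_for_model <- function(model, subjects, y) {
  pr <- predict(model, subjects)
  compute_fit_metrics(pr$mean, pr$s2_aleatoric + pr$s2_epistemic,
                      warp_response(model, y), model$train_summary)
}

#' ICC(2,1): two-way random effects, absolute agreement, single measurement
#'
#' Computed from the two-way ANOVA mean squares of a complete
#' subjects x iterations matrix:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where rows are subjects, columns are repeated draws (the "raters").
#'
#' @param z_by_iteration Numeric matrix, subjects (rows) x iterations
#'   (columns); no missing cells.
#' @return An `nm_icc` list: `icc` plus the three mean squares and variance
#'   components.
#' @export
icc_2_1 <- function(z_by_iteration) {
  M <- as.matrix(z_by_iteration)
  n <- nrow(M)
  k <- ncol(M)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 iterations")
  if (anyNA(M)) stop("missing cells are not allowed (no imputation)")
  grand <- mean(M)
  row_m <- rowMeans(M)
  col_m <- colMeans(M)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_t <- sum((M - grand)^2)
  ss_e <- ss_t - ss_r - ss_c
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)
  structure(list(
    icc = icc, ms_subject = ms_r, ms_iteration = ms_c, ms_residual = ms_e,
    var_subject = (ms_r - ms_e) / k,
    var_iteration = (ms_c - ms_e) / n,
    var_residual = ms_e,
    n_subjects = n, n_iterations = k
  ), class = "nm_icc")
}

#' Per-subject z-score error against the full-sample reference
#'
#' For each subject, `mse` is the mean over retained ROIs of
#' `(z_sub - z_full)^2` and `mbe` the mean of `(z_sub - z_full)`; negative
#' `mbe` means deviations are overestimated (more negative z than the
#' reference model would give).
#'
#' @param z_sub Deviation-score matrix from a subsampled model
#'   (subjects x ROI).
#' @param z_full Matching matrix from the full-sample reference model.
#' @return Data frame with `id`, `mse`, `mbe`.
#' @export
z_error <- function(z_sub, z_full) {
  if (!identical(dim(z_sub), dim(z_full)) ||
      !identical(dimnames(z_sub), dimnames(z_full)))
    stop("z_sub and z_full must share subjects and ROIs")
  d <- z_sub - z_full
  data.frame(id = rownames(z_sub) %||% as.character(seq_len(nrow(d))),
             mse = rowMeans(d^2), mbe = rowMeans(d),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Exclude extreme values by the k x IQR rule within cells
#'
#' Values outside `[Q1 - k*IQR, Q3 + k*IQR]` of their cell (default cell:
#' strategy x n x group, pooling iterations) are flagged for exclusion before
#' cell-level averaging, damping the influence of rare aberrant iterations.
#'
#' @param df Data frame.
#' @param value_col Name of the numeric column to screen.
#' @param by Character vector of cell-defining columns (may be empty).
#' @param k IQR multiplier (default 3).
#' @return `df` with a logical `excluded` column appended.
#' @export
iqr_exclude <- function(df, value_col, by = character(0), k = 3) {
  cell <- if (length(by)) interaction(df[by], drop = TRUE) else factor(rep(1, nrow(df)))
  excluded <- logical(nrow(df))
  for (lev in levels(cell)) {
    i <- which(cell == lev)
    v <- df[[value_col]][i]
    q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- q[2] - q[1]
    excluded[i] <- v < q[1] - k * iqr | v > q[2] + k * iqr
  }
  df$excluded <- excluded
  df
}

#' Cubic age profile of per-subject error
#'
#' Ordinary least squares of subject-level MSE on `{age, age^2, age^3}` plus
#' intercept; used to localize where on the age axis deviation-score errors
#' concentrate.
#'
#' @param mse Per-subject error values.
#' @param ages Matching ages.
#' @return List with `coefficients` (intercept, age, age^2, age^3), `fitted`,
#'   and `rank_deficient` flag.
#' @export
mse_age_profile <- function(mse, ages) {
  if (length(mse) < 5) stop("need at least 5 subjects")
  fit <- stats::lm(mse ~ ages + I(ages^2) + I(ages^3))
  co <- stats::coef(fit)
  list(coefficients = stats::setNames(as.numeric(co),
                                      c("intercept", "age", "age2", "age3")),
       fitted = stats::fitted(fit),
       rank_deficient = anyNA(co) || fit$rank < 4)
}
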