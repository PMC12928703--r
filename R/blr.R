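#' Negative log marginal likelihood of the warped Bayesian linear regression
#'
#' Responses are warped by the sinh-arcsinh function
#' `phi(y) = sinh(delta * asinh(y) - epsilon)`; the Bayesian linear regression
#' evidence with isotropic weight prior precision `alpha_w` and noise
#' precision `beta_n` is evaluated on the warped responses, and the
#' log-Jacobian of the warp is added over observations:
#' \deqn{-\log p(y) = -\log p_{BLR}(\phi(y)) - \sum_i \log \phi'(y_i).}
#'
#' Hyperparameters are passed on log scale for the precisions and tail weight:
#' `hyper = (log alpha_w, log beta_n, epsilon, log delta)`. A non-finite
#' return signals degenerate hyperparameters (the optimizer backs away).
#'
#' @param hyper Numeric length-4 vector `(log alpha_w, log beta_n, epsilon,
#'   log delta)`.
#' @param design Design matrix (N x p), e.g. from [build_design()].
#' @param y Response vector (already standardized if the caller standardizes).
#' @return Scalar negative log likelihood.
#' @export
negative_log_likelihood <- function(hyper, design, y) {
  cache <- list(X = design, XtX = crossprod(design), y = y,
                p = ncol(design), n = nrow(design))
  nll_core(hyper, cache)
}

# Hyperparameter box: keeps the Powell search inside a numerically safe
# region; the data never push sensible fits near these walls.
hyper_ok <- function(h) {
  all(is.finite(h)) && all(abs(h[c(1, 2)]) <= 20) && abs(h[3]) <= 5 &&
    abs(h[4]) <= log(100)
}

nll_core <- function(hyper, cache) {
  if (!hyper_ok(hyper)) return(Inf)
  alpha <- exp(hyper[1])
  beta <- exp(hyper[2])
  eps <- hyper[3]
  delta <- exp(hyper[4])
  t <- sinh_arcsinh(cache$y, eps, delta)
  if (!all(is.finite(t))) return(Inf)
  A <- alpha * diag(cache$p) + beta * cache$XtX
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(Inf)
  Xt_t <- crossprod(cache$X, t)
  m <- beta * backsolve(R, forwardsolve(t(R), Xt_t))
  rss <- sum(t^2) - 2 * sum(m * Xt_t) + drop(crossprod(m, cache$XtX %*% m))
  log_ev <- 0.5 * cache$p * hyper[1] + 0.5 * cache$n * hyper[2] -
    0.5 * cache$n * log(2 * pi) -
    0.5 * beta * rss - 0.5 * alpha * sum(m^2) -
    sum(log(diag(R)))
  jac <- sum(log(sinh_arcsinh_deriv(cache$y, eps, delta)))
  out <- -log_ev - jac
  if (!is.finite(out)) return(Inf)
  out
}

# Posterior for fixed hyperparameters: mean m and covariance A^{-1}.
blr_posterior <- function(hyper, cache) {
  alpha <- exp(hyper[1])
  beta <- exp(hyper[2])
  t <- sinh_arcsinh(cache$y, hyper[3], exp(hyper[4]))
  A <- alpha * diag(cache$p) + beta * cache$XtX
  R <- chol(A)
  m <- beta * backsolve(R, forwardsolve(t(R), crossprod(cache$X, t)))
  list(m = drop(m), A_inv = chol2inv(R), t = t)
}

#' Fit a warped BLR normative model for one region of interest
#'
#' Responses are standardized by the training mean/SD (stabilizes the
#' hyperparameter search), then modelled as
#' `phi(y_std) ~ N(design %*% w, 1/beta_n)` with weight prior
#' `w ~ N(0, I/alpha_w)`. The four hyperparameters
#' `(log alpha_w, log beta_n, epsilon, log delta)` minimize the negative log
#' marginal likelihood via Powell's conjugate-direction method, restarted from
#' the origin and two fixed jittered points; the best finite optimum wins.
#'
#' @param subjects Data frame with `age`, `sex`, `site` for the training set.
#' @param y Numeric response vector (one ROI), same length as rows.
#' @param basis An [basis_spec()] (defaults to one built from `subjects`).
#' @param standardize Standardize `y` by training mean/SD first (default TRUE;
#'   disable when fitting data already on the model's own scale, e.g. for
#'   exact warp-parameter recovery studies).
#' @param warp Fit the sinh-arcsinh warp (default TRUE); `FALSE` pins
#'   `(epsilon, delta) = (0, 1)`, reducing to standard BLR.
#' @param tol Powell convergence tolerance on the NLL (default 1e-6).
#' @param fixed_hyper Optional length-4 vector `(log alpha_w, log beta_n,
#'   epsilon, log delta)`; when given, the optimization is skipped and the
#'   posterior is computed at exactly these hyperparameters.
#' @return An `nm_model` with posterior mean/covariance, hyperparameters,
#'   warp, training summaries, and fit diagnostics (`nll`, `converged`,
#'   `flagged`).
#' @export
fit_roi <- function(subjects, y, basis = NULL, standardize = TRUE,
                    warp = TRUE, tol = 1e-6, fixed_hyper = NULL) {
  if (length(y) != nrow(subjects)) stop("y and subjects disagree")
  if (length(y) < 5) stop("need at least 5 training subjects")
  if (!all(is.finite(y))) stop("y must be finite")
  if (is.null(basis)) {
    basis <- basis_spec(subjects$age, site_levels = sort(unique(subjects$site)))
  }
  y_mean <- if (standardize) mean(y) else 0
  y_sd <- if (standardize) stats::sd(y) else 1
  flagged <- FALSE
  if (!is.finite(y_sd) || y_sd <= 0) {
    y_sd <- 1  # constant response: degenerate but well-defined predictions
    flagged <- TRUE
  }
  y_std <- (y - y_mean) / y_sd

  X <- build_design(subjects, basis)
  cache <- list(X = X, XtX = crossprod(X), y = y_std, p = ncol(X), n = nrow(X))
  if (!is.null(fixed_hyper)) {
    stopifnot(length(fixed_hyper) == 4)
    best <- list(par = fixed_hyper, value = nll_core(fixed_hyper, cache),
                 converged = TRUE)
    warp <- TRUE
  } else if (warp) {
    obj <- function(h) nll_core(h, cache)
    starts <- list(c(0, 0, 0, 0),
                   c(1, -1, 0.3, 0.2),
                   c(-1, 1, -0.3, -0.2))
  } else {
    obj <- function(h) nll_core(c(h, 0, 0), cache)
    starts <- list(c(0, 0), c(1, -1), c(-1, 1))
  }
  if (is.null(fixed_hyper)) {
    best <- NULL
    for (s in starts) {
      fit <- powell_minimize(obj, s, tol = tol)
      if (is.finite(fit$value) && (is.null(best) || fit$value < best$value)) {
        best <- fit
      }
    }
    if (is.null(best) || !is.finite(best$value)) {
      flagged <- TRUE
      best <- list(par = rep(0, length(starts[[1]])), value = Inf,
                   converged = FALSE)
    }
  }
  hyper <- if (warp) best$par else c(best$par, 0, 0)
  post <- blr_posterior(hyper, cache)
  t_train <- post$t
  loss_trivial <- 0.5 * log(2 * pi * var_pop(t_train)) +
    (t_train - mean(t_train))^2 / (2 * var_pop(t_train))
  structure(list(
    basis = basis,
    warp = list(epsilon = hyper[3], delta = exp(hyper[4])),
    alpha_w = exp(hyper[1]),
    beta_n = exp(hyper[2]),
    m = post$m,
    A_inv = post$A_inv,
    y_mean = y_mean,
    y_sd = y_sd,
    standardize = standardize,
    train_summary = list(
      mean_w = mean(t_train),
      var_w = var_pop(t_train),
      mean_train_loss = mean(loss_trivial),
      n_train = length(y)
    ),
    adapt_offsets = numeric(0),
    nll = best$value,
    converged = isTRUE(best$converged),
    flagged = flagged || !isTRUE(best$converged)
  ), class = "nm_model")
}

#' @export
print.nm_model <- function(x, ...) {
  cat(sprintf(
    "<nm_model> n_train=%d eps=%.3f delta=%.3f alpha=%.3g beta=%.3g nll=%.3f%s\n",
    x$train_summary$n_train, x$warp$epsilon, x$warp$delta, x$alpha_w,
    x$beta_n, x$nll, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

# Map an observed response onto the model's warped (Gaussian) space.
warp_response <- function(model, y) {
  sinh_arcsinh((y - model$y_mean) / model$y_sd,
               model$warp$epsilon, model$warp$delta)
}

# Inverse: warped-space value back to the measurement scale.
unwarp_response <- function(model, t) {
  model$y_mean + model$y_sd *
    sinh_arcsinh_inv(t, model$warp$epsilon, model$warp$delta)
}

#' Predict from a fitted normative model
#'
#' Returns the warped-space predictive mean, the aleatoric variance
#' `1/beta_n`, the epistemic (leverage) variance `x' A^{-1} x`, and optionally
#' data-space centiles
#' `phi^{-1}(mean + qnorm(q) * sqrt(s2_a + s2_e))` mapped back through the
#' training standardization. Centiles use total variance by default;
#' `centile_variance = "aleatoric"` restricts to the irreducible part.
#'
#' @param object A fitted `nm_model`.
#' @param subjects Data frame with `age`, `sex`, `site`.
#' @param q Optional vector of centile probabilities in (0, 1).
#' @param centile_variance `"total"` (default) or `"aleatoric"`.
#' @param ... Unused.
#' @return List with `mean` (warped space), `s2_aleatoric`, `s2_epistemic`,
#'   and (if `q` given) `centiles`, an N x length(q) matrix on the
#'   measurement scale.
#' @export
predict.nm_model <- function(object, subjects, q = NULL,
                             centile_variance = c("total", "aleatoric"), ...) {
  centile_variance <- match.arg(centile_variance)
  if (is.null(object$m)) stop("model is not fitted")
  adapted <- length(object$adapt_offsets) > 0
  X <- build_design(subjects, object$basis,
                    unknown_site = if (adapted) "reference" else "error")
  mean_w <- drop(X %*% object$m)
  if (adapted) {
    off <- object$adapt_offsets[subjects$site]
    off[is.na(off)] <- 0
    mean_w <- mean_w + off
  }
  s2e <- rowSums((X %*% object$A_inv) * X)
  s2a <- 1 / object$beta_n
  out <- list(mean = mean_w, s2_aleatoric = rep(s2a, length(mean_w)),
              s2_epistemic = s2e)
  if (!is.null(q)) {
    if (any(q <= 0 | q >= 1)) stop("q must lie strictly inside (0, 1)")
    s2 <- if (centile_variance == "total") s2a + s2e else rep(s2a, length(mean_w))
    cent <- vapply(q, function(qq) {
      unwarp_response(object, mean_w + stats::qnorm(qq) * sqrt(s2))
    }, numeric(length(mean_w)))
    out$centiles <- matrix(cent, ncol = length(q),
                           dimnames = list(NULL, format(q)))
  }
  out
}

#' Deviation (z) scores under a fitted normative model
#'
#' `z = (phi(y_std) - predicted mean) / sqrt(s2_aleatoric + s2_epistemic)`:
#' the warped residual scaled by the total predictive standard deviation,
#' combining irreducible observation noise with posterior parameter
#' uncertainty.
#'
#' @param model A fitted `nm_model`.
#' @param subjects Data frame with `age`, `sex`, `site`.
#' @param y Observed responses.
#' @return List with `z`, `warped_residual`, `s2_aleatoric`, `s2_epistemic`.
#' @export
zscores <- function(model, subjects, y) {
  pr <- predict(model, subjects)
  t <- warp_response(model, y)
  resid <- t - pr$mean
  s2 <- pr$s2_aleatoric + pr$s2_epistemic
  list(z = resid / sqrt(s2), warped_residual = resid,
       s2_aleatoric = pr$s2_aleatoric, s2_epistemic = pr$s2_epistemic)
}

#' Transfer-learning adaptation by mean-level offsets
#'
#' Recalibrates a pre-trained model to a new cohort: for each target site, the
#' offset is the mean warped residual of the adaptation subjects, added to all
#' subsequent predictions for that site. Variance, warp and posterior
#' covariance are left untouched, so explained variance and correlation on a
#' fixed test set are unchanged by adaptation.
#'
#' @param model A fitted `nm_model` (the pre-trained reference model).
#' @param subjects Adaptation subjects (data frame with `age`, `sex`, `site`).
#' @param y Their observed responses.
#' @return The adapted `nm_model`.
#' @export
adapt <- function(model, subjects, y) {
  if (nrow(subjects) < 1) stop("empty adaptation set")
  probe <- model
  probe$adapt_offsets <- stats::setNames(0, "..probe..")  # force reference-site design
  pr <- predict(probe, subjects)
  resid <- warp_response(model, y) - pr$mean
  offsets <- tapply(resid, subjects$site, mean)
  model$adapt_offsets <- stats::setNames(as.numeric(offsets), names(offsets))
  model
}

#' Serialize / restore a normative model as JSON text
#'
#' Versioned flat document holding the basis spec, warp, hyperparameters,
#' posterior arrays and training summaries; round-trips exactly.
#'
#' @param model An `nm_model`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @export
model_to_json <- function(model, path = NULL) {
  doc <- list(
    schema = "normref-model/1",
    basis = list(degree = model$basis$degree,
                 interior_knots = model$basis$interior_knots,
                 boundary = model$basis$boundary,
                 site_levels = model$basis$site_levels,
                 n_spline = model$basis$n_spline),
    warp = model$warp,
    alpha_w = model$alpha_w, beta_n = model$beta_n,
    m = model$m, A_inv = model$A_inv,
    y_mean = model$y_mean, y_sd = model$y_sd,
    standardize = model$standardize,
    train_summary = model$train_summary,
    adapt_offsets = as.list(model$adapt_offsets),
    nll = model$nll, converged = model$converged, flagged = model$flagged
  )
  txt <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    invisible(path)
  } else txt
}

#' @rdname model_to_json
#' @param json JSON string or file path produced by [model_to_json()].
#' @export
model_from_json <- function(json) {
  if (length(json) == 1 && file.exists(json)) json <- paste(readLines(json), collapse = "")
  doc <- jsonlite::fromJSON(json)
  if (!identical(doc$schema, "normref-model/1")) stop("unknown model schema")
  basis <- structure(list(
    degree = as.integer(doc$basis$degree),
    interior_knots = as.numeric(doc$basis$interior_knots),
    boundary = as.numeric(doc$basis$boundary),
    site_levels = as.character(doc$basis$site_levels),
    n_spline = as.integer(doc$basis$n_spline)
  ), class = "nm_basis")
  structure(list(
    basis = basis,
    warp = list(epsilon = doc$warp$epsilon, delta = doc$warp$delta),
    alpha_w = doc$alpha_w, beta_n = doc$beta_n,
    m = as.numeric(doc$m), A_inv = as.matrix(doc$A_inv),
    y_mean = doc$y_mean, y_sd = doc$y_sd,
    standardize = doc$standardize,
    train_summary = doc$train_summary,
    adapt_offsets = unlist(doc$adapt_offsets) %||% numeric(0),
    nll = doc$nll, converged = doc$converged, flagged = doc$flagged
  ), class = "nm_model")
}

#' Fit normative models for every ROI of a cohort subset
#'
#' @param cohort An `nm_cohort`.
#' @param ids Training subject ids.
#' @param rois ROI labels or indices (default: all).
#' @param basis Optional shared [basis_spec()]; built from the training
#'   subjects when `NULL`.
#' @param workers Parallel workers for per-ROI fits (forked via the parallel
#'   package when > 1); fits consume no RNG, so parallel and serial runs are
#'   identical and results are merged in deterministic ROI order.
#' @param ... Passed to [fit_roi()].
#' @return Named list of `nm_model` (class `nm_model_set`); flagged fits are
#'   kept but marked.
#' @export
fit_cohort_models <- function(cohort, ids, rois = NULL, basis = NULL,
                              workers = 1L, ...) {
  sub <- cohort$subjects[match(ids, cohort$subjects$id), , drop = FALSE]
  if (is.null(rois)) rois <- cohort$roi_labels
  if (is.numeric(rois)) rois <- cohort$roi_labels[rois]
  if (is.null(basis)) basis <- basis_spec(sub$age, site_levels = sort(unique(cohort$subjects$site)))
  idx <- match(ids, cohort$subjects$id)
  fit_one <- function(r) fit_roi(sub, cohort$values[idx, r], basis = basis, ...)
  models <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(rois, fit_one, mc.cores = workers)
  } else {
    lapply(rois, fit_one)
  }
  names(models) <- rois
  class(models) <- "nm_model_set"
  models
}

#' Deviation-score matrix for a set of fitted models
#'
#' @param models An `nm_model_set` from [fit_cohort_models()].
#' @param cohort The cohort to score.
#' @param ids Subject ids to score.
#' @return Numeric matrix subjects x ROI of z-scores (flagged models give NA
#'   columns).
#' @export
zscore_matrix <- function(models, cohort, ids) {
  sub <- cohort$subjects[match(ids, cohort$subjects$id), , drop = FALSE]
  idx <- match(ids, cohort$subjects$id)
  z <- sapply(names(models), function(r) {
    mdl <- models[[r]]
    if (mdl$flagged) return(rep(NA_real_, length(ids)))
    zscores(mdl, sub, cohort$values[idx, r])$z
  })
  z <- matrix(z, nrow = length(ids), dimnames = list(ids, names(models)))
  z
}
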