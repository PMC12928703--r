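#' Linear mixed model for fit metrics across the sampling sweep
#'
#' Fits `outcome ~ log(n) * strategy + (1 | roi)` by REML after z-scoring the
#' outcome and `log(n)` over the full table (so coefficients are comparable
#' standardized effect sizes). The representative strategy is the reference
#' level; p-values are Wald z statistics on the fixed effects.
#'
#' @param df Data frame with columns `n`, `strategy`, `roi`, and the outcome.
#' @param outcome Name of the outcome column.
#' @return An `nm_lmm`: data frame of terms with `beta`, `se`, `z`, `p`, plus
#'   attributes `re_variance`, `formula_tag`, `fit` (the lme4 object).
#' @export
fit_lmm_fit_metrics <- function(df, outcome) {
  d <- prepare_lmm_table(df, outcome, ref_group = FALSE)
  single <- nlevels(d$strategy) < 2
  form <- if (single) {
    warning("single strategy level: strategy terms dropped")
    outcome_z ~ logn_z + (1 | roi)
  } else {
    outcome_z ~ logn_z * strategy + (1 | roi)
  }
  lmm_result(form, d, "fit-metric form")
}

#' Linear mixed model for per-subject deviation outcomes
#'
#' Fits `outcome ~ log(n) * strategy * group + (1 | id)` (random intercept per
#' individual), with representative sampling and the HC group as reference
#' levels; standardization and inference as in [fit_lmm_fit_metrics()].
#'
#' @param df Data frame with columns `n`, `strategy`, `group`, `id`, and the
#'   outcome.
#' @inheritParams fit_lmm_fit_metrics
#' @export
fit_lmm_deviation <- function(df, outcome) {
  d <- prepare_lmm_table(df, outcome, ref_group = TRUE)
  single <- nlevels(d$strategy) < 2
  form <- if (single) {
    warning("single strategy level: strategy terms dropped")
    outcome_z ~ logn_z * group + (1 | id)
  } else {
    outcome_z ~ logn_z * strategy * group + (1 | id)
  }
  lmm_result(form, d, "deviation form")
}

prepare_lmm_table <- function(df, outcome, ref_group) {
  if (!outcome %in% names(df)) stop("missing outcome column: ", outcome)
  d <- df[stats::complete.cases(df[[outcome]], df$n), , drop = FALSE]
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  d$outcome_z <- zs(d[[outcome]])
  d$logn_z <- zs(log(d$n))
  levs <- unique(as.character(d$strategy))
  d$strategy <- factor(d$strategy,
                       levels = c(intersect("representative", levs),
                                  setdiff(levs, "representative")))
  if (ref_group && !is.null(d$group)) {
    gl <- unique(as.character(d$group))
    d$group <- factor(d$group, levels = c(intersect("HC", gl), setdiff(gl, "HC")))
  }
  d
}

lmm_result <- function(form, d, tag) {
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  zst <- beta / se
  out <- data.frame(term = names(beta), beta = as.numeric(beta),
                    se = as.numeric(se), z = as.numeric(zst),
                    p = 2 * stats::pnorm(-abs(zst)),
                    row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  attr(out, "re_variance") <- stats::setNames(vc$vcov, vc$grp)
  attr(out, "formula_tag") <- tag
  attr(out, "fit") <- fit
  class(out) <- c("nm_lmm", class(out))
  out
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values; monotone nondecreasing after sorting.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
fdr_correct <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Write an LMM coefficient table as CSV (term x outcome grid)
#'
#' @param results Named list of `nm_lmm` results (names become outcome
#'   columns).
#' @param path CSV path.
#' @export
write_lmm_table <- function(results, path) {
  terms <- unique(unlist(lapply(results, `[[`, "term")))
  grid <- data.frame(term = terms, stringsAsFactors = FALSE)
  for (nm in names(results)) {
    r <- results[[nm]]
    i <- match(terms, r$term)
    grid[[paste0(nm, "_beta")]] <- r$beta[i]
    grid[[paste0(nm, "_p")]] <- r$p[i]
  }
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}
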