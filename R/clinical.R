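#' Negative-deviation outlier flags
#'
#' A subject x ROI cell is an outlier when its deviation score is strictly
#' below the threshold (default -1.96, the conventional printed bound for the
#' bottom 2.5% of the normative range). Only negative outliers are flagged:
#' the clinical readout targets atrophy.
#'
#' @param z Deviation-score matrix (subjects x ROI).
#' @param threshold Outlier threshold (default -1.96; strict `<`).
#' @return Logical matrix of the same shape.
#' @export
outlier_flags <- function(z, threshold = -1.96) {
  if (any(!is.finite(z))) stop("z must be finite")
  z < threshold
}

#' Total outlier count per subject
#'
#' Number of ROIs in which each subject is flagged as a negative outlier
#' (row sums of the flag matrix).
#'
#' @param flags Logical matrix from [outlier_flags()].
#' @return Integer vector, one count per subject.
#' @export
toc <- function(flags) {
  as.integer(rowSums(flags))
}

#' Percentage of outlier subjects per ROI, by group
#'
#' @param flags Logical matrix from [outlier_flags()].
#' @param groups Group label per subject (e.g. `"HC"`/`"AD"`).
#' @return Data frame `roi`, `group`, `pct` (0-100).
#' @export
roi_outlier_pct <- function(flags, groups) {
  groups <- as.character(groups)
  if (length(groups) != nrow(flags)) stop("groups must match subjects")
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    idx <- groups == g
    if (!any(idx)) stop("empty group")
    data.frame(roi = colnames(flags) %||% as.character(seq_len(ncol(flags))),
               group = g,
               pct = 100 * colMeans(flags[idx, , drop = FALSE]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}

# L2-regularized linear SVC with squared-hinge loss, fitted by BFGS.
# Deterministic given the data; margins y*f below 1 are penalized
# quadratically, which keeps the objective differentiable.
svc_fit <- function(X, y, C = 1) {
  y <- ifelse(y > 0, 1, -1)
  p <- ncol(X)
  obj <- function(wb) {
    w <- wb[seq_len(p)]
    f <- drop(X %*% w) + wb[p + 1]
    s <- pmax(0, 1 - y * f)
    0.5 * sum(w^2) + C * sum(s^2)
  }
  grad <- function(wb) {
    w <- wb[seq_len(p)]
    f <- drop(X %*% w) + wb[p + 1]
    s <- pmax(0, 1 - y * f)
    gw <- w - 2 * C * drop(crossprod(X, y * s))
    gb <- -2 * C * sum(y * s)
    c(gw, gb)
  }
  fit <- stats::optim(rep(0, p + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  list(w = fit$par[seq_len(p)], b = fit$par[p + 1])
}

svc_decision <- function(model, X) drop(X %*% model$w) + model$b

#' HC/AD classification AUC from deviation scores
#'
#' Linear support-vector classifier (unit regularization, squared hinge) on
#' ROI-level z-score features, evaluated by stratified k-fold cross-validation:
#' features are standardized per fold using training-fold statistics only,
#' per-fold ROC areas are computed from the decision scores, and their mean is
#' returned.
#'
#' @param z Deviation-score matrix (subjects x ROI).
#' @param labels Diagnosis per subject (`"HC"`/`"AD"`; `"AD"` is positive).
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param C Regularization weight of the squared-hinge term (default 1).
#' @return Mean AUC across folds (`nm_auc` scalar with per-fold attribute).
#' @export
classify_auc <- function(z, labels, folds = 10L, seed = 1L, C = 1) {
  labels <- as.character(labels)
  pos <- labels == "AD"
  if (length(unique(labels)) < 2) stop("both classes must be present")
  folds <- min(folds, sum(pos), sum(!pos))
  fold_id <- integer(length(labels))
  with_seed(seed, {
    for (cls in list(which(pos), which(!pos))) {
      fold_id[cls] <- rep_len(seq_len(folds), length(cls))[sample.int(length(cls))]
    }
  })
  aucs <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    mu <- colMeans(z[tr, , drop = FALSE])
    sd <- apply(z[tr, , drop = FALSE], 2, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    Xtr <- sweep(sweep(z[tr, , drop = FALSE], 2, mu), 2, sd, "/")
    Xte <- sweep(sweep(z[!tr, , drop = FALSE], 2, mu), 2, sd, "/")
    mdl <- svc_fit(Xtr, ifelse(pos[tr], 1, -1), C = C)
    roc_auc(svc_decision(mdl, Xte), pos[!tr])
  }, numeric(1))
  structure(mean(aucs), fold_auc = aucs, class = "nm_auc")
}

#' Top regions by group effect size, with outlier percentages
#'
#' Ranks ROIs by Cohen's d separating two groups on their deviation scores
#' (reference group minus comparison, so atrophy gives positive d when the
#' comparison group deviates negatively) and returns the top `k` together
#' with per-group outlier percentages — a plain-table stand-in for regional
#' outlier heatmaps.
#'
#' @param z Deviation-score matrix (subjects x ROI).
#' @param groups Group label per subject (two levels, e.g. `"HC"`/`"AD"`).
#' @param k Number of regions to keep (default 20).
#' @param reference Label of the reference group (default `"HC"`).
#' @param threshold Outlier bound passed to [outlier_flags()].
#' @return Data frame `roi`, `cohens_d`, one `pct_<group>` column per group.
#' @export
top_effect_regions <- function(z, groups, k = 20L, reference = "HC",
                               threshold = -1.96) {
  groups <- as.character(groups)
  levs <- unique(groups)
  if (length(levs) != 2) stop("exactly two groups are required")
  other <- setdiff(levs, reference)
  a <- z[groups == reference, , drop = FALSE]
  b <- z[groups == other, , drop = FALSE]
  sp <- sqrt(((nrow(a) - 1) * apply(a, 2, stats::var) +
              (nrow(b) - 1) * apply(b, 2, stats::var)) /
             (nrow(a) + nrow(b) - 2))
  d <- (colMeans(a) - colMeans(b)) / sp
  pct <- roi_outlier_pct(outlier_flags(z, threshold), groups)
  out <- data.frame(roi = colnames(z), cohens_d = as.numeric(d),
                    stringsAsFactors = FALSE)
  for (g in c(reference, other)) {
    out[[paste0("pct_", g)]] <- pct$pct[pct$group == g][match(out$roi,
      pct$roi[pct$group == g])]
  }
  out <- out[order(-out$cohens_d), , drop = FALSE]
  utils::head(out, k)
}
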