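#' Design basis specification for a normative model
#'
#' Cubic B-spline basis on age with three evenly spaced interior knots over
#' the training age range (7 spline columns forming a partition of unity on
#' the boundary interval), plus an intercept, a male indicator and a block of
#' dummy-coded site indicators with the first (reference) site dropped.
#' Design column count is `1 + 7 + 1 + (n_sites - 1)`.
#'
#' Ages outside the boundary are handled by linear extension of the spline
#' columns (value plus first derivative at the nearest boundary), giving
#' bounded extrapolation instead of undefined behaviour.
#'
#' @param ages Training ages (define the boundary and knots).
#' @param site_levels Character vector of site labels; the first is the
#'   reference level.
#' @param degree Spline degree (default 3, cubic).
#' @param n_interior_knots Number of evenly spaced interior knots (default 3).
#' @return An `nm_basis` list.
#' @export
basis_spec <- function(ages, site_levels = character(0), degree = 3L,
                       n_interior_knots = 3L) {
  if (!all(is.finite(ages))) stop("ages must be finite")
  lo <- min(ages)
  hi <- max(ages)
  if (lo >= hi) stop("degenerate age range")
  interior <- seq(lo, hi, length.out = n_interior_knots + 2L)[-c(1L, n_interior_knots + 2L)]
  structure(list(
    degree = as.integer(degree),
    interior_knots = interior,
    boundary = c(lo, hi),
    site_levels = as.character(site_levels),
    n_spline = as.integer(n_interior_knots + degree + 1L)
  ), class = "nm_basis")
}

# Evaluate the spline block (partition of unity on [lo, hi], linear extension
# outside) for arbitrary ages.
spline_block <- function(age, basis) {
  lo <- basis$boundary[1]
  hi <- basis$boundary[2]
  ord <- basis$degree + 1L
  kn <- c(rep(lo, ord), basis$interior_knots, rep(hi, ord))
  x <- pmin(pmax(age, lo), hi)
  B <- splines::splineDesign(kn, x, ord = ord)
  low <- age < lo
  if (any(low)) {
    b0 <- drop(splines::splineDesign(kn, lo, ord = ord))
    d0 <- drop(splines::splineDesign(kn, lo, ord = ord, derivs = 1L))
    B[low, ] <- rep(1, sum(low)) %o% b0 + (age[low] - lo) %o% d0
  }
  high <- age > hi
  if (any(high)) {
    b1 <- drop(splines::splineDesign(kn, hi, ord = ord))
    d1 <- drop(splines::splineDesign(kn, hi, ord = ord, derivs = 1L))
    B[high, ] <- rep(1, sum(high)) %o% b1 + (age[high] - hi) %o% d1
  }
  B
}

#' Build the design matrix for a set of subjects
#'
#' Rows follow the basis layout: intercept, age-spline columns, male
#' indicator, site dummy block (reference site dropped).
#'
#' @param subjects Data frame with columns `age`, `sex` (`"F"`/`"M"`), `site`.
#' @param basis An [basis_spec()].
#' @param unknown_site `"error"` (default) rejects site labels absent from the
#'   registry; `"reference"` maps them to the reference level (used by
#'   transfer-learning adaptation, where the target site is represented by a
#'   learned mean offset instead of a dummy column).
#' @return Numeric design matrix.
#' @export
build_design <- function(subjects, basis, unknown_site = c("error", "reference")) {
  unknown_site <- match.arg(unknown_site)
  if (!all(is.finite(subjects$age))) stop("ages must be finite")
  B <- spline_block(subjects$age, basis)
  X <- cbind(intercept = 1, B, male = as.numeric(subjects$sex == "M"))
  colnames(X)[2:(1 + basis$n_spline)] <- sprintf("age_bs%d", seq_len(basis$n_spline))
  ns <- length(basis$site_levels)
  if (ns >= 1L) {
    idx <- match(subjects$site, basis$site_levels)
    if (anyNA(idx)) {
      if (unknown_site == "error") stop("unknown site label")
      idx[is.na(idx)] <- 1L
    }
    if (ns >= 2L) {
      S <- matrix(0, nrow(X), ns - 1L,
                  dimnames = list(NULL, paste0("site_", basis$site_levels[-1])))
      for (k in 2:ns) S[idx == k, k - 1L] <- 1
      X <- cbind(X, S)
    }
  }
  X
}
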