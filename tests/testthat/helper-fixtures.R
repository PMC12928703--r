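# Small fixture builders shared across the suite; everything is generated in
# code, nothing is read from disk.

tiny_config <- function(n_hc = 200, n_ad = 0, n_roi_c = 2, n_roi_s = 1, ...) {
  synthetic_config(n_hc = n_hc, n_ad = n_ad,
                   n_cortical_roi = n_roi_c, n_subcortical_roi = n_roi_s, ...)
}

# A hand-built cohort with fully controlled ages/sexes (no measurements
# needed) for the sampling tests.
manual_cohort <- function(ages, sexes, sites = "site01", dx = "HC") {
  n <- length(ages)
  subjects <- data.frame(
    id = sprintf("M%04d", seq_len(n)),
    age = ages,
    sex = rep_len(sexes, n),
    site = rep_len(sites, n),
    dx = rep_len(dx, n),
    stringsAsFactors = FALSE
  )
  values <- matrix(rnorm(n), n, 1, dimnames = list(subjects$id, "ct_001"))
  structure(list(subjects = subjects, values = values,
                 roi_labels = "ct_001", roi_class = "cortical",
                 sites = unique(subjects$site), config = NULL),
            class = "nm_cohort")
}

# Data drawn exactly from the warped-BLR generative law (the correctly
# specified case), used for recovery and calibration tests.
model_law_data <- function(n, eps, delta, sigma = 1, w_age = 0, seed = 1) {
  set.seed(seed)
  sub <- data.frame(age = runif(n, 44, 82),
                    sex = sample(c("F", "M"), n, TRUE),
                    site = "site01", stringsAsFactors = FALSE)
  bs <- basis_spec(sub$age, site_levels = "site01")
  X <- build_design(sub, bs)
  w <- c(0.3, w_age * sin(1:7), 0.1)  # w_age > 0 gives genuine age structure
  t_true <- drop(X %*% w) + sigma * rnorm(n)
  list(sub = sub, basis = bs, X = X, w = w, t = t_true,
       y = sinh_arcsinh_inv(t_true, eps, delta))
}
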