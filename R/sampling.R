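#' Stratified train/test split of a cohort
#'
#' Healthy controls are split into train/test within strata defined by
#' site x sex x 5-year age bin; every AD subject goes to the test set. The
#' global number of training HC is exactly `round(train_frac * n_HC)`
#' (largest-remainder allocation across strata), and every stratum's training
#' fraction is within one subject of `train_frac`. Strata with fewer than two
#' HC are merged with the nearest age bin of the same site x sex before
#' allocation.
#'
#' @param cohort An `nm_cohort`.
#' @param train_frac Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @return An `nm_split`: list with `train_ids`, `test_ids` (HC test plus all
#'   AD), `hc_test_ids`, `strata` (per-HC stratum labels), `seed`.
#' @export
#' @examples
#' coh <- generate_cohort(synthetic_config(n_hc = 100, n_ad = 10,
#'   n_cortical_roi = 2, n_subcortical_roi = 1), seed = 1)
#' sp <- stratified_split(coh, seed = 7)
#' length(sp$train_ids)
stratified_split <- function(cohort, train_frac = 0.8, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  hc <- cohort$subjects[cohort$subjects$dx == "HC", , drop = FALSE]
  if (nrow(hc) < 2) stop("need at least 2 HC to split")
  bin <- floor(hc$age / 5) * 5
  strat <- paste(hc$site, hc$sex, bin, sep = "|")

  # merge strata of size < 2 into the nearest 5-year bin of same site x sex
  repeat {
    tab <- table(strat)
    small <- names(tab)[tab < 2]
    if (!length(small)) break
    changed <- FALSE
    for (s in small) {
      parts <- strsplit(s, "|", fixed = TRUE)[[1]]
      sel <- strat == s
      peers <- unique(strat[!sel & hc$site == parts[1] & hc$sex == parts[2]])
      if (!length(peers)) {
        peers <- unique(strat[!sel & hc$site == parts[1]])
        if (!length(peers)) peers <- unique(strat[!sel])
      }
      if (!length(peers)) next
      pb <- suppressWarnings(as.numeric(vapply(
        strsplit(peers, "|", fixed = TRUE), `[`, character(1), 3)))
      target <- peers[which.min(abs(pb - as.numeric(parts[3])))]
      strat[sel] <- target
      changed <- TRUE
    }
    if (!changed) break
  }

  n_train_total <- round(train_frac * nrow(hc))
  levs <- sort(unique(strat))
  n_s <- as.integer(table(factor(strat, levels = levs)))
  quota <- train_frac * n_s
  base <- floor(quota)
  rem <- n_train_total - sum(base)
  train_ids <- character(0)
  with_seed(seed, {
    if (rem > 0) {
      frac <- quota - base
      ord <- order(-frac, stats::runif(length(levs)))  # largest remainder, random ties
      base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
    } else if (rem < 0) {
      ord <- order(quota - base, stats::runif(length(levs)))
      k <- -rem
      for (i in ord) {
        if (k == 0L) break
        if (base[i] > 0L) { base[i] <- base[i] - 1L; k <- k - 1L }
      }
    }
    for (i in seq_along(levs)) {
      ids_s <- hc$id[strat == levs[i]]
      take <- sample(ids_s, min(base[i], length(ids_s)))
      train_ids <- c(train_ids, take)
    }
  })
  hc_test <- setdiff(hc$id, train_ids)
  ad_ids <- cohort$subjects$id[cohort$subjects$dx == "AD"]
  structure(list(
    train_ids = sort(train_ids),
    test_ids = c(sort(hc_test), ad_ids),
    hc_test_ids = sort(hc_test),
    strata = stats::setNames(strat, hc$id),
    train_frac = train_frac,
    seed = as.integer(seed)
  ), class = "nm_split")
}

#' Sample-size grid for subsampling sweeps
#'
#' Increments of 5 from 5 to 200, then increments of 50 up to
#' `min(600, max_n)`, truncated at `max_n`.
#'
#' @param max_n Largest usable training-set size (>= 5).
#' @return Increasing integer vector.
#' @export
#' @examples
#' sample_size_grid(600) # 48 values
sample_size_grid <- function(max_n) {
  if (max_n < 5) stop("max_n must be >= 5")
  g <- c(seq(5L, 200L, by = 5L), seq(250L, 600L, by = 50L))
  g[g <= max_n]
}

#' Describe one training-set draw
#'
#' A fully seeded specification of a subsample: strategy, size, beta
#' parameters for age-skewed draws, sex ratio, bin count and iteration.
#' Skewed strategies fix their beta parameters (`left_skew` = Beta(2, 5)
#' favouring young ages, `right_skew` = Beta(5, 2) favouring old ages).
#'
#' @param strategy One of `"representative"`, `"left_skew"`, `"right_skew"`,
#'   `"sex_ratio"`.
#' @param n Requested subsample size (>= 1).
#' @param sex_ratio Length-2 integer F:M ratio, used by `"sex_ratio"` draws.
#' @param n_bins Number of age bins (default 10).
#' @param iteration Iteration index (1-based).
#' @param seed Integer seed; defaults to a hash of the other fields.
#' @param bin_weighting `"mass"` (integrated Beta CDF mass per bin, default)
#'   or `"pdf"` (density at bin centers) for skewed draws.
#' @return An `nm_scheme` list.
#' @export
sampling_scheme <- function(strategy = c("representative", "left_skew",
                                         "right_skew", "sex_ratio"),
                            n, sex_ratio = c(1L, 1L), n_bins = 10L,
                            iteration = 1L, seed = NULL,
                            bin_weighting = c("mass", "pdf")) {
  strategy <- match.arg(strategy)
  bin_weighting <- match.arg(bin_weighting)
  if (n < 1) stop("n must be >= 1")
  beta_params <- switch(strategy,
    left_skew = c(2, 5),
    right_skew = c(5, 2),
    NULL
  )
  if (is.null(seed)) seed <- derive_seed("scheme", strategy, n,
                                         paste(sex_ratio, collapse = ":"),
                                         iteration)
  structure(list(strategy = strategy, n = as.integer(n),
                 beta_params = beta_params,
                 sex_ratio = as.integer(sex_ratio),
                 n_bins = as.integer(n_bins),
                 iteration = as.integer(iteration),
                 seed = as.integer(seed),
                 bin_weighting = bin_weighting),
            class = "nm_scheme")
}

#' Beta-distribution weights over equal-width age bins
#'
#' Weight of bin i is the Beta(`alpha`, `beta`) probability mass on the bin's
#' sub-interval of `[0, 1]` (exact, via the Beta CDF), or optionally the
#' density at the bin center.
#'
#' @param n_bins Number of equal-width bins.
#' @param alpha,beta Beta shape parameters.
#' @param method `"mass"` or `"pdf"`.
#' @return Weights summing to 1.
#' @export
beta_bin_weights <- function(n_bins, alpha, beta, method = c("mass", "pdf")) {
  method <- match.arg(method)
  edges <- seq(0, 1, length.out = n_bins + 1)
  w <- if (method == "mass") {
    diff(stats::pbeta(edges, alpha, beta))
  } else {
    stats::dbeta((edges[-1] + edges[-(n_bins + 1)]) / 2, alpha, beta)
  }
  w / sum(w)
}

# Allocate n draws over bins with target weights, respecting per-bin capacity.
# Base counts are floor(target); leftover units go to bins chosen uniformly at
# random among those with spare capacity (under the caller's RNG). When a bin
# is exhausted its demand is redistributed proportionally to the remaining
# bins' weights, iterating until n units are placed.
allocate_counts <- function(n, weights, capacity) {
  k <- length(weights)
  stopifnot(length(capacity) == k)
  if (sum(capacity) < n) stop("requested n exceeds available subjects")
  alloc <- integer(k)
  repeat {
    need <- n - sum(alloc)
    if (need == 0L) break
    spare <- capacity - alloc
    w <- weights
    w[spare == 0L] <- 0
    if (sum(w) <= 0) w <- as.numeric(spare > 0L)
    w <- w / sum(w)
    base <- pmin(floor(need * w), spare)
    left <- need - sum(base)
    extra <- integer(k)
    if (left > 0L) {
      cand <- which(spare - base > 0L)
      while (left > 0L && length(cand)) {
        pick <- if (length(cand) >= left) {
          cand[sample.int(length(cand), left)]
        } else cand
        extra[pick] <- extra[pick] + 1L
        left <- left - length(pick)
        cand <- which(spare - base - extra > 0L)
      }
    }
    alloc <- alloc + base + extra
  }
  alloc
}

# Split a per-bin total into (F, M) counts, |F - M| <= 1 overall, respecting
# per-sex capacity; `diff_env` carries the running F - M balance.
split_sexes <- function(total, cap_f, cap_m, balance) {
  f <- total %/% 2L
  m <- total %/% 2L
  if (total %% 2L == 1L) {
    give_f <- if (balance < 0) TRUE else if (balance > 0) FALSE else
      stats::runif(1) < 0.5
    if (give_f) f <- f + 1L else m <- m + 1L
  }
  # shift across sexes when one pool is short
  if (f > cap_f) { m <- m + (f - cap_f); f <- cap_f }
  if (m > cap_m) { f <- f + (m - cap_m); m <- cap_m }
  if (f > cap_f) stop("bin population too small for requested draw")
  c(f = f, m = m)
}

#' Draw a representative subsample
#'
#' Ages of the candidate pool are discretized into `n_bins` quantile bins
#' (equal occupancy); an equal number of subjects is drawn per bin (leftover
#' units spread uniformly at random), with equal numbers of females and males
#' (within 1) overall.
#'
#' @param cohort An `nm_cohort`.
#' @param pool_ids Candidate subject ids (the training set).
#' @param scheme A [sampling_scheme()] with strategy `"representative"`.
#' @return Character vector of `scheme$n` selected ids.
#' @export
draw_representative <- function(cohort, pool_ids, scheme) {
  stopifnot(scheme$strategy %in% c("representative", "sex_ratio"))
  sub <- cohort$subjects[match(pool_ids, cohort$subjects$id), , drop = FALSE]
  n <- scheme$n
  if (n > nrow(sub)) stop("requested n exceeds available subjects")
  with_seed(scheme$seed, draw_representative_impl(sub, n, scheme$n_bins))
}

draw_representative_impl <- function(sub, n, n_bins) {
  if (n == nrow(sub)) return(sample(sub$id))
  edges <- unique(stats::quantile(sub$age, probs = seq(0, 1, length.out = n_bins + 1)))
  edges[1] <- -Inf
  edges[length(edges)] <- Inf
  bin <- cut(sub$age, edges, labels = FALSE)
  k <- max(bin)
  cap <- tabulate(bin, nbins = k)
  totals <- allocate_counts(n, rep(1, k), cap)
  ids <- character(0)
  balance <- 0L
  for (b in sample(seq_len(k))) {  # random bin order for unbiased sex parity
    if (totals[b] == 0L) next
    in_b <- sub[bin == b, , drop = FALSE]
    fm <- split_sexes(totals[b], sum(in_b$sex == "F"), sum(in_b$sex == "M"),
                      balance)
    balance <- balance + fm[["f"]] - fm[["m"]]
    pf <- in_b$id[in_b$sex == "F"]
    pm <- in_b$id[in_b$sex == "M"]
    ids <- c(ids,
             pf[sample.int(length(pf), fm[["f"]])],
             pm[sample.int(length(pm), fm[["m"]])])
  }
  ids
}

#' Draw an age-skewed subsample
#'
#' Ages of the pool are discretized into `n_bins` equal-width bins; bin draw
#' probabilities are proportional to the Beta(`alpha`, `beta`) mass on each
#' bin's sub-interval of `[0, 1]` (`left_skew`: Beta(2, 5); `right_skew`:
#' Beta(5, 2)). Subjects are drawn without replacement; exhausted bins
#' redistribute their demand proportionally to the remaining bins' weights.
#'
#' @inheritParams draw_representative
#' @param scheme Scheme with strategy `"left_skew"` or `"right_skew"`.
#' @export
draw_age_skewed <- function(cohort, pool_ids, scheme) {
  stopifnot(scheme$strategy %in% c("left_skew", "right_skew"))
  sub <- cohort$subjects[match(pool_ids, cohort$subjects$id), , drop = FALSE]
  n <- scheme$n
  if (n > nrow(sub)) stop("requested n exceeds available subjects")
  w <- beta_bin_weights(scheme$n_bins, scheme$beta_params[1],
                        scheme$beta_params[2], scheme$bin_weighting)
  rng <- range(sub$age)
  edges <- seq(rng[1], rng[2], length.out = scheme$n_bins + 1)
  edges[1] <- -Inf
  edges[length(edges)] <- Inf
  bin <- cut(sub$age, edges, labels = FALSE)
  cap <- tabulate(bin, nbins = scheme$n_bins)
  with_seed(scheme$seed, {
    counts <- allocate_counts(n, w, cap)
    ids <- character(0)
    for (b in seq_len(scheme$n_bins)) {
      if (counts[b] == 0L) next
      pool_b <- sub$id[bin == b]
      ids <- c(ids, pool_b[sample.int(length(pool_b), counts[b])])
    }
    ids
  })
}

#' Draw a sex-imbalanced subsample
#'
#' The representative age procedure is applied separately to the female and
#' male pools with target counts in the scheme's F:M ratio (rounded, summing
#' to `n`).
#'
#' @inheritParams draw_representative
#' @param scheme Scheme with strategy `"sex_ratio"`.
#' @export
draw_sex_imbalanced <- function(cohort, pool_ids, scheme) {
  stopifnot(scheme$strategy == "sex_ratio")
  sub <- cohort$subjects[match(pool_ids, cohort$subjects$id), , drop = FALSE]
  n <- scheme$n
  r <- scheme$sex_ratio
  n_f <- as.integer(round(n * r[1] / sum(r)))
  n_m <- n - n_f
  pf <- sub[sub$sex == "F", , drop = FALSE]
  pm <- sub[sub$sex == "M", , drop = FALSE]
  if (n_f > nrow(pf)) stop("female pool too small for requested ratio")
  if (n_m > nrow(pm)) stop("male pool too small for requested ratio")
  with_seed(scheme$seed, {
    ids_f <- if (n_f > 0L) draw_one_sex(pf, n_f, scheme$n_bins) else character(0)
    ids_m <- if (n_m > 0L) draw_one_sex(pm, n_m, scheme$n_bins) else character(0)
    c(ids_f, ids_m)
  })
}

# representative age bins within a single-sex pool
draw_one_sex <- function(sub, n, n_bins) {
  if (n == nrow(sub)) return(sample(sub$id))
  edges <- unique(stats::quantile(sub$age, probs = seq(0, 1, length.out = n_bins + 1)))
  edges[1] <- -Inf
  edges[length(edges)] <- Inf
  bin <- cut(sub$age, edges, labels = FALSE)
  k <- max(bin)
  counts <- allocate_counts(n, rep(1, k), tabulate(bin, nbins = k))
  ids <- character(0)
  for (b in seq_len(k)) {
    if (counts[b] == 0L) next
    pool_b <- sub$id[bin == b]
    ids <- c(ids, pool_b[sample.int(length(pool_b), counts[b])])
  }
  ids
}

#' Draw a subsample according to a sampling scheme
#'
#' Dispatches to [draw_representative()], [draw_age_skewed()] or
#' [draw_sex_imbalanced()] based on `scheme$strategy`.
#'
#' @inheritParams draw_representative
#' @export
draw_sample <- function(cohort, pool_ids, scheme) {
  switch(scheme$strategy,
    representative = draw_representative(cohort, pool_ids, scheme),
    left_skew = ,
    right_skew = draw_age_skewed(cohort, pool_ids, scheme),
    sex_ratio = draw_sex_imbalanced(cohort, pool_ids, scheme)
  )
}

#' Age-bin coverage of a test set by a training draw
#'
#' Age is discretized into `n_bins` quantile bins using a reference set (the
#' full training cohort); coverage is
#' \deqn{\mathrm{Coverage} = \sum_i \min(n_{train}(i), n_{test}(i)) / \sum_i n_{test}(i)}
#' ranging from 0 (no test-set ages covered) to 1 (complete coverage of the
#' test-set age distribution).
#'
#' @param train_ids,test_ids Subject id vectors.
#' @param cohort An `nm_cohort` holding both sets.
#' @param reference_ids Ids whose ages define the quantile bin edges
#'   (defaults to `train_ids`; in sweeps, pass the FULL training set).
#' @param n_bins Number of quantile bins (default 20).
#' @return An `nm_coverage` list: `bin_edges`, `n_train_per_bin`,
#'   `n_test_per_bin`, `coverage`.
#' @export
coverage <- function(train_ids, test_ids, cohort, reference_ids = train_ids,
                     n_bins = 20L) {
  if (!length(test_ids)) stop("empty test set")
  if (!length(reference_ids)) stop("empty reference set")
  ages <- stats::setNames(cohort$subjects$age, cohort$subjects$id)
  edges <- unique(stats::quantile(ages[reference_ids],
                                  probs = seq(0, 1, length.out = n_bins + 1)))
  edges[1] <- -Inf
  edges[length(edges)] <- Inf
  n_tr <- if (length(train_ids)) {
    tabulate(cut(ages[train_ids], edges, labels = FALSE), nbins = length(edges) - 1)
  } else rep(0L, length(edges) - 1)
  n_te <- tabulate(cut(ages[test_ids], edges, labels = FALSE),
                   nbins = length(edges) - 1)
  structure(list(
    bin_edges = edges,
    n_train_per_bin = n_tr,
    n_test_per_bin = n_te,
    coverage = sum(pmin(n_tr, n_te)) / sum(n_te)
  ), class = "nm_coverage")
}

#' Write a draw manifest (replayable record of a subsample)
#'
#' @param scheme A [sampling_scheme()].
#' @param ids Selected subject ids.
#' @param path CSV path.
#' @export
write_draw_manifest <- function(scheme, ids, path) {
  df <- data.frame(
    strategy = scheme$strategy, n = scheme$n,
    beta_alpha = if (is.null(scheme$beta_params)) NA else scheme$beta_params[1],
    beta_beta = if (is.null(scheme$beta_params)) NA else scheme$beta_params[2],
    sex_ratio = paste(scheme$sex_ratio, collapse = ":"),
    n_bins = scheme$n_bins, iteration = scheme$iteration,
    seed = scheme$seed, id = ids, stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
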