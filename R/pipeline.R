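#' Configuration of a subsampling experiment
#'
#' Bundles everything [run_sweep()] and [run_adaptation_arm()] need: the
#' cohort source, sampling strategies, the sample-size grid, iteration count,
#' thresholds, seeding and output location.
#'
#' @param cohort A [synthetic_config()], an `nm_cohort`, or a path to a cohort
#'   CSV written by [write_cohort_csv()].
#' @param strategies Character vector of strategies (see [sampling_scheme()]).
#' @param sex_ratios List of F:M integer pairs used when `"sex_ratio"` is
#'   among the strategies.
#' @param grid Integer vector of training sizes; `NULL` = [sample_size_grid()]
#'   up to the available training size.
#' @param iterations Random draws per (strategy, n) cell (default 10).
#' @param rois ROI labels/indices to model (`NULL` = all).
#' @param train_frac HC training fraction (default 0.8).
#' @param outlier_threshold Clinical outlier bound on z (default -1.96).
#' @param adaptation_reference Optional [synthetic_config()] for the large
#'   pre-training cohort of the transfer-learning arm.
#' @param out_dir Output directory for [write_results()] / the CLI.
#' @param master_seed Seed from which all per-task seeds are derived.
#' @param workers Parallel workers for per-ROI fitting (results are merged in
#'   deterministic ROI order, so parallel and serial runs are identical).
#' @return An `nm_experiment_config` list.
#' @export
experiment_config <- function(cohort,
                              strategies = c("representative", "left_skew", "right_skew"),
                              sex_ratios = list(c(1L, 1L)),
                              grid = NULL,
                              iterations = 10L,
                              rois = NULL,
                              train_frac = 0.8,
                              outlier_threshold = -1.96,
                              adaptation_reference = NULL,
                              out_dir = NULL,
                              master_seed = 1L,
                              workers = 1L) {
  if (iterations < 1) stop("iterations must be >= 1")
  structure(list(cohort = cohort, strategies = strategies,
                 sex_ratios = sex_ratios, grid = grid,
                 iterations = as.integer(iterations), rois = rois,
                 train_frac = train_frac,
                 outlier_threshold = outlier_threshold,
                 adaptation_reference = adaptation_reference,
                 out_dir = out_dir, master_seed = as.integer(master_seed),
                 workers = as.integer(workers)),
            class = "nm_experiment_config")
}

#' Desk-scale experiment preset
#'
#' A small default world for interactive use and testing: 20 ROIs, grid
#' `{5, 10, 15, 20, 25, 50, 100, 200}`, 10 iterations. The full 167-ROI,
#' 48-point grid is available via `preset = "full"`.
#'
#' @param n_hc,n_ad Cohort sizes.
#' @param preset `"desk"` (default) or `"full"`.
#' @param grid Optional grid override; the desk default is
#'   `{5, 10, 15, 20, 25, 50, 100, 200}`.
#' @param ... Passed on to [experiment_config()].
#' @export
preset_config <- function(n_hc = 1000, n_ad = 100, preset = c("desk", "full"),
                          grid = NULL, ...) {
  preset <- match.arg(preset)
  if (preset == "desk") {
    cfg <- synthetic_config(n_hc = n_hc, n_ad = n_ad,
                            n_cortical_roi = 14, n_subcortical_roi = 6)
    experiment_config(cfg,
                      grid = grid %||% c(5L, 10L, 15L, 20L, 25L, 50L, 100L, 200L),
                      ...)
  } else {
    cfg <- synthetic_config(n_hc = n_hc, n_ad = n_ad)
    experiment_config(cfg, grid = grid, ...)
  }
}

resolve_cohort <- function(config) {
  ch <- config$cohort
  if (inherits(ch, "nm_cohort")) return(ch)
  if (inherits(ch, "nm_synth_config")) {
    return(generate_cohort(ch, seed = derive_seed(config$master_seed, "cohort")))
  }
  if (is.character(ch)) return(read_cohort_csv(ch))
  stop("unsupported cohort source")
}

schemes_for <- function(config, n) {
  out <- list()
  for (s in config$strategies) {
    if (s == "sex_ratio") {
      for (r in config$sex_ratios) {
        for (it in seq_len(config$iterations)) {
          lab <- paste0("sex_", r[1], "to", r[2])
          out[[length(out) + 1L]] <- list(
            label = lab,
            scheme = sampling_scheme("sex_ratio", n, sex_ratio = r, iteration = it,
              seed = derive_seed(config$master_seed, lab, n, it)))
        }
      }
    } else {
      for (it in seq_len(config$iterations)) {
        out[[length(out) + 1L]] <- list(
          label = s,
          scheme = sampling_scheme(s, n, iteration = it,
            seed = derive_seed(config$master_seed, s, n, it)))
      }
    }
  }
  out
}

# Shared preamble of both arms: cohort, fixed split, ROI list, grid.
sweep_frame <- function(config) {
  cohort <- resolve_cohort(config)
  split <- stratified_split(cohort, config$train_frac,
                            seed = derive_seed(config$master_seed, "split"))
  rois <- config$rois %||% cohort$roi_labels
  if (is.numeric(rois)) rois <- cohort$roi_labels[rois]
  n_train <- length(split$train_ids)
  grid <- config$grid %||% sample_size_grid(n_train)
  usable <- grid[grid <= n_train]
  if (length(usable) < length(grid)) {
    warning(sprintf("dropping grid values above the training size (%d): %s",
                    n_train, paste(setdiff(grid, usable), collapse = ", ")))
  }
  list(cohort = cohort, split = split, rois = rois, grid = usable)
}

#' Run the full subsampling sweep
#'
#' Fits the full-sample reference model once, then for every
#' (strategy, n, iteration): draws a training subsample, refits all ROI
#' models, and evaluates on the FIXED test set — fit metrics per ROI (HC
#' test), z-score errors against the reference model (HC and AD), coverage of
#' the HC test ages, total outlier counts, and HC/AD classification AUC.
#' ICC(2,1) of the HC-test z-scores across iterations is computed per
#' (strategy, n, roi). Every row carries a derived seed; re-running the same
#' config reproduces identical tables.
#'
#' @param config An [experiment_config()].
#' @return An `nm_results` list of tidy data frames (`fit_metrics`, `icc`,
#'   `z_errors`, `toc`, `auc`, `coverage`), the `reference` block (models,
#'   reference z-scores and metrics), `manifests`, and the `split`.
#' @export
run_sweep <- function(config) {
  fr <- sweep_frame(config)
  cohort <- fr$cohort
  split <- fr$split
  rois <- fr$rois
  test_sub <- cohort$subjects[match(split$test_ids, cohort$subjects$id), , drop = FALSE]
  hc_test <- split$hc_test_ids
  groups <- stats::setNames(test_sub$dx, test_sub$id)
  has_ad <- any(test_sub$dx == "AD")

  ref_models <- fit_cohort_models(cohort, split$train_ids, rois,
                                  workers = config$workers)
  z_ref <- zscore_matrix(ref_models, cohort, split$test_ids)
  ref_fit <- roi_fit_table(ref_models, cohort, hc_test,
                           strategy = "full", n = length(split$train_ids),
                           iteration = 0L)

  fit_rows <- list(ref_fit)
  zerr_rows <- list()
  toc_rows <- list()
  auc_rows <- list()
  cov_rows <- list()
  manifests <- list()
  z_store <- list()  # [strategy|n][[roi]] subjects x iterations, for ICC

  for (n in fr$grid) {
    for (task in schemes_for(config, n)) {
      sch <- task$scheme
      lab <- task$label
      ids <- draw_sample(cohort, split$train_ids, sch)
      manifests[[paste(lab, n, sch$iteration, sep = "|")]] <-
        list(scheme = sch, ids = ids)
      models <- fit_cohort_models(cohort, ids, rois, workers = config$workers)
      fit_rows[[length(fit_rows) + 1L]] <-
        roi_fit_table(models, cohort, hc_test, lab, n, sch$iteration)
      z <- zscore_matrix(models, cohort, split$test_ids)
      ok <- !apply(is.na(z), 2, any) & !apply(is.na(z_ref), 2, any)
      ze <- z_error(z[, ok, drop = FALSE], z_ref[, ok, drop = FALSE])
      ze$group <- groups[ze$id]
      ze <- cbind(strategy = lab, n = n, iteration = sch$iteration, ze)
      zerr_rows[[length(zerr_rows) + 1L]] <- ze
      flags <- outlier_flags(z[, ok, drop = FALSE], config$outlier_threshold)
      toc_rows[[length(toc_rows) + 1L]] <- data.frame(
        strategy = lab, n = n, iteration = sch$iteration,
        id = rownames(z), group = groups[rownames(z)],
        toc = toc(flags), stringsAsFactors = FALSE)
      if (has_ad) {
        auc_rows[[length(auc_rows) + 1L]] <- data.frame(
          strategy = lab, n = n, iteration = sch$iteration,
          auc = as.numeric(classify_auc(z[, ok, drop = FALSE], groups[rownames(z)],
            seed = derive_seed(config$master_seed, "auc", lab, n, sch$iteration))))
      }
      cov <- coverage(ids, hc_test, cohort, reference_ids = split$train_ids)
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        strategy = lab, n = n, iteration = sch$iteration,
        coverage = cov$coverage)
      key <- paste(lab, n, sep = "|")
      if (is.null(z_store[[key]])) z_store[[key]] <- list()
      z_store[[key]][[length(z_store[[key]]) + 1L]] <- z[hc_test, , drop = FALSE]
    }
  }

  icc_rows <- list()
  for (key in names(z_store)) {
    mats <- z_store[[key]]
    if (length(mats) < 2) next
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    for (r in colnames(mats[[1]])) {
      cols <- vapply(mats, function(m) m[, r], numeric(nrow(mats[[1]])))
      if (anyNA(cols)) next
      icc_rows[[length(icc_rows) + 1L]] <- data.frame(
        strategy = parts[1], n = as.integer(parts[2]), roi = r,
        icc = icc_2_1(cols)$icc, stringsAsFactors = FALSE)
    }
  }

  bindr <- function(lst) if (length(lst)) do.call(rbind, lst) else NULL
  ref_toc <- toc(outlier_flags(z_ref[, !apply(is.na(z_ref), 2, any), drop = FALSE],
                               config$outlier_threshold))
  structure(list(
    fit_metrics = bindr(fit_rows),
    icc = bindr(icc_rows),
    z_errors = bindr(zerr_rows),
    toc = bindr(toc_rows),
    auc = bindr(auc_rows),
    coverage = bindr(cov_rows),
    reference = list(models = ref_models, z = z_ref, fit_metrics = ref_fit,
                     toc = data.frame(id = rownames(z_ref),
                                      group = groups[rownames(z_ref)],
                                      toc = ref_toc, stringsAsFactors = FALSE)),
    manifests = manifests,
    split = split,
    config = config
  ), class = "nm_results")
}

# Tidy per-ROI fit metric rows for one model set on the HC test subjects.
roi_fit_table <- function(models, cohort, hc_test_ids, strategy, n, iteration) {
  sub <- cohort$subjects[match(hc_test_ids, cohort$subjects$id), , drop = FALSE]
  idx <- match(hc_test_ids, cohort$subjects$id)
  rows <- lapply(names(models), function(r) {
    mdl <- models[[r]]
    if (mdl$flagged) return(NULL)
    fm <- fit_metrics_for_model(mdl, sub, cohort$values[idx, r])
    cbind(strategy = strategy, n = n, iteration = iteration, roi = r, fm)
  })
  do.call(rbind, rows)
}

#' Run the transfer-learning adaptation arm
#'
#' Pre-trains per-ROI models on a large synthetic reference cohort
#' (site-shifted from the target), then reuses the direct arm's subsampling
#' draws as adaptation sets: each drawn subset recalibrates the pre-trained
#' models by site-level mean offsets, and the adapted models are evaluated on
#' the SAME fixed test set as [run_sweep()]. The full-adaptation model (the
#' entire target training set as adaptation set) is the reference for z-score
#' errors. Target site labels are namespaced so they never collide with
#' reference sites.
#'
#' @param config An [experiment_config()] with `adaptation_reference` set.
#' @return An `nm_results` list mirroring [run_sweep()] (fit metrics, z
#'   errors, toc, auc, coverage), tagged `arm = "adapted"`.
#' @export
run_adaptation_arm <- function(config) {
  if (is.null(config$adaptation_reference))
    stop("config$adaptation_reference is required for the adaptation arm")
  fr <- sweep_frame(config)
  cohort <- fr$cohort
  # namespace target sites so pretrained models treat them as new sites
  cohort$subjects$site <- paste0("target:", cohort$subjects$site)
  cohort$sites <- paste0("target:", cohort$sites)
  split <- fr$split
  rois <- fr$rois
  test_sub <- cohort$subjects[match(split$test_ids, cohort$subjects$id), , drop = FALSE]
  hc_test <- split$hc_test_ids
  groups <- stats::setNames(test_sub$dx, test_sub$id)
  has_ad <- any(test_sub$dx == "AD")

  ref_cohort <- generate_cohort(config$adaptation_reference,
                                seed = derive_seed(config$master_seed, "refcohort"))
  ref_hc <- ref_cohort$subjects$id[ref_cohort$subjects$dx == "HC"]
  pretrained <- fit_cohort_models(ref_cohort, ref_hc, rois,
                                  workers = config$workers)

  adapt_set <- function(models, ids) {
    sub <- cohort$subjects[match(ids, cohort$subjects$id), , drop = FALSE]
    idx <- match(ids, cohort$subjects$id)
    out <- lapply(names(models), function(r) adapt(models[[r]], sub,
                                                   cohort$values[idx, r]))
    names(out) <- names(models)
    class(out) <- "nm_model_set"
    out
  }

  full_adapted <- adapt_set(pretrained, split$train_ids)
  z_full <- zscore_matrix(full_adapted, cohort, split$test_ids)
  fit_rows <- list(roi_fit_table(full_adapted, cohort, hc_test,
                                 "full", length(split$train_ids), 0L))
  zerr_rows <- list(); toc_rows <- list(); auc_rows <- list(); cov_rows <- list()
  manifests <- list()

  for (n in fr$grid) {
    for (task in schemes_for(config, n)) {
      sch <- task$scheme
      lab <- task$label
      ids <- draw_sample(cohort, split$train_ids, sch)
      manifests[[paste(lab, n, sch$iteration, sep = "|")]] <-
        list(scheme = sch, ids = ids)
      models <- adapt_set(pretrained, ids)
      fit_rows[[length(fit_rows) + 1L]] <-
        roi_fit_table(models, cohort, hc_test, lab, n, sch$iteration)
      z <- zscore_matrix(models, cohort, split$test_ids)
      ok <- !apply(is.na(z), 2, any) & !apply(is.na(z_full), 2, any)
      ze <- z_error(z[, ok, drop = FALSE], z_full[, ok, drop = FALSE])
      ze$group <- groups[ze$id]
      zerr_rows[[length(zerr_rows) + 1L]] <-
        cbind(strategy = lab, n = n, iteration = sch$iteration, ze)
      flags <- outlier_flags(z[, ok, drop = FALSE], config$outlier_threshold)
      toc_rows[[length(toc_rows) + 1L]] <- data.frame(
        strategy = lab, n = n, iteration = sch$iteration,
        id = rownames(z), group = groups[rownames(z)],
        toc = toc(flags), stringsAsFactors = FALSE)
      if (has_ad) {
        auc_rows[[length(auc_rows) + 1L]] <- data.frame(
          strategy = lab, n = n, iteration = sch$iteration,
          auc = as.numeric(classify_auc(z[, ok, drop = FALSE], groups[rownames(z)],
            seed = derive_seed(config$master_seed, "auc", lab, n, sch$iteration))))
      }
      cov <- coverage(ids, hc_test, cohort, reference_ids = split$train_ids)
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        strategy = lab, n = n, iteration = sch$iteration,
        coverage = cov$coverage)
    }
  }
  bindr <- function(lst) if (length(lst)) do.call(rbind, lst) else NULL
  structure(list(
    fit_metrics = bindr(fit_rows),
    icc = NULL,
    z_errors = bindr(zerr_rows),
    toc = bindr(toc_rows),
    auc = bindr(auc_rows),
    coverage = bindr(cov_rows),
    reference = list(models = full_adapted, pretrained = pretrained, z = z_full),
    manifests = manifests,
    split = split,
    config = config,
    arm = "adapted"
  ), class = "nm_results")
}

#' Difference curves between the direct and adapted arms
#'
#' Mean metric per (strategy, n) in each arm and their difference
#' (direct minus adapted); for losses (MSLL, SMSE, MSE) positive differences
#' favour the adapted models.
#'
#' @param direct,adapted `nm_results` from [run_sweep()] and
#'   [run_adaptation_arm()].
#' @param metric Fit-metric column name (e.g. `"msll"`).
#' @return Data frame `strategy`, `n`, `direct`, `adapted`, `difference`.
#' @export
compare_arms <- function(direct, adapted, metric = "msll") {
  agg <- function(res) {
    df <- res$fit_metrics
    df <- df[df$strategy != "full", , drop = FALSE]
    stats::aggregate(df[[metric]],
                     by = list(strategy = df$strategy, n = df$n),
                     FUN = mean, na.rm = TRUE)
  }
  a <- agg(direct)
  b <- agg(adapted)
  m <- merge(a, b, by = c("strategy", "n"), suffixes = c("_direct", "_adapted"))
  data.frame(strategy = m$strategy, n = m$n,
             direct = m$x_direct, adapted = m$x_adapted,
             difference = m$x_direct - m$x_adapted)
}

#' Write sweep results as tidy CSV tables plus a run manifest
#'
#' Emits `fit_metrics.csv`, `icc.csv`, `z_errors.csv`, `toc.csv`, `auc.csv`,
#' `coverage.csv`, a long-format `metrics_long.csv`
#' (strategy, n, iteration, roi, metric, value) and `manifest.json` (config
#' hash, seeds, package version).
#'
#' @param results An `nm_results`.
#' @param dir Output directory (created if needed).
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("fit_metrics", "icc", "z_errors", "toc", "auc", "coverage")) {
    if (!is.null(results[[nm]])) {
      utils::write.csv(results[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  fm <- results$fit_metrics
  if (!is.null(fm)) {
    long <- stats::reshape(
      fm, direction = "long",
      varying = list(c("msll", "smse", "ev", "rho", "lower_tail_pct", "upper_tail_pct")),
      v.names = "value", timevar = "metric",
      times = c("msll", "smse", "ev", "rho", "lower_tail_pct", "upper_tail_pct"))
    long <- long[order(long$metric, long$strategy, long$n, long$iteration),
                 c("strategy", "n", "iteration", "roi", "metric", "value")]
    utils::write.csv(long, file.path(dir, "metrics_long.csv"), row.names = FALSE)
  }
  if (length(results$manifests)) {
    draws <- do.call(rbind, lapply(results$manifests, function(m) {
      data.frame(strategy = m$scheme$strategy, n = m$scheme$n,
                 iteration = m$scheme$iteration, seed = m$scheme$seed,
                 id = m$ids, stringsAsFactors = FALSE)
    }))
    rownames(draws) <- NULL
    utils::write.csv(draws, file.path(dir, "draws.csv"), row.names = FALSE)
  }
  manifest <- list(
    package = "normref",
    version = as.character(utils::packageVersion("normref")),
    master_seed = results$config$master_seed,
    config_hash = derive_seed(paste(utils::capture.output(utils::str(results$config)),
                                    collapse = "\n")),
    n_manifest_draws = length(results$manifests),
    arm = results$arm %||% "direct"
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort CSV), `sweep` (direct
#' arm), `adapt` (transfer-learning arm), `evaluate` (summaries of a written
#' run), `report` (LMM coefficient tables for a written run). Flags:
#' `--config FILE` (flat `key: value` file), `--seed INT`, `--out DIR`,
#' `--workers INT`, `--preset desk|full`. Progress is logged to stderr.
#'
#' @param args Character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly (0 on success).
#' @export
nm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: normref <simulate|sweep|adapt|evaluate|report> [--config FILE] ",
            "[--seed INT] [--out DIR] [--workers INT] [--preset desk|full]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- parse_cli_flags(args[-1])
  seed <- as.integer(opts$seed %||% 1L)
  out <- opts$out %||% "normref-out"
  preset <- opts$preset %||% "desk"
  workers <- as.integer(opts$workers %||% 1L)
  kv <- if (!is.null(opts$config)) read_flat_config(opts$config) else list()
  t0 <- Sys.time()
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out, "run.log")
  log_msg <- function(...) {
    line <- paste0(sprintf("[normref %s] ", format(Sys.time(), "%H:%M:%S")), ...)
    message(line)  # stderr
    cat(line, "\n", file = logfile, append = TRUE, sep = "")
  }

  scfg <- synthetic_config(
    n_hc = as.integer(kv$n_hc %||% 1000), n_ad = as.integer(kv$n_ad %||% 100),
    n_sites = as.integer(kv$n_sites %||% 1),
    n_cortical_roi = as.integer(kv$n_cortical_roi %||% if (preset == "full") 148 else 14),
    n_subcortical_roi = as.integer(kv$n_subcortical_roi %||% if (preset == "full") 19 else 6),
    master_seed = seed)

  status <- 0L
  if (cmd == "simulate") {
    coh <- generate_cohort(scfg, seed = seed)
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_cohort_csv(coh, file.path(out, "cohort.csv"))
    write_config_txt(scfg, file.path(out, "config.txt"))
    log_msg("wrote ", file.path(out, "cohort.csv"))
  } else if (cmd %in% c("sweep", "adapt")) {
    grid <- if (!is.null(kv$grid)) as.integer(strsplit(kv$grid, ",")[[1]]) else
      if (preset == "desk") c(5L, 10L, 15L, 20L, 25L, 50L, 100L, 200L) else NULL
    strategies <- if (!is.null(kv$strategies)) strsplit(kv$strategies, ",")[[1]] else
      c("representative", "left_skew", "right_skew")
    ecfg <- experiment_config(
      cohort = if (!is.null(kv$cohort_csv)) kv$cohort_csv else scfg,
      strategies = strategies, grid = grid,
      iterations = as.integer(kv$iterations %||% 10L),
      master_seed = seed, workers = workers,
      adaptation_reference = if (cmd == "adapt") {
        synthetic_config(n_hc = as.integer(kv$reference_n_hc %||% 5000), n_ad = 0L,
                         n_sites = as.integer(kv$reference_n_sites %||% 3),
                         site_offsets = rep(1.0, as.integer(kv$reference_n_sites %||% 3)),
                         n_cortical_roi = scfg$n_cortical_roi,
                         n_subcortical_roi = scfg$n_subcortical_roi,
                         master_seed = seed)
      } else NULL)
    log_msg("running ", cmd, " (", length(ecfg$strategies), " strategies, ",
            "iterations=", ecfg$iterations, ")")
    res <- if (cmd == "sweep") run_sweep(ecfg) else run_adaptation_arm(ecfg)
    write_results(res, out)
    log_msg("results written to ", out)
  } else if (cmd == "evaluate") {
    fm <- utils::read.csv(file.path(out, "fit_metrics.csv"))
    summ <- stats::aggregate(fm[c("msll", "smse", "ev", "rho")],
                             by = list(strategy = fm$strategy, n = fm$n),
                             FUN = stats::median, na.rm = TRUE)
    utils::write.csv(summ, file.path(out, "summary.csv"), row.names = FALSE)
    log_msg("wrote ", file.path(out, "summary.csv"))
  } else if (cmd == "report") {
    fm <- utils::read.csv(file.path(out, "fit_metrics.csv"))
    fm <- fm[fm$strategy != "full", , drop = FALSE]
    results <- list()
    for (m in c("msll", "smse", "ev", "rho")) {
      results[[m]] <- tryCatch(fit_lmm_fit_metrics(fm, m),
                               error = function(e) NULL)
    }
    results <- Filter(Negate(is.null), results)
    write_lmm_table(results, file.path(out, "lmm_fit_metrics.csv"))
    log_msg("wrote ", file.path(out, "lmm_fit_metrics.csv"))
  } else {
    message("unknown subcommand: ", cmd)
    status <- 1L
  }
  log_msg(sprintf("done in %.1fs", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(status)
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        opts[[key]] <- TRUE
        i <- i + 1L
      }
    } else i <- i + 1L
  }
  opts
}

read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = ":"))
  }
  kv
}
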