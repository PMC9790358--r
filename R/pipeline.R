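#' Analysis configuration
#'
#' Bundles everything [run_analysis()] needs: either a cohort specification
#' (simulation mode) or paths to a trial-log CSV and a metadata CSV (data
#' mode), the observer settings, and the analysis flags.
#'
#' @param cohort a [cohort_spec()] for simulation mode, or `NULL`.
#' @param trials_path,metadata_path CSV paths for data mode (both required
#'   together), or `NULL`.
#' @param observer an [observer_config()]; `NULL` derives it from the task
#'   configuration (true generative parameters — the observer has no free
#'   parameters).
#' @param task the [task_config()] describing the sessions (used to derive
#'   the observer and to validate data-mode input).
#' @param output_dir directory where [write_report()] puts tables, or
#'   `NULL`.
#' @param seed integer seed governing all stochastic stages.
#' @param pooled_tertiles use pooled instead of per-subject tertile edges.
#' @param linear_geometry treat the 0-360 scale as linear instead of
#'   circular.
#' @param low_pe_only also refit the regressions on small-PE trials only.
#' @param medication_analysis run the three-group (CTL / MED- / MED+)
#'   battery using the metadata's medication labels.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(cohort = NULL, trials_path = NULL,
                            metadata_path = NULL, observer = NULL,
                            task = task_config(), output_dir = NULL,
                            seed = 1L, pooled_tertiles = FALSE,
                            linear_geometry = FALSE, low_pe_only = FALSE,
                            medication_analysis = FALSE) {
  sim_mode <- !is.null(cohort)
  data_mode <- !is.null(trials_path) || !is.null(metadata_path)
  if (sim_mode == data_mode) {
    stop("supply exactly one of `cohort` or `trials_path`+`metadata_path`")
  }
  if (data_mode && (is.null(trials_path) || is.null(metadata_path))) {
    stop("data mode needs both trials_path and metadata_path")
  }
  if (sim_mode) task <- cohort$task
  if (is.null(observer)) {
    observer <- observer_config(
      hazard = task$hazard, noise_var = task$noise_sd^2,
      n_positions = task$n_positions,
      geometry = if (linear_geometry) "linear" else "circular")
  }
  structure(list(cohort = cohort, trials_path = trials_path,
                 metadata_path = metadata_path, observer = observer,
                 task = task, output_dir = output_dir,
                 seed = as.integer(seed),
                 pooled_tertiles = pooled_tertiles,
                 linear_geometry = linear_geometry,
                 low_pe_only = low_pe_only,
                 medication_analysis = medication_analysis),
            class = "analysis_config")
}

#' Read / write the canonical trial-log CSV
#'
#' The pipeline's standard input format: one row per trial with columns
#' `subject_id`, `group`, `medication`, `block`, `trial`, `latent_mean`,
#' `changepoint`, `outcome`, `bucket`, `confidence`, `hit`, `points`.
#' Angles are validated to [0, 360) and confidence to integers 1-100.
#'
#' @param trials trial-record table.
#' @param path file path.
#' @return `read_trials()` returns the validated table.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "block", "trial", "outcome", "bucket",
            "confidence", "hit")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  }
  for (col in c("outcome", "bucket", "latent_mean")) {
    if (!col %in% names(x)) next
    bad <- which(!is.finite(x[[col]]) | x[[col]] < 0 | x[[col]] >= 360)
    if (length(bad)) {
      stop(path, ": column ", col, " out of [0,360) in row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  bad <- which(!is.finite(x$confidence) | x$confidence < 1 |
                 x$confidence > 100 | x$confidence != round(x$confidence))
  if (length(bad)) {
    stop(path, ": column confidence must be integer in [1,100]; row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  x$hit <- as.logical(x$hit)
  if ("changepoint" %in% names(x)) {
    x$changepoint <- as.logical(x$changepoint)
  }
  x
}

#' Run the full analysis pipeline
#'
#' Simulation mode simulates the cohort from `config$cohort`; data mode
#' loads the trial-log and metadata CSVs. Either way the pipeline then runs
#' the reduced Bayesian observer on every subject's outcome sequence,
#' derives trialwise learning rates with the zero-PE / last-trial /
#' group-95th-percentile exclusions, z-scores confidence, bins trials into
#' prediction-error tertiles, summarises subjects, fits the three
#' per-subject regressions, and runs the group battery: routed overall
#' learning-rate and confidence comparisons, Welch-James group x tertile
#' test on learning rates, Huynh-Feldt mixed ANOVA on confidence, per-bin
#' post-hocs, beta comparisons, median R-squared, peri-change-point
#' profiles, covariate correlations, and (optionally) the three-group
#' medication battery.
#'
#' @param config an [analysis_config()].
#' @return an `analysis_report` (list of tables and `pi_test` results with
#'   a provenance block). If `config$output_dir` is set the tables are also
#'   written there as CSV.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  geometry <- if (config$linear_geometry) "linear" else "circular"

  if (!is.null(config$cohort)) {
    sim <- simulate_cohort(config$cohort)
    trials <- sim$trials
    metadata <- sim$metadata
  } else {
    trials <- read_trials(config$trials_path)
    metadata <- utils::read.csv(config$metadata_path,
                                stringsAsFactors = FALSE)
    if (!"subject_id" %in% names(metadata)) {
      stop(config$metadata_path, ": missing column subject_id")
    }
  }

  ## observer per subject (conditioned on outcomes only)
  traces <- lapply(split(trials, trials$subject_id), function(d) {
    tr <- run_observer_session(d[order(d$block, d$trial), ],
                               config$observer)
    tr$subject_id <- d$subject_id[1]
    tr
  })

  ## trialwise metrics
  derived <- derive_trial_metrics(trials, geometry = geometry)
  derived <- filter_learning_rates(derived)
  derived <- bin_by_pe_magnitude(derived, pooled = config$pooled_tertiles)
  derived$z_confidence <- unsplit(
    lapply(split(derived$confidence, derived$subject_id),
           zscore_confidence), derived$subject_id)
  summaries <- summarize_subject(derived)
  extra <- setdiff(names(metadata), names(summaries))
  if (length(extra)) {
    summaries <- merge(summaries,
                       metadata[, c("subject_id", extra), drop = FALSE],
                       by = "subject_id", sort = TRUE)
  }

  subjects <- sort(unique(derived$subject_id))
  groups2 <- summaries$group[match(subjects, summaries$subject_id)]
  glv <- unique(groups2)

  ## per-subject regressions
  fits <- list(action = list(), confidence = list(), coupling = list())
  fits_lowpe <- if (config$low_pe_only) fits[c("action", "confidence")]
                else NULL
  for (s in subjects) {
    d <- derived[derived$subject_id == s, ]
    tr <- traces[[s]]
    fits$action[[s]] <- fit_action_model(d, tr)
    fits$confidence[[s]] <- fit_confidence_model(d, tr)
    fits$coupling[[s]] <- fit_coupling_model(d, geometry)
    if (config$low_pe_only) {
      # hit is constant on small-PE trials (they land inside the bucket),
      # so the refit drops that predictor
      dl <- d[!is.na(d$pe_bin) & d$pe_bin == "small", ]
      fits_lowpe$action[[s]] <- fit_action_model(dl, tr,
                                                 include_hit = FALSE)
      fits_lowpe$confidence[[s]] <- fit_confidence_model(
        dl, tr, include_hit = FALSE)
    }
  }

  ## group battery (two-group: first two group labels in the data)
  stats_out <- list()
  if (length(glv) >= 2) {
    ga <- glv[1]; gb <- glv[2]
    in_a <- summaries$group == ga; in_b <- summaries$group == gb
    stats_out$overall_alpha <- rank_sum_test(
      summaries$overall_mean_alpha[in_a],
      summaries$overall_mean_alpha[in_b])
    stats_out$overall_z_confidence <- compare_groups(
      summaries$mean_z_confidence[in_a],
      summaries$mean_z_confidence[in_b])
    tt_excl <- stats::t.test(summaries$proportion_excluded[in_a],
                             summaries$proportion_excluded[in_b],
                             var.equal = TRUE)
    stats_out$proportion_excluded <- new_pi_test(
      "student_t", tt_excl$statistic, sum(in_a) + sum(in_b) - 2,
      tt_excl$p.value)

    two <- summaries[summaries$group %in% c(ga, gb), ]
    long_alpha <- bin_long(two, "mean_alpha")
    long_conf <- bin_long(two, "mean_z_confidence")
    stats_out$alpha_by_bin_wj <- welch_james_adf(long_alpha)
    stats_out$confidence_by_bin_anova <- mixed_anova_hf(long_conf)
    stats_out$alpha_bin_posthoc <- lapply(
      stats::setNames(nm = c("small", "medium", "large")), function(b) {
        t <- rank_sum_test(
          two[[paste0("mean_alpha_", b)]][two$group == ga],
          two[[paste0("mean_alpha_", b)]][two$group == gb])
        t$p_value <- min(1, 3 * t$p_value)
        t$correction <- "bonferroni"
        t
      })

    beta_cmp <- list()
    for (m in c("action", "confidence", "coupling")) {
      preds <- setdiff(names(fits[[m]][[1]]$betas), "intercept")
      ra <- fits[[m]][subjects[groups2 == ga]]
      rb <- fits[[m]][subjects[groups2 == gb]]
      beta_cmp[[m]] <- lapply(stats::setNames(nm = preds), function(p) {
        compare_betas(ra, rb, p)
      })
    }
    stats_out$beta_comparisons <- beta_cmp
  }

  median_r2 <- lapply(fits, function(f) median_r_squared(f, groups2))

  ## medication (three-group) battery
  med_out <- NULL
  if (config$medication_analysis) {
    med <- summaries$medication
    lab <- ifelse(med %in% c("MED-", "MED+"), med, summaries$group)
    if (length(unique(lab)) != 3) {
      stop("medication analysis needs labels forming exactly 3 groups")
    }
    # refilter with the three-group 95th percentiles, as in the
    # three-group analysis
    derived3 <- derive_trial_metrics(trials, geometry = geometry)
    derived3$group <- lab[match(derived3$subject_id,
                                summaries$subject_id)]
    derived3 <- filter_learning_rates(derived3)
    derived3 <- bin_by_pe_magnitude(derived3,
                                    pooled = config$pooled_tertiles)
    derived3$z_confidence <- derived$z_confidence
    sum3 <- summarize_subject(derived3)
    med_out <- list(
      alpha_kw = kruskal_wallis_posthoc(sum3$overall_mean_alpha,
                                        sum3$group),
      z_confidence_kw = kruskal_wallis_posthoc(sum3$mean_z_confidence,
                                               sum3$group),
      alpha_by_bin_wj = welch_james_adf(bin_long(sum3, "mean_alpha")),
      summaries = sum3)
  }

  ## peri-change-point profiles (only when ground-truth flags exist)
  peri <- NULL
  if ("changepoint" %in% names(derived)) {
    human <- derived
    human$alpha[human$excluded] <- NA
    peri_h <- peri_changepoint_profile(
      human, c("alpha", "z_confidence"), window = 4, by = "group")
    model <- do.call(rbind, lapply(subjects, function(s) {
      tr <- traces[[s]]
      d <- derived[derived$subject_id == s, ]
      tr$changepoint <- d$changepoint[match(
        paste(tr$block, tr$trial), paste(d$block, d$trial))]
      tr$subject_id <- s
      tr
    }))
    peri_m <- peri_changepoint_profile(
      model, c("learning_rate", "confidence"), window = 4)
    peri_m$group <- "model"
    peri <- rbind(peri_h, peri_m)
  }

  correlations <- NULL
  cov_cols <- setdiff(names(metadata),
                      c("subject_id", "group", "medication"))
  if (length(cov_cols)) {
    correlations <- correlate_with_covariates(
      summaries, metadata[, c("subject_id", cov_cols), drop = FALSE],
      by_group = TRUE)
  }

  report <- structure(list(
    subject_summary = summaries,
    derived = derived,
    group_stats = stats_out,
    regressions = lapply(fits, regression_table),
    median_r_squared = median_r2,
    regressions_low_pe = if (config$low_pe_only) {
      lapply(fits_lowpe, regression_table)
    },
    medication = med_out,
    peri_changepoint = peri,
    correlations = correlations,
    exclusion_thresholds = attr(derived, "thresholds"),
    provenance = list(seed = config$seed,
                      mode = if (is.null(config$cohort)) "data"
                             else "simulation",
                      observer = unclass(config$observer),
                      task = unclass(config$task),
                      flags = config[c("pooled_tertiles", "linear_geometry",
                                       "low_pe_only",
                                       "medication_analysis")],
                      package_version =
                        as.character(utils::packageVersion("predinfer")))),
    class = "analysis_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

# reshape a subject-summary table into long subject x pe-bin format
bin_long <- function(summaries, prefix) {
  bins <- c("small", "medium", "large")
  do.call(rbind, lapply(bins, function(b) {
    data.frame(subject_id = summaries$subject_id,
               group = summaries$group, within = b,
               value = summaries[[paste0(prefix, "_", b)]])
  }))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Predictive-inference analysis report (",
      x$provenance$mode, " mode, seed ", x$provenance$seed, ")\n",
      sep = "")
  gm <- stats::aggregate(
    x$subject_summary[c("overall_mean_alpha", "mean_alpha_small",
                        "mean_z_confidence")],
    by = list(group = x$subject_summary$group), FUN = mean)
  cat("\nGroup means:\n")
  print(gm, digits = 3)
  if (length(x$group_stats)) {
    cat("\nOverall learning rate: ")
    print(x$group_stats$overall_alpha)
    cat("Overall z-confidence:  ")
    print(x$group_stats$overall_z_confidence)
  }
  cat("\nMedian R-squared:\n")
  print(vapply(x$median_r_squared, function(v)
    round(stats::median(v), 3), numeric(1)))
  invisible(x)
}

#' Write an analysis report's tables to a directory
#'
#' Emits subject summaries, the group-test table, regression tables,
#' peri-change-point profile, correlations and a plain-text provenance
#' summary as CSV/text files.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, nm) {
    if (!is.null(x)) {
      utils::write.csv(x, file.path(dir, nm), row.names = FALSE)
    }
  }
  w(report$subject_summary, "subject_summary.csv")
  if (length(report$group_stats)) {
    w(test_table(report$group_stats), "group_stats.csv")
  }
  for (m in names(report$regressions)) {
    w(report$regressions[[m]], paste0("regression_", m, ".csv"))
  }
  w(report$peri_changepoint, "peri_changepoint.csv")
  w(report$correlations, "correlations.csv")
  if (!is.null(report$medication)) {
    w(test_table(report$medication[c("alpha_kw", "z_confidence_kw",
                                     "alpha_by_bin_wj")]),
      "medication_stats.csv")
  }
  writeLines(c("predinfer analysis provenance",
               utils::capture.output(utils::str(report$provenance))),
             file.path(dir, "provenance.txt"))
  invisible(dir)
}
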