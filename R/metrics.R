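#' Trialwise prediction errors and empirical learning rates
#'
#' For each subject and block computes the signed circular prediction error
#' `delta_t = circ_diff(outcome_t, bucket_t)` and the empirical learning
#' rate `alpha_t = circ_diff(bucket_{t+1}, bucket_t) / delta_t` — the
#' fraction of the prediction error incorporated into the next bucket
#' placement. The last trial of each block (no next placement) and trials
#' with `delta_t = 0` (learning rate undefined) are flagged excluded with
#' reasons `"last_trial"` and `"zero_pe"`.
#'
#' @param trials trial-record data frame with columns `block`, `trial`,
#'   `outcome`, `bucket` (and optionally `subject_id`, `group`, which are
#'   carried through).
#' @param geometry `"circular"` (default) or `"linear"` differencing.
#' @return the input plus columns `delta`, `abs_delta`, `alpha`, `excluded`
#'   (logical), `exclude_reason` (NA for retained trials).
#' @export
derive_trial_metrics <- function(trials, geometry = "circular") {
  need <- c("block", "trial", "outcome", "bucket")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trials missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(!is.finite(trials$outcome) | !is.finite(trials$bucket))
  if (length(bad)) stop("missing outcome/bucket in row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  trials$.row <- seq_len(nrow(trials))
  key <- if ("subject_id" %in% names(trials)) {
    interaction(trials$subject_id, trials$block, drop = TRUE)
  } else factor(trials$block)
  if (any(tapply(trials$trial, key, length) < 2)) {
    stop("each block needs at least 2 trials")
  }
  parts <- lapply(split(trials, key), function(bl) {
    bl <- bl[order(bl$trial), , drop = FALSE]
    n <- nrow(bl)
    delta <- signed_diff(bl$outcome, bl$bucket, geometry)
    upd <- c(signed_diff(bl$bucket[-1], bl$bucket[-n], geometry), NA)
    alpha <- ifelse(delta != 0, upd / delta, NA_real_)
    reason <- rep(NA_character_, n)
    reason[delta == 0] <- "zero_pe"
    reason[n] <- "last_trial"
    bl$delta <- delta
    bl$abs_delta <- abs(delta)
    bl$alpha <- alpha
    bl$excluded <- !is.na(reason)
    bl$exclude_reason <- reason
    bl
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$.row), , drop = FALSE]
  out$.row <- NULL
  rownames(out) <- NULL
  out
}

#' Exclude extreme learning rates by group percentile
#'
#' Within each group, pools all currently retained learning rates across
#' subjects, computes the 95th percentile (linear interpolation between
#' order statistics), and flags trials whose learning rate strictly exceeds
#' it as excluded with reason `"percentile"`. Only the upper tail is
#' filtered; negative learning rates are retained.
#'
#' @param derived output of [derive_trial_metrics()].
#' @param group_assignment named character vector mapping `subject_id` to
#'   group; omitted if `derived` already has a `group` column.
#' @param probs percentile used as the exclusion threshold (default 0.95).
#' @return `derived` with the additional exclusions applied; the per-group
#'   thresholds are attached as attribute `"thresholds"`.
#' @export
filter_learning_rates <- function(derived, group_assignment = NULL,
                                  probs = 0.95) {
  if (!"group" %in% names(derived)) {
    if (is.null(group_assignment)) stop("no group information supplied")
    derived$group <- unname(group_assignment[derived$subject_id])
  }
  if (anyNA(derived$group)) stop("every subject must be mapped to a group")
  thresholds <- c()
  for (g in unique(derived$group)) {
    idx <- derived$group == g & !derived$excluded
    if (!any(idx)) stop("group with zero retained trials: ", g)
    thr <- stats::quantile(derived$alpha[idx], probs, type = 7,
                           names = FALSE)
    out_idx <- idx & derived$alpha > thr
    derived$excluded[out_idx] <- TRUE
    derived$exclude_reason[out_idx] <- "percentile"
    thresholds[g] <- thr
  }
  attr(derived, "thresholds") <- thresholds
  derived
}

#' Standardise confidence ratings within subject
#'
#' Converts raw 1-100 confidence ratings to z-scores (sample SD, n-1
#' denominator), giving each subject mean 0 and SD 1 so that confidence can
#' be compared on a relative scale across subjects with different baseline
#' confidence.
#'
#' @param confidence numeric vector of one subject's ratings (length >= 2,
#'   non-constant).
#' @return z-scored vector.
#' @export
zscore_confidence <- function(confidence) {
  if (length(confidence) < 2) stop("need at least 2 confidence ratings")
  s <- stats::sd(confidence)
  if (!is.finite(s) || s == 0) {
    stop("confidence is constant; z-scores are undefined")
  }
  (confidence - mean(confidence)) / s
}

#' Bin retained trials into prediction-error-magnitude tertiles
#'
#' Computes tertile edges on the absolute prediction error of retained
#' trials (linear-interpolation quantiles), by default separately per
#' subject, and labels each retained trial `small`, `medium` or `large`.
#' Ties at an edge go to the lower bin. Excluded trials get `NA`.
#'
#' @param derived output of [derive_trial_metrics()] /
#'   [filter_learning_rates()].
#' @param pooled logical; if `TRUE`, edges are computed once on all
#'   retained trials pooled across subjects.
#' @return `derived` with a `pe_bin` factor column
#'   (levels `small < medium < large`).
#' @export
bin_by_pe_magnitude <- function(derived, pooled = FALSE) {
  assign_bins <- function(absd) {
    edges <- stats::quantile(absd, c(1, 2) / 3, type = 7, names = FALSE)
    idx <- 1L + (absd > edges[1]) + (absd > edges[2])
    factor(c("small", "medium", "large")[idx],
           levels = c("small", "medium", "large"))
  }
  derived$pe_bin <- factor(rep(NA_character_, nrow(derived)),
                           levels = c("small", "medium", "large"))
  keep <- !derived$excluded
  if (pooled) {
    if (sum(keep) < 3) stop("fewer than 3 retained trials")
    derived$pe_bin[keep] <- assign_bins(derived$abs_delta[keep])
  } else {
    key <- if ("subject_id" %in% names(derived)) derived$subject_id
           else rep("all", nrow(derived))
    for (s in unique(key)) {
      idx <- keep & key == s
      if (sum(idx) < 3) stop("fewer than 3 retained trials for subject ", s)
      derived$pe_bin[idx] <- assign_bins(derived$abs_delta[idx])
    }
  }
  derived
}

#' Per-subject behavioural summary
#'
#' Mean retained learning rate overall and per prediction-error tertile,
#' mean z-scored confidence overall and per tertile, and the proportion of
#' excluded trials — the per-subject quantities entering the group-level
#' comparisons.
#'
#' @param derived output of the derive/filter/bin chain; needs columns
#'   `alpha`, `z_confidence`, `pe_bin`, `excluded` (and `subject_id`,
#'   `group` if present).
#' @return data frame with one row per subject.
#' @export
summarize_subject <- function(derived) {
  key <- if ("subject_id" %in% names(derived)) derived$subject_id
         else rep("all", nrow(derived))
  parts <- lapply(split(derived, key), function(d) {
    keep <- !d$excluded
    row <- data.frame(
      subject_id = if ("subject_id" %in% names(d)) d$subject_id[1] else "all",
      overall_mean_alpha = mean(d$alpha[keep]),
      proportion_excluded = mean(d$excluded))
    if ("group" %in% names(d)) row$group <- d$group[1]
    if ("medication" %in% names(d)) row$medication <- d$medication[1]
    for (b in levels(d$pe_bin)) {
      row[[paste0("mean_alpha_", b)]] <-
        mean(d$alpha[keep & d$pe_bin == b])
    }
    if ("z_confidence" %in% names(d)) {
      row$mean_z_confidence <- mean(d$z_confidence)
      for (b in levels(d$pe_bin)) {
        row[[paste0("mean_z_confidence_", b)]] <-
          mean(d$z_confidence[keep & d$pe_bin == b])
      }
    }
    row
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Peri-change-point profiles
#'
#' Averages chosen trial-level variables at relative positions
#' `-window .. +window` around each change point whose full window lies
#' inside a block, optionally split by a grouping column — the standard way
#' to compare human and model adjustment dynamics around change points.
#'
#' @param data trial-level data frame with `block`, `trial`, `changepoint`
#'   columns (plus `subject_id` if multiple subjects).
#' @param vars character vector of column names to average.
#' @param window number of trials on each side (default 4).
#' @param by optional name of a grouping column (e.g. `"group"`).
#' @return long data frame with columns `offset`, `variable`, `mean`, `n`
#'   (and the `by` column); positions with no data are omitted. Returns an
#'   empty profile with a warning when there are no usable change points.
#' @export
peri_changepoint_profile <- function(data, vars, window = 4, by = NULL) {
  stopifnot(all(vars %in% names(data)))
  key_cols <- intersect(c("subject_id", "block"), names(data))
  key <- interaction(data[key_cols], drop = TRUE)
  rows <- list()
  for (blk in split(data, key)) {
    blk <- blk[order(blk$trial), , drop = FALSE]
    n <- nrow(blk)
    cps <- which(blk$changepoint)
    cps <- cps[cps - window >= 1 & cps + window <= n]
    for (cp in cps) {
      for (off in -window:window) {
        r <- blk[cp + off, c(vars, by), drop = FALSE]
        r$offset <- off
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  if (!length(rows)) {
    warning("no change points with a full window inside a block")
    out <- data.frame(offset = integer(), variable = character(),
                      mean = numeric(), n = integer())
    if (!is.null(by)) out[[by]] <- character()
    return(out)
  }
  long <- do.call(rbind, rows)
  split_key <- if (is.null(by)) factor(long$offset) else
    interaction(long$offset, long[[by]], drop = TRUE)
  parts <- lapply(split(long, split_key), function(d) {
    res <- lapply(vars, function(v) {
      vals <- d[[v]][!is.na(d[[v]])]
      if (!length(vals)) return(NULL)
      r <- data.frame(offset = d$offset[1], variable = v,
                      mean = mean(vals), n = length(vals))
      if (!is.null(by)) r[[by]] <- d[[by]][1]
      r
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$variable, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}
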