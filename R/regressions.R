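# Per-subject linear models linking behaviour to observer quantities.
# All three fits are ordinary least squares with an intercept, wrapped in a
# small classed object so betas, R^2 and trial counts travel together.

new_pi_regression <- function(model, fit, betas, n_used, subject_id = NA) {
  structure(list(subject_id = subject_id, model = model, betas = betas,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n_trials_used = n_used, fit = fit),
            class = "pi_regression")
}

check_full_rank <- function(X, labels) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- labels[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
}

#' @export
print.pi_regression <- function(x, ...) {
  cat(sprintf("%s model%s: R^2 = %.4f on %d trials\n", x$model,
              if (is.na(x$subject_id)) "" else
                paste0(" [", x$subject_id, "]"),
              x$r_squared, x$n_trials_used))
  print(round(x$betas, 4))
  invisible(x)
}

#' @export
coef.pi_regression <- function(object, ...) object$betas

#' Fit the action regression for one subject
#'
#' Models how much of each prediction error the subject's bucket update
#' incorporates, as a function of the reduced observer's quantities. The
#' response is `alpha_t * |delta_t|` (the action update projected on the
#' error direction) and the predictors, each multiplied by `|delta_t|`, are
#' the absolute prediction error itself, the change-point probability, the
#' relative uncertainty, and the hit indicator (1 = hit, 0 = miss). The
#' last trial of each block (learning rate undefined) and zero-PE trials
#' are dropped.
#'
#' @param derived one subject's rows from [derive_trial_metrics()] (needs
#'   `alpha`, `abs_delta`, `hit`, `block`, `trial`).
#' @param trace the subject's observer trace aligned by `block` and
#'   `trial` (needs `cpp`, `relative_uncertainty`).
#' @param include_hit include the hit/miss predictor (default `TRUE`). On
#'   small-PE-only subsets every trial is a hit by task geometry (small
#'   errors land inside the bucket), which would make the column
#'   collinear; such refits set this to `FALSE`.
#' @return a `pi_regression` with betas named `intercept`, `abs_pe`,
#'   `cpp`, `ru`, `hit`.
#' @export
fit_action_model <- function(derived, trace, include_hit = TRUE) {
  d <- merge(derived, trace[, c("block", "trial", "cpp",
                                "relative_uncertainty")],
             by = c("block", "trial"), sort = FALSE)
  d <- d[!is.na(d$alpha), , drop = FALSE]
  X <- cbind(abs_pe = d$abs_delta,
             cpp = d$cpp * d$abs_delta,
             ru = d$relative_uncertainty * d$abs_delta,
             hit = as.numeric(d$hit) * d$abs_delta)
  if (!include_hit) X <- X[, colnames(X) != "hit", drop = FALSE]
  check_full_rank(cbind(1, X), c("intercept", colnames(X)))
  y <- d$alpha * d$abs_delta
  fit <- stats::lm(y ~ X)
  betas <- stats::coef(fit)
  names(betas) <- c("intercept", colnames(X))
  sid <- if ("subject_id" %in% names(d)) d$subject_id[1] else NA
  new_pi_regression("action", fit, betas, nrow(d), sid)
}

#' Fit the confidence regression for one subject
#'
#' Models the trialwise z-scored confidence report from the previous
#' trial's observer quantities (confidence reflects what was just
#' experienced): predictors are `|delta|`, change-point probability,
#' relative uncertainty and hit on trial t-1; the response is not scaled by
#' `|delta|`. The first trial of each block (no previous trial) is dropped.
#'
#' @param derived one subject's rows; needs `z_confidence`, `abs_delta`,
#'   `hit`, `block`, `trial`.
#' @param trace aligned observer trace (as in [fit_action_model()]).
#' @inheritParams fit_action_model
#' @return a `pi_regression` with betas named `intercept`, `abs_pe_prev`,
#'   `cpp_prev`, `ru_prev`, `hit_prev`.
#' @export
fit_confidence_model <- function(derived, trace, include_hit = TRUE) {
  d <- merge(derived, trace[, c("block", "trial", "cpp",
                                "relative_uncertainty")],
             by = c("block", "trial"), sort = FALSE)
  parts <- lapply(split(d, d$block), function(bl) {
    bl <- bl[order(bl$trial), , drop = FALSE]
    n <- nrow(bl)
    data.frame(z_confidence = bl$z_confidence[-1],
               abs_pe_prev = bl$abs_delta[-n],
               cpp_prev = bl$cpp[-n],
               ru_prev = bl$relative_uncertainty[-n],
               hit_prev = as.numeric(bl$hit[-n]))
  })
  dd <- do.call(rbind, parts)
  pred_cols <- c("abs_pe_prev", "cpp_prev", "ru_prev",
                 if (include_hit) "hit_prev")
  X <- as.matrix(dd[, pred_cols])
  check_full_rank(cbind(1, X), c("intercept", colnames(X)))
  fit <- stats::lm(dd$z_confidence ~ X)
  betas <- stats::coef(fit)
  names(betas) <- c("intercept", colnames(X))
  sid <- if ("subject_id" %in% names(d)) d$subject_id[1] else NA
  new_pi_regression("confidence", fit, betas, nrow(dd), sid)
}

#' Fit the action-confidence coupling regression for one subject
#'
#' Regresses the absolute action update `|circ_diff(b_t, b_{t-1})|` on the
#' absolute confidence update `|z_t - z_{t-1}|` (within block, trial >= 2).
#' The slope is the subject's action-confidence association strength: if
#' actions and confidence move in tandem, large bucket adjustments
#' accompany large confidence changes.
#'
#' @param derived one subject's rows; needs `bucket`, `z_confidence`,
#'   `block`, `trial`.
#' @param geometry `"circular"` (default) or `"linear"` bucket updates.
#' @return a `pi_regression` with betas `intercept` and `conf_update`.
#' @export
fit_coupling_model <- function(derived, geometry = "circular") {
  parts <- lapply(split(derived, derived$block), function(bl) {
    bl <- bl[order(bl$trial), , drop = FALSE]
    n <- nrow(bl)
    data.frame(
      action_update = abs(signed_diff(bl$bucket[-1], bl$bucket[-n],
                                      geometry)),
      conf_update = abs(bl$z_confidence[-1] - bl$z_confidence[-n]))
  })
  dd <- do.call(rbind, parts)
  if (nrow(dd) < 3) stop("need at least 3 usable trials")
  if (stats::sd(dd$conf_update) == 0) {
    stop("confidence updates have zero variance")
  }
  fit <- stats::lm(action_update ~ conf_update, data = dd)
  betas <- stats::coef(fit)
  names(betas) <- c("intercept", "conf_update")
  sid <- if ("subject_id" %in% names(derived)) derived$subject_id[1] else NA
  new_pi_regression("coupling", fit, betas, nrow(dd), sid)
}

#' Collect per-subject regression results into a table
#'
#' @param results list of `pi_regression` objects (one model type).
#' @return data frame with one row per subject: betas, `r_squared`,
#'   `n_trials_used`.
#' @export
regression_table <- function(results) {
  out <- do.call(rbind, lapply(results, function(r) {
    row <- as.data.frame(as.list(r$betas))
    cbind(data.frame(subject_id = r$subject_id, model = r$model), row,
          data.frame(r_squared = r$r_squared,
                     n_trials_used = r$n_trials_used))
  }))
  rownames(out) <- NULL
  out
}

#' Compare one regression beta between two groups
#'
#' Extracts the per-subject coefficient for `predictor` from each group's
#' results and compares the groups with the routed two-sample test (Student
#' t, Welch t under variance heterogeneity, Wilcoxon rank-sum under
#' non-normality; see [compare_groups()]).
#'
#' @param results_a,results_b lists of `pi_regression` objects for the two
#'   groups.
#' @param predictor beta name, e.g. `"cpp"`.
#' @return a `pi_test` result.
#' @export
compare_betas <- function(results_a, results_b, predictor) {
  get <- function(rs) vapply(rs, function(r) {
    if (!predictor %in% names(r$betas)) {
      stop("unknown predictor: ", predictor)
    }
    r$betas[[predictor]]
  }, numeric(1))
  compare_groups(get(results_a), get(results_b))
}

#' Median R-squared per group
#'
#' The goodness-of-fit summary for a per-subject regression model: the
#' median across subjects of the individual R-squared values.
#'
#' @param results list of `pi_regression` objects.
#' @param groups character vector of group labels aligned with `results`;
#'   `NULL` gives a single overall median.
#' @return named numeric vector of medians.
#' @export
median_r_squared <- function(results, groups = NULL) {
  r2 <- vapply(results, function(r) r$r_squared, numeric(1))
  if (is.null(groups)) return(c(all = stats::median(r2)))
  vapply(split(r2, groups), stats::median, numeric(1))
}
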