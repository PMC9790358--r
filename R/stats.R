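# Group-comparison battery. Standard tests delegate to stats/car; the
# Welch-James approximate-degrees-of-freedom test is implemented here
# (Johansen's formulation, untrimmed means).

new_pi_test <- function(test_name, statistic, df, p_value,
                        effect_size = NA_real_, effect_size_kind = "none",
                        correction = "none", routing = NULL) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 df = df, p_value = unname(min(max(p_value, 0), 1)),
                 effect_size = unname(effect_size),
                 effect_size_kind = effect_size_kind,
                 correction = correction, routing = routing),
            class = "pi_test")
}

#' @export
print.pi_test <- function(x, ...) {
  dfs <- if (all(is.na(x$df))) "" else
    paste0("(", paste(formatC(x$df, format = "g", digits = 4),
                      collapse = ", "), ")")
  cat(sprintf("%s%s = %.4g, p = %.4g", x$test_name, dfs, x$statistic,
              x$p_value))
  if (!is.na(x$effect_size)) {
    cat(sprintf(", %s = %.3g", x$effect_size_kind, x$effect_size))
  }
  if (x$correction != "none") cat(" [", x$correction, "-corrected]",
                                  sep = "")
  cat("\n")
  invisible(x)
}

#' Collect `pi_test` results into a table
#'
#' @param tests a (possibly nested) list of `pi_test` objects.
#' @return data frame with one row per test.
#' @export
test_table <- function(tests) {
  flat <- list()
  add <- function(x, nm) {
    if (inherits(x, "pi_test")) {
      flat[[length(flat) + 1L]] <<- cbind(
        data.frame(label = nm, test = x$test_name,
                   statistic = x$statistic,
                   df1 = x$df[1], df2 = if (length(x$df) > 1) x$df[2]
                   else NA_real_,
                   p_value = x$p_value, effect_size = x$effect_size,
                   effect_size_kind = x$effect_size_kind,
                   correction = x$correction))
    } else if (is.list(x)) {
      for (i in seq_along(x)) {
        add(x[[i]], paste(nm, names(x)[i] %||% i, sep = "."))
      }
    }
  }
  for (i in seq_along(tests)) add(tests[[i]], names(tests)[i] %||% i)
  out <- do.call(rbind, flat)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a) || !nzchar(a)) b else a

#' Wilcoxon rank-sum test with normal-approximation Z
#'
#' Two-sided rank-sum test using midranks with the tie-corrected normal
#' approximation (no continuity correction), reporting the Z statistic
#' signed by group order — positive when the first group's ranks are high —
#' and the Wilcoxon r effect size `|Z|/sqrt(N)`.
#'
#' @param x,y numeric samples (each length >= 2).
#' @return a `pi_test` with `statistic` = Z.
#' @export
rank_sum_test <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  if (length(unique(c(x, y))) == 1) stop("all values tied across groups")
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (w - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  new_pi_test("wilcoxon_rank_sum", z, NA_real_, p,
              effect_size = wilcoxon_r(z, n),
              effect_size_kind = "wilcoxon_r")
}

#' Wilcoxon r effect size
#'
#' `r = |Z| / sqrt(N)` where N is the total number of observations entering
#' the rank test.
#'
#' @param z_statistic the test's Z statistic.
#' @param n_total total sample size.
#' @return the effect size (non-negative).
#' @export
wilcoxon_r <- function(z_statistic, n_total) {
  stopifnot(n_total >= 1)
  abs(z_statistic) / sqrt(n_total)
}

#' Cohen's d from a two-sample t statistic
#'
#' `d = |t| * sqrt(1/n1 + 1/n2)`; equivalent to the pooled-SD definition
#' (see [cohen_d_pooled()]) for Student-t inputs.
#'
#' @param t_statistic the t statistic.
#' @param n1,n2 group sizes (>= 2).
#' @return Cohen's d.
#' @export
cohen_d <- function(t_statistic, n1, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  abs(t_statistic) * sqrt(1 / n1 + 1 / n2)
}

#' Cohen's d from group means and SDs
#'
#' `d = |m1 - m2| / s_pooled` with the pooled (n-1 weighted) SD.
#'
#' @param m1,m2 group means.
#' @param s1,s2 group SDs.
#' @param n1,n2 group sizes (>= 2).
#' @return Cohen's d.
#' @export
cohen_d_pooled <- function(m1, m2, s1, s2, n1, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  abs(m1 - m2) / sp
}

#' Routed two-group comparison
#'
#' The assumption-routed decision rule for comparing a continuous measure between
#' two groups: Shapiro-Wilk normality in each group and Levene's test for
#' variance homogeneity (both at alpha = 0.05) route the comparison to a
#' Student t test (both assumptions hold), Welch's t test (normality holds,
#' homogeneity rejected) or the Wilcoxon rank-sum test (normality
#' rejected). Cohen's d accompanies t-family results, Wilcoxon r rank-based
#' ones; the routing diagnostics are attached.
#'
#' @param x,y numeric samples (each length >= 2).
#' @param alpha significance level of the routing tests.
#' @return a `pi_test` with a `routing` element recording the decision.
#' @export
compare_groups <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  sw_p <- vapply(list(x, y), function(v) {
    if (length(v) < 3 || stats::sd(v) == 0) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  normal_ok <- all(is.na(sw_p) | sw_p >= alpha)
  lev <- car::leveneTest(c(x, y),
                         factor(rep(c("a", "b"), c(length(x), length(y)))))
  lev_p <- lev[["Pr(>F)"]][1]
  homo_ok <- is.na(lev_p) || lev_p >= alpha
  routing <- list(shapiro_p = sw_p, levene_p = lev_p,
                  route = if (!normal_ok) "rank_sum"
                          else if (!homo_ok) "welch_t" else "student_t")
  if (routing$route == "rank_sum") {
    out <- rank_sum_test(x, y)
    out$routing <- routing
    return(out)
  }
  tt <- stats::t.test(x, y, var.equal = routing$route == "student_t")
  new_pi_test(if (routing$route == "student_t") "student_t" else "welch_t",
              tt$statistic, unname(tt$parameter), tt$p.value,
              effect_size = cohen_d(tt$statistic, length(x), length(y)),
              effect_size_kind = "cohen_d", routing = routing)
}

#' Mixed ANOVA with Huynh-Feldt correction
#'
#' Standard mixed-design (one between-subject factor, one within-subject
#' factor) analysis of variance. Sums of squares and the Huynh-Feldt
#' sphericity correction are obtained from `car::Anova` on a multivariate
#' linear model; the within and interaction effects are reported with
#' HF-corrected p values and the epsilon (capped at 1). With a two-level
#' within factor sphericity is vacuous and epsilon is exactly 1.
#'
#' @param data long data frame.
#' @param value,subject,group,within names of the value, subject-id,
#'   between-factor and within-factor columns.
#' @return list of `pi_test`: `group`, `within`, `interaction`.
#' @export
mixed_anova_hf <- function(data, value = "value", subject = "subject_id",
                           group = "group", within = "within") {
  d <- data[, c(subject, group, within, value)]
  names(d) <- c("subject", "group", "within", "value")
  d$within <- factor(d$within)
  k <- nlevels(d$within)
  wide <- stats::reshape(d, idvar = c("subject", "group"),
                         timevar = "within", direction = "wide")
  ycols <- paste0("value.", levels(d$within))
  if (!all(ycols %in% names(wide)) || anyNA(wide[ycols])) {
    stop("missing cells: every subject needs a value at every within level")
  }
  Y <- as.matrix(wide[, ycols])
  gfac <- factor(wide$group)
  ng <- nlevels(gfac)
  # sum-to-zero contrasts so type-III tests are on unweighted means
  mlm <- stats::lm(Y ~ gfac, contrasts = list(gfac = "contr.sum"))
  idata <- data.frame(within = factor(levels(d$within),
                                      levels = levels(d$within)))
  an <- car::Anova(mlm, idata = idata, idesign = ~within, type = 3)
  s <- suppressWarnings(summary(an, multivariate = FALSE))
  ut <- s$univariate.tests
  grow <- ut["gfac", ]
  res <- list(group = new_pi_test(
    "mixed_anova_group", grow["F value"],
    c(grow["num Df"], grow["den Df"]), grow["Pr(>F)"]))
  for (eff in c("within", "interaction")) {
    rn <- if (eff == "within") "within" else "gfac:within"
    row <- ut[rn, ]
    if (k == 2) {
      eps <- 1
      p <- row["Pr(>F)"]
    } else {
      adj <- s$pval.adjustments
      eps <- min(1, adj[rn, "HF eps"])
      p <- adj[rn, "Pr(>F[HF])"]
    }
    res[[eff]] <- new_pi_test(
      paste0("mixed_anova_", eff), row["F value"],
      c(row["num Df"] * eps, row["den Df"] * eps), p,
      correction = "huynh-feldt")
    res[[eff]]$epsilon <- eps
  }
  res
}

# Johansen's Welch-James statistic for a linear hypothesis R mu = 0 on the
# stacked group-by-measure mean vector, with Satterthwaite-type df.
wj_statistic <- function(R, means, covs, ns) {
  g <- length(ns); k <- length(means[[1]])
  mu <- unlist(means)
  Shat <- matrix(0, g * k, g * k)
  for (j in seq_len(g)) {
    idx <- ((j - 1) * k + 1):(j * k)
    Shat[idx, idx] <- covs[[j]] / ns[j]
  }
  RSR <- R %*% Shat %*% t(R)
  if (rcond(RSR) < 1e-12) stop("singular within-group covariance")
  Rmu <- R %*% mu
  T <- drop(t(Rmu) %*% solve(RSR, Rmu))
  r <- nrow(R)
  M <- Shat %*% t(R) %*% solve(RSR) %*% R
  A <- 0
  for (j in seq_len(g)) {
    Q <- matrix(0, g * k, g * k)
    idx <- ((j - 1) * k + 1):(j * k)
    diag(Q)[idx] <- 1
    MQ <- M %*% Q
    A <- A + (sum(diag(MQ %*% MQ)) + sum(diag(MQ))^2) / (ns[j] - 1)
  }
  A <- A / 2
  c_const <- r + 2 * A - 6 * A / (r + 2)
  Fstat <- T / c_const
  df2 <- r * (r + 2) / (3 * A)
  list(F = Fstat, df1 = r, df2 = df2,
       p = stats::pf(Fstat, r, df2, lower.tail = FALSE))
}

#' Welch-James approximate-degrees-of-freedom test
#'
#' Heteroscedasticity-robust test for a between x within design (Johansen's
#' formulation on untrimmed means): each group contributes its own
#' mean vector and covariance matrix, and group, within and interaction
#' effects are tested with approximate (fractional) error degrees of
#' freedom. In the two-group, one-measure case it reduces exactly to
#' Welch's t test.
#'
#' @inheritParams mixed_anova_hf
#' @return list of `pi_test`: `group` (omitted when there is a single
#'   group), `within` (omitted for a single measure), `interaction`
#'   (requires both).
#' @export
welch_james_adf <- function(data, value = "value", subject = "subject_id",
                            group = "group", within = "within") {
  d <- data[, c(subject, group, within, value)]
  names(d) <- c("subject", "group", "within", "value")
  d$within <- factor(d$within); d$group <- factor(d$group)
  k <- nlevels(d$within); g <- nlevels(d$group)
  stopifnot(g >= 1, k >= 1)
  wide <- stats::reshape(d, idvar = c("subject", "group"),
                         timevar = "within", direction = "wide")
  ycols <- paste0("value.", levels(d$within))
  if (anyNA(wide[ycols])) stop("missing cells in within-factor table")
  means <- list(); covs <- list(); ns <- integer(g)
  for (j in seq_len(g)) {
    Yj <- as.matrix(wide[wide$group == levels(d$group)[j], ycols,
                         drop = FALSE])
    ns[j] <- nrow(Yj)
    if (ns[j] < 2) stop("each group needs >= 2 subjects")
    means[[j]] <- colMeans(Yj)
    covs[[j]] <- stats::cov(Yj)
  }
  cb <- function(m) cbind(diag(m - 1), -1)   # (m-1) x m contrast
  ones <- function(m) matrix(1 / m, 1, m)
  res <- list()
  mk <- function(name, R) {
    w <- wj_statistic(R, means, covs, ns)
    new_pi_test(paste0("welch_james_", name), w$F, c(w$df1, w$df2), w$p)
  }
  if (g > 1) res$group <- mk("group", kronecker(cb(g), ones(k)))
  if (k > 1) res$within <- mk("within", kronecker(ones(g), cb(k)))
  if (g > 1 && k > 1) {
    res$interaction <- mk("interaction", kronecker(cb(g), cb(k)))
  }
  res
}

#' Kruskal-Wallis omnibus with Bonferroni-corrected pairwise post-hocs
#'
#' Three-group rank analysis: tie-corrected Kruskal-Wallis chi-square
#' omnibus (via `stats::kruskal.test`), followed by the three pairwise
#' rank-sum tests with p values multiplied by 3 (capped at 1).
#'
#' @param values numeric vector.
#' @param labels group labels (exactly 3 distinct, each with >= 2 values).
#' @return list with `omnibus` (a `pi_test`) and `pairwise` (named list of
#'   Bonferroni-corrected `pi_test`s).
#' @export
kruskal_wallis_posthoc <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 3) stop("exactly 3 groups required")
  if (any(table(labels) < 2)) stop("each group needs >= 2 values")
  kw <- stats::kruskal.test(values, labels)
  omnibus <- new_pi_test("kruskal_wallis", kw$statistic,
                         unname(kw$parameter), kw$p.value)
  lv <- levels(labels)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  pairwise <- lapply(pairs, function(pr) {
    t <- rank_sum_test(values[labels == pr[1]], values[labels == pr[2]])
    t$p_value <- min(1, 3 * t$p_value)
    t$correction <- "bonferroni"
    t
  })
  names(pairwise) <- vapply(pairs, paste, collapse = "_vs_",
                            FUN.VALUE = character(1))
  list(omnibus = omnibus, pairwise = pairwise)
}

#' Pearson correlations between task measures and covariates
#'
#' @param summaries subject-summary data frame (one row per subject).
#' @param covariates data frame with `subject_id` and covariate columns.
#' @param measures names of summary columns to correlate (default: the
#'   learning-rate and confidence summaries present).
#' @param by_group logical; also compute correlations within each group.
#' @return data frame with `group`, `measure`, `covariate`, `r`, `p`, `n`.
#' @export
correlate_with_covariates <- function(summaries, covariates,
                                      measures = NULL, by_group = FALSE) {
  overlap <- intersect(setdiff(names(summaries), "subject_id"),
                       setdiff(names(covariates), "subject_id"))
  d <- merge(summaries[, setdiff(names(summaries), overlap), drop = FALSE],
             covariates, by = "subject_id")
  if (is.null(measures)) {
    measures <- intersect(c("overall_mean_alpha", "mean_alpha_small",
                            "mean_z_confidence"), names(summaries))
  }
  cov_names <- setdiff(names(covariates),
                       c("subject_id", "group", "medication"))
  cov_names <- cov_names[vapply(covariates[cov_names], is.numeric,
                                logical(1))]
  one <- function(dd, label) {
    rows <- list()
    for (m in measures) for (cv in cov_names) {
      ok <- stats::complete.cases(dd[[m]], dd[[cv]])
      if (sum(ok) < 3) stop("fewer than 3 complete pairs for ", m, " x ", cv)
      if (stats::sd(dd[[m]][ok]) == 0 || stats::sd(dd[[cv]][ok]) == 0) {
        stop("zero variance in pair ", m, " x ", cv)
      }
      ct <- stats::cor.test(dd[[m]][ok], dd[[cv]][ok])
      rows[[length(rows) + 1L]] <- data.frame(
        group = label, measure = m, covariate = cv,
        r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
    }
    do.call(rbind, rows)
  }
  out <- one(d, "all")
  if (by_group && "group" %in% names(d)) {
    for (g in unique(d$group)) out <- rbind(out, one(d[d$group == g, ], g))
  }
  rownames(out) <- NULL
  out
}
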