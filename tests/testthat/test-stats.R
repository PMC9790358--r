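test_that("rank-sum Z matches the exact permutation distribution and wilcox.test", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  y <- c(4.4, 6.1, 5.9, 8.0)
  t <- rank_sum_test(x, y)
  # exact two-sided p over all 70 rank assignments; the normal
  # approximation at n = 4 + 4 is documented to be within ~0.02
  p_exact <- oracle_ranksum_exact_p(x, y)
  expect_lt(abs(t$p_value - p_exact), 0.02)
  # agrees with the uncorrected normal approximation in wilcox.test
  expect_equal(t$p_value,
               suppressWarnings(wilcox.test(x, y, correct = FALSE,
                                            exact = FALSE)$p.value),
               tolerance = 1e-12)
  expect_lt(t$statistic, 0)  # first group ranks lower
  # identical groups: Z = 0, p = 1
  set.seed(71)
  z <- rnorm(10)
  t0 <- rank_sum_test(z, z)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  expect_error(rank_sum_test(rep(1, 5), rep(1, 5)), "tied")
})

test_that("rank-sum test has power against a 2-SD location shift", {
  hits <- vapply(1:200, function(i) {
    withr::with_seed(7100 + i, {
      rank_sum_test(rnorm(30), rnorm(30, 2))$p_value < 0.01
    })
  }, logical(1))
  expect_gt(mean(hits), 0.99)
})

test_that("effect sizes reproduce the published worked examples", {
  # two-group rank-sum on 73 subjects
  expect_equal(round(wilcoxon_r(-2.18, 73), 2), 0.26)
  # t test on 46 vs 27 subjects
  expect_equal(round(cohen_d(-2.12, 46, 27), 2), 0.51)
  expect_equal(wilcoxon_r(0, 50), 0)
  # monotone decreasing in N at fixed Z
  expect_true(all(diff(wilcoxon_r(2, c(10, 20, 40, 80))) < 0))
  expect_equal(cohen_d(0, 10, 10), 0)
  # t-based and pooled-SD variants agree for Student-t input
  set.seed(72)
  for (i in 1:10) {
    a <- rnorm(12, 0, 1.5)
    b <- rnorm(17, 0.4, 1.5)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(unname(cohen_d(tt$statistic, 12, 17)),
                 cohen_d_pooled(mean(a), mean(b), sd(a), sd(b), 12, 17),
                 tolerance = 1e-10)
  }
})

test_that("routed comparison picks Student, Welch or rank-sum as assumptions fail", {
  set.seed(73)
  a <- rnorm(40); b <- rnorm(40, 0.2)
  r1 <- compare_groups(a, b)
  expect_equal(r1$routing$route, "student_t")
  expect_equal(r1$effect_size_kind, "cohen_d")
  # variance ratio 10 triggers the Welch route in most samples
  routes <- vapply(1:100, function(i) {
    withr::with_seed(7300 + i, {
      compare_groups(rnorm(30, 0, 1), rnorm(30, 0, sqrt(10)))$routing$route
    })
  }, character(1))
  expect_gt(mean(routes == "welch_t"), 0.90)
  # heavy skew triggers the rank route
  r3 <- withr::with_seed(74, compare_groups(rexp(40)^3, rexp(40)^3))
  expect_equal(r3$routing$route, "rank_sum")
})

test_that("Huynh-Feldt mixed ANOVA handles two- and three-level within factors", {
  set.seed(75)
  # 2 within levels: sphericity vacuous, epsilon exactly 1
  d2 <- data.frame(subject_id = rep(sprintf("s%02d", 1:20), 2),
                   group = rep(rep(c("a", "b"), each = 10), 2),
                   within = rep(c("w1", "w2"), each = 20),
                   value = rnorm(40))
  m2 <- mixed_anova_hf(d2)
  expect_equal(m2$within$epsilon, 1)
  expect_equal(m2$interaction$epsilon, 1)
  # compound-symmetric data: epsilon near 1, F equal to aov oracle
  n <- 30
  subj_eff <- rnorm(n, 0, 1)
  Y <- outer(subj_eff, rep(1, 3)) + matrix(rnorm(n * 3), n, 3)
  d3 <- data.frame(subject_id = rep(sprintf("s%02d", 1:n), 3),
                   group = rep(rep(c("a", "b"), each = n / 2), 3),
                   within = rep(c("w1", "w2", "w3"), each = n),
                   value = c(Y))
  m3 <- mixed_anova_hf(d3)
  expect_gt(m3$within$epsilon, 0.9)
  ao <- summary(aov(value ~ group * within + Error(subject_id / within),
                    data = transform(d3, within = factor(within))))
  f_aov <- ao[["Error: subject_id:within"]][[1]]["within", "F value"]
  uncorrected_f <- m3$within$statistic
  expect_equal(uncorrected_f, f_aov, tolerance = 1e-6)
  expect_error(mixed_anova_hf(d3[-1, ]), "missing cells")
})

test_that("Welch-James reduces exactly to Welch's t with one measure", {
  set.seed(76)
  x <- rnorm(14, 0, 1); y <- rnorm(23, 0.8, 2.5)
  d <- data.frame(subject_id = sprintf("s%02d", 1:37),
                  group = rep(c("a", "b"), c(14, 23)),
                  within = "m1", value = c(x, y))
  wj <- welch_james_adf(d)
  tt <- t.test(x, y)
  expect_equal(wj$group$statistic, unname(tt$statistic^2),
               tolerance = 1e-8)
  expect_equal(wj$group$df[2], unname(tt$parameter), tolerance = 1e-8)
  expect_equal(wj$group$p_value, tt$p.value, tolerance = 1e-8)
})

test_that("Welch-James agrees with the mixed ANOVA on homoscedastic data", {
  set.seed(77)
  p_wj <- p_ma <- matrix(NA_real_, 60, 2)
  for (i in 1:60) {
    n <- 24
    Y <- matrix(rnorm(n * 3), n, 3)
    d <- data.frame(subject_id = rep(sprintf("s%02d", 1:n), 3),
                    group = rep(rep(c("a", "b"), each = n / 2), 3),
                    within = rep(c("w1", "w2", "w3"), each = n),
                    value = c(Y))
    wj <- welch_james_adf(d)
    ma <- mixed_anova_hf(d)
    p_wj[i, ] <- c(wj$group$p_value, wj$interaction$p_value)
    p_ma[i, ] <- c(ma$group$p_value, ma$interaction$p_value)
  }
  # same nulls: p values track each other closely on average
  expect_gt(cor(p_wj[, 1], p_ma[, 1]), 0.99)
  expect_gt(cor(p_wj[, 2], p_ma[, 2]), 0.95)
  expect_lt(mean(abs(p_wj - p_ma)), 0.05)
})

test_that("Kruskal-Wallis omnibus matches its defining formula and corrects post-hocs", {
  v <- c(2.1, 5.3, 1.4, 7.7, 3.2, 9.9, 4.4, 6.1, 8.8)
  g <- rep(c("a", "b", "c"), 3)
  kw <- kruskal_wallis_posthoc(v, g)
  expect_equal(kw$omnibus$statistic, oracle_kw_statistic(v, g),
               tolerance = 1e-12)
  expect_equal(length(kw$pairwise), 3)
  # pairwise p = min(1, 3 x raw)
  raw <- rank_sum_test(v[g == "a"], v[g == "b"])$p_value
  expect_equal(kw$pairwise$a_vs_b$p_value, min(1, 3 * raw))
  expect_equal(kw$pairwise$a_vs_b$correction, "bonferroni")
  # three identical groups: p ~ 1
  set.seed(78)
  z <- rnorm(8)
  kw0 <- kruskal_wallis_posthoc(rep(z, 3), rep(c("a", "b", "c"), each = 8))
  expect_gt(kw0$omnibus$p_value, 0.99)
  expect_error(kruskal_wallis_posthoc(v, rep(c("a", "b"), c(4, 5))),
               "3 groups")
})

test_that("correlations match manual arithmetic and respect degenerate input", {
  s <- data.frame(subject_id = sprintf("s%d", 1:5),
                  overall_mean_alpha = c(2, 4, 5, 7, 9))
  cov <- data.frame(subject_id = sprintf("s%d", 1:5),
                    score = c(1, 3, 4, 8, 10))
  out <- correlate_with_covariates(s, cov,
                                   measures = "overall_mean_alpha")
  # hand computation of Pearson r on the 5-point table
  x <- s$overall_mean_alpha; y <- cov$score
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_manual, tolerance = 1e-12)
  expect_equal(out$n, 5)
  # exact linear relation
  cov2 <- data.frame(subject_id = s$subject_id, score = 2 * x + 1)
  out2 <- correlate_with_covariates(s, cov2,
                                    measures = "overall_mean_alpha")
  expect_equal(out2$r, 1, tolerance = 1e-12)
  cov3 <- data.frame(subject_id = s$subject_id, score = rep(1, 5))
  expect_error(correlate_with_covariates(s, cov3,
                                         measures = "overall_mean_alpha"),
               "zero variance")
})

test_that("null correlations stay within the n = 73 sampling band", {
  inside <- vapply(1:200, function(i) {
    withr::with_seed(7900 + i, {
      abs(cor(rnorm(73), rnorm(73))) < 0.23
    })
  }, logical(1))
  expect_gt(mean(inside), 0.90)
  expect_lt(mean(inside), 0.99)
})

test_that("tests are invariant to group relabelling up to the statistic's sign", {
  set.seed(80)
  a <- rnorm(15); b <- rnorm(12, 0.5)
  t1 <- rank_sum_test(a, b); t2 <- rank_sum_test(b, a)
  expect_equal(t1$statistic, -t2$statistic, tolerance = 1e-12)
  expect_equal(t1$p_value, t2$p_value, tolerance = 1e-12)
  expect_equal(t1$effect_size, t2$effect_size, tolerance = 1e-12)
  c1 <- compare_groups(a, b); c2 <- compare_groups(b, a)
  expect_equal(c1$statistic, -c2$statistic, tolerance = 1e-12)
  expect_equal(c1$p_value, c2$p_value, tolerance = 1e-12)
})
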