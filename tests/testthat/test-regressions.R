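# builds a derived table + trace where the action update is an exact or
# noisy linear function of the observer quantities
make_constructed_subject <- function(seed, b_pe = 0.2, b_cpp = 0.6,
                                     noise_sd = 0, conf_beta = NULL,
                                     conf_noise = 0.1) {
  cfg <- task_config()
  s <- generate_session(cfg, seed = seed)
  ocfg <- observer_config(hazard = cfg$hazard, noise_var = cfg$noise_sd^2)
  tr <- predinfer:::run_observer_session(s, ocfg)
  withr::with_seed(seed + 5000, {
    parts <- lapply(split(s, s$block), function(bl) {
      n <- nrow(bl)
      cpp <- tr$cpp[tr$block == bl$block[1]]
      bucket <- numeric(n)
      b <- bl$outcome[1]
      eps <- rnorm(n, 0, noise_sd)
      for (t in seq_len(n)) {
        bucket[t] <- b
        delta <- circ_diff(bl$outcome[t], b)
        b <- wrap_angle(b + (b_pe + b_cpp * cpp[t]) * delta + eps[t])
      }
      sc <- score_trial(bl$outcome, bucket, cfg)
      cbind(bl, data.frame(bucket = bucket, hit = sc$hit))
    })
    rec <- do.call(rbind, parts)
    rec$subject_id <- "s"
    d <- derive_trial_metrics(rec)
    if (!is.null(conf_beta)) {
      # confidence built from the previous trial's cpp plus noise
      conf <- numeric(nrow(tr))
      for (bl in unique(tr$block)) {
        i <- which(tr$block == bl)
        cpp_prev <- c(0, tr$cpp[i][-length(i)])
        conf[i] <- conf_beta * cpp_prev + rnorm(length(i), 0, conf_noise)
      }
      d$z_confidence <- conf
    }
    list(derived = d, trace = tr)
  })
}

test_that("an exact linear agent is recovered perfectly by the action model", {
  sub <- make_constructed_subject(seed = 61, b_pe = 0.5, b_cpp = 0,
                                  noise_sd = 0)
  fit <- fit_action_model(sub$derived, sub$trace)
  expect_equal(unname(fit$betas["abs_pe"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(fit$betas[c("intercept", "cpp", "ru", "hit")]),
               rep(0, 4), tolerance = 1e-7)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # block-final trials are dropped: 4 blocks of 75 -> at most 296 usable
  expect_equal(fit$n_trials_used,
               300 - 4 - sum(sub$derived$exclude_reason == "zero_pe",
                             na.rm = TRUE))
})

test_that("action-model betas are recovered on average across noisy subjects", {
  est <- vapply(1:100, function(i) {
    sub <- make_constructed_subject(seed = 6000 + i, b_pe = 0.2,
                                    b_cpp = 0.6, noise_sd = 2)
    fit_action_model(sub$derived, sub$trace)$betas[c("abs_pe", "cpp")]
  }, numeric(2))
  expect_lt(abs(mean(est["abs_pe", ]) - 0.2), 0.05)
  expect_lt(abs(mean(est["cpp", ]) - 0.6), 0.05)
})

test_that("confidence-model betas are recovered on average", {
  est <- vapply(1:100, function(i) {
    sub <- make_constructed_subject(seed = 7000 + i, conf_beta = -0.5,
                                    conf_noise = 0.1)
    fit_confidence_model(sub$derived, sub$trace)$betas["cpp_prev"]
  }, numeric(1))
  expect_lt(abs(mean(est) + 0.5), 0.05)
})

test_that("confidence-model betas cover zero when confidence is pure noise", {
  covered <- matrix(FALSE, 100, 4)
  for (i in 1:100) {
    sub <- make_constructed_subject(seed = 8000 + i, conf_beta = 0,
                                    conf_noise = 1)
    fit <- fit_confidence_model(sub$derived, sub$trace)$fit
    ci <- confint(fit, level = 0.95)[-1, , drop = FALSE]
    covered[i, ] <- ci[, 1] <= 0 & 0 <= ci[, 2]
  }
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.99)
})

test_that("confidence model drops the first trial of each block", {
  sub <- make_subject(seed = 62)
  fit <- fit_confidence_model(sub$derived, sub$trace)
  expect_equal(fit$n_trials_used, 300 - 4)
})

test_that("coupling slope is exact for constructed proportional updates", {
  set.seed(63)
  z <- cumsum(rnorm(50, 0, 0.3))
  b <- wrap_angle(100 + cumsum(c(0, 2 * abs(diff(z)))))
  d <- data.frame(subject_id = "s", block = 1, trial = 1:50,
                  bucket = b, z_confidence = z)
  fit <- fit_coupling_model(d)
  expect_equal(unname(fit$betas["conf_update"]), 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # independent streams: mean slope near zero across subjects
  slopes <- vapply(1:100, function(i) {
    withr::with_seed(9000 + i, {
      d2 <- data.frame(subject_id = "s", block = 1, trial = 1:150,
                       bucket = wrap_angle(cumsum(rnorm(150, 0, 5))),
                       z_confidence = rnorm(150))
      fit_coupling_model(d2)$betas["conf_update"]
    })
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 0.15)
  # constant confidence is degenerate
  d3 <- data.frame(subject_id = "s", block = 1, trial = 1:10,
                   bucket = 1:10, z_confidence = 0)
  expect_error(fit_coupling_model(d3), "zero variance")
})

test_that("regression residuals are orthogonal to every predictor", {
  sub <- make_subject(seed = 64)
  for (fit in list(fit_action_model(sub$derived, sub$trace),
                   fit_confidence_model(sub$derived, sub$trace),
                   fit_coupling_model(sub$derived))) {
    X <- model.matrix(fit$fit)
    r <- residuals(fit$fit)
    scaled <- abs(t(X) %*% r) / (nrow(X) * apply(abs(X), 2, max))
    expect_lt(max(scaled), 1e-8)
  }
})

test_that("closed-form OLS matches a gradient-descent oracle", {
  set.seed(65)
  for (i in 1:5) {
    X <- cbind(1, matrix(rnorm(40 * 3), 40, 3))
    y <- X %*% c(1, -0.5, 2, 0.3) + rnorm(40, 0, 0.5)
    beta_lm <- unname(coef(lm(y ~ X - 1)))
    beta_gd <- oracle_ols_bfgs(X, y)
    expect_equal(beta_lm, beta_gd, tolerance = 1e-6)
  }
})

test_that("beta comparison routes and errors sensibly", {
  sub_a <- lapply(1:6, function(i) {
    make_constructed_subject(seed = 300 + i, b_pe = 0.2, b_cpp = 0.6,
                             noise_sd = 2)
  })
  fits_a <- lapply(sub_a, function(s) fit_action_model(s$derived, s$trace))
  cmp <- compare_betas(fits_a[1:3], fits_a[4:6], "cpp")
  expect_s3_class(cmp, "pi_test")
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
  expect_error(compare_betas(fits_a[1:3], fits_a[4:6], "nonexistent"),
               "unknown predictor")
})

test_that("median R-squared summarises per-group goodness of fit", {
  mk <- function(r2) structure(list(r_squared = r2), class = "pi_regression")
  expect_equal(unname(median_r_squared(lapply(c(0.1, 0.5, 0.9), mk))), 0.5)
  res <- lapply(c(0.1, 0.5, 0.9, 0.2, 0.4), mk)
  by_g <- median_r_squared(res, c("a", "a", "a", "b", "b"))
  expect_equal(unname(by_g), c(0.5, 0.3))
  # exact-construction agents reach R^2 = 1
  sub <- make_constructed_subject(seed = 66, b_pe = 0.5, b_cpp = 0,
                                  noise_sd = 0)
  expect_equal(unname(median_r_squared(list(
    fit_action_model(sub$derived, sub$trace)))), 1, tolerance = 1e-10)
})

test_that("low-PE-only refits run through the same operations", {
  sub <- make_subject(seed = 67)
  d <- filter_learning_rates(sub$derived)
  d <- bin_by_pe_magnitude(d)
  dl <- d[!is.na(d$pe_bin) & d$pe_bin == "small", ]
  # small-PE trials are all hits, so the hit predictor is dropped
  expect_error(fit_action_model(dl, sub$trace), "collinear.*hit")
  fit <- fit_action_model(dl, sub$trace, include_hit = FALSE)
  expect_s3_class(fit, "pi_regression")
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  expect_lt(fit$n_trials_used, nrow(d) / 2)
})
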