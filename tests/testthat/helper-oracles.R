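# Independent oracles and fixture builders used across the test files.
# Oracles are deliberately naive (sorting, grids, enumeration) and share no
# code with the implementation they check.

# linear-interpolation quantile by explicit sort-and-interpolate
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1, n)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# full-Bayes filtering of a static Gaussian mean on a dense grid:
# posterior variance after each outcome, Gaussian prior
oracle_grid_bayes_var <- function(outcomes, prior_mean, prior_var,
                                  noise_var, half_width = 80,
                                  step = 0.02) {
  grid <- seq(prior_mean - half_width, prior_mean + half_width, by = step)
  logp <- stats::dnorm(grid, prior_mean, sqrt(prior_var), log = TRUE)
  vars <- numeric(length(outcomes))
  for (t in seq_along(outcomes)) {
    logp <- logp + stats::dnorm(outcomes[t], grid, sqrt(noise_var),
                                log = TRUE)
    p <- exp(logp - max(logp))
    p <- p / sum(p)
    m <- sum(p * grid)
    vars[t] <- sum(p * (grid - m)^2)
  }
  vars
}

# exact two-sided rank-sum p by enumeration of all rank assignments
# (untied samples only)
oracle_ranksum_exact_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  stopifnot(length(unique(r)) == n)
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  subsets <- utils::combn(n, n1)
  ws <- apply(subsets, 2, function(idx) sum(seq_len(n)[idx]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# exact Kruskal-Wallis statistic from its defining formula (no ties)
oracle_kw_statistic <- function(values, labels) {
  r <- rank(values)
  n <- length(values)
  groups <- split(r, labels)
  12 / (n * (n + 1)) *
    sum(vapply(groups, function(g) length(g) * mean(g)^2, numeric(1))) -
    3 * (n + 1)
}

# gradient-based least squares: minimise RSS with BFGS from zero start
oracle_ols_bfgs <- function(X, y) {
  rss <- function(b) sum((y - X %*% b)^2)
  grad <- function(b) -2 * drop(t(X) %*% (y - X %*% b))
  stats::optim(rep(0, ncol(X)), rss, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))$par
}

# noiseless observer-coupled agent profile (deterministic behaviour)
noiseless_profile <- function(policy = "observer_coupled", base_gain = 1,
                              smallpe_boost = 0) {
  agent_profile(policy = policy, base_gain = base_gain,
                smallpe_boost = smallpe_boost,
                motor_noise_sd = 0, motor_noise_weber = 0,
                confidence_noise_sd = 2)
}

# one simulated subject's derived table + aligned observer trace
make_subject <- function(seed = 1, profile = preset_profiles()$CTL,
                         cfg = task_config(), z_conf = TRUE) {
  session <- generate_session(cfg, seed = seed)
  rec <- simulate_agent(profile, session, cfg, seed = seed + 1000)
  rec$subject_id <- "S001"
  rec$group <- "CTL"
  d <- derive_trial_metrics(rec)
  if (z_conf) d$z_confidence <- zscore_confidence(d$confidence)
  trace <- predinfer:::run_observer_session(
    session, observer_config(hazard = cfg$hazard,
                             noise_var = cfg$noise_sd^2,
                             n_positions = cfg$n_positions))
  list(derived = d, trace = trace, session = session)
}

# tiny two-group cohort spec for pipeline tests
tiny_cohort <- function(seed = 1, n_ctl = 6, n_ocd = 5) {
  p <- preset_profiles()
  cohort_spec(list(CTL = list(n = n_ctl, profile = p$CTL),
                   OCD = list(n = n_ocd, profile = p$OCD)),
              task = task_config(), seed = seed)
}
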