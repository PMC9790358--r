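#' Configuration for the reduced Bayesian observer
#'
#' The observer is a quasi-optimal, reduced approximation to full Bayesian
#' change-point filtering: it tracks a single belief about the latent mean
#' together with its uncertainty, and on every trial computes the
#' change-point probability (the posterior probability that the outcome was
#' drawn from a freshly resampled mean) and the relative uncertainty (belief
#' uncertainty as a fraction of total predictive variance). Its learning
#' rate is `alpha = cpp + (1 - cpp) * ru`.
#'
#' @param hazard assumed per-trial change-point probability (default 0.125,
#'   the task's true value).
#' @param noise_var outcome noise variance sigma_N^2 in squared degrees
#'   (default 144, i.e. SD 12).
#' @param n_positions support of the uniform change-point distribution
#'   (default 360).
#' @param initial_uncertainty initial belief variance sigma^2_mu in squared
#'   degrees; defaults to `noise_var` (an uninformative start).
#' @param confidence_map which model-confidence summary to report:
#'   `"cpp_ru"` (default, `(1 - cpp) * (1 - ru)`), `"one_minus_alpha"`, or
#'   `"neg_total_uncertainty"` (minus the predictive variance).
#' @param geometry `"circular"` (default) or `"linear"` treatment of the
#'   0-360 scale.
#' @return an object of class `observer_config`.
#' @export
observer_config <- function(hazard = 0.125, noise_var = 144,
                            n_positions = 360,
                            initial_uncertainty = noise_var,
                            confidence_map = c("cpp_ru", "one_minus_alpha",
                                               "neg_total_uncertainty"),
                            geometry = c("circular", "linear")) {
  confidence_map <- match.arg(confidence_map)
  geometry <- match.arg(geometry)
  if (!is.finite(hazard) || hazard < 0 || hazard > 1) {
    stop("hazard must be in [0, 1]")
  }
  stopifnot(noise_var > 0, n_positions >= 1, initial_uncertainty >= 0)
  structure(list(hazard = hazard, noise_var = noise_var,
                 n_positions = as.integer(n_positions),
                 initial_uncertainty = initial_uncertainty,
                 confidence_map = confidence_map, geometry = geometry),
            class = "observer_config")
}

#' Change-point probability of an outcome
#'
#' Posterior probability that an outcome at signed distance `delta` from the
#' current belief came from a freshly resampled (uniform) mean rather than
#' the current Gaussian regime:
#' `cpp = H * u / (H * u + (1 - H) * g)`, where `u = 1/n_positions` and `g`
#' is the Gaussian density of `delta` with variance
#' `noise_var + mean_uncertainty`.
#'
#' @param delta signed prediction error(s), degrees.
#' @param noise_var outcome noise variance, squared degrees.
#' @param mean_uncertainty current belief variance, squared degrees.
#' @param config an [observer_config()] supplying `hazard` and
#'   `n_positions`.
#' @return probabilities in [0, 1], non-decreasing in `abs(delta)`.
#' @export
change_point_probability <- function(delta, noise_var, mean_uncertainty,
                                     config = observer_config()) {
  stopifnot(noise_var > 0, mean_uncertainty >= 0)
  h <- config$hazard
  if (h == 0) return(rep(0, length(delta)))
  if (h == 1) return(rep(1, length(delta)))
  u <- 1 / config$n_positions
  g <- stats::dnorm(delta, 0, sqrt(noise_var + mean_uncertainty))
  h * u / (h * u + (1 - h) * g)
}

#' Learning rate of the reduced observer
#'
#' `alpha = cpp + (1 - cpp) * ru`: fully reset the belief when a change
#' point is certain, otherwise weigh the outcome by the relative
#' uncertainty (the Kalman gain of the stable regime).
#'
#' @param cpp change-point probability in [0, 1].
#' @param relative_uncertainty relative uncertainty in [0, 1).
#' @return learning rate in [0, 1].
#' @export
model_learning_rate <- function(cpp, relative_uncertainty) {
  stopifnot(all(cpp >= 0 & cpp <= 1),
            all(relative_uncertainty >= 0 & relative_uncertainty <= 1))
  cpp + (1 - cpp) * relative_uncertainty
}

#' One observer update
#'
#' Given the pre-outcome state (belief and belief variance) and an outcome,
#' computes the trial's prediction error, change-point probability, relative
#' uncertainty and learning rate, and returns the post-outcome state. The
#' belief moves by `alpha * delta` (wrapped); the belief variance becomes
#' `cpp * s2 + (1 - cpp) * ru * s2 + cpp * (1 - cpp) * (delta * (1 - ru))^2`
#' with `s2 = noise_var` — the reduced-Bayesian mixture of the reset and
#' stable regimes plus the variance contributed by regime ambiguity. With
#' `cpp = 0` this is exact conjugate-Gaussian filtering.
#'
#' @param state list with `belief` (degrees) and `mean_uncertainty`
#'   (squared degrees).
#' @param outcome observed angle, degrees.
#' @param config an [observer_config()].
#' @return list with the updated `belief` and `mean_uncertainty` plus the
#'   trial quantities `delta`, `cpp`, `relative_uncertainty`,
#'   `learning_rate`.
#' @export
update_belief_and_uncertainty <- function(state, outcome,
                                          config = observer_config()) {
  s2n <- config$noise_var
  v <- state$mean_uncertainty
  ru <- v / (v + s2n)
  delta <- signed_diff(outcome, state$belief, config$geometry)
  cpp <- change_point_probability(delta, s2n, v, config)
  alpha <- cpp + (1 - cpp) * ru
  belief <- state$belief + alpha * delta
  if (config$geometry == "circular") belief <- wrap_angle(belief)
  v_new <- cpp * s2n + (1 - cpp) * ru * s2n +
    cpp * (1 - cpp) * (delta * (1 - ru))^2
  list(belief = belief, mean_uncertainty = v_new, delta = delta, cpp = cpp,
       relative_uncertainty = ru, learning_rate = alpha)
}

#' Run the reduced Bayesian observer over an outcome sequence
#'
#' Processes outcomes in order, starting from `init_belief` (default: the
#' first outcome) with belief variance `config$initial_uncertainty`. Row `t`
#' of the trace holds the pre-outcome belief and relative uncertainty, the
#' prediction error and change-point probability produced by outcome `t`,
#' the learning rate applied to it, and the model confidence.
#'
#' @param outcomes numeric vector of outcome angles (degrees), length >= 1.
#' @param config an [observer_config()].
#' @param init_belief starting belief in degrees; `NULL` (default) uses the
#'   first outcome.
#' @return an `observer_trace`: a data frame with columns `trial`,
#'   `outcome`, `belief`, `delta`, `cpp`, `relative_uncertainty`,
#'   `learning_rate`, `mean_uncertainty`, `confidence`.
#' @export
run_observer <- function(outcomes, config = observer_config(),
                         init_belief = NULL) {
  if (length(outcomes) == 0) stop("empty outcome sequence")
  n <- length(outcomes)
  belief <- delta <- cpp <- ru <- alpha <- v <- numeric(n)
  state <- list(belief = if (is.null(init_belief)) outcomes[1] else init_belief,
                mean_uncertainty = config$initial_uncertainty)
  for (t in seq_len(n)) {
    belief[t] <- state$belief
    v[t] <- state$mean_uncertainty
    step <- update_belief_and_uncertainty(state, outcomes[t], config)
    delta[t] <- step$delta
    cpp[t] <- step$cpp
    ru[t] <- step$relative_uncertainty
    alpha[t] <- step$learning_rate
    state <- step[c("belief", "mean_uncertainty")]
  }
  tr <- data.frame(trial = seq_len(n), outcome = outcomes, belief = belief,
                   delta = delta, cpp = cpp, relative_uncertainty = ru,
                   learning_rate = alpha, mean_uncertainty = v)
  tr$confidence <- model_confidence(tr, config)
  class(tr) <- c("observer_trace", "data.frame")
  attr(tr, "config") <- config
  tr
}

#' Model confidence from an observer trace
#'
#' A monotone summary of the observer's certainty. The default map is
#' `(1 - cpp) * (1 - ru)`, strictly decreasing in both the change-point
#' probability and the relative uncertainty; alternatives are
#' `1 - learning_rate` and minus the total predictive variance.
#'
#' @param trace an `observer_trace` (or any data frame with the trace
#'   columns).
#' @param config an [observer_config()] whose `confidence_map` selects the
#'   variant.
#' @return numeric vector of per-trial model confidence.
#' @export
model_confidence <- function(trace, config = observer_config()) {
  switch(config$confidence_map,
         cpp_ru = (1 - trace$cpp) * (1 - trace$relative_uncertainty),
         one_minus_alpha = 1 - trace$learning_rate,
         neg_total_uncertainty =
           -(trace$mean_uncertainty + config$noise_var),
         stop("unknown confidence_map: ", config$confidence_map))
}

#' @export
print.observer_trace <- function(x, ...) {
  cat(sprintf("Reduced Bayesian observer trace: %d trials\n", nrow(x)))
  cat(sprintf("  mean learning rate %.3f, mean cpp %.3f, final RU %.4f\n",
              mean(x$learning_rate), mean(x$cpp),
              x$relative_uncertainty[nrow(x)]))
  invisible(x)
}

#' @export
summary.observer_trace <- function(object, ...) {
  out <- data.frame(
    quantity = c("learning_rate", "cpp", "relative_uncertainty",
                 "confidence"),
    mean = vapply(object[c("learning_rate", "cpp", "relative_uncertainty",
                           "confidence")], mean, numeric(1)),
    min = vapply(object[c("learning_rate", "cpp", "relative_uncertainty",
                          "confidence")], min, numeric(1)),
    max = vapply(object[c("learning_rate", "cpp", "relative_uncertainty",
                          "confidence")], max, numeric(1)))
  rownames(out) <- NULL
  out
}

# Run the observer per block of a session and bind the traces, adding
# block/trial columns aligned with the session rows.
run_observer_session <- function(session, config = observer_config()) {
  parts <- lapply(split(session, session$block), function(bl) {
    tr <- run_observer(bl$outcome, config)
    tr$block <- bl$block
    tr$trial <- bl$trial
    tr
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Write an observer trace to CSV
#'
#' @param trace an `observer_trace`.
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
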