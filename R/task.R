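#' Task configuration for the predictive-inference task
#'
#' Bundles the generative parameters of the circular "coin and bucket"
#' predictive-inference task: a latent mean on a 360-position ring is
#' resampled uniformly with per-trial hazard `hazard`, and each trial's
#' outcome is the latent mean plus Gaussian noise, wrapped to the ring.
#' A bucket centred within `bucket_halfwidth` degrees of the outcome scores
#' `reward_hit` points, otherwise `reward_miss`.
#'
#' @param n_blocks number of blocks (default 4).
#' @param trials_per_block trials per block (default 75).
#' @param hazard per-trial change-point probability (default 0.125).
#' @param noise_sd SD of outcome noise around the latent mean, in degrees
#'   (default 12).
#' @param n_positions number of possible change-point locations on the ring
#'   (default 360); new means are drawn from these discrete positions.
#' @param bucket_halfwidth half-width of the bucket in degrees (default 20);
#'   a hit is inclusive at the boundary.
#' @param reward_hit,reward_miss points awarded on a hit / miss
#'   (defaults +10 / -10).
#' @return an object of class `task_config` (a validated list).
#' @export
task_config <- function(n_blocks = 4, trials_per_block = 75, hazard = 0.125,
                        noise_sd = 12, n_positions = 360,
                        bucket_halfwidth = 20, reward_hit = 10,
                        reward_miss = -10) {
  stopifnot(n_blocks >= 1, trials_per_block >= 1, n_positions >= 1,
            bucket_halfwidth >= 0)
  if (!is.finite(hazard) || hazard < 0 || hazard > 1) {
    stop("hazard must be a probability in [0, 1]")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 hazard = hazard, noise_sd = noise_sd,
                 n_positions = as.integer(n_positions),
                 bucket_halfwidth = bucket_halfwidth,
                 reward_hit = reward_hit, reward_miss = reward_miss),
            class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Predictive-inference task configuration\n")
  cat(sprintf("  %d block(s) x %d trials, hazard %.4g\n",
              x$n_blocks, x$trials_per_block, x$hazard))
  cat(sprintf("  outcome noise SD %.4g deg, %d ring positions\n",
              x$noise_sd, x$n_positions))
  cat(sprintf("  bucket half-width %.4g deg, reward %+g / %+g\n",
              x$bucket_halfwidth, x$reward_hit, x$reward_miss))
  invisible(x)
}

#' Generate one task session
#'
#' Draws the latent-mean trajectory and outcomes for every block of a
#' session. The first trial of each block always resamples the mean (and is
#' flagged as a change point); afterwards the mean is resampled with
#' probability `config$hazard` on each trial, uniformly over the
#' `config$n_positions` integer ring positions. Outcomes are the latent mean
#' plus Gaussian noise (`config$noise_sd`), wrapped to [0, 360).
#'
#' @param config a [task_config()].
#' @param seed integer seed; identical seeds give identical sessions.
#' @return data frame with columns `block`, `trial`, `latent_mean`,
#'   `changepoint` (logical), `outcome`.
#' @export
generate_session <- function(config = task_config(), seed = 1L) {
  stopifnot(inherits(config, "task_config"))
  withr::with_seed(as.integer(seed), {
    blocks <- lapply(seq_len(config$n_blocks), function(b) {
      n <- config$trials_per_block
      cp <- stats::runif(n) < config$hazard
      cp[1] <- TRUE
      mu <- numeric(n)
      cur <- NA_real_
      draws <- sample.int(config$n_positions, sum(cp), replace = TRUE) - 1
      j <- 0L
      for (t in seq_len(n)) {
        if (cp[t]) {
          j <- j + 1L
          cur <- draws[j]
        }
        mu[t] <- cur
      }
      x <- wrap_angle(mu + stats::rnorm(n, 0, config$noise_sd))
      data.frame(block = b, trial = seq_len(n), latent_mean = mu,
                 changepoint = cp, outcome = x)
    })
    do.call(rbind, blocks)
  })
}

#' Score a trial
#'
#' A trial is a hit when the absolute circular distance between the outcome
#' and the bucket centre is at most `config$bucket_halfwidth` (inclusive).
#'
#' @param outcome,bucket angles in degrees (vectorised).
#' @param config a [task_config()].
#' @return data frame with logical `hit` and integer `points`.
#' @export
score_trial <- function(outcome, bucket, config = task_config()) {
  hit <- abs(circ_diff(outcome, bucket)) <= config$bucket_halfwidth
  data.frame(hit = hit,
             points = ifelse(hit, config$reward_hit, config$reward_miss))
}

#' Write / read a session to CSV
#'
#' Plain-text round trip for [generate_session()] output; floats carry full
#' precision (15 significant digits).
#'
#' @param session session data frame.
#' @param path file path.
#' @return `read_session()` returns the session data frame.
#' @export
write_session <- function(session, path) {
  out <- session
  for (nm in c("latent_mean", "outcome")) {
    out[[nm]] <- formatC(out[[nm]], digits = 15, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("block", "trial", "latent_mean", "changepoint", "outcome")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("session file missing column(s): ",
                         paste(miss, collapse = ", "))
  x$changepoint <- as.logical(x$changepoint)
  x
}
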