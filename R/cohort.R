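#' Agent behavioural profile
#'
#' Describes how a synthetic agent converts observer quantities into bucket
#' placements and confidence reports. Three updating policies are available:
#'
#' * `"observer_coupled"`: effective learning rate = `base_gain` times the
#'   reduced observer's learning rate on the agent's own prediction error;
#' * `"fixed_alpha"`: a constant effective learning rate of `base_gain`;
#' * `"smallpe_boosted"`: observer-coupled, plus an additive increment
#'   `smallpe_boost` whenever the absolute prediction error is below
#'   `smallpe_threshold` degrees — the "excessive updating after small
#'   errors" phenotype.
#'
#' Confidence reports are an affine map of model confidence plus Gaussian
#' noise, rounded and clamped to the 1-100 rating scale.
#'
#' @param policy one of `"observer_coupled"`, `"fixed_alpha"`,
#'   `"smallpe_boosted"`.
#' @param base_gain multiplicative gain on the observer learning rate (or
#'   the fixed rate itself under `"fixed_alpha"`); must be >= 0.
#' @param smallpe_boost additive learning-rate increment applied below the
#'   threshold (only used by `"smallpe_boosted"`).
#' @param smallpe_threshold absolute-prediction-error threshold in degrees.
#' @param motor_noise_sd baseline SD of Gaussian motor noise added to each
#'   bucket update, degrees; must be >= 0 (default 0.5, roughly the
#'   placement precision of a rotary-dial response).
#' @param motor_noise_weber signal-dependent component of motor noise: the
#'   noise SD on a trial is
#'   `motor_noise_sd + motor_noise_weber * |intended update|`, reflecting
#'   that large dial movements are less precise than small ones.
#' @param confidence_gain,confidence_offset affine map from model confidence
#'   (in [0, 1]) to the 1-100 rating scale:
#'   `rating = offset + gain * model_confidence + noise`.
#' @param confidence_noise_sd SD of the rating noise.
#' @param clinical_covariates optional named list; each element is
#'   `c(mean, sd)` of a Gaussian clinical score simulated per subject.
#' @return an object of class `agent_profile`.
#' @export
agent_profile <- function(policy = c("observer_coupled", "fixed_alpha",
                                     "smallpe_boosted"),
                          base_gain = 1, smallpe_boost = 0,
                          smallpe_threshold = 10, motor_noise_sd = 0.5,
                          motor_noise_weber = 0.15,
                          confidence_gain = 80, confidence_offset = 10,
                          confidence_noise_sd = 10,
                          clinical_covariates = NULL) {
  policy <- match.arg(policy)
  stopifnot(base_gain >= 0, motor_noise_sd >= 0, motor_noise_weber >= 0,
            confidence_noise_sd >= 0, smallpe_threshold >= 0)
  structure(list(policy = policy, base_gain = base_gain,
                 smallpe_boost = smallpe_boost,
                 smallpe_threshold = smallpe_threshold,
                 motor_noise_sd = motor_noise_sd,
                 motor_noise_weber = motor_noise_weber,
                 confidence_gain = confidence_gain,
                 confidence_offset = confidence_offset,
                 confidence_noise_sd = confidence_noise_sd,
                 clinical_covariates = clinical_covariates),
            class = "agent_profile")
}

#' Preset agent profiles for the default synthetic cohort
#'
#' Four documented presets emulating the qualitative group phenotypes the
#' pipeline is designed to detect: controls track the normative observer;
#' the patient presets add a learning-rate boost after small prediction
#' errors (strong for unmedicated, weak for medicated patients), with
#' identical confidence policies in all groups so that confidence is a true
#' null. Each preset carries a simulated trait-anxiety covariate (patients
#' elevated).
#'
#' @return named list of [agent_profile()] objects: `CTL`, `OCD`,
#'   `MED_MINUS`, `MED_PLUS`.
#' @export
preset_profiles <- function() {
  conf <- list(confidence_gain = 80, confidence_offset = 10,
               confidence_noise_sd = 10)
  mk <- function(boost, anx_mean) {
    do.call(agent_profile, c(list(
      policy = if (boost > 0) "smallpe_boosted" else "observer_coupled",
      base_gain = 1, smallpe_boost = boost, smallpe_threshold = 10,
      motor_noise_sd = 0.5, motor_noise_weber = 0.15,
      clinical_covariates = list(anxiety = c(anx_mean, 8))), conf))
  }
  list(CTL = mk(0, 40), OCD = mk(0.6, 55),
       MED_MINUS = mk(0.8, 56), MED_PLUS = mk(0.15, 53))
}

#' Simulate one agent on a session
#'
#' The agent starts each block with its bucket on the block's first outcome
#' (mirroring the observer's belief initialisation; the first trial's
#' prediction error is therefore 0 and is excluded downstream as a zero-PE
#' trial). On every trial it observes the outcome, updates an internal
#' reduced-observer state on its own prediction error, and moves the bucket
#' by `alpha_eff * delta` plus signal-dependent motor noise (SD
#' `motor_noise_sd + motor_noise_weber * |update|`), where `alpha_eff`
#' follows the profile's policy, clipped at 0. Confidence is the mapped,
#' noisy model
#' confidence; hits and points follow the task's scoring rule.
#'
#' @param profile an [agent_profile()].
#' @param session a session from [generate_session()].
#' @param config the [task_config()] used to score trials.
#' @param observer_cfg an [observer_config()] for the agent's internal
#'   model; defaults to the task's true parameters.
#' @param seed integer seed for motor and confidence noise.
#' @return data frame of trial records: `block`, `trial`, `latent_mean`,
#'   `changepoint`, `outcome`, `bucket`, `confidence`, `hit`, `points`.
#' @export
simulate_agent <- function(profile, session, config = task_config(),
                           observer_cfg = NULL, seed = 1L) {
  stopifnot(inherits(profile, "agent_profile"))
  if (is.null(observer_cfg)) {
    observer_cfg <- observer_config(hazard = config$hazard,
                                    noise_var = config$noise_sd^2,
                                    n_positions = config$n_positions)
  }
  withr::with_seed(as.integer(seed), {
    parts <- lapply(split(session, session$block), function(bl) {
      n <- nrow(bl)
      bucket <- numeric(n)
      conf <- integer(n)
      state <- list(belief = bl$outcome[1],
                    mean_uncertainty = observer_cfg$initial_uncertainty)
      b <- bl$outcome[1]
      motor_z <- stats::rnorm(n)   # scaled per trial by the noise model
      cnoise <- if (profile$confidence_noise_sd > 0) {
        stats::rnorm(n, 0, profile$confidence_noise_sd)
      } else rep(0, n)
      for (t in seq_len(n)) {
        bucket[t] <- b
        delta <- signed_diff(bl$outcome[t], b, observer_cfg$geometry)
        ru <- state$mean_uncertainty /
          (state$mean_uncertainty + observer_cfg$noise_var)
        cpp <- change_point_probability(delta, observer_cfg$noise_var,
                                        state$mean_uncertainty,
                                        observer_cfg)
        alpha_model <- cpp + (1 - cpp) * ru
        alpha_eff <- switch(profile$policy,
          fixed_alpha = profile$base_gain,
          observer_coupled = profile$base_gain * alpha_model,
          smallpe_boosted = profile$base_gain * alpha_model +
            if (abs(delta) < profile$smallpe_threshold)
              profile$smallpe_boost else 0)
        alpha_eff <- max(alpha_eff, 0)
        model_conf <- (1 - cpp) * (1 - ru)
        conf[t] <- as.integer(min(100, max(1, round(
          profile$confidence_offset +
            profile$confidence_gain * model_conf + cnoise[t]))))
        # advance the internal observer on the agent's own prediction error
        state <- update_belief_and_uncertainty(
          list(belief = b, mean_uncertainty = state$mean_uncertainty),
          bl$outcome[t], observer_cfg)["mean_uncertainty"]
        upd <- alpha_eff * delta
        noise_sd <- profile$motor_noise_sd +
          profile$motor_noise_weber * abs(upd)
        b <- b + upd + noise_sd * motor_z[t]
        if (observer_cfg$geometry == "circular") b <- wrap_angle(b)
      }
      sc <- score_trial(bl$outcome, bucket, config)
      cbind(bl, data.frame(bucket = bucket, confidence = conf,
                           hit = sc$hit, points = sc$points))
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  })
}

#' Cohort specification
#'
#' @param groups named list; each element is a list with fields `n`
#'   (subject count), `profile` (an [agent_profile()]) and optionally
#'   `medication` (a label stored in the metadata, default `"NONE"`).
#' @param task a [task_config()].
#' @param seed master integer seed; per-subject seeds are derived from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, task = task_config(), seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1,
            !anyDuplicated(names(groups)))
  n_total <- sum(vapply(groups, function(g) g$n, numeric(1)))
  if (n_total <= 0) stop("cohort must contain at least one subject")
  structure(list(groups = groups, task = task, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default two- or three-group cohort specification
#'
#' The default study-sized cohort: 46 controls and 27 patients. With
#' `medication_split = TRUE` the patient group is divided into 16
#' unmedicated (`MED-`, strong small-PE boost) and 11 medicated (`MED+`,
#' weak boost) subjects, all labelled `OCD` in the group column.
#'
#' @param medication_split logical; split patients by medication status.
#' @param task a [task_config()].
#' @param seed master seed.
#' @return a [cohort_spec()].
#' @export
default_cohort_spec <- function(medication_split = FALSE,
                                task = task_config(), seed = 1L) {
  p <- preset_profiles()
  groups <- if (medication_split) {
    list(CTL = list(n = 46, profile = p$CTL, medication = "NONE"),
         `OCD_MED-` = list(n = 16, profile = p$MED_MINUS,
                           medication = "MED-"),
         `OCD_MED+` = list(n = 11, profile = p$MED_PLUS,
                           medication = "MED+"))
  } else {
    list(CTL = list(n = 46, profile = p$CTL, medication = "NONE"),
         OCD = list(n = 27, profile = p$OCD, medication = "NONE"))
  }
  cohort_spec(groups, task = task, seed = seed)
}

#' Simulate a cohort of agents
#'
#' Generates an independent session and agent simulation per subject, with
#' per-subject seeds drawn deterministically from the master seed, and
#' returns the canonical trial-log and subject-metadata tables consumed by
#' the analysis pipeline.
#'
#' @param spec a [cohort_spec()].
#' @return list with `trials` (one row per subject x trial) and `metadata`
#'   (one row per subject: `subject_id`, `group`, `medication`, plus any
#'   simulated clinical covariates).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  counts <- vapply(spec$groups, function(g) as.integer(g$n), integer(1))
  n_total <- sum(counts)
  seeds <- withr::with_seed(spec$seed,
                            sample.int(.Machine$integer.max - 1L, n_total))
  cov_names <- unique(unlist(lapply(spec$groups, function(g)
    names(g$profile$clinical_covariates))))
  trial_parts <- vector("list", n_total)
  meta_parts <- vector("list", n_total)
  i <- 0L
  for (gname in names(spec$groups)) {
    g <- spec$groups[[gname]]
    med <- if (is.null(g$medication)) "NONE" else g$medication
    for (k in seq_len(g$n)) {
      i <- i + 1L
      sid <- sprintf("S%03d", i)
      session <- generate_session(spec$task, seed = seeds[i])
      rec <- simulate_agent(g$profile, session, spec$task,
                            seed = seeds[i] %% 2147483546L + 1L)
      rec <- cbind(data.frame(subject_id = sid, group = gname,
                              medication = med), rec)
      trial_parts[[i]] <- rec
      covs <- withr::with_seed(seeds[i] %% 2147483046L + 7L, {
        out <- lapply(cov_names, function(nm) {
          spec_c <- g$profile$clinical_covariates[[nm]]
          if (is.null(spec_c)) NA_real_
          else stats::rnorm(1, spec_c[1], spec_c[2])
        })
        names(out) <- cov_names
        out
      })
      meta_parts[[i]] <- cbind(data.frame(subject_id = sid, group = gname,
                                          medication = med),
                               as.data.frame(covs))
    }
  }
  trials <- do.call(rbind, trial_parts)
  metadata <- do.call(rbind, meta_parts)
  rownames(trials) <- rownames(metadata) <- NULL
  list(trials = trials, metadata = metadata)
}
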