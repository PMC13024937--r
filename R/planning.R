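# Sample-based planning: draw K candidate action sequences, roll each out
# through the unscented predictor, score by Monte-Carlo Expected Free Energy,
# select the minimiser.

#' Action prior specification
#'
#' Actions within a plan are i.i.d. zero-mean Gaussian accelerations.
#'
#' @param mean,sd prior mean and standard deviation (internal units / s^2).
#' @return named list.
#' @export
action_prior <- function(mean = 0, sd = 20) {
  stopifnot(is.finite(mean), sd >= 0)
  list(mean = mean, sd = sd)
}

#' Preference specification
#'
#' The preference distribution over observations factorises into a Bernoulli
#' preference for observing the cursor inside the target and a Gaussian
#' preference for cursor-position observations near the believed target
#' centre.
#'
#' @param p_in probability the agent prefers to assign to observing the
#'   in-target flag.
#' @param sd_px sd of the Gaussian position preference, display px.
#' @param log_floor lower bound applied to log-preference densities. A guard
#'   against numerical underflow of the density only; it must sit below the
#'   log-density at the largest plausible cursor-target distance, otherwise
#'   it flattens the preference landscape far from the target.
#' @param scale_factor display px per internal unit.
#' @return named list (sd stored on the internal scale).
#' @export
preference <- function(p_in = 0.98, sd_px = 50, log_floor = -1000,
                       scale_factor = 1000) {
  stopifnot(p_in > 0, p_in < 1, sd_px > 0)
  list(p_in = p_in, sd = sd_px / scale_factor, log_floor = log_floor)
}

#' Sample candidate plans from the action prior
#'
#' @param prior an [action_prior()].
#' @param K number of plans (>= 1).
#' @param N horizon in steps (>= 1).
#' @return K x N numeric matrix, one plan per row. Uses R's RNG stream.
#' @export
sample_plans <- function(prior, K, N) {
  if (K < 1 || N < 1) stop("K and N must be at least 1")
  matrix(prior$mean + prior$sd * rnorm(K * N), nrow = K, ncol = N)
}

#' Roll a plan out through the unscented predictor
#'
#' Iterated [ukf_predict()] with no observation updates: the sequence of
#' predicted beliefs the agent commits to when it adopts a plan.
#'
#' @param start an `mf_belief`.
#' @param plan numeric vector of actions.
#' @param gm an `iaif_gm`.
#' @return list of predicted `mf_belief`s, one per step.
#' @export
rollout_plan <- function(start, plan, gm) {
  cu <- start$cursor
  mat <- .cpp_rollout_cursor(cu$mean,
                             c(cu$cov[1, 1], cu$cov[1, 2], cu$cov[2, 2]),
                             as.numeric(plan), gm$dt, gm$damping_mean,
                             gm$damping_var, gm$ukf$alpha, gm$ukf$beta,
                             gm$ukf$kappa)
  lapply(seq_len(nrow(mat)), function(i) {
    b <- start
    cov <- matrix(c(mat[i, 3], mat[i, 4], mat[i, 4], mat[i, 5]), 2, 2)
    ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < 0)) cov <- psd_clip(cov)
    b$cursor <- gaussian_belief(mat[i, 1:2], cov)
    b
  })
}

#' Hallucinate observations from a predicted belief
#'
#' Ancestral sampling: hidden state from the belief, then an observation
#' through the model's observation map with the model's noise. Uses R's RNG
#' stream.
#'
#' @param belief an `mf_belief` over a future state.
#' @param gm an `iaif_gm`.
#' @param m number of draws.
#' @return data.frame with columns `cursor_pos`, `target_pos`,
#'   `target_halfext`, `in_target`.
#' @export
hallucinate_observations <- function(belief, gm, m) {
  if (m < 1) stop("m must be at least 1")
  s1 <- belief$cursor$mean[1] + sqrt(max(belief$cursor$cov[1, 1], 0)) * rnorm(m)
  s3 <- belief$target_pos$mean + sqrt(max(belief$target_pos$cov[1], 0)) * rnorm(m)
  s4 <- belief$target_halfext$mean +
    sqrt(max(belief$target_halfext$cov[1], 0)) * rnorm(m)
  data.frame(
    cursor_pos = s1 + sqrt(gm$obs_noise_var[["cursor"]]) * rnorm(m),
    target_pos = s3 + sqrt(gm$obs_noise_var[["target_pos"]]) * rnorm(m),
    target_halfext = s4 + sqrt(gm$obs_noise_var[["target_halfext"]]) * rnorm(m),
    in_target = as.integer(abs(s1 - s3) <= s4))
}

# Log preference density of hallucinated observations.
log_preference <- function(obs, pref, pref_center) {
  lp <- ifelse(obs$in_target == 1L, log(pref$p_in), log(1 - pref$p_in)) +
    dnorm(obs$cursor_pos, pref_center, pref$sd, log = TRUE)
  pmax(lp, pref$log_floor)
}

#' Pragmatic value of a predicted belief (Monte-Carlo)
#'
#' Negative expected log preference density of hallucinated observations;
#' lower is better. The position preference is centred on the agent's
#' believed target position at planning time (`pref_center`).
#'
#' @param pred predicted `mf_belief`.
#' @param pref a [preference()].
#' @param gm an `iaif_gm`.
#' @param m Monte-Carlo sample count.
#' @param pref_center centre of the position preference (internal scale);
#'   defaults to the predicted belief's target-position mean.
#' @return scalar estimate. Uses R's RNG stream.
#' @export
pragmatic_value <- function(pred, pref, gm, m = 32,
                            pref_center = pred$target_pos$mean) {
  obs <- hallucinate_observations(pred, gm, m)
  -mean(log_preference(obs, pref, pref_center))
}

#' Expected information gain of a predicted belief (Monte-Carlo)
#'
#' Mean Kullback-Leibler divergence between the belief updated on a
#' hallucinated observation and the predicted belief. Excluded from the EFE
#' by default (`use_info_gain = FALSE` in [agent_config()]): on this task it
#' was not observed to change behaviour and it dominates planning cost.
#'
#' @inheritParams pragmatic_value
#' @param lr learning rates used for the hallucinated update.
#' @return non-negative scalar estimate. Uses R's RNG stream.
#' @export
information_gain <- function(pred, gm, m = 32, lr = learning_rates()) {
  obs <- hallucinate_observations(pred, gm, m)
  kls <- vapply(seq_len(m), function(i) {
    o <- structure(as.list(obs[i, ]), class = "iaif_obs")
    upd <- vi_update(pred, o, gm, lr)
    gaussian_kl(upd$cursor, pred$cursor) +
      gaussian_kl(upd$target_pos, pred$target_pos) +
      gaussian_kl(upd$target_halfext, pred$target_halfext)
  }, numeric(1))
  mean(kls)
}

#' Evaluate one plan (reference implementation)
#'
#' Rolls the plan out and scores the step-wise Expected Free Energy at each
#' predicted belief; the plan's EFE is the arithmetic mean of the step-wise
#' values. This R path is the readable reference; [select_plan()] uses the
#' compiled engine with replayable per-(plan, step) streams.
#'
#' @param start an `mf_belief`.
#' @param plan numeric action vector.
#' @param gm an `iaif_gm`.
#' @param pref a [preference()].
#' @param m Monte-Carlo samples per step.
#' @param use_info_gain include the information-gain term.
#' @param lr learning rates for hallucinated updates (information gain only).
#' @return list with `stepwise_efe`, `mean_efe`, `predicted_beliefs`.
#' @export
evaluate_plan <- function(start, plan, gm, pref, m = 32,
                          use_info_gain = FALSE, lr = learning_rates()) {
  beliefs <- rollout_plan(start, plan, gm)
  pref_center <- start$target_pos$mean
  step <- vapply(beliefs, function(b) {
    g <- pragmatic_value(b, pref, gm, m, pref_center)
    if (use_info_gain) g <- g - information_gain(b, gm, m, lr)
    g
  }, numeric(1))
  list(stepwise_efe = step, mean_efe = mean(step), predicted_beliefs = beliefs)
}

# Compiled evaluation of a matrix of plans with per-(plan, step) streams.
eval_plans_engine <- function(start, plans, gm, pref, m, seed,
                              step_offset = 0L, plan_offset = 0L,
                              pref_center = start$target_pos$mean) {
  cu <- start$cursor
  .cpp_eval_plans(plans, cu$mean,
                  c(cu$cov[1, 1], cu$cov[1, 2], cu$cov[2, 2]),
                  start$target_pos$mean, start$target_pos$cov[1],
                  start$target_halfext$mean, start$target_halfext$cov[1],
                  gm$dt, gm$damping_mean, gm$damping_var,
                  gm$ukf$alpha, gm$ukf$beta, gm$ukf$kappa,
                  gm$obs_noise_var[["cursor"]],
                  pref_center, pref$sd^2,
                  log(pref$p_in), log(1 - pref$p_in), pref$log_floor,
                  as.integer(m), as.numeric(seed),
                  as.integer(step_offset), as.integer(plan_offset))
}

#' Sample, evaluate and select the minimum-EFE plan
#'
#' Draws K plans from the action prior, evaluates each with the compiled
#' Monte-Carlo engine, and returns the plan with the lowest mean EFE (ties
#' broken by lowest candidate index), together with its predicted-belief
#' sequence and step-wise EFEs — the references the re-planning triggers
#' compare against during execution.
#'
#' @param start an `mf_belief`.
#' @param gm an `iaif_gm`.
#' @param pref a [preference()].
#' @param K number of candidate plans.
#' @param N horizon.
#' @param m Monte-Carlo samples per rollout step.
#' @param prior an [action_prior()].
#' @param seed integer seed for this planning phase (plan sampling and all
#'   Monte-Carlo streams derive from it).
#' @param plans optional K x N matrix of externally supplied candidate plans
#'   (overrides sampling; used e.g. for exhaustive-enumeration checks).
#' @param use_info_gain include the information-gain term (uses the reference
#'   path; substantially slower).
#' @param lr learning rates, used only when `use_info_gain = TRUE`.
#' @return list of class `planning_result`: `plan`, `stepwise_efe`,
#'   `mean_efe`, `predicted_beliefs`, `chosen_index`, `n_candidates`,
#'   `phase_seed`, `all_mean_efe`.
#' @export
select_plan <- function(start, gm, pref, K, N, m = 32,
                        prior = action_prior(), seed = 1L,
                        use_info_gain = FALSE, lr = learning_rates(),
                        plans = NULL) {
  if (K < 1 || N < 1) stop("K and N must be at least 1")
  if (is.null(plans)) {
    set.seed(as.integer(seed %% .Machine$integer.max))
    plans <- sample_plans(prior, K, N)
  } else {
    plans <- as.matrix(plans)
    K <- nrow(plans); N <- ncol(plans)
  }
  if (use_info_gain) {
    evals <- lapply(seq_len(K), function(j)
      evaluate_plan(start, plans[j, ], gm, pref, m, TRUE, lr))
    mean_efe <- vapply(evals, `[[`, numeric(1), "mean_efe")
    j <- which.min(mean_efe)
    ev <- evals[[j]]
    stepwise <- ev$stepwise_efe
    beliefs <- ev$predicted_beliefs
  } else {
    res <- eval_plans_engine(start, plans, gm, pref, m, seed)
    mean_efe <- res$mean
    j <- which.min(mean_efe)
    stepwise <- res$stepwise[j, ]
    beliefs <- rollout_plan(start, plans[j, ], gm)
  }
  structure(list(plan = plans[j, ], stepwise_efe = stepwise,
                 mean_efe = mean_efe[j], predicted_beliefs = beliefs,
                 chosen_index = j, n_candidates = K, phase_seed = seed,
                 pref_center = start$target_pos$mean,
                 all_mean_efe = mean_efe),
            class = "planning_result")
}
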