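# The closed sensorimotor loop: act, predict, observe (delayed), infer,
# test triggers, re-plan when fired.

#' Agent configuration
#'
#' @param K candidate plans per planning phase.
#' @param N planning horizon in steps.
#' @param trigger a [trigger_config()].
#' @param prior an [action_prior()].
#' @param pref a [preference()].
#' @param m Monte-Carlo samples per rollout step.
#' @param lr per-block [learning_rates()].
#' @param damping_mean,damping_var the agent's Gaussian belief over the
#'   damping parameter (model uncertainty).
#' @param init list of initial-belief spreads (internal scale):
#'   `cursor_pos_sd`, `cursor_vel_sd`, `target_pos_sd` (large: the target can
#'   appear on either side at varying distance), `target_halfext_mean`,
#'   `target_halfext_sd`.
#' @param use_info_gain include the information-gain EFE term (off by
#'   default).
#' @param flip_prob label-flip probability of the binary-channel update.
#' @param delay_mode how the perceptual delay is book-kept. `"direct"`
#'   (default): the delayed observation is fused as if current — the simplest
#'   consistent bookkeeping; all compared agents share the same (small)
#'   backward bias during fast movements. `"lagged_fusion"`: a belief carried
#'   at the observation's emission time is updated with it and then
#'   re-predicted to the current step through the actions executed in between
#'   (the standard delayed-measurement filter; unbiased, but the re-predicted
#'   belief carries open-loop inflation that largely cancels in the
#'   divergence-trigger comparison).
#' @param ukf sigma-point parameters.
#' @return an object of class `iaif_agent_config`.
#' @export
agent_config <- function(K = 1000, N = 12, trigger = trigger_config(),
                         prior = action_prior(), pref = preference(),
                         m = 32, lr = learning_rates(),
                         damping_mean = 10, damping_var = 1,
                         init = list(cursor_pos_sd = 0.005,
                                     cursor_vel_sd = 0.01,
                                     target_pos_sd = 0.5,
                                     target_halfext_mean = 0.08,
                                     target_halfext_sd = 0.03),
                         use_info_gain = FALSE, flip_prob = 0.1,
                         delay_mode = c("direct", "lagged_fusion"),
                         ukf = ukf_params()) {
  stopifnot(K >= 1, N >= 1, m >= 1)
  delay_mode <- match.arg(delay_mode)
  structure(list(K = as.integer(K), N = as.integer(N), trigger = trigger,
                 prior = prior, pref = pref, m = as.integer(m), lr = lr,
                 damping_mean = damping_mean, damping_var = damping_var,
                 init = init, use_info_gain = use_info_gain,
                 flip_prob = flip_prob, delay_mode = delay_mode,
                 ukf = ukf),
            class = "iaif_agent_config")
}

#' Initial mean-field belief
#'
#' Cursor centred at the true start with small uncertainty; target position
#' centred at the start with large uncertainty (it could appear on either
#' side at varying distance); broad half-extent prior.
#'
#' @param agent_cfg an [agent_config()].
#' @param env_cfg an [iaif_env_config()] (supplies the assumed observation
#'   noise).
#' @return an `mf_belief`.
#' @export
make_initial_belief <- function(agent_cfg, env_cfg) {
  init <- agent_cfg$init
  mf_belief(
    cursor = gaussian_belief(c(0, 0), diag(c(init$cursor_pos_sd^2,
                                             init$cursor_vel_sd^2))),
    target_pos = gaussian_belief(0, init$target_pos_sd^2),
    target_halfext = gaussian_belief(init$target_halfext_mean,
                                     init$target_halfext_sd^2),
    damping = gaussian_belief(agent_cfg$damping_mean, agent_cfg$damping_var),
    obs_noise_var = env_cfg$obs_noise_sd^2)
}

# The generative model implied by an agent + environment configuration.
make_gm <- function(agent_cfg, env_cfg) {
  iaif_gm(dt = env_cfg$dt, damping_mean = agent_cfg$damping_mean,
          damping_var = agent_cfg$damping_var,
          obs_noise_var = env_cfg$obs_noise_sd^2, ukf = agent_cfg$ukf)
}

# Deterministic derivation of per-(stream, step) seeds from the master seed.
# Streams: 1 = environment noise, 2 = planning phases, 3 = EFE re-scoring.
# Kept below 2^31 - 1; multipliers small enough for exact double arithmetic.
mix_seed <- function(master, stream, step) {
  ((master %% 2147483647) * 69069 + stream * 1000003 + step * 97) %% 2147483647 + 1
}

#' Predict then (optionally) update the belief
#'
#' Composition of the unscented prediction through the executed action and,
#' when an observation is available, the variational update.
#'
#' @param belief an `mf_belief`.
#' @param action executed scalar control.
#' @param obs an `iaif_obs` or `NULL`.
#' @param gm an `iaif_gm`.
#' @param lr learning rates.
#' @param flip_prob binary-channel flip probability.
#' @return the new `mf_belief`.
#' @export
predict_then_update <- function(belief, action, obs, gm,
                                lr = learning_rates(), flip_prob = 0.1) {
  b <- ukf_predict(belief, action, gm)
  vi_update(b, obs, gm, lr, flip_prob)
}

#' Run one closed-loop trial
#'
#' Executes the full sensorimotor loop for `env_cfg$n_steps` steps: a
#' mandatory initial planning phase, then per step: apply the next plan
#' action to the environment, predict the belief through it, receive the
#' delayed observation and update, and test the configured re-planning
#' trigger(s) (exhaustion first). A fired trigger causes re-planning at the
#' start of the next step, from the then-current belief; planning is
#' instantaneous in model time. Fully reproducible given `seed`.
#'
#' @param env_cfg an [iaif_env_config()].
#' @param agent_cfg an [agent_config()].
#' @param target one row of [make_target_layout()].
#' @param seed master integer seed. Environment noise, plan sampling and all
#'   Monte-Carlo streams derive from it through documented sub-streams, so
#'   agents with different trigger settings share the same environment noise
#'   under the same master seed.
#' @return an object of class `iaif_trial`: `log` (one row per step),
#'   `planning` (one row per planning phase), `env_cfg`, `agent_cfg`,
#'   `target`, `seed`, `compute_units`.
#' @export
run_trial <- function(env_cfg, agent_cfg, target, seed = 1L) {
  gm <- make_gm(agent_cfg, env_cfg)
  belief <- make_initial_belief(agent_cfg, env_cfg)
  state <- env_init(target, env_cfg)
  n <- env_cfg$n_steps
  N <- agent_cfg$N
  sf <- env_cfg$scale_factor
  trig <- agent_cfg$trigger

  buffer <- list()
  exec <- NULL
  pending <- TRUE  # initial planning phase is mandatory
  compute_units <- 0L
  log <- vector("list", n)
  planning <- list()
  # delayed-measurement bookkeeping: belief at the emission time of the
  # newest fused observation, plus the actions executed since
  lag_belief <- belief
  actions_hist <- numeric(n)

  for (t in seq_len(n)) {
    planned_now <- FALSE
    if (pending) {
      pr <- select_plan(belief, gm, agent_cfg$pref, agent_cfg$K, N,
                        agent_cfg$m, agent_cfg$prior,
                        seed = mix_seed(seed, 2, t),
                        use_info_gain = agent_cfg$use_info_gain,
                        lr = agent_cfg$lr)
      exec <- list(plan = pr$plan, stepwise_efe = pr$stepwise_efe,
                   predicted_beliefs = pr$predicted_beliefs,
                   exec_index = 0L, chosen_index = pr$chosen_index,
                   phase_seed = pr$phase_seed, pref_center = pr$pref_center)
      compute_units <- compute_units + agent_cfg$K * N
      planned_now <- TRUE
      planning[[length(planning) + 1L]] <- data.frame(
        step = t, K = agent_cfg$K, chosen_index = pr$chosen_index,
        mean_efe = pr$mean_efe,
        efe_q25 = unname(stats::quantile(pr$all_mean_efe, 0.25)),
        efe_q75 = unname(stats::quantile(pr$all_mean_efe, 0.75)))
      pending <- FALSE
    }

    k <- exec$exec_index + 1L
    action <- exec$plan[k]
    state <- step_env(state, action, env_cfg$dt)
    exec$exec_index <- k
    actions_hist[t] <- action

    set.seed(mix_seed(seed, 1, t))
    raw_obs <- emit_observation(state, env_cfg$obs_noise_sd)
    rel <- delayed_observation(buffer, raw_obs, env_cfg$delay_steps)
    buffer <- rel$buffer
    obs <- rel$obs

    if (agent_cfg$delay_mode == "lagged_fusion") {
      if (!is.null(obs)) {
        # fuse at emission time t - delay, then re-predict to now
        t_emit <- obs$emitted_at
        lag_belief <- vi_update(ukf_predict(lag_belief, actions_hist[t_emit], gm),
                                obs, gm, agent_cfg$lr, agent_cfg$flip_prob)
        belief <- lag_belief
        for (i in seq_len(t - t_emit))
          belief <- ukf_predict(belief, actions_hist[t_emit + i], gm)
      } else {
        belief <- ukf_predict(belief, action, gm)
      }
    } else {
      belief <- predict_then_update(belief, action, obs, gm, agent_cfg$lr,
                                    agent_cfg$flip_prob)
    }

    # exhaustion first; the configured trigger(s) only once observations flow
    dec <- exhaustion_check(exec)
    if (!dec$fired) {
      if (trig$mode == "classic") {
        dec <- trigger_decision(TRUE, "classic")
      } else if (!is.null(obs)) {
        dec <- combined_trigger(exec, belief,
                                exec$predicted_beliefs[[k]], trig, gm,
                                agent_cfg$pref, agent_cfg$m,
                                seed = mix_seed(seed, 3, t))
        if (!is.na(dec$efe_updated))
          compute_units <- compute_units + (N - k)
      }
    }
    pending <- dec$fired

    log[[t]] <- data.frame(
      t = t, time_s = t * env_cfg$dt, action = action,
      s1_px = state$cursor_pos * sf, s2_px = state$cursor_vel * sf,
      s3_px = state$target_pos * sf, s4_px = state$target_halfext * sf,
      o1_px = obs_or_na(obs, "cursor_pos") * sf,
      o3_px = obs_or_na(obs, "target_pos") * sf,
      o4_px = obs_or_na(obs, "target_halfext") * sf,
      o_flag = if (is.null(obs)) NA_integer_ else obs$in_target,
      in_target = in_target(state$cursor_pos, state$target_pos,
                            state$target_halfext),
      bel_pos_px = belief$cursor$mean[1] * sf,
      bel_pos_sd_px = sqrt(max(belief$cursor$cov[1, 1], 0)) * sf,
      bel_vel_px = belief$cursor$mean[2] * sf,
      bel_tpos_px = belief$target_pos$mean * sf,
      bel_tpos_sd_px = sqrt(max(belief$target_pos$cov[1], 0)) * sf,
      bel_thalf_px = belief$target_halfext$mean * sf,
      planned = planned_now, exec_index = k,
      trigger_cause = dec$cause, div_value = dec$div_value,
      efe_updated = dec$efe_updated, efe_planned = dec$efe_planned)
  }

  structure(list(log = do.call(rbind, log),
                 planning = do.call(rbind, planning),
                 env_cfg = env_cfg, agent_cfg = agent_cfg,
                 target = as.list(target), seed = seed,
                 compute_units = compute_units),
            class = "iaif_trial")
}

obs_or_na <- function(obs, field) {
  if (is.null(obs)) NA_real_ else obs[[field]]
}

#' Run the continuously re-planning baseline
#'
#' Convenience wrapper: [run_trial()] with an always-firing trigger, i.e.
#' classic active inference that plans in every time step.
#'
#' @inheritParams run_trial
#' @return an `iaif_trial`.
#' @export
run_classic_baseline <- function(env_cfg, agent_cfg, target, seed = 1L) {
  agent_cfg$trigger <- trigger_config("classic")
  run_trial(env_cfg, agent_cfg, target, seed)
}
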