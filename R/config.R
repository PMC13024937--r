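# Structured config file support for the command-line entry points.

#' Default configuration as a nested list
#'
#' Mirrors the YAML config schema: `environment` (dt, n_steps, delay_ms,
#' widths_px, distances_px, obs_noise_sd_px, damping, scale_factor),
#' `agent` (k, horizon, mode, eps_div, eps_efe, action_prior_sd,
#' preference_sd_px, preference_p_in, mc_samples, learning rates,
#' damping belief, initial-belief spreads) and `experiment`
#' (n_reps, master_seed).
#'
#' @return nested list.
#' @export
default_config <- function() {
  list(
    environment = list(dt = 0.02, n_steps = 100, delay_ms = 100,
                       widths_px = c(100, 60),
                       distances_px = c(450, 750, 1070),
                       width_is_half_extent = TRUE,
                       obs_noise_sd_px = list(cursor = 10, target_pos = 10,
                                              target_halfext = 5),
                       damping = 10, scale_factor = 1000),
    agent = list(k = 1000, horizon = 12, mode = "combined", eps_div = 50,
                 eps_efe = 0, efe_relative = FALSE, action_prior_sd = 20,
                 preference_sd_px = 50, preference_p_in = 0.98,
                 mc_samples = 32,
                 lr = list(cursor = 0.5, target_pos = 1, target_halfext = 0.5),
                 damping_mean = 10, damping_var = 1,
                 use_info_gain = FALSE),
    experiment = list(n_reps = 10, master_seed = 1))
}

#' Load a YAML config file, filling unset keys with defaults
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return nested config list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_lists(cfg, user)
}

merge_lists <- function(base, upd) {
  for (nm in names(upd)) {
    if (is.list(base[[nm]]) && is.list(upd[[nm]]))
      base[[nm]] <- merge_lists(base[[nm]], upd[[nm]])
    else base[[nm]] <- upd[[nm]]
  }
  base
}

#' Build runtime objects from a config list
#'
#' @param cfg nested list as from [load_config()].
#' @return list with `env_cfg`, `agent_cfg`, `layout`, `experiment`.
#' @export
build_from_config <- function(cfg = default_config()) {
  e <- cfg$environment
  env_cfg <- iaif_env_config(
    dt = e$dt, n_steps = e$n_steps, delay_s = e$delay_ms / 1000,
    damping = e$damping,
    obs_noise_sd_px = c(cursor = e$obs_noise_sd_px$cursor,
                        target_pos = e$obs_noise_sd_px$target_pos,
                        target_halfext = e$obs_noise_sd_px$target_halfext),
    scale_factor = e$scale_factor)
  layout <- make_target_layout(e$widths_px, e$distances_px,
                               e$width_is_half_extent)
  a <- cfg$agent
  agent_cfg <- agent_config(
    K = a$k, N = a$horizon,
    trigger = trigger_config(a$mode, eps_div = a$eps_div,
                             eps_efe = a$eps_efe,
                             efe_relative = isTRUE(a$efe_relative)),
    prior = action_prior(sd = a$action_prior_sd),
    pref = preference(p_in = a$preference_p_in, sd_px = a$preference_sd_px,
                      scale_factor = e$scale_factor),
    m = a$mc_samples,
    lr = learning_rates(a$lr$cursor, a$lr$target_pos, a$lr$target_halfext),
    damping_mean = a$damping_mean, damping_var = a$damping_var,
    use_info_gain = isTRUE(a$use_info_gain))
  list(env_cfg = env_cfg, agent_cfg = agent_cfg, layout = layout,
       experiment = cfg$experiment)
}
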