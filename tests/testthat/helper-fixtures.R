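# Shared fixtures: small, fast configurations used across test files.

fast_env <- function(n_steps = 100, delay_s = 0.1, noise = c(10, 10, 5)) {
  iaif_env_config(n_steps = n_steps, delay_s = delay_s,
                  obs_noise_sd_px = c(cursor = noise[1], target_pos = noise[2],
                                      target_halfext = noise[3]))
}

fast_agent <- function(mode = "efe", K = 20, N = 12, eps_div = 50, ...) {
  agent_config(K = K, N = N,
               trigger = trigger_config(mode, eps_div = eps_div), ...)
}

wide_target <- function(idx = 0) {
  lay <- make_target_layout()
  lay[lay$index == idx, ]
}

# A mildly informative mean-field belief used as a generic starting point.
test_belief <- function(pos = 0, vel = 0, tpos = 0.4, tpos_var = 1e-3,
                        twid = 0.1, twid_var = 1e-4) {
  mf_belief(
    cursor = gaussian_belief(c(pos, vel), diag(c(1e-4, 1e-4))),
    target_pos = gaussian_belief(tpos, tpos_var),
    target_halfext = gaussian_belief(twid, twid_var),
    damping = gaussian_belief(10, 1),
    obs_noise_var = c(cursor = 1e-4, target_pos = 1e-4, target_halfext = 2.5e-5))
}

# Deterministic closed-form pragmatic value for a degenerate belief (zero
# state covariance, zero observation noise): the Monte-Carlo estimate
# collapses onto the log preference at the predicted mean. Independent of
# the compiled engine.
det_pragmatic <- function(pos, tpos, twid, pref) {
  inside <- abs(pos - tpos) <= twid
  lp <- (if (inside) log(pref$p_in) else log(1 - pref$p_in)) +
    dnorm(pos, tpos, pref$sd, log = TRUE)
  -max(lp, pref$log_floor)
}

# Euler simulation of the cursor: the deterministic oracle for rollouts.
euler_traj <- function(pos, vel, actions, d, dt) {
  out <- matrix(NA_real_, length(actions), 2)
  for (i in seq_along(actions)) {
    pos <- pos + dt * vel
    vel <- vel + dt * (-d * vel + actions[i])
    out[i, ] <- c(pos, vel)
  }
  out
}
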