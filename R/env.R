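# Generative process: cursor dynamics, target layout, noisy delayed channel.
#
# Positions and velocities are kept on an internal scale (display px divided
# by `scale_factor`, default 1000) for numerical conditioning; conversions are
# exact multiplications.

#' Environment configuration
#'
#' @param dt step duration in seconds.
#' @param n_steps trial length in steps.
#' @param delay_s perceptual delay in seconds; rounded to whole steps.
#' @param damping damping coefficient of the second-order lag (1/s).
#' @param obs_noise_sd_px named numeric vector of observation-noise standard
#'   deviations, display px, for the continuous channels
#'   (`cursor`, `target_pos`, `target_halfext`). The in-target flag is binary
#'   and transmitted without additive noise.
#' @param scale_factor display px per internal unit.
#' @return an object of class `iaif_env_config`.
#' @export
iaif_env_config <- function(dt = 0.02, n_steps = 100, delay_s = 0.1,
                            damping = 10,
                            obs_noise_sd_px = c(cursor = 10, target_pos = 10,
                                                target_halfext = 5),
                            scale_factor = 1000) {
  stopifnot(dt > 0, n_steps >= 1, delay_s >= 0, damping > 0, scale_factor > 0)
  obs_noise_sd_px <- obs_noise_sd_px[c("cursor", "target_pos", "target_halfext")]
  if (any(is.na(obs_noise_sd_px)) || any(obs_noise_sd_px < 0))
    stop("obs_noise_sd_px needs non-negative 'cursor', 'target_pos', 'target_halfext'")
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 delay_steps = as.integer(round(delay_s / dt)),
                 damping = damping,
                 obs_noise_sd = obs_noise_sd_px / scale_factor,
                 scale_factor = scale_factor),
            class = "iaif_env_config")
}

#' Convert between display pixels and the internal scale
#'
#' @param x numeric values.
#' @param scale_factor display px per internal unit.
#' @return converted values.
#' @export
px_to_internal <- function(x, scale_factor = 1000) x / scale_factor

#' @rdname px_to_internal
#' @export
internal_to_px <- function(x, scale_factor = 1000) x * scale_factor

#' Initial environment state
#'
#' The cursor starts at the origin with zero velocity; the hidden state also
#' carries the target centre and half-extent.
#'
#' @param target one row of [make_target_layout()] (or a list with
#'   `center_px` and `halfext_px`).
#' @param env an `iaif_env_config`.
#' @return an object of class `env_state` on the internal scale.
#' @export
env_init <- function(target, env = iaif_env_config()) {
  structure(list(cursor_pos = 0, cursor_vel = 0,
                 target_pos = target$center_px / env$scale_factor,
                 target_halfext = target$halfext_px / env$scale_factor,
                 damping = env$damping, time_index = 0L),
            class = "env_state")
}

#' Step the environment forward
#'
#' Deterministic forward-Euler update of the damped second-order lag with
#' zero stiffness: `pos' = pos + dt*vel`, `vel' = vel + dt*(-d*vel + a)`.
#' Target components are unchanged.
#'
#' @param state an `env_state`.
#' @param action scalar control (internal acceleration units).
#' @param dt step duration in seconds.
#' @return the updated `env_state`.
#' @export
step_env <- function(state, action, dt) {
  if (!is.finite(action)) stop("non-finite action")
  if (!all(is.finite(c(state$cursor_pos, state$cursor_vel)))) stop("non-finite state")
  if (dt <= 0) stop("dt must be positive")
  pos <- state$cursor_pos + dt * state$cursor_vel
  vel <- state$cursor_vel + dt * (-state$damping * state$cursor_vel + action)
  state$cursor_pos <- pos
  state$cursor_vel <- vel
  state$time_index <- state$time_index + 1L
  state
}

#' In-target indicator
#'
#' The cursor counts as inside the target when its distance to the target
#' centre does not exceed the half-extent.
#'
#' @param cursor_pos,target_pos,target_halfext numeric (same scale).
#' @return 0/1 integer vector.
#' @export
in_target <- function(cursor_pos, target_pos, target_halfext) {
  as.integer(abs(cursor_pos - target_pos) <= target_halfext)
}

#' Emit a noisy observation from the environment
#'
#' The observation map is `g(s) = (s1, s3, s4, c)`: cursor position, target
#' position, target half-extent, and the binary in-target flag. Independent
#' Gaussian noise is added to the continuous channels; the flag is computed
#' from the true state and transmitted noiselessly. Uses R's RNG stream.
#'
#' @param state an `env_state`.
#' @param obs_noise_sd named sds (internal scale) as in [iaif_env_config()].
#' @return a list of class `iaif_obs` with fields `cursor_pos`, `target_pos`,
#'   `target_halfext`, `in_target` and `emitted_at`.
#' @export
emit_observation <- function(state, obs_noise_sd) {
  noise <- rnorm(3L) * obs_noise_sd[c("cursor", "target_pos", "target_halfext")]
  structure(list(
    cursor_pos = state$cursor_pos + noise[[1]],
    target_pos = state$target_pos + noise[[2]],
    target_halfext = state$target_halfext + noise[[3]],
    in_target = in_target(state$cursor_pos, state$target_pos, state$target_halfext),
    emitted_at = state$time_index), class = "iaif_obs")
}

#' Delay buffer for observations
#'
#' Models the fixed perceptual delay: the agent at step t receives the
#' observation emitted `delay_steps` earlier (or nothing during the first
#' `delay_steps` steps).
#'
#' @param buffer list of previously pushed observations (emission order).
#' @param current the observation emitted this step.
#' @param delay_steps non-negative integer delay.
#' @return list with `obs` (the released observation or `NULL`) and `buffer`.
#' @export
delayed_observation <- function(buffer, current, delay_steps) {
  if (delay_steps < 0) stop("delay must be non-negative")
  buffer <- c(buffer, list(current))
  n <- length(buffer)
  if (n <= delay_steps) return(list(obs = NULL, buffer = buffer))
  list(obs = buffer[[n - delay_steps]], buffer = buffer[(n - delay_steps):n])
}

#' Build the pointing-task target layout
#'
#' Twelve targets: two printed widths times three distances, mirrored on both
#' sides of the start position. Indices 0-5 carry the first (wide) width,
#' 6-11 the second; within a width group targets are ordered by distance then
#' side (negative first).
#'
#' @param widths_px two printed target widths (px).
#' @param distances_px three target distances from the start (px).
#' @param width_is_half_extent if `TRUE` (default) the printed width is taken
#'   as the half-extent `s4` directly; if `FALSE` as the full width
#'   (`s4 = width / 2`).
#' @return data.frame of class `target_layout` with columns `index`,
#'   `center_px`, `halfext_px`, `width_px`, `distance_px`, `id_bits`.
#' @export
make_target_layout <- function(widths_px = c(100, 60),
                               distances_px = c(450, 750, 1070),
                               width_is_half_extent = TRUE) {
  if (length(widths_px) != 2 || any(widths_px <= 0))
    stop("need two positive widths")
  if (length(distances_px) != 3 || any(distances_px <= 0))
    stop("need three positive distances")
  rows <- list()
  idx <- 0L
  for (w in widths_px) {
    for (d in sort(distances_px)) {
      for (side in c(-1, 1)) {
        rows[[length(rows) + 1L]] <- data.frame(
          index = idx, center_px = side * d,
          halfext_px = if (width_is_half_extent) w else w / 2,
          width_px = w, distance_px = d,
          id_bits = index_of_difficulty(d, w))
        idx <- idx + 1L
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("target_layout", class(out))
  out
}

#' Fitts-law index of difficulty
#'
#' Shannon form `log2(1 + D / W)` for distance `D` and printed target width
#' `W`.
#'
#' @param distance_px distance to the target centre (px), non-negative.
#' @param width_px printed target width (px), positive.
#' @return index of difficulty in bits.
#' @export
index_of_difficulty <- function(distance_px, width_px) {
  if (any(width_px <= 0)) stop("width must be positive")
  if (any(distance_px < 0)) stop("distance must be non-negative")
  log2(1 + distance_px / width_px)
}
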