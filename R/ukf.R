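# Unscented prediction of the mean-field belief through the generative model.

#' Sigma-point parameters for the unscented transform
#'
#' @param alpha,beta,kappa standard unscented-transform parameters.
#' @return a named list.
#' @export
ukf_params <- function(alpha = 1, beta = 2, kappa = 0) {
  stopifnot(alpha > 0)
  list(alpha = alpha, beta = beta, kappa = kappa)
}

#' Generative model specification
#'
#' The model family equals the generative process (damped second-order lag
#' plus the `g(s) = (s1, s3, s4, c)` observation map), with a Gaussian belief
#' over the damping parameter expressing model uncertainty.
#'
#' @param dt step duration (s).
#' @param damping_mean,damping_var prior belief over the damping parameter.
#' @param obs_noise_var named variances (internal scale) of the continuous
#'   observation channels assumed by the model.
#' @param ukf sigma-point parameters from [ukf_params()].
#' @return an object of class `iaif_gm`.
#' @export
iaif_gm <- function(dt = 0.02, damping_mean = 10, damping_var = 1,
                    obs_noise_var = c(cursor = 1e-4, target_pos = 1e-4,
                                      target_halfext = 2.5e-5),
                    ukf = ukf_params()) {
  stopifnot(dt > 0, damping_var >= 0)
  obs_noise_var <- obs_noise_var[c("cursor", "target_pos", "target_halfext")]
  if (any(is.na(obs_noise_var)) || any(obs_noise_var < 0))
    stop("obs_noise_var needs non-negative 'cursor', 'target_pos', 'target_halfext'")
  structure(list(dt = dt, damping_mean = damping_mean,
                 damping_var = damping_var, obs_noise_var = obs_noise_var,
                 ukf = ukf), class = "iaif_gm")
}

#' Predict the belief through an action (unscented Kalman prediction)
#'
#' Propagates the cursor block through the model dynamics by the unscented
#' transform, with the uncertain damping parameter appended as an extra sigma
#' dimension so that parameter uncertainty inflates the predicted state
#' covariance. Target, parameter and noise factors pass through unchanged
#' (their dynamics are the identity). The predicted covariance is
#' re-symmetrised and clipped to the PSD cone if numerically indefinite.
#'
#' @param belief an `mf_belief`.
#' @param action scalar control.
#' @param gm an `iaif_gm`.
#' @return the predicted `mf_belief`.
#' @export
ukf_predict <- function(belief, action, gm) {
  if (!is.finite(action)) stop("non-finite action")
  cu <- belief$cursor
  out <- .cpp_ukf_cursor(cu$mean,
                         c(cu$cov[1, 1], cu$cov[1, 2], cu$cov[2, 2]),
                         action, gm$dt, gm$damping_mean, gm$damping_var,
                         gm$ukf$alpha, gm$ukf$beta, gm$ukf$kappa)
  cov <- matrix(c(out[3], out[4], out[4], out[5]), 2, 2)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < 0)) cov <- psd_clip(cov)  # repair indefinite output
  belief$cursor <- gaussian_belief(out[1:2], cov)
  belief
}
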