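# Gaussian and mean-field beliefs, and the divergence between them.

#' Construct a Gaussian belief
#'
#' A Gaussian belief is a mean vector and a covariance matrix. The covariance
#' is re-symmetrised on construction and checked to be positive semi-definite
#' up to a tolerance; eigenvalues below `-tol` are an error, eigenvalues in
#' `(-tol, 0)` are clipped to zero.
#'
#' @param mean numeric vector.
#' @param cov numeric matrix (or scalar for a univariate belief).
#' @param tol PSD tolerance.
#' @return an object of class `gaussian_belief` with elements `mean`, `cov`.
#' @export
gaussian_belief <- function(mean, cov, tol = 1e-8) {
  mean <- as.numeric(mean)
  if (!all(is.finite(mean))) stop("belief mean must be finite")
  cov <- as.matrix(cov)
  if (nrow(cov) != length(mean) || ncol(cov) != length(mean))
    stop("covariance dimensions do not match the mean")
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -tol)) stop("covariance is not positive semi-definite")
  if (any(ev < 0)) cov <- psd_clip(cov)
  structure(list(mean = mean, cov = cov), class = "gaussian_belief")
}

# Clip negative eigenvalues to zero and re-symmetrise.
psd_clip <- function(cov) {
  e <- eigen(cov, symmetric = TRUE)
  v <- pmax(e$values, 0)
  cov <- e$vectors %*% (v * t(e$vectors))
  (cov + t(cov)) / 2
}

# Invert a covariance with a small jitter on the diagonal (internal scale).
cov_solve <- function(cov, jitter = 1e-9) {
  solve(cov + diag(jitter, nrow(cov)))
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat("Gaussian belief, dim", length(x$mean), "\n")
  cat("  mean:", signif(x$mean, 4), "\n")
  cat("  sd:  ", signif(sqrt(pmax(diag(x$cov), 0)), 4), "\n")
  invisible(x)
}

#' Construct a mean-field belief for the pointing task
#'
#' The approximate posterior factorises over independent blocks: the cursor
#' block (position, velocity), the target position, the target half-extent,
#' the model parameter (damping), and the observation-noise covariance (held
#' fixed; noise learning is out of scope). All quantities are on the internal
#' scale (display px / 1000).
#'
#' @param cursor `gaussian_belief` of dimension 2 over (position, velocity).
#' @param target_pos univariate `gaussian_belief` over the target centre.
#' @param target_halfext univariate `gaussian_belief` over the target
#'   half-extent.
#' @param damping univariate `gaussian_belief` over the damping parameter.
#' @param obs_noise_var named numeric vector of observation-noise variances
#'   for the continuous channels (`cursor`, `target_pos`, `target_halfext`).
#' @return an object of class `mf_belief`.
#' @export
mf_belief <- function(cursor, target_pos, target_halfext, damping,
                      obs_noise_var) {
  stopifnot(inherits(cursor, "gaussian_belief"), length(cursor$mean) == 2,
            inherits(target_pos, "gaussian_belief"), length(target_pos$mean) == 1,
            inherits(target_halfext, "gaussian_belief"),
            length(target_halfext$mean) == 1,
            inherits(damping, "gaussian_belief"), length(damping$mean) == 1)
  obs_noise_var <- obs_noise_var[c("cursor", "target_pos", "target_halfext")]
  if (any(is.na(obs_noise_var)) || any(obs_noise_var < 0))
    stop("obs_noise_var must contain non-negative 'cursor', 'target_pos', 'target_halfext'")
  structure(list(cursor = cursor, target_pos = target_pos,
                 target_halfext = target_halfext, damping = damping,
                 obs_noise_var = obs_noise_var),
            class = "mf_belief")
}

#' @export
print.mf_belief <- function(x, ...) {
  cat("Mean-field belief (internal scale):\n")
  cat(sprintf("  cursor pos %.4f (sd %.4f), vel %.4f (sd %.4f)\n",
              x$cursor$mean[1], sqrt(max(x$cursor$cov[1, 1], 0)),
              x$cursor$mean[2], sqrt(max(x$cursor$cov[2, 2], 0))))
  cat(sprintf("  target pos %.4f (sd %.4f), half-extent %.4f (sd %.4f)\n",
              x$target_pos$mean, sqrt(max(x$target_pos$cov[1], 0)),
              x$target_halfext$mean, sqrt(max(x$target_halfext$cov[1], 0))))
  cat(sprintf("  damping %.2f (sd %.3f)\n",
              x$damping$mean, sqrt(max(x$damping$cov[1], 0))))
  invisible(x)
}

# Closed-form KL(p || q) between Gaussians.
gaussian_kl <- function(p, q, jitter = 1e-9) {
  k <- length(p$mean)
  if (length(q$mean) != k) stop("belief dimensions do not match")
  qi <- cov_solve(q$cov, jitter)
  dm <- q$mean - p$mean
  ld <- determinant(q$cov + diag(jitter, k), logarithm = TRUE)$modulus -
    determinant(p$cov + diag(jitter, k), logarithm = TRUE)$modulus
  0.5 * (sum(diag(qi %*% p$cov)) + drop(t(dm) %*% qi %*% dm) - k + as.numeric(ld))
}

#' Symmetrised Kullback-Leibler divergence between Gaussian beliefs
#'
#' Computes `(KL(p || q) + KL(q || p)) / 2` in closed form. For mean-field
#' beliefs the divergences of the independent state blocks (cursor, target
#' position, target half-extent) are summed; parameter and noise factors are
#' excluded because acting on the system does not move them.
#'
#' @param p,q `gaussian_belief` or `mf_belief` objects.
#' @param jitter diagonal jitter used when inverting covariances.
#' @return non-negative scalar divergence.
#' @export
symmetrised_kl <- function(p, q, jitter = 1e-9) {
  if (inherits(p, "mf_belief") && inherits(q, "mf_belief")) {
    return(symmetrised_kl(p$cursor, q$cursor, jitter) +
             symmetrised_kl(p$target_pos, q$target_pos, jitter) +
             symmetrised_kl(p$target_halfext, q$target_halfext, jitter))
  }
  0.5 * (gaussian_kl(p, q, jitter) + gaussian_kl(q, p, jitter))
}
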