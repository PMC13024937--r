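# Variational belief update from a (possibly delayed) observation.
#
# Each continuous observation channel is linear-Gaussian in exactly one
# mean-field block, so the per-block conjugate Gaussian posterior is
# available in closed form. The update blends prior and conjugate posterior
# in natural-parameter space by a per-block learning rate: lr = 1 reproduces
# exact conjugate Bayes, lr = 0 keeps the prior. The binary in-target flag
# has no Gaussian likelihood; it updates the target blocks through a
# likelihood-weighted sigma-point approximation (moment-matched back to a
# Gaussian), an acknowledged approximation.

#' Per-block learning rates
#'
#' The target-position block uses a higher rate because the belief about the
#' target must move quickly once the target is first observed.
#'
#' @param cursor,target_pos,target_halfext rates in `[0, 1]`.
#' @return named numeric vector.
#' @export
learning_rates <- function(cursor = 0.5, target_pos = 1, target_halfext = 0.5) {
  lr <- c(cursor = cursor, target_pos = target_pos,
          target_halfext = target_halfext)
  if (any(lr < 0 | lr > 1)) stop("learning rates must lie in [0, 1]")
  lr
}

# Conjugate Gaussian measurement update for y = H x + e, e ~ N(0, R),
# blended with the prior in natural-parameter space by lr.
blend_update <- function(mean, cov, H, y, R, lr, jitter = 1e-9) {
  H <- matrix(H, nrow = 1)
  S <- drop(H %*% cov %*% t(H)) + R
  K <- (cov %*% t(H)) / S
  post_mean <- mean + drop(K) * (y - drop(H %*% mean))
  post_cov <- cov - (K %*% H %*% cov)
  post_cov <- (post_cov + t(post_cov)) / 2
  if (lr >= 1) return(list(mean = post_mean, cov = post_cov))
  if (lr <= 0) return(list(mean = mean, cov = cov))
  Lp <- cov_solve(cov, jitter); Lq <- cov_solve(post_cov, jitter)
  Lb <- (1 - lr) * Lp + lr * Lq
  eb <- (1 - lr) * (Lp %*% mean) + lr * (Lq %*% post_mean)
  cb <- solve(Lb)
  cb <- (cb + t(cb)) / 2
  list(mean = drop(cb %*% eb), cov = cb)
}

# Likelihood-weighted sigma-point update of the target blocks from the binary
# in-target flag. Sigma points are drawn jointly over (cursor pos, target
# pos, target half-extent); each point is weighted by the probability of the
# observed flag under a small label-flip noise, then the target blocks are
# moment-matched to the weighted cloud.
flag_update <- function(belief, flag_obs, lr, flip_prob = 0.1) {
  mu <- c(belief$cursor$mean[1], belief$target_pos$mean,
          belief$target_halfext$mean)
  sd3 <- sqrt(pmax(c(belief$cursor$cov[1, 1], belief$target_pos$cov[1],
                     belief$target_halfext$cov[1]), 0))
  n <- 3
  scale <- sqrt(n)  # unit sigma scaling (alpha = 1, kappa = 0)
  pts <- rbind(mu,
               t(mu + scale * diag(sd3)),
               t(mu - scale * diag(sd3)))
  wm <- c(0, rep(1 / (2 * n), 2 * n))
  cflag <- as.integer(abs(pts[, 1] - pts[, 2]) <= pts[, 3])
  lik <- ifelse(cflag == flag_obs, 1 - flip_prob, flip_prob)
  w <- wm * lik
  if (sum(w) <= 0) return(belief)
  w <- w / sum(w)
  for (blk in c("target_pos", "target_halfext")) {
    j <- if (blk == "target_pos") 2L else 3L
    m_post <- sum(w * pts[, j])
    v_post <- sum(w * (pts[, j] - m_post)^2)
    v_post <- max(v_post, 1e-12)
    upd <- blend_natural_1d(belief[[blk]]$mean, belief[[blk]]$cov[1],
                            m_post, v_post, lr[[blk]])
    belief[[blk]] <- gaussian_belief(upd$mean, upd$var)
  }
  belief
}

# 1-d natural-parameter blend between prior (m0, v0) and posterior (m1, v1).
blend_natural_1d <- function(m0, v0, m1, v1, lr, jitter = 1e-9) {
  if (lr >= 1) return(list(mean = m1, var = v1))
  if (lr <= 0) return(list(mean = m0, var = v0))
  l0 <- 1 / (v0 + jitter); l1 <- 1 / (v1 + jitter)
  lb <- (1 - lr) * l0 + lr * l1
  list(mean = ((1 - lr) * l0 * m0 + lr * l1 * m1) / lb, var = 1 / lb)
}

#' Variational update of the belief from an observation
#'
#' Runs independent per-block updates: the cursor-position channel updates
#' the cursor block, the target-position channel the target-position block,
#' the half-extent channel the half-extent block, and the binary in-target
#' flag the two target blocks via a weighted sigma-point approximation.
#' Each block blends prior and conjugate posterior in natural-parameter space
#' by its learning rate.
#'
#' @param predicted the predicted `mf_belief`.
#' @param obs an `iaif_obs`, or `NULL` (no update, e.g. during the delay
#'   window).
#' @param gm an `iaif_gm` supplying the assumed observation-noise variances.
#' @param lr per-block rates from [learning_rates()].
#' @param flip_prob label-flip probability used for the binary channel.
#' @return the updated `mf_belief`.
#' @export
vi_update <- function(predicted, obs, gm, lr = learning_rates(),
                      flip_prob = 0.1) {
  if (is.null(obs)) return(predicted)
  b <- predicted
  if (is.finite(obs$cursor_pos)) {
    u <- blend_update(b$cursor$mean, b$cursor$cov, c(1, 0), obs$cursor_pos,
                      gm$obs_noise_var[["cursor"]], lr[["cursor"]])
    b$cursor <- gaussian_belief(u$mean, u$cov)
  }
  if (is.finite(obs$target_pos)) {
    u <- blend_update(b$target_pos$mean, b$target_pos$cov, 1, obs$target_pos,
                      gm$obs_noise_var[["target_pos"]], lr[["target_pos"]])
    b$target_pos <- gaussian_belief(u$mean, u$cov)
  }
  if (is.finite(obs$target_halfext)) {
    u <- blend_update(b$target_halfext$mean, b$target_halfext$cov, 1,
                      obs$target_halfext,
                      gm$obs_noise_var[["target_halfext"]],
                      lr[["target_halfext"]])
    b$target_halfext <- gaussian_belief(u$mean, u$cov)
  }
  if (!is.null(obs$in_target) && is.finite(obs$in_target)) {
    b <- flag_update(b, obs$in_target, lr, flip_prob)
  }
  b
}
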