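test_that("gaussian beliefs are re-symmetrised and PSD-checked on construction", {
  b <- gaussian_belief(c(0, 0), matrix(c(1, 0.2, 0.200000001, 1), 2, 2))
  expect_identical(b$cov, t(b$cov))
  expect_error(gaussian_belief(0, -1), "positive semi-definite")
  expect_error(gaussian_belief(c(0, NA), diag(2)), "finite")
})

test_that("symmetrised KL matches the closed form and its invariances", {
  p <- gaussian_belief(0, 1)
  expect_equal(symmetrised_kl(p, p), 0, tolerance = 1e-8)
  # unit mean separation at unit variance: 0.5 in each direction
  q <- gaussian_belief(1, 1)
  expect_equal(symmetrised_kl(p, q), 0.5, tolerance = 1e-6)

  # symmetry on random pairs, non-negativity
  set.seed(4)
  for (i in 1:100) {
    a <- gaussian_belief(rnorm(2), crossprod(matrix(rnorm(4), 2)) + diag(0.1, 2))
    b <- gaussian_belief(rnorm(2), crossprod(matrix(rnorm(4), 2)) + diag(0.1, 2))
    d1 <- symmetrised_kl(a, b); d2 <- symmetrised_kl(b, a)
    expect_equal(d1, d2, tolerance = 1e-9)
    expect_gte(d1, 0)
  }

  # quadratic scaling with mean separation at fixed covariance
  d1 <- symmetrised_kl(gaussian_belief(0, 2), gaussian_belief(1, 2))
  d2 <- symmetrised_kl(gaussian_belief(0, 2), gaussian_belief(3, 2))
  expect_equal(d2 / d1, 9, tolerance = 1e-8)

  expect_error(symmetrised_kl(p, gaussian_belief(c(0, 0), diag(2))),
               "dimensions")

  # mean-field divergence sums the state blocks
  b1 <- test_belief(); b2 <- test_belief(tpos = 0.5)
  expect_equal(symmetrised_kl(b1, b2),
               symmetrised_kl(b1$cursor, b2$cursor) +
                 symmetrised_kl(b1$target_pos, b2$target_pos) +
                 symmetrised_kl(b1$target_halfext, b2$target_halfext),
               tolerance = 1e-12)
})

test_that("unscented prediction is exact where closed forms exist", {
  gm <- iaif_gm(damping_mean = 10, damping_var = 0)

  # degenerate belief through the deterministic map = environment step
  b <- test_belief()
  b$cursor <- gaussian_belief(c(0.1, 0.4), matrix(0, 2, 2))
  pred <- ukf_predict(b, 2, gm)
  tr <- euler_traj(0.1, 0.4, 2, 10, gm$dt)
  expect_equal(pred$cursor$mean, tr[1, ], tolerance = 1e-12)
  expect_equal(max(abs(pred$cursor$cov)), 0, tolerance = 1e-12)
  # target, parameter and noise factors pass through untouched
  expect_identical(pred$target_pos, b$target_pos)
  expect_identical(pred$target_halfext, b$target_halfext)
  expect_identical(pred$damping, b$damping)

  # known damping: equals the exact linear Kalman prediction A mu, A S A^T
  set.seed(11)
  for (i in 1:20) {
    S <- crossprod(matrix(rnorm(4), 2)) + diag(1e-4, 2)
    mu <- rnorm(2); a <- rnorm(1, sd = 5)
    b$cursor <- gaussian_belief(mu, S)
    pred <- ukf_predict(b, a, gm)
    A <- matrix(c(1, 0, gm$dt, 1 - gm$damping_mean * gm$dt), 2, 2)
    expect_equal(pred$cursor$mean, drop(A %*% mu + c(0, gm$dt * a)),
                 tolerance = 1e-9)
    expect_equal(pred$cursor$cov, A %*% S %*% t(A), tolerance = 1e-9)
  }

  # damping uncertainty inflates the predicted velocity variance
  b$cursor <- gaussian_belief(c(0, 0.8), diag(c(1e-4, 1e-4)))
  v_known <- ukf_predict(b, 0, gm)$cursor$cov[2, 2]
  gm_unc <- iaif_gm(damping_mean = 10, damping_var = 2)
  v_unc <- ukf_predict(b, 0, gm_unc)$cursor$cov[2, 2]
  expect_gt(v_unc, v_known)
})

test_that("variational update reproduces conjugate Bayes at lr = 1 and respects limits", {
  gm <- iaif_gm()
  b <- test_belief(tpos = 0.2, tpos_var = 0.05)
  obs <- structure(list(cursor_pos = 0.03, target_pos = 0.41,
                        target_halfext = 0.09, in_target = NA),
                   class = "iaif_obs")

  lr1 <- learning_rates(1, 1, 1)
  upd <- vi_update(b, obs, gm, lr1)

  # independent conjugate oracle, cursor block: y = [1 0] x + e
  P <- b$cursor$cov; R <- gm$obs_noise_var[["cursor"]]
  S <- P[1, 1] + R; K <- P[, 1] / S
  mu_star <- b$cursor$mean + K * (obs$cursor_pos - b$cursor$mean[1])
  P_star <- P - outer(K, P[1, ])
  expect_equal(upd$cursor$mean, mu_star, tolerance = 1e-10)
  expect_equal(upd$cursor$cov, (P_star + t(P_star)) / 2, tolerance = 1e-10)

  # univariate target block: precision-weighted mean
  v0 <- 0.05; m0 <- 0.2; r <- gm$obs_noise_var[["target_pos"]]
  expect_equal(upd$target_pos$mean,
               (m0 / v0 + obs$target_pos / r) / (1 / v0 + 1 / r),
               tolerance = 1e-10)
  expect_equal(upd$target_pos$cov[1], 1 / (1 / v0 + 1 / r), tolerance = 1e-10)

  # lr = 0 keeps the prior
  upd0 <- vi_update(b, obs, gm, learning_rates(0, 0, 0))
  expect_equal(upd0$cursor$mean, b$cursor$mean)
  expect_equal(upd0$target_pos$cov, b$target_pos$cov)

  # uninformative likelihood limit: noise variance to infinity
  gm_inf <- iaif_gm(obs_noise_var = c(cursor = Inf, target_pos = Inf,
                                      target_halfext = Inf))
  upd_inf <- vi_update(b, obs, gm_inf, lr1)
  expect_equal(upd_inf$cursor$mean, b$cursor$mean, tolerance = 1e-8)
  expect_equal(upd_inf$target_pos$mean, b$target_pos$mean, tolerance = 1e-8)

  # no observation (delay window): belief unchanged
  expect_identical(vi_update(b, NULL, gm), b)
})

test_that("observing only the cursor channel never moves the target blocks", {
  gm <- iaif_gm()
  b <- test_belief()
  obs <- structure(list(cursor_pos = 0.1, target_pos = NA,
                        target_halfext = NA, in_target = NA),
                   class = "iaif_obs")
  upd <- vi_update(b, obs, gm, learning_rates(1, 1, 1))
  expect_identical(upd$target_pos, b$target_pos)
  expect_identical(upd$target_halfext, b$target_halfext)
  expect_false(isTRUE(all.equal(upd$cursor$mean, b$cursor$mean)))
})

test_that("the binary flag channel updates only the target blocks, coherently", {
  gm <- iaif_gm()
  b <- test_belief(pos = 0.4, tpos = 0.4, tpos_var = 0.02, twid = 0.1,
                   twid_var = 2e-3)
  obs_only_flag <- function(flag) structure(
    list(cursor_pos = NA, target_pos = NA, target_halfext = NA,
         in_target = flag), class = "iaif_obs")
  upd1 <- vi_update(b, obs_only_flag(1L), gm, learning_rates(1, 1, 1))
  upd0 <- vi_update(b, obs_only_flag(0L), gm, learning_rates(1, 1, 1))
  expect_identical(upd1$cursor, b$cursor)
  # observing "inside" with the cursor at the believed centre should not
  # shrink the believed half-extent; observing "outside" should
  expect_gte(upd1$target_halfext$mean + 1e-9, upd0$target_halfext$mean)
})

test_that("predict/update preserve belief validity on randomised inputs", {
  gm <- iaif_gm()
  set.seed(21)
  for (i in 1:300) {
    b <- mf_belief(
      cursor = gaussian_belief(rnorm(2), crossprod(matrix(rnorm(4), 2)) +
                                 diag(1e-6, 2)),
      target_pos = gaussian_belief(rnorm(1), rexp(1)),
      target_halfext = gaussian_belief(abs(rnorm(1, 0.1)), rexp(1, 100)),
      damping = gaussian_belief(10, rexp(1)),
      obs_noise_var = c(cursor = 1e-4, target_pos = 1e-4,
                        target_halfext = 2.5e-5))
    p <- ukf_predict(b, rnorm(1, sd = 10), gm)
    o <- structure(list(cursor_pos = rnorm(1), target_pos = rnorm(1),
                        target_halfext = abs(rnorm(1, 0.1)),
                        in_target = rbinom(1, 1, 0.5)), class = "iaif_obs")
    u <- vi_update(p, o, gm)
    for (blk in list(u$cursor, u$target_pos, u$target_halfext)) {
      expect_identical(blk$cov, t(blk$cov))
      expect_gte(min(eigen(blk$cov, symmetric = TRUE,
                           only.values = TRUE)$values), -1e-10)
    }
  }
})

test_that("the filter is statistically consistent on model-generated data (NEES)", {
  # linear-Gaussian scenario: known damping, cursor-position observations,
  # exact conjugate updates; estimation error should be chi-square consistent
  gm <- iaif_gm(damping_mean = 10, damping_var = 0,
                obs_noise_var = c(cursor = 1e-4, target_pos = 1e-4,
                                  target_halfext = 2.5e-5))
  lr1 <- learning_rates(1, 1, 1)
  P0 <- diag(c(0.01, 0.01))
  set.seed(31)
  n_rep <- 200; n_step <- 40
  nees <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    x <- drop(chol(P0) %*% rnorm(2))
    b <- test_belief()
    b$cursor <- gaussian_belief(c(0, 0), P0)
    for (t in seq_len(n_step)) {
      a <- rnorm(1, sd = 5)
      x <- c(x[1] + gm$dt * x[2], x[2] + gm$dt * (-10 * x[2] + a))
      b <- ukf_predict(b, a, gm)
      o <- structure(list(cursor_pos = x[1] + rnorm(1, sd = 1e-2),
                          target_pos = NA, target_halfext = NA,
                          in_target = NA), class = "iaif_obs")
      b <- vi_update(b, o, gm, lr1)
    }
    e <- b$cursor$mean - x
    nees[r] <- drop(t(e) %*% solve(b$cursor$cov) %*% e)
  }
  # mean NEES of dim-2 errors across independent replicates
  lo <- qchisq(0.025, 2 * n_rep) / n_rep
  hi <- qchisq(0.975, 2 * n_rep) / n_rep
  expect_gt(mean(nees), lo)
  expect_lt(mean(nees), hi)
})

test_that("hallucinated observations follow the belief's predictive law", {
  gm <- iaif_gm()
  b <- test_belief()

  # degenerate: zero state covariance and (near) zero noise collapses draws
  b0 <- b
  b0$cursor <- gaussian_belief(c(0.2, 0), matrix(0, 2, 2))
  b0$target_pos <- gaussian_belief(0.4, 0)
  b0$target_halfext <- gaussian_belief(0.1, 0)
  gm0 <- iaif_gm(obs_noise_var = c(cursor = 0, target_pos = 0,
                                   target_halfext = 0))
  h <- hallucinate_observations(b0, gm0, 50)
  expect_true(all(h$cursor_pos == 0.2))
  expect_true(all(h$target_pos == 0.4))
  expect_true(all(h$in_target == 0L))  # |0.2 - 0.4| > 0.1

  # CLT: empirical mean of the cursor channel near the predictive mean
  set.seed(5)
  h <- hallucinate_observations(b, gm, 1e4)
  se <- sqrt(b$cursor$cov[1, 1] + gm$obs_noise_var[["cursor"]]) / 100
  expect_lt(abs(mean(h$cursor_pos) - b$cursor$mean[1]), 4 * se)

  # seeded: identical draw sequences
  set.seed(8); h1 <- hallucinate_observations(b, gm, 20)
  set.seed(8); h2 <- hallucinate_observations(b, gm, 20)
  expect_identical(h1, h2)
})
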