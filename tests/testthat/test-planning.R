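test_that("plan sampling matches the action prior", {
  set.seed(2)
  p <- sample_plans(action_prior(sd = 10), 1, 12)
  expect_identical(dim(p), c(1L, 12L))

  p0 <- sample_plans(action_prior(mean = 3, sd = 0), 7, 4)
  expect_true(all(p0 == 3))

  set.seed(3)
  p <- sample_plans(action_prior(mean = 1, sd = 10), 1000, 12)
  se <- 10 / sqrt(length(p))
  expect_lt(abs(mean(p) - 1), 4 * se)

  expect_error(sample_plans(action_prior(), 0, 5), "at least 1")
})

test_that("rollouts iterate the unscented prediction with no observations", {
  gm <- iaif_gm()
  b <- test_belief()

  # base case: one step equals a single prediction
  r1 <- rollout_plan(b, 5, gm)
  expect_equal(r1[[1]]$cursor, ukf_predict(b, 5, gm)$cursor, tolerance = 1e-12)

  # zero-uncertainty start with known parameters: means follow the
  # deterministic Euler trajectory
  gm0 <- iaif_gm(damping_var = 0)
  b0 <- b
  b0$cursor <- gaussian_belief(c(0, 0), matrix(0, 2, 2))
  set.seed(12)
  plan <- rnorm(12, sd = 10)
  ro <- rollout_plan(b0, plan, gm0)
  tr <- euler_traj(0, 0, plan, gm0$damping_mean, gm0$dt)
  means <- t(vapply(ro, function(x) x$cursor$mean, numeric(2)))
  expect_equal(means, tr, tolerance = 1e-10)

  # covariance trace non-decreasing under non-contracting dynamics (d = 0)
  gm_nc <- iaif_gm(damping_mean = 0, damping_var = 0)
  b1 <- b
  b1$cursor <- gaussian_belief(c(0, 0), diag(c(1e-4, 1e-4)))
  ro <- rollout_plan(b1, rep(1, 10), gm_nc)
  trs <- vapply(ro, function(x) sum(diag(x$cursor$cov)), numeric(1))
  expect_true(all(diff(trs) >= -1e-15))
})

test_that("pragmatic value prefers beliefs on target and degenerates correctly", {
  gm0 <- iaif_gm(obs_noise_var = c(cursor = 0, target_pos = 0,
                                   target_halfext = 0))
  pref <- preference()

  # grid over belief locations: the minimum sits at the target centre
  mk <- function(pos) {
    b <- test_belief(tpos = 0.45, tpos_var = 0, twid = 0.1, twid_var = 0)
    b$cursor <- gaussian_belief(c(pos, 0), matrix(0, 2, 2))
    b
  }
  grid <- seq(-0.2, 1.1, by = 0.05)
  vals <- vapply(grid, function(g) pragmatic_value(mk(g), pref, gm0, m = 4),
                 numeric(1))
  expect_equal(grid[which.min(vals)], 0.45)
  # and matches the deterministic closed form at a few points
  for (g in c(-0.2, 0.45, 0.8))
    expect_equal(pragmatic_value(mk(g), pref, gm0, m = 8),
                 det_pragmatic(g, 0.45, 0.1, pref), tolerance = 1e-12)

  # near-uniform preference: value almost independent of the belief
  flat <- preference(p_in = 0.5, sd_px = 1e9)
  v1 <- pragmatic_value(mk(0), flat, gm0, m = 4)
  v2 <- pragmatic_value(mk(1), flat, gm0, m = 4)
  expect_equal(v1, v2, tolerance = 1e-6)

  # seeded determinism
  gm <- iaif_gm()
  b <- test_belief()
  set.seed(9); a1 <- pragmatic_value(b, pref, gm, m = 32)
  set.seed(9); a2 <- pragmatic_value(b, pref, gm, m = 32)
  expect_identical(a1, a2)
})

test_that("information gain is non-negative and vanishes for uninformative channels", {
  b <- test_belief(tpos_var = 0.01)
  gm_inf <- iaif_gm(obs_noise_var = c(cursor = 1e12, target_pos = 1e12,
                                      target_halfext = 1e12))
  set.seed(14)
  expect_lt(information_gain(b, gm_inf, m = 16), 1e-6)

  # near-exact observation of the state: gain is large and positive
  gm_sharp <- iaif_gm(obs_noise_var = c(cursor = 1e-12, target_pos = 1e-12,
                                        target_halfext = 1e-12))
  expect_gt(information_gain(b, gm_sharp, m = 4), 10)

  set.seed(15)
  for (i in 1:20) {
    bb <- test_belief(tpos = rnorm(1), tpos_var = rexp(1, 10))
    expect_gte(information_gain(bb, iaif_gm(), m = 4), 0)
  }
})

test_that("plan evaluation averages step-wise EFE and is reproducible", {
  gm <- iaif_gm()
  b <- test_belief()
  pref <- preference()
  set.seed(16)
  plan <- rnorm(12, sd = 10)
  set.seed(17)
  ev <- evaluate_plan(b, plan, gm, pref, m = 16)
  expect_identical(length(ev$stepwise_efe), 12L)
  expect_equal(ev$mean_efe, mean(ev$stepwise_efe))
  expect_identical(length(ev$predicted_beliefs), 12L)

  # engine path under a degenerate belief: identical plans evaluate
  # identically, and exact ties break to the lowest candidate index
  gm0 <- iaif_gm(damping_var = 0,
                 obs_noise_var = c(cursor = 0, target_pos = 0,
                                   target_halfext = 0))
  b0 <- test_belief(tpos = 0.45, tpos_var = 0, twid = 0.1, twid_var = 0)
  b0$cursor <- gaussian_belief(c(0, 0), matrix(0, 2, 2))
  e1 <- select_plan(b0, gm0, pref, K = 4, N = 6, m = 8, seed = 5,
                    plans = matrix(rep(plan[1:6], each = 4), 4, 6))
  expect_true(all(abs(e1$all_mean_efe - e1$all_mean_efe[1]) < 1e-12))
  expect_identical(e1$chosen_index, 1L)
})

test_that("plan selection minimises mean EFE and matches brute-force enumeration", {
  pref <- preference()
  gm0 <- iaif_gm(damping_var = 0,
                 obs_noise_var = c(cursor = 0, target_pos = 0,
                                   target_halfext = 0))
  b0 <- test_belief(tpos = 0.45, tpos_var = 0, twid = 0.1, twid_var = 0)
  b0$cursor <- gaussian_belief(c(0, 0), matrix(0, 2, 2))

  # rigged candidate: an artificially perfect plan is always chosen
  set.seed(18)
  K <- 5
  plans <- matrix(rnorm(K * 2, sd = 3), K, 2)
  plans[3, ] <- c(40, 5)  # drives the cursor hard toward the target
  res <- select_plan(b0, gm0, pref, K, 2, m = 4, plans = plans)
  expect_identical(res$chosen_index, 3L)

  # brute force over all 3^2 plans from a 3-point action set: deterministic
  # EFE via the closed-form oracle on the Euler trajectory
  acts <- c(-20, 0, 40)
  all_plans <- as.matrix(expand.grid(a1 = acts, a2 = acts))
  res <- select_plan(b0, gm0, pref, nrow(all_plans), 2, m = 4,
                     plans = all_plans)
  brute <- apply(all_plans, 1, function(pl) {
    tr <- euler_traj(0, 0, pl, gm0$damping_mean, gm0$dt)
    mean(vapply(seq_len(2), function(i)
      det_pragmatic(tr[i, 1], 0.45, 0.1, pref), numeric(1)))
  })
  expect_identical(res$chosen_index, as.integer(which.min(brute)))
  expect_equal(res$all_mean_efe, unname(brute), tolerance = 1e-10)

  # K = 1 returns the only candidate; chosen EFE <= all candidates always
  gm <- iaif_gm()
  b <- test_belief()
  r1 <- select_plan(b, gm, pref, K = 1, N = 3, m = 4, seed = 2)
  expect_identical(r1$chosen_index, 1L)
  for (s in 1:5) {
    r <- select_plan(b, gm, pref, K = 30, N = 6, m = 8, seed = s)
    expect_true(all(r$mean_efe <= r$all_mean_efe + 1e-12))
    expect_equal(r$mean_efe, mean(r$stepwise_efe))
  }
})

test_that("goal-directed plans score lower EFE than their mirror images", {
  gm <- iaif_gm()
  pref <- preference()
  b <- test_belief(tpos = 0.45, tpos_var = 1e-4)
  toward <- rep(15, 12)
  res <- select_plan(b, gm, pref, 2, 12, m = 32, seed = 1,
                     plans = rbind(toward, -toward))
  expect_identical(res$chosen_index, 1L)
  expect_lt(res$all_mean_efe[1], res$all_mean_efe[2])
})

test_that("Monte-Carlo EFE noise shrinks as 1/sqrt(m)", {
  gm <- iaif_gm()
  pref <- preference()
  b <- test_belief(tpos = 0.3, tpos_var = 5e-3)
  plan <- matrix(rep(10, 6), 1, 6)
  est <- function(m, s) eval_plans_engine(b, plan, gm, pref, m, seed = s)$mean
  s_small <- sd(vapply(1:50, function(s) est(8, s), numeric(1)))
  s_large <- sd(vapply(1:50, function(s) est(32, s), numeric(1)))
  expect_gt(s_small / s_large, 1.4)  # ideal ratio 2
  expect_lt(s_small / s_large, 2.9)
})
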