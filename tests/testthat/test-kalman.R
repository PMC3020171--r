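test_that("state initialization follows the configuration", {
  st <- kf_init(5, kalman_config(p0 = 1e4))
  expect_identical(st$x_hat, numeric(5))
  expect_identical(st$p_cov, diag(1e4, 5))
  expect_identical(st$k, 0L)
  expect_identical(st$rss, 0)
  # minimal dimension
  st1 <- kf_init(1)
  expect_length(st1$x_hat, 1L)
  # idempotent / deterministic
  expect_identical(kf_init(5), kf_init(5))
  expect_error(kalman_config(r = 0), "r > 0")
  expect_error(kalman_config(q = -1), "q >= 0")
})

test_that("prediction adds q to the covariance diagonal only", {
  st <- kf_init(4, kalman_config(q = 0, p0 = 2))
  expect_identical(kf_predict(st, kalman_config(q = 0))$p_cov, st$p_cov)
  cfg <- kalman_config(q = 0.3)
  p1 <- kf_predict(st, cfg)
  expect_equal(sum(diag(p1$p_cov)), sum(diag(st$p_cov)) + 4 * 0.3)
  # repeated prediction without data grows P linearly: P(k) = P0 + k*Q
  pk <- st
  for (i in 1:10) pk <- kf_predict(pk, cfg)
  expect_equal(pk$p_cov, diag(2 + 10 * 0.3, 4), tolerance = 1e-12)
})

test_that("measurement update has the textbook closed forms", {
  cfg <- kalman_config(q = 0, r = 1, p0 = 1)
  # zero row: uninformative, nothing moves except the counters
  st <- kf_init(3, cfg)
  up <- kf_update(st, 5, c(0, 0, 0), cfg)
  expect_identical(up$x_hat, st$x_hat)
  expect_identical(up$p_cov, st$p_cov)
  expect_identical(up$k, 1L)
  # scalar case: H = 1, P = 1, r = 1 -> gain 1/2, estimate moves halfway
  st1 <- kf_init(1, cfg)
  up1 <- kf_update(st1, 2, 1, cfg)
  expect_equal(as.numeric(up1$x_hat), 1)
  expect_equal(as.numeric(up1$p_cov), 0.5)
  expect_error(kf_update(st1, NaN, 1, cfg), "non-finite")
  expect_error(kf_update(st1, 1, c(1, 2), cfg), "wrong length")
})

test_that("q = 0 diffuse filtering reproduces batch OLS step by step", {
  H <- random_design(200)
  withr::with_seed(12, {
    y <- as.numeric(H %*% c(1, 0.2, 0.1, -0.1, 0.05)) + rnorm(200, 0, 0.5)
  })
  run <- kf_filter(y, H, kalman_config(q = 0, r = 1, p0 = 1e8),
    ar = FALSE, keep = "all"
  )
  for (k in c(6, 10, 50, 200)) {
    ora <- oracle_ols_t(y, H, k, c(1, 0, 0, 0, 0))
    expect_equal(unname(run$beta_traj[k, ]), ora$beta, tolerance = 1e-6)
    expect_equal(run$t_traj[k], ora$t, tolerance = 1e-4)
  }
})

test_that("covariance stays symmetric positive semidefinite under random streams", {
  cfg <- kalman_config(q = 1e-4, r = 0.25, p0 = 10)
  st <- kf_init(5, cfg)
  withr::with_seed(13, {
    for (i in 1:1000) {
      st <- kf_predict(st, cfg)
      st <- kf_update(st, rnorm(1), rnorm(5), cfg)
      expect_identical(st$p_cov, t(st$p_cov))
    }
  })
  ev <- eigen(st$p_cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  expect_gte(st$rss, 0)
})

test_that("parameter recovery with study-default noise settings is unbiased", {
  # y = H beta + white noise (0.5 uM), paper-default q and r: the final
  # task coefficient averages within 10% of the true amplitude
  H <- nirs_design(ref_protocol())$matrix
  b1 <- vapply(1:50, function(s) {
    sim <- nirs_simulate(
      n_channels = 1, active_channels = 1, amplitude_um = 1,
      noise_sd_um = 0.5, physio = NULL, drift = NULL, seed = 1000 + s
    )
    kf_filter(sim_channel_matrix(sim)[, 1], H, kalman_config(),
      ar = FALSE, keep = "final"
    )$beta[1]
  }, 0)
  expect_equal(mean(b1), 1, tolerance = 0.1)
})

test_that("innovations are white when the model is correctly specified", {
  H <- random_design(2000, seed = 31)
  withr::with_seed(32, {
    y <- as.numeric(H %*% c(1, 0.5, 0, 0, 0)) + rnorm(2000, 0, 0.5)
  })
  run <- kf_filter(y, H, kalman_config(q = 0, p0 = 1e8), ar = FALSE, keep = "all")
  innov <- run$innovations[-seq_len(50)] # drop the settling phase
  expect_lt(abs(oracle_lag1(innov)), 0.1)
})

test_that("channels evolve independently and in parallel", {
  cfg <- kalman_config()
  row <- c(0.5, 1, 0.1)
  states <- replicate(24, kf_init(3, cfg), simplify = FALSE)
  ars <- replicate(24, ar_init(), simplify = FALSE)
  # identical inputs -> identical states
  out <- kf_step_channels(states, rep(1.3, 24), row, cfg, ars)
  expect_true(all(vapply(
    out$states, function(s) identical(s, out$states[[1]]), logical(1)
  )))
  # permutation equivariance
  y <- seq(0.1, 2.4, by = 0.1)
  perm <- withr::with_seed(14, sample(24))
  o1 <- kf_step_channels(states, y, row, cfg, ars)
  o2 <- kf_step_channels(states[perm], y[perm], row, cfg, ars[perm])
  expect_identical(o1$states[perm], o2$states)
  # single channel equals a direct predict/update composition
  direct <- kf_update(kf_predict(kf_init(3, cfg), cfg), 1.3, row, cfg)
  solo <- kf_step_channels(list(kf_init(3, cfg)), 1.3, row, cfg)$states[[1]]
  expect_identical(solo, direct)
  expect_error(kf_step_channels(states, 1:3, row, cfg), "mismatch")
})

test_that("streaming driver composes the exported per-step operations", {
  # kf_filter (fast loop) vs explicit ar_whiten + kf_predict + kf_update +
  # ar_update_rho composition: identical trajectories
  H <- random_design(120, seed = 41)
  withr::with_seed(42, y <- as.numeric(H %*% c(1, 0.3, 0, 0, 0)) + oracle_ar1(120, 0.5, 0.4))
  cfg <- kalman_config()
  run <- kf_filter(y, H, cfg, ar = TRUE, ar_burn_in = 10, keep = "all")
  st <- kf_init(5, cfg)
  ar <- ar_init(burn_in = 10)
  for (k in seq_along(y)) {
    w <- ar_whiten(ar, y[k], H[k, ])
    ar <- w$state
    st <- kf_update(kf_predict(st, cfg), w$y_star, w$row_star, cfg)
    ar <- ar_update_rho(ar, y[k] - sum(H[k, ] * st$x_hat))
    expect_equal(unname(run$beta_traj[k, ]), unname(st$x_hat), tolerance = 1e-12)
  }
  expect_equal(run$rho, ar$rho, tolerance = 1e-12)
  expect_equal(run$state$rss, st$rss, tolerance = 1e-10)
})

test_that("vectorized shared-design path equals the per-channel loop", {
  H <- random_design(150, seed = 51)
  withr::with_seed(52, Y <- matrix(rnorm(150 * 6), 150))
  cfg <- kalman_config(q = 1e-4, r = 0.25, p0 = 1e3)
  multi <- kf_filter_matrix(Y, H, cfg)
  for (i in 1:6) {
    solo <- kf_filter(Y[, i], H, cfg, ar = FALSE, keep = "final")
    expect_equal(multi$beta[, i], unname(solo$beta), tolerance = 1e-12)
    expect_equal(multi$t[i], solo$t, tolerance = 1e-10)
  }
})
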