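test_that("t-statistic has the closed forms and flags untestable states", {
  # zero numerator -> t = 0
  st <- kf_init(2, kalman_config())
  st$x_hat <- c(0, 1)
  st$gram <- diag(c(4, 4))
  st$sxy <- c(0, 4)
  st$syy <- 8
  st$k <- 10L
  res <- t_statistic(st)
  expect_equal(res$t, 0)
  expect_identical(res$dof, 8L)
  # scalar model: beta = 2, sigma2 = 1, gram = 4 -> t = 4
  s1 <- kf_init(1, kalman_config())
  s1$x_hat <- 2
  s1$gram <- matrix(4)
  s1$k <- 5L
  # choose syy/sxy so rss = syy - 2*2*sxy + 4*4 gives sigma2 = 1 at dof 4
  s1$sxy <- 4 # rss = syy - 16 + 16
  s1$syy <- 4
  expect_equal(t_statistic(s1)$t, 4)
  # not yet testable: dof < 1 or singular gram
  fresh <- kf_init(3, kalman_config())
  expect_false(t_statistic(fresh)$testable)
  fresh$k <- 10L # dof fine, but gram still singular
  expect_false(t_statistic(fresh)$testable)
})

test_that("streamed t trajectory matches a direct formula evaluator", {
  # independent evaluator of t(k) = c'b / sqrt(sigma2 * c' G^-1 c) with
  # sigma2 = sum(y - H b)^2 / (k - L), at the streamed coefficients
  H <- random_design(300, seed = 61)
  withr::with_seed(62, {
    y <- as.numeric(H %*% c(0.8, 0.2, 0, 0, 0)) + rnorm(300, 0, 0.5)
  })
  run <- kf_filter(y, H, kalman_config(q = 0, p0 = 1e8), ar = FALSE, keep = "all")
  cvec <- c(1, 0, 0, 0, 0)
  for (k in c(10, 100, 300)) {
    b <- run$beta_traj[k, ]
    resid <- y[seq_len(k)] - as.numeric(H[seq_len(k), ] %*% b)
    sigma2 <- sum(resid^2) / (k - 5)
    G <- crossprod(H[seq_len(k), ])
    t_ora <- sum(cvec * b) / sqrt(sigma2 * as.numeric(t(cvec) %*% solve(G) %*% cvec))
    expect_equal(run$t_traj[k], t_ora, tolerance = 1e-8)
  }
})

test_that("Bonferroni threshold follows the closed form and is monotone", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 2), (1 - 0.95^2) / 2)
  expect_equal(bonferroni_threshold(0.05, 2), 0.04875)
  # strictly decreasing over an exhaustive sweep
  pb <- bonferroni_threshold(0.05, 1:10000)
  expect_true(all(diff(pb) < 0))
  expect_error(bonferroni_threshold(0.05, 0), "j")
  expect_error(bonferroni_threshold(1.2, 3), "p_in")
})

test_that("activation map updates respect the one-tailed null and first crossings", {
  map <- activation_map_init(3, p_in = 0.05, j_policy = "per_step")
  # all t <= 0: nothing activates
  map <- activation_map_update(map, c(-1, 0, -0.5), c(10L, 10L, 10L), k = 20)
  expect_false(any(map$active))
  expect_true(all(is.na(map$first_active_time_s)))
  # overwhelming evidence activates under both policies
  for (pol in c("per_step", "cumulative")) {
    m <- activation_map_init(3, p_in = 0.05, j_policy = pol)
    m <- activation_map_update(m, c(30, 0, NA), c(100L, 100L, NA), k = 50)
    expect_identical(which(m$active), 1L)
    expect_equal(m$first_active_time_s[1], 50 / 1.81)
  }
  # first crossing is never unset, and active implies p <= corrected threshold
  m <- activation_map_init(1, j_policy = "per_step")
  m <- activation_map_update(m, 30, 100L, k = 10)
  t10 <- m$first_active_time_s
  m <- activation_map_update(m, 0, 101L, k = 11)
  expect_false(m$active)
  expect_identical(m$first_active_time_s, t10)
  m2 <- activation_map_update(m, 5, 102L, k = 12)
  expect_true(m2$active)
  expect_lte(m2$p_uncorrected, m2$p_threshold_corrected)
  # cumulative policy tightens the threshold as testable steps accumulate
  mc <- activation_map_init(2, j_policy = "cumulative")
  mc <- activation_map_update(mc, c(1, 1), c(10L, 10L), k = 1)
  th1 <- mc$p_threshold_corrected
  mc <- activation_map_update(mc, c(1, 1), c(11L, 11L), k = 2)
  expect_lt(mc$p_threshold_corrected, th1)
})

test_that("one active channel is detected with calibrated specificity", {
  # 24 channels, one true response: the true channel is always in the final
  # active set, and false positives occur at the rate the corrected
  # threshold implies (p_b from the closed form at j = 24)
  H <- nirs_design(ref_protocol())$matrix
  p_b <- bonferroni_threshold(0.05, 24)
  hits <- logical(50)
  fp <- integer(50)
  for (s in 1:50) {
    sim <- nirs_simulate(
      n_channels = 24, active_channels = 6, amplitude_um = 1,
      noise_sd_um = 0.5, physio = NULL, drift = NULL, seed = 2000 + s
    )
    res <- kf_filter_matrix(
      sim_channel_matrix(sim), H, kalman_config(q = 0, r = 1, p0 = 1e8)
    )
    pv <- pt(res$t, res$dof, lower.tail = FALSE)
    act <- which(pv <= p_b)
    hits[s] <- 6L %in% act
    fp[s] <- length(setdiff(act, 6L))
  }
  expect_true(all(hits))
  # mean false-positive count consistent with 23 * p_b (within 3 sd)
  expect_lt(mean(fp), 23 * p_b + 3 * sqrt(23 * p_b / 50))
})
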