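test_that("reference protocol arithmetic gives a 552 s record", {
  p <- ref_protocol()
  expect_identical(p$total_duration_s, 552)
  expect_identical(p$n_samples, as.integer(round(552 * 1.81)))
  s <- stimulus_vector(p)
  expect_length(s, p$n_samples)
  expect_setequal(unique(s), c(0L, 1L))
})

test_that("stimulus vector matches a per-sample block-membership oracle", {
  p <- nirs_protocol(7.3, 3, 11.1, 17.9, 2.7)
  s <- stimulus_vector(p)
  # oracle: a sample k belongs to a task block iff floored block bounds admit it
  fs <- p$sampling_rate_hz
  in_task <- vapply(seq_along(s) - 1L, function(k) {
    any(vapply(0:(p$n_sessions - 1), function(ses) {
      on <- p$preparation_s + ses * (p$task_s + p$rest_s)
      k >= floor(on * fs) && k < floor((on + p$task_s) * fs)
    }, logical(1)))
  }, logical(1))
  expect_identical(s, as.integer(in_task))
  # no stimulus at all
  expect_true(all(stimulus_vector(nirs_protocol(10, 1, 0, 30, 2)) == 0L))
})

test_that("double-gamma kernel peaks at the configured delay and truncates", {
  fs <- 50
  k <- double_gamma_kernel(hrf_params(), fs)
  # dense oracle evaluation of the argmax
  expect_equal((which.max(k) - 1) / fs, 6, tolerance = 0.1)
  expect_equal(max(k), 1) # peak-normalized
  expect_length(k, length(seq(0, 32, by = 1 / fs))) # truncation contract
  # undershoot_ratio -> Inf leaves the pure peak gamma
  k_inf <- double_gamma_kernel(hrf_params(undershoot_ratio = 1e12), fs)
  tt <- seq(0, 32, by = 1 / fs)
  pure <- dgamma(tt, shape = 7, rate = 1)
  expect_equal(k_inf, pure / max(pure), tolerance = 1e-6)
  expect_error(hrf_params(peak_dispersion_s = 0), "positive")
})

test_that("DCT regressors are unit-normalized and mutually orthogonal", {
  X <- dct_regressors(1000, 2, n_terms = 3)
  G <- crossprod(X)
  expect_equal(G, diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  # single term: monotone decreasing half-cosine
  x1 <- dct_regressors(500, 2, n_terms = 1)[, 1]
  expect_true(all(diff(x1) < 0))
  # cutoff mode: m = floor(2 * T * cutoff), bounded below by min_terms
  expect_identical(ncol(dct_regressors(1000, 2, cutoff_hz = 0.004)), 4L)
  expect_error(dct_regressors(999, 1.81, cutoff_hz = 0.0006), "n_terms or min_terms")
  expect_identical(
    ncol(dct_regressors(999, 1.81, cutoff_hz = 0.0006, min_terms = 3)), 3L
  )
})

test_that("design matrix has the documented structure and L = 5", {
  d <- nirs_design(ref_protocol())
  expect_identical(d$n_regressors, 5L)
  expect_identical(d$regressor_names, c("task", "baseline", "dct_1", "dct_2", "dct_3"))
  H <- d$matrix
  expect_identical(nrow(H), ref_protocol()$n_samples)
  expect_true(all(H[, "baseline"] == 1))
  # causality: zero before the first onset
  first_on <- floor(42 * 1.81)
  expect_true(all(H[seq_len(first_on), "task"] == 0))
  # DCT columns orthogonal to each other and near-orthogonal to baseline
  expect_lt(max(abs(crossprod(H[, 3:5]) - diag(3))), 1e-8)
  expect_lt(max(abs(crossprod(H[, 3:5], H[, 2]))), 1e-8)
  # task column equals the direct convolution oracle
  stim <- as.numeric(stimulus_vector(ref_protocol()))
  kern <- double_gamma_kernel(hrf_params(), 1.81)
  expect_equal(H[, "task"], oracle_convolve(stim, kern),
    tolerance = 1e-10, ignore_attr = TRUE
  )
  # zero stimulus -> zero task column
  d0 <- nirs_design(nirs_protocol(10, 1, 0, 30, 2))
  expect_true(all(d0$matrix[, "task"] == 0))
  # determinism: rebuilding is bit-identical
  expect_identical(d$matrix, nirs_design(ref_protocol())$matrix)
})

test_that("design rows are plain indexed lookups", {
  d <- nirs_design(ref_protocol())
  expect_equal(design_row(d, 0), d$matrix[1, ])
  expect_length(design_row(d, 500), 5L)
  expect_identical(unname(design_row(d, 0)[1:2]), c(0, 1))
  expect_error(design_row(d, -1), "out of range")
  expect_error(design_row(d, 999), "out of range")
  td <- tidy(d)
  expect_identical(names(td)[1], "time_s")
  expect_identical(nrow(td), nrow(d$matrix))
})
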