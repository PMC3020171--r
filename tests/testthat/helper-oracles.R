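# Independent oracles used across the suite. These are deliberately naive
# (elementwise loops, full refits) and never call the package's streaming
# code paths.

# elementwise -log10 intensity ratio
oracle_od <- function(intensity, ref = 1L) {
  out <- intensity
  for (j in seq_along(intensity)) {
    for (i in seq_len(nrow(intensity))) {
      out[i, j] <- -log10(intensity[[j]][i] / intensity[[j]][ref])
    }
  }
  out
}

# direct O(N*K) causal convolution
oracle_convolve <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(min(i, length(k)))) {
      acc <- acc + x[i - j + 1L] * k[j]
    }
    out[i] <- acc
  }
  out
}

# batch OLS coefficient and one-tailed t of contrast c on the first k rows,
# via lm() (the textbook route)
oracle_ols_t <- function(y, H, k, contrast) {
  df <- as.data.frame(H[seq_len(k), , drop = FALSE])
  df$y <- y[seq_len(k)]
  fit <- lm(y ~ . - 1, data = df)
  b <- coef(fit)
  sigma2 <- sum(residuals(fit)^2) / (k - ncol(H))
  vc <- solve(crossprod(as.matrix(df[, seq_len(ncol(H))])))
  tval <- sum(contrast * b) / sqrt(sigma2 * as.numeric(t(contrast) %*% vc %*% contrast))
  list(beta = unname(b), t = tval)
}

# lag-1 autocorrelation, plain formula
oracle_lag1 <- function(x) {
  n <- length(x)
  sum(x[-1] * x[-n]) / sum(x[-n]^2)
}

# AR(1) series with stationary start, own RNG draw
oracle_ar1 <- function(n, rho, sd) {
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sd / sqrt(1 - rho^2))
  for (i in 2:n) e[i] <- rho * e[i - 1] + rnorm(1, 0, sd)
  e
}

# small well-conditioned random design with a leading "task" column
random_design <- function(n, L = 5L, seed = 11) {
  withr::with_seed(seed, {
    H <- cbind(rnorm(n), 1, matrix(rnorm(n * (L - 2L)), n))
    colnames(H) <- c("task", "baseline", paste0("x", seq_len(L - 2L)))
    H
  })
}

ref_protocol <- function() nirs_protocol(42, 10, 21, 30, 1.81)
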