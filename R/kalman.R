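#' Kalman estimator configuration
#'
#' The GLM coefficient vector is modeled as a random walk with zero drift
#' (identity transition matrix) and process noise variance `q` per
#' coefficient; the scalar observation noise has variance `r`. The values
#' used in the finger-tapping study were q = 0.01^2 (from "(1 percent/sec)^2")
#' and r = 0.5^2 uM^2 (from "(0.5 uM/sec)^2"), obtained from training data;
#' here they are plain configuration inputs.
#'
#' Setting `q = 0` with a large (diffuse) `p0` makes the filter a recursive
#' least-squares estimator whose trajectory reproduces batch ordinary least
#' squares; this is the reference mode for statistical calibration.
#'
#' @param q Process-noise variance per coefficient (>= 0). Default 1e-4.
#' @param r Observation-noise variance (> 0). Default 0.25.
#' @param p0 Initial error-covariance diagonal (> 0). Default 1e4
#'   (weakly informative); use ~1e8 for the diffuse/OLS-equivalent mode.
#' @param x0 Initial coefficient vector; default zeros.
#' @return An object of class `kalman_config`.
#' @export
kalman_config <- function(q = 1e-4, r = 0.25, p0 = 1e4, x0 = NULL) {
  stopifnot(is.numeric(q), q >= 0, is.numeric(r), r > 0, is.numeric(p0), p0 > 0)
  structure(list(q = q, r = r, p0 = p0, x0 = x0), class = "kalman_config")
}

#' Initialize a per-channel Kalman state
#'
#' @param n_regressors Number of GLM coefficients L (>= 1).
#' @param cfg A [kalman_config()].
#' @return An object of class `kalman_state` holding the coefficient vector
#'   `x_hat` (zero-initialized unless `cfg$x0` is given), covariance
#'   `p_cov = p0 * I`, step counter `k`, and the running sufficient
#'   statistics for the t-test: `gram` (sum of outer products of the rows
#'   seen), `sxy` (sum of row * y), `syy` (sum of y^2) and the implied
#'   residual sum of squares `rss`.
#' @export
kf_init <- function(n_regressors, cfg = kalman_config()) {
  stopifnot(inherits(cfg, "kalman_config"), n_regressors >= 1)
  L <- as.integer(n_regressors)
  x0 <- if (is.null(cfg$x0)) numeric(L) else cfg$x0
  if (length(x0) != L) stop("x0 has wrong length", call. = FALSE)
  structure(
    list(
      x_hat = x0,
      p_cov = diag(cfg$p0, L),
      k = 0L,
      gram = matrix(0, L, L),
      sxy = numeric(L),
      syy = 0,
      rss = 0,
      n_regressors = L
    ),
    class = "kalman_state"
  )
}

#' Kalman prediction step
#'
#' Under the random-walk coefficient model with identity transition matrix,
#' the predicted coefficients are unchanged and the predicted covariance is
#' `P + q * I`.
#'
#' @param state A [kf_init()] state.
#' @param cfg A [kalman_config()].
#' @return The predicted `kalman_state`.
#' @export
kf_predict <- function(state, cfg) {
  stopifnot(inherits(state, "kalman_state"), inherits(cfg, "kalman_config"))
  if (cfg$q > 0) {
    diag(state$p_cov) <- diag(state$p_cov) + cfg$q
  }
  state
}

#' Kalman measurement update for one (whitened) sample
#'
#' Scalar-observation update: with innovation `dy = y - h' x` and innovation
#' variance `E = h' P h + r`, the gain is `K = P h / E`, the coefficients
#' move to `x + K dy`, and the covariance becomes `(I - K h') P`,
#' re-symmetrized. The running Gram matrix and the cross/sum-of-squares
#' accumulators are extended with the pair, and `rss` is recomputed from
#' them at the current coefficients (the residual sum of squares of the
#' current fit over all samples seen).
#'
#' @param state A predicted `kalman_state` (see [kf_predict()]).
#' @param y_star Measurement (whitened when prewhitening is enabled), uM.
#' @param row_star Design row (same whitening), numeric length L.
#' @param cfg A [kalman_config()].
#' @return The updated `kalman_state`.
#' @export
kf_update <- function(state, y_star, row_star, cfg) {
  stopifnot(inherits(state, "kalman_state"), inherits(cfg, "kalman_config"))
  h <- as.numeric(row_star)
  if (length(h) != state$n_regressors) {
    stop("design row has wrong length", call. = FALSE)
  }
  if (!is.finite(y_star) || !all(is.finite(h))) {
    stop(sprintf("non-finite input at step %d", state$k + 1L), call. = FALSE)
  }
  P <- state$p_cov
  Ph <- P %*% h
  E <- sum(h * Ph) + cfg$r
  K <- Ph / E
  innov <- y_star - sum(h * state$x_hat)
  x <- state$x_hat + as.numeric(K) * innov
  P <- P - tcrossprod(as.numeric(K), as.numeric(Ph))
  state$p_cov <- (P + t(P)) / 2
  state$x_hat <- x
  state$gram <- state$gram + tcrossprod(h)
  state$sxy <- state$sxy + h * y_star
  state$syy <- state$syy + y_star^2
  state$rss <- max(
    0,
    state$syy - 2 * sum(x * state$sxy) + sum(x * (state$gram %*% x))
  )
  state$k <- state$k + 1L
  state
}

#' Advance all channels by one time step
#'
#' Applies (optionally) the AR(1) whitening, then the predict and update
#' steps, independently to every channel. Channels share the design row but
#' are otherwise uncoupled.
#'
#' @param states List of per-channel `kalman_state`s.
#' @param y_vec Numeric vector, one measurement per channel (uM).
#' @param row Shared design row H(k).
#' @param cfg A [kalman_config()].
#' @param ar_states Optional list of per-channel [ar_init()] states; when
#'   supplied, each pair is whitened before the update and the rho estimate
#'   is refreshed from the post-update raw-scale residual.
#' @return List with updated `states` and `ar_states`.
#' @export
kf_step_channels <- function(states, y_vec, row, cfg, ar_states = NULL) {
  nc <- length(states)
  if (length(y_vec) != nc) {
    stop("channel count mismatch between states and measurements", call. = FALSE)
  }
  if (!is.null(ar_states) && length(ar_states) != nc) {
    stop("channel count mismatch between states and AR states", call. = FALSE)
  }
  for (i in seq_len(nc)) {
    y <- y_vec[i]
    h <- row
    if (!is.null(ar_states)) {
      w <- ar_whiten(ar_states[[i]], y, row)
      y <- w$y_star
      h <- w$row_star
      ar_states[[i]] <- w$state
    }
    st <- kf_predict(states[[i]], cfg)
    st <- kf_update(st, y, h, cfg)
    states[[i]] <- st
    if (!is.null(ar_states)) {
      resid <- y_vec[i] - sum(row * st$x_hat)
      ar_states[[i]] <- ar_update_rho(ar_states[[i]], resid)
    }
  }
  list(states = states, ar_states = ar_states)
}

#' Run the full recursive estimator over one channel's series
#'
#' Streaming driver used by the pipeline: for each time step it whitens the
#' measurement/design-row pair (if enabled), performs the Kalman predict and
#' update, refreshes the AR(1) coefficient from the raw-scale residual, and
#' (optionally) evaluates the running t-statistic of a contrast. The
#' estimate at step k uses only samples 1..k.
#'
#' @param y Numeric vector of measurements (uM), length n.
#' @param H Design matrix, n x L.
#' @param cfg A [kalman_config()].
#' @param ar Logical: enable AR(1) prewhitening (default TRUE).
#' @param ar_burn_in,ar_fixed_rho Passed to [ar_init()].
#' @param contrast Contrast vector over regressors; default selects the
#'   first (task) coefficient.
#' @param keep `"all"` stores per-step trajectories of coefficients,
#'   t-statistics and innovations; `"final"` stores only the last step
#'   (fast path for simulation studies).
#' @return A list with `state` (final `kalman_state`), `rho` (final AR
#'   estimate), `t`, `dof`, `beta` (final values), and with `keep = "all"`
#'   the matrices/vectors `beta_traj` (n x L), `t_traj`, `dof_traj`,
#'   `innovations`, `rho_traj` (NA where not yet testable).
#' @export
kf_filter <- function(y, H, cfg = kalman_config(), ar = TRUE,
                      ar_burn_in = 30L, ar_fixed_rho = NULL,
                      contrast = NULL, keep = c("all", "final")) {
  keep <- match.arg(keep)
  H <- as.matrix(H)
  n <- length(y)
  stopifnot(nrow(H) == n)
  L <- ncol(H)
  if (is.null(contrast)) contrast <- c(1, numeric(L - 1L))
  stopifnot(length(contrast) == L, any(contrast != 0))
  if (!all(is.finite(y)) || !all(is.finite(H))) {
    stop(sprintf(
      "non-finite input at step %d",
      which(!is.finite(y) | rowSums(!is.finite(H)) > 0)[1L]
    ), call. = FALSE)
  }

  q <- cfg$q
  r <- cfg$r
  P <- diag(cfg$p0, L)
  x <- if (is.null(cfg$x0)) numeric(L) else cfg$x0
  G <- matrix(0, L, L)
  sxy <- numeric(L)
  syy <- 0
  rho <- if (is.null(ar_fixed_rho)) 0 else ar_fixed_rho
  fixed <- !is.null(ar_fixed_rho)
  s_cross <- 0
  s_lag <- 0
  prev_resid <- NA_real_
  prev_y <- NA_real_
  prev_h <- NULL

  store <- keep == "all"
  if (store) {
    beta_traj <- matrix(NA_real_, n, L)
    t_traj <- rep(NA_real_, n)
    dof_traj <- rep(NA_integer_, n)
    innovations <- rep(NA_real_, n)
    rho_traj <- rep(NA_real_, n)
  }

  for (k in seq_len(n)) {
    hraw <- H[k, ]
    if (ar && !is.na(prev_y)) {
      ys <- y[k] - rho * prev_y
      h <- hraw - rho * prev_h
    } else {
      ys <- y[k]
      h <- hraw
    }
    prev_y <- y[k]
    prev_h <- hraw
    # predict
    if (q > 0) diag(P) <- diag(P) + q
    # update
    Ph <- as.numeric(P %*% h)
    E <- sum(h * Ph) + r
    K <- Ph / E
    innov <- ys - sum(h * x)
    x <- x + K * innov
    P <- P - tcrossprod(K, Ph)
    P <- (P + t(P)) / 2
    G <- G + tcrossprod(h)
    sxy <- sxy + h * ys
    syy <- syy + ys * ys
    # AR(1) coefficient from the raw-scale residual
    if (ar) {
      resid <- y[k] - sum(hraw * x)
      if (!is.na(prev_resid)) {
        s_cross <- s_cross + resid * prev_resid
        s_lag <- s_lag + prev_resid^2
      }
      prev_resid <- resid
      if (!fixed && k >= ar_burn_in && s_lag > 0) {
        rho <- max(-0.99, min(0.99, s_cross / s_lag))
      }
    }
    if (store) {
      beta_traj[k, ] <- x
      innovations[k] <- innov
      rho_traj[k] <- rho
      if (k > L) {
        tt <- .t_from_suffstats(x, G, sxy, syy, k, L, contrast)
        t_traj[k] <- tt$t
        dof_traj[k] <- tt$dof
      }
    }
  }

  state <- structure(
    list(
      x_hat = x, p_cov = P, k = n, gram = G, sxy = sxy, syy = syy,
      rss = max(0, syy - 2 * sum(x * sxy) + sum(x * (G %*% x))),
      n_regressors = L
    ),
    class = "kalman_state"
  )
  final_t <- if (n > L) .t_from_suffstats(x, G, sxy, syy, n, L, contrast) else
    list(t = NA_real_, dof = NA_integer_)
  out <- list(
    state = state, rho = rho, beta = x,
    t = final_t$t, dof = final_t$dof
  )
  if (store) {
    colnames(beta_traj) <- colnames(H)
    out$beta_traj <- beta_traj
    out$t_traj <- t_traj
    out$dof_traj <- dof_traj
    out$innovations <- innovations
    out$rho_traj <- rho_traj
  }
  out
}

# t-statistic from running sufficient statistics; NA when gram is singular
.t_from_suffstats <- function(x, G, sxy, syy, k, L, contrast) {
  dof <- k - L
  if (dof < 1L) {
    return(list(t = NA_real_, dof = NA_integer_))
  }
  Ginv_c <- tryCatch(solve(G, contrast), error = function(e) NULL)
  if (is.null(Ginv_c)) {
    return(list(t = NA_real_, dof = NA_integer_))
  }
  rss <- max(0, syy - 2 * sum(x * sxy) + sum(x * (G %*% x)))
  sigma2 <- rss / dof
  denom <- sqrt(sigma2 * sum(contrast * Ginv_c))
  tval <- if (denom > 0) sum(contrast * x) / denom else NA_real_
  list(t = tval, dof = as.integer(dof))
}

#' Vectorized multi-channel filter for a shared design (no whitening)
#'
#' When prewhitening is disabled, every channel sees the same design row at
#' each step, so the covariance, gain and Gram matrix are identical across
#' channels and the coefficient updates vectorize: this computes exactly the
#' same recursion as [kf_filter()] channel by channel, in one pass.
#'
#' @param Y Matrix of measurements, n x n_channels.
#' @param H Design matrix, n x L.
#' @param cfg A [kalman_config()].
#' @param contrast Contrast vector (default first coefficient).
#' @return A list with `beta` (L x n_channels final coefficients), `t`,
#'   `dof`, `rss` (per channel), and `gram`.
#' @export
kf_filter_matrix <- function(Y, H, cfg = kalman_config(), contrast = NULL) {
  Y <- as.matrix(Y)
  H <- as.matrix(H)
  n <- nrow(Y)
  stopifnot(nrow(H) == n)
  L <- ncol(H)
  nc <- ncol(Y)
  if (is.null(contrast)) contrast <- c(1, numeric(L - 1L))
  q <- cfg$q
  r <- cfg$r
  P <- diag(cfg$p0, L)
  X <- matrix(if (is.null(cfg$x0)) 0 else cfg$x0, L, nc)
  G <- matrix(0, L, L)
  SXY <- matrix(0, L, nc)
  syy <- numeric(nc)
  for (k in seq_len(n)) {
    h <- H[k, ]
    if (q > 0) diag(P) <- diag(P) + q
    Ph <- as.numeric(P %*% h)
    E <- sum(h * Ph) + r
    K <- Ph / E
    innov <- Y[k, ] - as.numeric(crossprod(X, h)) # length nc
    X <- X + tcrossprod(K, innov)
    P <- P - tcrossprod(K, Ph)
    P <- (P + t(P)) / 2
    G <- G + tcrossprod(h)
    SXY <- SXY + tcrossprod(h, Y[k, ])
    syy <- syy + Y[k, ]^2
  }
  dof <- n - L
  rss <- pmax(0, syy - 2 * colSums(X * SXY) + colSums(X * (G %*% X)))
  tvals <- rep(NA_real_, nc)
  if (dof >= 1L) {
    Ginv_c <- tryCatch(solve(G, contrast), error = function(e) NULL)
    if (!is.null(Ginv_c)) {
      se <- sqrt((rss / dof) * sum(contrast * Ginv_c))
      tvals <- ifelse(se > 0, as.numeric(crossprod(X, contrast)) / se, NA_real_)
    }
  }
  list(beta = X, t = tvals, dof = as.integer(dof), rss = rss, gram = G)
}
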