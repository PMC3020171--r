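#' Initialize AR(1) prewhitening state
#'
#' Serial correlation in the regression error inflates t-values. The error
#' is modeled as an AR(1) process and both the measurement and the design
#' row are differenced by the running estimate of the lag-1 autocorrelation
#' coefficient rho before each filter update. While fewer than `burn_in`
#' residuals have been seen, the transform is the identity (rho reads 0).
#'
#' @param burn_in Number of residuals to accumulate before whitening
#'   activates (default 30).
#' @param fixed_rho Optional: freeze rho at this value (e.g. from training
#'   data) instead of estimating it online.
#' @return An object of class `ar_state`.
#' @export
ar_init <- function(burn_in = 30L, fixed_rho = NULL) {
  if (!is.null(fixed_rho)) {
    stopifnot(is.numeric(fixed_rho), abs(fixed_rho) < 1)
  }
  structure(
    list(
      rho = if (is.null(fixed_rho)) 0 else fixed_rho,
      fixed = !is.null(fixed_rho),
      burn_in = as.integer(burn_in),
      n_resid = 0L,
      prev_resid = NA_real_,
      s_cross = 0, # sum e(k) e(k-1)
      s_lag = 0, # sum e(k-1)^2
      prev_y = NA_real_,
      prev_row = NULL
    ),
    class = "ar_state"
  )
}

#' Update the running autocorrelation estimate from a residual
#'
#' Accumulates the lag-1 residual autocorrelation
#' `rho = sum e(k) e(k-1) / sum e(k-1)^2`, clipped to `[-0.99, 0.99]` to
#' keep the AR transform invertible. The exposed `rho` stays at its initial
#' value until `burn_in` residuals have been seen, and is never updated when
#' the state was created with `fixed_rho`. A degenerate zero-variance
#' residual stream leaves rho unchanged.
#'
#' @param state An [ar_init()] state.
#' @param residual Current-step regression residual `y(k) - H(k) %*% beta(k)`
#'   on the raw (unwhitened) scale, in uM.
#' @return The updated `ar_state`.
#' @export
ar_update_rho <- function(state, residual) {
  stopifnot(inherits(state, "ar_state"), is.numeric(residual))
  if (!is.na(state$prev_resid)) {
    state$s_cross <- state$s_cross + residual * state$prev_resid
    state$s_lag <- state$s_lag + state$prev_resid^2
  }
  state$prev_resid <- residual
  state$n_resid <- state$n_resid + 1L
  if (!state$fixed && state$n_resid >= state$burn_in && state$s_lag > 0) {
    state$rho <- max(-0.99, min(0.99, state$s_cross / state$s_lag))
  }
  state
}

#' Apply the AR(1) whitening transform to a measurement/design-row pair
#'
#' Returns `y*(k) = y(k) - rho * y(k-1)` and `H*(k) = H(k) - rho * H(k-1)`.
#' The first sample of a stream has no predecessor and passes through
#' unchanged. The untransformed pair is stored for the next call.
#'
#' @param state An [ar_init()] state.
#' @param y Measurement at the current step, uM.
#' @param row Design row H(k), numeric vector of length L.
#' @return List with `y_star`, `row_star`, and the updated `state`.
#' @export
ar_whiten <- function(state, y, row) {
  stopifnot(inherits(state, "ar_state"), is.numeric(y), length(y) == 1L)
  if (!is.null(state$prev_row) && length(state$prev_row) != length(row)) {
    stop("design row length changed mid-stream", call. = FALSE)
  }
  if (is.na(state$prev_y)) {
    y_star <- y
    row_star <- row
  } else {
    y_star <- y - state$rho * state$prev_y
    row_star <- row - state$rho * state$prev_row
  }
  state$prev_y <- y
  state$prev_row <- row
  list(y_star = y_star, row_star = row_star, state = state)
}
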