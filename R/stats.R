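#' Contrast specification
#'
#' @param c Contrast vector over the L regressors; the default (built by
#'   callers when `NULL`) selects the first coefficient, i.e. the task
#'   response. The test is one-tailed for positive contrast values: a task
#'   coefficient significantly greater than zero indicates activation.
#' @param n_regressors Length to build a default contrast for.
#' @return Numeric contrast vector.
#' @export
task_contrast <- function(n_regressors, c = NULL) {
  if (is.null(c)) c <- c(1, numeric(n_regressors - 1L))
  stopifnot(length(c) == n_regressors, any(c != 0))
  c
}

#' Running t-statistic of a contrast from a Kalman state
#'
#' Computes `t = c' beta / sqrt(sigma2 * c' Gram^-1 c)` where `sigma2` is
#' the residual sum of squares of the current coefficients over all k
#' samples seen, divided by the degrees of freedom `k - L`. Before the
#' degrees of freedom are positive, or while the Gram matrix is singular,
#' the channel is not yet testable and `t` is `NA` (no error: the streaming
#' loop simply keeps going).
#'
#' @param state A `kalman_state` (see [kf_init()], [kf_update()]).
#' @param contrast Contrast vector of length L; default selects the first
#'   (task) coefficient.
#' @return A list with `t`, `dof`, and `testable` (logical).
#' @examples
#' # after k updates of a 5-regressor model, dof = k - 5
#' @export
t_statistic <- function(state, contrast = NULL) {
  stopifnot(inherits(state, "kalman_state"))
  L <- state$n_regressors
  contrast <- task_contrast(L, contrast)
  res <- .t_from_suffstats(
    state$x_hat, state$gram, state$sxy, state$syy, state$k, L, contrast
  )
  res$testable <- !is.na(res$t)
  res
}

#' Bonferroni-corrected per-test threshold
#'
#' For j tests at individual level `p_in`, the corrected per-test threshold
#' is `p_b = (1 - (1 - p_in)^j) / j`. For a single test it equals `p_in`,
#' and it decreases strictly as the number of tests grows.
#'
#' @param p_in Individual-test p-value threshold, in (0, 1).
#' @param j Number of tests (>= 1).
#' @return The corrected threshold `p_b`.
#' @examples
#' bonferroni_threshold(0.05, 1) # 0.05
#' bonferroni_threshold(0.05, 2) # 0.04875
#' @export
bonferroni_threshold <- function(p_in, j) {
  stopifnot(is.numeric(p_in), all(p_in > 0), all(p_in < 1))
  if (any(j < 1)) stop("j must be >= 1", call. = FALSE)
  (1 - (1 - p_in)^j) / j
}

#' Initialize a per-channel activation map
#'
#' @param n_channels Number of channels.
#' @param p_in Individual-test p-value threshold (default 0.05).
#' @param j_policy How the Bonferroni test count j grows: `"cumulative"`
#'   (channels x testable steps so far; conservative, accounts for the
#'   cumulative type-I error of testing at every time step) or `"per_step"`
#'   (channel count only).
#' @param sampling_rate_hz Sampling rate, used to express detection times in
#'   seconds.
#' @return An object of class `activation_map`.
#' @export
activation_map_init <- function(n_channels, p_in = 0.05,
                                j_policy = c("cumulative", "per_step"),
                                sampling_rate_hz = 1.81) {
  j_policy <- match.arg(j_policy)
  structure(
    list(
      n_channels = as.integer(n_channels),
      p_in = p_in,
      j_policy = j_policy,
      sampling_rate_hz = sampling_rate_hz,
      n_testable_steps = 0L,
      k = 0L,
      t_values = rep(NA_real_, n_channels),
      dof = rep(NA_integer_, n_channels),
      p_uncorrected = rep(NA_real_, n_channels),
      p_threshold_corrected = NA_real_,
      active = rep(FALSE, n_channels),
      first_active_time_s = rep(NA_real_, n_channels),
      first_active_time_uncorrected_s = rep(NA_real_, n_channels)
    ),
    class = "activation_map"
  )
}

#' Update the activation map with the current step's t-statistics
#'
#' Converts each testable channel's t-value to an upper-tail p-value of the
#' t-distribution with its degrees of freedom, derives the Bonferroni test
#' count j under the configured policy, marks channels with
#' `p <= bonferroni_threshold(p_in, j)` active, and records first-crossing
#' times (both corrected and uncorrected); once recorded, a first-crossing
#' time is never unset.
#'
#' @param map An [activation_map_init()] object.
#' @param t_values Numeric vector of per-channel t-statistics (NA where not
#'   yet testable).
#' @param dof Integer vector of per-channel degrees of freedom.
#' @param k Current 0-based time step (detection time is `k /
#'   sampling_rate_hz` seconds).
#' @return The updated `activation_map`.
#' @export
activation_map_update <- function(map, t_values, dof, k) {
  stopifnot(inherits(map, "activation_map"))
  stopifnot(length(t_values) == map$n_channels, length(dof) == map$n_channels)
  map$k <- as.integer(k)
  testable <- !is.na(t_values) & !is.na(dof) & dof >= 1L
  map$t_values <- t_values
  map$dof <- dof
  p <- rep(NA_real_, map$n_channels)
  p[testable] <- stats::pt(t_values[testable], dof[testable], lower.tail = FALSE)
  map$p_uncorrected <- p
  if (any(testable)) {
    map$n_testable_steps <- map$n_testable_steps + 1L
    j <- switch(map$j_policy,
      per_step = map$n_channels,
      cumulative = map$n_channels * map$n_testable_steps
    )
    p_b <- bonferroni_threshold(map$p_in, j)
    map$p_threshold_corrected <- p_b
    now_active <- testable & !is.na(p) & p <= p_b
    map$active <- now_active
    t_s <- k / map$sampling_rate_hz
    newly <- now_active & is.na(map$first_active_time_s)
    map$first_active_time_s[newly] <- t_s
    newly_un <- testable & !is.na(p) & p <= map$p_in &
      is.na(map$first_active_time_uncorrected_s)
    map$first_active_time_uncorrected_s[newly_un] <- t_s
  }
  map
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf(
    "<activation_map> %d channels @ step %d (j_policy %s, p_in %g)\n",
    x$n_channels, x$k, x$j_policy, x$p_in
  ))
  cat(sprintf(
    "  active: %s\n",
    if (any(x$active)) toString(which(x$active)) else "none"
  ))
  invisible(x)
}

#' Activation map as a tibble
#'
#' @param x An `activation_map`.
#' @param ... Unused.
#' @return One row per channel: t, dof, uncorrected p, active flag, first
#'   crossing times (corrected and uncorrected) in seconds.
#' @method tidy activation_map
#' @export
tidy.activation_map <- function(x, ...) {
  tibble::tibble(
    channel = seq_len(x$n_channels),
    t = x$t_values,
    dof = x$dof,
    p_uncorrected = x$p_uncorrected,
    active = x$active,
    first_active_time_s = x$first_active_time_s,
    first_active_time_uncorrected_s = x$first_active_time_uncorrected_s
  )
}
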