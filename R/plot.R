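#' Plot per-channel t-statistic trajectories of a fit
#'
#' @param object A [nirs_fit()] fitted with `keep_trajectories = TRUE`.
#' @param what `"t"` (default) or `"beta1"`.
#' @param ... Unused.
#' @return A ggplot: one line per channel over time, with the uncorrected
#'   one-tailed critical value drawn for reference when plotting t.
#' @method autoplot nirs_fit
#' @export
autoplot.nirs_fit <- function(object, what = c("t", "beta1"), ...) {
  what <- match.arg(what)
  if (is.null(object$trajectories)) {
    stop("fit was run with keep_trajectories = FALSE", call. = FALSE)
  }
  df <- dplyr::filter(object$trajectories, !is.na(.data[[what]]))
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$time_s, y = .data[[what]],
      group = .data$channel, colour = factor(.data$channel)
    )
  ) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = "time (s)",
      y = if (what == "t") "t-statistic" else expression(hat(beta)[1] ~ (mu * M)),
      colour = "channel"
    ) +
    ggplot2::theme_minimal()
  if (what == "t") {
    crit <- stats::qt(object$p_in, df = max(object$n_samples -
      object$design$n_regressors, 1), lower.tail = FALSE)
    p <- p + ggplot2::geom_hline(yintercept = crit, linetype = "dashed")
  }
  p
}

#' Plot simulated channels
#'
#' @param object A [nirs_simulate()] result.
#' @param channels Channels to draw (default: up to 6).
#' @param ... Unused.
#' @return A ggplot of the HbO series, faceted by channel.
#' @method autoplot nirs_sim
#' @export
autoplot.nirs_sim <- function(object, channels = NULL, ...) {
  if (is.null(channels)) {
    channels <- utils::head(unique(object$data$channel), 6L)
  }
  df <- dplyr::filter(object$data, .data$channel %in% channels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$hbo)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = expression(Delta * HbO ~ (mu * M))) +
    ggplot2::theme_minimal()
}

#' Topographic activation map at a snapshot
#'
#' Draws per-channel t-values on a probe layout. The layout drives plotting
#' only; the analysis itself is layout-agnostic.
#'
#' @param fit A [nirs_fit()].
#' @param layout A data frame with columns `channel`, `x`, `y` (and
#'   optionally `label`).
#' @param snapshot Name of a stored snapshot (see `snapshot_times_s` in
#'   [nirs_fit()]); default uses the final map.
#' @return A ggplot: channels placed at their layout coordinates, colored by
#'   t-value, active channels outlined.
#' @export
plot_activation_map <- function(fit, layout, snapshot = NULL) {
  stopifnot(inherits(fit, "nirs_fit"))
  map <- if (is.null(snapshot)) tidy(fit$map) else fit$snapshots[[snapshot]]
  if (is.null(map)) stop("unknown snapshot '", snapshot, "'", call. = FALSE)
  df <- dplyr::left_join(map, tibble::as_tibble(layout), by = "channel")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(
      ggplot2::aes(fill = .data$t, stroke = ifelse(.data$active, 1.5, 0.2)),
      shape = 21, size = 8
    ) +
    ggplot2::geom_text(ggplot2::aes(label = .data$channel), size = 3) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "t") +
    ggplot2::theme_void()
}
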