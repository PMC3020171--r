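#' Read an analysis configuration from YAML
#'
#' The configuration mirrors the function arguments: `protocol`
#' (preparation_s, n_sessions, task_s, rest_s, sampling_rate_hz), `mbll`
#' (wavelengths_nm, distance_mm, dpf, reference_index), `hrf`, `design`
#' (n_dct or dct_cutoff_hz), `kalman` (q, r, p0), `ar` (enabled, burn_in,
#' fixed_rho), `test` (p_in, j_policy).
#'
#' @param path Path to a YAML file; see
#'   `system.file("extdata", "example-config.yaml", package = "nirstream")`.
#' @return A named list with parsed component objects: `protocol`,
#'   `constants` (when mbll distance is present), `hrf`, and the raw lists.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(raw = cfg)
  if (!is.null(cfg$protocol)) {
    out$protocol <- do.call(nirs_protocol, cfg$protocol)
  }
  if (!is.null(cfg$hrf)) {
    out$hrf <- do.call(hrf_params, cfg$hrf)
  } else {
    out$hrf <- hrf_params()
  }
  if (!is.null(cfg$mbll) && !is.null(cfg$mbll$distance_mm)) {
    out$constants <- optical_constants(
      distance_mm = cfg$mbll$distance_mm,
      wavelengths_nm = cfg$mbll$wavelengths_nm %||% c(760, 830),
      dpf = cfg$mbll$dpf %||% c(6, 6)
    )
  }
  k <- cfg$kalman %||% list()
  out$kalman <- kalman_config(
    q = as.numeric(k$q %||% 1e-4),
    r = as.numeric(k$r %||% 0.25),
    p0 = as.numeric(k$p0 %||% 1e4)
  )
  out$ar <- list(
    enabled = cfg$ar$enabled %||% TRUE,
    burn_in = cfg$ar$burn_in %||% 30L,
    fixed_rho = cfg$ar$fixed_rho
  )
  out$test <- list(
    p_in = cfg$test$p_in %||% 0.05,
    j_policy = cfg$test$j_policy %||% "cumulative"
  )
  out$design <- list(
    n_dct = cfg$design$n_dct %||% 3L,
    dct_cutoff_hz = cfg$design$dct_cutoff_hz
  )
  out
}

#' Write the result files of a fit
#'
#' Writes `detection.csv` (per-channel detection times), `estimates.csv`
#' (final per-channel summary), `trajectories.csv` (when kept), one
#' `map_<time>.csv` per snapshot, and `metadata.json` (settings and
#' package version). Output is deterministic for a deterministic fit.
#'
#' @param fit A [nirs_fit()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(fit, dir) {
  stopifnot(inherits(fit, "nirs_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  paths <- c(paths, wr(tidy(fit), "estimates.csv"))
  paths <- c(paths, wr(fit$detection, "detection.csv"))
  if (!is.null(fit$trajectories)) {
    paths <- c(paths, wr(fit$trajectories, "trajectories.csv"))
  }
  for (nm in names(fit$snapshots)) {
    paths <- c(paths, wr(fit$snapshots[[nm]], paste0("map_", nm, ".csv")))
  }
  meta <- list(
    package = "nirstream",
    version = as.character(utils::packageVersion("nirstream")),
    n_samples = fit$n_samples,
    n_channels = fit$n_channels,
    n_regressors = fit$design$n_regressors,
    kalman = fit$config[c("q", "r", "p0")],
    ar = fit$ar,
    p_in = fit$p_in,
    j_policy = fit$j_policy
  )
  mp <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, mp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
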