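#' Default physiological oscillation set
#'
#' Cardiac, respiratory and Mayer-wave sinusoids commonly visible in NIRS
#' series. At the 1.81 Hz sampling rate of the reference protocol the
#' cardiac component is above Nyquist and aliases; it is kept deliberately
#' to exercise realistic aliasing.
#'
#' @return A tibble with columns `frequency_hz`, `amplitude_um`, `phase`.
#' @export
physio_defaults <- function() {
  tibble::tibble(
    source = c("cardiac", "respiratory", "mayer"),
    frequency_hz = c(1.1, 0.3, 0.1),
    amplitude_um = c(0.15, 0.1, 0.2),
    phase = c(0, 0, 0)
  )
}

#' Default very-low-frequency drift specification
#'
#' A slow sinusoid (0.002 Hz, i.e. ~1.1 cycles over the 552 s reference
#' record, producing a visible baseline shift) plus a small random walk
#' standing in for optode-shift drift.
#'
#' @param sine_amplitude_um,sine_freq_hz,sine_phase Sinusoid component.
#' @param rw_sd_um Per-step standard deviation of the random-walk component.
#' @return A list drift specification accepted by [nirs_simulate()].
#' @export
drift_defaults <- function(sine_amplitude_um = 0.5, sine_freq_hz = 0.002,
                           sine_phase = pi / 2, rw_sd_um = 0.01) {
  list(
    sine_amplitude_um = sine_amplitude_um,
    sine_freq_hz = sine_freq_hz,
    sine_phase = sine_phase,
    rw_sd_um = rw_sd_um
  )
}

#' Simulate multichannel block-design NIRS data with known ground truth
#'
#' Per channel, the HbO concentration-change series is the exact sum of
#' stated components: `amplitude * (stimulus (x) double-gamma kernel)` for
#' active channels, the physiological sinusoids, the drift, and AR(1)
#' measurement noise `e(k) = ar_rho * e(k-1) + w(k)` with white innovations
#' `w ~ N(0, noise_sd_um^2)` (stationary initialization). Output is
#' bit-reproducible under `seed`.
#'
#' @param protocol A [nirs_protocol()] (default: the 42 s + 10 x (21 s +
#'   30 s) reference protocol at 1.81 Hz).
#' @param n_channels Number of channels (default 24).
#' @param active_channels Channels carrying a true task response.
#' @param amplitude_um True response amplitude in uM for active channels
#'   (recycled).
#' @param noise_sd_um Innovation standard deviation of the measurement
#'   noise, uM.
#' @param ar_rho AR(1) coefficient of the measurement noise, |rho| < 1.
#' @param physio Data frame of sinusoids (`frequency_hz`, `amplitude_um`,
#'   `phase`), [physio_defaults()], or `NULL` for none.
#' @param drift A [drift_defaults()] list or `NULL` for none.
#' @param hrf [hrf_params()] used for the true response shape.
#' @param seed Integer RNG seed; `NULL` uses the current RNG state.
#' @return An object of class `nirs_sim`: list with `data` (long tibble:
#'   `time_s`, `channel`, `hbo`), `truth` (tibble: `channel`, `beta1`,
#'   `active`), `components` (list of n x n_channels matrices summing
#'   exactly to the signal), `protocol`, `seed`.
#' @examples
#' sim <- nirs_simulate(n_channels = 4, active_channels = 2, seed = 1,
#'                      physio = NULL, drift = NULL)
#' sim$truth
#' @export
nirs_simulate <- function(protocol = nirs_protocol(), n_channels = 24,
                          active_channels = if (n_channels >= 6) 6 else 1,
                          amplitude_um = 1.0,
                          noise_sd_um = 0.5, ar_rho = 0,
                          physio = physio_defaults(),
                          drift = drift_defaults(),
                          hrf = hrf_params(), seed = NULL) {
  stopifnot(inherits(protocol, "nirs_protocol"), n_channels >= 1)
  active_channels <- as.integer(active_channels)
  if (length(active_channels) && (any(active_channels < 1) ||
    any(active_channels > n_channels))) {
    stop("active_channels outside the channel set", call. = FALSE)
  }
  stopifnot(all(amplitude_um >= 0), noise_sd_um >= 0, abs(ar_rho) < 1)
  amp <- numeric(n_channels)
  amp[active_channels] <- rep_len(amplitude_um, length(active_channels))

  n <- protocol$n_samples
  tt <- protocol_times(protocol)
  stim <- stimulus_vector(protocol)
  kern <- double_gamma_kernel(hrf, protocol$sampling_rate_hz)
  response <- .causal_convolve(as.numeric(stim), kern)[seq_len(n)]

  gen <- function() {
    task <- outer(response, amp)
    phys <- matrix(0, n, n_channels)
    if (!is.null(physio) && nrow(as.data.frame(physio)) > 0) {
      ph <- as.data.frame(physio)
      wave <- rowSums(vapply(
        seq_len(nrow(ph)),
        function(i) {
          ph$amplitude_um[i] * sin(2 * pi * ph$frequency_hz[i] * tt + ph$phase[i])
        },
        numeric(n)
      ))
      phys <- matrix(wave, n, n_channels)
    }
    dr <- matrix(0, n, n_channels)
    if (!is.null(drift)) {
      sine <- drift$sine_amplitude_um *
        sin(2 * pi * drift$sine_freq_hz * tt + drift$sine_phase)
      dr <- matrix(sine, n, n_channels)
      if (drift$rw_sd_um > 0) {
        dr <- dr + apply(
          matrix(stats::rnorm(n * n_channels, 0, drift$rw_sd_um), n), 2, cumsum
        )
      }
    }
    noise <- matrix(0, n, n_channels)
    if (noise_sd_um > 0) {
      w <- matrix(stats::rnorm(n * n_channels, 0, noise_sd_um), n)
      if (ar_rho != 0) {
        marg <- noise_sd_um / sqrt(1 - ar_rho^2)
        init <- stats::rnorm(n_channels, 0, marg)
        noise <- vapply(
          seq_len(n_channels),
          function(j) {
            as.numeric(stats::filter(w[, j], ar_rho,
              method = "recursive", init = init[j]
            ))
          },
          numeric(n)
        )
      } else {
        noise <- w
      }
    }
    list(task = task, physio = phys, drift = dr, noise = noise)
  }
  comps <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  hbo <- comps$task + comps$physio + comps$drift + comps$noise

  data <- tibble::tibble(
    time_s = rep(tt, n_channels),
    channel = rep(seq_len(n_channels), each = n),
    hbo = as.numeric(hbo)
  )
  structure(
    list(
      data = data,
      truth = tibble::tibble(
        channel = seq_len(n_channels),
        beta1 = amp,
        active = amp > 0
      ),
      components = comps,
      protocol = protocol,
      seed = seed
    ),
    class = "nirs_sim"
  )
}

#' @export
print.nirs_sim <- function(x, ...) {
  nc <- length(unique(x$data$channel))
  cat(sprintf(
    "<nirs_sim> %d channels x %d samples (%g s @ %g Hz), active: %s\n",
    nc, x$protocol$n_samples, x$protocol$total_duration_s,
    x$protocol$sampling_rate_hz,
    if (any(x$truth$active)) toString(x$truth$channel[x$truth$active]) else "none"
  ))
  invisible(x)
}

#' Simulated HbO series as a channel matrix
#'
#' @param sim A [nirs_simulate()] result.
#' @return Numeric matrix, n_samples x n_channels.
#' @export
sim_channel_matrix <- function(sim) {
  stopifnot(inherits(sim, "nirs_sim"))
  with(sim$components, task + physio + drift + noise)
}

#' Simulate raw dual-wavelength intensities from a concentration simulation
#'
#' Couples a deoxy-hemoglobin series to the simulated HbO series
#' (`dHbR = hbr_ratio * dHbO`, conventional inverse coupling), maps both
#' through the forward Beer-Lambert model to optical density, and converts
#' to intensities `I(k) = I(0) * 10^(-dOD)`. Running [intensity_to_od()]
#' followed by [od_to_hemoglobin()] on the result recovers the simulated
#' concentrations relative to the reference (first) sample, for any
#' baseline intensity.
#'
#' @param sim A [nirs_simulate()] result.
#' @param constants An [optical_constants()] object.
#' @param baseline_intensity Intensity at the reference step (scalar or one
#'   per channel x wavelength column), arbitrary device units.
#' @param hbr_ratio HbR/HbO coupling ratio (default -0.3).
#' @return A tibble of intensities with columns `ch<i>_w<lambda>`.
#' @export
nirs_simulate_intensity <- function(sim, constants, baseline_intensity = 1,
                                    hbr_ratio = -0.3) {
  stopifnot(inherits(sim, "nirs_sim"), inherits(constants, "optical_constants"))
  hbo <- sim_channel_matrix(sim)
  nc <- ncol(hbo)
  cols <- list()
  for (ch in seq_len(nc)) {
    cols[[sprintf("ch%d_hbo", ch)]] <- hbo[, ch]
    cols[[sprintf("ch%d_hbr", ch)]] <- hbr_ratio * hbo[, ch]
  }
  od <- hemoglobin_to_od(tibble::as_tibble(cols), constants)
  inten <- purrr::map(od, function(x) 10^(-x))
  inten <- tibble::as_tibble(inten)
  for (j in seq_along(inten)) {
    inten[[j]] <- inten[[j]] * rep_len(baseline_intensity, ncol(inten))[j]
  }
  inten
}
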