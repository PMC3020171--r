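#' Double-gamma hemodynamic response parameters
#'
#' The canonical hemodynamic impulse response is modeled as a difference of
#' two gamma-shaped functions: a positive peak and a delayed undershoot
#' scaled down by `undershoot_ratio`. Gamma shapes are parameterized so the
#' mode of each component equals its delay (shape = 1 + delay/dispersion,
#' rate = 1/dispersion), i.e. the kernel peaks at `peak_delay_s`.
#'
#' @param peak_delay_s Time to peak of the positive lobe, seconds.
#' @param undershoot_delay_s Time to the undershoot trough, seconds.
#' @param peak_dispersion_s,undershoot_dispersion_s Width parameters, seconds.
#' @param undershoot_ratio Peak-to-undershoot amplitude ratio.
#' @param kernel_length_s Truncation length of the sampled kernel, seconds.
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                       peak_dispersion_s = 1, undershoot_dispersion_s = 1,
                       undershoot_ratio = 6, kernel_length_s = 32) {
  if (peak_dispersion_s <= 0 || undershoot_dispersion_s <= 0) {
    stop("hrf dispersions must be positive", call. = FALSE)
  }
  stopifnot(kernel_length_s > peak_delay_s, undershoot_ratio > 0)
  structure(
    list(
      peak_delay_s = peak_delay_s,
      undershoot_delay_s = undershoot_delay_s,
      peak_dispersion_s = peak_dispersion_s,
      undershoot_dispersion_s = undershoot_dispersion_s,
      undershoot_ratio = undershoot_ratio,
      kernel_length_s = kernel_length_s
    ),
    class = "hrf_params"
  )
}

#' Sampled double-gamma hemodynamic response kernel
#'
#' @param params An [hrf_params()] object.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return Numeric vector: the kernel sampled on `seq(0, kernel_length_s,
#'   by = 1/sampling_rate_hz)`, peak-normalized to a maximum of 1.
#' @examples
#' k <- double_gamma_kernel(hrf_params(), 10)
#' which.max(k) # near 6 s * 10 Hz
#' @export
double_gamma_kernel <- function(params = hrf_params(), sampling_rate_hz) {
  stopifnot(inherits(params, "hrf_params"), sampling_rate_hz > 0)
  tt <- seq(0, params$kernel_length_s, by = 1 / sampling_rate_hz)
  k <- .double_gamma(tt, params)
  k / max(k)
}

# unnormalized double-gamma evaluated at times tt (seconds)
.double_gamma <- function(tt, params) {
  peak <- stats::dgamma(tt,
    shape = 1 + params$peak_delay_s / params$peak_dispersion_s,
    rate = 1 / params$peak_dispersion_s
  )
  under <- stats::dgamma(tt,
    shape = 1 + params$undershoot_delay_s / params$undershoot_dispersion_s,
    rate = 1 / params$undershoot_dispersion_s
  )
  peak - under / params$undershoot_ratio
}

#' Discrete cosine transform high-pass regressor set
#'
#' Low-order DCT-II basis columns `c_r(k) = cos(pi * r * (2k + 1) / (2N))`,
#' r = 1..m, unit-normalized. These absorb very-low-frequency drifts when
#' included in the design matrix; column r oscillates at frequency
#' `r / (2 * T)` for a record of duration T seconds.
#'
#' The set size m is `n_terms` when given directly; with `cutoff_hz` it is
#' the number of DCT frequencies at or below the cutoff, but never below
#' `min_terms`.
#'
#' @param n_samples Number of time steps N (>= 2).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param n_terms Explicit number of columns (takes precedence).
#' @param cutoff_hz Alternative specification: include frequencies up to this
#'   cutoff.
#' @param min_terms Lower bound on the set size in cutoff mode.
#' @return Numeric matrix with `n_samples` rows and m columns, columns named
#'   `dct_1..dct_m`.
#' @export
dct_regressors <- function(n_samples, sampling_rate_hz, n_terms = NULL,
                           cutoff_hz = NULL, min_terms = 0L) {
  stopifnot(n_samples >= 2, sampling_rate_hz > 0)
  if (is.null(n_terms)) {
    if (is.null(cutoff_hz) || cutoff_hz <= 0) {
      stop("supply n_terms, or a positive cutoff_hz", call. = FALSE)
    }
    total_s <- n_samples / sampling_rate_hz
    m <- max(floor(2 * total_s * cutoff_hz), min_terms)
    if (m == 0) {
      stop(
        "cutoff_hz admits no DCT component over this record; ",
        "set n_terms or min_terms explicitly",
        call. = FALSE
      )
    }
  } else {
    m <- n_terms
  }
  stopifnot(m >= 1)
  k <- seq_len(n_samples) - 1
  cols <- vapply(
    seq_len(m),
    function(r) {
      v <- cos(pi * r * (2 * k + 1) / (2 * n_samples))
      v / sqrt(sum(v^2))
    },
    numeric(n_samples)
  )
  colnames(cols) <- paste0("dct_", seq_len(m))
  cols
}

#' Build the GLM design matrix for a block-design protocol
#'
#' Column 1 is the task regressor: the protocol's stimulus vector convolved
#' with the double-gamma hemodynamic kernel (causal convolution, truncated
#' to the record length). Column 2 is a constant baseline. The remaining
#' columns are the DCT high-pass set. With the default 3 DCT terms the
#' design has L = 5 regressors.
#'
#' @param protocol A [nirs_protocol()].
#' @param hrf An [hrf_params()] object.
#' @param n_dct Number of DCT drift regressors (default 3).
#' @param dct_cutoff_hz Alternative DCT specification, see [dct_regressors()].
#' @param min_dct Lower bound on the DCT set size in cutoff mode.
#' @return An object of class `nirs_design`: a list with `matrix`
#'   (n_samples x L), `regressor_names`, `n_regressors`, `protocol`, `hrf`.
#' @examples
#' d <- nirs_design(nirs_protocol())
#' d$n_regressors # 5
#' @export
nirs_design <- function(protocol, hrf = hrf_params(), n_dct = 3L,
                        dct_cutoff_hz = NULL, min_dct = 0L) {
  stopifnot(inherits(protocol, "nirs_protocol"))
  n <- protocol$n_samples
  stim <- stimulus_vector(protocol)
  kern <- double_gamma_kernel(hrf, protocol$sampling_rate_hz)
  task <- .causal_convolve(as.numeric(stim), kern)[seq_len(n)]
  dct <- dct_regressors(n, protocol$sampling_rate_hz,
    n_terms = if (is.null(dct_cutoff_hz)) n_dct else NULL,
    cutoff_hz = dct_cutoff_hz, min_terms = min_dct
  )
  H <- cbind(task = task, baseline = 1, dct)
  structure(
    list(
      matrix = H,
      regressor_names = colnames(H),
      n_regressors = ncol(H),
      protocol = protocol,
      hrf = hrf
    ),
    class = "nirs_design"
  )
}

# full (causal) discrete convolution, length N + K - 1; direct filtering
# rather than FFT so that zero runs (pre-onset causality) stay exactly zero
.causal_convolve <- function(x, k) {
  nk <- length(k)
  xp <- c(numeric(nk - 1L), x, numeric(nk - 1L))
  out <- stats::filter(xp, k, method = "convolution", sides = 1)
  as.numeric(out[-seq_len(nk - 1L)])
}

#' @export
print.nirs_design <- function(x, ...) {
  cat(sprintf(
    "<nirs_design> %d samples x %d regressors (%s)\n",
    nrow(x$matrix), x$n_regressors, paste(x$regressor_names, collapse = ", ")
  ))
  invisible(x)
}

#' Extract one design row
#'
#' @param design A [nirs_design()].
#' @param k 0-based time step.
#' @return Numeric vector of length L, the regressor row H(k).
#' @export
design_row <- function(design, k) {
  stopifnot(inherits(design, "nirs_design"))
  n <- nrow(design$matrix)
  if (length(k) != 1L || k < 0 || k >= n) {
    stop(sprintf("time step k=%s out of range [0, %d)", toString(k), n),
      call. = FALSE
    )
  }
  design$matrix[k + 1L, ]
}

#' Design matrix as a tibble
#'
#' @param x A [nirs_design()].
#' @param ... Unused.
#' @return A tibble with `time_s` and one column per regressor.
#' @method tidy nirs_design
#' @export
tidy.nirs_design <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$matrix)) |>
    dplyr::mutate(time_s = protocol_times(x$protocol), .before = 1L)
}
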