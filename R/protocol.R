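#' Define a block-design experimental protocol
#'
#' A protocol describes the timing of a block-design fNIRS experiment: a
#' preparation (baseline) period followed by `n_sessions` repetitions of a
#' task block and a rest block, all sampled at a fixed rate.
#'
#' @param preparation_s Seconds of baseline before the first task block.
#' @param n_sessions Number of task/rest sessions (>= 1).
#' @param task_s Task-block duration in seconds.
#' @param rest_s Rest-block duration in seconds.
#' @param sampling_rate_hz Sampling rate in Hz (> 0).
#'
#' @return An object of class `nirs_protocol`: a list with the arguments plus
#'   `total_duration_s` and `n_samples` (`round(total_duration_s *
#'   sampling_rate_hz)`).
#'
#' @examples
#' # 42 s preparation, then 10 sessions of 21 s finger tapping + 30 s rest,
#' # sampled at 1.81 Hz: a 552 s record.
#' p <- nirs_protocol(42, 10, 21, 30, 1.81)
#' p$total_duration_s
#' @export
nirs_protocol <- function(preparation_s = 42, n_sessions = 10, task_s = 21,
                          rest_s = 30, sampling_rate_hz = 1.81) {
  stopifnot(
    is.numeric(preparation_s), length(preparation_s) == 1L, preparation_s >= 0,
    is.numeric(n_sessions), length(n_sessions) == 1L, n_sessions >= 1,
    n_sessions == as.integer(n_sessions),
    is.numeric(task_s), length(task_s) == 1L, task_s >= 0,
    is.numeric(rest_s), length(rest_s) == 1L, rest_s >= 0,
    is.numeric(sampling_rate_hz), length(sampling_rate_hz) == 1L,
    sampling_rate_hz > 0
  )
  preparation_s <- as.numeric(preparation_s)
  task_s <- as.numeric(task_s)
  rest_s <- as.numeric(rest_s)
  sampling_rate_hz <- as.numeric(sampling_rate_hz)
  total <- preparation_s + n_sessions * (task_s + rest_s)
  if (total <= 0) {
    stop("invalid protocol: total duration is zero", call. = FALSE)
  }
  structure(
    list(
      preparation_s = preparation_s,
      n_sessions = as.integer(n_sessions),
      task_s = task_s,
      rest_s = rest_s,
      sampling_rate_hz = sampling_rate_hz,
      total_duration_s = total,
      n_samples = as.integer(round(total * sampling_rate_hz))
    ),
    class = "nirs_protocol"
  )
}

#' @export
print.nirs_protocol <- function(x, ...) {
  cat(sprintf(
    "<nirs_protocol> %g s preparation + %d x (%g s task + %g s rest) @ %g Hz\n",
    x$preparation_s, x$n_sessions, x$task_s, x$rest_s, x$sampling_rate_hz
  ))
  cat(sprintf("  total %g s, %d samples\n", x$total_duration_s, x$n_samples))
  invisible(x)
}

#' Sample times of a protocol
#'
#' @param protocol A [nirs_protocol()].
#' @return Numeric vector of sample times in seconds, `k / sampling_rate_hz`
#'   for 0-based step `k`.
#' @export
protocol_times <- function(protocol) {
  stopifnot(inherits(protocol, "nirs_protocol"))
  (seq_len(protocol$n_samples) - 1) / protocol$sampling_rate_hz
}

#' Binary stimulus vector for a block-design protocol
#'
#' Marks every sample falling inside a task block with 1 and every other
#' sample with 0. Block onsets/offsets are floored to sample indices and
#' blocks cover half-open intervals `[onset, offset)`, so block lengths are
#' deterministic.
#'
#' @inheritParams protocol_times
#' @return Integer vector of length `protocol$n_samples` with values 0/1.
#' @examples
#' s <- stimulus_vector(nirs_protocol())
#' sum(s) # task samples across the 10 sessions
#' @export
stimulus_vector <- function(protocol) {
  stopifnot(inherits(protocol, "nirs_protocol"))
  fs <- protocol$sampling_rate_hz
  stim <- integer(protocol$n_samples)
  session_s <- protocol$task_s + protocol$rest_s
  for (s in seq_len(protocol$n_sessions) - 1L) {
    onset <- protocol$preparation_s + s * session_s
    i0 <- floor(onset * fs)
    i1 <- floor((onset + protocol$task_s) * fs)
    if (i1 > i0) {
      idx <- seq.int(i0, i1 - 1L) + 1L
      idx <- idx[idx <= protocol$n_samples]
      stim[idx] <- 1L
    }
  }
  stim
}
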