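#' Default extinction coefficients for HbO and HbR
#'
#' Molar extinction coefficients of oxy- and deoxy-hemoglobin at the two
#' standard continuous-wave NIRS wavelengths, in uM^-1 mm^-1, derived from
#' the widely used compiled hemoglobin absorption tables. Override with a
#' device-specific table where available.
#'
#' @param wavelengths_nm Numeric vector of wavelengths to look up; only 760
#'   and 830 nm are tabulated here.
#' @return A tibble with columns `wavelength_nm`, `alpha_hbo`, `alpha_hbr`.
#' @export
extinction_defaults <- function(wavelengths_nm = c(760, 830)) {
  tab <- tibble::tibble(
    wavelength_nm = c(760, 830),
    alpha_hbo = c(5.86e-05, 9.74e-05),
    alpha_hbr = c(1.548e-04, 6.93e-05)
  )
  out <- tab[match(wavelengths_nm, tab$wavelength_nm), ]
  if (anyNA(out$alpha_hbo)) {
    stop("no default extinction coefficients for wavelength(s) ",
      toString(setdiff(wavelengths_nm, tab$wavelength_nm)),
      " nm; supply a table",
      call. = FALSE
    )
  }
  out
}

#' Optical constants for the modified Beer-Lambert law
#'
#' @param distance_mm Source-detector separation L in mm. No default: this
#'   is geometry of the probe and must be supplied.
#' @param wavelengths_nm The two laser wavelengths in nm.
#' @param extinction A data frame with columns `wavelength_nm`, `alpha_hbo`,
#'   `alpha_hbr` in uM^-1 mm^-1; defaults to [extinction_defaults()].
#' @param dpf Differential path length factor, one value per wavelength
#'   (recycled if scalar). Dimensionless; 6.0 is a common adult-head value.
#' @param max_condition Upper bound on the condition number of the 2x2
#'   extinction matrix.
#' @return An object of class `optical_constants`.
#' @export
optical_constants <- function(distance_mm, wavelengths_nm = c(760, 830),
                              extinction = extinction_defaults(wavelengths_nm),
                              dpf = c(6, 6), max_condition = 1e6) {
  if (missing(distance_mm) || !is.numeric(distance_mm) || distance_mm <= 0) {
    stop("distance_mm must be supplied and positive", call. = FALSE)
  }
  if (length(wavelengths_nm) != 2L) {
    stop("exactly two wavelengths are required", call. = FALSE)
  }
  dpf <- rep_len(dpf, 2L)
  stopifnot(all(dpf > 0))
  ext <- as.data.frame(extinction)
  idx <- match(wavelengths_nm, ext$wavelength_nm)
  if (anyNA(idx)) stop("extinction table is missing a wavelength", call. = FALSE)
  E <- cbind(ext$alpha_hbo[idx], ext$alpha_hbr[idx])
  kap <- kappa(E, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition) {
    stop(sprintf(
      "extinction matrix is ill-conditioned (condition %.3g > %.3g)",
      kap, max_condition
    ), call. = FALSE)
  }
  structure(
    list(
      wavelengths_nm = wavelengths_nm,
      ext_matrix = E, # rows: wavelengths; cols: HbO, HbR
      dpf = dpf,
      distance_mm = distance_mm
    ),
    class = "optical_constants"
  )
}

#' @export
print.optical_constants <- function(x, ...) {
  cat(sprintf(
    "<optical_constants> L = %g mm, DPF = %s, wavelengths %s nm\n",
    x$distance_mm, toString(x$dpf), toString(x$wavelengths_nm)
  ))
  invisible(x)
}

# parse "ch<i>_w<lambda>" headers into (channel, wavelength)
.parse_intensity_names <- function(nms) {
  m <- regmatches(nms, regexec("^ch([0-9]+)_w([0-9]+)$", nms))
  ok <- lengths(m) == 3L
  if (!all(ok)) {
    stop("intensity columns must be named ch<i>_w<lambda>; offending: ",
      toString(nms[!ok]),
      call. = FALSE
    )
  }
  tibble::tibble(
    name = nms,
    channel = as.integer(vapply(m, `[`, "", 2L)),
    wavelength_nm = as.numeric(vapply(m, `[`, "", 3L))
  )
}

#' Convert raw light intensities to optical-density changes
#'
#' The optical-density change of each channel/wavelength series is obtained
#' by dividing the light intensity at each time step by the intensity at a
#' reference time step (the first, by default) and taking -log10 of the
#' ratio. The result is exactly 0 at the reference step, and is invariant
#' under global rescaling of the intensities.
#'
#' @param intensity A data frame, one row per time step, columns named
#'   `ch<i>_w<lambda>` holding strictly positive intensities (arbitrary
#'   device units).
#' @param reference_index 1-based row used as the reference (default 1).
#' @return A tibble of the same shape: optical-density changes
#'   (dimensionless), same column names.
#' @examples
#' x <- tibble::tibble(ch1_w760 = c(1, 0.1, 1), ch1_w830 = c(2, 2, 2))
#' intensity_to_od(x)
#' @export
intensity_to_od <- function(intensity, reference_index = 1L) {
  df <- as.data.frame(intensity)
  info <- .parse_intensity_names(names(df))
  n <- nrow(df)
  if (reference_index < 1L || reference_index > n) {
    stop("reference_index out of range", call. = FALSE)
  }
  for (j in seq_along(df)) {
    bad <- which(!is.finite(df[[j]]) | df[[j]] <= 0)
    if (length(bad)) {
      stop(sprintf(
        "nonpositive intensity in channel %d, wavelength %g nm, time step %d",
        info$channel[j], info$wavelength_nm[j], bad[1L]
      ), call. = FALSE)
    }
  }
  out <- purrr::map(df, function(col) -log10(col / col[reference_index]))
  tibble::as_tibble(out)
}

#' Convert optical-density changes to hemoglobin concentration changes
#'
#' Solves the modified Beer-Lambert law per channel and time step: the
#' optical-density change at wavelength lambda is
#' `(alpha_HbO(lambda) * dC_HbO + alpha_HbR(lambda) * dC_HbR) * L * DPF(lambda)`,
#' a 2x2 linear system in the two concentration changes.
#'
#' @param od A data frame of optical-density changes with columns
#'   `ch<i>_w<lambda>` (two wavelengths per channel), e.g. from
#'   [intensity_to_od()].
#' @param constants An [optical_constants()] object.
#' @return A tibble with columns `ch<i>_hbo` and `ch<i>_hbr`: concentration
#'   changes in uM.
#' @export
od_to_hemoglobin <- function(od, constants) {
  stopifnot(inherits(constants, "optical_constants"))
  df <- as.data.frame(od)
  info <- .parse_intensity_names(names(df))
  channels <- sort(unique(info$channel))
  wl <- constants$wavelengths_nm
  # per-wavelength total path: L * DPF
  path <- constants$distance_mm * constants$dpf
  A <- constants$ext_matrix * path # 2x2: OD = A %*% c(dHbO, dHbR)
  Ainv <- solve(A)
  cols <- list()
  for (ch in channels) {
    nm1 <- sprintf("ch%d_w%g", ch, wl[1])
    nm2 <- sprintf("ch%d_w%g", ch, wl[2])
    if (!nm1 %in% names(df) || !nm2 %in% names(df)) {
      stop(sprintf(
        "channel %d is missing one of the wavelengths %s nm", ch, toString(wl)
      ), call. = FALSE)
    }
    od2 <- rbind(df[[nm1]], df[[nm2]])
    conc <- Ainv %*% od2
    cols[[sprintf("ch%d_hbo", ch)]] <- conc[1L, ]
    cols[[sprintf("ch%d_hbr", ch)]] <- conc[2L, ]
  }
  tibble::as_tibble(cols)
}

#' Forward modified Beer-Lambert law
#'
#' Maps hemoglobin concentration changes to optical-density changes; the
#' inverse of [od_to_hemoglobin()]. Used by the intensity simulator and by
#' round-trip tests.
#'
#' @param hemo A data frame with columns `ch<i>_hbo`, `ch<i>_hbr` in uM.
#' @param constants An [optical_constants()] object.
#' @return A tibble of optical-density changes, columns `ch<i>_w<lambda>`.
#' @export
hemoglobin_to_od <- function(hemo, constants) {
  stopifnot(inherits(constants, "optical_constants"))
  df <- as.data.frame(hemo)
  chs <- sort(unique(as.integer(sub("^ch([0-9]+)_(hbo|hbr)$", "\\1", names(df)))))
  wl <- constants$wavelengths_nm
  A <- constants$ext_matrix * (constants$distance_mm * constants$dpf)
  cols <- list()
  for (ch in chs) {
    conc <- rbind(df[[sprintf("ch%d_hbo", ch)]], df[[sprintf("ch%d_hbr", ch)]])
    od2 <- A %*% conc
    cols[[sprintf("ch%d_w%g", ch, wl[1])]] <- od2[1L, ]
    cols[[sprintf("ch%d_w%g", ch, wl[2])]] <- od2[2L, ]
  }
  tibble::as_tibble(cols)
}

#' Select one channel's chromophore series
#'
#' @param hemo A data frame with `ch<i>_hbo` / `ch<i>_hbr` columns.
#' @param channel Channel number.
#' @param chromophore `"hbo"` (default; the task analysis uses the HbO
#'   series) or `"hbr"`.
#' @return Numeric vector, concentration change in uM.
#' @export
hemo_channel <- function(hemo, channel, chromophore = c("hbo", "hbr")) {
  chromophore <- match.arg(chromophore)
  nm <- sprintf("ch%d_%s", channel, chromophore)
  df <- as.data.frame(hemo)
  if (!nm %in% names(df)) {
    stop(sprintf("unknown channel/chromophore column '%s'", nm), call. = FALSE)
  }
  df[[nm]]
}
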