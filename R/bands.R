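#' Construct a wavenumber axis
#'
#' Builds the shared Raman-shift axis used by the spectrum simulator and the
#' preprocessing steps. The default covers the fingerprint region typically
#' recorded by portable Raman instruments.
#'
#' @param start First wavenumber (cm^-1). Must be smaller than `stop`.
#' @param stop Last wavenumber (cm^-1). Included only when
#'   `stop - start` is a multiple of `step`.
#' @param step Channel spacing (cm^-1), strictly positive.
#'
#' @return A strictly increasing numeric vector of wavenumbers starting at
#'   `start` with spacing `step`.
#' @examples
#' ax <- build_axis(400, 1800, 2)
#' length(ax) # 701 channels
#' @export
build_axis <- function(start = 400, stop = 1800, step = 2) {
  if (!is.numeric(start) || !is.numeric(stop) || !is.numeric(step) ||
      length(start) != 1L || length(stop) != 1L || length(step) != 1L) {
    stop("`start`, `stop` and `step` must be single numbers", call. = FALSE)
  }
  if (step <= 0) {
    stop("`step` must be strictly positive (got ", step, ")", call. = FALSE)
  }
  if (start >= stop) {
    stop("`start` must be smaller than `stop` (got [", start, ", ", stop, "])",
         call. = FALSE)
  }
  seq(from = start, to = stop, by = step)
}

#' Describe a single Raman band
#'
#' A band is modelled as a Lorentzian line: at unit concentration its
#' contribution to the spectrum is
#' `amplitude * hwhm^2 / ((nu - center)^2 + hwhm^2)`, so the profile equals
#' `amplitude` at the band center and half of that one HWHM away.
#'
#' @param center Band center (cm^-1).
#' @param hwhm Half-width at half-maximum (cm^-1), strictly positive.
#' @param amplitude Relative intensity per mg/L, non-negative.
#'
#' @return A one-row data frame with columns `center`, `hwhm`, `amplitude`.
#' @export
band <- function(center, hwhm, amplitude) {
  if (hwhm <= 0) stop("`hwhm` must be > 0", call. = FALSE)
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  data.frame(center = center, hwhm = hwhm, amplitude = amplitude)
}

#' Bundle the bands of one analyte
#'
#' @param name Analyte identifier, e.g. `"PS"` or `"SB"`.
#' @param bands A data frame with columns `center`, `hwhm`, `amplitude`
#'   (rows typically built with [band()] and `rbind`). At least one band;
#'   centers must be unique within the analyte.
#'
#' @return An object of class `analyte_library`.
#' @export
analyte_library <- function(name, bands) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.data.frame(bands) ||
      !all(c("center", "hwhm", "amplitude") %in% names(bands))) {
    stop("`bands` must be a data frame with columns center, hwhm, amplitude",
         call. = FALSE)
  }
  if (nrow(bands) < 1L) {
    stop("analyte '", name, "' needs at least one band", call. = FALSE)
  }
  if (anyDuplicated(bands$center)) {
    stop("band centers must be unique within analyte '", name, "'",
         call. = FALSE)
  }
  if (any(bands$hwhm <= 0)) stop("all band hwhm must be > 0", call. = FALSE)
  if (any(bands$amplitude < 0)) {
    stop("all band amplitudes must be >= 0", call. = FALSE)
  }
  structure(list(name = name, bands = bands), class = "analyte_library")
}

#' @export
print.analyte_library <- function(x, ...) {
  cat("Analyte band library:", x$name, "\n")
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' Default synthetic band libraries for PS and SB
#'
#' These wavenumbers and amplitudes are synthetic stand-ins chosen so that
#' the strongest PS band (1640 cm^-1) and the strongest SB band (1600 cm^-1)
#' produce overlapping characteristic-peak windows, the configuration that
#' makes mixture calibration non-trivial. They are not measured band
#' positions of potassium sorbate or sodium benzoate.
#'
#' @return A named list of two [analyte_library()] objects, `PS` and `SB`.
#' @export
default_libraries <- function() {
  list(
    PS = analyte_library("PS", rbind(
      band(1640, 12, 1.0),
      band(1380, 10, 0.6),
      band(1140, 10, 0.4)
    )),
    SB = analyte_library("SB", rbind(
      band(1600, 10, 1.0),
      band(1026, 8, 0.5),
      band(1002, 6, 0.9)
    ))
  )
}

#' Evaluate an analyte's unit-concentration clean spectrum
#'
#' Sums the Lorentzian contributions of all bands of one analyte on the given
#' axis. Multiplying this profile by a concentration (mg/L) gives that
#' analyte's clean, noise-free signal in linear response mode.
#'
#' @param library An [analyte_library()].
#' @param axis Wavenumber axis from [build_axis()].
#'
#' @return Numeric vector of intensities, same length as `axis`,
#'   non-negative everywhere.
#' @export
analyte_profile <- function(library, axis) {
  if (!inherits(library, "analyte_library")) {
    stop("`library` must be an analyte_library", call. = FALSE)
  }
  if (length(axis) < 1L || is.unsorted(axis, strictly = TRUE)) {
    stop("`axis` must be a strictly increasing wavenumber vector",
         call. = FALSE)
  }
  b <- library$bands
  out <- numeric(length(axis))
  for (i in seq_len(nrow(b))) {
    out <- out + b$amplitude[i] * b$hwhm[i]^2 /
      ((axis - b$center[i])^2 + b$hwhm[i]^2)
  }
  out
}
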