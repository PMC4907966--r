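#' Noise and response configuration for the spectrum simulator
#'
#' The measurement model applied to each simulated spectrum is
#' `g * sum_a r(c_a) * profile_a(nu) + baseline(nu) + eps(nu)` where
#' `g` is a per-spectrum log-normal enhancement factor (site-to-site
#' substrate variability: replicate spectra are taken at random positions on
#' the substrate), `eps` is iid additive Gaussian channel noise, and `r(c)`
#' is the concentration response — linear by default, Langmuir-saturating
#' when `saturation_c50` is set.
#'
#' @param sigma_mult Standard deviation (log scale) of the per-spectrum
#'   log-normal multiplicative factor `g`; 0 disables it (g = 1).
#' @param sigma_add_frac Additive Gaussian noise s.d. expressed as a fraction
#'   of the maximum clean intensity over the simulated design.
#' @param baseline_amplitude Maximum magnitude of a slowly varying random
#'   cubic baseline (intensity units); 0 disables the baseline.
#' @param saturation_c50 Optional Langmuir half-saturation concentration
#'   (mg/L). When set, `r(c) = c * c50 / (c50 + c)`; when `NULL` the
#'   response is linear, `r(c) = c`.
#'
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(sigma_mult = 0.03, sigma_add_frac = 0.005,
                         baseline_amplitude = 0, saturation_c50 = NULL) {
  if (sigma_mult < 0) stop("`sigma_mult` must be >= 0", call. = FALSE)
  if (sigma_add_frac < 0) stop("`sigma_add_frac` must be >= 0", call. = FALSE)
  if (baseline_amplitude < 0) {
    stop("`baseline_amplitude` must be >= 0", call. = FALSE)
  }
  if (!is.null(saturation_c50) && saturation_c50 <= 0) {
    stop("`saturation_c50` must be > 0 when given", call. = FALSE)
  }
  structure(list(sigma_mult = sigma_mult,
                 sigma_add_frac = sigma_add_frac,
                 baseline_amplitude = baseline_amplitude,
                 saturation_c50 = saturation_c50),
            class = "noise_config")
}

# concentration response: linear, or Langmuir-saturating when c50 is set
.response <- function(conc, c50) {
  if (is.null(c50)) conc else conc * c50 / (c50 + conc)
}

# clean (noise-free, unit-enhancement) signal for one concentration vector
.clean_signal <- function(concentrations, profiles, c50) {
  out <- numeric(nrow(profiles))
  for (a in colnames(profiles)) {
    out <- out + .response(concentrations[[a]], c50) * profiles[, a]
  }
  out
}

# draws (in order): g [1 lognormal], baseline [4 normal if enabled],
# eps [n normal if enabled] — the draw order is part of the determinism
# contract for a given seed
.simulate_intensity <- function(concentrations, profiles, noise, axis,
                                add_sd) {
  clean <- .clean_signal(concentrations, profiles, noise$saturation_c50)
  g <- if (noise$sigma_mult > 0) {
    stats::rlnorm(1, meanlog = 0, sdlog = noise$sigma_mult)
  } else 1
  intensity <- g * clean
  if (noise$baseline_amplitude > 0) {
    u <- 2 * (axis - axis[1]) / (axis[length(axis)] - axis[1]) - 1
    coefs <- stats::rnorm(4)
    bl <- coefs[1] + coefs[2] * u + coefs[3] * u^2 + coefs[4] * u^3
    peak <- max(abs(bl))
    if (peak > 0) intensity <- intensity + bl / peak * noise$baseline_amplitude
  }
  if (add_sd > 0) {
    intensity <- intensity + stats::rnorm(length(axis), sd = add_sd)
  }
  intensity
}

.profile_matrix <- function(libraries, axis) {
  stopifnot(length(libraries) >= 1L, !is.null(names(libraries)))
  vapply(libraries, analyte_profile, numeric(length(axis)), axis = axis)
}

.check_concentrations <- function(concentrations, libraries) {
  if (is.null(names(concentrations)) ||
      !setequal(names(concentrations), names(libraries))) {
    stop("`concentrations` must be named after the analytes: ",
         paste(names(libraries), collapse = ", "), call. = FALSE)
  }
  if (any(concentrations < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  concentrations[names(libraries)]
}

#' Simulate one SERS spectrum
#'
#' Draws a single spectrum from the measurement model described in
#' [noise_config()], using the current RNG state (set a seed beforehand for
#' reproducibility; [simulate_dataset()] does this for you).
#'
#' @param concentrations Named numeric vector of analyte concentrations
#'   (mg/L), names matching `names(libraries)`.
#' @param libraries Named list of [analyte_library()] objects.
#' @param noise A [noise_config()].
#' @param axis Wavenumber axis.
#' @param add_sd Additive noise s.d. in intensity units. Defaults to
#'   `sigma_add_frac` times this spectrum's own clean maximum; when
#'   simulating a whole design, [simulate_dataset()] passes the design-wide
#'   clean maximum instead so every spectrum shares one noise floor.
#'
#' @return An object of class `spectrum`: list with `axis`, `intensity`
#'   and `concentrations`.
#' @export
simulate_spectrum <- function(concentrations, libraries = default_libraries(),
                              noise = noise_config(), axis = build_axis(),
                              add_sd = NULL) {
  concentrations <- .check_concentrations(concentrations, libraries)
  profiles <- .profile_matrix(libraries, axis)
  if (is.null(add_sd)) {
    clean <- .clean_signal(concentrations, profiles, noise$saturation_c50)
    add_sd <- noise$sigma_add_frac * max(clean)
  }
  intensity <- .simulate_intensity(concentrations, profiles, noise, axis,
                                   add_sd)
  structure(list(axis = axis, intensity = intensity,
                 concentrations = concentrations),
            class = "spectrum")
}

#' Simulate every spectrum of a concentration design
#'
#' Generates `nrow(design) * replicates` spectra. The additive-noise scale is
#' `sigma_add_frac` times the maximum clean intensity over the whole design,
#' so all spectra share a single instrument noise floor. Identical
#' `(design, libraries, noise, axis, seed)` give a bit-identical result.
#'
#' @param design A design table from [single_analyte_design()] or
#'   [mixture_design()] (data frame with `sample_id` and one `<analyte>_mgL`
#'   column per analyte).
#' @param libraries Named list of [analyte_library()] objects.
#' @param noise A [noise_config()].
#' @param axis Wavenumber axis.
#' @param seed Integer seed fixing all random draws.
#' @param replicates Spectra per sample; defaults to the design's own
#'   replicate count.
#'
#' @return An object of class `spectrum_set`: shared `axis`, an
#'   `intensities` matrix (one row per spectrum), and a `labels` data frame
#'   (`sample_id`, `replicate`, one concentration column per analyte).
#' @export
simulate_dataset <- function(design, libraries = default_libraries(),
                             noise = noise_config(), axis = build_axis(),
                             seed = 0, replicates = NULL) {
  stopifnot(is.data.frame(design), "sample_id" %in% names(design))
  if (is.null(replicates)) replicates <- attr(design, "replicates")
  if (is.null(replicates)) replicates <- 1L
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  conc_cols <- paste0(names(libraries), "_mgL")
  if (!all(conc_cols %in% names(design))) {
    stop("design lacks concentration columns: ",
         paste(setdiff(conc_cols, names(design)), collapse = ", "),
         call. = FALSE)
  }
  if (any(as.matrix(design[conc_cols]) < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("sample_ids must be unique", call. = FALSE)
  }

  profiles <- .profile_matrix(libraries, axis)
  conc_of <- function(i) {
    stats::setNames(as.numeric(design[i, conc_cols]), names(libraries))
  }
  clean_max <- 0
  for (i in seq_len(nrow(design))) {
    clean_max <- max(clean_max,
                     .clean_signal(conc_of(i), profiles,
                                   noise$saturation_c50))
  }
  add_sd <- noise$sigma_add_frac * clean_max

  set.seed(seed)
  n_spec <- nrow(design) * replicates
  intensities <- matrix(0, nrow = n_spec, ncol = length(axis))
  labels <- data.frame(sample_id = rep(design$sample_id, each = replicates),
                       replicate = rep(seq_len(replicates), nrow(design)))
  for (a in names(libraries)) {
    labels[[paste0(a, "_mgL")]] <-
      rep(design[[paste0(a, "_mgL")]], each = replicates)
  }
  row <- 0L
  for (i in seq_len(nrow(design))) {
    conc <- conc_of(i)
    for (r in seq_len(replicates)) {
      row <- row + 1L
      intensities[row, ] <- .simulate_intensity(conc, profiles, noise, axis,
                                                add_sd)
    }
  }
  structure(list(axis = axis, intensities = intensities, labels = labels,
                 seed = seed, noise = noise, averaged = FALSE),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("SERS spectrum set:", nrow(x$intensities), "spectra,",
      length(x$axis), "channels (",
      x$axis[1], "-", x$axis[length(x$axis)], "cm^-1 )\n")
  cat("  samples:", length(unique(x$labels$sample_id)),
      if (isTRUE(x$averaged)) " (replicate-averaged)" else "", "\n", sep = "")
  invisible(x)
}
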