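#' Average replicate spectra per sample
#'
#' Collapses a spectrum set to one channelwise-mean spectrum per sample,
#' the representation the calibration models are fitted on.
#'
#' @param spectra A `spectrum_set` from [simulate_dataset()] or
#'   [read_spectra_csv()].
#'
#' @return A `spectrum_set` with one row per sample; labels keep
#'   `sample_id` and the true concentrations, `replicate` is dropped.
#' @export
average_replicates <- function(spectra) {
  stopifnot(inherits(spectra, "spectrum_set"))
  ids <- spectra$labels$sample_id
  uids <- unique(ids)
  conc_cols <- setdiff(names(spectra$labels), c("sample_id", "replicate"))
  inten <- matrix(0, nrow = length(uids), ncol = length(spectra$axis))
  labels <- data.frame(sample_id = uids)
  for (cc in conc_cols) labels[[cc]] <- NA_real_
  for (i in seq_along(uids)) {
    sel <- which(ids == uids[i])
    inten[i, ] <- colMeans(spectra$intensities[sel, , drop = FALSE])
    for (cc in conc_cols) {
      v <- unique(spectra$labels[[cc]][sel])
      if (length(v) != 1L) {
        stop("sample ", uids[i], " has inconsistent '", cc, "' labels",
             call. = FALSE)
      }
      labels[[cc]][i] <- v
    }
  }
  structure(list(axis = spectra$axis, intensities = inten, labels = labels,
                 seed = spectra$seed, noise = spectra$noise, averaged = TRUE),
            class = "spectrum_set")
}

#' Construct a window set directly from intervals
#'
#' @param analyte Analyte name the windows belong to.
#' @param intervals Two-column matrix (or list of length-2 vectors) of
#'   closed wavenumber intervals `[lo, hi]`. Overlapping or touching
#'   intervals are merged; the result is sorted by `lo`.
#'
#' @return An object of class `window_set`.
#' @export
window_set <- function(analyte, intervals) {
  if (is.list(intervals)) intervals <- do.call(rbind, intervals)
  intervals <- matrix(as.numeric(intervals), ncol = 2)
  if (any(intervals[, 1] >= intervals[, 2])) {
    stop("every interval must have lo < hi", call. = FALSE)
  }
  ord <- order(intervals[, 1])
  intervals <- intervals[ord, , drop = FALSE]
  merged <- intervals[1, , drop = FALSE]
  for (i in seq_len(nrow(intervals))[-1]) {
    k <- nrow(merged)
    if (intervals[i, 1] <= merged[k, 2]) {
      merged[k, 2] <- max(merged[k, 2], intervals[i, 2])
    } else {
      merged <- rbind(merged, intervals[i, ])
    }
  }
  colnames(merged) <- c("lo", "hi")
  structure(list(analyte = analyte, intervals = merged),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat("Characteristic-peak windows for", x$analyte, "(cm^-1):\n")
  apply(x$intervals, 1, function(r) cat("  [", r[1], ",", r[2], "]\n"))
  invisible(x)
}

#' Derive characteristic-peak windows from a band library
#'
#' Each band contributes the interval `center +/- k * hwhm`; overlapping
#' intervals are merged. With the default `k = 3` a window spans the region
#' where a Lorentzian band is visually prominent.
#'
#' @param library An [analyte_library()].
#' @param k Half-width multiplier, strictly positive.
#'
#' @return A [window_set()].
#' @export
windows_from_bands <- function(library, k = 3) {
  stopifnot(inherits(library, "analyte_library"))
  if (k <= 0) stop("`k` must be > 0", call. = FALSE)
  b <- library$bands
  window_set(library$name,
             cbind(b$center - k * b$hwhm, b$center + k * b$hwhm))
}

#' Restrict spectra to an analyte's windows and attach the response
#'
#' Keeps exactly the channels whose wavenumber falls inside any window
#' interval (closed endpoints, decided on the printed wavenumber), and pairs
#' the restricted spectra with the target analyte's true concentrations —
#' the observing matrix and response of a calibration model.
#'
#' @param spectra A `spectrum_set` (usually replicate-averaged).
#' @param windows A [window_set()].
#' @param target Target analyte name; its `<target>_mgL` label column
#'   becomes the response `y`.
#'
#' @return An object of class `feature_matrix`: `X` (rows = spectra,
#'   columns = retained channels, increasing wavenumber), `wavenumbers`,
#'   `y` (mg/L), `sample_ids`, `target`, `windows`.
#' @export
extract_windows <- function(spectra, windows, target) {
  stopifnot(inherits(spectra, "spectrum_set"), inherits(windows, "window_set"))
  ycol <- paste0(target, "_mgL")
  if (!ycol %in% names(spectra$labels)) {
    stop("no concentration labels for target analyte '", target, "'",
         call. = FALSE)
  }
  sel <- rep(FALSE, length(spectra$axis))
  for (i in seq_len(nrow(windows$intervals))) {
    sel <- sel | (spectra$axis >= windows$intervals[i, 1] &
                    spectra$axis <= windows$intervals[i, 2])
  }
  if (!any(sel)) {
    stop("window set for '", windows$analyte, "' (",
         paste(apply(windows$intervals, 1,
                     function(r) paste0("[", r[1], ",", r[2], "]")),
               collapse = " "),
         ") selects no channels on this axis", call. = FALSE)
  }
  X <- spectra$intensities[, sel, drop = FALSE]
  colnames(X) <- spectra$axis[sel]
  structure(list(X = X, wavenumbers = spectra$axis[sel],
                 y = spectra$labels[[ycol]],
                 sample_ids = spectra$labels$sample_id,
                 target = target, windows = windows),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Calibration feature matrix for", x$target, ":",
      nrow(x$X), "spectra x", ncol(x$X), "window channels\n")
  invisible(x)
}
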