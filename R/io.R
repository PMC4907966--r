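#' Write a spectrum set to CSV (with a labels sidecar)
#'
#' The spectra file has the wavenumber axis in its first column and one
#' column per spectrum; the sidecar holds one row per spectrum with
#' `sample_id`, `replicate` and the true concentrations. Intensities are
#' written with 10 significant digits so a write/read cycle is stable.
#'
#' @param spectra A `spectrum_set`.
#' @param path Output CSV path for the spectra.
#' @param labels_path Output CSV path for the labels; defaults to
#'   `<path minus .csv>_labels.csv`.
#'
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path,
                              labels_path = .labels_path_for(path)) {
  stopifnot(inherits(spectra, "spectrum_set"))
  lab <- spectra$labels
  rep_part <- if ("replicate" %in% names(lab)) {
    paste0("_r", lab$replicate)
  } else ""
  cols <- paste0("s", lab$sample_id, rep_part)
  m <- cbind(wavenumber = .fmt10(spectra$axis),
             matrix(.fmt10(t(spectra$intensities)),
                    nrow = length(spectra$axis),
                    dimnames = list(NULL, cols)))
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(lab, labels_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.fmt10 <- function(x) sprintf("%.10g", x)

.labels_path_for <- function(path) {
  sub("\\.csv$", "_labels.csv", path)
}

.numeric_or_stop <- function(chr, what, rows, cols) {
  num <- suppressWarnings(as.numeric(chr))
  bad <- which(is.na(num) & !is.na(chr) & nzchar(chr))
  if (length(bad) || anyNA(chr)) {
    idx <- if (length(bad)) bad[1] else which(is.na(chr))[1]
    stop("non-numeric value in ", what, " at row ", rows[idx],
         ", column '", cols[idx], "'", call. = FALSE)
  }
  num
}

#' Read a spectrum set written by [write_spectra_csv()]
#'
#' @param path Spectra CSV (first column: strictly increasing wavenumbers).
#' @param labels_path Labels sidecar CSV; defaults to the sibling
#'   `*_labels.csv`.
#'
#' @return A `spectrum_set`.
#' @export
read_spectra_csv <- function(path, labels_path = .labels_path_for(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty spectra file: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) != 1L) {
    stop("ragged spectra CSV: lines ",
         paste(which(nf != nf[1]), collapse = ", "),
         " have a different column count", call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("spectra file needs a wavenumber column and at least one spectrum",
         call. = FALSE)
  }
  nr <- nrow(df)
  axis <- .numeric_or_stop(df[[1]], basename(path),
                           seq_len(nr) + 1L, rep(names(df)[1], nr))
  if (is.unsorted(axis, strictly = TRUE)) {
    stop("wavenumber axis must be strictly increasing", call. = FALSE)
  }
  inten <- matrix(0, nrow = ncol(df) - 1L, ncol = nr)
  for (j in 2:ncol(df)) {
    inten[j - 1L, ] <- .numeric_or_stop(df[[j]], basename(path),
                                        seq_len(nr) + 1L,
                                        rep(names(df)[j], nr))
  }
  if (!file.exists(labels_path)) {
    stop("labels sidecar not found: ", labels_path, call. = FALSE)
  }
  labels <- utils::read.csv(labels_path)
  if (nrow(labels) != nrow(inten)) {
    stop("labels sidecar has ", nrow(labels), " rows but the spectra file ",
         "has ", nrow(inten), " spectra", call. = FALSE)
  }
  structure(list(axis = axis, intensities = inten, labels = labels,
                 seed = NA_integer_, noise = NULL,
                 averaged = !"replicate" %in% names(labels)),
            class = "spectrum_set")
}

#' Write / read a concentration design table
#'
#' @param design A `design_table`.
#' @param path CSV path with columns `sample_id`, `PS_mgL`, `SB_mgL`.
#' @return `path` (write) or a `design_table` (read).
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @param replicates Replicate count to attach on read.
#' @rdname write_design_csv
#' @export
read_design_csv <- function(path, replicates = 5) {
  d <- utils::read.csv(path)
  if (!"sample_id" %in% names(d)) {
    stop("design CSV must have a sample_id column", call. = FALSE)
  }
  structure(d, replicates = as.integer(replicates),
            class = c("design_table", "data.frame"))
}

.MODEL_SCHEMA <- "serscal-plsr-1"

#' Serialize a fitted calibration model to JSON
#'
#' Stores everything prediction needs — centering means, weights, loadings,
#' response loadings, the regression coefficient, the component count and
#' the window/channel layout — with full numeric precision, so a
#' write/read cycle predicts identically to the original model.
#'
#' @param model A `sers_plsr` fit.
#' @param path Output JSON path.
#'
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "sers_plsr"))
  payload <- list(
    schema = .MODEL_SCHEMA,
    target = model$target,
    ncomp = model$ncomp,
    early_stop = isTRUE(model$early_stop),
    nchan = length(model$coefficients),
    x_mean = unname(model$x_mean),
    y_mean = model$y_mean,
    weights = as.numeric(model$weights),
    loadings = as.numeric(model$loadings),
    y_loadings = as.numeric(model$y_loadings),
    coefficients = unname(model$coefficients),
    wavenumbers = model$wavenumbers,
    windows = if (!is.null(model$windows)) {
      list(analyte = model$windows$analyte,
           intervals = apply(model$windows$intervals, 1, as.numeric,
                             simplify = FALSE))
    })
  # I(17) significant digits: doubles survive the decimal round trip exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a calibration model written by [write_model_json()]
#'
#' @param path JSON path.
#' @return A `sers_plsr` model usable with [predict.sers_plsr()].
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        stop("cannot parse model file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
                      })
  if (!identical(payload$schema, .MODEL_SCHEMA)) {
    stop("unsupported model schema: ",
         if (is.null(payload$schema)) "<missing>" else payload$schema,
         " (expected ", .MODEL_SCHEMA, ")", call. = FALSE)
  }
  p <- payload$nchan
  a <- payload$ncomp
  windows <- NULL
  if (!is.null(payload$windows) && length(payload$windows)) {
    ints <- payload$windows$intervals
    if (is.list(ints)) ints <- do.call(rbind, ints)
    windows <- window_set(payload$windows$analyte, ints)
  }
  structure(list(coefficients = payload$coefficients,
                 x_mean = payload$x_mean, y_mean = payload$y_mean,
                 weights = matrix(payload$weights, nrow = p, ncol = a),
                 loadings = matrix(payload$loadings, nrow = p, ncol = a),
                 y_loadings = payload$y_loadings,
                 scores = NULL,
                 ncomp = a, ncomp_requested = a,
                 early_stop = isTRUE(payload$early_stop),
                 rmsecv = NULL, fitted.values = NULL, residuals = NULL,
                 y = NULL,
                 wavenumbers = payload$wavenumbers, windows = windows,
                 target = payload$target, sample_ids = NULL,
                 call = NULL),
            class = "sers_plsr")
}
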