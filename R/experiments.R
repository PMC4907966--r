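#' Configuration for a calibration/validation experiment
#'
#' Bundles everything an end-to-end run needs: the concentration design, the
#' target analyte, the band libraries and noise model, the window rule, the
#' replicate count and the two seeds (calibration and independent test set
#' are fresh draws of the same design with disjoint seeds).
#'
#' @param design `"single"` (8-level PS dilution series) or `"mixture"`
#'   (36-composition PS x SB factorial).
#' @param target Target analyte; must be present in `libraries`.
#' @param libraries Named list of [analyte_library()] objects.
#' @param noise A [noise_config()].
#' @param axis Wavenumber axis.
#' @param window_k Half-width multiplier for [windows_from_bands()].
#' @param replicates Spectra per sample.
#' @param seed_cal,seed_test Seeds for the calibration and test draws; must
#'   differ.
#' @param max_ncomp Cap for cross-validated component selection.
#' @param ncomp Fixed component count; `NULL` (default) cross-validates.
#'
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(design = c("single", "mixture"),
                              target = "PS",
                              libraries = default_libraries(),
                              noise = noise_config(),
                              axis = build_axis(),
                              window_k = 3,
                              replicates = 5,
                              seed_cal = 0, seed_test = 100,
                              max_ncomp = 10, ncomp = NULL) {
  design <- match.arg(design)
  if (!target %in% names(libraries)) {
    stop("target analyte '", target, "' is not in the band libraries",
         call. = FALSE)
  }
  if (seed_cal == seed_test) {
    stop("calibration and test seeds must differ", call. = FALSE)
  }
  structure(list(design = design, target = target, libraries = libraries,
                 noise = noise, axis = axis, window_k = window_k,
                 replicates = replicates, seed_cal = seed_cal,
                 seed_test = seed_test, max_ncomp = max_ncomp,
                 ncomp = ncomp),
            class = "experiment_config")
}

.design_for <- function(config) {
  switch(config$design,
         single = single_analyte_design(config$replicates),
         mixture = mixture_design(config$replicates))
}

# shared pipeline: simulate cal + test, average, window-restrict, fit,
# evaluate both sets
.run_experiment <- function(config) {
  design <- .design_for(config)
  cal <- simulate_dataset(design, config$libraries, config$noise,
                          config$axis, seed = config$seed_cal)
  test <- simulate_dataset(design, config$libraries, config$noise,
                           config$axis, seed = config$seed_test)
  cal_avg <- average_replicates(cal)
  test_avg <- average_replicates(test)
  windows <- windows_from_bands(config$libraries[[config$target]],
                                config$window_k)
  fm_cal <- extract_windows(cal_avg, windows, config$target)
  fit <- plsr_fit(fm_cal, ncomp = config$ncomp,
                  max_ncomp = config$max_ncomp)
  fm_test <- extract_windows(test_avg, windows, config$target)
  pred_cal <- predict(fit)
  pred_test <- predict(fit, fm_test)
  predictions <- rbind(
    data.frame(set = "calibration", sample_id = fm_cal$sample_ids,
               actual = fm_cal$y, predicted = pred_cal),
    data.frame(set = "test", sample_id = fm_test$sample_ids,
               actual = fm_test$y, predicted = pred_test))
  metrics <- c(cal_r2 = r_squared(pred_cal, fm_cal$y),
               cal_rmse = rmse(pred_cal, fm_cal$y),
               test_r2 = r_squared(pred_test, fm_test$y),
               test_rmse = rmse(pred_test, fm_test$y))
  structure(list(design = config$design, target = config$target,
                 predictions = predictions, metrics = metrics,
                 ncomp = fit$ncomp, rmsecv = fit$rmsecv, model = fit,
                 seeds = c(cal = config$seed_cal, test = config$seed_test)),
            class = "calibration_report")
}

#' Run the single-analyte calibration experiment
#'
#' Simulates the 8-level PS dilution series (calibration) and an independent
#' test series of the same levels, averages the replicate spectra, restricts
#' to the PS characteristic-peak windows, cross-validates the component
#' count, fits the PLS1 model and evaluates both sets.
#'
#' @param config An [experiment_config()] with `design = "single"`.
#'
#' @return A `calibration_report`: per-sample predicted/actual table,
#'   R-squared and RMSE for calibration and test, the selected component
#'   count and the fitted model.
#' @export
run_single_analyte_experiment <- function(config = experiment_config("single")) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$design != "single") {
    stop("config must use the single-analyte design", call. = FALSE)
  }
  .run_experiment(config)
}

#' Run a mixture calibration experiment for one analyte
#'
#' Same pipeline as [run_single_analyte_experiment()] on the 36-composition
#' PS x SB factorial. The model sees only the target analyte's windows —
#' which by construction contain signal from the other analyte — so this is
#' the interference-resistance setting.
#'
#' @param config An [experiment_config()] with `design = "mixture"`.
#' @param target Target analyte (`"PS"` or `"SB"`); overrides the config's.
#'
#' @return A `calibration_report`.
#' @export
run_mixture_experiment <- function(config = experiment_config("mixture"),
                                   target = config$target) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$design != "mixture") {
    stop("config must use the mixture design", call. = FALSE)
  }
  if (!target %in% names(config$libraries)) {
    stop("target analyte '", target, "' is not in the band libraries",
         call. = FALSE)
  }
  config$target <- target
  .run_experiment(config)
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Calibration report:", x$design, "design, target", x$target, "\n")
  cat("  latent variables:", x$ncomp, "\n")
  cat(sprintf("  calibration: R^2 = %.4f, RMSE = %.4g mg/L\n",
              x$metrics["cal_r2"], x$metrics["cal_rmse"]))
  cat(sprintf("  test:        R^2 = %.4f, RMSE = %.4g mg/L\n",
              x$metrics["test_r2"], x$metrics["test_rmse"]))
  invisible(x)
}

#' Interference-deviation analysis of mixture predictions
#'
#' Groups the mixture calibration predictions by the true concentration of
#' the target analyte (six groups of six compositions, the co-analyte
#' sweeping 0 to 100 mg/L within each group) and reports each sample's
#' deviation from its group's mean prediction. Small deviations mean the
#' co-analyte's overlapping signal does not leak into the prediction.
#'
#' @param report A `calibration_report` from [run_mixture_experiment()].
#' @param set Which prediction set to analyse (default calibration).
#'
#' @return An `interference_report`: per-sample table with `sample_id`,
#'   `actual`, `predicted`, `group_mean`, `deviation`, plus `max_abs_dev`.
#' @export
interference_analysis <- function(report, set = c("calibration", "test")) {
  stopifnot(inherits(report, "calibration_report"))
  set <- match.arg(set)
  p <- report$predictions[report$predictions$set == set, ]
  counts <- table(p$actual)
  if (any(counts < 2)) {
    stop("grouping by true ", report$target,
         " level produced a singleton group; cannot average", call. = FALSE)
  }
  gm <- stats::ave(p$predicted, p$actual)
  tab <- data.frame(sample_id = p$sample_id, actual = p$actual,
                    predicted = p$predicted, group_mean = gm,
                    deviation = p$predicted - gm)
  structure(list(target = report$target, set = set, table = tab,
                 max_abs_dev = max(abs(tab$deviation))),
            class = "interference_report")
}

#' @export
print.interference_report <- function(x, ...) {
  cat("Interference deviations for", x$target, "(", x$set, "set )\n")
  cat(sprintf("  max |deviation from same-level mean|: %.4g mg/L\n",
              x$max_abs_dev))
  invisible(x)
}

#' @export
plot.interference_report <- function(x, ...) {
  graphics::barplot(x$table$deviation, names.arg = x$table$sample_id,
                    xlab = "sample", ylab = "deviation (mg/L)",
                    main = paste("Deviation from same-level mean:",
                                 x$target), ...)
  invisible(x)
}

#' Reproduce all three calibration studies over several seed pairs
#'
#' Runs the single-analyte PS experiment and the mixture PS and SB
#' experiments over `nseeds` calibration/test seed pairs (calibration seeds
#' `master_seed + 0 .. nseeds-1`, test seeds offset by 100), and reports
#' per-seed metrics together with their medians — the medians tame the
#' Monte-Carlo variation of any single draw.
#'
#' @param master_seed Base seed; every random draw derives from it.
#' @param nseeds Number of seed pairs (default 5).
#' @param noise A [noise_config()].
#' @param libraries Band libraries.
#' @param axis Wavenumber axis.
#' @param replicates Spectra per sample.
#' @param outdir Optional directory; when given, per-seed metrics, the
#'   summary and the predicted-vs-actual tables are written there as
#'   CSV/JSON.
#'
#' @return An object of class `reproduction_summary`: `per_seed` (data
#'   frame of metrics per experiment and seed pair), `summary` (medians),
#'   and the last seed pair's reports.
#' @export
reproduce_all <- function(master_seed = 0, nseeds = 5,
                          noise = noise_config(),
                          libraries = default_libraries(),
                          axis = build_axis(), replicates = 5,
                          outdir = NULL) {
  experiments <- list(
    single_PS = list(design = "single", target = "PS"),
    mixture_PS = list(design = "mixture", target = "PS"),
    mixture_SB = list(design = "mixture", target = "SB"))
  rows <- list()
  last_reports <- list()
  predictions <- list()
  for (i in seq_len(nseeds) - 1L) {
    seed_cal <- master_seed + i
    seed_test <- master_seed + 100L + i
    for (nm in names(experiments)) {
      ex <- experiments[[nm]]
      cfg <- experiment_config(ex$design, target = ex$target,
                               libraries = libraries, noise = noise,
                               axis = axis, replicates = replicates,
                               seed_cal = seed_cal, seed_test = seed_test)
      rep_i <- .run_experiment(cfg)
      rows[[length(rows) + 1L]] <-
        data.frame(experiment = nm, seed_cal = seed_cal,
                   seed_test = seed_test, ncomp = rep_i$ncomp,
                   t(rep_i$metrics))
      last_reports[[nm]] <- rep_i
      pr <- rep_i$predictions
      pr$experiment <- nm
      pr$seed_cal <- seed_cal
      predictions[[length(predictions) + 1L]] <- pr
    }
  }
  per_seed <- do.call(rbind, rows)
  med <- do.call(rbind, lapply(split(per_seed, per_seed$experiment),
                               function(d) {
    data.frame(experiment = d$experiment[1],
               cal_r2 = stats::median(d$cal_r2),
               cal_rmse = stats::median(d$cal_rmse),
               test_r2 = stats::median(d$test_r2),
               test_rmse = stats::median(d$test_rmse))
  }))
  rownames(med) <- NULL
  out <- structure(list(master_seed = master_seed, nseeds = nseeds,
                        per_seed = per_seed, summary = med,
                        reports = last_reports),
                   class = "reproduction_summary")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per_seed, file.path(outdir, "metrics_per_seed.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, predictions),
                     file.path(outdir, "predictions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(master_seed = master_seed, nseeds = nseeds,
           summary = med),
      file.path(outdir, "summary.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.reproduction_summary <- function(x, ...) {
  cat("Reproduction over", x$nseeds, "seed pairs (master seed",
      x$master_seed, ") — median metrics:\n")
  print(transform(x$summary,
                  cal_r2 = round(cal_r2, 4),
                  cal_rmse = round(cal_rmse, 4),
                  test_r2 = round(test_r2, 4),
                  test_rmse = round(test_rmse, 4)),
        row.names = FALSE)
  invisible(x)
}
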