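#' Single-analyte calibration design
#'
#' Eight potassium sorbate (PS) levels spanning 0.3 to 10 mg/L with no
#' sodium benzoate, the dilution series used for the single-analyte
#' calibration and its independent test series.
#'
#' @param replicates Spectra per sample (default 5, one per randomly chosen
#'   substrate position).
#'
#' @return A data frame of class `design_table` with columns `sample_id`,
#'   `PS_mgL`, `SB_mgL` and a `replicates` attribute.
#' @export
single_analyte_design <- function(replicates = 5) {
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  d <- data.frame(sample_id = 1:8,
                  PS_mgL = c(0.3, 0.5, 0.8, 1, 3, 5, 8, 10),
                  SB_mgL = 0)
  structure(d, replicates = as.integer(replicates),
            class = c("design_table", "data.frame"))
}

#' Mixture calibration design (6 x 6 factorial)
#'
#' The 36 PS/SB compositions of the mixture study: the full factorial of
#' PS and SB over \{0, 1, 5, 10, 50, 100\} mg/L. Samples are numbered in
#' blocks of constant SB (0, 1, 5, 10, 50, 100 mg/L) with PS ascending
#' inside each block, so sample 1 is (PS 0, SB 0), sample 21 is
#' (PS 5, SB 10) and sample 36 is (PS 100, SB 100).
#'
#' @param replicates Spectra per sample (default 5).
#'
#' @return A data frame of class `design_table` with columns `sample_id`,
#'   `PS_mgL`, `SB_mgL` and a `replicates` attribute.
#' @export
mixture_design <- function(replicates = 5) {
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  levels <- c(0, 1, 5, 10, 50, 100)
  grid <- expand.grid(PS_mgL = levels, SB_mgL = levels,
                      KEEP.OUT.ATTRS = FALSE)
  d <- data.frame(sample_id = 1:36, PS_mgL = grid$PS_mgL,
                  SB_mgL = grid$SB_mgL)
  structure(d, replicates = as.integer(replicates),
            class = c("design_table", "data.frame"))
}
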