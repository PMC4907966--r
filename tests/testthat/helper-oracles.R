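# Independent oracles and small fixtures shared across test files.

# minimum-norm least squares via the SVD pseudo-inverse (independent of the
# package's NIPALS path)
lstsq_minnorm <- function(X, y, rel_cutoff = 1e-10) {
  sv <- svd(X)
  keep <- sv$d > rel_cutoff * max(sv$d)
  drop(sv$v[, keep, drop = FALSE] %*%
         (crossprod(sv$u[, keep, drop = FALSE], y) / sv$d[keep]))
}

# small two-analyte libraries with deliberately overlapping strong bands,
# on a short axis, for fast zero-noise exactness checks
tiny_libraries <- function() {
  list(
    A = analyte_library("A", rbind(band(480, 8, 1.0), band(560, 6, 0.5))),
    B = analyte_library("B", rbind(band(500, 10, 0.8), band(620, 6, 0.7)))
  )
}

tiny_axis <- function() build_axis(400, 700, 2)

zero_noise <- function() noise_config(sigma_mult = 0, sigma_add_frac = 0,
                                      baseline_amplitude = 0)

# libraries for PS/SB-style runs on the tiny axis (keeps the overlapping
# window structure but cheap to simulate)
tiny_psb_libraries <- function() {
  list(
    PS = analyte_library("PS", rbind(band(520, 8, 1.0), band(640, 6, 0.4))),
    SB = analyte_library("SB", rbind(band(505, 7, 0.9), band(600, 6, 0.6)))
  )
}

# random calibration problem with a planted linear signal
random_problem <- function(n, p, ncomp_signal = 2, noise_sd = 0.05,
                           seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- numeric(p)
  beta[seq_len(min(ncomp_signal, p))] <- rnorm(min(ncomp_signal, p))
  y <- drop(X %*% beta) + rnorm(n, sd = noise_sd)
  list(X = X, y = y)
}
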