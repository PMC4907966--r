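test_that("build_axis produces the requested channel grid and rejects bad input", {
  ax <- build_axis(400, 1800, 2)
  expect_length(ax, 701)
  expect_equal(ax[1], 400)
  expect_equal(ax[length(ax)], 1800)
  expect_false(is.unsorted(ax, strictly = TRUE))

  expect_equal(build_axis(400, 401, 2), 400)

  expect_error(build_axis(400, 1800, 0), "step")
  expect_error(build_axis(400, 1800, -1), "step")
  expect_error(build_axis(1800, 400, 2), "smaller")
})

test_that("analyte_profile evaluates Lorentzian bands correctly", {
  lib <- analyte_library("X", band(1640, 12, 1))
  expect_equal(analyte_profile(lib, 1640), 1.0)
  expect_equal(analyte_profile(lib, 1652), 0.5) # one HWHM away

  # two-band profile equals the per-band sum computed by an independent loop
  lib2 <- analyte_library("Y", rbind(band(1000, 10, 0.7), band(1100, 5, 1.2)))
  ax <- build_axis(900, 1200, 1)
  manual <- numeric(length(ax))
  for (i in seq_along(ax)) {
    manual[i] <- 0.7 * 10^2 / ((ax[i] - 1000)^2 + 10^2) +
      1.2 * 5^2 / ((ax[i] - 1100)^2 + 5^2)
  }
  expect_equal(analyte_profile(lib2, ax), manual)
  expect_true(all(analyte_profile(lib2, ax) >= 0))

  expect_error(analyte_library("Z", data.frame(center = numeric(),
                                               hwhm = numeric(),
                                               amplitude = numeric())),
               "at least one band")
  expect_error(analyte_library("Z", rbind(band(1000, 5, 1), band(1000, 6, 1))),
               "unique")
})

test_that("simulate_spectrum follows the measurement model", {
  libs <- tiny_libraries()
  ax <- tiny_axis()
  nz <- zero_noise()

  s0 <- simulate_spectrum(c(A = 0, B = 0), libs, nz, ax)
  expect_true(all(s0$intensity == 0))

  set.seed(1)
  s1 <- simulate_spectrum(c(A = 2, B = 3), libs, nz, ax)
  s2 <- simulate_spectrum(c(A = 4, B = 6), libs, nz, ax)
  expect_equal(s2$intensity, 2 * s1$intensity, tolerance = 1e-14)

  # closed-form channel-by-channel check, single analyte at 10 mg/L
  s10 <- simulate_spectrum(c(A = 10, B = 0), libs, nz, ax)
  expect_equal(s10$intensity, 10 * analyte_profile(libs$A, ax),
               tolerance = 1e-14)

  expect_error(simulate_spectrum(c(A = -1, B = 0), libs, nz, ax),
               "non-negative")
  expect_error(simulate_spectrum(c(A = 1), libs, nz, ax), "named")
})

test_that("zero-noise simulation is an exact linear map of concentrations", {
  libs <- tiny_libraries()
  ax <- tiny_axis()
  nz <- zero_noise()
  set.seed(7)
  for (i in 1:10) {
    c1 <- c(A = runif(1, 0, 10), B = runif(1, 0, 10))
    c2 <- c(A = runif(1, 0, 10), B = runif(1, 0, 10))
    lambda <- runif(1, 0.1, 5)
    add <- simulate_spectrum(c1 + c2, libs, nz, ax)$intensity
    expect_equal(add,
                 simulate_spectrum(c1, libs, nz, ax)$intensity +
                   simulate_spectrum(c2, libs, nz, ax)$intensity,
                 tolerance = 1e-12)
    expect_equal(simulate_spectrum(lambda * c1, libs, nz, ax)$intensity,
                 lambda * simulate_spectrum(c1, libs, nz, ax)$intensity,
                 tolerance = 1e-12)
  }
})

test_that("saturating response follows the Langmuir form", {
  libs <- tiny_libraries()["A"]
  ax <- tiny_axis()
  sat <- noise_config(sigma_mult = 0, sigma_add_frac = 0,
                      saturation_c50 = 5)
  s <- simulate_spectrum(c(A = 20), libs, sat, ax)
  expect_equal(s$intensity, (20 * 5 / 25) * analyte_profile(libs$A, ax),
               tolerance = 1e-14)
})

test_that("concentration designs match the study layouts", {
  d <- single_analyte_design(replicates = 5)
  expect_equal(nrow(d), 8)
  expect_equal(d$PS_mgL, c(0.3, 0.5, 0.8, 1, 3, 5, 8, 10))
  expect_equal(min(d$PS_mgL), 0.3)
  expect_true(all(d$SB_mgL == 0))
  expect_identical(attr(d, "replicates"), 5L)

  m <- mixture_design()
  expect_equal(nrow(m), 36)
  # full factorial over the six levels
  lv <- c(0, 1, 5, 10, 50, 100)
  expect_setequal(interaction(m$PS_mgL, m$SB_mgL),
                  interaction(expand.grid(lv, lv)[, 1],
                              expand.grid(lv, lv)[, 2]))
  # numbering: blocks of constant SB, PS ascending inside each block
  expect_equal(unlist(m[m$sample_id == 1, c("PS_mgL", "SB_mgL")],
                      use.names = FALSE), c(0, 0))
  expect_equal(unlist(m[m$sample_id == 21, c("PS_mgL", "SB_mgL")],
                      use.names = FALSE), c(5, 10))
  expect_equal(unlist(m[m$sample_id == 36, c("PS_mgL", "SB_mgL")],
                      use.names = FALSE), c(100, 100))
  expect_error(mixture_design(replicates = 0), ">= 1")
})

test_that("simulate_dataset is reproducible and separates clean from noise", {
  libs <- tiny_libraries()
  ax <- tiny_axis()
  design <- mixture_design(replicates = 5)
  names(design)[2:3] <- c("A_mgL", "B_mgL")

  set1 <- simulate_dataset(design, libs, noise_config(), ax, seed = 11)
  expect_equal(nrow(set1$intensities), 180) # 36 samples x 5 replicates

  set2 <- simulate_dataset(design, libs, noise_config(), ax, seed = 11)
  expect_identical(serialize(set1, NULL), serialize(set2, NULL))

  # different seeds: different noise, identical clean component
  set3 <- simulate_dataset(design, libs, noise_config(), ax, seed = 12)
  expect_false(identical(set1$intensities, set3$intensities))
  clean <- simulate_dataset(design, libs, zero_noise(), ax, seed = 12)
  expect_identical(clean$intensities,
                   simulate_dataset(design, libs, zero_noise(), ax,
                                    seed = 99)$intensities)
  # clean signal is non-negative at every channel
  expect_true(all(clean$intensities >= 0))
})

test_that("the multiplicative enhancement factor has the log-normal mean", {
  lib <- list(A = analyte_library("A", band(450, 8, 1)))
  ax <- build_axis(440, 460, 2)
  design <- structure(data.frame(sample_id = 1, A_mgL = 1),
                      replicates = 10000L,
                      class = c("design_table", "data.frame"))
  sigma <- 0.2
  set <- simulate_dataset(design, lib,
                          noise_config(sigma_mult = sigma,
                                       sigma_add_frac = 0), ax, seed = 3)
  peak <- which(ax == 450)
  g <- set$intensities[, peak] / analyte_profile(lib$A, ax)[peak]
  expected <- exp(sigma^2 / 2)
  se <- sd(g) / sqrt(length(g))
  expect_lt(abs(mean(g) - expected), 3 * se)
})
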