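test_that("22 MeV depth dose reproduces the calibrated range anchors", {
  sc <- build_scenario("tandem22")
  d <- bragg_depth_dose(ia_beam(22), sc)
  # 80% distal fall-off ~4.92 mm past the tank entrance (Ti + air +
  # polyimide water-equivalent shifts included)
  expect_equal(distal_falloff_depth(d, 0.8), 4.92e-3, tolerance = 0.01)
  # axial FWHM of the mono-energetic peak ~430 um
  expect_equal(bragg_peak_fwhm(d), 430e-6, tolerance = 0.05)
})

test_that("130 MeV clinical beam peaks at 11.4 cm", {
  sc <- build_scenario("clinical_liver")
  d <- bragg_depth_dose(ia_beam(130, protons_per_pulse = 1e6), sc)
  expect_equal(bragg_peak_depth(d), 0.114, tolerance = 2e-3)
})

test_that("dose maps respect conservation and positivity", {
  sc <- build_scenario("tandem22")
  beam <- ia_beam(22, protons_per_pulse = 2.8e6)
  d1 <- bragg_depth_dose(beam, sc, dim = "1d")
  expect_true(all(d1$values >= 0))
  # on-axis integral equals the per-area energy fluence at the axis,
  # minus the small fraction deposited upstream in the Ti window and air:
  # sum(D rho dx) <= E_total / (2 pi sigma^2)
  MeV <- 1.602176634e-13
  rho <- ionobeat:::scenario_property(sc, d1$x, "rho")
  lhs <- sum(d1$values * rho) * (d1$x[2] - d1$x[1])
  rhs <- 2.8e6 * 22 * MeV / (2 * pi * beam$lateral_sigma^2)
  expect_lt(lhs, rhs)
  expect_gt(lhs, 0.95 * rhs)
  expect_equal(max(bragg_depth_dose(ia_beam(22, protons_per_pulse = 0),
                                    sc)$values), 0)
  expect_error(bragg_depth_dose(ia_beam(300), sc), "calibrated table")
})

test_that("ripple filter substitute spreads the peak as calibrated", {
  sc <- build_scenario("tandem22_ripple")
  beam <- ia_beam(22)
  mono <- bragg_depth_dose(beam, sc)
  # degenerate zero-width shift law reduces to the mono-energetic curve
  deg <- ripple_spread_dose(beam, sc,
                            shift_distribution = list(type = "uniform",
                                                      max = 0))
  expect_equal(deg$values, mono$values, tolerance = 1e-12)
  # preset law: 90% distal fall-off at ~3.04 mm
  spread <- ripple_spread_dose(beam, sc)
  expect_equal(distal_falloff_depth(spread, 0.9), 3.04e-3, tolerance = 0.02)
  # any non-degenerate mixture is at least as wide as the mono peak
  for (mx in c(0.5e-3, 1e-3, 2e-3)) {
    sp <- ripple_spread_dose(beam, sc,
                             shift_distribution = list(type = "uniform",
                                                       max = mx))
    expect_gte(bragg_peak_fwhm(sp), bragg_peak_fwhm(mono) * 0.999)
    expect_true(all(sp$values >= 0))
  }
  expect_error(ripple_spread_dose(beam, sc,
    shift_distribution = list(type = "discrete", shift = 1e-3,
                              weight = -1)))
})

test_that("luminescence wavelengths follow the lambda^-2 law", {
  sc <- build_scenario("tandem22")
  d <- bragg_depth_dose(ia_beam(22), sc, dim = "1d")
  od <- optical_energy_deposition(d, sc, light_yield = 0.1,
                                  n_photons = 4e4, seed = 21)
  # mean of lambda^-2 on [300, 700]: log(7/3) / (1/300 - 1/700) = 444.8 nm
  expect_equal(od$mean_wavelength_nm, 444.83, tolerance = 0.01)
  # chi-squared goodness of fit of the sampled wavelength histogram
  set.seed(21)
  u <- stats::runif(4e4)
  lam <- 1 / (1 / 300 - u * (1 / 300 - 1 / 700))
  br <- seq(300, 700, by = 40)
  obs <- table(cut(lam, br))
  pexp <- diff((1 / 300 - 1 / br) / (1 / 300 - 1 / 700))
  chi <- stats::chisq.test(as.numeric(obs), p = pexp)
  expect_gt(chi$p.value, 0.001)
})

test_that("photon transport conserves energy to near machine precision", {
  sc <- build_scenario("tandem22")
  d <- bragg_depth_dose(ia_beam(22), sc, dim = "1d")
  od <- optical_energy_deposition(d, sc, light_yield = 0.1,
                                  n_photons = 2e5, seed = 3)
  expect_lt(abs(od$absorbed_J + od$escaped_J - od$emitted_J),
            1e-12 * od$emitted_J)
  expect_true(all(od$values >= 0))
  # Y = 0 -> all-zero map
  od0 <- optical_energy_deposition(d, sc, light_yield = 0,
                                   n_photons = 1e4, seed = 3)
  expect_equal(max(od0$values), 0)
})

test_that("ink absorption concentrates deposition at the phantom entrance", {
  sc <- build_scenario("tandem22")
  d <- bragg_depth_dose(ia_beam(22), sc, dim = "1d")
  od <- optical_energy_deposition(d, sc, light_yield = 0.1,
                                  n_photons = 2e5, seed = 5)
  # sharp gradient at the water / CA phantom interface (1.6 mm): the peak
  # deposition sits in the first ink cells and upstream water deposition
  # is negligible in comparison
  xpk <- od$x[which.max(od$values)]
  expect_lt(abs(xpk - 1.65e-3), 0.3e-3)
  up <- od$values[od$x > 0.2e-3 & od$x < 1.4e-3]
  expect_lt(max(up), 0.01 * max(od$values))
})

test_that("Monte Carlo error shrinks like 1/sqrt(n_photons)", {
  sc <- build_scenario("tandem22")
  d <- bragg_depth_dose(ia_beam(22), sc, dim = "1d")
  probe <- function(n, seeds) vapply(seeds, function(s) {
    od <- optical_energy_deposition(d, sc, light_yield = 0.1,
                                    n_photons = n, seed = s)
    sum(od$values[od$x > 1.6e-3 & od$x < 2.0e-3])
  }, numeric(1))
  s1 <- stats::sd(probe(2e3, 1:24))
  s2 <- stats::sd(probe(8e3, 1:24))
  # quadrupling n halves the standard error (within sampling noise)
  expect_equal(s1 / s2, 2, tolerance = 0.45)
})

test_that("determinism: same seed gives identical optical maps", {
  sc <- build_scenario("tandem22")
  d <- bragg_depth_dose(ia_beam(22), sc, dim = "1d")
  a <- optical_energy_deposition(d, sc, n_photons = 1e4, seed = 8)
  b <- optical_energy_deposition(d, sc, n_photons = 1e4, seed = 8)
  expect_identical(a$values, b$values)
})
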