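test_that("initial pressure follows D * Gamma * rho", {
  sc <- water_box_scenario()
  x <- seq(12.5e-6, 40e-3, by = 25e-6)
  d <- ia_dosemap(x, rep(1, length(x)), beam = ia_beam(22),
                  lateral_sigma = 1e-3)
  pf <- initial_pressure(d, sc)
  # 1 Gy in water: 1 * 0.11 * 998 = 109.78 Pa
  expect_equal(unique(round(pf$p0, 6)), 109.78, tolerance = 1e-6)
  # zero dose -> zero pressure; doubling Gamma doubles p0
  d0 <- ia_dosemap(x, rep(0, length(x)))
  expect_equal(max(abs(initial_pressure(d0, sc)$p0)), 0)
  sc2 <- water_box_scenario()
  sc2$layers[[1]]$material$grueneisen <- 0.22
  expect_equal(initial_pressure(d, sc2)$p0, 2 * pf$p0, tolerance = 1e-12)
})

test_that("grid time step follows the CFL rule", {
  sc <- build_scenario("tandem22")
  # dx = 25 um, CFL = 0.3, c_ref = 2400 (polyimide) -> dt = 3.125 ns
  expect_equal(sc$grid$dt, 3.125e-9)
  expect_error(ia_grid(cfl = 0.5), "CFL")
})

test_that("1D propagation matches the d'Alembert solution within 1%", {
  sc <- water_box_scenario(len = 40e-3, sensor = 30e-3)
  dx <- sc$grid$dx
  x <- seq(dx / 2, 40e-3, by = dx)
  sig <- 10 * dx
  p0v <- exp(-(x - 10e-3)^2 / (2 * sig^2))
  pf <- structure(list(x = x, y = NULL, p0 = p0v, lateral_sigma = NA,
                       protons_ref = 1), class = "ia_pressure_field")
  tr <- propagate(pf, sc, t_end = 25e-6, fs = 1 / sc$grid$dt)
  c0 <- 1484.1
  xs <- x[which.min(abs(x - 30e-3))]
  exact <- 0.5 * (exp(-(xs - c0 * tr$time - 10e-3)^2 / (2 * sig^2)) +
                  exp(-(xs + c0 * tr$time - 10e-3)^2 / (2 * sig^2)))
  expect_lt(max(abs(tr$pressure - exact)) / max(exact), 0.01)
})

test_that("time of flight equals distance over speed of sound", {
  sc <- water_box_scenario(len = 40e-3, sensor = 28e-3)
  dx <- sc$grid$dx
  x <- seq(dx / 2, 40e-3, by = dx)
  p0v <- exp(-(x - 6e-3)^2 / (2 * (5 * dx)^2))
  pf <- structure(list(x = x, y = NULL, p0 = p0v, lateral_sigma = NA,
                       protons_ref = 1), class = "ia_pressure_field")
  tr <- propagate(pf, sc, t_end = 20e-6)
  t_pk <- tr$time[which.max(tr$pressure)]
  expect_equal(t_pk, 22e-3 / 1484.1, tolerance = 1e-3)
})

test_that("2D amplitude decays like 1/sqrt(r) for a compact source", {
  w <- builtin_material("water")
  dx <- 50e-6
  sc <- ia_scenario(list(list(material = w, x0 = 0, x1 = 25.6e-3)),
                    sensor = list(position = 20e-3, geometry = "point"),
                    grid = ia_grid(dx = dx, dy = dx), preset = "box2d")
  x <- seq(dx / 2, 25.6e-3, by = dx)
  src_x <- 4e-3
  sig <- 1.5 * dx                      # compact source, diameter ~6 cells
  y <- seq(-10 * dx, 10 * dx, by = dx)
  p0m <- outer(exp(-(x - src_x)^2 / (2 * sig^2)),
               exp(-y^2 / (2 * sig^2)))
  pf <- structure(list(x = x, y = y, p0 = p0m, lateral_sigma = sig,
                       protons_ref = 1), class = "ia_pressure_field")
  peak_at <- function(r) {
    sc$sensor$position <- src_x + r
    tr <- propagate(pf, sc, t_end = (r + 4e-3) / 1400, pml_size = 24)
    max(tr$pressure)
  }
  r1 <- 4e-3; r2 <- 16e-3              # >= 10 source diameters
  ratio <- peak_at(r1) / peak_at(r2)
  expect_equal(ratio, sqrt(r2 / r1), tolerance = 0.05)
})

test_that("absorbing boundaries only remove energy after the transient", {
  sc <- water_box_scenario(len = 30e-3, sensor = 20e-3)
  dx <- sc$grid$dx
  x <- seq(dx / 2, 30e-3, by = dx)
  p0v <- exp(-(x - 15e-3)^2 / (2 * (8 * dx)^2))
  pf <- structure(list(x = x, y = NULL, p0 = p0v, lateral_sigma = NA,
                       protons_ref = 1), class = "ia_pressure_field")
  tr <- propagate(pf, sc, t_end = 60e-6)
  # windowed signal energy decays once the wave has left the domain
  e1 <- sum(tr$pressure[tr$time < 20e-6]^2)
  e2 <- sum(tr$pressure[tr$time > 40e-6]^2)
  expect_lt(e2, 0.01 * e1)
})

test_that("pulse-train convolution is linear with the right identities", {
  sc <- water_box_scenario(len = 40e-3, sensor = 28e-3)
  dx <- sc$grid$dx
  x <- seq(dx / 2, 40e-3, by = dx)
  p0v <- exp(-(x - 6e-3)^2 / (2 * (5 * dx)^2))
  pf <- structure(list(x = x, y = NULL, p0 = p0v, lateral_sigma = NA,
                       protons_ref = 1e6), class = "ia_pressure_field")
  imp <- propagate(pf, sc, t_end = 20e-6)
  # near-delta train with the same particle count reproduces the impulse
  delta <- square_pulse_train(width = 1 / imp$fs, period = 1 / imp$fs,
                              n_cycles = 1, protons_per_pulse = 1e6,
                              dt = 1 / imp$fs)
  out <- apply_pulse_train(imp, delta)
  n <- length(imp$pressure)
  expect_equal(out$pressure[1:n], imp$pressure, tolerance = 1e-6)
  # doubling the protons doubles the amplitude
  double <- square_pulse_train(200e-9, 400e-9, 25, protons_per_pulse = 2e6)
  single <- square_pulse_train(200e-9, 400e-9, 25, protons_per_pulse = 1e6)
  o2 <- apply_pulse_train(imp, double)
  o1 <- apply_pulse_train(imp, single)
  expect_equal(o2$pressure, 2 * o1$pressure, tolerance = 1e-9)
  # 25-cycle 400 ns burst puts the dominant line at 2.5 MHz
  o <- apply_pulse_train(imp, square_pulse_train(200e-9, 400e-9, 25))
  nf <- 2^18
  S <- Mod(stats::fft(c(o$pressure, numeric(nf - length(o$pressure)))))
  f <- (0:(nf - 1)) * o$fs / nf
  sel <- f > 1.5e6 & f < 20e6
  expect_equal(f[sel][which.max(S[sel])], 2.5e6, tolerance = 0.02)
  expect_error(apply_pulse_train(imp, list(intensity = numeric(0))))
})

test_that("detector response is the stated bandpass", {
  fs <- fs_acq
  killed <- detector_response(sinusoid_trace(0.01e6, n = 2^15) )
  # DC / far out-of-band content is strongly suppressed after the transient
  tail_idx <- seq(2^14, 2^15)
  s5 <- detector_response(sinusoid_trace(5e6, n = 2^15))
  g5 <- max(abs(s5$pressure[tail_idx]))
  expect_gt(g5, 10^(-1 / 20))          # within 1 dB of unity at 5 MHz
  s25 <- detector_response(sinusoid_trace(25e6, n = 2^15))
  g25 <- max(abs(s25$pressure[tail_idx]))
  expect_gt(20 * log10(g5 / g25), 8)   # >= 8 dB down at 25 MHz
  const <- ia_trace((0:(2^15 - 1)) / fs, rep(1, 2^15))
  dc <- detector_response(const)
  expect_lt(max(abs(dc$pressure[tail_idx])), 1e-3)
  expect_error(detector_response(sinusoid_trace(1e6), band = c(0.15e6, 90e6)),
               "Nyquist")
})

test_that("photoacoustic superposition is an exact linear combination", {
  a <- sinusoid_trace(1e6, n = 4096)
  b <- sinusoid_trace(2e6, n = 4096, amp = 0.5)
  s0 <- superpose_photoacoustic(a, b, 0)
  expect_equal(s0$pressure, a$pressure)
  s <- superpose_photoacoustic(a, b, 5e5)
  expect_equal(s$pressure, a$pressure + 5e5 * b$pressure)
  expect_identical(s$component, "combined")
  short <- ia_trace(a$time[1:100], a$pressure[1:100])
  expect_error(superpose_photoacoustic(a, short), "time axis")
})

test_that("correction factor x light yield equivalence holds", {
  # factor 5e5 applied to a map computed at Y = 0.1 photon/MeV equals a
  # map computed at Y = 5e4 photons/MeV (same photon histories)
  sc <- build_scenario("tandem22")
  d <- bragg_depth_dose(ia_beam(22), sc, dim = "1d")
  lo <- optical_energy_deposition(d, sc, light_yield = 0.1,
                                  n_photons = 2e4, seed = 13)
  hi <- optical_energy_deposition(d, sc, light_yield = 5e4,
                                  n_photons = 2e4, seed = 13)
  expect_equal(5e5 * lo$values, hi$values, tolerance = 1e-9)
})
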