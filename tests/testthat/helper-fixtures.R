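# shared fixtures: all synthetic, built in code

fs_acq <- 156.25e6

sinusoid_trace <- function(f0, n = 2^14, amp = 1, phase = 0, fs = fs_acq) {
  t <- (0:(n - 1)) / fs
  ia_trace(t, amp * sin(2 * pi * f0 * t + phase))
}

two_delta_trace <- function(dt_sep, n = 2^17, a2 = 0.8, fs = fs_acq) {
  t <- (0:(n - 1)) / fs
  p <- numeric(n)
  p[1000] <- 1
  p[1000 + round(dt_sep * fs)] <- a2
  ia_trace(t, p)
}

gaussian_pulse_trace <- function(t0, sigma, n = 2^16, fs = fs_acq) {
  t <- (0:(n - 1)) / fs
  ia_trace(t, exp(-(t - t0)^2 / (2 * sigma^2)))
}

# uniform water box for propagation oracles
water_box_scenario <- function(len = 40e-3, sensor = 30e-3, dx = 25e-6,
                               geometry = "point") {
  w <- builtin_material("water")
  ia_scenario(list(list(material = w, x0 = 0, x1 = len)),
              sensor = list(position = sensor, geometry = geometry,
                            diameter = 3.5e-3),
              grid = ia_grid(dx = dx, dy = 2 * dx), preset = "water_box")
}
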