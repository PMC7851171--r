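#' @useDynLib ionobeat, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# CSDA range of protons in water (PSTAR-like tabulation), g/cm^2.
# Interpolated log-log; the analytic depth-dose model is calibrated against
# this table.
.proton_range_table <- cbind(
  energy_MeV = c(1, 2, 5, 10, 15, 20, 25, 30, 40, 50, 60, 70, 80, 90, 100,
                 125, 150, 175, 200, 250),
  range_gcm2 = c(2.458e-3, 7.555e-3, 3.623e-2, 1.230e-1, 2.539e-1, 4.260e-1,
                 6.370e-1, 8.853e-1, 1.489, 2.227, 3.093, 4.080, 5.184,
                 6.398, 7.718, 11.46, 15.77, 20.68, 25.96, 37.94))

#' CSDA range of protons in water
#'
#' Log-log interpolation of an embedded stopping-power/range table
#' (PSTAR-style values for liquid water).
#'
#' @param energy_MeV proton kinetic energy in MeV (1-250).
#' @param rho water density in kg/m^3 used to convert areal to linear range.
#' @return range in meters of water.
#' @export
proton_range <- function(energy_MeV, rho = 998) {
  tb <- .proton_range_table
  if (any(energy_MeV < tb[1, 1] | energy_MeV > tb[nrow(tb), 1]))
    stop("beam energy outside the calibrated table (1-250 MeV)")
  lr <- stats::spline(log(tb[, 1]), log(tb[, 2]), xout = log(energy_MeV),
                      method = "hyman")$y
  exp(lr) / (rho / 1000) / 100    # g/cm^2 -> cm of water -> m
}

# Range-straggling width multiplier: scales the Bortfeld-style straggling
# sigma (0.012 * R0^0.935 cm) and is calibrated once so that the axial FWHM
# of the 22 MeV Bragg peak in water is ~430 um.
.straggle_sigma_scale <- 1.0577

# Ripple-filter substitute: a uniform water-equivalent range-shift
# distribution with this maximum shift (m), plus a lateral beam broadening
# factor; calibrated so the 90% distal fall-off of the spread-out 22 MeV
# beam lands at ~3.04 mm.
.ripple_max_shift <- 2.376e-3
.ripple_lateral_broadening <- 2.0

#' Proton beam specification
#'
#' @param energy_MeV kinetic energy in MeV (> 0).
#' @param protons_per_pulse particles per pulse.
#' @param lateral_sigma Gaussian beam sigma in m; the default corresponds to
#'   the ~4 mm^2 focal spot (`pi * sigma^2 = 4 mm^2`).
#' @param lateral_jitter optional data.frame with columns `offset` (m) and
#'   `weight` (summing to 1) describing beam-position instability.
#' @return An object of class `ia_beam`.
#' @export
ia_beam <- function(energy_MeV, protons_per_pulse = 2.8e6,
                    lateral_sigma = sqrt(4e-6 / pi),
                    lateral_jitter = NULL) {
  if (energy_MeV <= 0) stop("energy must be > 0")
  if (protons_per_pulse < 0) stop("protons_per_pulse must be >= 0")
  if (!is.null(lateral_jitter)) {
    stopifnot(all(c("offset", "weight") %in% names(lateral_jitter)))
    if (any(lateral_jitter$weight < 0))
      stop("jitter weights must be >= 0")
    if (abs(sum(lateral_jitter$weight) - 1) > 1e-9)
      stop("jitter weights must sum to 1")
  }
  structure(list(energy_MeV = energy_MeV,
                 protons_per_pulse = protons_per_pulse,
                 lateral_sigma = lateral_sigma,
                 lateral_jitter = lateral_jitter),
            class = "ia_beam")
}

# Per-proton stopping power profile in water, on a fine water-equivalent
# depth grid (m), normalized so that integral(S dz) = energy (full
# stopping). Bortfeld-style power-law slowing down convolved with a
# Gaussian range-straggling kernel.
.bragg_water_profile <- function(energy_MeV, dz = 5e-6,
                                 sigma_scale = .straggle_sigma_scale) {
  R0 <- proton_range(energy_MeV)                 # m of water
  R0cm <- R0 * 100
  sigma <- sigma_scale * 0.012 * R0cm^0.935 / 100  # m
  zmax <- R0 + 6 * sigma
  z <- seq(dz / 2, zmax, by = dz)
  u <- pmax(R0cm - z * 100, 0)                   # residual range, cm
  shat <- ifelse(u > 0,
                 17.93 * pmax(u, dz * 50)^(-0.435) +
                   (0.444 + 31.7 * 0.1 / R0cm) * u^0.565,
                 0)
  # Gaussian smearing (range straggling)
  nk <- ceiling(4 * sigma / dz)
  kz <- (-nk:nk) * dz
  kern <- exp(-kz^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  s <- stats::filter(c(rep(0, nk), shat, rep(0, nk)), kern, sides = 2)
  s <- as.numeric(s[(nk + 1):(nk + length(shat))])
  s[is.na(s)] <- 0
  s <- s / (sum(s) * dz) * energy_MeV            # MeV per m (per proton)
  list(z = z, S = s, R0 = R0, sigma = sigma)
}

# Water-equivalent depth at scenario positions x (m), including upstream
# beam-line degraders.
.water_equivalent_depth <- function(scenario, x) {
  wet0 <- beamline_wet(scenario)
  x0 <- vapply(scenario$layers, `[[`, numeric(1), "x0")
  x1 <- vapply(scenario$layers, `[[`, numeric(1), "x1")
  wer <- vapply(scenario$layers, function(l)
    l$material$water_equivalent_ratio, numeric(1))
  # WET accumulated at each layer start (beam enters at x = 0)
  start <- pmax(x0, 0)
  stop_ <- pmax(x1, 0)
  wlen <- (stop_ - start) * wer
  cum0 <- c(0, cumsum(wlen))[seq_along(wlen)]
  idx <- scenario_layer_index(scenario, x)
  wet0 + cum0[idx] + pmax(x - start[idx], 0) * wer[idx]
}

#' Gridded dose map container
#'
#' @param x axial cell-center coordinates (m).
#' @param values dose in Gy: a vector (1D, on-axis) or a matrix with rows
#'   indexed by `x` and columns by `y`.
#' @param y lateral cell-center coordinates (m) for 2D maps.
#' @param beam the generating [ia_beam()].
#' @param lateral_sigma effective lateral Gaussian sigma of the map (m).
#' @param total_energy_J total deposited energy bookkeeping value.
#' @return An object of class `ia_dosemap`.
#' @export
ia_dosemap <- function(x, values, y = NULL, beam = NULL,
                       lateral_sigma = NA_real_, total_energy_J = NA_real_) {
  if (any(values < 0)) stop("dose must be >= 0 everywhere")
  structure(list(x = x, y = y, values = values, beam = beam,
                 lateral_sigma = lateral_sigma,
                 total_energy_J = total_energy_J),
            class = "ia_dosemap")
}

# On-axis profile of a dose map.
dose_axis_profile <- function(dose) {
  if (is.matrix(dose$values)) {
    j0 <- which.min(abs(dose$y))
    dose$values[, j0]
  } else dose$values
}

#' Analytic proton depth-dose (Bragg curve) on a scenario grid
#'
#' Lays the calibrated analytic Bragg curve onto the scenario's axial grid
#' after water-equivalent shifting through the upstream degraders and
#' in-domain layers, with a lateral Gaussian profile in 2D mode.
#'
#' Dose is reported in Gy on the beam axis (1D) or on the axial-lateral
#' plane through the axis (2D), using the beam's Gaussian focal spot to set
#' the energy-per-area normalization.
#'
#' @param beam an [ia_beam()].
#' @param scenario an [ia_scenario()].
#' @param dim `"1d"` (on-axis) or `"2d"`.
#' @param range_shift additional water-equivalent range shift in m
#'   (positive shortens the range), used by [ripple_spread_dose()].
#' @param lateral_offset lateral beam-center offset in m (2D only).
#' @return An [ia_dosemap()].
#' @examples
#' sc <- build_scenario("tandem22")
#' d <- bragg_depth_dose(ia_beam(22), sc)
#' distal_falloff_depth(d, 0.8)   # ~4.92e-3 m past the tank entrance
#' @export
bragg_depth_dose <- function(beam, scenario, dim = c("1d", "2d"),
                             range_shift = 0, lateral_offset = 0) {
  dim <- match.arg(dim)
  dx <- scenario$grid$dx
  xr <- c(scenario$layers[[1]]$x0,
          scenario$layers[[length(scenario$layers)]]$x1)
  x <- seq(xr[1] + dx / 2, xr[2], by = dx)
  prof <- .bragg_water_profile(beam$energy_MeV)
  weq <- .water_equivalent_depth(scenario, x) + range_shift
  if (max(prof$z) > max(weq))
    stop("beam ranges out of the simulated domain")
  S <- stats::approx(prof$z, prof$S, xout = weq, yleft = prof$S[1],
                     yright = 0, rule = 2)$y
  S[x < 0] <- 0                                   # upstream of the entrance
  wer <- scenario_property(scenario, x, "water_equivalent_ratio")
  rho <- scenario_property(scenario, x, "rho")
  sig <- beam$lateral_sigma
  aeff <- 2 * pi * sig^2                          # on-axis Gaussian norm
  MeV <- 1.602176634e-13
  n <- beam$protons_per_pulse
  d_axis <- n * S * wer / (rho * aeff) * MeV      # Gy on axis
  etot <- n * beam$energy_MeV * MeV
  if (dim == "1d") {
    return(ia_dosemap(x, d_axis, beam = beam, lateral_sigma = sig,
                      total_energy_J = etot))
  }
  dy <- scenario$grid$dy
  ny <- 2 * ceiling(4 * sig / dy) + 1
  y <- (seq_len(ny) - (ny + 1) / 2) * dy
  vals <- outer(d_axis, exp(-(y - lateral_offset)^2 / (2 * sig^2)))
  ia_dosemap(x, vals, y = y, beam = beam, lateral_sigma = sig,
             total_energy_J = etot)
}

#' Spread-out Bragg peak from a parametric range-shift law
#'
#' Emulates a ripple filter as a weighted mixture of axially shifted Bragg
#' curves (uniform water-equivalent shift distribution by default), with an
#' additional lateral beam broadening from scattering in the filter, and
#' averages over the beam lateral-position jitter when the beam defines
#' jitter positions.
#'
#' @inheritParams bragg_depth_dose
#' @param shift_distribution `list(type = "uniform", max = <m>)` or
#'   `list(type = "discrete", shift = <m vector>, weight = <vector>)`. When
#'   `NULL`, the scenario's attached ripple law (preset `tandem22_ripple`)
#'   is used.
#' @param n_shift number of quadrature nodes for the uniform law.
#' @return An [ia_dosemap()].
#' @export
ripple_spread_dose <- function(beam, scenario, shift_distribution = NULL,
                               dim = c("1d", "2d"), n_shift = 41) {
  dim <- match.arg(dim)
  if (is.null(shift_distribution)) {
    rp <- scenario$meta$ripple
    if (is.null(rp)) stop("scenario carries no ripple law; pass shift_distribution")
    shift_distribution <- list(type = "uniform", max = rp$max_shift)
    broaden <- rp$lateral_broadening
  } else broaden <- .ripple_lateral_broadening
  sd <- shift_distribution
  if (identical(sd$type, "uniform")) {
    if (sd$max < 0) stop("shift distribution must have finite non-negative support")
    if (sd$max == 0) { shifts <- 0; w <- 1 }
    else {
      shifts <- seq(0, sd$max, length.out = n_shift)
      w <- rep(1 / n_shift, n_shift)
    }
  } else if (identical(sd$type, "discrete")) {
    shifts <- sd$shift; w <- sd$weight
    if (!length(w) || any(w < 0)) stop("shift weights must be non-negative")
    w <- w / sum(w)
  } else stop("unknown shift distribution type")

  beam2 <- beam
  degenerate <- length(shifts) == 1L && shifts[1] == 0
  if (!degenerate) beam2$lateral_sigma <- beam$lateral_sigma * broaden
  offsets <- data.frame(offset = 0, weight = 1)
  if (!is.null(beam$lateral_jitter) && dim == "2d")
    offsets <- beam$lateral_jitter
  acc <- NULL
  for (io in seq_len(nrow(offsets))) {
    for (is in seq_along(shifts)) {
      d <- bragg_depth_dose(beam2, scenario, dim = dim,
                            range_shift = shifts[is],
                            lateral_offset = offsets$offset[io])
      contrib <- d$values * (w[is] * offsets$weight[io])
      acc <- if (is.null(acc)) contrib else acc + contrib
      tmpl <- d
    }
  }
  tmpl$values <- acc
  tmpl
}

#' Depth of the distal dose fall-off
#'
#' Locates the depth beyond the Bragg maximum where the on-axis dose drops
#' to `frac` of its peak value (linear interpolation between grid cells).
#'
#' @param dose an [ia_dosemap()].
#' @param frac fall-off fraction (0.8 for the mono-energetic range
#'   convention, 0.9 for the spread-out convention used here).
#' @return depth in m (same axis origin as the scenario).
#' @export
distal_falloff_depth <- function(dose, frac = 0.8) {
  p <- dose_axis_profile(dose)
  ipk <- which.max(p)
  target <- frac * p[ipk]
  below <- which(p[ipk:length(p)] <= target)
  if (!length(below)) return(NA_real_)
  i2 <- ipk + below[1] - 1L
  i1 <- i2 - 1L
  f <- (p[i1] - target) / (p[i1] - p[i2])
  dose$x[i1] + f * (dose$x[i2] - dose$x[i1])
}

#' @rdname distal_falloff_depth
#' @export
bragg_peak_depth <- function(dose) {
  p <- dose_axis_profile(dose)
  # parabolic refinement around the grid maximum
  i <- which.max(p)
  if (i > 1 && i < length(p)) {
    a <- p[i - 1]; b <- p[i]; cc <- p[i + 1]
    den <- a - 2 * b + cc
    off <- if (den != 0) 0.5 * (a - cc) / den else 0
    dose$x[i] + off * (dose$x[2] - dose$x[1])
  } else dose$x[i]
}

#' Axial full width at half maximum of the Bragg peak
#'
#' @param dose an [ia_dosemap()].
#' @return FWHM in m of the on-axis dose peak.
#' @export
bragg_peak_fwhm <- function(dose) {
  p <- dose_axis_profile(dose)
  x <- dose$x
  ipk <- which.max(p)
  half <- p[ipk] / 2
  il <- which(p[1:ipk] <= half)
  ir <- which(p[ipk:length(p)] <= half)
  if (!length(il) || !length(ir)) return(NA_real_)
  i1 <- il[length(il)]
  xl <- x[i1] + (x[i1 + 1] - x[i1]) * (half - p[i1]) / (p[i1 + 1] - p[i1])
  i2 <- ipk + ir[1] - 1L
  xr <- x[i2 - 1] + (x[i2] - x[i2 - 1]) * (p[i2 - 1] - half) / (p[i2 - 1] - p[i2])
  xr - xl
}
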