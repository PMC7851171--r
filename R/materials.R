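#' Acoustic and optical material definition
#'
#' A material bundles the acoustic properties used by the thermoacoustic
#' pressure conversion and wave propagation (density, speed of sound,
#' Grueneisen parameter), the optical absorption spectrum used by the
#' luminescence-photon transport, the luminescence light yield, and the
#' water-equivalent ratio used when shifting proton ranges through upstream
#' degraders.
#'
#' @param name character scalar identifying the material.
#' @param rho mass density in kg/m^3 (> 0).
#' @param c speed of sound in m/s (> 0).
#' @param grueneisen dimensionless Grueneisen parameter (>= 0). See
#'   [material_grueneisen()] to derive it from compressibility, speed of
#'   sound and heat capacity.
#' @param mu_a optical absorption in 1/mm: either a single non-negative
#'   number (wavelength independent) or a two-column matrix/data.frame with
#'   wavelength (nm) and absorption (1/mm), interpolated log-linearly over
#'   300-700 nm.
#' @param light_yield luminescence photons emitted per MeV of deposited
#'   energy (>= 0).
#' @param water_equivalent_ratio linear stopping-power ratio relative to
#'   water, used to convert geometric to water-equivalent thickness.
#'
#' @return An object of class `ia_material`.
#' @export
ia_material <- function(name, rho, c, grueneisen,
                        mu_a = 0, light_yield = 0.1,
                        water_equivalent_ratio = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(rho) || rho <= 0) stop("rho must be > 0")
  if (!is.numeric(c) || c <= 0) stop("speed of sound must be > 0")
  if (!is.numeric(grueneisen) || grueneisen < 0) stop("grueneisen must be >= 0")
  if (light_yield < 0) stop("light_yield must be >= 0")
  if (water_equivalent_ratio <= 0) stop("water_equivalent_ratio must be > 0")
  if (is.data.frame(mu_a)) mu_a <- as.matrix(mu_a)
  if (is.matrix(mu_a)) {
    if (ncol(mu_a) != 2L) stop("tabulated mu_a needs columns (wavelength_nm, mu_a)")
    if (any(mu_a[, 2] < 0)) stop("mu_a must be >= 0")
  } else {
    stopifnot(is.numeric(mu_a), length(mu_a) == 1L)
    if (mu_a < 0) stop("mu_a must be >= 0")
  }
  structure(
    list(name = name, rho = rho, c = c, grueneisen = grueneisen,
         mu_a = mu_a, light_yield = light_yield,
         water_equivalent_ratio = water_equivalent_ratio),
    class = "ia_material")
}

#' @export
print.ia_material <- function(x, ...) {
  cat(sprintf("<ia_material> %s: rho=%g kg/m^3, c=%g m/s, Gamma=%g, WER=%g\n",
              x$name, x$rho, x$c, x$grueneisen, x$water_equivalent_ratio))
  invisible(x)
}

#' Grueneisen parameter from thermodynamic properties
#'
#' Computes the dimensionless thermoelastic conversion efficiency
#' `Gamma = beta * c^2 / Cp` relating absorbed energy density to the initial
#' thermoacoustic pressure.
#'
#' @param beta volumetric thermal expansivity in 1/K (> 0).
#' @param c speed of sound in m/s (> 0).
#' @param Cp isobaric specific heat capacity in J/(kg K) (> 0).
#' @return Dimensionless Grueneisen parameter.
#' @examples
#' # water near 20.5 degC
#' material_grueneisen(beta = 2.093e-4, c = 1484.1, Cp = 4182)
#' @export
material_grueneisen <- function(beta, c, Cp) {
  if (any(beta < 0)) stop("beta must be >= 0")
  if (any(c <= 0) || any(Cp <= 0)) stop("c and Cp must be > 0")
  beta * c^2 / Cp
}

# Pure-water optical absorption table, 1/mm vs nm (Pope & Fry style values,
# Segelstein-like in the near UV). Only the order of magnitude matters for
# photon transport: water is essentially transparent (mean free paths of
# meters) compared to India ink.
.water_mu_a_table <- cbind(
  wavelength_nm = c(300, 320, 340, 360, 380, 400, 420, 440, 460, 480,
                    500, 520, 540, 560, 580, 600, 620, 640, 660, 680, 700),
  mu_a = c(1.41e-5, 9.0e-6, 6.6e-6, 4.6e-6, 1.14e-5, 6.6e-6, 4.5e-6,
           6.4e-6, 9.8e-6, 1.3e-5, 2.0e-5, 4.2e-5, 5.0e-5, 6.3e-5,
           9.5e-5, 2.22e-4, 2.76e-4, 3.3e-4, 4.1e-4, 4.7e-4, 6.24e-4))

# India ink absorption for 1% concentration, anchored to 3.7e3 1/mm at
# 632.8 nm; the spectrum of ink is nearly flat over the visible range.
.ink_mu_a_1pct <- 3.7e3

#' Evaluate a material's optical absorption at given wavelengths
#'
#' @param material an `ia_material`.
#' @param wavelength_nm numeric vector of wavelengths in nm.
#' @return absorption coefficient(s) in 1/mm.
#' @export
material_mu_a <- function(material, wavelength_nm) {
  mu <- material$mu_a
  if (is.matrix(mu)) {
    # log-linear interpolation, clamped at the table ends
    lv <- stats::approx(mu[, 1], log(pmax(mu[, 2], 1e-300)),
                        xout = wavelength_nm, rule = 2)$y
    exp(lv)
  } else {
    rep(mu, length(wavelength_nm))
  }
}

#' Built-in materials
#'
#' Returns one of the standard materials used by the scenario presets.
#' Water takes the tank-temperature properties (998 kg/m^3, 1484.1 m/s,
#' Gamma = 0.11 at 20.5 degC). The polyimide foil speed of sound is
#' 2400 m/s; its density and Grueneisen parameter default to
#' literature-typical values (1420 kg/m^3, 0.9). India ink solutions share
#' the acoustic properties of water. The hepatic tumor uses a speed of sound
#' of 1556.9 m/s and ink-like optical absorption; liver uses water-like
#' optics.
#'
#' @param name one of `"water"`, `"polyimide"`, `"air"`, `"titanium"`,
#'   `"india_ink"`, `"liver"`, `"tumor"`.
#' @param ink_concentration ink volume concentration in percent (scales the
#'   ink absorption linearly; default 1).
#' @param light_yield photons/MeV for the returned material (default 0.1).
#' @return An `ia_material`.
#' @export
builtin_material <- function(name, ink_concentration = 1, light_yield = 0.1) {
  switch(name,
    water = ia_material("water", rho = 998, c = 1484.1, grueneisen = 0.11,
                        mu_a = .water_mu_a_table, light_yield = light_yield,
                        water_equivalent_ratio = 1),
    polyimide = ia_material("polyimide", rho = 1420, c = 2400,
                            grueneisen = 0.9, mu_a = .water_mu_a_table,
                            light_yield = light_yield,
                            water_equivalent_ratio = 1.40),
    air = ia_material("air", rho = 1.204, c = 343, grueneisen = 0.4,
                      mu_a = 1e-9, light_yield = 0,
                      water_equivalent_ratio = 1.06e-3),
    titanium = ia_material("titanium", rho = 4506, c = 6070,
                           grueneisen = 1.1, mu_a = 1e6, light_yield = 0,
                           water_equivalent_ratio = 2.43),
    india_ink = ia_material("india_ink", rho = 998, c = 1484.1,
                            grueneisen = 0.11,
                            mu_a = .ink_mu_a_1pct * ink_concentration,
                            light_yield = light_yield,
                            water_equivalent_ratio = 1),
    liver = ia_material("liver", rho = 1060, c = 1585, grueneisen = 0.2,
                        mu_a = .water_mu_a_table, light_yield = light_yield,
                        water_equivalent_ratio = 1.06),
    tumor = ia_material("tumor", rho = 1045, c = 1556.9, grueneisen = 0.2,
                        mu_a = .ink_mu_a_1pct, light_yield = light_yield,
                        water_equivalent_ratio = 1.04),
    stop("unknown material: ", name)
  )
}
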