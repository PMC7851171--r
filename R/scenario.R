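#' Simulation grid specification
#'
#' Holds the spatial discretization and the time step derived from the CFL
#' stability condition `dt = cfl * dx / c_ref`, where `c_ref` is the maximum
#' speed of sound in the simulated geometry.
#'
#' @param dx axial grid spacing in m (default 25 um).
#' @param dy lateral grid spacing in m (default 50 um), used in 2D mode.
#' @param cfl Courant-Friedrichs-Lewy number (default 0.3, must be <= 0.3).
#' @param c_ref reference (maximum) speed of sound in m/s.
#' @return An object of class `ia_grid`.
#' @export
ia_grid <- function(dx = 25e-6, dy = 50e-6, cfl = 0.3, c_ref = 1484.1) {
  if (dx <= 0 || dy <= 0) stop("grid spacings must be > 0")
  if (cfl <= 0 || cfl > 0.3) stop("CFL must lie in (0, 0.3]")
  if (c_ref <= 0) stop("c_ref must be > 0")
  structure(list(dx = dx, dy = dy, cfl = cfl, c_ref = c_ref,
                 dt = cfl * dx / c_ref),
            class = "ia_grid")
}

.layer <- function(material, x0, x1) {
  stopifnot(inherits(material, "ia_material"), x1 > x0)
  list(material = material, x0 = x0, x1 = x1)
}

.validate_layers <- function(layers) {
  if (!length(layers)) stop("scenario needs at least one layer")
  x0 <- vapply(layers, `[[`, numeric(1), "x0")
  x1 <- vapply(layers, `[[`, numeric(1), "x1")
  o <- order(x0)
  layers <- layers[o]; x0 <- x0[o]; x1 <- x1[o]
  if (length(layers) > 1L) {
    gaps <- utils::head(x1, -1) - utils::tail(x0, -1)
    scale <- max(abs(x1))
    if (any(abs(gaps) > 1e-12 * max(scale, 1)))
      stop("layers must tile the axis without gaps or overlaps")
  }
  layers
}

#' Layered phantom scenario
#'
#' A scenario is the full geometric and material description of one
#' simulated experiment: the ordered material layers along the beam axis
#' (0-based axial coordinate with origin at the water-tank / phantom
#' entrance, beam travelling in +x), the upstream beam-line degraders
#' (traversed by the protons but not simulated acoustically), the water
#' temperature, the sensor placement and the grid specification.
#'
#' Use [build_scenario()] for the presets used throughout the package.
#'
#' @param layers list of layers, each `list(material, x0, x1)` (m).
#' @param beamline list of upstream degraders, each
#'   `list(material, thickness)` (m), in beam order.
#' @param temperature water temperature in degC (recorded; the built-in
#'   water properties correspond to 20.5 degC).
#' @param sensor `list(position, geometry, diameter)` with position in m on
#'   the beam axis, geometry `"point"` or `"disk"`, and aperture diameter in
#'   m for disk sensors (default 3.5 mm).
#' @param grid an [ia_grid()]; its `c_ref` is overwritten with the maximum
#'   speed of sound over the scenario materials.
#' @param preset optional name of the generating preset.
#' @param meta optional named list of extra scenario annotations.
#' @return An object of class `ia_scenario`.
#' @export
ia_scenario <- function(layers, beamline = list(), temperature = 20.5,
                        sensor = list(position = 36e-3, geometry = "disk",
                                      diameter = 3.5e-3),
                        grid = ia_grid(), preset = NA_character_,
                        meta = list()) {
  layers <- .validate_layers(layers)
  x0 <- layers[[1]]$x0
  x1 <- layers[[length(layers)]]$x1
  if (sensor$position < x0 || sensor$position > x1)
    stop("sensor position lies outside the layered domain")
  if (is.null(sensor$diameter)) sensor$diameter <- 3.5e-3
  cmax <- max(vapply(layers, function(l) l$material$c, numeric(1)))
  grid$c_ref <- cmax
  grid$dt <- grid$cfl * grid$dx / grid$c_ref
  structure(list(layers = layers, beamline = beamline,
                 temperature = temperature, sensor = sensor, grid = grid,
                 preset = preset, meta = meta),
            class = "ia_scenario")
}

#' @export
print.ia_scenario <- function(x, ...) {
  cat(sprintf("<ia_scenario> preset=%s, %d layers on [%g, %g] mm, T=%g degC\n",
              x$preset, length(x$layers), 1e3 * x$layers[[1]]$x0,
              1e3 * x$layers[[length(x$layers)]]$x1, x$temperature))
  for (l in x$layers)
    cat(sprintf("  [%9.3f, %9.3f] mm  %s\n", 1e3 * l$x0, 1e3 * l$x1,
                l$material$name))
  cat(sprintf("  sensor: %s at %g mm; c_ref=%g m/s, dt=%g ns\n",
              x$sensor$geometry, 1e3 * x$sensor$position,
              x$grid$c_ref, 1e9 * x$grid$dt))
  invisible(x)
}

# Index of the layer containing each x (clamped to the domain ends).
scenario_layer_index <- function(scenario, x) {
  x0 <- vapply(scenario$layers, `[[`, numeric(1), "x0")
  x1v <- scenario$layers[[length(scenario$layers)]]$x1
  idx <- findInterval(x, c(x0, x1v), rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), length(scenario$layers))
}

# Vector of a material property evaluated at positions x.
scenario_property <- function(scenario, x, field) {
  vals <- vapply(scenario$layers, function(l) l$material[[field]], numeric(1))
  vals[scenario_layer_index(scenario, x)]
}

# Beam-line water-equivalent thickness (m) of the upstream degraders.
beamline_wet <- function(scenario) {
  extra <- scenario$meta$beamline_wet
  if (is.null(extra)) extra <- 0
  if (!length(scenario$beamline)) return(extra)
  extra + sum(vapply(scenario$beamline, function(d)
    d$thickness * d$material$water_equivalent_ratio, numeric(1)))
}

# Water-equivalent thickness calibration of the clinical beam line (range
# shifter and nozzle of the 130 MeV treatment beam), chosen so that the
# Bragg peak of the analytic depth-dose model falls at 11.4 cm along the
# beam axis inside the phantom.
.clinical_beamline_wet <- 1.248e-3

#' Build one of the preset scenarios
#'
#' Three presets cover the studied configurations:
#' \describe{
#'   \item{`tandem22`}{22 MeV mono-energetic beam entering a water tank
#'     through a 50 um polyimide foil after the 11.4 um titanium vacuum
#'     window and a 6 cm air gap. A contrast-agent phantom (sealed by a
#'     50 um polyimide foil) starts 1.6 mm past the tank entrance. A 3.5 mm
#'     disk sensor faces the beam on axis, 36 mm from the entrance window.}
#'   \item{`tandem22_ripple`}{as `tandem22`, with a ripple-filter range
#'     spreading law attached (see [ripple_spread_dose()]).}
#'   \item{`clinical_liver`}{130 MeV beam stopping inside a 2 cm hepatic
#'     tumor embedded in liver; the tumor is positioned so that the Bragg
#'     peak (11.4 cm along the beam axis) lies a configurable distance past
#'     the proximal tumor edge (default 14.49 mm). An ideal point sensor
#'     sits 27 cm from the phantom entrance.}
#' }
#'
#' @param preset `"tandem22"`, `"tandem22_ripple"` or `"clinical_liver"`.
#' @param overrides named list of recognized parameter overrides:
#'   `phantom_material` (`"india_ink"` or `"water"`), `ink_concentration`,
#'   `phantom_start`, `phantom_length`, `rear_foil` (logical),
#'   `sensor_position`, `sensor_geometry`, `light_yield`, `temperature`,
#'   `bragg_to_edge`, `tumor_offset`, `beamline_wet`, `dx`, `dy`, `cfl`.
#' @return An [ia_scenario()].
#' @export
build_scenario <- function(preset = c("tandem22", "tandem22_ripple",
                                      "clinical_liver"),
                           overrides = list()) {
  preset <- match.arg(preset)
  unknown <- setdiff(names(overrides),
                     c("phantom_material", "ink_concentration",
                       "phantom_start", "phantom_length", "rear_foil",
                       "sensor_position", "sensor_geometry", "light_yield",
                       "temperature", "bragg_to_edge", "tumor_offset",
                       "beamline_wet", "dx", "dy", "cfl"))
  if (length(unknown))
    stop("unknown override(s): ", paste(unknown, collapse = ", "))
  ov <- function(key, default) {
    if (!is.null(overrides[[key]])) overrides[[key]] else default
  }
  ly <- ov("light_yield", 0.1)

  if (preset %in% c("tandem22", "tandem22_ripple")) {
    foil <- builtin_material("polyimide", light_yield = ly)
    water <- builtin_material("water", light_yield = ly)
    ca_name <- ov("phantom_material", "india_ink")
    ca <- builtin_material(ca_name, light_yield = ly,
                           ink_concentration = ov("ink_concentration", 1))
    p0 <- ov("phantom_start", 1.6e-3)
    plen <- ov("phantom_length", 20e-3)
    foil_t <- 50e-6
    sens <- ov("sensor_position", 36e-3)
    xmax <- max(sens + 10e-3, p0 + plen + 10e-3)
    layers <- list(
      .layer(builtin_material("air"), -2e-3, 0),
      .layer(foil, 0, foil_t),
      .layer(water, foil_t, p0),
      .layer(foil, p0, p0 + foil_t),
      .layer(ca, p0 + foil_t, p0 + foil_t + plen))
    nxt <- p0 + foil_t + plen
    if (isTRUE(ov("rear_foil", FALSE))) {
      layers <- c(layers, list(.layer(foil, nxt, nxt + foil_t)))
      nxt <- nxt + foil_t
    }
    layers <- c(layers, list(.layer(water, nxt, xmax)))
    beamline <- list(list(material = builtin_material("titanium"),
                          thickness = 11.4e-6),
                     list(material = builtin_material("air"),
                          thickness = 6e-2))
    meta <- list(phantom_start = p0, phantom_material = ca_name)
    if (preset == "tandem22_ripple")
      meta$ripple <- list(max_shift = .ripple_max_shift,
                          lateral_broadening = .ripple_lateral_broadening)
    sc <- ia_scenario(
      layers, beamline = beamline, temperature = ov("temperature", 20.5),
      sensor = list(position = sens,
                    geometry = ov("sensor_geometry", "disk"),
                    diameter = 3.5e-3),
      grid = ia_grid(dx = ov("dx", 25e-6), dy = ov("dy", 50e-6),
                     cfl = ov("cfl", 0.3)),
      preset = preset, meta = meta)
    return(sc)
  }

  # clinical_liver
  liver <- builtin_material("liver", light_yield = ly)
  tumor <- builtin_material("tumor", light_yield = ly)
  water <- builtin_material("water", light_yield = ly)
  bragg_depth <- 0.114                     # design anchor along the beam axis
  b2e <- ov("bragg_to_edge", 14.49e-3)
  t0 <- ov("tumor_offset", bragg_depth - b2e)
  tlen <- 20e-3
  if (t0 <= 0) stop("tumor offset places the tumor outside the phantom")
  sens <- ov("sensor_position", 0.27)
  xmax <- sens + 15e-3
  layers <- list(
    .layer(water, -5e-3, 0),
    .layer(liver, 0, t0),
    .layer(tumor, t0, t0 + tlen),
    .layer(liver, t0 + tlen, xmax))
  sc <- ia_scenario(
    layers, beamline = list(), temperature = ov("temperature", 20.5),
    sensor = list(position = sens,
                  geometry = ov("sensor_geometry", "point"),
                  diameter = 3.5e-3),
    grid = ia_grid(dx = ov("dx", 50e-6), dy = ov("dy", 50e-6),
                   cfl = ov("cfl", 0.3)),
    preset = preset,
    meta = list(tumor_offset = t0, tumor_length = tlen,
                bragg_depth = bragg_depth,
                beamline_wet = ov("beamline_wet", .clinical_beamline_wet)))
  sc
}
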