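#' Scenario serialization
#'
#' Scenarios round-trip losslessly through a versioned YAML schema. All
#' lengths are in meters, densities in kg/m^3, speeds of sound in m/s,
#' optical absorption in 1/mm, temperatures in degC; the units are recorded
#' in the file itself.
#'
#' @param scenario an [ia_scenario()].
#' @param path file to write to (YAML).
#' @return `scenario_write()` returns `path` invisibly; `scenario_read()`
#'   returns the reconstructed [ia_scenario()].
#' @export
scenario_write <- function(scenario, path) {
  mat2list <- function(m) {
    mu <- m$mu_a
    mu_out <- if (is.matrix(mu)) {
      list(wavelength_nm = as.numeric(mu[, 1]), mu_a = as.numeric(mu[, 2]))
    } else as.numeric(mu)
    list(name = m$name, rho = m$rho, c = m$c, grueneisen = m$grueneisen,
         mu_a = mu_out, light_yield = m$light_yield,
         water_equivalent_ratio = m$water_equivalent_ratio)
  }
  doc <- list(
    schema = "ionobeat/scenario",
    schema_version = 1L,
    units = list(length = "m", density = "kg/m^3", speed_of_sound = "m/s",
                 mu_a = "1/mm", temperature = "degC"),
    preset = scenario$preset,
    temperature = scenario$temperature,
    sensor = scenario$sensor,
    grid = list(dx = scenario$grid$dx, dy = scenario$grid$dy,
                cfl = scenario$grid$cfl),
    layers = lapply(scenario$layers, function(l)
      list(material = mat2list(l$material), x0 = l$x0, x1 = l$x1)),
    beamline = lapply(scenario$beamline, function(d)
      list(material = mat2list(d$material), thickness = d$thickness)),
    meta = scenario$meta)
  writeLines(yaml::as.yaml(doc, precision = 17), path)
  invisible(path)
}

#' @rdname scenario_write
#' @export
scenario_read <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$schema, "ionobeat/scenario"))
    stop("not an ionobeat scenario file")
  if (doc$schema_version != 1L)
    stop("unsupported scenario schema version: ", doc$schema_version)
  list2mat <- function(m) {
    mu <- m$mu_a
    mu_in <- if (is.list(mu)) {
      cbind(wavelength_nm = as.numeric(mu$wavelength_nm),
            mu_a = as.numeric(mu$mu_a))
    } else as.numeric(mu)
    ia_material(m$name, rho = m$rho, c = m$c, grueneisen = m$grueneisen,
                mu_a = mu_in, light_yield = m$light_yield,
                water_equivalent_ratio = m$water_equivalent_ratio)
  }
  layers <- lapply(doc$layers, function(l)
    .layer(list2mat(l$material), l$x0, l$x1))
  beamline <- lapply(doc$beamline, function(d)
    list(material = list2mat(d$material), thickness = d$thickness))
  sensor <- doc$sensor
  ia_scenario(layers, beamline = beamline, temperature = doc$temperature,
              sensor = sensor,
              grid = ia_grid(dx = doc$grid$dx, dy = doc$grid$dy,
                             cfl = doc$grid$cfl),
              preset = if (is.null(doc$preset)) NA_character_ else doc$preset,
              meta = doc$meta)
}
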