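#' Pressure trace container
#'
#' A uniformly sampled sensor time series, the unit every analysis stage
#' consumes. The default sampling rate matches the acquisition system
#' (156.25 MHz).
#'
#' @param time time axis in s (uniform).
#' @param pressure pressure in Pa.
#' @param component provenance label: `"iono"`, `"photo"`, `"combined"` or
#'   free text.
#' @param meta named list of provenance details (scenario preset, pulse
#'   train id, ...).
#' @return An object of class `ia_trace`.
#' @export
ia_trace <- function(time, pressure, component = "iono", meta = list()) {
  stopifnot(length(time) == length(pressure))
  if (length(time) < 2L) stop("trace needs >= 2 samples")
  dt <- diff(time[1:2])
  if (any(!is.finite(pressure))) stop("pressure must be finite")
  structure(list(time = time, pressure = pressure, fs = 1 / dt,
                 component = component, meta = meta),
            class = "ia_trace")
}

#' @export
print.ia_trace <- function(x, ...) {
  cat(sprintf(
    "<ia_trace> %s: %d samples @ %.4g MHz, t in [%.3g, %.3g] us, peak |p| = %.4g Pa\n",
    x$component, length(x$time), x$fs / 1e6, 1e6 * min(x$time),
    1e6 * max(x$time), max(abs(x$pressure))))
  invisible(x)
}

#' @export
plot.ia_trace <- function(x, ...) {
  graphics::plot(x$time * 1e6, x$pressure, type = "l",
                 xlab = expression(t ~ (mu * s)), ylab = "p (Pa)", ...)
  invisible(x)
}

# Resample a trace onto a new uniform rate by linear interpolation.
trace_resample <- function(trace, fs) {
  if (abs(trace$fs - fs) < 1e-6 * fs) return(trace)
  t_new <- seq(trace$time[1], trace$time[length(trace$time)], by = 1 / fs)
  p_new <- stats::approx(trace$time, trace$pressure, xout = t_new)$y
  ia_trace(t_new, p_new, component = trace$component, meta = trace$meta)
}

#' Pressure trace CSV round trip
#'
#' @param trace an [ia_trace()].
#' @param path CSV file path.
#' @return the path (write) / the reconstructed trace (read).
#' @export
trace_write <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time, pressure_Pa = trace$pressure),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname trace_write
#' @export
trace_read <- function(path) {
  d <- utils::read.csv(path)
  ia_trace(d[[1]], d[[2]], component = "imported")
}
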