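.E_CHARGE <- 1.602176634e-19

#' Beam intensity time profiles
#'
#' A pulse train is the beam intensity (protons/s) on a uniform time axis,
#' together with the bookkeeping needed by the acoustic convolution stage:
#' total particle count, total charge and the generating parameters.
#'
#' @name pulse_trains
#' @details
#' The default time resolution is the acquisition sampling interval
#' (1/156.25 MHz); [synchrotron_burst()] refines it automatically when the
#' micro-pulse width demands it.
NULL

.pulse_train <- function(t, intensity, kind, parameters, seed = NULL) {
  if (any(intensity < -1e-12)) stop("intensity must be >= 0")
  intensity[intensity < 0] <- 0
  dt <- t[2] - t[1]
  total <- sum(intensity) * dt
  structure(list(time = t, intensity = intensity, dt = dt,
                 total_protons = total,
                 total_charge = total * .E_CHARGE,
                 kind = kind, parameters = parameters, seed = seed),
            class = "ia_pulsetrain")
}

#' @export
print.ia_pulsetrain <- function(x, ...) {
  cat(sprintf(
    "<ia_pulsetrain> %s: %d samples, dt=%.3g ns, %.4g protons (%.4g pC)\n",
    x$kind, length(x$time), 1e9 * x$dt, x$total_protons,
    1e12 * x$total_charge))
  invisible(x)
}

#' Square pulse train
#'
#' `n_cycles` rectangular pulses of the given width and period. The
#' discretized intensity uses exact fractional sample coverage, so the
#' time integral equals `n_cycles * protons_per_pulse` to round-off.
#'
#' @param width pulse width in s (0 < width <= period).
#' @param period pulse repetition period in s.
#' @param n_cycles number of pulses (>= 1).
#' @param protons_per_pulse particles in each pulse.
#' @param dt sample interval in s (default 1/156.25 MHz).
#' @return An `ia_pulsetrain`.
#' @examples
#' tr <- square_pulse_train(200e-9, 400e-9, 25, 2.8e6)
#' max(tr$time)   # 10 us burst
#' @export
square_pulse_train <- function(width, period, n_cycles = 1,
                               protons_per_pulse = 2.8e6,
                               dt = 1 / 156.25e6) {
  if (width <= 0 || width > period) stop("need 0 < width <= period")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  t_end <- n_cycles * period
  n <- ceiling(t_end / dt) + 1L
  t <- (0:(n - 1L)) * dt
  # cumulative on-time, clamped to the n_cycles pulses
  ontime <- function(tt) {
    tt <- pmin(pmax(tt, 0), t_end)
    k <- pmin(floor(tt / period), n_cycles - 1)
    k * width + pmin(tt - k * period, width)
  }
  cover <- (ontime(t + dt) - ontime(t)) / dt
  intensity <- cover * protons_per_pulse / width
  .pulse_train(t, intensity, "square_burst",
               list(width = width, period = period, n_cycles = n_cycles,
                    duty = width / period,
                    protons_per_pulse = protons_per_pulse))
}

#' Gaussian proton pulse (synchro-cyclotron)
#'
#' A single Gaussian pulse truncated at +/- 5 sigma, normalized so the time
#' integral equals the particle count. Either `fwhm` or `sigma` may be
#' given; they are related by `FWHM = 2 sqrt(2 ln 2) sigma`.
#'
#' @param fwhm full width at half maximum in s (e.g. 2.5e-6 for the
#'   2.5 us clinical pulse).
#' @param sigma alternative width parameterization in s.
#' @param protons particles in the pulse.
#' @param dt sample interval in s.
#' @return An `ia_pulsetrain`.
#' @examples
#' gaussian_pulse(fwhm = 2.5e-6, protons = 1e6)$total_charge  # ~0.16 pC
#' @export
gaussian_pulse <- function(fwhm = NULL, sigma = NULL, protons = 1e6,
                           dt = 1 / 156.25e6) {
  if (is.null(sigma)) {
    if (is.null(fwhm)) stop("give fwhm or sigma")
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
  }
  if (sigma <= 0) stop("pulse width must be > 0")
  if (protons < 0) stop("protons must be >= 0")
  t_end <- 10 * sigma
  n <- ceiling(t_end / dt) + 1L
  t <- (0:(n - 1L)) * dt
  g <- exp(-(t - 5 * sigma)^2 / (2 * sigma^2))
  s <- sum(g) * dt
  intensity <- if (s > 0 && protons > 0) g / s * protons else 0 * g
  .pulse_train(t, intensity, "gaussian",
               list(sigma = sigma, fwhm = sigma * 2 * sqrt(2 * log(2)),
                    protons = protons))
}

#' Stochastic synchrotron spill micro-structure
#'
#' A quasi-continuous burst of Gaussian micro-pulses (width `sigma_micro`)
#' repeated every `period_micro` (pulse repetition frequency
#' `1/period_micro`, 4.39 MHz at the default 228 ns). Each micro-pulse
#' amplitude is scaled by an independent Poisson(1) draw to model spill
#' fluence fluctuation, so the expected time integral of the burst equals
#' `rate * duration`. Micro-pulse arrival-time jitter can be enabled with
#' `arrival_jitter_sd` (default off).
#'
#' The sample interval is refined automatically to resolve the micro-pulse
#' shape (at least `min_samples_per_sigma` samples per sigma) unless `dt`
#' is given explicitly.
#'
#' @param duration burst length in s (default 50 ms).
#' @param sigma_micro micro-pulse Gaussian sigma in s (default 19.75 ns).
#' @param period_micro micro-pulse repetition period in s (default 228 ns).
#' @param rate mean particle rate in protons/s (default 3.2e9).
#' @param seed integer seed (required: the train is stochastic).
#' @param dt sample interval in s; `NULL` for automatic.
#' @param min_samples_per_sigma resolution criterion for the automatic dt.
#' @param arrival_jitter_sd Gaussian sd of arrival-time jitter in s.
#' @return An `ia_pulsetrain`.
#' @export
synchrotron_burst <- function(duration = 50e-3, sigma_micro = 19.75e-9,
                              period_micro = 228e-9, rate = 3.2e9,
                              seed = 1L, dt = NULL,
                              min_samples_per_sigma = 8,
                              arrival_jitter_sd = 0) {
  if (duration < period_micro) stop("duration must cover >= 1 micro-pulse")
  if (is.null(seed)) stop("a seed is required for the stochastic burst")
  fs_acq <- 156.25e6
  if (is.null(dt)) {
    dt <- 1 / fs_acq
    while (sigma_micro / dt < min_samples_per_sigma) dt <- dt / 2
  }
  n_micro <- floor(duration / period_micro)
  set.seed(seed)
  amp <- stats::rpois(n_micro, 1)
  centers <- (seq_len(n_micro) - 0.5) * period_micro
  if (arrival_jitter_sd > 0)
    centers <- centers + stats::rnorm(n_micro, 0, arrival_jitter_sd)
  protons_k <- amp * rate * period_micro
  n <- ceiling(duration / dt) + 1L
  t <- (0:(n - 1L)) * dt
  half <- ceiling(5 * sigma_micro / dt)
  ci <- round(centers / dt) + 1L
  # two passes: per-pulse discrete normalization, then accumulation
  gsum <- numeric(n_micro)
  for (j in (-half):half) {
    idx <- ci + j
    valid <- idx >= 1L & idx <= n
    tt <- (idx - 1L) * dt
    gsum[valid] <- gsum[valid] +
      exp(-(tt[valid] - centers[valid])^2 / (2 * sigma_micro^2))
  }
  scale_k <- ifelse(gsum > 0, protons_k / (gsum * dt), 0)
  intensity <- numeric(n)
  for (j in (-half):half) {
    idx <- ci + j
    valid <- which(idx >= 1L & idx <= n)
    tt <- (idx[valid] - 1L) * dt
    contrib <- scale_k[valid] *
      exp(-(tt - centers[valid])^2 / (2 * sigma_micro^2))
    iv <- idx[valid]
    # micro-pulses are spaced wider than the kernel support: indices unique
    intensity[iv] <- intensity[iv] + contrib
  }
  .pulse_train(t, intensity, "synchrotron",
               list(duration = duration, sigma_micro = sigma_micro,
                    period_micro = period_micro, rate = rate,
                    n_micro = n_micro,
                    prf_Hz = 1 / period_micro,
                    arrival_jitter_sd = arrival_jitter_sd),
               seed = seed)
}

#' Pulse-train CSV round trip
#'
#' Two-column CSV (time in s, intensity in protons/s).
#'
#' @param train an `ia_pulsetrain`.
#' @param path CSV file path.
#' @return `pulsetrain_write()` the path, invisibly; `pulsetrain_read()`
#'   the reconstructed train (kind `"imported"`).
#' @export
pulsetrain_write <- function(train, path) {
  utils::write.csv(data.frame(time_s = train$time,
                              intensity_protons_per_s = train$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname pulsetrain_write
#' @export
pulsetrain_read <- function(path) {
  d <- utils::read.csv(path)
  .pulse_train(d[[1]], d[[2]], "imported", list())
}
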