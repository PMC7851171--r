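#' Convolve an impulse response with a beam time structure
#'
#' The propagated trace assumes instantaneous (delta-pulse) energy
#' deposition by `protons_ref` particles. Convolving with a pulse train
#' rescales and spreads the response over the actual beam time profile:
#' `p(t) = sum_tau impulse(t - tau) * intensity(tau) * dtau / protons_ref`
#' (pressure is proportional to dose, hence to the particle count).
#'
#' @param impulse an [ia_trace()] impulse response.
#' @param train an `ia_pulsetrain`; resampled internally to the trace rate
#'   if needed.
#' @param protons_ref particle count behind the impulse response; defaults
#'   to `impulse$meta$protons_ref`.
#' @return An [ia_trace()] of length `length(impulse) + length(train) - 1`.
#' @export
apply_pulse_train <- function(impulse, train, protons_ref = NULL) {
  if (!length(train$intensity)) stop("empty pulse train")
  if (is.null(protons_ref)) protons_ref <- impulse$meta$protons_ref
  if (is.null(protons_ref))
    stop("protons_ref unknown: pass it or use a propagated impulse response")
  fs <- impulse$fs
  if (abs(train$dt - 1 / fs) > 1e-9 * train$dt) {
    t_new <- seq(0, train$time[length(train$time)], by = 1 / fs)
    intensity <- stats::approx(train$time, train$intensity, xout = t_new,
                               rule = 2)$y
  } else intensity <- train$intensity
  h <- impulse$pressure
  w <- intensity / fs / protons_ref
  n <- length(h) + length(w) - 1L
  nf <- .next_pow2(n)
  H <- stats::fft(c(h, numeric(nf - length(h))))
  W <- stats::fft(c(w, numeric(nf - length(w))))
  y <- Re(stats::fft(H * W, inverse = TRUE))[seq_len(n)] / nf
  t_out <- impulse$time[1] + (seq_len(n) - 1L) / fs
  ia_trace(t_out, y, component = impulse$component,
           meta = c(impulse$meta, list(train_kind = train$kind,
                                       train_protons = train$total_protons)))
}

#' Detector electrical response
#'
#' Applies the broadband transducer surrogate response: a cascaded
#' second-order-section bandpass Butterworth filter of order 2
#' (0.15-15 MHz by default), forward (causal) by default as for the real
#' front-end electronics; set `zero_phase = TRUE` for analysis-only
#' zero-delay filtering.
#'
#' @param trace an [ia_trace()].
#' @param band length-2 passband in Hz.
#' @param zero_phase logical; forward-backward filtering when `TRUE`.
#' @return the filtered [ia_trace()].
#' @export
detector_response <- function(trace, band = c(0.15e6, 15e6),
                              zero_phase = FALSE) {
  if (band[2] >= trace$fs / 2) stop("band above the Nyquist frequency")
  sos <- butter_sos(2, band, "pass", trace$fs)
  p <- if (zero_phase) sos_filtfilt(sos, trace$pressure)
       else sos_filter(sos, trace$pressure)
  ia_trace(trace$time, p, component = trace$component,
           meta = c(trace$meta, list(detector_band_Hz = band)))
}

#' Superpose the photoacoustic onto the ionoacoustic trace
#'
#' `combined = iono + correction_factor * photo`. The correction factor
#' rescales the photoacoustic contribution simulated at the literature
#' light yield of 0.1 photon/MeV; a factor of 5e5 is equivalent to a light
#' yield of about 5e4 photons/MeV.
#'
#' @param iono,photo [ia_trace()] objects on identical time axes.
#' @param correction_factor non-negative multiplier for the photoacoustic
#'   component.
#' @return combined [ia_trace()] (component `"combined"`).
#' @export
superpose_photoacoustic <- function(iono, photo, correction_factor = 5e5) {
  if (length(iono$time) != length(photo$time) ||
      abs(iono$time[1] - photo$time[1]) > 1e-12 ||
      abs(iono$fs - photo$fs) > 1e-3)
    stop("traces must share one time axis")
  ia_trace(iono$time, iono$pressure + correction_factor * photo$pressure,
           component = "combined",
           meta = c(iono$meta, list(correction_factor = correction_factor)))
}
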