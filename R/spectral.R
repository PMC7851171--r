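#' Spectral amplitude at the excitation frequency
#'
#' Windows the trace (half-open window on the sample grid), zero-pads in
#' the time domain to reach the requested frequency resolution, and
#' evaluates the magnitude spectrum at the bin nearest `f0`. The amplitude
#' is normalized so that a unit sinusoid filling the window yields 1.
#'
#' @param trace an [ia_trace()].
#' @param f0 excitation frequency in Hz (below Nyquist).
#' @param window analysis window `c(t_start, t_end)` in s (default
#'   21-22.5 us, the direct-signal window that excludes the tank entrance
#'   window signal in the tandem setup).
#' @param df frequency resolution in Hz obtained by zero padding
#'   (default 5 kHz).
#' @return An object of class `ia_spectral_amplitude` with fields `f0`,
#'   `df`, `window`, `amplitude` (Pa) and `f_eval` (the evaluated bin).
#' @export
amplitude_at_frequency <- function(trace, f0, window = c(21e-6, 22.5e-6),
                                   df = 5e3) {
  if (f0 >= trace$fs / 2) stop("f0 must be below the Nyquist frequency")
  if (df <= 0) stop("df must be > 0")
  sel <- trace$time >= window[1] & trace$time < window[2]
  if (!any(sel)) stop("analysis window lies outside the trace")
  x <- trace$pressure[sel]
  nwin <- length(x)
  nfft <- max(nwin, round(trace$fs / df))
  df_act <- trace$fs / nfft
  X <- stats::fft(c(x, numeric(nfft - nwin)))
  k <- round(f0 / df_act)
  amp <- 2 * Mod(X[k + 1]) / nwin
  structure(list(f0 = f0, df = df_act, window = window,
                 amplitude = amp, f_eval = k * df_act),
            class = "ia_spectral_amplitude")
}

#' Phase shift between two traces at the excitation frequency
#'
#' Both traces are bandpass filtered (cascaded second-order-section
#' Butterworth, band `f0 +/- 10%`), analytic signals are formed via the
#' Hilbert construction, and the phase shift is the circular mean over the
#' window of the angle of `analytic_test * Conj(analytic_reference)`,
#' reported in degrees in (-180, 180].
#'
#' @param reference,test [ia_trace()] objects with identical sampling.
#' @param f0 excitation frequency in Hz.
#' @param window analysis window `c(t_start, t_end)` in s.
#' @return phase shift in degrees.
#' @export
phase_shift <- function(reference, test, f0, window = c(21e-6, 22.5e-6)) {
  if (abs(reference$fs - test$fs) > 1e-3)
    stop("traces must share the sampling rate")
  if (f0 >= reference$fs / 2) stop("f0 must be below the Nyquist frequency")
  sos <- butter_sos(2, c(0.9 * f0, 1.1 * f0), "pass", reference$fs)
  ar <- analytic_signal(sos_filter(sos, reference$pressure))
  at <- analytic_signal(sos_filter(sos, test$pressure))
  sel <- reference$time >= window[1] & reference$time < window[2]
  if (!any(sel)) stop("analysis window lies outside the trace")
  er <- Mod(ar[sel])
  if (max(er) < 1e-12 * max(Mod(ar), 1e-300))
    stop("reference envelope vanishes in the window: phase undefined")
  z <- at[sel] * Conj(ar[sel])
  ph <- Arg(sum(z)) * 180 / pi
  if (ph <= -180) ph <- ph + 360
  ph
}

#' Bragg-peak-to-target-edge distance from spectrum beats
#'
#' Implements the frequency-domain range estimator for quasi-continuous
#' beams: the magnitude spectrum of the trace oscillates (beats) with a
#' period set by the time-of-flight difference between the Bragg-peak
#' pulse and the target-entrance pulse. The spectrum is smoothed with a
#' zero-phase second-order Butterworth lowpass whose cutoff retains
#' spectral oscillations up to the `tof_cutoff` quefrency, the smoothed
#' envelope is Fourier transformed, the quefrency axis is mapped to
#' distance via `d = c * quefrency`, and the strongest beat peak beyond
#' `min_distance` is reported.
#'
#' @param trace an [ia_trace()].
#' @param c speed of sound used for the quefrency-to-distance mapping in
#'   m/s (the tumor speed of sound, 1556.9, for the clinical scenario).
#' @param tof_cutoff maximum retained quefrency in s (default 120 us).
#' @param truth optional `list(distance =, range =)` in m enabling the
#'   relative-error fields.
#' @param min_distance beat peaks below this distance are attributed to
#'   the zero-quefrency lobe and ignored (default 2 mm); it also sets the
#'   quefrency highpass (`min_distance / c`) that removes the smooth
#'   spectral baseline before the beat transform.
#' @param band optional `c(f_lo, f_hi)` in Hz restricting the analysis to
#'   the spectral support of the signal (e.g. `c(0, 1e6)` for clinical
#'   traces whose interfering components live below 1 MHz); `NULL` uses
#'   the full spectrum.
#' @param detection_threshold a candidate peak counts as a detected beat
#'   only if it exceeds this multiple of the local background (median beat
#'   magnitude in an annulus of `1..5 x min_distance` around the peak);
#'   single-source spectra produce only broad undulations that fail this
#'   prominence test.
#' @return An object of class `ia_beat_result`: `detected`,
#'   `peak_distance` (m), `peak_quefrency` (s), `distance` / `beat`
#'   axes of the beat magnitude, the spectrum `frequency` / `envelope`,
#'   and when truth is given `rel_error_range_pct`,
#'   `rel_error_distance_pct`.
#' @export
beat_distance <- function(trace, c, tof_cutoff = 120e-6, truth = NULL,
                          min_distance = 2e-3, band = NULL,
                          detection_threshold = 1.25) {
  fs <- trace$fs
  n <- .next_pow2(length(trace$pressure))   # fast, fine-grained FFT size
  S <- Mod(stats::fft(c(trace$pressure,
                        numeric(n - length(trace$pressure)))))[seq_len(n / 2)]
  df <- fs / n
  fax <- (seq_along(S) - 1L) * df
  if (!is.null(band)) {
    S <- S[fax >= band[1] & fax <= band[2]]
    fax <- fax[fax >= band[1] & fax <= band[2]]
  }
  q_nyq <- 1 / (2 * df)
  if (tof_cutoff >= q_nyq)
    stop("trace too short to resolve beats below the quefrency cutoff")
  sosl <- butter_sos(2, tof_cutoff, "low", 1 / df)  # quefrency lowpass
  env <- sos_filtfilt(sosl, S)
  # smooth spectral baseline (quefrencies below min_distance / c) removed
  q_hp <- min_distance / c
  det <- env - sos_filtfilt(butter_sos(2, q_hp, "low", 1 / df), env)
  nb <- .next_pow2(4 * length(det))         # zero-pad for peak resolution
  B <- Mod(stats::fft(c(det, numeric(nb - length(det)))))[seq_len(nb / 2)]
  q <- (seq_along(B) - 1L) / (nb * df)
  d <- c * q
  sel <- which(d > min_distance & q <= tof_cutoff)
  res <- structure(list(frequency = fax,
                        envelope = env, quefrency = q, distance = d,
                        beat = B, c = c, detected = FALSE,
                        peak_distance = NA_real_,
                        peak_quefrency = NA_real_, truth = truth),
                   class = "ia_beat_result")
  if (!length(sel)) return(res)
  bs <- B[sel]
  # local maxima only: a single-source spectrum has no interior beat peak
  g <- diff(bs)
  locmax <- which(g[-1] < 0 & g[-length(g)] > 0) + 1L
  if (!length(locmax)) return(res)
  pk <- locmax[which.max(bs[locmax])]
  dpk <- d[sel][pk]
  ann <- abs(d[sel] - dpk) > min_distance &
    abs(d[sel] - dpk) < 5 * min_distance
  if (any(ann) &&
      bs[pk] < detection_threshold * stats::median(bs[ann])) return(res)
  i <- sel[pk]
  # parabolic interpolation of the beat peak
  off <- 0
  if (i > 1 && i < length(B)) {
    den <- B[i - 1] - 2 * B[i] + B[i + 1]
    if (den != 0) off <- 0.5 * (B[i - 1] - B[i + 1]) / den
  }
  qpk <- (i - 1 + off) / (nb * df)
  res$detected <- TRUE
  res$peak_quefrency <- qpk
  res$peak_distance <- c * qpk
  if (!is.null(truth)) {
    res$rel_error_distance_pct <-
      abs(res$peak_distance - truth$distance) / truth$distance * 100
    res$rel_error_range_pct <-
      abs(res$peak_distance - truth$distance) / truth$range * 100
  }
  res
}

#' @export
print.ia_beat_result <- function(x, ...) {
  if (x$detected) {
    cat(sprintf("<ia_beat_result> beat at %.3f us -> distance %.3f mm (c = %g m/s)\n",
                1e6 * x$peak_quefrency, 1e3 * x$peak_distance, x$c))
    if (!is.null(x$truth))
      cat(sprintf("  truth %.3f mm: error %.3f%% of distance, %.3f%% of range\n",
                  1e3 * x$truth$distance, x$rel_error_distance_pct,
                  x$rel_error_range_pct))
  } else cat("<ia_beat_result> no beat detected\n")
  invisible(x)
}

#' @export
plot.ia_beat_result <- function(x, xlim_mm = c(0, 30), ...) {
  graphics::plot(1e3 * x$distance, x$beat, type = "l", xlim = xlim_mm,
                 xlab = "distance (mm)", ylab = "beat magnitude", ...)
  if (x$detected)
    graphics::abline(v = 1e3 * x$peak_distance, lty = 2, col = 2)
  invisible(x)
}
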