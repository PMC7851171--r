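# Periodized orthogonal discrete wavelet transform built on the Daubechies
# filter bank (see wavelet_coefs.R). The periodized variant keeps exact
# perfect reconstruction at every level, including levels shorter than the
# filter support.

# one analysis step: x (even length) -> list(ca, cd)
.dwt_step <- function(x, lo, hi) {
  N <- length(x)
  half <- N / 2
  k2 <- 2 * (0:(half - 1))
  ca <- numeric(half); cd <- numeric(half)
  for (m in seq_along(lo)) {
    idx <- (k2 + (m - 1)) %% N + 1
    ca <- ca + lo[m] * x[idx]
    cd <- cd + hi[m] * x[idx]
  }
  list(ca = ca, cd = cd)
}

# one synthesis step (adjoint of .dwt_step)
.idwt_step <- function(ca, cd, lo, hi) {
  half <- length(ca)
  N <- 2 * half
  x <- numeric(N)
  k2 <- 2 * (0:(half - 1))
  for (m in seq_along(lo)) {
    idx <- (k2 + (m - 1)) %% N + 1
    x[idx] <- x[idx] + lo[m] * ca + hi[m] * cd
  }
  x
}

# full decomposition to `levels`; returns list(approx, details=list(d1..dL))
.dwt_per <- function(x, levels, lo = .db38_lo, hi = .db38_hi) {
  details <- vector("list", levels)
  cur <- x
  for (j in seq_len(levels)) {
    s <- .dwt_step(cur, lo, hi)
    details[[j]] <- s$cd
    cur <- s$ca
  }
  list(approx = cur, details = details)
}

.idwt_per <- function(dec, lo = .db38_lo, hi = .db38_hi) {
  cur <- dec$approx
  for (j in rev(seq_along(dec$details)))
    cur <- .idwt_step(cur, dec$details[[j]], lo, hi)
  cur
}

#' Wavelet denoising of a pressure trace
#'
#' Denoises broadband ionoacoustic signals with a Daubechies-38
#' decomposition over 10 levels: detail levels whose frequency band lies
#' above `f_cut` (10 MHz at the acquisition rate) are zeroed, a hard
#' threshold at `threshold_frac` of the maximum absolute detail
#' coefficient is applied at `threshold_level`, and the signal is
#' reconstructed. The trace is reflection-padded to a multiple of
#' `2^levels` and cropped after reconstruction.
#'
#' @param trace an [ia_trace()].
#' @param levels number of decomposition levels (default 10).
#' @param threshold_level detail level receiving the hard threshold
#'   (default 5).
#' @param threshold_frac threshold as a fraction of that level's maximum
#'   absolute coefficient (default 0.1).
#' @param f_cut detail bands above this frequency are zeroed (Hz).
#' @return the denoised [ia_trace()].
#' @export
wavelet_denoise <- function(trace, levels = 10, threshold_level = 5,
                            threshold_frac = 0.1, f_cut = 10e6) {
  x <- trace$pressure
  n <- length(x)
  block <- 2^levels
  n_pad <- ceiling(n / block) * block
  if (n_pad > n) {
    # reflect-pad at the end (repeat reflection if the trace is very short)
    pad <- numeric(0)
    while (length(pad) < n_pad - n) pad <- c(pad, rev(x), x)
    x <- c(x, pad[seq_len(n_pad - n)])
  }
  dec <- .dwt_per(x, levels)
  fs <- trace$fs
  for (j in seq_len(levels)) {
    band_hi <- fs / 2^j
    if (band_hi > f_cut) {
      dec$details[[j]][] <- 0
    } else if (j == threshold_level) {
      thr <- threshold_frac * max(abs(dec$details[[j]]))
      dec$details[[j]][abs(dec$details[[j]]) < thr] <- 0
    }
  }
  y <- .idwt_per(dec)[seq_len(n)]
  ia_trace(trace$time, y, component = trace$component,
           meta = c(trace$meta, list(denoised = TRUE)))
}
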