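# Cascaded second-order-section Butterworth filters. Sections are derived
# from the signal-package Butterworth design by zero/pole pairing, which
# keeps the narrow relative bandwidths used here (e.g. 0.15 MHz at a
# 156.25 MHz rate) numerically well conditioned.

.tf2sos <- function(b, a) {
  k <- b[1] / a[1]
  zz <- polyroot(rev(b / b[1]))
  pp <- polyroot(rev(a / a[1]))
  # order poles into conjugate pairs, largest magnitude (most critical) first
  pu <- pp[order(-Mod(pp), Im(pp))]
  used_z <- rep(FALSE, length(zz))
  used_p <- rep(FALSE, length(pp))
  sections <- list()
  while (any(!used_p)) {
    i1 <- which(!used_p)[which.max(Mod(pp[!used_p]))]
    p1 <- pp[i1]; used_p[i1] <- TRUE
    if (abs(Im(p1)) > 1e-10) {
      i2 <- which(!used_p & abs(pp - Conj(p1)) < 1e-8)[1]
    } else {
      cand <- which(!used_p & abs(Im(pp)) < 1e-10)
      i2 <- if (length(cand)) cand[which.max(Mod(pp[cand]))] else NA
    }
    psec <- if (!is.na(i2)) { used_p[i2] <- TRUE; c(p1, pp[i2]) } else p1
    # nearest unused zeros
    zsec <- complex(0)
    for (rep_ in seq_along(psec)) {
      if (!any(!used_z)) break
      j <- which(!used_z)[which.min(abs(zz[!used_z] - p1))]
      zsec <- c(zsec, zz[j]); used_z[j] <- TRUE
    }
    bs <- Re(c(1, -sum(zsec), if (length(zsec) == 2) prod(zsec) else 0))
    if (length(zsec) == 0) bs <- c(1, 0, 0)
    if (length(zsec) == 1) bs <- Re(c(1, -zsec, 0))
    as_ <- Re(c(1, -sum(psec), if (length(psec) == 2) prod(psec) else 0))
    if (length(psec) == 1) as_ <- Re(c(1, -psec, 0))
    sections[[length(sections) + 1L]] <- list(b = bs, a = as_)
  }
  sections[[1]]$b <- sections[[1]]$b * k
  sections
}

# order-n Butterworth as cascaded biquads; type "pass" needs band = c(lo, hi)
# in Hz, "low"/"high" a scalar cutoff.
butter_sos <- function(order, band, type, fs) {
  ny <- fs / 2
  if (any(band >= ny)) stop("filter band must lie below the Nyquist frequency")
  ba <- signal::butter(order, band / ny, type = type)
  .tf2sos(ba$b, ba$a)
}

# causal (forward-only) cascade
sos_filter <- function(sos, x) {
  for (s in sos) x <- as.numeric(signal::filter(s$b, s$a, x))
  x
}

# zero-phase cascade (forward-backward per section)
sos_filtfilt <- function(sos, x) {
  for (s in sos) {
    x <- as.numeric(signal::filter(s$b, s$a, x))
    x <- rev(as.numeric(signal::filter(s$b, s$a, rev(x))))
  }
  x
}

# analytic signal via the frequency-domain Hilbert construction
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
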