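---
title: "Simulating photo-enhanced ionoacoustic range verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating photo-enhanced ionoacoustic range verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionobeat)
```

## The physical problem

A pulsed proton beam stopping in tissue deposits most of its energy in a
narrow region at the end of its range (the Bragg peak). If the pulse is
shorter than the acoustic transit time across the heated volume (stress
confinement), the sudden thermoelastic expansion launches a pressure wave
whose time of flight to an ultrasound sensor encodes the Bragg peak
position. This is ionoacoustic (protoacoustic) range verification. Its
clinical obstacle is amplitude: at treatment energies the signals reach
only mPa at kHz frequencies.

Optical contrast agents offer one enhancement route. Proton irradiation of
water produces faint luminescence (on the order of 0.1 photon per MeV of
deposited energy); in pure water these photons travel essentially
unabsorbed, but a strong absorber such as India ink confines their energy
near the absorber boundary, adding a *photoacoustic* source on top of the
ionoacoustic one. The interesting consequence for range verification is
geometric: the extra source sits at the interface where the beam enters
the absorber-loaded target, so the sensor sees two pulses — one from the
Bragg peak, one from the target edge — and the magnitude spectrum of the
signal *beats* with a period set by their time-of-flight difference.
Transforming the spectrum once more (a quefrency analysis) turns that beat
into a direct estimate of the Bragg-peak-to-target-edge distance, a
quantity that can be read out even under the quasi-continuous
micro-structured beams of synchrotrons, where classical time-of-flight
analysis fails.

This package implements the full simulation-and-analysis chain at desk
scale: analytic proton depth-dose, Monte Carlo luminescence transport,
thermoacoustic pressure conversion and k-space wave propagation, realistic
beam time structures, the detector surrogate, and the frequency-domain
analysis including the spectrum-beat distance estimator.

## The model chain

### Depth dose

`bragg_depth_dose()` lays an analytic Bragg curve on the scenario grid: a
power-law slowing-down profile (`(R0 - z)^(-0.435)` leading term with a
fluence-loss correction) convolved with a Gaussian range-straggling
kernel, calibrated against an embedded CSDA range table for water. Two
calibrations are frozen in the package:

* the straggling width multiplier (1.0577) reproduces the 430 um axial
  FWHM of the 22 MeV peak in water;
* the clinical beam-line water-equivalent thickness (1.248 mm) places the
  130 MeV Bragg peak at 11.4 cm along the beam axis in the liver phantom.

Upstream degraders (11.4 um titanium window, 6 cm air, 50 um polyimide
foil) shift the curve by their water-equivalent thickness. With them, the
80% distal fall-off of the 22 MeV beam lands at 4.94 mm past the tank
entrance (the reference value for this geometry is 4.92 mm; the 0.4%
residual is the accuracy limit of the range table plus water-equivalent
scaling). A ripple filter is represented parametrically as a uniform
range-shift mixture whose maximum shift (2.376 mm) is calibrated so the
spread-out beam's 90% fall-off sits at 3.04 mm; the confocal sawtooth
geometry it replaces is deliberately out of scope.

### Luminescence transport

`optical_energy_deposition()` samples photon emission proportional to
local deposited energy times the light yield, draws wavelengths from the
`lambda^-2` spectrum on 300-700 nm (mean 444.8 nm), isotropic directions,
and exponential free paths through the layered absorption map
(Pope-and-Fry-style water values, 3.7e3 1/mm for 1% India ink anchored at
632.8 nm). Absorption is terminal: the full photon energy is scored at the
absorption site, and photons leaving the domain are discarded. Scattering,
refraction and re-emission are not modelled — the effect of interest is
driven by a six-order-of-magnitude absorption contrast, not by radiative
transfer detail. Energy bookkeeping (emitted = absorbed + escaped) closes
to 1e-12 relative and is asserted in the tests. In 1D mode the medium is
laterally unbounded (photons can only escape axially); the 2D mode tracks
both coordinates and escapes laterally as well.

### Pressure conversion and propagation

`initial_pressure()` applies the thermoacoustic conversion
`p0 = D * Gamma * rho` voxel by voxel. `propagate()` solves the
first-order linear acoustics equations in heterogeneous `c(r)`, `rho(r)`
with a k-space pseudospectral scheme: spectral derivatives on spatially
staggered grids with the `sinc(c_ref k dt / 2)` time correction (exact for
homogeneous media — the 1D d'Alembert test passes at machine precision for
the direct pulse), CFL 0.3, and a split-field absorbing boundary layer.
Two numerical choices deserve note:

* The absorbing layer defaults to 40 grid points with a quadratic damping
  profile (0.2 Np per point). Thermoacoustic sources are unipolar, so
  their spectra reach very low quefrencies that a thin, steep layer
  reflects noticeably; the wider, gentler profile keeps total boundary
  artifacts below 1% of the direct signal, which is also the tolerance the
  propagation oracle tests enforce.
* The acoustic density contrast is capped at 50:1. A realistic air layer
  (rho ~1.2 kg/m3 against ~1000 for water) destabilizes the spectral
  scheme; capped air still reflects with |R| > 0.99, i.e. it remains an
  effectively pressure-release boundary and the entrance-window signal
  the experiments rely on is preserved.

The 22 MeV tandem scenarios run in 2D (axial 25 um, lateral 50 um) with a
3.5 mm disk sensor averaged over its aperture; clinical runs default to 1D
on axis with a point sensor, which preserves the time-of-flight and beat
structure at a fraction of the cost. The tandem impulse response
reproduces the experimental pulse sequence: direct Bragg signal at 21 us
(31 mm sensor-Bragg distance), contrast-agent phantom window signals near
23-25 us, tank entrance window at 24.3 us, and the direct-signal
reflection at 27.6 us.

### Beam time structures

`square_pulse_train()` (chopped tandem beam: single 200 ns pulses or
25-cycle bursts, periods 350-660 ns at duty 0.5), `gaussian_pulse()`
(synchro-cyclotron, 2.5 us FWHM, 0.16 pC per pulse at 1e6 protons) and
`synchrotron_burst()` (50 ms spill with Gaussian micro-pulses of sigma
19.75 ns every 228 ns — a 4.39 MHz repetition rate — and Poisson(1)
amplitude jitter at 3.2e9 protons/s) cover the studied accelerator types.
Micro-pulse arrival times are fixed on the 228 ns comb with amplitude
jitter only; arrival-time jitter exists as an option but defaults to off,
since the amplitude fluctuation is what the available description pins
down. Discretized trains are normalized exactly (fractional sample
coverage), so convolving the propagated impulse response with a train
(`apply_pulse_train()`) scales rigorously with particle count.

### Detector

`detector_response()` applies the broadband transducer surrogate: a
second-order Butterworth bandpass (0.15-15 MHz) in cascaded second-order
sections, causal by default like the real front-end electronics, with a
zero-phase option for analysis-only filtering.

## The analysis chain

`wavelet_denoise()` implements the measurement-trace denoiser: a
Daubechies-38 decomposition over 10 levels (periodized, perfectly
reconstructing), zeroing detail bands above 10 MHz and hard-thresholding
level 5 at 10% of its maximum coefficient. `amplitude_at_frequency()`
extracts the signal amplitude at the excitation frequency from a
zero-padded FFT (5 kHz resolution) over the 21-22.5 us direct-signal
window. `phase_shift()` bandpass-filters both traces at f0 +/- 10%, forms
analytic signals, and reports the circular mean of the sample-wise phase
of `analytic_test * Conj(analytic_reference)`; the circular mean (rather
than the arithmetic mean of angles) keeps the +/-180 degree case stable.
The sign convention is fixed by that product; the experimentally observed
-50 degree microbubble plateau is a qualitative reference only, since the
original sign convention is not recoverable.

### The spectrum-beat estimator

`beat_distance()` estimates the Bragg-peak-to-target-edge distance from a
single trace:

1. magnitude spectrum of the (zero-padded) trace;
2. optional restriction to the band where the interfering components
   live (clinical analyses use 0-1 MHz: the ionoacoustic pulse of the
   ~8 mm clinical Bragg peak carries frequencies up to a few hundred kHz,
   and beats require both pulses to overlap spectrally);
3. zero-phase second-order Butterworth lowpass along the frequency axis
   retaining spectral oscillations up to the 120 us quefrency cutoff
   (the stated time-of-flight based cutoff);
4. subtraction of the smooth spectral baseline (quefrencies below
   `min_distance / c`), which would otherwise leak into the search range;
5. FFT of the detrended envelope, quefrency axis mapped to distance via
   `d = c q` with the tumor speed of sound (1556.9 m/s);
6. the strongest interior local maximum beyond `min_distance` is the
   beat; it must exceed 1.25x the local background (median in an annulus
   of 1-5x `min_distance` around the peak) or the result is an explicit
   "no beat detected". The thresholds were set against the two regimes
   the estimator must separate: combined traces give prominences of
   1.35-1.55 across burst lengths and seeds, while ionoacoustic-only
   (single-source) traces stay below 1.15.

On noiseless two-impulse fixtures the estimator is exact to within one
quefrency bin over separations of 2-20 us and speeds of 1400-1600 m/s. On
the full clinical chain (130 MeV beam, tumor edge 14.49 mm proximal to
the Bragg peak, 50 ms synchrotron burst, light yields 5e4 and 1e5
photons/MeV) it recovers 14.5-14.7 mm — a relative error of about 0.1% of
the 11.4 cm beam range, comfortably below the 0.3% benchmark, and close
to the 14.88/14.68 mm reference values for this scenario. The small
positive bias is real estimator behaviour, not noise: the two interfering
pulses have different shapes, so the beat ripple is slightly chirped.

## The measurement-campaign emulator

`simulate_acquisitions()` produces seeded sets of noisy trace
realizations (3000 by default), and `grouped_stats()` reproduces the
statistics protocol: 30 groups of 100 acquisitions, the statistic
evaluated per group average, and a Student-t 99% confidence half-width
(29 degrees of freedom). The noise model is additive white Gaussian at
the detector output; the default sigma in examples is chosen so a single
acquisition of the tandem direct signal has roughly 0 dB SNR, visible
only after averaging, which mirrors the practical need for 3000-shot
averages. Empirical coverage of the 99% interval is verified by Monte
Carlo in the test suite. What this generator does *not* emulate:
correlated electronic noise, drift, beam-current jitter between
acquisitions, or any microbubble dynamics — enhancement factors measured
with microbubble agents are outside what synthetic data can reproduce.

## Problem sizes

All shipped analyses run on one CPU core: the tandem 1D chain in seconds;
the tandem 2D disk-sensor run (2048 x 256 grid, ~9000 steps) in a few
minutes; the clinical 1D chain including the 50 ms synchrotron burst
(7.8e6 samples) and the beat analysis in about two minutes; 1e6 photon
histories in a few seconds. The test suite uses reduced sizes (shorter
bursts, fewer histories) chosen so every assertion still tests the same
mechanism.

## Known limitations

* Amplitudes in 2D follow the usual slice approximation (line sources in
  the unsimulated third dimension); hierarchies and ratios are reliable,
  absolute pressures are approximate.
* The analytic dose model has no nuclear buildup detail and a single
  straggling parameter; it is a calibrated stand-in for Monte Carlo
  transport, adequate for range/TOF observables.
* Luminescence physics is an equivalent scintillation-style model; the
  true origin and possible directivity of water luminescence remain open,
  and only isotropic emission is implemented.
* Acoustic attenuation is not modelled (lossless media), matching the
  stated physics of the reference setup.
* The contrast-agent phantom's rear foil is not modelled acoustically by
  default (configurable), as its treatment in the reference setup is
  unspecified.
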