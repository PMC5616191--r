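---
title: "Deciding whether an LFP oscillation is local or volume-conducted"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding whether an LFP oscillation is local or volume-conducted}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfplocal)
```

## The problem

A band-limited oscillation seen in a local field potential (LFP) is not
necessarily generated by the tissue around the electrode. Because brain
tissue conducts electric fields essentially instantaneously at
physiological frequencies, a strong distant oscillator — hippocampal or
entorhinal theta, for instance — can appear on every channel of a probe
implanted in a structure that generates no such rhythm itself. Treating
such a volume-conducted signal as a local network oscillation leads to
wrong conclusions about the recorded circuit.

`lfplocal` implements a battery of diagnostics that jointly separate the
two situations, together with a synthetic-data generator that produces
multichannel recordings with *known* ground truth, so every diagnostic can
be validated end to end. The motivating use case is theta (6–10 Hz) in the
rodent dorsolateral striatum recorded simultaneously with somatosensory
cortex during treadmill running, with 5-s "run" epochs contrasted against
5-s intertrial "baseline" epochs, but nothing in the code is specific to
that preparation.

## The evidence triad

Three statistically independent lines of evidence feed a final verdict.

**1. Rereferencing.** A signal that is identical (up to gain) on all
channels vanishes under a bipolar derivation (channel minus the mean of a
neighboring shank) or a common-average reference (CAR). The package
quantifies "the peak disappears" as the *whitened peak-to-flank ratio*:
power is multiplied by $f^2$ to flatten the $1/f^2$ background, and the
value at 8 Hz is divided by the mean at 5 and 12 Hz. The branch compares
this ratio after rereferencing with the monopolar value; a surviving
fraction below `r_max` (default 0.2) indicates a shared, i.e. not local,
source.

**2. Imaginary coherence.** The coherency
$C_{xy}(f) = S_{xy}(f) / \sqrt{S_{xx}(f)\,S_{yy}(f)}$ has modulus
(coherence) near 1 whenever two channels see the same signal, regardless
of its origin. Volume conduction, however, is instantaneous: it produces
synchronization at exactly zero phase lag, so the *imaginary part* of the
coherency and the coherence *angle* both vanish. A genuinely lagged
interaction leaves a nonzero imaginary part. The branch passes (toward the
volume-conduction verdict) when the band-averaged within-structure
imaginary coherence is below `i_max` (default 0.05) in absolute value.

**3. Spectral Granger causality.** For a channel pair recorded in the two
structures, the total interdependence at frequency $f$,
$f_{x,y}(f) = -\ln\!\left(1 - |C_{xy}(f)|^2\right)$, decomposes exactly as
$$f_{x,y}(f) = f_{x \to y}(f) + f_{y \to x}(f) + f_{x \cdot y}(f),$$
two directed terms plus an instantaneous term that captures common outside
influence. If a distant generator drives both structures by field spread,
the instantaneous term dominates. The branch passes when its band share
exceeds `s_min` (default 0.8). The decomposition is estimated
*nonparametrically*: the multitaper cross-spectral matrix on the full FFT
grid is factorized as $S(f) = H(f)\,\Sigma\,H(f)^{*}$ by Wilson's
iterative algorithm, and the directed terms follow Geweke's formulas, e.g.
$$f_{y \to x}(f) = \ln
  \frac{S_{xx}(f)}{S_{xx}(f) - \left(\Sigma_{yy} -
  \Sigma_{xy}^2/\Sigma_{xx}\right) |H_{xy}(f)|^2}.$$

All three branches passing yields `volume_conducted`; none passing yields
`locally_generated`; anything in between is `mixed`, and a missing branch
withholds the verdict. The thresholds are explicit configuration — the
original qualitative argument is formalized here, and the defaults are the
package's own choices.

A fourth, descriptive line is spike–LFP entrainment: a locally generated
rhythm should pace local spiking. Per unit the package computes spike
phases (band-pass plus analytic signal, phase 0° at the oscillation peak),
the Rayleigh test of circular uniformity, the pairwise phase consistency
(PPC) spectrum, and a von Mises fit $(\kappa, \theta)$. A unit is
`theta_specific` when Rayleigh $p < 0.01$ in the theta band *and* its PPC
spectrum peaks within one grid step of 8 Hz; units significant only with a
PPC maximum below 6 Hz are `low_freq_modulated`; units with fewer than 20
spikes are excluded. The entrained fraction is reported but deliberately
kept out of the verdict rule: firing can be paced by genuinely synaptic
low-frequency input even when the LFP rhythm itself is conducted in.

## Spectral estimation choices

Spectra are multitaper estimates with Slepian (DPSS) tapers computed
in-package from the symmetric tridiagonal eigenproblem (Sturm bisection
plus inverse iteration, in C++), with unit taper weights. Two smoothing
modes exist:

* **Frequency-proportional** (`smoothing_param * f`, default 0.8·f, seven
  tapers, 1–20 Hz in 0.2 Hz steps): one taper family per output frequency,
  evaluated by direct DFT at that frequency. This reproduces the kind of
  display spectra produced by the common Matlab toolboxes with
  proportional smoothing.
* **Fixed bandwidth** (half-bandwidth in Hz): one taper family, FFT onto a
  uniform grid with zero-padding to the next power of two and nearest-bin
  lookup. All *quantitative* diagnostics (peak ratios, coherency,
  factorization) use this mode — the peak/flank ratio needs a peak that is
  not smeared over the flanks (default 1 Hz half-bandwidth), and Wilson
  factorization requires a single consistent uniform grid spanning
  $[0, f_s/2]$.

PSDs are one-sided densities: a white-noise spectrum integrates to the
signal variance. Whitening multiplies by $f^2$ and is exactly invertible
on the stored grid. Before factorization the channel pair is decimated to
125 Hz (anti-aliased); the 1–20 Hz band of interest lies far below the
resulting Nyquist frequency and the shorter FFT grid conditions the
factorization well.

## Numerical choices

* **Wilson factorization** starts from the Cholesky factor of the
  frequency-averaged spectrum and iterates the causal-part operator; both
  the lag-0 and the Nyquist-lag Fourier coefficients are Hermitian-split
  (halved diagonal, upper triangle kept). Convergence is quadratic; the
  relative-update tolerance of 1e-12 leaves the final iterate at machine
  precision (reconstruction residuals ~1e-15). Channels are internally
  prenormalized to unit mean power so results are exactly invariant to
  channel rescaling. Non-positive-definite input spectra are rejected with
  the offending frequency named.
* **Instantaneous term.** $f_{x \cdot y} = f_{x,y} - f_{x\to y} -
  f_{y\to x}$ can come out negative under estimation noise (a known
  property of the pointwise Geweke decomposition, observed down to about
  −0.06 on white-noise nulls). Negative values are clipped to zero, clip
  counts are logged, and the total is recomposed so the decomposition
  identity holds exactly after clipping. Band shares therefore sum to 1 by
  construction.
* **Exact Wilcoxon.** Frequency-wise run-vs-baseline comparisons use the
  one-sided paired signed-rank test with zero differences dropped; for
  fewer than 25 informative pairs the exact null distribution is computed
  by the shift algorithm with midranks (so ties are handled exactly — a
  uniform positive shift across 12 pairs gives $p = 2^{-12}$), otherwise
  the normal approximation with continuity correction. Multiple testing is
  controlled by Benjamini–Hochberg step-up at $q = 0.05$ across the
  frequency grid.
* **Rayleigh p-values** use $Z = n\bar R^2$ with the standard
  small-sample-corrected exponential approximation; its null rejection
  rate at $p < 0.01$ calibrates to 1.0–1.1% over $10^4$ simulations.
* **Phase convention.** Phase is measured in degrees in $(-180, 180]$,
  0° at the oscillation peak, increasing with time — identically in the
  generator and the spike-phase analysis, so generator/estimator round
  trips are exact contracts.
* **Sample convention.** Epochs are half-open 0-based sample intervals of
  exactly `round(epoch_len * fs)` samples.
* **Filters.** All filtering is forward–backward (zero-phase): an order-8
  Butterworth low-pass at 0.4·target rate before decimation, an order-1
  high-pass / order-4 low-pass cascade for the 0.1–250 Hz passband, and
  second-order band-stop notches (±1 Hz) at every multiple of 50 Hz up to
  Nyquist.

## The synthetic-data generator

Narrowband sources are AR(2) processes with a complex pole pair at the
center frequency and modulus $r = \exp(-\pi\,\mathrm{bw}/f_s)$, scaled by
the Yule–Walker closed form so the stationary standard deviation equals
the requested amplitude. Volume conduction is a pure instantaneous gain
matrix (no dipole geometry or conductivity modeling). Directed
interactions are stationary VARs (companion spectral radius checked at
construction); a per-channel integer delay map can impose traveling phase
gradients. Units are inhomogeneous Poisson processes with intensity
$\lambda(t) = r_0 \exp\!\big(\kappa \cos(\varphi(t) - \theta)\big) /
I_0(\kappa)$, generated by Lewis–Shedler thinning, so the marginal rate is
exactly $r_0$ and spike phases are von Mises.

The packaged study conditions (`demo_session_config()`) were chosen once,
as values a electrophysiologist would call realistic, and are not
calibrated to any specific recordings (none are available): sampling rate
1250 Hz, 12 trials per session, 5-s epochs separated by 2-s gaps, six
channels on three shanks (two striatal, one cortical), run/baseline theta
amplitude ratio 2, white local noise of 0.5 standard deviations against
unit-variance sources. Under volume conduction those conditions give
within-structure theta coherence around 0.99 and an instantaneous Geweke
share around 0.92 — the regime reported for real probe recordings. The
locally generated scenario uses a theta-resonant VAR driving the cortical
group at a 25 ms delay, with a 15 ms phase gradient across striatal
shanks.

What the generator deliberately does **not** emulate: $1/f$ background
structure (local noise is white), amplitude-ramped epoch transitions (the
run/baseline step is instantaneous), electrode drift, spike waveforms and
sorting errors, and gain inhomogeneity in the volume-conducted scenario
(gains are exactly equal, matching the classic modeling assumption that
conducted signal is equally present on all channels). Passing tests
therefore show the *statistical machinery* is correct, not that real
recordings will be as clean: with a 5–10% gain spread, the bipolar
residual of a strong conducted source can still carry a visible whitened
peak over a weak white-noise floor, and the rereferencing branch becomes
conservative.

## Validation problem sizes

The test suite regenerates all data from code. The heavier checks use: 40
five-second epochs for the zero-lag coherency null; 400 epochs of 2048
samples of the benchmark VAR(2) for the nonparametric-versus-parametric
Granger comparison (peak values compared as means over ±1 Hz around the
spectral peak, which removes single-bin estimation noise); ~1.8 × 10⁴
spikes for von Mises recovery; 10⁴ replicates for the Rayleigh and FDR
calibrations; and ten sessions per scenario for the verdict battery.

## Known limitations

* Granger machinery is bivariate (one channel pair), as the question is a
  two-structure comparison; conditional/multivariate extensions are out of
  scope.
* The imaginary-coherence diagnostic cannot distinguish several
  phase-shifted distant generators from genuine local coupling — the
  verdict can only be as good as the triad's joint assumptions.
* No weighted phase-lag index or debiased coherency variants; the
  imaginary part of coherency is the implemented statistic, and the module
  boundary makes such variants a natural extension point.
* Artifact rejection is an automated variance z-score across epochs
  (default threshold 4, per epoch over the channel maximum); the original
  procedure this stands in for was interactive visual inspection.
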