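# lfplocal

Tools for answering a deceptively simple question in multichannel
electrophysiology: **is this band-limited LFP oscillation generated by the
tissue around the probe, or volume-conducted from somewhere else?**
Because brain tissue conducts fields essentially instantaneously, a strong
distant oscillator (hippocampal theta being the classic culprit) can
dominate every channel of a probe in a structure that produces no such
rhythm itself. `lfplocal` is aimed at electrophysiologists who record
continuous signals on multi-shank probes together with spike trains and
want a quantitative, reproducible version of the standard evidence triad.

## What it computes

For channels $x, y$ with cross-spectrum $S_{xy}(f)$ (multitaper, Slepian
tapers):

* **Coherency** $C_{xy}(f) = S_{xy}/\sqrt{S_{xx} S_{yy}}$, its modulus
  (coherence), argument (coherence angle), and imaginary part. Zero-lag
  field spread gives coherence ≈ 1 with a null imaginary part and angle;
  a genuine time lag does not.
* **Rereferencing** — bipolar (against a neighboring shank's mean) and
  common-average derivations, with the whitened ($f^2$-scaled)
  peak-to-flank ratio quantifying whether the spectral peak survives.
* **Nonparametric spectral Granger causality** — Wilson factorization
  $S(f) = H(f)\Sigma H(f)^*$ of the cross-spectral matrix, then Geweke's
  decomposition of the total interdependence
  $f_{x,y} = -\ln(1-|C_{xy}|^2)$ into $f_{x\to y} + f_{y\to x} +
  f_{x\cdot y}$; a dominant instantaneous term $f_{x\cdot y}$ signals a
  common external source.
* **Spike–LFP entrainment** — per-unit spike phases, Rayleigh test,
  pairwise phase consistency (PPC) spectrum, von Mises $(\kappa,\theta)$
  fits, and a theta-specificity classification.
* **Paired statistics** — frequency-wise one-sided paired Wilcoxon tests
  (exact for small n, midranks under ties) with Benjamini–Hochberg FDR
  control.
* **A synthetic-data generator** with known ground truth (volume-conducted
  sources, lagged VAR coupling, traveling phase gradients, phase-modulated
  units) so the whole pipeline can be validated end to end, and a verdict
  rule combining the three evidence branches.

## Worked example

Simulate a session in which an 8 Hz oscillator reaches every channel by
pure volume conduction (plus a slow 2 Hz component and phase-modulated
units), then run the full pipeline:

```r
library(lfplocal)

cfg    <- demo_session_config("volume_conduction", seed = 42)
ds     <- simulate_session(cfg)
report <- run_pipeline(ds)
print(report)
#> <verdict_report>
#>   verdict: volume_conducted
#>   - rereferenced/monopolar whitened theta peak ratio = 0.02780675 (volume-conducted if < 0.2)
#>   - within-structure theta imaginary coherence = -0.003472089 (volume-conducted if |.| < 0.05)
#>   - instantaneous Geweke share in theta band = 0.9242128 (volume-conducted if > 0.8)
#>   entrained unit fraction: 0.50
```

Reading the evidence: the monopolar whitened spectrum has a prominent
theta peak (peak/flank ratio ≈ 30), of which only ~3% survives bipolar or
common-average rereferencing; theta coherence between striatal shanks is
0.997 while its imaginary part is −0.003 (zero-lag synchronization); and
92% of the striatum–cortex total interdependence in the theta band is
instantaneous (directed shares 0.04 and 0.03). All three branches point
the same way, so the oscillation is called volume-conducted — which is the
scenario's ground truth. Running the same pipeline on
`demo_session_config("lagged_coupling", ...)`, where theta is generated
within the striatal group and drives cortex at a 25 ms delay, flips every
branch and yields `locally_generated`.

A thin command-line wrapper is installed with the package:

```sh
Rscript inst/scripts/lfplocal simulate --scenario volume_conduction --seed 1 --out runs/vc
Rscript inst/scripts/lfplocal report --data runs/vc --out runs/vc
```

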