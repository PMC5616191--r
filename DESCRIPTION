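Package: lfplocal
Title: Local Versus Volume-Conducted Origin of Band-Limited LFP Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a band-limited local field potential
    (LFP) oscillation recorded on a multichannel probe is generated locally or
    volume-conducted from a distant source. Implements multitaper power and
    cross-spectral estimation with Slepian (DPSS) tapers, bipolar and
    common-average rereferencing, coherency-based diagnostics (coherence,
    imaginary coherence, coherence angle), nonparametric spectral Granger
    causality via Wilson spectral matrix factorization with the Geweke
    decomposition into directed and instantaneous terms, spike-LFP entrainment
    statistics (Rayleigh test, pairwise phase consistency, von Mises fits),
    frequency-wise paired Wilcoxon testing with false discovery rate control,
    and a synthetic-data generator with known ground truth for validating the
    whole pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
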