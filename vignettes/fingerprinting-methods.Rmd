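---
title: "Methods: MALDI-TOF fingerprinting of microalgae and their mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MALDI-TOF fingerprinting of microalgae and their mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycoMS)
```

## The problem

Open-pond microalgae production is vulnerable to contamination by
phenotypically similar competitors, and the conventional identification
tools (microscopy, 18S rDNA sequencing) are too slow for near-real-time
monitoring. Whole-cell MALDI-TOF mass spectrometry offers an alternative:
a crude protein extract of a culture, spotted with matrix and ionized in
positive linear mode, yields a spectrum of intact protein masses in the
m/z 2,000–20,000 range that acts as a strain-level fingerprint. phycoMS
implements the full analysis chain for such fingerprints — preprocessing,
peak detection, replicate consensus, similarity clustering, mixed-culture
peak attribution — together with the sequence-side comparator (Kimura
two-parameter distances, neighbor joining) and a synthetic-data generator
that makes every stage testable without instrument data.

## Preprocessing model

A profile spectrum is an intensity trace $y(m)$ on an ordered m/z axis,
windowed to m/z 2,000–20,000. Preprocessing is, in order:

1. **Savitzky–Golay smoothing** — local least-squares polynomial fit
   (default order 3) evaluated at the window center; terminal windows are
   filled by evaluating the terminal polynomial fit, so polynomials up to
   the chosen order are exact fixed points including at the edges.
2. **TopHat baseline subtraction** — subtract the morphological opening
   (erosion then dilation with a flat structuring element, default 150 Da).
   The opening is the tightest under-curve at that scale, so the output is
   non-negative and the operation is idempotent.
3. **Noise estimation** — 1.4826 × MAD of the baseline-subtracted trace, a
   robust analogue of a normal standard deviation that ignores the sparse
   tall peaks.
4. **Mass calibration** — least-squares fit of reference calibrant masses
   (ACTH 1–17 2093.46, ACTH 18–39 2464.19, oxidized insulin B 3494.65,
   insulin 5730.61, cytochrome c 12362.00, apomyoglobin 16952.30 Da)
   against their observed positions, linear or quadratic; affine
   (respectively quadratic) axis distortions are recovered exactly.

**Why the smoothing window default is 7 points, not the 15–25 often used on
vendor profiles.** Vendor raw traces are oversampled (several points per
Da), so a 21-point window is still narrower than a peak. This package's
reference grid — and its simulator's grid — is 1 Da, where protein peaks
are only ~5–15 points wide (FWHM). A cubic fit whose window exceeds the
peak width undershoots on the flanks by ~1–3% of peak height; because the
morphological opening is an envelope of *minima*, those undershoot lobes
drag the baseline estimate down between tall peaks and TopHat then leaves
low plateaus that read as spurious S:N ≥ 5 peaks. Keeping the window at or
below one FWHM (7 points at the default simulated FWHM of 5 Da) reduces the
undershoot to ~0.2% and removes the artifact. Both parameters are exposed
(`smooth.window_points`, `smooth.poly_order`); users with oversampled input
should scale the window with their point density.

## Peak detection, quality gating, prominence

Peaks are strict local maxima of the preprocessed trace with
`intensity / noise >= snr_min` (default 2). The reported position is the
intensity-weighted centroid of the contiguous points at or above half
height, and the width is the interpolated FWHM. Apexes within 10 points of
either end of the trace are discarded: those values come from the
smoother's edge extrapolation, not from measurement.

The shot-burst quality gate accepts a spectrum iff its base peak (most
intense peak) has S:N ≥ 2 and intensity ≥ 100, the base-peak width is
within the 10 m/z bound, and there are at most 500 peaks. All thresholds
are inclusive ("2 or greater"), and the width bound is read as a maximum by
default — the acquisition-software convention is ambiguous, so a
`width_is_max = FALSE` reading is available.

At S:N ≥ 2 on a 1 Da grid, roughly half of the smoothed-noise local maxima
survive the threshold, so a raw peak list carries on the order of a
thousand noise-level entries. These are real local maxima, but they are not
reportable fingerprint peaks, and with a ±2 Da tolerance they chance-match
across replicates and samples. Stages that *compare* peak lists (the QC
gate's peak count, mixture attribution) therefore operate on the
**prominent** subset, S:N ≥ 5 (`peaks.prominence_snr`); the value matches
the S:N ≥ 5 carve-out used in the package's own recovery acceptance test.
`detect_peaks()` output is unfiltered so that threshold studies remain
possible.

## Replicate consensus and composite spectra

Two peaks are the same feature iff their m/z differ by at most 2 Da
(inclusive — peaks are *different* only when they differ by *more* than
±2). Matching between two lists is greedy one-to-one in order of ascending
|Δm/z|.

A consensus peak must be present in **all** replicates. Groups are seeded
by the first replicate and each further replicate is matched against the
running mean position of each group; a group is retained iff every member
lies within the tolerance of the final group mean, which becomes the
consensus position (capture window during matching is twice the tolerance).
The acceptance is deliberately center-based rather than pairwise: with
replicate mass jitter of sd 0.7 Da, each centroid is within ±2 Da of the
consensus center with probability ≈ 99.9%, whereas the *worst pairwise
distance* among three replicates exceeds 2 Da about 7% of the time. A
pairwise-chain rule would therefore silently drop ~5–7% of genuine peaks at
exactly the replicate variability the generator states; the center rule
keeps them while still requiring every replicate to attest the peak.

Composite ("summary") spectra average the replicates whose mean Pearson
similarity to the other replicates — computed on profiles binned to a
common grid — is at least 0.65 (inclusive). Excluded replicates are
reported with their scores.

## Similarity, UPGMA, pseudo-gels

Fingerprint similarity is the Pearson product-moment correlation of
binned full profiles (default bin 3 Da over the mass window; a
peak-presence binary-vector route can be built from consensus tables if
preferred — curve mode is the default because it needs no peak-calling
choices). The dendrogram is classical UPGMA on `d = 1 − r`: average
linkage, merge height = half the average inter-cluster distance (so
cophenetic distance = 2 × merge height reproduces an ultrametric input
exactly), ties broken toward the lowest original label index. The
implementation is checked against a brute-force average-linkage oracle on
thousands of random matrices. Pseudo-gels render each binned fingerprint as
a gel lane with band darkness monotone in intensity.

## Mixture (polyculture) peak attribution

Given consensus peak lists for constituents and mixtures, every distinct
peak — distinct after single-linkage chaining of the pooled sorted m/z at
the ±2 Da tolerance — is labelled:

* **M**: constituent-derived, observed in at least one mixture;
* **P**: constituent-derived, observed in no mixture (ion-suppressed);
* **S**: mixture-specific, matching no constituent peak.

Per-sample presence flags are preserved, so a peak seen in only one of two
mixtures is still M with its flags showing which. The suppression report
counts M vs P per constituent. The packaged `polyculture_example()` peak
lists (three *Chlorella*/*Scenedesmus* constituents, two mixtures)
reproduce the published attribution: eight M peaks, one suppressed peak at
m/z 2735, and three mixture-specific peaks at m/z 6481, 11048, 11230.

## Sequence-side comparator

`kimura_distance()` implements the two-parameter correction
$d = -\tfrac12 \ln\!\big((1-2P-Q)\sqrt{1-2Q}\big)$ with transition and
transversion proportions computed over comparable sites (both characters in
A/C/G/T/U; U read as T; N and gaps excluded). The "12% gap penalty" of the
original typing software has unpublished semantics; this package's declared
reading adds `gap_penalty / L_comparable` per column where exactly one
sequence is gapped (default 0.12, set 0 to disable), and results with and
without it can be produced side by side. Saturated configurations
($1-2P-Q \le 0$ or $1-2Q \le 0$) raise an error rather than returning a
complex logarithm.

`neighbor_joining()` is classical NJ (Q-criterion, standard branch-length
formulas), deterministic tie-breaks by label order, unrooted output,
negative branch-length estimates clamped to zero and counted. It
reconstructs additive distances exactly (path-length error < 1e-9 on random
trees up to 8 taxa). `compare_partitions()` reports per-class monophyly in
the MS dendrogram versus the sequence tree plus their Robinson–Foulds
distance — the package's quantitative form of the observation that sequence
trees organize strains by class while MS fingerprints separate strains
below the class level.

## The synthetic world

`make_template()` draws 6–56 peak positions (the empirically observed range
for microalgal fingerprints) uniformly over m/z 2,000–20,000 with a minimum
4 Da separation, and log-normal mean intensities (median 1500 a.u., log-sd
0.5). `simulate_spectrum()` renders Gaussian peaks (default FWHM 5 Da) on a
1 Da grid, with per-replicate position jitter (sd 0.7 Da), log-normal
intensity variation (CV 15%), a smooth exponentially decaying baseline
(200 a.u., 3000 Da scale) and additive white noise (sd 10 a.u. — a noise
floor ~1% of a typical peak, so the designed base-peak S:N is well above
10). Mixtures scale each strain's intensities by proportion × suppression
and can inject novel peaks verbatim; every simulated object carries its
ground truth as an attribute.

Defaults that required a judgment call:

* **FWHM 5 Da** — the low end of linear-TOF protein peak widths. The
  generator's 4 Da minimum separation encodes the assumption that template
  peaks are individually resolvable at the ±2 Da tolerance; widths much
  above 5 Da contradict that (two 8 Da-wide peaks 6 Da apart have a single
  maximum) and also push merged base-peak widths past the 10 m/z gate.
* **Jitter 0.7 Da** — keeps replicate centroids inside the matching
  tolerance with high probability while still exercising it; a pathological
  setting (sd 5) demonstrably destroys consensus and is covered by a test.

What the generator does **not** emulate: isotope envelopes and charge
states, detector saturation, chemical (matrix-cluster) noise with its
strong low-mass rise, mass-dependent peak width, and correlated
shot-to-shot drift. A green synthetic test therefore establishes that the
*algorithms* implement their contracts under the stated statistical
structure — not that the defaults are tuned for any particular instrument.

**Known residual artifact.** Template (or cross-strain) peak pairs
4–4.5 Da apart sit below the Rayleigh-like resolution limit of 5 Da-wide
peaks: they merge into one maximum whose centroid can be just over 2 Da
from both true positions. Depending on the seed this yields occasionally
one or two consensus or mixture-specific peaks that strict ±2 matching
counts as false (observed at roughly one seed in three; never more than
two peaks). This is a property of the stated world, not a detector bug;
it is why real fingerprint work treats peaks closer than the tolerance as
one feature.

## Numerical and tie-break conventions

* Matching boundaries are inclusive everywhere (a 2.0 Da difference is the
  same peak; S:N exactly 2 passes the gate; similarity exactly 0.65 is
  included).
* Base-peak ties break to the lower m/z; UPGMA merge ties to the lowest
  label index; NJ Q-criterion ties to the first pair in label order.
* Duplicate m/z points merge by intensity sum on read (total ion signal is
  preserved).
* All simulators take explicit integer seeds; a fixed seed gives
  bit-identical output.

## Limitations

* Reference-database species identification (Biotyper-style score matching)
  is out of scope; the package types *within* a studied collection.
* Multiple sequence alignment is consumed, not computed.
* The gap-penalty rule is a declared stand-in for an undocumented
  commercial setting.
* Quantitative deconvolution of mixture proportions is not attempted; the
  mixture module classifies peak provenance only.
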