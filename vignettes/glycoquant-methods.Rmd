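---
title: "Dual-label quantitative glycomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-label quantitative glycomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoquant)
```

This vignette documents the models behind `glycoquant`, the parameters that
matter and why their defaults are what they are, what the synthetic-data
generator does and does not emulate, and the package's known limitations.

## The labeling model

Cells grown on amide-¹⁵N glutamine route the amide nitrogen through the
hexosamine pathway into UDP-GlcNAc and CMP-NeuAc, so every aminosugar
residue of a released N-glycan carries exactly one labelable nitrogen:
HexNAc and NeuAc count one each, Hex and Fuc none. A glycan with
composition HexNAc~a~Hex~b~Fuc~c~NeuAc~d~ therefore shifts by

$$\Delta m = (a + d)\,(m_{^{15}\mathrm N} - m_{^{14}\mathrm N})
           = (a + d) \times 0.99703\ \mathrm{Da}$$

between its light and heavy forms. Masses are monoisotopic throughout,
computed from an embedded CIAAW atomic-mass table (H, C, N, O, Na); the
default ion is the singly charged sodiated adduct, the dominant species for
neutral N-glycans in positive-mode MALDI. Permethylated masses (sum of
permethylated residue masses plus a fixed 46.0055 Da end-group increment,
calibrated so permethylated HexNAc₄Hex₅ [M+Na]⁺ ≈ 2070.0) are supported for
annotation only: the quantitative pipeline operates on native glycans.
Residue-sum arithmetic and literature-reported permethylated values can
disagree by ~0.2 Da (rounding conventions of observed vs theoretical values
are rarely stated); the package records its own arithmetic and does not
force agreement.

### Enrichment

`enrichment` is the isotopic purity of the labeled glutamine pool. A
labeled nitrogen position is ¹⁵N with probability
$e + (1-e)\,p_{^{15}\mathrm N}^{nat}$: with probability $1-e$ the position
drew from the unlabeled (natural) pool. This makes `enrichment = 0` reduce
exactly to the natural envelope and `enrichment = 1` to a clean
$\Delta m$ shift. Commercial amide-¹⁵N-Gln is typically 98% pure; at
$e = 0.98$ a two-aminosugar glycan keeps ~96% of its heavy envelope at the
fully labeled position with a −1 Da satellite of ~4%. The pipeline default
is $e = 1$ (complete incorporation after six or more doublings in labeling
medium); 0.98 is available via `ion_spec(enrichment = 0.98)` for users who
want to model the label purity explicitly. At the ratio precision the CV
gate implies (±10–20%), the difference is negligible.

## Aggregated isotopic envelopes

Envelopes are computed on the integer neutron-shift grid by per-element
binomial/multinomial expansion, convolved across elements with exact
centroid-mass tracking, so bins are spaced ~1.003 Da apart — matching a
QIT-TOF at roughly unit resolution, where fine isotopic structure is not
resolved. Defaults: 10 aggregated peaks per envelope, intermediate
truncation at $10^{-15}$ relative abundance. The test suite checks the
convolution route against an exhaustive enumeration over all isotopologue
combinations (multinomial probabilities per element) to $10^{-10}$ per
peak; centroid masses of bins carrying measurable abundance agree to
$10^{-9}$ Da, while bins below $10^{-8}$ relative abundance are
truncation-sensitive and not meaningful at instrument precision.

## Spectral processing

Profile spectra are smoothed with a Gaussian kernel (edge-reflected, total
ion current preserved to 0.1%) and centroided by threshold-25% centroid
detection: local maxima above an absolute offset define peaks; each
centroid m/z is the intensity-weighted mean over the contiguous region
where intensity ≥ 25% of the apex; intensity is the apex height and area
the trapezoidal integral over the region. The offset is instrument-specific
(often quoted in mV); the package takes it in the spectrum's own intensity
units with default 0.5. Non-uniform m/z grids are resampled by linear
interpolation before smoothing — simple and testable, at the cost of
slight peak-shape distortion for strongly non-uniform grids. Base-peak
normalization (highest peak = 100%) is provided because vendor software
exports it; quantification is scale-invariant, so normalization cannot
affect ratios.

## Assignment

Observed peaks are matched to the nearest library entry within a 0.3 Da
tolerance (published observed-vs-theoretical deviations for this analyte
class are ≤ 0.2 Da), with ties broken by smaller absolute error then
lexicographic composition, and all within-tolerance alternatives reported
as an ambiguity list. Two filters precede matching in the pipeline, both
consequences of matching a *monoisotopic* library against a *full*
spectrum:

* **Deisotoping** (`monoisotopic_peaks()`): a peak with another peak one
  isotopologue spacing below it at ≥ 30% of its intensity is an isotopic
  satellite, not a cluster leader. The 30% floor is conservative: for CHNO
  analytes in this mass range every satellite's lower neighbour is at
  least ~60% of its height.
* **Heavy-partner rejection**: every light cluster has a heavy partner
  $\Delta m$ above it whose leading peak survives deisotoping. Because
  NeuAc differs from 2 × Fuc by only 1.02 Da, such partners can coincide
  with sialylated library entries. Assignments are walked in ascending
  m/z and any peak sitting at an accepted assignment's heavy-leader
  position is rejected as that assignment's labeling partner. A genuine
  glycan exactly co-located with another's heavy cluster would be lost —
  at unit resolution this degeneracy is unresolvable without MS/MS.

## Classification

The curated composition→class map transcribes the MS/MS- and
database-backed interpretations of the 17-glycan secretome panel
(`skov3_panel()`), including the four bisecting-GlcNAc compositions
(HexNAc₅Hex₅, HexNAc₅Hex₅Fuc, HexNAc₆Hex₆Fuc, HexNAc₇Hex₇Fuc). It
deliberately overrides the heuristic because composition alone cannot
separate bisecting from antennary isomers: HexNAc₅Hex₅Fuc is curated as
bisecting while HexNAc₅Hex₅Fuc₂ — the same core — is complex biantennary.
The heuristic fallback (HexNAc2 without fucose → high mannose; HexNAc3 →
hybrid; HexNAc4 → complex biantennary; HexNAc ≥ 5 → antennary guess,
flagged ambiguous) is provenance-labeled so downstream users can tell
curated from guessed classes. Sialylated compositions inherit their
desialylated parent's class, consistent with sialylation decorating an
existing scaffold. Glycosidic B/Y fragment masses (composition-level
multiset losses, optional water-loss variants) support MS/MS annotation of
bisecting assignments; complementary pairs obey
$m_B + m_Y = m_{precursor} + m_{\mathrm{Na}^+}$.

## Ratio estimation

The estimator is a two-template non-negative least squares fit: expected
light and heavy isotopologue positions are merged into unit-resolution
clusters, observed centroid areas are summed per cluster, and the two
channel amounts solve $\min_{a_L, a_H \ge 0} \lVert y - a_L L - a_H H
\rVert_2$ (solved by `pracma::lsqnonneg`). The ratio is $a_L / a_H$.

This matters precisely when the label shift overlaps the light envelope.
For HexNAc₂Hex₆ (shift 1.994 Da) at a true ratio of 0.5, the heavy
monoisotopic cluster contains the light M+2 isotopologue; the naive
monoisotopic height ratio follows $r / (1 + r\,L_2/H_0) \approx 0.44$ — an
11% underestimate — while the envelope fit recovers 0.500. For
well-separated pairs (shift beyond the envelope span) the fit reduces
exactly to the summed-envelope intensity ratio. A grid-search minimizer of
the same objective serves as an independent cross-check in the tests.

Numerical conventions: centroid **areas** are the default response (apex
heights optional) since vendor "signal intensity" is ambiguous; both
estimators (`"nnls"`, `"monoisotopic"`) are exposed so their difference is
inspectable; undefined ratios (zero heavy signal) propagate as flags, never
infinities; a window with no signal yields a low-signal flag. Replicate
aggregation uses the arithmetic mean and the sample (n−1) standard
deviation for CV%. Change calls are a pure threshold function of the mean
ratio — below 0.83 down, above 1.20 up, boundaries inclusive of "no" — and
the CV ≤ 20% QC gate flags rather than drops records. No ratio
renormalization (e.g. median-centering) is applied: the 1:1 mixture is by
protein amount and the published ratios show no evidence of re-centering.

## The synthetic-data generator

`skov3_scenario()` packages the study design: 17 glycans at their published
SKOV3-ip/SKOV3 ratios, light = SKOV3-ip, 3 independent mixtures × 3 MALDI
spots (n = 9), sodiated positive-mode ions. Per replicate, each glycan's
light amount is `abundance × exp(ε_mix + ε_spot)` and heavy
`abundance/ratio × exp(ε'_mix + ε'_spot)` with independent Gaussian
log-noise, so the light/heavy ratio is correct in expectation and the
mixture-level draws are shared across spots of the same mixture. Peaks are
rendered either directly as centroided peak lists or as Gaussian profiles
(σ = 0.12 Da, unit-resolution regime) on a 0.02 Da grid with an additive
baseline (0.2 units) and a per-glycan m/z calibration jitter
(σ = 0.01 Da). One global seed drives deterministic per-replicate
substreams; the same seed reproduces a fixture bit for bit.

Noise defaults were fixed once, on design grounds: multiplicative
(lognormal) channel noise matches MALDI's spot-to-spot behaviour, and the
variance is allocated spot-dominated (σ_mix = 0.02, σ_spot = 0.067,
per-measurement ratio CV ≈ 10%, within the 2.4–18.1% replicate CV range
reported for this design). The allocation matters: with only three
mixtures, mixture-dominated noise of the same total magnitude would leave
the *n = 9 mean itself* wandering by ~5%, which is inconsistent with
0.83/1.20 thresholds being meaningful for ratios like 1.32 — the published
design evidently had tighter mixture-level reproducibility than that. Both
knobs are exposed for users who disagree.

What the generator does **not** emulate: ionization bias between glycans,
detector saturation, matrix cluster interference, in-source decay of
sialylated species, baseline drift, and mass-dependent resolution. Passing
tests on synthetic data therefore demonstrate correctness of the
*computational* chain under the stated statistical model — not robustness
to every artifact of real MALDI data.

## Problem sizes and determinism

The default end-to-end scenario is 9 profile spectra of ~80,000 points
covering m/z ~1400–2760, processed in a few seconds; parameter-recovery
checks use centroided output (5 ratio levels × 17 glycans × 9 replicates).
All simulations are seeded; the packaged default seed is part of the
scenario definition.

## Known limitations

* Residue-class compositions only: no topology, linkage or O-glycans.
* The curated class map covers the secretome panel and its sialylated
  variants; outside it, HexNAc ≥ 5 classes are heuristic guesses and
  flagged as such.
* Quantification assumes the two channels co-crystallize identically
  (the premise of mixing before spotting); differential suppression
  between light and heavy forms is not modeled (and physically should not
  occur for isotopologues).
* The overlap correction assumes the theoretical envelope shape is right;
  badly calibrated spectra (errors ≫ 0.3 Da) or unresolved co-eluting
  compositions inside a window inflate the residual flag rather than being
  corrected.
* Fragment enumeration is composition-level; it annotates but does not
  prove topology.
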