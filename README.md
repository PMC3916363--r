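# glycoquant

Relative quantification of N-glycans from dual metabolic stable-isotope
labeling (amide-¹⁴N/¹⁵N-Gln) MALDI-TOF experiments.

## The problem

Comparing the N-glycomes of two biological samples — here, the secretomes of
an ovarian cancer cell line (SKOV3) and its highly metastatic derivative
(SKOV3-ip) — by MALDI-TOF MS requires a labeling scheme that lets both
samples be measured in one spectrum. Metabolic labeling with amide-¹⁵N
glutamine routes heavy nitrogen through the hexosamine pathway into every
aminosugar residue, so each glycan appears as a light/heavy pair whose mass
difference is

```
Δm = (n_HexNAc + n_NeuAc) × (m(¹⁵N) − m(¹⁴N)) = n_labeled × 0.99703 Da
```

The catch: for glycans with only two aminosugars the shift is ~2 Da, which
lands the heavy monoisotopic cluster inside the light envelope's ¹³C
isotopologues. A naive monoisotopic height ratio is then biased; `glycoquant`
instead models the observed cluster intensities **y** as a non-negative
linear combination of the two theoretical aggregated envelopes,

```
y ≈ a_L · L + a_H · H,   a_L, a_H ≥ 0  (non-negative least squares)
```

and reports the ratio `a_L / a_H` (light/heavy = SKOV3-ip/SKOV3). Replicate
ratios (3 independent mixtures × 3 MALDI spots, n = 9) are aggregated into a
mean and CV% (100 × sd/mean); a glycan is called **down** below 0.83, **up**
above 1.20, **no** change otherwise — thresholds justified by all replicate
CVs staying below 20%. Compositions are annotated with a curated structure
class (high mannose, hybrid, complex biantennary, tri-/tetra-antennary,
bisecting GlcNAc); composition alone cannot distinguish a bisecting GlcNAc
from an antennary isomer, so curated MS/MS-backed assignments override the
composition heuristic.

The package covers the computational glycomics pipeline end to end: residue
chemistry and theoretical m/z libraries, aggregated isotopic envelopes with
partial ¹⁵N enrichment, profile-spectrum smoothing/centroiding/
normalization, peak-to-composition assignment, envelope deconvolution,
replicate aggregation and change calls, plus a synthetic-data generator that
reproduces the full study design for testing. Downstream wet-lab validation
(qPCR, lectin blots, migration assays, immunohistochemistry) is outside its
scope.

## Worked example

Simulate the default scenario — the 17-glycan secretome panel at its
published SKOV3-ip/SKOV3 ratios, 9 replicate profile spectra — and run the
pipeline:

```r
library(glycoquant)

sim <- simulate_experiment(skov3_scenario())
cfg <- pipeline_config(light_name = "SKOV3-ip", heavy_name = "SKOV3")
fit <- run_pipeline(cfg, sim$spectra)
fit
#> Dual-label glycan quantification: 17 glycans, 9 replicates (SKOV3-ip/SKOV3 ratios, nnls estimator)
#>      composition        glycan_class bisecting theoretical_mz mean_ratio cv_pct n change
#>      HexNAc2Hex6        High mannose     FALSE         1419.5      1.457    4.2 9     up
#>      HexNAc3Hex5              Hybrid     FALSE         1460.5      2.185    5.9 9     up
#>      HexNAc2Hex7        High mannose     FALSE         1581.5      0.940   14.6 9     no
#>      ...
#>      HexNAc5Hex5           Bisecting      TRUE         1866.7      0.285    3.4 9   down
#>      HexNAc5Hex5Fuc1           Bisecting  TRUE         2012.7      0.119   10.6 9   down
#>      ...
#>      HexNAc7Hex7Fuc1           Bisecting  TRUE         2743.0      0.751   11.7 9   down

summary(fit)
#> Glycan class summary (17 glycans):
#>         glycan_class n min_ratio median_ratio max_ratio up no down
#>            Bisecting 4     0.119        0.311     0.751  0  0    4
#>  Complex biantennary 4     0.606        2.711     3.307  3  0    1
#>  High mannose        4     0.940        1.438     1.997  3  1    0
#>  ...
#> Bisecting GlcNAc glycans: 4, ratios 0.12-0.75, calls: down
```

Every glycan's change call matches its true ratio, all CVs stay below 20%,
and the four bisecting-GlcNAc glycans — and only those — are uniformly
down-regulated in the metastatic line, the panel's headline pattern.

Individual pieces are available directly:

```r
composition_mass(glycan(hexnac = 5, hex = 5, fuc = 1))   # 2012.719 ([M+Na]+)
build_pair(glycan(hexnac = 2, hex = 6))$shift            # 1.994 Da label shift
change_call(c(1.46, 0.95, 0.28))                         # "up" "no" "down"
```

A thin CLI over the same functions lives at `inst/cli/glycoquant.R`
(subcommands `make-fixtures`, `centroid`, `annotate`, `quantify`, `run`,
`summarize`).

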