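# cobraAlu

Simulation, densitometric deconvolution and case-control analysis for
**COBRA-Alu** methylation assays — the combined bisulfite restriction
analysis read-out of Alu retroelement methylation used as a surrogate for
global DNA methylation in peripheral blood.

## The assay and the model

Bisulfite treatment converts unmethylated cytosine to uracil (read as T
after PCR) while 5-methylcytosine is protected. The Alu consensus amplicon
(117 bp) carries two interrogated CpG sites; after conversion a TaqI site
(`TCGA`) survives at a CpG only if it was methylated, so digestion cuts
each molecule 0, 1 or 2 times depending on its pattern:

| pattern | meaning | measured fragments (bp) |
|---|---|---|
| `uCuC` | both sites unmethylated | 117 |
| `mCuC` | site 1 methylated | 43 + 74 |
| `uCmC` | site 2 methylated | 75 + 42 |
| `mCmC` | both methylated | 43 + 42 (internal 32 bp below gel range) |

Stain signal is proportional to DNA mass, so dividing each band pool by a
fragment length recovers molar abundances:

```
A = I117 / 117      B = (I75 + I74) / 74.5      D = (I43 + I42) / 43.5
C = D − B           (hypermethylated abundance, clamped at 0 with a QC flag)
```

and the reported pattern percentages are

```
%mCmC = 100·C/(A+B+C)          %uCuC = 100·A/(A+B+C)
%(uCmC+mCuC) = 100·B/(A+B+C)   %mC = 100·(2B+2C)/(2A+2B+2C) = 100·2D/(2A+2D)
```

The package provides the forward model (pattern counts → band
intensities, with a band-noise model and two staining stoichiometries),
the exact inverse above, a calibrated synthetic cohort generator emulating
a type 1 diabetes (T1D) case-control study (36 patients / 29 matched
controls), and the nonparametric statistical layer (median/IQR,
Mann-Whitney U, Spearman rho, chi-squared) that assembles the three
study-style report tables. It is aimed at anyone who wants to validate or
power COBRA-style densitometric deconvolution before pointing it at real
gels.

## Worked example

One sample whose five bands, after length normalization, give
`A = B = C = 1` — a perfectly even mixture of the three pattern classes:

```r
library(cobraAlu)
bands <- band_intensities(I117 = 117, I75 = 37.25, I74 = 37.25,
                          I43 = 43.5, I42 = 43.5)
compute_profile(normalize_bands(bands))
#> Alu methylation profile: mC 66.7%, mCmC 33.3%, partial (uCmC+mCuC) 33.3%, uCuC 33.3%
```

One third of molecules are fully methylated, one third partially, one
third unmethylated; total methylation `mC` is 66.7% because each partial
molecule contributes one methylated site out of two.

A full synthetic study — simulate a cohort, deconvolve every sample,
summarize recovery:

```r
rt <- cobra_roundtrip(default_run_config(seed = 7))
rt
#> COBRA-Alu round-trip validation
#>   max |recovered - latent| share error: 5.7 percentage points
#>   mean absolute error: uCuC 1.19, partial 1.31, mCmC 1.85
#>   per-arm medians of recovered percentages:
#>    group       mC     mCmC  partial     uCuC
#>  control 70.50628 35.34088 33.20243 29.49372
#>      T1D 66.66784 22.65241 42.22661 33.33216
```

With 10,000 molecules per sample and 5% band noise, individual samples
recover their latent pattern shares to within a few percentage points, and
the T1D arm shows its characteristic excess of the partial pattern
(~42% vs ~33% here) at similar total methylation. `rt$report` holds the
three analysis tables (group comparison, pattern-covariate associations,
age-at-diagnosis split). A command-line front end over the same functions
lives in `inst/scripts/cobra-alu.R` (subcommands `simulate`, `deconvolve`,
`analyze`, `roundtrip`).

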