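---
title: "COBRA-Alu densitometric deconvolution: model, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{COBRA-Alu densitometric deconvolution: model, calibration and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobraAlu)
```

## The measurement model

COBRA (combined bisulfite restriction analysis) on Alu repeats is a
semi-quantitative, gel-based read-out of global DNA methylation. The
package models the assay in three layers.

**Digestion.** The 117 bp Alu amplicon carries two interrogated CpG
sites. Bisulfite conversion rewrites unmethylated C to T while protecting
5-methylcytosine; a TaqI site (`TCGA`) therefore survives at a CpG exactly
when it was methylated, and the digest cuts each molecule once per
methylated site. The default `alu_amplicon()` places the cuts at 43 and
75 bp from the 5' end, so the four molecule patterns map to fragments
117 (`uCuC`), 43+74 (`mCuC`), 75+42 (`uCmC`) and 43+32+42 (`mCmC`), and
the five distinct measurable sizes are the bands a gel actually shows:

```{r}
band_catalog(alu_amplicon())
```

The assignment of the two partial patterns to the two fragment pairs is
not observable downstream — the 74/75 and 42/43 bands are pooled before
any quantity is computed — so the convention (site 1 yields 43+74) is a
documented, configurable choice with no numerical consequence. The 32 bp
internal fragment of `mCmC` lies below the gel scoring range
(`measurable_min`, default 40 bp): it is modeled, conserved in the length
bookkeeping, and excluded from the band catalog. Cut placement chemistry
is abstracted: the model stores fragment sizes, not enzyme offsets.
Bisulfite conversion is modeled on the top strand only and assumed
complete; PCR bias and partial conversion are out of scope.

**Staining.** Intercalating stains report DNA *mass*, i.e. fragment
length × molarity. That is precisely why the deconvolution divides each
band pool by a fragment length: `A = I117/117`, `B = (I75+I74)/74.5`,
`D = (I43+I42)/43.5` are molar abundances, and `C = D − B` isolates the
hypermethylated molecules, whose small fragments reach the 42/43 pool
while their mid-sized fragments never reach the 74/75 pool.

Two staining stoichiometries are provided because the arithmetic above
contains a genuine subtlety. Physically, every `mCmC` molecule deposits
*two* small fragments (43 and 42), so with true-length deposits the small
pool carries `D ≈ B + 2C` and the `C = D − B` rule overstates the
hypermethylated abundance about two-fold. Moreover the conventional small
divisor 43.5 is not the 42/43 pair mean (42.5), while the mid divisor
74.5 *is* the 74/75 pair mean, so the two pools are normalized on
slightly different scales. The package resolves this as follows:

* `stoichiometry = "calibrated"` (default): each molecule makes one
  pool-calibrated deposit per cut outcome — 117 into the full band, 74.5
  into the mid pool, and a single 43.5 into the small pool (alternated
  between the 43/42 bands). Under the conventional divisors this gives
  `A = n_uCuC`, `B = n_partial`, `D = B + C` *exactly*, making the
  standard formulas a zero-error inverse of the forward model.
* `stoichiometry = "physical"`: true-length deposits, both small
  fragments of every `mCmC` molecule counted. Its exact inverse is
  `deconvolution = "physical_corrected"` (which replaces `C` with
  `(D − B)/2`) on `band_divisors("pair_mean")` normalization; reading the
  same gel with the conventional rule instead recovers `C` exactly
  doubled, a bias the test suite asserts rather than hides.

Band noise is multiplicative lognormal per band, mean 1, with
coefficient of variation `noise_cv` (default 5%, a typical densitometry
repeatability figure). If noise drives `D` below `B`, `C` is clamped to 0
and the sample is flagged (`qc_flag`), never silently dropped.

**Deconvolution.** `compute_profile()` applies the share formulas.
Total methylation is computed as `mC = mCmC + partial`, which is
algebraically identical to both conventional forms
`100·(2B+2C)/(2A+2B+2C)` and `100·2D/(2A+2D)` whenever `C = D − B`, and
keeps the two profile identities — shares sum to 100 and
`mC = mCmC + partial` — exact even on clamped samples. A useful corollary
is `mC = 100 − uCuC` for every sample.

## The synthetic cohort generator

The generator emulates the shape of a T1D case-control methylation study:
two arms (36 patients, 29 controls), clinical covariates, and latent
per-subject pattern compositions. It exists so that every downstream
stage can be exercised and power-checked without access to patient data.

**Pattern simplex.** Each subject's composition over (`uCuC`, `partial`,
`mCmC`) follows a logistic-normal law: log-scale location at the arm's
median composition plus independent Gaussian perturbations per component,
mapped through softmax. Logistic-normal (rather than Dirichlet) was
chosen because covariate effects then enter additively on the log scale.
A wrinkle worth recording: the published per-arm medians cannot be used
verbatim as a latent composition. The reported T1D medians
(uCuC 33.5 / partial 41.9 / mCmC 24.8 / mC 67.3) sum to over 100 and
violate the per-sample identity `mC = 100 − uCuC` by 0.8 points — both
perfectly possible for marginal medians of real data, but impossible for
a single composition. The calibration therefore pins the partial and mC
medians (the quantities the study's headline findings rest on) and lets
the other two absorb the slack: T1D (32.7, 41.9, 25.4), control
(32.0, 36.0, 32.0). All four pattern medians remain inside the reported
IQRs.

The per-component scales were fitted once by stochastic approximation
(400,000 draws, common random numbers) against the reported IQRs, and
frozen as `cohort_config()` defaults. Three share medians cannot all be hit exactly
— softmax leaves two effective degrees of freedom and spread depresses
the median sum — so the defaults land within 0.35 percentage points of
each target, comfortably inside the ±1.5 point tolerance used in
validation. The fitted T1D `uCuC` scale sits at 0: compositional closure
from the other two components already generates more than the target
`uCuC` spread.

**Covariates.** Skewed variables (fasting glucose, disease duration) are
log-normal, the rest normal, each parameterized by reported median and
IQR (scale = IQR/1.349); T1D age is `age_at_diagnosis + duration`, which
lands its median near the reported 27.5 years; sex is Bernoulli at the
reported male fractions; the complications flag is Bernoulli(0.3), a
configurable placeholder since no prevalence was reported.

**Associations.** HbA1c shifts the partial-pattern log weight and age at
diagnosis shifts the `mCmC` (up) and partial (down) log weights, each per
standard deviation of the arm-standardized covariate. Effect sizes were
tuned by the same one-off simulation to reproduce the reported rank
correlations (rho ≈ 0.29 HbA1c–partial; 0.43 / −0.43 for age at
diagnosis) and frozen. Effects act in the patient arm, where the
associations were observed; the control arm is association-free. The
within-arm correlations between mC and the other patterns are emergent
properties of the simplex law, not calibration targets.

**What the generator does not emulate.** Gel saturation, background
subtraction and lane effects; incomplete bisulfite conversion; PCR bias
across the ~3,500 genomic Alu loci the primers co-amplify;
blood cell-type composition; inter-assay drift (real experiments carry
cell-line controls for this). Passing round-trip tests therefore
demonstrates that the *deconvolution arithmetic and statistical layer*
behave as specified under the stated noise model — not that the assay
itself is unbiased on real gels.

## Statistical conventions

Reporting is deliberately nonparametric throughout, matching
small-sample methylation practice: median/IQR summaries with type-7
(linear interpolation) quartiles; Mann-Whitney U reported in the
min-orientation convention (`U = min(U_x, U_y)`, the form SPSS prints),
exact enumeration for untied samples with `min(n) ≤ 8` and the
tie-corrected, continuity-corrected normal approximation otherwise;
Spearman rho as Pearson on mid-ranks with the two-sided t approximation
on n−2 degrees of freedom; Pearson chi-squared without continuity
correction for the 2×2 sex table (a flag enables Yates). No
multiple-testing adjustment is applied — every p-value is reported
against a single 0.05 threshold, so the association table's 30 rows
should be read accordingly. Normality screening is omitted by design:
the pipeline fixes nonparametric tests rather than branching per
variable.

## Numerical and reproducibility choices

* One global seed is expanded into per-stage streams
  (`derive_seed(seed, stage)`, an affine map modulo 2^31−1), so cohort
  draw, molecule sampling and band noise are individually reproducible
  and identical configurations produce byte-identical outputs.
* Molecule counts are multinomial by default; `sampling = "exact"` uses
  expected counts, which with zero noise makes the full pipeline an
  identity on latent shares to below 1e−9 — the suite's round-trip
  anchor.
* Degenerate inputs fail loudly and specifically: all-zero band rows
  become per-row error records (a run never aborts mid-table), empty
  age-at-diagnosis strata, constant inputs to Spearman, non-cytosine
  methylation positions and unknown configuration keys all raise
  descriptive errors.
* Validation problem sizes: identity and formula properties run over
  10,000 random abundance triples; calibration recovery averages per-arm
  medians over 200 simulated studies at the design size (36/29); the
  type-I error of the partial-pattern comparison is estimated from 1,000
  null studies (both arms drawn from the control law) and checked
  against a 5% ± 2% band at the 0.05 threshold. These sizes give Monte
  Carlo error well below the tolerances they are checked against.

## Known limitations

The deconvolution is exactly identifiable only because the assay pools
the two partial patterns; `mCuC` and `uCmC` are not separable from five
bands and are never reported separately. The `C = D − B` step amplifies
relative noise when `B` and `D` are close (hypomethylated samples), which
is where QC flags concentrate. Calibration reproduces marginal medians,
IQRs and the targeted rank correlations, but not the full joint
distribution of a real cohort; in particular covariate-covariate
dependence (e.g. age with blood pressure) is not modeled.
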