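---
title: "Pedigree, genomic and single-step evaluation of repeated lactation records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree, genomic and single-step evaluation of repeated lactation records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdblup)
```

## The model

Every 305-day lactation record is modelled under a repeatability animal
model:

$$y_{ijkp} = \mu + \text{breed}_i + \text{lact}_j + \text{HYS}_k +
a_p + pe_p + e_{ijkp}$$

with fixed breed, lactation-number and herd-year-season (HYS) effects, a
random additive genetic effect $a \sim N(0, K\sigma^2_A)$, a random
permanent-environment effect $pe \sim N(0, I\sigma^2_{PE})$ shared by a
cow's repeated records, and residual $e \sim N(0, I\sigma^2_E)$. The three
evaluation methods differ *only* in the covariance structure $K$:

* pBLUP: $K = A$, the pedigree numerator relationship matrix;
* GBLUP: $K = G$, the VanRaden method-1 genomic relationship matrix among
  genotyped animals;
* ssGBLUP: $K = H$, which equals $A$ with the genotyped block $A_{22}$
  replaced by $G$; only $H^{-1}$ is ever formed,
  $H^{-1} = A^{-1} + \begin{pmatrix}0&0\\0&\tau G^{-1}-\omega
  A_{22}^{-1}\end{pmatrix}$, defaults $\tau=\omega=1$.

`solve_mme()` solves Henderson's mixed-model equations for all three —
the tests assert that the code path is literally identical, with the
inverse structure as the only argument that changes, and that the
solutions match an independent GLS/BLUP oracle
($\hat u = \sigma^2_A K Z' V^{-1}(y - X\hat\beta_{GLS})$, dense $V$
inversion) to 1e-8 on random instances.

## Parameters that matter

* **Heritability `h2`** (per trait: 0.19 MY, 0.17 FY, 0.19 PY) and
  **repeatability** (default 0.40). These are *inputs*, not estimates: the
  solver only uses the ratios $\lambda_A = \sigma^2_E/\sigma^2_A$ and
  $\lambda_{PE} = \sigma^2_E/\sigma^2_{PE}$ derived from them. REML
  estimation is out of scope by design. The repeatability default is an
  assumption (the study this design follows never prints its estimates);
  0.40 is a typical dairy value for 305-day yields. When
  `repeatability == h2` the permanent-environment effect has zero variance
  and is dropped from the equations.
* **QC thresholds**: MAF < 0.05, HWE $\chi^2$ p < 1e-15, autosomes 1–29,
  and a missing-map filter, applied in the fixed order no-location →
  non-autosomal → monomorphic/MAF → HWE, each SNP counted once under its
  first failure. A chi-square goodness-of-fit test was chosen for HWE (the
  exact test is an alternative; at the extreme 1e-15 threshold the choice
  is immaterial for all but tiny samples).
* **Blend weight `blend_weight`** (default 0.05): $G$ is returned as
  $(1-\beta)G_{raw} + \beta A_{22}$ (identity if no $A_{22}$ is given).
  Raw VanRaden matrices are singular whenever animals outnumber effective
  SNP segments; blending guarantees a positive-definite $G$ — required
  for $G^{-1}$ in GBLUP and for the single-step correction block. No
  mean/scale tuning of $G$ toward $A_{22}$ is applied by default: it is
  not part of the base construction, and keeping it off makes the blend's
  effect explicit.
* **`tau` / `omega`** scale the genomic and pedigree-correction blocks of
  $H^{-1}$; the defaults (1, 1) are the original single-step formulation.

## Validation design and statistics

`assign_folds()` splits cows into three test sets by their *count* of
lactation records — 1, 2 or 3, regardless of which parities those are.
Per fold, test phenotypes are masked, the model is refitted on the
remaining records, and the held-out records are adjusted with the
*training* fixed-effect estimates ($y^* = y - x'\hat b$, averaged per
cow). Records whose fixed levels (typically an HYS class) were not
estimable in training are excluded with a logged count. Using training
rather than whole-data estimates avoids leakage; a whole-data variant
would be the other defensible reading and can be obtained by fitting once
on all records and passing that solution to `adjust_phenotypes()`.

The accuracy statistic is

$$r = \frac{\mathrm{corr}(\widehat{BV}, \overline{y^*})}
{\sqrt{h^2 / (rep + (1-rep)/n)}}.$$

The denominator is the square root of the heritability of an $n$-record
mean, $\sqrt{n h^2 / (1 + (n-1)rep)}$: at $n = 1$ it reduces to $h$
exactly. (The printed source formula is typographically corrupted; this is
the unique reading consistent with its own $n=1$ anchor and the classical
repeated-records identity, and both are asserted in the tests.)
Correlation is Pearson, on per-cow pairs of EBV and mean adjusted
phenotype. Dispersion bias is the OLS slope of adjusted phenotype on EBV;
1 means no bias, below 1 over-dispersed EBVs. Trait-level values average
the three folds; the reported ± is the sd across folds (the source tables
never define their ±; sd across folds is our interpretation).

## What the simulator emulates — and what it does not

`simulate_herd()` generates the world the analysis assumes: a
six-generation discrete pedigree (~2,640 animals at defaults) across 12
herds linked by a small shared sire pool; three breeds (BUL, BRA, AME,
founder probabilities 0.60/0.25/0.15, sires all BUL) with two cross
classes; gene-dropped biallelic SNPs (founder frequencies Beta(2,2); 2%
no-location, 2% non-autosomal, 4% low-MAF, 2% all-heterozygote HWE chaff
so each QC rule has known targets); 1–3 records per cow with the
1/2/3-record proportions 0.364/0.311/0.325 taken from the source study's
test-set tallies; and partial genotyping (904/1975 ≈ 46% of phenotyped
cows revealed).

Phenotype construction: true breeding values are $M_c u$ over the clean
SNPs with $u \sim N(0, \sigma^2_A / (2\Sigma p(1-p)))$, centred on the
population mean (the evaluation is invariant to the base; centring keeps
the realized phenotypic mean on target despite genetic drift through the
small sire pool). Fixed effects are breed offsets of ±5% of the trait
mean, lactation offsets of 0/4/6% (older cows yield more), and HYS effects
$N(0, (0.15 \cdot \text{mean})^2)$ over herd × year × two calving seasons
— consecutive lactations fall in consecutive years so contemporary groups
hold tens of records, as in a real recording system. Each drawn effect
vector is centred; the variance components are back-solved from the target
phenotypic sd (505.9 kg) *after* subtracting the realized fixed-effect
variance, so the random part carries exactly the configured $h^2$ and
repeatability. Residuals that would produce non-positive 305-day yields
are redrawn (a mild truncation, matching the strictly positive range of
real yields).

Not emulated: realistic linkage disequilibrium and chip ascertainment
(SNPs are in linkage equilibrium at the founders), selection across
generations, genotyping error, dominance or epistasis, and unknown-parent
groups. A green directional test therefore establishes that the methods
rank as expected *when the model is true and pedigree depth is complete* —
it does not reproduce the absolute accuracies of the restricted real data,
where pedigree information is weaker and genomic gains are relatively
larger.

## Numerical choices

* Mixed-model equations are assembled sparsely (`Matrix`) and solved by
  sparse Cholesky with one step of iterative refinement; pBLUP systems are
  fully sparse, single-step systems carry one dense genotyped block.
* $A^{-1}$ uses Henderson's rules with inbreeding coefficients read off
  the tabular $A$ (exact at these scales; the Meuwissen–Luo algorithm
  would replace it for very large pedigrees).
* A single unknown parent is treated as an unrelated, non-inbred phantom
  (Mendelian-sampling variance $0.75 - 0.25F_{known}$).
* Fixed effects use reference-level (drop-first) coding with the intercept
  retained; aliased columns are removed by pivoted QR with a warning.
  Individual coefficients are therefore not unique under confounding, but
  adjusted phenotypes depend only on estimable functions.
* Missing dosages are imputed with the column mean $2p$ — neutral under
  the subsequent $2p$ centring.
* Folds with fewer than 3 usable test animals are skipped with a warning;
  zero EBV variance yields a missing slope rather than an error.

## Known limitations

Variance components must be supplied, not estimated; multi-trait and
random-regression (test-day) models are out of scope; the dense tabular
$A$ bounds practical pedigree size to a few tens of thousands; the CLI's
`report` merger assumes one row per (trait, method) pair; and the
simulator's breed/HYS magnitudes, while plausible for dairy populations,
are assumptions — they are configurable and flagged as such.
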