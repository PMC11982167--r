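---
title: "Models and methods behind pleiometa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pleiometa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pleiometa` implements a complete workflow for finding *stable pleiotropic
QTL* — loci that affect several grain nutritional elements consistently
across field environments — in panels of inbred lines. This vignette
explains the statistical models behind each stage, the tunable parameters
and their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices a maintainer should know about.

## The analysis problem

A panel of inbred wheat-type lines is phenotyped for 13 grain element
concentrations (B, Ca, Co, Cu, Fe, K, Mg, Mn, Mo, Na, Ni, P, Zn) in six
replicated field trials, and genotyped with a dense SNP array. Elements
fall into two groups with positive genetic correlations inside each group
and negative correlations between groups; a pleiotropic locus whose allele
raises the first group while lowering the second is *antagonistic*.
Per-trait, per-environment association scans are underpowered for such
loci; combining all scans into one multi-trait statistic is the core of
the method.

## Stage by stage

### Genotype quality control (`qc_genotypes`)

Three filters are applied in a fixed order, each with a strict inequality:

* lines with **over 40%** missing calls are removed (missingness assessed
  on the unfiltered SNP set);
* SNPs with call rate **below 60%** are removed;
* SNPs with minor allele frequency **below 5%** are removed.

Remaining missing calls are imputed by LD-kNN: for each SNP the `l = 30`
SNPs in highest r² with it are used to compute a missing-aware Manhattan
distance from the target line to every line observed at that SNP, and the
`k = 5` nearest lines cast an inverse-distance-weighted vote over the
genotype classes. Observed calls are never altered. Accuracy is estimated
by masking 1% of observed cells and re-imputing them
(`imputation_concordance` in the QC report). Two implementation notes:
the r² used to *rank* candidate predictor SNPs is computed on standardized,
zero-filled dosages (a single BLAS cross-product; ranking agreement with
the pairwise-complete correlation exceeds 99% in our checks), and distance
ties are broken by line order so the imputation is deterministic.

### Field-trial BLUEs (`fit_trial`, `blues_all`)

Each environment × element is fitted separately with the mixed model

    value = mu + line (fixed) + row + col + rep (random) + e

by REML (via lme4). The best linear unbiased estimate of a line is the
generalized-least-squares estimate of `mu + line`. Row, column and
replicate effects are independent, identically distributed random
effects: this deliberately simplifies a full spatial adjustment (no
AR1×AR1 residual correlation), which also keeps the model identifiable on
small trials. Random terms with fewer than two levels, or one observation
per level, are dropped; a singular fit falls back by dropping random terms
one at a time (recorded in `dropped_terms`), ending at ordinary least
squares, where BLUEs are raw line means. On balanced complete-block data
with no row/column variance, BLUEs equal line means to optimizer
tolerance (about 1e-6; the boundary variance estimates are zero only to
the tolerance of lme4's optimizer).

### Genomic relatedness (`compute_grm`)

The allele-frequency-standardized relatedness matrix is

    G[j,k] = (1/m) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))

with frequencies estimated from the analyzed lines. For fully inbred lines
the diagonal of this matrix is near 2 (there are no heterozygotes), not 1.
`compute_grm` reports the raw matrix; the REML fits rescale it internally
to unit mean diagonal so that `h2 = vg / (vg + ve)` always reads as the
genetic fraction of line-value variance, and the scan's variance ratio is
converted back to the raw scale. `stabilize_grm` shifts the spectrum
upward by `|min eigenvalue| + 1e-6` only when the smallest eigenvalue is
negative. For the four subset trials, the GWAS uses the sub-matrix of the
full-panel GRM (frequencies are not re-estimated), keeping allele-effect
signs comparable across analyses.

### GREML heritability and genetic correlations

The univariate model `y = mu + g + e`, `g ~ N(0, vg G)`, `e ~ N(0, ve I)`
is fitted by REML after one eigendecomposition of G: with
`lambda = vg/ve` the rotated covariance is diagonal, every likelihood
evaluation is O(n), and the likelihood is profiled over `h2` on [0, 1]
(golden-section/parabolic search, tolerance 1e-9; boundary optima are
flagged and get no curvature-based standard error).

The bivariate model gives the genetic correlation
`rg = Vg12 / sqrt(Vg11 Vg22)` from 2×2 genetic and residual covariance
matrices, Cholesky-parameterized so both stay positive definite, optimized
by Nelder-Mead then BFGS from univariate starting values; `rg` is clipped
to [-1, 1] (clipping recorded). Lines are used complete-case, since the
subset trials observe far fewer lines than the full-panel trials. Exactly
collinear traits make this likelihood unbounded (the residual correlation
runs to 1), so the fit detects phenotypic |cor| > 1 - 1e-8 and collapses
to the univariate model.

Per-trial correlations are averaged across trials by an unweighted
arithmetic mean (non-converged fits excluded and counted). Elements are
grouped by average-linkage hierarchical clustering on distance `1 - rg`,
cut at k = 2; manual overrides are applied after clustering and recorded,
mirroring the practice of re-assigning a borderline element on biological
grounds.

### Mixed-linear-model scan (`mlm_scan`)

Each SNP is tested as a fixed effect in
`y = mu + x beta + g + e` under covariance `ve (lambda G + I)`. The
default mode re-optimizes `lambda` per SNP by REML on a 61-point log grid
spanning 1e-5 to 1e5 with golden-section refinement (the exact-mixed-model
strategy); `null_lambda` mode reuses the null-model ratio for all SNPs
(the EMMAX/P3D approximation), which is what the large calibration
experiments use. The Wald statistic `t = beta/se` is referred to
Student-t with `n - 2` degrees of freedom. The alternate allele is the
effect allele in every analysis, so `t` signs are comparable. Monomorphic
SNPs in an analysis subset are emitted with `beta = 0, p = 1` and a flag,
keeping the t-matrix rectangular.

### Multi-trait meta-analysis (`meta_chi2`, `run_meta_design`)

For SNP i with signed t-values `t_i` across analyses,

    chi2_i = t_i' V^{-1} t_i

where V is the Pearson correlation matrix of the t columns over SNPs.
The global p-value is the upper chi-square tail with df equal to the rank
of V restricted to the analyses where the SNP is present (missing entries
are handled by per-SNP subsetting of t and V rather than dropping the
SNP — necessary because only a subset of lines is phenotyped in four of
six trials). Rank-deficient V is inverted by Moore-Penrose pseudo-inverse
(eigenvalues below 1e-10 of the maximum treated as zero). Three analyses
are run: Meta1 (group-one elements × all environments), Meta2 (group two),
and Meta (all columns), all at the Bonferroni threshold `alpha / m`.

`estimate_v` exposes `trim_quantile`: SNPs whose |t| exceeds that
per-column quantile are excluded before correlating. The default (1.0,
no trimming) matches the convention of estimating V from all SNPs, which
is appropriate when true QTL are a negligible fraction of markers. On
deliberately small simulated panels the QTL fraction is orders of
magnitude larger and untrimmed V absorbs genuine signal, deflating every
chi-square; the acceptance workflow therefore trims at 0.95. This is a
property of panel scale, not of the statistic.

Significant SNPs are clustered into QTL per chromosome: the most
significant unassigned SNP seeds a cluster and every unassigned
significant SNP with `r2 > 0.5` *to that lead* joins it, repeating until
none remain. Lead-based assignment (rather than chaining through nearest
members) is deterministic and matches lead-SNP reporting; ties in
significance break by position. Allelic effects at a reported SNP are
summarized per analysis as the difference of homozygote-class BLUE means
in units of the phenotypic SD, heterozygotes excluded.

### LD decay (`ld_analysis`)

r² is the squared Pearson correlation of dosages (phase-free). The decay
curve is a degree-2 loess (tricube weights) of r² on intra-chromosomal
pair distance, evaluated on a 200-point grid; the background (critical) LD
is the 99th linear-interpolation quantile of r² between inter-chromosomal
pairs; the LD block size is the first grid distance at which the smoothed
curve falls to the background, linearly interpolated — undefined (and
reported as such) when the curve never reaches it, zero when it starts
below it. Pair sampling is capped (defaults: 200,000 intra-chromosomal
pairs per chromosome, 100,000 inter-chromosomal) to stay desk-scale; the
span default is 0.5.

## The synthetic-data generator

The generator exists so that every stage can be verified against ground
truth; its defaults emulate the structure the analysis assumes.

* **Genotypes** (`simulate_genotypes`): fully homozygous doubled
  haplotypes copied from 30 founder haplotypes along each chromosome,
  switching founders between adjacent SNPs with probability
  `1 - exp(-d/ld_scale)`. The founders themselves carry internal LD
  (each founder keeps its previous allele with probability
  `exp(-d/ld_scale)`, otherwise redraws from the site frequency);
  without that, r² would be capped near `1/n_founders` at any distance.
  `ld_scale = 3.5e6` bp is calibrated once so that the span-0.5 decay
  curve of a typical panel crosses its background LD near 7 Mb.
  Genetic-map positions are bp / 4.5 Mb per cM, for reporting only.
* **Architecture** (`simulate_architecture`): shared QTL effect vectors
  are drawn from a multivariate normal whose correlation matrix has
  `rg_within = 0.45` inside each element group and `rg_between = -0.20`
  across groups; private QTL (2 per element) affect one element each;
  antagonistic QTL get a common-magnitude effect, positive for group one
  and negative for group two. Antagonistic loci are drawn major-effect
  (|N(2, 0.5)| before scaling, versus N(0, 1) for shared QTL): they stand
  for the kind of single strong locus the analysis is designed to
  surface, not for polygenic background. Effects are rescaled per element
  so the realized genetic variance equals `h2/(1-h2)` with
  `h2_target = 0.42` against a unit effective residual.
* **Trials** (`simulate_trials`): six randomized complete-block trials
  (two on the full panel, four on a 200-line subset), two replicates,
  plot value = intercept + genetic value × environment scaler + replicate
  effect + independent quadratic row and column trends (total SD
  `spatial_sd = 0.5`) + residual. The default residual SD is `sqrt(2)`
  so that with two replicates the per-line BLUE error variance is about
  one, making BLUE-level GREML heritability match `h2_target`.

What the generator does **not** emulate: coalescent ancestry, selection
or pedigree structure, AR1×AR1 spatial residual correlation,
genotype-by-environment interaction beyond scalar environment
multipliers, and genotyping-platform artifacts. Tests passing on this
generator therefore demonstrate correctness of the estimators under the
stated model, not robustness to every feature of real field data.

All randomness flows from one integer seed through named sub-streams
(`derive_seed(seed, stage)`), so adding a stage never perturbs another.

## Numerical choices and degenerate inputs

* REML likelihood comparisons against a dense direct evaluation (explicit
  inverse and log-determinants) agree to 1e-6 on small instances; the two
  code paths share no linear algebra.
* The h2 profile search runs on [1e-6, 1 - 1e-6] with explicit boundary
  checks; boundary optima are reported with `boundary = TRUE`.
* `scan_at_lambda` clamps negative residual sums of squares (roundoff at
  near-perfect fits) to zero.
* Loess spans too small for a local quadratic are widened with a warning;
  smoothed r² is floored at zero; NA predictions at the grid edges carry
  the nearest fitted value.
* Neighbor-distance ties in imputation and significance ties in QTL
  clustering break by line order and position respectively; both are
  logged as deterministic conventions.
* TSV output uses `.` for undefined values and is locale-independent.

## Problem sizes used by the tests and the acceptance run

The shipped test-suite and `scripts/acceptance.R` use scaled panels chosen
as the smallest sizes at which each property is informative: oracle
comparisons at n = 30-50; recovery experiments at n = 500 lines × ~2,000
SNPs over 20 seeds; null calibration at 300 lines × 10,000 SNPs × 26
analyses; power ordering at 300 lines × ~300 SNPs over 25 seeds per
condition; the end-to-end acceptance study at 300 lines (120-line subset
in four of six trials) × ~1,600 SNPs with all 13 elements. The acceptance
run reports, among others, the mean GREML h² across the 78 trials, the
averaged within- and between-group genetic correlations, the grouping
agreement with truth, imputation concordance, background LD and block
size, QTL counts for Meta1/Meta2/Meta, and whether the antagonistic locus
is recovered.

## Known limitations

* The BLUE model omits spatial residual correlation; strongly structured
  field error will leak into BLUE standard errors.
* Bivariate REML reports no standard error for rg (a convergence flag is
  provided instead); averaging across trials is unweighted.
* The meta statistic assumes the t-correlation matrix is estimated well;
  with few SNPs or a high QTL fraction it is noisy and conservative
  without trimming (see above).
* GEMMA-style score/likelihood-ratio p-values are not implemented; the
  Wald test with `n - 2` degrees of freedom is used throughout.
* Dosages are treated additively; dominance is not modeled anywhere.
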