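---
title: "Chromosome-specific inbreeding from runs of homozygosity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosome-specific inbreeding from runs of homozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rohline)
```

## Overview

`rohline` implements a complete analysis chain for studying inbreeding
depression at chromosome resolution in closed livestock populations:
quality control of SNP genotypes, pedigree inbreeding coefficients
(F~PED~), sliding-window detection of runs of homozygosity (ROH), the
genomic inbreeding coefficient F~ROH~ and its per-chromosome partition,
inbreeding-depression regressions, and cross-validated phenotype
prediction with chromosome selection. A gene-dropping simulator generates
closed-line populations with known identity-by-descent (IBD) ground truth,
so every estimator in the chain can be validated against what it is meant
to estimate.

This vignette documents the statistical models, the conventions that had to
be pinned down, the defaults and their rationale, and the limits of what
the synthetic validation can show.

## Pedigree inbreeding

`compute_fped()` uses Henderson's tabular method: in pedigree order, the
numerator relationship matrix is built as

- `a_ii = 1 + 0.5 * a[sire, dam]` (a missing parent contributes 0), and
- `a_ij = 0.5 * (a[j, sire(i)] + a[j, dam(i)])` for previously processed
  `j`,

with `F_i = a_ii - 1`. For pedigrees above `max_tabular` animals (default
2000) the dense matrix is not materialized; the Meuwissen–Luo recursion
carries only the diagonal and yields the same values to numerical
precision (verified to 1e-12 in the tests). Founders have F = 0; genetic
groups / phantom-parent adjustments are out of scope.

As an independent oracle, `wright_path_fped()` computes F by Wright's path
counting: the sum over common ancestors Z of the parents, and over pairs of
ancestral paths sharing no animal but Z, of `0.5^(n_s + n_d + 1) * (1 +
F_Z)`. It is exponential in pedigree depth and exists for testing; the
tabular method is the production path. The test suite checks the two agree
to 1e-12 on 200 random pedigrees and that classical configurations come
out exactly (full sibs 0.25, half sibs 0.125, parent–offspring 0.25,
double first cousins 0.125).

## Quality control

`filter_snps()` applies three filters **in a fixed order** — call rate
< 0.90, then minor allele frequency < 0.05, then Hardy–Weinberg
heterozygote deviation > 0.15 — because the per-criterion removal counts
depend on the order and must be reproducible. Allele frequencies are
recomputed on the SNPs surviving the previous step, using non-missing
calls. The HWE criterion is interpreted as the absolute difference between
the observed heterozygote frequency and its expectation `2p(1-p)`; this
matches the common preprocessing-tool semantics of a percentage deviation
from equilibrium. All boundary comparisons are strict: a SNP at exactly 90%
call rate survives.

Animals with call rate below 0.90 are *flagged, never removed* — in a small
closed herd every genotyped animal is valuable and a low call rate warrants
investigation of the assay, not silent deletion. Phenotypes equal to zero
are treated as missing, and values outside mean ± 3 SD (computed on the
nonzero values) are discarded, again with strict boundaries.

## ROH detection

`detect_roh()` implements the sliding-window method. A window of
`window_size_snps` (default 15) slides one SNP at a time; a window is
homozygous when it has at most `max_het_in_run` heterozygotes and
`max_miss_in_run` missing calls (defaults 2 and 2). Each SNP's score is the
fraction of covering windows that are homozygous, and the SNP is flagged at
score ≥ `window_threshold` (default 0.05). Flagged stretches become
candidate runs; candidates are split at inter-SNP gaps above `max_gap_bp`
(default 1 Mb); within a candidate, a heterozygous or missing call that
would exceed its allowance ends the run just before it and a fresh
candidate starts just after. Surviving runs must carry ≥ `min_snp` SNPs
(default 30), span ≥ `min_length_bp` (default 1 Mb) and average at least
one SNP per `min_density_bp_per_snp` (default 500 kb).

Conventions that the literature leaves open and that are pinned here:

- Run length is `end_bp - start_bp + 1` with both ends on mapped SNPs
  (closed, 1-based); the density filter uses this length.
- The het/missing allowance applies at the *run* level; windows reuse the
  same limits.
- Minima pass at equality ("≥"), maxima pass at equality ("≤").
- Window size, threshold and gap are not fixed by the run-level filters
  above; the defaults (15 SNPs, 0.05, 1 Mb) follow the widely used
  detection tools and are exposed as parameters.
- Missing calls count toward a run's SNP total but are neither homozygous
  nor heterozygous.

`brute_force_roh()` applies the same rules through an independent,
deliberately naive code path (explicit window enumeration and a per-SNP
state machine, no shared helpers) and is compared segment-for-segment
against the production detector on 1000 random vectors in the acceptance
suite. With `window_size_snps = 1`, threshold 1 and zero allowances the
detector provably reduces to a plain consecutive-homozygote scan, which the
tests check against a closed-form reference.

One caveat found during development: "raising the heterozygote allowance
never decreases total ROH length" is *not* a theorem once the SNP-count and
length filters interact with run truncation — a shifted truncation point
can leave a remnant too short to pass a filter it previously passed. The
monotonicity property is therefore asserted only in the filter-free
regime, where it does hold.

## FROH and its partition

`compute_froh()` defines F~ROH-CHRc~ as the summed ROH length on
chromosome c divided by the length of c, and genome-wide F~ROH~ as total
ROH length over total length — identically the length-weighted mean of the
per-chromosome values, an identity the tests verify to 1e-12. The default
denominator is the **SNP-covered length** (first to last mapped SNP): with
panel data the covered length is the observable universe, and using it
makes a fully homozygous animal reach F~ROH~ = 1 exactly. Assembly lengths
can be supplied instead wherever a length table is accepted.

The X chromosome (coded 30) is treated as missing for males: excluded from
their per-chromosome table and from both sums of their genome-wide ratio.
For females X is included by default (`include_x_females = FALSE` opts
out). Animals with genome-wide F~ROH~ exactly 0 can be dropped with
`filter_positive_froh()` — applied genome-wide, not per chromosome, and
with a strict inequality.

## Phenotype correction and depression regressions

Phenotypes are corrected in a separate step: `correct_phenotypes()` fits
OLS of raw ADG on categorical sex and categorical year of birth and returns
the residuals. Year is deliberately *unordered* categorical rather than a
linear trend: in a closed line inbreeding rises with time, and a linear
year term would absorb part of the inbreeding signal; the categorical fit
is the conservative choice. Correcting first and regressing on inbreeding
afterwards coincides with the joint model exactly when the design is
balanced (the Frisch–Waugh property); the tests document this on a balanced
fixture. A factor with one level present is dropped with a warning; a level
carried by a single animal is retained (its residual is absorbed).

`fit_depression()` fits `y = mu + F a + e` by OLS with classical standard
errors and two-sided t-tests, and refuses zero-variance or collinear
predictors by name. `per_chromosome_fits()` runs one single-predictor model
per chromosome; the X model uses females only. Slopes are in kg/day per
unit inbreeding coefficient.

## Cross-validation and chromosome selection

`cv_accuracy()` repeats (default 500 times) a uniform random 80/20 split:
OLS on the `floor(0.8 n)` training animals, Pearson correlation between
predictions and observations on the rest. `floor` is pinned for
reproducibility (at n = 672 this gives 537/135 where rounding would give
538/134 — a one-animal difference that must simply be fixed one way). A
round with zero-variance predictions or a rank-deficient training design
records accuracy 0 and is flagged rather than failing. The running mean is
declared converged at the smallest K after which every change stays below
`convergence_tol` (default 1e-4); with noisy accuracy distributions (SD
around 0.2) this strict criterion is often not met within 500 rounds, which
the result object reports honestly.

`compare_predictor_sets()` evaluates several predictor sets on **one shared
split sequence** (common random numbers), so per-round differences are
paired and model contrasts have far lower variance than independent runs
would give; animals missing in any set (male X) are dropped listwise for
all sets to keep the pairing exact. `tukey_compare()` then applies the
studentized-range test to the per-round accuracy samples and builds a
compact letter display by greedy insert-and-absorb, ordered by decreasing
mean; two groups share no letter exactly when their adjusted p-value is
below 0.05. (The 500 rounds of one data set are resampling replicates, not
independent samples; the Tukey comparison is reproduced as the field uses
it, without endorsing that independence assumption.)

`select_chromosomes()` ranks chromosomes by full-data p-value, absolute
slope, or mean CV accuracy, with ties broken toward the lower chromosome
number, truncated at `k` or at a threshold.

## The simulator

`simulate_pedigree()` builds a closed line: two founder bulls made paternal
half sibs through a shared phantom sire, 50 unrelated founder cows, and
discrete generations in which 2 sires service up to 50 dams, each dam
leaving 2 calves of random sex. Eight generations of this mating structure
alone (no selection is simulated) drive mean pedigree F of the final
generation to ≈ 0.4 and of the whole population to ≈ 0.2 — the inbreeding
build-up characteristic of a long-closed line.

`gene_drop()` assigns every founder uniquely labeled chromosome haplotypes
and simulates meiosis with crossovers from a Poisson process at 1 cM/Mb
(Haldane model, no interference), checked by a chi-square goodness-of-fit
on simulated meioses. An animal's true IBD fraction per chromosome is the
base-pair fraction where its two haplotype labels coincide; its expectation
equals pedigree F, which the tests verify by replicate gene drops
(full-sib offspring: 0.25 within 3 Monte-Carlo SE). SNP alleles are
assigned to founder haplotypes at frequencies drawn from
`maf_range = (0.05, 0.5)`, so short chance-homozygous (IBS) stretches occur
and the ROH length/SNP filters have something real to reject. The male X is
haploid (one maternal copy, recorded as homozygous genotypes) and its IBD
is undefined, matching the analysis-side convention.

`simulate_phenotype()` generates
`adg = mu + sex_effect·[male] + year_effect[year] + Σ_c b_c·IBD_c + ε`.
Defaults: `mu = 0.83`, `sex_effect = 0.15` (bulls out-gain heifers),
`year_effect_sd = 0.08`, depression `b_c = -0.2` kg/day on chromosomes 2, 4
and 10 and zero elsewhere, and `residual_sd = 0.33`. The residual SD was
calibrated once so that the marginal phenotype SD lands near 0.353 kg/day
(five-seed check: mean 0.797, SD 0.355); the remaining genetic variance of
ADG beyond the inbreeding-linked part (heritability ≈ 0.25) is not modeled
separately — it is absorbed into the residual, which is the right level of
detail for validating inbreeding estimators but *not* for studying
polygenic prediction.

What the simulator deliberately does not emulate: linkage disequilibrium
among founder alleles, coalescent founder haplotype structure, mutation,
selection on the phenotype, and non-uniform recombination maps. Passing
tests on this synthetic population therefore demonstrate that the
estimators and the cross-validation machinery are correct and calibrated
under the stated generative model — not that real cattle data will show
effects of any particular size.

## Problem sizes used in the automated checks

The validation suite runs entirely from code at sizes chosen to give the
properties adequate power while staying desk-scale: oracle equivalence on
200 random pedigrees (≤ 30 animals) and 1000 random genotype vectors
(≤ 200 SNPs); 2000 replicate gene drops for the IBD calibration; 200
regression replicates at n = 500 for slope coverage; and 50 replicate
closed-line populations (30 founder dams, 5 generations, 4 offspring per
dam, ten 10-Mb chromosomes — about 950 animals each) for the
planted-effect recovery experiment. That population size was fixed after a
design-time power pilot showed 9/10 recovery at ~650 animals and 20/20 at
~950; the acceptance threshold (planted chromosomes 2, 4, 10 take the
top-3 single-chromosome CV accuracies in ≥ 90% of replicates) was set
before the pilot. The default full-scale study (29 autosomes + X, ~30 K
SNPs, ~850 animals) is exercised by `scripts/acceptance.R`.

## Known limitations

- The ROH detector and its oracle implement one published rule set; other
  tools differ in window scoring details, and ROH counts are sensitive to
  those choices. All parameters are exposed; defaults are documented above.
- The positive-F~ROH~ filter conditions the analysis sample on detectable
  homozygosity; with short genomes (e.g. the tiny test preset) this both
  inflates mean F~ROH~ and weakens its correlation with F~PED~.
- Tukey comparisons across cross-validation rounds treat paired resamples
  as samples; letters should be read as a conventional summary, not as
  exact family-wise error control.
- Depression slopes from per-chromosome models ignore the correlation of
  chromosome-level IBD within animals; the multi-chromosome and
  selected-chromosome models address prediction, not causal attribution.
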