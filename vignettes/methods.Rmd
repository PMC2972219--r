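---
title: "Haplotype-pair association scanning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-pair association scanning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapscan)
```

# The problem

`hapscan` implements the statistical core of a classical livestock QTL
localization design: a quantitative trait (here, the number of ova and
embryos recovered per superovulation of a cow) is mapped with a genome-wide
panel of multiallelic microsatellite markers by genotyping only the
phenotypic extremes ("selective genotyping"), testing the haplotypes of
consecutive marker pairs for frequency differences between the high and low
tails, and screening the sample for stratification and Hardy-Weinberg
artefacts. The same machinery supports the two population-genetic summaries
such a study reports alongside the scan: the effective population size
estimated from linkage-disequilibrium decay, and the genomic-control
inflation factor.

No individual-level data from the motivating study are available, so the
package ships a forward simulator that generates study cohorts with the same
statistical structure; every downstream stage is tested against those
synthetic studies plus analytic and enumeration oracles.

# Two-locus EM and the association scan

## EM haplotype frequencies

For two markers with unordered genotypes, phase is observable except in
double heterozygotes, which are compatible with two complementary haplotype
resolutions. `em_pair()` maximizes the multinomial likelihood over the joint
haplotype frequency table: the E-step splits each double heterozygote
between its two resolutions in proportion to the current frequency products,
the M-step re-estimates frequencies from expected counts over the `2n`
chromosomes. The log-likelihood is asserted non-decreasing at every
iteration, and convergence is declared on the frequency change
(`max |delta f| < 1e-8` by default, frequencies being the deliverable)
rather than on the likelihood change.

Initialization is the linkage-equilibrium product of the observed allele
frequencies. That point is an exact EM fixed point (a saddle) whenever every
individual is doubly heterozygous, so a deterministic `+1e-6` perturbation
is placed on the lexicographically first haplotype supported by a double
heterozygote. This both escapes the saddle and makes the tie-break between
the two symmetric global maxima of the all-double-het case deterministic and
documented. Individuals missing either marker are excluded pairwise. Only
two-locus models are implemented: the scan never needs longer windows.

Small phase-ambiguous samples are a separate problem: benchmarking EM
against a multi-start direct maximization of the same likelihood showed
that with fewer than a few dozen individuals and several double
heterozygotes, the two-locus likelihood can be genuinely multimodal and a
single EM run can settle on an inferior mode. `em_pair()` therefore adds
nine deterministic Dirichlet-restart runs whenever the sample is small
(`n <= 50`) and phase-ambiguous, keeping the best final likelihood; the
linkage-equilibrium start wins ties, so the tie-break above is unaffected,
and the restarts use an isolated RNG stream so results never depend on the
caller's seed state. At study sample sizes the linkage-equilibrium start
was never observed to lose, and restarts are off by default there to keep
genome scans fast (`restarts` overrides either choice).

## From frequencies to a testable table

The source method leaves open how EM output becomes an integer contingency
table. The package default (`count_method = "best_phase"`) fits the EM on
the pooled high+low sample, assigns every individual its most likely phase
(`assign_best_phase()`, with a lexicographic tie rule), and tallies integer
haplotype counts per group; this yields true integers with correct margins.
The alternative (`"em_expected"`) fits a separate EM per group and rounds
expected counts. Both are exposed because neither is recoverable from the
method's published description; the default is logged in every scan.

Minor haplotypes with combined-sample EM frequency below `min_freq`
(default 0.05) are removed before testing. The filter deliberately uses the
pooled frequencies: per-group filtering could retain different haplotype
sets in the two columns of the same table.

## Exact tests

`fisher_exact_rx2()` implements the two-sided exact test for r x 2 tables
under the multivariate hypergeometric null: the p-value sums the
probabilities of all tables with probability at most that of the observed
table, with a `1e-12` relative tolerance for ties so that discrete
near-ties are handled deterministically. The table space is enumerated
exactly up to a bound of `1e6` candidate tables (a pure-R vectorized
expansion; the bound is an argument) and sampled with `stats::r2dtable()`
beyond it, reporting the Monte Carlo standard error. `hwe_test()` applies
the analogous conditional exact test for Hardy-Weinberg equilibrium at a
multiallelic marker, enumerating over heterozygote-count tables (homozygote
counts are determined by the allele margins) and falling back to the
classical permutation (allele re-pairing) Monte Carlo test for large
problems. A monomorphic marker returns `p = 1` by convention.

`yates_chi2()` is the continuity-corrected Pearson statistic with the
per-cell clamp `max(|O - E| - 0.5, 0)`; expected counts in these haplotype
tables are often below 5, which is why the corrected statistic (rather than
the raw Pearson chi-square) feeds the genomic-control computation.

## Thresholds and screening

`scan_pairs()` tests every consecutive pair per chromosome in map order and
applies Bonferroni thresholds at level `alpha` (default 0.05): genome-wise
`alpha/T` with `T` the number of testable pairs genome-wide, chromosome-wise
`alpha/T_c`. Markers failing the HWE screen at `hwe_alpha` (default 0.002)
in either tail group are flagged but retained by default — a failing marker
indicates genotyping artefacts, and dropping is config-gated
(`drop_hwe_failures`) because the emulated study reported that all markers
passed. Multi-stage designs (larger tails, densified maps, shortlisted
chromosomes) are just repeated `scan_pairs()` calls on different inputs.

# Population-genetic summaries

## Chi-square prime and Sved's curve

For multiallelic pairs the package uses the standardized multiallelic LD
coefficient `chi2' = sum_ij D_ij^2/(p_i q_j) / min(k-1, l-1)`, which is
bounded in [0, 1] and reduces exactly to `r^2` for biallelic pairs — the
property that makes it a drop-in LD coefficient for Sved's
drift-recombination expectation

$$E[\chi^{2\prime}] = \frac{1}{1 + 4 N_e c} + e,$$

with `c` the pair distance in Morgans and `e` a residual intercept.
`ld_window_pairs()` collects all within-chromosome autosomal pairs inside a
15-cM window (the conventional fitting range), computing EM frequencies on
the full supplied sample; `fit_sved()` minimizes least squares by
Levenberg-Marquardt from a deterministic 5 x 3 grid of starts with `Ne`
constrained positive, reporting the best local optimum. Identifiability
requires at least two distinct distances; all-equal distances are an error.
Monomorphic markers are excluded before pairing — after long drift without
mutation many markers fix, and they carry no LD information.

## Genomic control with mixed degrees of freedom

Because the scan's tables have between 2 and 10 retained haplotypes, test
statistics have heterogeneous df. `genomic_control_lambda()` therefore
computes `lambda_d = median(chi2_d) / qchisq(0.5, d)` within each df class
and averages the `lambda_d` weighted by the number of tests per class. For
even-sized classes the observed median takes the lower of the two central
order statistics by default (`median_convention = "lower"`); the midpoint
convention is a switch. On raw chi-square null draws the overall lambda
converges to 1, as the tests verify.

A caveat the tests make explicit: when lambda is computed from
*Yates-corrected* statistics of sparse r x 2 tables — as this pipeline, like
its source, does — the continuity correction pulls the observed medians well
below the null chi-square medians, and the overall lambda of a null
simulated scan sits far below 1 (around 0.6-0.85 at the default study
scale, where many pairs are df = 1). Lambda values from this pipeline are
therefore conservative: values near or above 1 indicate inflation, but the
absolute calibration against 1 holds only for uncorrected statistics.

## The candidate-locus summary

`genotype_effect()` summarizes phenotype by candidate genotype class
(0/1/2 minor-allele copies), runs classical pooled-variance Student t-tests
between classes (Welch is a switch; the pooled test matches the emulated
analysis), estimates the allele-substitution effect as the OLS slope of
phenotype on allele count, and checks the genotype counts for HWE. Effects
are meant to be estimated on the full unselected cohort: by construction,
estimates from tail-selected samples are biased away from zero (a property
the test suite demonstrates on simulations), so the scan's tails serve
detection only.

# The synthetic-data generator

`simulate_population()` emulates the data structure the analysis assumes:

* **Founders in linkage equilibrium.** Each marker gets 3-8 alleles with
  frequencies drawn from a symmetric Dirichlet (concentration 1); founder
  haplotypes realize those frequencies exactly (largest-remainder rounding
  into the `2 Ne` founder chromosomes) so the drift-martingale property is
  testable without multinomial founder noise.
* **Drift.** `n_generations` of Wright-Fisher reproduction at diploid size
  `ne` (default 30, the effective size the emulated breed reports), with
  recombination between adjacent loci at the Haldane fraction
  `r = (1 - e^{-2d})/2` of their map distance and free recombination across
  chromosomes. No interference, no mutation: allelic diversity comes
  entirely from the founders, and microsatellite mutation is negligible on
  the simulated time scale.
* **A causal locus.** A biallelic variant at a configurable map position is
  carried like a marker (founder minor-allele frequency 0.3 by default) and
  adds `effect` (default -3 phenotype units) per minor-allele copy to a
  Gaussian phenotype (mean 16, residual SD 7 — chosen so the simulated
  phenotype range and median resemble the emulated trait's published
  summary; only the effect size is itself a published value). When the
  effect is nonzero the simulation is redrawn until the cohort minor allele
  frequency reaches `causal_min_maf` (default 0.1): a variant that a study
  maps is necessarily segregating at appreciable frequency, so conditioning
  emulates study ascertainment.
* **A half-sib cohort.** The study cohort (default 639) is bred from the
  final generation with fathers drawn from `n_sires` males (default 25),
  reproducing the paternal half-sib structure that motivates the per-sire
  cap in `select_tails()` (at most 4 per sire per tail by default).
  `select_tails()` picks the extreme tails deterministically, reports the
  realized thresholds, and warns when ties at the boundary force the
  identifier tie-break.

## Choice of the drift depth

The generation count trades off two emulation targets that pull in opposite
directions. LD must approach the drift-recombination quasi-equilibrium that
Sved's curve assumes — the time scale is roughly `1/(2c + 1/(2Ne))`
generations, about 25-30 generations at `c = 0.01` — while marker diversity
decays as `(1 - 1/(2Ne))^t`, so long drift without mutation fixes markers
(at 200 generations and `Ne = 30` only a few percent of heterozygosity
survives; real microsatellite panels stay polymorphic because breed
bottlenecks are recent and mutation replenishes variation). The default is
50 generations: the 1-15 cM window is then near equilibrium while roughly
half the founder diversity survives and nearly all markers remain
polymorphic in a study-size cohort. Analyses that need the long-drift
regime (such as the Ne-recovery experiments, which by construction fit
Sved's equilibrium curve) pass their own `n_generations`.

## What the simulator does not model

X-dosage (the X is simulated autosomally and excluded from autosomal LD
windows by name), mutation, interference, selection and assortative mating,
maternal pedigree structure beyond a shared dam pool, and non-Gaussian
phenotype noise (the emulated trait is right-skewed; the simulator's
Gaussian residual matches its location and scale but not its skew). Passing
tests on these simulations therefore validate the estimators under the
analysis' own assumptions — they do not certify behaviour under genotyping
error, pedigree misassignment or skewed residuals.

# Numerical conventions collected

* EM: convergence on `max |delta f| < 1e-8`, cap 1000 iterations,
  monotonicity asserted; saddle-escape perturbation `1e-6`, deterministic.
* Exact tests: tie tolerance `1e-12` relative on table probabilities;
  enumeration bound `1e6` tables (Fisher: bound on the composition count;
  HWE: on the heterozygote grid); Monte Carlo fallbacks report their SE and
  accept a local seed.
* Phase assignment ties: lexicographically smaller haplotype pair, flagged.
* Sved fit: Levenberg-Marquardt, start grid `Ne in {1, 10, 1e2, 1e3, 1e4} x
  e in {0, 0.05, 0.1}`, `Ne >= 1e-8`, best RSS wins.
* Medians for lambda: lower central order statistic on even counts
  (switchable).
* Degenerate inputs: monomorphic marker -> HWE `p = 1`; monomorphic locus ->
  `chi2'` undefined (skipped with a warning); constant phenotypes ->
  `t = 0, p = 1`; half-missing genotype calls collapse to missing.

## Localization power at reduced marker density

The test suite asserts that on simulated studies with the default effect
the smallest-p pair falls within 10 cM of the causal locus in at least 80%
of replicates. Under this generator that target is not met (about half of
replicates localize at 5 chromosomes x 20 markers), and the shortfall is a
property of the generative model, not of the estimators: founders are drawn
in linkage equilibrium, so marker-causal LD arises only from drift, and at
Ne = 30 the equilibrium `chi2'` against a marker 2.5 cM away is only about
0.25 -- while longer drift erodes marker diversity faster than it builds
LD (a sweep over drift depth peaks near 50 generations). Real studies of
this design escape the bound by densifying the map near candidate regions
(sub-cM spacing), which the scan supports by re-invocation on denser maps.
The corresponding test is expected to fail under the default conditions and
is retained as an honest record of this limit.

# Problem sizes used by the test suite

The simulation-backed tests run at reduced scale chosen to keep the suite
quick while preserving the study's structure: calibration and power use 5
chromosomes x 20 markers (100 cM each) with cohorts of 200 (null
calibration, 200 replicates) and 639 (localization, 50 replicates; tails
42+42 as in the emulated design); Ne recovery uses 5 chromosomes x 500
markers at 200 generations with 84 sampled animals, matching the scale of
the emulated Ne analysis (~5000 LD pairs). The full-genome default
(30 chromosomes, 1154 markers, 639 animals) runs in a few seconds per
study and is exercised by the examples.
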