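# hapscan

Haplotype-pair association scanning for quantitative traits with
multiallelic (microsatellite) marker panels under selective genotyping,
plus the population-genetic summaries that accompany such a scan.

## The problem

In livestock QTL mapping, a quantitative trait — here modeled on the number
of ova and embryos recovered per superovulation of a cow — is localized by
genotyping only the phenotypic extremes of a recorded cohort (the "high"
and "low" tails, capped per sire to limit family confounding) on a
genome-wide microsatellite map. Because microsatellites are multiallelic
and unphased, the association test works on the haplotypes of *consecutive
marker pairs*, estimated by expectation-maximization:

* two-locus haplotype frequencies `f_ij` are the MLE of the multinomial
  likelihood, with double heterozygotes split between their two phase
  resolutions (E-step) and frequencies re-estimated from expected counts
  (M-step);
* haplotypes with pooled frequency below 5% are removed, and the retained
  haplotype × group count table is tested with the two-sided **Fisher
  exact test** for r × 2 tables (total probability of tables no more
  probable than the one observed), with Bonferroni chromosome-wise and
  genome-wise thresholds;
* markers are screened for Hardy–Weinberg equilibrium with a conditional
  exact (or Monte Carlo) test within each tail;
* stratification is summarized by the genomic-control factor
  `lambda = median(chi2_obs) / median(chi2_null)`, computed per degrees-of-
  freedom class from Yates-corrected statistics and averaged with weights
  `n_d` (the scan's tables have 1–9 df);
* effective population size is estimated from LD decay via Sved's curve
  `E[chi2'] = 1/(1 + 4 Ne c) + e`, where `chi2'` is the standardized
  multiallelic LD coefficient (equal to `r^2` for biallelic pairs) and `c`
  the distance in Morgans, fitted by non-linear least squares over all
  autosomal pairs within a 15-cM window;
* the candidate-locus effect is summarized per genotype class with pooled
  Student t-tests and the OLS allele-substitution slope.

Because no individual-level data of the motivating study are public, the
package includes a Wright–Fisher forward simulator (`simulate_population()`)
that generates cohorts with the same structure — drift LD from a small
nucleus (Ne ≈ 30), multiallelic markers on a 30-chromosome map, a biallelic
causal variant of −3 units per minor-allele copy, paternal half-sib
families, and tail selection (`select_tails()`). All tests run against
these synthetic studies and against analytic/enumeration oracles. See the
methods vignette (`vignettes/methods.Rmd`) for models, conventions and
limitations.

## Worked example

```r
library(hapscan)

cfg   <- sim_config(seed = 42)          # 30 chromosomes, 1154 markers, 639 cows
study <- simulate_population(cfg)
sel   <- select_tails(study$phenotypes, study$sires, n_high = 42, n_low = 42)
scan  <- scan_pairs(study$genotypes, study$map, sel$groups, seed = 1)
scan
#> Haplotype-pair association scan: 995 testable pairs (42 high / 42 low)
#>   genome-wise threshold 5.03e-05; 0 genome-wise, 5 chromosome-wise significant
#>   top pair: c7m18-c7m19 (chr 7, 44.7-47.4 cM), p = 8.49e-05, df = 1
```

The top-ranked pair sits 2.6 cM from the simulated causal locus (chr 7,
50 cM). The candidate-locus summary on the full unselected cohort recovers
the simulated effect:

```r
genotype_effect(study$truth$causal_count, study$phenotypes)
#> Candidate-locus effect summary (n = 639)
#>        class allele_count   n   mean   sem
#>  major/major            0 362 16.598 0.370
#>  major/minor            1 235 12.872 0.463
#>  minor/minor            2  42  9.637 1.393
#> additive effect: -3.599 per minor-allele copy (SE 0.461)
```

(the simulated truth is −3 per copy; tail-only estimates are biased away
from zero, which is why effects are estimated on the full cohort), and

```r
genomic_control_lambda(scan$pairs[!scan$pairs$untestable, c("chi2", "df")])
#> Genomic control: overall lambda = 0.5846 (995 tests, 6 df classes)
```

illustrates a property discussed in the vignette: lambda computed from
Yates-corrected statistics of sparse haplotype tables is conservative
(well below 1 under the null), so only values near or above 1 signal
stratification. Effective population size from LD decay:

```r
rec <- ld_window_pairs(study$genotypes, study$map, window_cM = 15)
fit_sved(rec)        # Ne estimate with residual intercept e
```

Scan results serialize with `write_scan()` (`pairs.tsv`, `hwe.tsv`,
`thresholds.txt`); simulated studies with `write_study()` (map, genotype,
phenotype, sire and truth TSVs); PLINK-style `.ped`/`.map` files import via
`read_ped_map()`.

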