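# madcpipe

Mid-density targeted-amplicon genotyping panels (DArTag and similar
platforms) return read counts for a few thousand fixed loci as an MADC
("missing allele discovery count") table: one row per microhaplotype
discovered at each target locus, one column per sample. `madcpipe` is an
R toolkit for the full analysis chain built on such data in breeding
programs of a predominantly diploid crop with tetraploid relatives and
interspecific hybrids — the setting of the cranberry (*Vaccinium
macrocarpon*) 3K panel this package models its workflow on:

* **MADC processing** — parse/write the MADC dialect, reduce
  microhaplotypes to target-SNP Ref/Alt counts, deduplicate target SNPs
  within a 15 bp window (`read_madc()`, `write_madc()`, `dedup_window()`).
* **QC statistics** — read-threshold missingness (`< 10` reads = missing)
  with sample-then-marker filtering, pooled read-ratio MAF, the singleton
  polymorphism threshold 1/(total gametes), PIC (Botstein), pairwise IBS,
  and allele-ratio PCA.
* **Ploidy inference** — per-marker standardization of B-allele
  frequencies against reference samples, then per-sample scoring of the
  heterozygous peak structure (`standardize_baf()`, `call_ploidy()`,
  two-pass `ploidy_pipeline()`). The first-generation colchicine-doubled
  tetraploid failure mode (diploid-like ratios at 0, 1/2, 1) is
  reproduced and documented.
* **Dosage calling** — per-marker beta-binomial mixture with allele bias
  `h`, overdispersion `rho` and sequencing error `eps`, expected alt
  fraction `xi(d) = xi0 / (h (1 - xi0) + xi0)` with
  `xi0 = (d/m)(1-eps) + (1-d/m) eps`, fitted by EM under a population
  ("norm") or biparental Mendelian ("f1") prior (`fit_norm_model()`,
  `fit_f1_model()`), with the standard post-dosage filters
  (`0.05 < h < 2`, `prop_mis < 0.1`, `od < 0.05`).
* **Hybrid sub-genome classification** — parental read totals against a
  10-read threshold classify loci as genome-specific / shared / failed;
  hybrids are genotyped at ploidy 1 (specific) and 4 (shared)
  (`classify_loci()`, `call_hybrid_dosages()`).
* **Two-point linkage** — F1 marker screening (monomorphic, unexpected,
  redundant, high-missing, segregation-distorted under Bonferroni),
  grid-ML recombination fractions with phase enumeration, LOD, RF-based
  filtering, ±5-neighbor repositioning of physically misplaced markers,
  linkage-group clustering, and Haldane two-point map summaries.
* **Panel design** — exact HWE test, candidate filters (quality > 20,
  MAF > 5%, missing < 75%, HWE p > 0.01), and evenly spaced selection
  with QTL/genic priority and mandatory markers (`select_even()`).
* **Simulator** — mixed-ploidy cohorts, colchicine-doubled tetraploids,
  F1 crosses with Haldane crossovers on 12 chromosomes, two-sub-genome
  hybrids with amplification classes, all with ground truth
  (`simulate_cohort()`, `simulate_f1()`, `simulate_hybrid()`).

See `vignettes/madcpipe-methods.Rmd` for the models, parameter choices
and limitations.

## Worked example

```r
library(madcpipe)

cfg <- sim_config(n_loci = 300, seed = 42)       # study-scale defaults
sim <- simulate_cohort(cfg, n_samples = 40, ploidy = 2)
sim$counts
#> count_matrix: 300 loci x 40 samples
#>   total reads: 349161 (Ref) + 371249 (Alt)

ms <- missingness(sim$counts)                    # <10 reads = missing
mean(ms$report$sample_missing)
#> [1] 0.0003

poly <- polymorphic_call(maf_from_reads(sim$counts), sim$counts$samples)
poly$threshold                                   # singleton = 1/(40 x 2) gametes
#> [1] 0.0125

fit <- fit_norm_model(sim$counts, m = 2)         # beta-binomial EM dosages
mean(fit$geno$dosage == sim$truth$dosage, na.rm = TRUE)
#> [1] 1
sum(filter_postdosage(fit$fits)$keep)            # bias/prop_mis/od filters
#> [1] 300

summary(pic_from_genotypes(fit$geno))            # max attainable PIC = 0.375
#> mean 0.307, max 0.375

pp <- ploidy_pipeline(sim$counts)                # two-pass ploidy calls
sum(pp$call == 2, na.rm = TRUE)
#> [1] 40
```

The simulated cohort is deep (mean 60 reads) and clean, hence the
near-zero missingness and exact dosage recovery; the interesting cases —
tetraploids, colchicine generations, contaminated F1s, hybrid
amplification classes — are exercised in the test suite and the
vignette.

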