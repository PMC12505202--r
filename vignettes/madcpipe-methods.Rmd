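---
title: "Methods and design notes for madcpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for madcpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(madcpipe)
```

## Scope

`madcpipe` processes mid-density targeted-amplicon genotyping data of the
kind produced by DArTag-style platforms and distributed as MADC (missing
allele discovery count) files: per-sample read counts for each
microhaplotype discovered at a fixed set of ~3,000 target loci. The
package covers the analysis chain used to design and validate such a
panel in a predominantly diploid crop with tetraploid relatives and
interspecific hybrids: read-count QC, ploidy inference, allele-dosage
calling, hybrid sub-genome classification, two-point linkage utilities,
and even-spacing panel design, plus a simulator that generates all of
these data types with ground truth.

Out of scope by design: multipoint HMM map estimation and phasing (the
two-point utilities here are a documented approximation), liftover
alignment against a second reference genome, and oligo/assay design.

## Data model

Only the target SNP site of each amplicon is analyzed. The `Ref`
microhaplotype matches the reference sequence exactly; `Alt` differs
only at the target SNP. All other (`Other_k`) microhaplotypes carry
off-target variants: they are tallied in the parse report but excluded
from genotype computation, and total depth is defined as Ref + Alt
throughout (this is also the denominator of the missingness rule). A
cell with fewer than 10 total reads is missing; 10 exactly is observed.
Because nearby target SNPs share amplicon sequence, only one target SNP
is retained per 15 bp window, using a greedy left-to-right scan that
keeps the leftmost marker of each conflict chain (inclusive distance,
ties at identical position broken by locus id). The retention rule is
this package's choice; only the window size is inherited from the
platform convention.

## Dosage model

For a marker with ploidy $m$, latent dosage $d \in \{0..m\}$, depth $n$
and alternative-read count $a$:

$$a \sim \mathrm{BetaBinomial}(n,\ \xi(d),\ \rho), \qquad
\xi_0(d) = \frac{d}{m}(1-\varepsilon) + \Big(1-\frac{d}{m}\Big)\varepsilon,
\qquad
\xi(d) = \frac{\xi_0}{h(1-\xi_0) + \xi_0}$$

where $\varepsilon \in [0, 0.5)$ is the sequencing error rate, $h > 0$
the allele bias ($h > 1$ depresses the alternative allele) and
$\rho \in [0,1)$ the overdispersion. $\xi(d)$ is strictly increasing in
$d$ for any valid parameters, and reduces to $d/m$ when $h = 1$,
$\varepsilon = 0$ (both are property-tested).

Two genotype priors are provided, mirroring the two population types the
pipeline meets. The `norm` prior is a normal density over dosages
(mean $\mu$, sd $\sigma$) renormalized on $0..m$, suitable for panels of
unrelated accessions. The `f1` prior is the Mendelian
gamete-combination distribution implied by the two parents' dosages;
parent dosages are estimated first from the parents' own reads under a
neutral emission model and then held fixed (jointly updating them adds
little at typical parental depths and complicates the likelihood
surface; markers where a parent is missing fall back to the `norm`
prior with a warning).

Per marker, $(h, \rho, \varepsilon)$ and, for `norm`, $(\mu, \sigma)$
are estimated by generalized EM over the latent dosages: the E-step
computes dosage posteriors, and each M-step improves the expected
complete-data log-likelihood by short Nelder-Mead runs started at the
current values, which guarantees a non-decreasing marginal
log-likelihood (asserted per iteration in the test suite).
Initialization is $h = 1$, $\varepsilon = 0.005$, $\rho = 0.01$,
$\mu = m \times$ pooled alt ratio, $\sigma = m/4$; convergence at
$|\Delta \log L| < 10^{-6}$ or 200 iterations, with three random
restarts on non-convergence (flagged, retained). Calls are posterior
modes; `prop_mis`, the misclassification proportion used downstream, is
the mean of one minus the maximum posterior — the filter name is
standard, the estimator is this package's choice.

Post-dosage marker filters follow the conventional open intervals:
$0.05 < h < 2$, `prop_mis` $< 0.1$, $\rho < 0.05$; a marker is
*informative* when at least two distinct non-missing dosages occur.

No bit-level parity with any external dosage caller is claimed; the
contract is the model family and its decision surface.

## Ploidy inference

Ploidy shows in the modal structure of a sample's standardized B-allele
frequencies (alt/(ref+alt)): one interior class near 1/2 for diploids,
three near 1/4, 1/2, 3/4 for tetraploids. Raw ratios are first
standardized per marker against reference samples of known dosage: the
reference dosage-cluster means (clusters need at least 3 samples, and at
least 2 clusters per marker) are mapped onto their expected positions
$d/m$ by piecewise-linear interpolation, with constant extrapolation
outside the outer clusters and clamping to [0, 1]. Markers with
non-monotone cluster means are dropped and logged.

Scoring: for each candidate ploidy $m$, the score is the mean distance
of het-band ratios (band (0.1, 0.9)) to the nearest interior peak
$k/m$, plus $\lambda$ (default 0.5) times the fraction of interior
peaks whose *occupancy* falls below `occ_min` (default 0.05). Occupancy
of a peak is defined as the share of het-band ratios within 0.04 of it.
The tight window matters: a candidate with more peaks always wins on
raw distance, so the discriminating signal is whether the extra peaks
are genuinely populated, and the noise tails of a neighboring dosage
class (beta-binomial overdispersion puts roughly a percent of a
diploid's het ratios near the quarter positions) must not count as
population. With the default read depths, a true side class occupies
its peak an order of magnitude above `occ_min` while noise tails stay
well below it. Samples with fewer than 50 het-band markers are
`undetermined`. Candidates default to {2, 4}; triploid/hexaploid
candidates are supported but off by default for this use case.

The two-pass workflow (`ploidy_pipeline()`) standardizes first against
all samples using tentative diploid dosage calls, then re-standardizes
against the confirmed diploids, mirroring how reference sets are
bootstrapped in practice when most of a panel is diploid.

First-generation colchicine-doubled tetraploids are a documented,
deliberate failure mode: every allele is duplicated, ratios occupy only
{0, 1/2, 1}, and the sample scores as diploid despite tetraploid genome
content. The simulator reproduces this (`colchicine_gen = 1`), and
second-generation material (tetrasomic gametes from doubled parents)
recovers the tetraploid call.

## Hybrid sub-genome classification

With parental groups from the two species, a locus is classified by
total parental reads against a threshold of 10: cranberry-specific
(blueberry parents at or below, cranberry parents above),
blueberry-specific (converse), shared (both above), failed (neither).
"Across the group" is read as the *sum* over the group's samples; the
stricter every-sample rule is available via `rule = "each"`. Specific
loci are genotyped in hybrids at ploidy 1 (alt-allele presence) and
shared loci at ploidy 4; the ploidy-1 setting is followed even though
two copies of the amplifying sub-genome are biologically expected, and
the alternative is exposed through `specific_ploidy`. Single-copy
heterozygotes at specific loci are genuinely ambiguous under a
two-class model, which bounds attainable agreement there.

## Two-point linkage utilities

Screening removes, in a fixed, logged order: markers with a missing
parent call; markers monomorphic in the offspring; markers with
non-segregating parent patterns or offspring calls impossible given the
parents (tolerance 5%, so isolated genotyping errors do not trigger
it); redundant markers (identical offspring vectors, first kept);
markers over 10% missing; and markers failing the segregation
chi-square test at Bonferroni-adjusted $p \le 0.05$, the divisor being
the number of markers entering that step.

RF estimation maximizes the exact 3x3 joint-dosage likelihood of each
marker pair on a grid of $r \in [0, 0.5]$ (step 0.005) over all
admissible phase configurations (two per doubly heterozygous parent),
breaking phase ties toward the smaller estimate. Testcross pairs
through different parents carry no two-point linkage information and
are reported NA, as are pairs with fewer than 10 jointly observed
offspring. LOD is $\log_{10} L(\hat r) / L(0.5)$. The grid resolution
(0.0025 worst-case rounding in $\hat r$) is far below sampling error at
the population sizes involved.

`rf_filter` removes markers with fewer than 2 linked partners
($r \le 0.3$, LOD $\ge 3$) or whose linked partners span more than 3
chromosomes; these defaults are this package's own. Repositioning
detaches a marker showing weak linkage (RF > 0.4) with *any* of its ±5
physical neighbors (the literal reading; an all-of rule is available)
and reassigns it when strong links (RF < 0.1) point to exactly one
other chromosome, with no physical position there. Reassignment never
happens without detachment. Linkage groups are connected components of
the graph with edges at $r \le 0.25$ and LOD $\ge 5$.

The two-point map orders a group by physical position (reassigned
markers inserted after their strongest-linked neighbor) and accumulates
Haldane distances $d = -50\ln(1-2r)$ over adjacent pairs. When an
adjacent pair is not estimable, the gap is bridged through the nearest
preceding marker with an estimable RF to the current marker,
subtracting map already accumulated since it (floored at 0); a pair
estimated at independence contributes a capped, flagged 50 cM; a pair
with no bridge at all contributes 0, flagged, since there is no
distance evidence. Two-point maps inflate with marker density and
genotyping error relative to multipoint HMM maps, which is why map
length is validated on simulation with a wide (20%) tolerance and why
published multipoint map lengths are not a comparison surface.

## The simulator

`sim_config()` defaults describe the study conditions the package is
validated under: 12 chromosomes of 41 Mbp / 94 cM (the genome size and
joint-map average of the target crop), 3,059 loci, founder alt-allele
frequencies uniform on (0.1, 0.9), negative-binomial depth with mean 60
and size 8 (the platform's nominal depth is "above 30"; the mean and
overdispersion are this package's realistic choice), lognormal allele
bias with sdlog 0.25, overdispersion 0.01, sequencing error 0.005. F1
gametes recombine by the Haldane model (Poisson crossovers, no
interference), consistent with the two-point mathematics downstream;
contaminants are unrelated founders. Hybrid simulation assigns loci to
amplification classes multinomially and generates reads only from
amplifying sub-genomes; non-amplifying and failed cells receive uniform
0-2 background reads (no published depth distribution exists for failed
loci; this is documented as the package's choice). All randomness
derives from `cfg$seed` with a fixed offset per generator.

What the simulator does *not* emulate — and therefore what passing
tests cannot certify on real data: linkage disequilibrium and pedigree
structure among "unrelated" founders, locus-specific amplification
dropout correlated with divergence from the reference, interference in
recombination, aneuploidy and segmental polyploidy, and batch or plate
effects on depth.

## Problem sizes and numerical choices

The test suite and acceptance checks run at deliberately modest sizes
chosen to keep the full suite in the low minutes on one CPU while
leaving comfortable statistical margins: cohorts of 30-60 samples with
100-500 markers for dosage and ploidy recovery, F1 populations of
100-200 offspring, a 12-chromosome / 480-locus panel for linkage-group
recovery, and 200-replicate loops for distributional properties.
Thresholds asserted in tests (e.g. dosage-call accuracy at or above
0.95 for diploid cohorts, 0.90 for tetraploid cohorts whose
Bayes-optimal rate at these depths is itself a few points below the
diploid one, ploidy recovery at or above 0.98) were fixed from the
model analysis above, not fitted to runs. Beta-binomial densities are
evaluated in log space via `lbeta`; mixture posteriors use the
log-sum-exp guard; the EM records its likelihood trace so monotonicity
is testable; HWE uses the exact conditional test (numerically safe at
small counts, where the chi-square approximation is not).

## Known limitations

Two-point maps are approximations: no multipoint order optimization or
phasing output is attempted. The `f1` model fixes parental genotypes
rather than updating them jointly. PIC for tetraploids applies the
standard biallelic formula with frequencies from dosages/(4n), the same
formula used across ploidies. PCA imputes missing ratio cells with the
marker mean, the simplest choice, which shrinks structure slightly for
high-missingness groups. The panel-validation workflow that reproduces
published full-dataset statistics requires that dataset to be obtained
separately; it is not redistributable here.
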