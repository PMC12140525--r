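---
title: "Homozygosity mapping with rohmap: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygosity mapping with rohmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohmap)
```

## The problem

In populations with elevated parental relatedness, recessive disease alleles
surface as long runs of homozygosity (ROH): stretches where both chromosome
copies descend from a recent common ancestor. Two complementary questions
follow. First, does overall homozygosity burden associate with disease risk
or age at onset? Second, can specific loci be mapped by finding genomic
regions where affected individuals are homozygous and unaffected individuals
are not? `rohmap` implements both, from PLINK-format genotypes through to
prioritized homozygous variant candidates, with a synthetic-cohort generator
that plants known ROH so every stage is testable against ground truth.

## ROH calling

The caller slides a 50-SNP window one SNP at a time along each autosome. A
window is *homozygous* when it contains at most 1 heterozygous call and at
most 5 missing calls — the single-het allowance absorbs genotyping error
inside a true autozygous tract, the missing allowance absorbs array dropout.
Each SNP is scored with the fraction of windows containing it that are
homozygous; a SNP is *marked* when that fraction reaches 5%. Maximal runs of
consecutive marked SNPs become candidate segments, split wherever two
consecutive SNPs lie more than 1 Mb apart, and kept when they satisfy all of:

| parameter | default | meaning |
|---|---|---|
| `window_snps` | 50 | SNPs per sliding window |
| `window_max_het` | 1 | heterozygous calls allowed per homozygous window |
| `window_max_missing` | 5 | missing calls allowed per homozygous window |
| `snp_hit_threshold` | 0.05 | homozygous-window fraction that marks a SNP |
| `min_snps` | 100 | minimum SNPs per segment |
| `min_length_kb` | 1,500 | strict lower bound on segment span |
| `max_gap_kb` | 1,000 | maximum gap between consecutive segment SNPs |
| `max_kb_per_snp` | 50 | maximum average spacing (density bound) |

The >1.5 Mb cut-off targets autozygosity rather than linkage-disequilibrium
structure: shorter homozygous stretches mostly reflect ancient haplotype
sharing and population substructure, while long ones indicate recent
parental co-ancestry and are the informative signal for recessive disease.

Three numerical choices deserve note where the convention is genuinely open.
(1) The per-SNP denominator shrinks at chromosome edges: only fully contained
windows are counted, and chromosomes with fewer SNPs than one window yield no
calls. (2) Segment span runs from the first to the last *marked* SNP
(1-based, inclusive), and `n_snps` counts every array SNP in that span,
missing calls included. (3) With a 50-window denominator, marking requires at
least 3 homozygous windows (ceiling of 5% of 50), so the outermost one or two
SNPs of a clean homozygous run are typically not marked — a 150-SNP planted
run is called as a 148-SNP segment. The package's test suite pins this
behavior against a brute-force oracle that materializes every window and
applies the rules literally.

## Homozygosity metrics and consanguinity

Per individual: S_ROH (summed segment length, kb), N_ROH (count), AV_ROH
(S/N, defined as 0 for individuals with no segments, avoiding an undefined
division while preserving "no burden"), and F_ROH = S_ROH / 2,875,001.522 kb,
the GRCh38.p14 autosomal length. For simulated genomes the denominator is
overridden with the simulated map's span — otherwise F_ROH would be
meaninglessly small. Consanguinity is `f_roh > 0.0156`, strictly: 0.0156 is
the pedigree inbreeding coefficient of second-cousin offspring,
$2 \times (1/2)^{3+3+1} = 0.015625$, rounded to three significant figures.
The threshold value, not its genealogical label, is what the classifier
implements.

Length-stratified analyses subset segments at strict thresholds >2 Mb to
>10 Mb (1 Mb steps) and recompute AV_ROH on each subset, since length bands
time the underlying parental co-ancestry. Burden analyses can exclude known
recessive Parkinson's disease genes (PRKN, DJ-1/PARK7, PINK1) by removing
whole segments overlapping each gene ± 1 Mb; removal rather than truncation
is the conservative choice for burden testing (it can only shrink a metric)
and truncation remains available as `mode = "truncate"`.

## Quality control

Standard pre-association filters, each with its conventional threshold:
sample call rate ≥ 95% (strictly-below removed); heterozygosity-based
inbreeding F = (O − E)/(n − E) with E = Σ(1 − 2pq), flagging |F| > 0.25
(the uncorrected expectation is used rather than the (n−1)/n small-sample
correction — the difference is O(1/n) and irrelevant at the flag threshold);
Hardy-Weinberg exact test (conditional distribution of the heterozygote
count given allele counts) removing SNPs below 1e-10; minor allele frequency
≥ 5%; and greedy LD pruning in 50 kb physical windows advancing 5 SNPs,
removing the lower-MAF member of any pair with r² > 0.5. Relatedness is
estimated with the KING robust between-family estimator
$\phi = (N_{het,het} - 2N_{AA,aa}) / (N_{het(i)} + N_{het(j)})$
over mutually non-missing SNPs, and pairs at φ ≥ 0.0884 (second degree or
closer) are pruned greedily — the sample in the most remaining related pairs
is dropped first, ties dropping controls before cases (a deliberate
power-preserving rule) and then the later sample id. Principal components
come from the standardized, mean-imputed genotype matrix, with each
component's largest-magnitude loading made positive so signs are
reproducible.

The family-segregation branch deliberately *keeps* related individuals: the
pipeline's `families` stage re-runs calling on the call-rate-filtered cohort
after variant-level missingness (≤5%) and Hardy-Weinberg filters, rather
than on the relatedness-pruned dataset used for burden association — pruning
would remove exactly the relatives the analysis needs.

## Association battery

Case-control contrasts are fitted by maximum-likelihood logistic regression
(case = 1), age-at-onset models by ordinary least squares, each reporting the
ROH metric's coefficient, standard error and two-sided Wald p-value — the
Wald presentation matches the β ± SE + p reporting convention of burden
tables. Contrasts: all cases vs controls; early-onset (onset < 45) vs
controls; late-onset (≥ 45) vs controls; early vs late onset (early = 1);
five onset bands (<35, 35–44, 45–54, 55–65, >65) vs controls; each with and
without recessive-gene exclusion; plus linear onset models. Covariates are
age at sampling, sex (0/1, unknown-sex rows dropped with a log message) and
a configurable number of PCs (default 5). Age-at-onset models adjust for sex
and PCs only by default, since onset is the outcome — the age covariate is
switchable for users who prefer it. Missing case onset ages are imputed with
the per-group mean of observed case onsets before stratification. Separation
and singular designs return flagged rows rather than errors so a battery
always completes, and every row carries the family-wise Bonferroni alpha
(0.05 / number of fitted models; the nine-range alpha 0.05/9 applies to the
length-threshold sweep).

## Homozygosity mapping

Overlapping segments are pooled greedily: the longest unassigned segment
seeds a pool (ties to the earlier chromosome and start), every unassigned
segment overlapping the pool's current consensus joins it, and the consensus
is maintained as the *intersection* of member spans — so every member
contains the whole consensus, and a segment that would empty the intersection
is left to seed a later pool. Intersection is the strictest of the plausible
consensus definitions (union and coverage-quorum are the alternatives); it
makes "carrier of the pool" sharp — a carrier is any sample with a segment
overlapping the consensus — at the cost of consensus shrinkage when many
partially-overlapping segments join, which is why pool-size filtering
(> 100 kb and > 100 SNPs, both strict, guarding against sparse-marker false
positives) is applied for the case-exclusive consanguinity and early-onset
workflows but not when testing enrichment power. Carrier proportions are
compared with the pooled two-proportion z-test without continuity correction
(`z² ` equals the uncorrected chi-square statistic; the equivalence is
asserted in tests to 1e-8), Bonferroni-corrected by the number of pools
tested. Pools intersect known gene regions with a ± 1 Mb flank.

Families are inferred from the kinship graph (connected components at
φ ≥ 0.0884) rather than pedigree files, since declared family ids are often
incomplete. A pool segregates in a family when at least two affected members
carry it, every affected pair's allelic match over mutually non-missing
consensus SNPs is ≥ 0.95 (identical genotype codes; 0.95 tolerates residual
genotyping error), and no control carries the consensus.

Variants inside prioritized pools are filtered to maximum credible
ancestry-group allele frequency ≤ 0.01 (inclusive), a consequence among the
protein-truncating, splice-disrupting, missense and in-frame classes, and at
least one homozygous alternate carrier; candidates are ranked by severity
class, then frequency, then position. In-silico scores (CADD, SIFT,
PolyPhen) are carried through but never filtered on.

## The synthetic-data generator

`simulate_cohort()` emulates the statistical structure the analyses assume:
exponential inter-SNP gaps (mean 20 kb, array density), allele-2 frequencies
uniform on 0.05–0.5 (the post-MAF-filter range), genotypes in Hardy-Weinberg
proportions, and *no linkage disequilibrium* — matching the LD-pruned
substrate and keeping the HWE goodness-of-fit oracle exact. Planted
homozygous segments (background Poisson per individual, consanguinity
plantings to a target F_ROH of 0.05, family-identical segments, a
case-enriched risk locus) overwrite genotypes with a single allele drawn at
each locus's frequency; heterozygous-call errors (5e-4 per SNP) are then
injected *inside planted segments only* — hom→het is the error mode that
stresses the window het allowance, which is the mechanism under test — and
missingness (0.002) genome-wide. The default genome is four chromosomes of
60/50/40/30 Mb (180 Mb, ~9,000 SNPs): large enough that planted 2–5 Mb
segments and their pools behave realistically, small enough that the full
test suite runs in minutes. Ages at sampling are Normal(62, 10) clipped to
18–90; a quarter of cases are early-onset by default. Family members are
built by resampling a shared template (each SNP kept with probability 0.5),
which produces kinship well above the 0.0884 threshold without simulating
meiosis.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: linkage disequilibrium and haplotype structure,
allele-frequency spectra below 5%, batch and platform artifacts, ancestry
admixture, X-chromosome homozygosity, and imputation uncertainty. Results on
real cohorts additionally depend on upstream genotyping QC and imputation
choices that are out of scope here.

## Problem sizes and reproducibility

The validation suite uses cohorts of 50–400 individuals on the 180 Mb
default genome: 20 random 300-SNP instances for caller-oracle equivalence,
~200 planted segments for recovery (observed ≈ 98% at default error rates),
1,000 null replicates for enrichment-test calibration, and 50 replicates of
a 200-case/200-control cohort with a 4 Mb risk locus (carrier rates 0.2 vs
0.05) for mapping power — observed 90% power with a 4% family-wise
false-pass rate at pool-level Bonferroni. All randomness flows from explicit
seeds; `simulate_cohort()` is byte-reproducible for a fixed seed, and the
staged pipeline writes md5 manifests so reruns can be verified
hash-identical.

## Known limitations

The intersection consensus can collapse to a short core in regions dense
with partially-overlapping segments, which dilutes carrier-based enrichment
and can drop a true locus below the pool-size filter; the union or quorum
consensus would trade sharpness of the carrier definition for stability.
Greedy relatedness pruning is not guaranteed minimal. The LD pruner is
quadratic per window and intended for array-density data, not sequencing
density. The simulator's family model produces sibling-like genotype sharing
without explicit meiosis, so it should not be used to study recombination
within families.
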