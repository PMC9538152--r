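---
title: "Quantifying genomic porosity in an interspecific fish cross: methods and design"
author: "introscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genomic porosity in an interspecific fish cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(introscan)
})
```

## The problem

When two long-diverged species are crossed in the laboratory, the fate of
their alleles in the hybrid offspring tells us how *porous* the two genomes
are: a locus whose alleles segregate in the F2 generation exactly as Mendel
predicts is freely exchangeable between the genomes, while a locus whose
allele frequencies or genotype proportions are distorted marks an
incompatibility or a selective filter. `introscan` implements the full
analysis chain for this question on biallelic SNP genotypes from a
two-species cross panel: wild parental populations of both species, F1
hybrids, an F1 x F1 intercross (F2) and a backcross to one parental
species.

Genotypes are coded 0/1/2 (copies of the "alternate" allele). After
*polarization*, code 0 is homozygous for the majority allele of the
reference parental species (called `parental_A` throughout; in a cyprinid
cross this would be the *P. toxostoma*-like side and `parental_B` the
*T. souffia*-like side). An F2 cohort bred from obligate-heterozygote F1s
then has expected mean genotype 1 and Hardy–Weinberg genotype proportions
at every truly diagnostic locus, which is what the distortion tests
exploit.

## Data model

The central container is `HybridGenotypes`, a `SummarizedExperiment` with
loci in rows (assay `"GT"`, values 0/1/2/`NA`), individuals in columns
(`colData`: `group`, `role`), and locus annotation in `rowData` (`chrom`,
`pos`, optional `gene`, plus columns added by the scoring steps:
`polarity`, `score`, `class`, `inPanel`, `dropReason`). All stages accept
and return this object, so the pipeline is a chain of ordinary function
calls.

## Stages and their statistics

### Missingness filters

`filterLociByMissingness(x, r = 0.7)` keeps exactly the loci genotyped in
at least `r` of the individuals of *every* group and `r` of all
individuals (the call-rate rule with ">= r" semantics, mirroring how
RAD-seq genotype callers apply their `-r` option per population).
`filterIndividualsByMissingness(x, maxNA = 0.8)` removes individuals
whose missing fraction *strictly* exceeds `maxNA`; an individual at
exactly 80% missing is kept. Both boundary conventions are deliberate and
tested.

### Replicate and contamination QC

Technical replicates (same DNA or tissue genotyped twice) are nearly
identical, so the distribution of pairwise genotype distances is
multimodal with a low mode near zero. The distance used is

$$d_{ij} = \sqrt{\tfrac{L}{n_{ij}} \sum_{\ell \in S_{ij}} (g_{i\ell}-g_{j\ell})^2},$$

the Euclidean distance on genotype codes over the loci non-missing in
both individuals, rescaled by total-loci/shared-loci. The rescaling is a
design choice (the plain pairwise-complete sum would systematically
shrink distances for incomplete pairs); on complete data it reduces to
the ordinary Euclidean distance and satisfies the metric axioms.

`detectReplicateThreshold()` replaces a by-eye cut of the distance
histogram with a reproducible rule: a Gaussian kernel density (Silverman
bandwidth) of the distances, cut at the first local minimum after the
first mode. Two overrides exist — a manual threshold and a "k smallest
distances" rule — because the automatic rule has a known failure mode:
when the dataset contains *no* replicates, the first valley separates
within-population from between-population pairs and everything below it
would be treated as duplicates. On data without declared replicates the
overrides, or a threshold of 0, are the right tool; `resolveReplicates()`
additionally reports below-threshold pairs that carry no replicate label
as contamination candidates rather than silently dropping them, and keeps
the least-missing member of each replicate cluster (ties broken by id).

### Discriminant score and panel

For each polarized locus the score is
$s = \frac12\left(\hat p_A(g{=}0) + \hat p_B(g{=}2)\right)$, the mean of
the species-specific homozygote proportions over non-missing parental
genotypes. It is 1 exactly when the two species are fixed for alternative
homozygotes (a *diagnostic* SNP). A locus enters the working panel when
its score strictly exceeds the threshold (default 0.9) and its
polarization was unambiguous; heterozygotes count against both
proportions (no partial credit), and missing genotypes are excluded from
the denominators so that missingness does not deflate the score.
`chromosomeEnrichment()` tests whether panel membership is homogeneous
across chromosomes with a plain Pearson chi-square on the 2 x K count
table (df = K − 1) and returns standardized residuals per chromosome.

### F1 Mendelian validation

Every true panel locus must be heterozygous in every F1, i.e. sit at the
point (mean 1, sd 0) of the volcano plot. `f1Volcano()` computes
per-locus mean/sd/t/p over non-missing F1 genotypes (one-sample two-sided
t-test of mean = 1, raw alpha 0.05 by default, optional
Benjamini–Hochberg flag) and a decision. Degenerate cases are defined
explicitly rather than left to floating point: sd = 0 with mean = 1 is a
perfect pass (p := 1), sd = 0 with mean != 1 a deterministic failure
(p := 0), and a single genotyped F1 is kept with a warning because the
test is undefined. Loci missing in all F1s are dropped first, so the
reported denominators chain (panel -> tested -> kept).

### Admixture summary

Missing cells are imputed by the group mean at the locus (falling back to
the global locus mean, with a warning, when a group is entirely missing),
*then* the matrix is normalized per locus by $\sqrt{\hat p(1-\hat p)}$
with $\hat p = \mu_j/2$; loci monomorphic after imputation carry no
information and are dropped. PCA is the eigendecomposition of the
individual covariance of this matrix; axis significance follows the
sequential largest-eigenvalue test against the Tracy–Widom (beta = 1)
distribution with a moment-based effective marker count.

Two numerical choices matter here:

* The TW cumulative distribution is evaluated through its shifted-gamma
  approximation (shape 46.446, scale 0.18605, shift 9.84801), which
  reproduces the tabulated 5% point 0.9793 to four decimals and gives
  continuous p-values from `pgamma` instead of table lookups. `ptw()` /
  `qtw()` expose it.
* The effective marker count is estimated from the eigenvalues
  *excluding* the one under test. Including a strongly structured leading
  eigenvalue collapses the moment estimate and with it the power of the
  test; excluding it restores power while leaving the null calibration
  slightly conservative (97–99% of null statistics fall below the 5%
  point in our simulations). When the estimator is invalid — its
  denominator is negative in expectation whenever markers outnumber the
  square of the sample count, as for independent simulated loci — or
  exceeds the actual marker count, the actual count is used; the trace
  normalization of the statistic makes that scale-consistent.

The per-individual `hybridIndex()` (sum of panel genotype values over
twice their count) is the package's model-free admixture summary: 0 =
fully parental_A, 0.5 = F1, 0.25 = expected first backcross to A. A
STRUCTURE-format exporter supports external model-based clustering; that
algorithm itself is out of scope here.

### F2 segregation distortion

Per locus, over the non-missing genotypes of an F2 cohort:

1. **Transmission** (gametic phase): one-sample two-sided t-test of mean
   genotype = 1, with the same sd = 0 conventions as the F1 filter.
   Rejection with mean < 1 is a shift toward parental_A alleles.
2. **Zygotic association**: exact Hardy–Weinberg test. Conditional on the
   allele counts, the heterozygote count follows the Levene distribution;
   the two-sided p-value is the sum of the probabilities of all
   compatible heterozygote counts no more probable than the observed one
   (the standard convention; a mid-p variant sits behind a flag).
   Enumeration is exact for any n; log-factorials keep it stable to
   n = 500 and beyond. Monomorphic tables return p = 1 by convention.
3. **D statistic**: $D = (n_1 - 2n\hat p\hat q)/2$, half the difference
   between observed and expected heterozygote counts. Sign conventions
   for this quantity differ between software packages; here **positive D
   means heterozygote excess**.
4. **Category**: the deterministic eight-way mapping of
   `classifyDistortion()` (neutral; balanced het excess; homozygote
   excess both sides; A- or B-shift in HW equilibrium; A- or B-shift
   with het excess; A-shift with A-homozygote excess). The one
   combination without a class of its own — a B-shift with homozygote
   excess — maps to the nearest class (B-shift in HWE) with an anomaly
   flag, and an A-shift whose homozygote excess is not on the A side is
   likewise flagged.

No multiple-testing correction is applied by default (the tallies follow
the raw-alpha convention); BH-FDR is available behind a flag. Cohorts are
arbitrary individual subsets, so survivor/non-survivor contrasts are two
calls with different id lists.

### Report arithmetic

`formatPercentage()` rounds half-up at 2 decimals (76.99 for 475/617) and
offers a whole-percent variant and a truncation mode, because printed
reports are not always consistent about the last digit (12/18 printed as
66.66 is truncation). The cascade report recomputes every percentage from
its own integer counts, and stage out-counts must equal the next stage's
in-counts — both are tested invariants.

## The simulator

`simulateHybridCross()` generates the full cross design with known truth,
so every stage above is testable without any external data. What it
emulates, and the defaults chosen where a value had to be fixed:

* **Marker classes.** 12% diagnostic loci (fixed inter-species
  differences), 25% partially diverged loci (side-specific major-allele
  frequencies drawn from Uniform(0.8, 1)), the rest shared polymorphism
  at a common frequency — chosen so that roughly a sixth of loci end up
  in the discriminant panel, the order of magnitude a strongly diverged
  species pair yields.
* **Cross structure.** One genitor per side produces the F1 family; F1
  haplotypes are tracked explicitly (one A-derived, one B-derived per
  locus), so transmission bias is modelled mechanistically: an F1 gamete
  carries the A-derived haplotype with probability `g` (0.5 = Mendelian).
  Group sizes default to 20 + 20 parents, 19 F1, 166 F2, 15 backcross.
* **Distorted regions.** Loci inside a configured block share one
  crossover-free gamete per meiosis (complete linkage), the simplest
  mechanism that produces chromosome-level clusters of distorted loci.
  The default places g = 0.7 on all loci of Chr5 and Chr20 (~8% of the
  genome at uniform locus assignment over 25 chromosomes). Viability
  selection (weights per genotype, rejection sampling, so frequencies are
  exactly Mendelian-times-weight) is applied per locus; a viability
  override inside a block therefore breaks the block linkage at the
  selected loci — an accepted simplification.
* **Noise.** Orientation of each locus is randomized (so polarization is
  genuinely exercised); optional uniform genotype miscalls
  (`genotypeErrorRate`); two sequencing-run missingness regimes, 50% and
  10% missing cells i.i.d., with 20% of individuals in the shallow run
  (the proportion such a mixed single-end/paired-end design actually
  produces); 30 technical replicates (exact copies at `errorRate = 0`,
  masked independently); and 2 contaminated samples built as a random
  union of two individuals' gametes. Contaminant sources are drawn from
  the largest group (the chance that two co-housed samples collide
  scales with cohort size, and mixing two members of the dominant
  cohort changes the role composition of the panel least).

Everything is deterministic given `seed`, and the generator returns the
complete truth (locus classes, orientation, per-locus g and viability,
replicate pairs, contaminant ids, run classes).

**What the simulator does not emulate** — and hence what passing tests do
*not* establish about real data: missingness is independent across cells
within an individual, whereas real RAD-seq missingness is locus-structured
(coverage-driven), so the interaction between the call-rate filter and
deep-vs-shallow runs is harsher here than in reality; there is no linkage
disequilibrium outside the distorted blocks and no recombination inside
them; loci are assigned to chromosomes uniformly; genotyping error is
uniform across genotype classes; and parental populations are panmictic
with no internal structure or relatedness.

## Problem sizes used in validation

The shipped test-suite exercises the components at sizes chosen to make
the statistical assertions sharp while staying comfortably reproducible
on a laptop: exhaustive exact-HW equivalence for every genotype table up
to n = 30 plus 1,000 random tables up to n = 500; type-I error of the F2
tests pooled over 20 null crosses of 1,000 diagnostic loci x 166 F2;
block-recovery and viability-recovery runs at 3,000–5,000 loci; replicate
recovery over 10 seeds at 1,000 loci with 20 injected replicate pairs;
and PCA/hybrid-index geometry at 2,000 loci. `scripts/acceptance.R`
re-runs the study-condition pipeline (5,000 loci, full group sizes) plus
a 10-seed null calibration and writes every headline quantity it
computes.

## Known limitations

* Under the default missingness regimes the per-group 70% call-rate rule
  removes a large share of loci (that is what the rule does to i.i.d.
  50%-missing samples); analyses that should not be confounded by the
  filter (e.g. pure distortion power studies) should call the component
  functions directly or relax `lociR`.
* The automatic replicate threshold assumes a replicate mode exists;
  supply `--`style overrides (`replicateThreshold`, `lowestK`) otherwise.
* TW p-values far in the tail rely on the shifted-gamma approximation and
  should be read as "overwhelming" rather than exact; axis tests beyond
  the first few axes inherit the usual sequential-testing caveats.
* The exact HW test is conservative by construction (discrete two-sided
  p), which the type-I simulations reflect.
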