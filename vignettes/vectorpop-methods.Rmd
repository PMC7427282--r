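---
title: "Methods: individual-based population genetics of forest and village mosquito cohorts"
author: "vectorpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual-based population genetics of forest and village mosquito cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vectorpop)
```

## The problem

*Aedes aegypti* in parts of Africa occupies three habitats at a single
locality: forest (sylvatic breeding sites such as rock pools and tree
holes), peridomestic (outdoor containers in villages) and domestic
(indoors). Whether the village-living mosquitoes form a genetically
distinct population from their forest neighbours — incipient
"domestication" — is a question about weak structure at a 3–13 km
spatial scale, with small per-site sample sizes and a severe confounder:
larvae collected from one breeding container are often full siblings,
which inflates apparent genetic structure unless detected and removed.

`vectorpop` implements the full analysis chain for this setting:
genotype QC, kinship-based sibling deduplication, diversity and
differentiation statistics, a sliding-window Fst genome scan, and
comparisons of pairwise kinship across habitat categories with
resampling-based inference. A cohort simulator with known ground truth
makes every stage testable without access to deposited data.

## Genotype model and input formats

Genotypes are diploid calls at positioned loci, stored as unordered
pairs of 0-based allele indices with an explicit missing state
(half-missing calls such as `0/.` are treated as fully missing, the
conservative PLINK convention). Biallelic SNPs arrive as VCF 4.x
(phased and unphased separators equivalent); microsatellite-like
multi-allelic loci arrive as a long-format table of repeat-size
integers, because VCF is awkward for length polymorphisms. Positions
are kept 1-based throughout, matching VCF; all window arithmetic uses
closed intervals `[start, start + size - 1]`. Assembly and coordinate
provenance are deliberately opaque: positions are treated as 1-based
integers per chromosome label.

## The six-stage QC cascade

The filter cascade removes, in this fixed order: (i) loci with more
than 10% missingness; (ii) samples with more than 10% missing loci;
(iii) loci failing an exact Hardy–Weinberg test at p < 1e-5 in *any*
population; (iv) loci whose variance inflation factor (VIF) within a
75 kb moving window exceeds 2; (v) loci with minor allele frequency
below 1%; (vi) samples whose heterozygosity deviates more than 3
standard deviations from the cohort mean. The order matters — it
changes the counts — so it is fixed and echoed in the report. Because
removing samples changes locus statistics, the cascade is repeated
until a round removes nothing (at most 5 rounds).

Numerical and design choices:

* **Exact HWE test.** The standard (non-mid-p) conditional exact test:
  all heterozygote counts compatible with the observed allele counts
  are enumerated and those with probability not exceeding the observed
  configuration's are summed. Ties are compared with a relative
  tolerance of 1e-12. Monomorphic tables return p = 1 with a flag.
* **Populations for stage (iii).** The grouping is not dictated by the
  data model; the default is habitat within locality, exposed as
  `pop_by` (habitat, locality, or site are alternatives).
* **VIF windows.** Windows advance by half a window (37.5 kb) along
  each chromosome. Within a window, pruning is greedy worst-first:
  while any VIF = 1/(1 − R²) exceeds the threshold, the locus with the
  largest VIF is removed; ties keep the locus at the smaller position.
  Perfect collinearity is detected on the correlation matrix and
  treated as infinite VIF. Missing dosages are mean-imputed for the
  regression — pairwise-complete correlation matrices need not be
  positive definite, which would make `VIF = diag(R^{-1})` undefined.
  Because removing a regressor can only lower the remaining R² values,
  a single left-to-right pass leaves every retained locus below the
  threshold in every window (verified post-hoc in the tests).
* **Per-sample heterozygosity.** Pipelines differ on whether stage
  (vi) uses the observed heterozygosity proportion or an inbreeding
  coefficient; both are implemented
  (`sample_het_outliers(method = "observed" | "inbreeding")`), with
  the observed proportion as the default statistic.
* **MAF for multi-allelic loci** is 1 − (majority allele frequency),
  which reduces to the minor allele frequency for SNPs. Stages (iii)
  and (iv) apply to biallelic loci only; multi-allelic loci pass
  through them.

## Loiselle kinship and sibling handling

The pairwise kinship coefficient is the multilocus Loiselle estimator:
for individuals *i*, *j*,

$$k_{ij} = \frac{\sum_l \sum_a \left[(x_{ila}-p_{la})(x_{jla}-p_{la}) +
\frac{p_{la}(1-p_{la})}{n_l-1}\right]}{\sum_l \sum_a p_{la}(1-p_{la})}$$

with $x_{ila} \in \{0, \tfrac12, 1\}$ the dosage fraction of allele *a*
in *i*, $p_{la}$ the allele frequency over **all** genotyped
individuals (reference-population semantics; per-population frequencies
are a documented alternative, not the default), and $n_l$ the number of
genotyped *individuals* at locus *l* — conventions differ between
implementations, so both choices are recorded here. Loci missing in
either pair member are excluded from numerator and denominator for that
pair; monomorphic loci contribute nothing. Negative estimates are
retained: the estimator is centred on zero for unrelated outbred pairs,
and truncation would bias every downstream comparison. Pedigree
expectations are 0.5 (self), 0.25 (full sibs), 0.125 (half sibs).

Sibling groups are the connected components of the graph with an edge
wherever k > 0.1875 — the midpoint of the full-sib and half-sib
expectations. One representative per group is retained: the member with
the least missingness, ties broken by lexicographically smaller id, so
deduplication is deterministic. The cascade is then re-run on the
deduplicated cohort, mirroring the two-pass filtering of the field
workflow.

## Diversity statistics

Expected heterozygosity uses the small-sample unbiased correction
$H_e = \frac{2n}{2n-1}(1-\sum_a p_a^2)$ — group sizes in this design
are small (4–19), so the correction is material. Allelic richness is
rarefied to *g* gene copies with the exact binomial form
$AR_g = \sum_a [1 - \binom{N-N_a}{g}/\binom{N}{g}]$, and private
allelic richness multiplies each allele's presence probability in the
focal group by its absence probability in every other group's rarefied
sample. The default *g* is twice the smallest group's sample count;
loci not rarefiable in every group are skipped with a warning. The
per-group headline value is the mean over loci (the per-locus sum is
also returned for pAR). Binomial terms are evaluated through
`lchoose`, keeping error well below 1e-10 at these sample sizes.

## Differentiation and the genome scan

Fst is the Weir–Cockerham (1984) moment estimator: per-locus variance
components *a* (among groups), *b* (among individuals within groups)
and *c* (within individuals) computed per allele and summed — which
makes the estimator multi-allelic-safe — with
$\theta = a/(a+b+c)$. The multilocus and per-window statistic is the
**ratio of sums** $\sum a / \sum(a+b+c)$, the convention of windowed
Fst tools; the mean of per-locus ratios is emitted alongside, since
the two diverge on heterogeneous loci. Negative estimates are reported,
not clipped: clipping biases genome-scan percentiles. Group
differentiation significance comes from a label-permutation test on
theta with p = (exceedances + 1)/(permutations + 1); this replaces an
exact test of genic differentiation with a self-contained,
assumption-light null, a deliberate design substitution.

The genome scan computes per-locus components once, then aggregates
them in 1 Mb windows advanced by 10 kb. Windows are anchored at
position 1 on each chromosome (the anchor is configurable; no anchor
convention is universal) and only fully contained windows are
generated, so a chromosome of length L yields
$\lfloor (L - \text{window})/\text{step} \rfloor + 1$ windows.
Windows with fewer than 3 informative SNPs are dropped and the dropped
fraction reported. A chromosome shorter than one window becomes a
single flagged window.

## Spatial inference

Pairs are categorised two ways: by location (within forest,
forest–village, within village, between villages — peridomestic and
domestic both count as village) and by habitat (the six unordered
habitat pairs). Where per-individual coordinates exist, a Mantel test
correlates pairwise kinship with geographic distance (great-circle for
lat/lon, Euclidean for planar coordinates); the permutation null
jointly permutes the sample labels of one matrix, and the default
p-value is two-sided on |r| — the direction of the effect is reported
alongside, since a one-sided convention would presuppose the sign. The
distance effect is then removed by OLS of k on distance, and the
residuals are compared across categories. Without coordinates the
residual stage is skipped with an explicit warning and raw kinship is
analysed — the behaviour required when sampling locations were not
recorded.

Kinship pairs sharing an individual are not independent, so the ANOVA
F across categories takes its p-value from resampling at the
**individual** level: habitat/site labels are permuted over
individuals, pair categories recomputed, and F recomputed, 1000 times
by default. The exchangeable unit is the individual; permuting pairs
directly would ignore exactly the dependence this design respects. An
alternative bootstrap mode resamples individuals with replacement and
rebuilds the pairs (iterations that empty a category are redrawn and
counted); permutation is the default because it is exact under the
exchangeability null — the two modes are both exposed since the
"bootstrap" of this field's workflows is usually the permutation
variant. Post-hoc Welch t statistics (equal variances are not assumed)
for each category pair take two-sided p-values from the same resampled
null, Holm-adjusted across category pairs.

## The cohort simulator

The simulator generates the statistical structure the analysis
assumes, with recorded ground truth:

* **Divergence.** Ancestral allele frequencies are uniform on
  [0.05, 0.95]; forest and village deme frequencies are Balding–Nichols
  draws $p_d \sim \mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, so the
  expected between-deme Fst equals the parameter F — a closed-form
  target the estimator tests recover. The weak-divergence regime of
  interest (Fst of order 0.01–0.03) is the default. A coalescent
  backend is out of scope: Balding–Nichols runs in seconds and gives
  an exact recovery target.
* **Sibships.** Families are two parents drawn from the site gene pool
  with offspring by Mendelian segregation, sharing a container id —
  the container-breeding biology that creates the sibling problem.
* **Isolation by distance.** Sites carry an extra Balding–Nichols
  divergence `F_site` around their deme frequency and sit at known
  coordinates, so same-site pairs share ancestry and kinship decays
  with distance. This hierarchical-site kernel reproduces the
  kinship–distance correlation the Mantel and residual stages need; it
  does not emulate continuous dispersal, only the discrete-site
  approximation of it.
* **Implants.** A genomic interval can be re-drawn at divergence
  F + delta, giving the genome scan a recoverable target with known
  coordinates.
* **Defaults** follow the study design the package addresses: one
  forest site plus village sites, sample counts 11/8 (La Lopé-style,
  no coordinates) and 11 with villages of 9/7/8/6 (Rabai-style, 3–7 km
  from the forest patch, coordinates recorded); three chromosomes of
  310/474/409 Mb with 23,000 SNPs by default, matching a
  post-filter density of roughly 16 SNPs per 1 Mb window.

What the simulator does **not** emulate: genotyping error and allele
dropout, linkage disequilibrium beyond what drift induces (loci are
drawn independently), selection, continuous-space dispersal, and
temporal structure. Passing tests therefore demonstrate correctness of
the estimators and inference machinery under the generating model, not
robustness to artefacts real array data may carry — the QC cascade is
tested separately against constructed violations.

The QC fixture generator is deterministic by design: clean loci use
balanced Hardy–Weinberg genotype multisets rotated across samples (so
every clean sample has an identical heterozygosity profile and the
outlier stage has a provably unique target) and sit 80 kb apart (so no
clean pair shares a pruning window); each planted violation is then an
unambiguous, manifest-listed target for exactly one cascade stage.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale, chosen so
each statistical check has clear resolution: estimator recovery at
n = 50 per deme and 2000 loci; kinship calibration at n = 100 and 1000
loci; sibling recovery over 100 cohorts of 30; scan localisation over
100 replicates of a 30 Mb chromosome at 16 SNPs/Mb; type-I calibration
over 300 replicates with 199 permutations each. All stochastic stages
take explicit integer seeds, the pipeline derives per-stage seeds from
one master seed, and a fixed seed reproduces simulator output
byte-for-byte (VCF output is deterministic, with no timestamps).

## Known limitations

* GENEPOP-style exact G tests are intentionally replaced by
  permutation tests; p-values are therefore Monte-Carlo estimates with
  granularity 1/(n_perm + 1).
* The VIF pruning pass is greedy; it matches the common
  community-tool behaviour but is not guaranteed to retain the
  globally maximal locus set (the tests compare it against brute-force
  subset search on small instances).
* Rarefaction skips loci not rarefiable in every group rather than
  re-rarefying per locus to a smaller g.
* The per-window SNP count refers to informative (polymorphic,
  genotyped-in-both-groups) loci, which is what the ratio-of-sums
  estimator actually uses.
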