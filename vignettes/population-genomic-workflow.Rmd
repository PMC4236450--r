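---
title: "Methods: downstream population-genomic analysis of a small whole-genome cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downstream population-genomic analysis of a small whole-genome cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and study design

`wgspopgen` implements the downstream analyses that turn a multi-sample
variant callset from a small, deeply sequenced cohort into population-genetic
statements: population-resolved allele frequencies, classification of rare and
private functional alleles with an enrichment test, a frequency-differentiation
outlier scan over GWAS-annotated SNPs, per-population nucleotide diversity,
population-structure analyses, and deletion-callset algebra with in-silico
validation. Upstream steps — read alignment, SNP/indel calling and
recalibration, read-pair deletion discovery, functional annotation — are out of
scope; their products (a VCF with `GT` fields and a functional-class INFO key,
BED callsets, a flag for external-genotyper success) are the package's inputs.

The design the defaults describe is one focal population of 16 diploid genomes
compared against 14 reference populations of 16 samples each (sub-sampled to
match the focal depth by the ascertainment filter below). Because real cohorts
of this kind are not redistributable, the package carries a first-class
synthetic-data generator whose planted ground truth drives every test.

# The synthetic-data generator

## Genotypes

Genotypes follow the Balding–Nichols model: per SNP an ancestral frequency
$p \sim \mathrm{Beta}(a, b)$, per population $k$ a drifted frequency

$$ q_k \sim \mathrm{Beta}\!\left(p\,\frac{1-F}{F},\; (1-p)\,\frac{1-F}{F}\right), $$

with $\mathrm{E}[q_k] = p$ and $\mathrm{Var}[q_k] = p(1-p)F$, and per diploid
sample a dosage $\sim \mathrm{Binomial}(2, q_k)$. This reproduces the one
feature the analyses actually consume — realistic *across-population allele
frequency differentiation at a controlled $F_{ST}$* — and deliberately omits
haplotype structure: no linkage disequilibrium is simulated, so LD pruning is
exercised on duplicated/correlated columns constructed in the tests rather
than on a recombination map. Defaults: $a = b = 1$ (a flat frequency
spectrum, clamped to $[0.02, 0.98]$ so both Beta shapes stay positive) and
$F = 0.1$, an intercontinental-scale divergence at which 16-sample cohorts
separate cleanly but not trivially.

On this background the generator plants, and records in a truth object:

* **GWAS outliers** — of the GWAS-annotated SNPs, a configurable few have the
  focal and reference frequencies pushed to opposite sides of
  $0.5 \pm (\Delta/2 + 0.2)$, so the realized sample difference clears the
  target $\Delta$ (default 0.5) despite binomial noise in 32 focal
  chromosomes.
* **Focal-only variants** at exact alternate-chromosome counts: 1 (rare
  singleton), 2–3 (low-count private), $>3$ (private), with every reference
  dosage zeroed. Counts are realized as heterozygous carriers, so they are
  exact, not expected, values.
* **A functional excess among rare alleles** — planted focal-only variants
  are non-synonymous with probability 0.6 against a 0.4 background, the
  effect size the enrichment power analysis assumes.

All draws flow from a single seed in documented order; the same seed
reproduces every file byte for byte. Deletion and concordance fixtures use
seed offsets (+2, +1) so each generator entry point is independently
reproducible.

## Deletions and validation truth

Deletion loci live in disjoint 250-kb genomic slots, which makes "distinct
loci never merge" a construction guarantee rather than a probabilistic one.
Each locus has 1–4 focal carriers; per-carrier calls jitter both breakpoints
by at most 2% of the length, so same-locus calls overlap reciprocally by at
least $(1-2j)/(1+2j) \approx 0.92$, comfortably above the 0.8 merging
threshold; locus sizes are drawn so the jittered calls stay strictly inside
the (50 bp, 100 kbp) size bounds. The heterozygous-SNP site list is the
genotype matrix's own het calls with every carrier het removed from the full
jitter envelope of its true loci, and one het SNP planted at the midpoint of
each *false* locus per carrier. Consequently het-SNP validation fails exactly
the planted `false_deletion_frac` of sites — the backbone of the acceptance
checks. A configurable fraction of loci is mirrored, with up-to-10%
breakpoint noise, in a simulated reference catalogue (plus decoy intervals)
for the novelty filter.

## Concordance fixture

The truth table is the generator's own focal genotypes at a random subset of
sites (reference-homozygous rows included — they define the assayed
universe); the callset is the same table with a 0.2% genotype-error rate and
a 0.2% drop-out rate. The measured FDR tracks the error rate; the measured
FNR is higher than the drop-out rate alone because an erroneous genotype at
a truth-variant site counts both as a wrong call and as a missed variant.

# Statistical methods and their parameters

**Allele counts.** Missing genotypes are excluded from both numerator and
denominator, so totals count called chromosomes. The 1/2/3 genotype coding
used by the structure pipeline has no missing state; the pipeline therefore
drops variants with any missingness before coding.

**Nucleotide diversity.** Per site,
$\pi = \frac{n}{n-1} 2\hat p(1-\hat p)$ with $n$ called chromosomes — the
unbiased estimator, identical to the mean difference over all
$\binom{n}{2}$ chromosome pairs (the test suite checks this equivalence
exactly). The genome-wide value divides the site sum by the total ungapped
chromosome length, so monomorphic positions contribute implicitly. Sites
with missing data in the focal population are removed from that
population's sum, and no Hardy–Weinberg filtering is applied. Whether the
$n/(n-1)$ correction is applied is an implementation choice documented
here, not asserted of any external dataset.

**Ascertainment (subset-polymorphism) filter.** A fixed-size random subset
(default 16, matching the focal cohort) is drawn from every population and a
variant is kept only if polymorphic within each subset; undersized
populations contribute all samples. This puts populations of unequal depth
on one footing at the cost of biasing toward common variation — the reason
the diversity stage runs *before* it.

**LD pruning.** PLINK-style `indep-pairwise` with window 50 variants, shift
5, $r^2 > 0.5$; within a window the *later* variant (position order) of an
offending pair is removed, matching common practice. Zero-variance variants
are treated as uncorrelated. A post-hoc property test asserts no surviving
within-window pair exceeds the bound.

**PCA.** Columns centred and scaled to unit variance (zero-variance columns
dropped with a warning), scores via `prcomp`; the explained fraction uses
all eigenvalues in the denominator. An all-constant matrix yields a flagged
degenerate result rather than an error.

**Genetic distance.** The formula behind individual-level trees is a
genuinely open choice; the default is the allele-sharing distance
$d(i,j) = \mathrm{mean}_v |g_{iv} - g_{jv}|/2$ (0 for identical genomes, 1
for opposite homozygotes everywhere), with Euclidean distance on the coded
matrix available behind a flag. Both are labelled implementation choices in
the documentation.

**Geographic distance.** Haversine great-circle distance on a 6371-km
sphere, in kilometres.

**Mantel test.** Pearson correlation of upper off-diagonal triangles;
the null permutes one matrix's labels jointly; the p-value is one-sided
(positive association is the alternative of interest — the question is
whether genetically similar individuals live closer together) with the
add-one correction $(\#\{r^\ast \ge r\}+1)/(B+1)$. Default $B = 9999$ for
interactive use; the workflow default is 999 and the calibration test uses
199, trading resolution for runtime. A two-sided reading is not offered
because no direction-agnostic hypothesis arises in this workflow.

**Neighbor joining.** Standard Saitou–Nei agglomeration via `ape::nj` — the
canonical implementation in R and the one this field uses; a from-scratch
brute-force NJ lives in the test helpers as an independent oracle, and both
are exact on additive matrices. Negative inferred branch lengths (possible
on non-additive input) are clamped to zero with a warning.

**Frequency differentiation.** Group frequencies pool counts
($\sum$ alt / $\sum$ called chromosomes), never average per-population
frequencies, which makes them invariant to relabelling subsets of a
population. The outlier threshold is the linear-interpolation quantile of
the $|\Delta f|$ distribution at the $(100 - 0.1)$-th percentile, with a
*strict* inequality above it — so an all-ties vector yields no outliers.
Whether a published scan of this kind interpolated or took an order
statistic is typically unstated; interpolation is this package's documented
choice.

**Sharing classes.** The five classes (monomorphic, shared, rare, low-count
private, private) partition all focal variants; "rare" requires both a
single focal chromosome and absence from every reference population.
Because figure-style usage sometimes means "singleton among the focal
genomes" without the absence condition, both predicates are exposed
(`rare_strict` vs `singleton`) and every output names its stratum. Focal
counts of 2–3 absent elsewhere get the explicit `low_count_private` class
rather than being silently merged into either neighbour.

**Enrichment test.** Yates-corrected chi-square in closed form,
$\chi^2 = N(|ad-bc| - N/2)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$, correction
floored at zero, p-value from the 1-df survival function; `chisq.test`
serves as an independent cross-check in the tests, never as the
implementation. Variants of functional class `other` are excluded before
tabulation, and zero margins are an error, not a silent zero.

**Deletion algebra.** Reciprocal overlap is
$\min(o/\mathrm{len}(a), o/\mathrm{len}(b))$ on 0-based half-open
intervals; merging applies single-linkage clustering at $\ge 0.8$ (the
published "at least 80%" maps to $\ge$; novelty's "> 50%" maps to a strict
$>$, each following its own wording). Single linkage can chain, so every
cluster is checked against its *seed* — the first member in
`(chrom, start, end, sample)` order — and members under the threshold are
split off and re-clustered; the seed's interval is the site representative,
which makes merging deterministic under input permutation and idempotent.
How a published pipeline chose merged breakpoints is typically unstated;
the seed-representative rule is this package's documented policy.
Heterozygous-SNP validation converts 1-based SNP positions to 0-based and
counts carrier hets in the half-open representative interval. Deleted-allele
frequency divides summed carrier genotypes by $2\times$ the genotyped cohort
size.

**Concordance.** Genotype-level matching: a call is correct only if site and
unphased genotype agree with the gold standard; truth sites not carrying a
variant (genotype 0) define the assayed universe and can convict a spurious
call. Site-level matching (ignoring zygosity) is a defensible alternative
reading of array benchmarking; genotype-level is this package's choice and
is stated, not asserted as anyone else's.

# Coordinates, naming, degenerate inputs

VCF positions are 1-based; all interval work is 0-based half-open, with one
conversion layer at the boundary (`pos - 1`), tested in both directions.
Chromosome names are compared after dialect normalization
(`"1"` ↔ `"chr1"`, `"MT"` ↔ `"chrM"`); disabling normalization turns a
silent dialect mismatch into an explicit error. Degenerate inputs get
explicit states rather than NaN surprises: all-missing allele counts are
flagged `degenerate`, an empty assayed overlap yields undefined (NA) rates,
a constant distance matrix is a Mantel error, an all-constant genotype
matrix is a flagged degenerate PCA.

# What the tests do and do not show

All empirical claims in this package are made on the generator's fixtures;
passing them shows the *operations* are correct and calibrated (oracle
equivalence for $\pi$ and the chi-square; brute-force equality for interval
merging and NJ; binomial-band calibration for the outlier scan; Mantel
type-I error in $[0.02, 0.08]$ at $\alpha = 0.05$ over 500 null replicates
of 199 permutations; exact recovery of planted validation failures). It
does not show that real cohorts satisfy the generator's assumptions —
no LD, no haplotypes, site-independent genotypes, carrier-exact deletion
truth. Problem sizes were chosen as the smallest at which each property is
sharp: 1,000 random counts for the $\pi$ oracle; 50 seeds × 1,000 intervals
for merging; 10,000 draws for scan calibration; 100 generator replicates at
~2,000 variants per stratum for enrichment power; two 16-sample populations
at $F_{ST}$ 0.15 with 5,000 post-pruning SNPs for PCA separation; 500 loci
at 10% planted false calls for validation. The workflow drivers under
`analysis/` use a 15-population, 8,000-SNP, 200-locus study.

# Known limitations

* The generator's geography is uniform noise in a bounding box, independent
  of genotype; the Mantel stage therefore only exercises the null. Planting
  an isolation-by-distance signal would require spatially structured
  frequencies, which the Balding–Nichols model does not provide.
* The `low_count_private` class and both rare predicates cover the
  ambiguity between singleton-based and absence-based definitions, but no
  attempt is made to decide which reading any particular published figure
  used.
* Deletion merging semantics (single linkage + seed check) is one
  defensible reading of "pairwise merged"; complete-linkage or
  consensus-interval policies would differ on chained clusters.
* Treemix-style admixture-graph fitting, model-based clustering and
  functional annotation are intentionally absent.
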