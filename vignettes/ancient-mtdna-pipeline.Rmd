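---
title: "Clone-based ancient mtDNA analysis with paleomito"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone-based ancient mtDNA analysis with paleomito}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleomito)
```

## The problem

Ancient human mtDNA studies based on PCR and bacterial cloning face two
entangled inference problems. First, the endogenous template is scarce
and chemically damaged: post-mortem hydrolytic deamination of cytosine
reads as clone-specific C→T (or, on the complementary strand, G→A)
substitutions — *type 2* miscoding lesions — while the rarer A→G/T→C
class is *type 1*. Second, human-on-human contamination is ubiquitous:
handlers' DNA can enter any reaction, and amplicons from previously
processed samples can carry over within a laboratory batch. The accepted
countermeasures are procedural (typed staff panels, batch tracking) and
statistical: clone every amplicon, sequence 10–15 clones, and accept a
variant only when it reproduces across independent extractions.

`paleomito` implements that chain as composable, seeded, tested
functions: haplotype representation, clone authentication, consensus
calling, lesion-rate estimation, haplogroup classification, and
population-level comparison.

## Haplotypes and the reference segment

All coordinates are 1-based inclusive rCRS positions. A haplotype is a
set of substitutions (or deletions) relative to the reference within an
explicit covered window; the complete analysis window is HVS1 np
16,126–16,369. The motif grammar is `"<position><base>"` tokens plus
`"<position>d"` for deletions; `"CRS"` denotes the empty set; insertion
notation is rejected because the downstream statistics (identity-based
sharing and F~ST~) are not defined for it here.

Two windows of the laboratory design matter throughout:

* amplicon fragments — fragment 1 covers np 16,126–16,258 and fragment 2
  np 16,258–16,369; these are the between-primer reads, so
  primer-annealing sites are structurally outside every scored window;
* the poly-C exclusion np 16,182–16,193 — length variation in the
  homopolymeric cytosine tract is unscorable by cloning, so the interval
  is excluded from variant calling, consensus support and lesion
  normalisation alike. The exclusion lives on the reference-segment
  object so every consumer applies it identically.

The packaged reference segment (`synthetic_hvs1_reference()`, np
16,095–16,400) is a deterministic **synthetic stand-in** for the
published reference: the true rCRS alleles are fixed at every position
used by the fixture, the decision table and the tests, and the poly-C
tract is a cytosine run. Because every statistic in the package is
reference-relative, the filler bases at unused positions are
inconsequential; nothing in the package should be read as the published
genome sequence.

Partial profiles carry their covered window explicitly, and haplotype
deduplication compares variant sets only. This reproduces the field's
counting convention — identical motifs observed at different coverage
collapse — and `distinct_haplotypes(..., complete_only = TRUE)` exposes
the stricter complete-window count, since both readings are in use.

## Clone authentication and consensus

Within one amplicon, the majority state per scored position defines the
provisional consensus; ties resolve to the reference base and are
flagged, a deliberately conservative choice consistent with requiring
replication before accepting a variant. Each clone is then labelled:

* *endogenous* — equal to the majority, or differing from it only by
  lesion-typed (type 1/type 2) substitutions, i.e. damage on the
  endogenous template;
* *staff contaminant* — equal (over the fragment window) to a staff
  motif while differing from the majority;
* *carry-over* — equal to another sample of the same batch while
  differing from the majority; cross-batch matches are not auto-labelled;
* *unclassified* — anything else, e.g. changes outside both lesion
  classes.

Contaminant-labelled clones never contribute to consensus support or to
lesion denominators.

A sample's consensus accepts a variant only when it appears in the
amplicon consensus of at least two amplifications from **independent
extractions**; when a sample has a single extract, independent PCRs are
accepted instead (`independence = "auto"`). Fragments lacking such
replication contribute no coverage, which is how partial-window profiles
arise. Reported profiles therefore satisfy the replication rule by
construction; non-reproducible amplicon variants are returned in the
`dropped` table rather than silently discarded. SNP typings are marked
validated only when the same allele is observed in two extracts.

## Lesion rates

The lesion rate is lesions per clone per nucleotide:

$$\hat\lambda \;=\; \frac{\sum_{\text{amplicons}} \#\text{lesions}}
{\sum_{\text{amplicons}} n_{\text{clones}} \times n_{\text{scored bases}}}$$

with scored bases excluding the poly-C interval (121 sites for fragment
1, 112 for fragment 2; primer sites are outside the windows). The pooled
form is the default because it matches the per-clone-per-nucleotide unit
and weights amplicons by the data they contribute; a per-amplicon mean
(`method = "per_pcr_mean"`) is exposed because the alternative reading
of the normalisation is defensible. A clone set with no deviations from
consensus scores exactly 0.

## Haplogroup classification

Classification is a small, editable decision table — not an embedded
phylogeny. Each rule carries a haplogroup label, required coding-region
SNP alleles over the nine-position panel
{7028, 12308, 14766, 10873, 10550, 12705, 10398, 10400, 4646}, optional
HVS1 motif conditions, and a priority rank. Matching proceeds by:

1. eliminating rules that conflict with a *typed* allele (untyped
   positions are wildcards — ancient typings are routinely incomplete);
2. ranking survivors by the number of positively matched SNP conditions;
3. refining ties by motif conditions, evaluated over the profile's
   covered window: a required variant at a covered position that is
   absent violates the rule, an uncovered position is a wildcard;
4. breaking what remains by priority.

SNP evidence thus outranks motif evidence on conflict. A call is *firm*
only if reclassification using validated typings alone returns the same
label; an assignment resting solely on unreplicated SNPs stays
provisional. On the packaged fixture this yields 14 firm calls of 15,
with the CRS-motif partial profile provisional.

Frequency tabulation pools raw labels through a configurable grouping
scheme (25 categories: the common West Eurasian haplogroups plus pooled
African, Asian, rare-U and rare-R bins); the scheme is a data file, not
code, so alternative groupings are testable. Denominators are firm calls
only, and an unmapped label is an error, never silently dropped.
Bootstrap intervals resample individuals with replacement and report
percentile bounds.

## Population comparison

**Sharing.** A database individual carries a query haplotype when the
variant sets over the comparison window are identical and, by default,
haplogroup labels agree. Complete-window query profiles are used by
default, with a flag to admit partials matched over their covered
window, since either convention is defensible for partially recovered
ancient profiles.

**F~ST~.** The estimator is two-population AMOVA with haplotype-identity
distance (0 for identical variant sets, 1 otherwise): sums of squared
differences among and within populations give variance components
σ²ₐ and σ²_w with the average-corrected sample size n′, and
F~ST~ = σ²ₐ/(σ²ₐ+σ²_w). Negative estimates are reported as computed;
two samples that are entirely identical define F~ST~ = 0. Significance
comes from permuting individuals between the populations with sample
sizes preserved, using the add-one estimator
p = (1 + #{F\*~ST~ ≥ F~ST~})/(1 + n~perm~), ties counted as exceedances
so p is never 0. Families of comparisons against one query population
are corrected together with Benjamini–Hochberg.

Two calibration facts are worth knowing. First, the identity-distance
estimator has an O(1/n) negative bias for samples of identical
composition; the suite checks |F~ST~| stays within that small-sample
envelope rather than asserting an exact zero. Second, the
tie-as-exceedance convention makes the permutation p conservative
whenever permuted statistics collide, which is pronounced for very small
or extremely diverse samples; calibration (size within the binomial 95%
CI at α = 0.05, Kolmogorov–Smirnov uniformity at α = 0.01 over 1,000
seeded null replicates) is therefore verified at a population-scale null
— 12 equifrequent haplotypes, 60 individuals per sample, 199
permutations — where tie mass is negligible. At desk scale the same
machinery simply errs on the conservative side.

**PCA + Ward.** Pooled haplogroup percentages are analysed by centred,
by default unit-variance (correlation-mode) PCA — the scaling that
treats a 2% haplogroup on a par with a 40% one; covariance mode is a
flag. Component signs follow a fixed convention (largest-magnitude
loading positive) so runs are comparable. Clustering is Ward's
minimum-variance criterion on Euclidean distances over the first six
component scores (both counts configurable); the partition is
characterised by its inertia decomposition — between + within = total,
asserted to 1e-9 — and by per-(cluster, variable) test values
$v = (\bar x_c - \bar x) \big/ \sqrt{\tfrac{N-n}{N-1}\,s^2/n}$ with the
overall variance taken with denominator N, plus t-test significance
marks of cluster means against the overall mean.

**Surfaces.** Geographic affinity maps use inverse-distance-weighted
interpolation on haversine distances, a documented and reproducible
substitute for proprietary contour interpolation: exact at data points,
never outside the data range, coincident points averaged with a
warning. Populations without a clear geographic anchor are excluded by
the caller. Power defaults to 2.

## The synthetic-data generator

`simulate_database()` draws, per population, haplogroup frequencies from
a Dirichlet distribution and gives each individual its haplogroup's
founder motif plus a Poisson(μ) number of private variants — a **star
phylogeny**. This is a deliberate simplification: it produces exactly
the structures the analyses consume (haplotype sharing within
haplogroups, frequency differentiation between populations) without a
coalescent simulator, but it has no within-haplogroup tree depth, no
recombination (none exists in mtDNA) and no rate heterogeneity across
sites. Mutations are transition-biased (90% by default, matching
control-region behaviour).

`simulate_clone_experiment()` emulates the laboratory design: per
extraction × PCR × fragment amplicon a uniform 10–15 clones; each
endogenous clone receives Bernoulli(λ) lesions per scored site, type 2
with probability 0.85 by default — deamination dominates observed
ancient damage — with λ defaulting to 0.005 per clone per site, the
middle of the per-sample range such material typically shows;
contaminant clones are copied verbatim from staff or batch-neighbour
motifs at configured fractions (default 10% staff, 5% carry-over).
Damage is independent per site and clone with no fragment-end
enrichment, matching the counting model of the estimator rather than
sequencer-level reality. Contaminant clones are simulated lesion-free.

Every stochastic emission is a pure function of (configuration, seed);
there is no hidden global state, and derived seeds are taken explicitly.
Passing tests on these simulations therefore demonstrate estimator
correctness under the generator's assumptions — independent per-site
damage, verbatim contamination, star-shaped diversity — and not
robustness to, e.g., chimeric amplicons, fragment-end damage gradients
or database misclassification in real data.

## Numerical choices and problem sizes

* Majority ties resolve to the reference base, flagged ambiguous.
* Equality of haplotypes is exact variant-set identity; windows are
  closed intervals; all coordinates 1-based.
* The recovery ratio is reported to one decimal (validated skeletons /
  sampled skeletons × 100).
* Inertia decompositions and the FST oracle comparison are asserted at
  1e-9 and 1e-12 respectively; percentage sums at 1e-9.
* The test suite runs its heavier studies at deliberate sizes: 200
  random instances for the F~ST~ oracle, 1,000 null replicates × 199
  permutations for calibration, 40 simulated skeletons (λ = 0.01, 20%
  contaminant clones) for end-to-end consensus recovery, and B = 10,000
  bootstrap replicates for the quantile comparison — sizes at which the
  checked properties are statistically identifiable while the whole
  suite stays desk-scale.

## Known limitations

* The decision table covers the haplogroups distinguishable by the
  nine-SNP panel plus HVS1 motifs; it is not a general tree-walking
  classifier, and finer subclade assignment is out of scope.
* Heteroplasmy, insertions and likelihood-based damage models
  (per-base qualities) are not represented.
* F~ST~ uses haplotype identity only; molecular-distance variants
  (e.g. nucleotide-difference or model-corrected distances) are out of
  scope, as is AMOVA with more than two groups.
* IDW surfaces are grids, not maps; rendering is left to the caller.
* The bundled reference segment is synthetic (see above); analyses of
  real sequence data should substitute the genuine reference segment via
  `reference_segment()`.
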