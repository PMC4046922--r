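# paleomito

Clone-based ancient mitochondrial DNA analysis: consensus haplotype
calling with damage and contamination accounting, decision-table
haplogroup classification, and multi-population comparison.

## What it is for

PCR-and-cloning studies of ancient human mtDNA read the first
hypervariable segment (HVS1, rCRS positions 16,126–16,369) from bone
extracts of archaeological skeletons. Every amplicon is cloned and 10–15
clones sequenced, because the underlying template is damaged (post-mortem
miscoding lesions, mostly cytosine deamination) and the reactions are
vulnerable to contamination by the handlers' own DNA and by carry-over
between samples of one batch. `paleomito` implements the full
computational chain such a study needs:

* **Haplotype representation** — haplotypes as sets of rCRS-relative
  substitutions ("motifs", e.g. `16224C 16311C`; `CRS` = no differences)
  with an explicit covered window, plus sequence↔motif conversion,
  window trimming and deduplication.
* **Authentication and consensus** (`label_clone_origins()`,
  `per_amplicon_consensus()`, `call_sample_consensus()`) — clones are
  labelled endogenous / staff contaminant / carry-over / unclassified
  against the amplicon majority, a typed staff panel and same-batch
  neighbours; a variant enters a sample's consensus only when attested by
  the amplicon consensus of at least two independent extractions (PCRs
  when only one extract exists).
* **Damage estimation** (`classify_lesions()`, `lesion_rate()`) — clone
  vs consensus substitutions typed as type 1 (A→G/T→C), type 2 (C→T/G→A)
  or other; the lesion rate is lesions per clone per nucleotide,
  `sum(lesions) / sum(n_clones × n_scored_bases)`, with the poly-C tract
  (16,182–16,193) and primer sites excluded.
* **Haplogroup classification** (`classify_profile()`) — an editable
  decision table over nine diagnostic coding-region SNPs
  (7028, 12308, 14766, 10873, 10550, 12705, 10398, 10400, 4646) plus
  HVS1 motif conditions; a call is *firm* only if it survives on
  replicated SNP typings alone.
* **Population comparison** — shared-haplotype counts and carrier
  percentages against a haplotype database; pairwise F<sub>ST</sub> by
  haplotype-identity AMOVA, F<sub>ST</sub> = σ²ₐ/(σ²ₐ+σ²_w), with
  permutation significance (`p = (1 + #{F*ST ≥ FST}) / (1 + n_perm)`)
  and Benjamini–Hochberg correction; correlation-mode PCA of pooled
  haplogroup frequencies with Ward clustering, inertia decomposition and
  cluster test values; inverse-distance-weighted geographic affinity
  surfaces.
* **Synthetic data** (`simulate_database()`,
  `simulate_clone_experiment()`, `simulate_staff_panel()`) — populations
  with Dirichlet haplogroup frequencies and star-phylogeny haplotype
  diversity, clone experiments with planted lesions and contamination,
  all with recorded ground truth for estimator-recovery testing.

The package ships a 15-skeleton Pre-Pottery Neolithic B typing fixture
(HVS1 motifs, covered windows, SNP typings with replication flags) used
throughout the examples and tests.

## Worked example

```r
library(paleomito)

calls <- classify_ppnb_fixture()
sum(calls$firm)
#> [1] 14

haplogroup_frequencies(calls$label, firm = calls$firm, grouping = NULL)
#>   population category n       pct
#> 1        pop        H 2 14.285714
#> 2        pop        K 6 42.857143
#> 3        pop       L3 1  7.142857
#> 4        pop       N* 1  7.142857
#> 5        pop       R0 3 21.428571
#> 6        pop       U* 1  7.142857
```

Fourteen of the fifteen profiles receive a firm haplogroup: the fifteenth
(sample H53, motif `CRS` over a partial window) is typed only by
unreplicated SNPs, so its HV label stays provisional. Among firm calls,
K is the most frequent lineage (6/14 = 42.9%), followed by R0 (21.4%)
and H (14.3%). Bootstrap intervals and an F<sub>ST</sub> comparison
against a simulated database:

```r
bootstrap_ci(calls$label[calls$firm], B = 1000, seed = 42)
#>   category   pct lower upper
#> 1        H 14.29  0.00  35.7
#> 2        K 42.86 14.29  64.3
#> ...

fx  <- ppnb_fixture()
complete <- subset(fx$profiles, window_lo == 16126 & window_hi == 16369)
sim <- simulate_database(simulation_config(n_populations = 3,
                                           n_per_pop = 40, seed = 7))
fst_permutation_test(complete$motif,
                     sim$db$motif[sim$db$population == "pop01"],
                     n_perm = 999, seed = 11)[c("fst", "p_raw")]
#> $fst
#> [1] 0.04974...
#> $p_raw
#> [1] 0.004
```

`run_pipeline(out_dir, seed)` chains all of this end to end and writes
CSV outputs plus a JSON manifest (inputs, parameters, seed) sufficient to
re-run the analysis bit-identically.

## Vignette

`vignettes/ancient-mtdna-pipeline.Rmd` describes the model and its
assumptions, every tunable parameter with its default and rationale,
what the synthetic-data generator does and does not emulate, and the
package's numerical conventions and known limitations.
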