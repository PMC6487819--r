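# skimbiome

Recovering a host-associated skin microbiome from the **by-catch** of host
shotgun sequencing — the reads that do not map to the host genome — and
doing it defensibly when the data were never designed for microbiology: no
extraction or library blanks, library inputs spanning orders of magnitude,
and laboratory or human-associated contaminants mixed into the signal.

`skimbiome` is an R package for researchers mining population-genomics
data sets for microbial signal. It implements the complete analysis chain
as tested, reusable functions, together with a synthetic-data generator
with known ground truth that backs every statistical claim in the test
suite. The motivating design is a skin-microbiome survey of 49 free-ranging
killer whales from five ecotypes, but every component takes plain
taxon-by-sample count tables and metadata.

## What is in the box

**Contamination forensics without negative controls**

* `taxon_frequency_test()` — flags taxa whose *relative* abundance falls
  with total library size, the signature of constant-input reagent
  contamination (Spearman correlation of per-taxon proportion vs. total
  reads, Benjamini–Hochberg FDR).
* `cooccurrence_network()` — standardized-effect-size co-occurrence scores
  for all taxon pairs against a permutation null that preserves each
  taxon's abundance distribution (999 null tables by default), with
  empirical two-sided p-values and BH q-values:
  `score = (r_obs − mean r_null) / sd r_null`.
* `expand_contaminants()` — guilt-by-association removal: the top 10% of
  taxa by absolute *significant* co-occurrence score with a confirmed
  contaminant seed, plus the seed.
* `identity_summary()`, `lane_consistency_cv()` — percent-identity
  profiling against reference genomes and between-lane abundance
  consistency.

**Preprocessing** — `merge_identical_reads()` (exact-duplicate read
collapse), `filter_min_reads()` (≥ 5 aligned reads per sample),
`downsample_counts()` (multivariate-hypergeometric depth subsampling),
`coverage_evenness_flag()` (read stacking / gap detection along a genome).

**Community statistics** — `genome_size_normalize()`, `tss_normalize()`,
`css_normalize()`; Bray–Curtis and binary Jaccard distances
(`community_distance()`); PCoA with negative-eigenvalue reporting
(`pcoa()`); weighted-average taxon loadings and "driving taxa"
(`taxon_loadings()`, `driving_taxa()`); sequential-SS PERMANOVA with
free permutations (`permanova()`, pseudo-F with
`p = (#{F_perm ≥ F_obs}+1)/(n_perm+1)`); dispersion homogeneity
(`dispersion_test()`).

**Networks** — `driving_subnetworks()` builds the co-occurrence
subnetworks around the driving taxa (top-20 significant partners each);
`export_graph()` writes GraphML and edge-list TSV.

**Source attribution** — `fit_source_mixture()` estimates the proportions
of a sink community drawn from each candidate source environment plus an
"Unknown" component, by collapsed Gibbs sampling of per-read source
assignments (Dirichlet-smoothed source distributions, learned Unknown
distribution, symmetric mixing prior; C++ inner loop).

**Diatom-load models** — `quasipoisson_glm()` (log link, Pearson
dispersion, t-tests), `diatom_association_models()` (region, pathogen
abundance/presence, algae-associated-taxon presence, each with
longitude/library-size/human-contamination covariates),
`colour_grade_association()` (one-sided rank trend of diatom load over
ordinal skin-colour grades).

**Synthetic data with ground truth** — `synthetic_scenario()`,
`generate_profiles()`, `generate_source_sink()`,
`generate_duplicated_reads()`; `run_pipeline()` drives everything end to
end from one scenario (or YAML config) and writes all TSV/GraphML outputs.

## Worked example

Generate a study-scale synthetic community (49 samples, five groups,
~300 taxa with planted contaminants), run the forensics, and test the
group effect:

```r
library(skimbiome)

sim <- generate_profiles(synthetic_scenario(), seed = 42)
counts <- filter_min_reads(sim$counts)

ft <- taxon_frequency_test(counts, sim$metadata)
ft
#> Library-size frequency test (spearman, BH alpha = 0.05)
#>   303 taxa tested, 20 flagged as candidate contaminants
#>       taxon  statistic            p            q flagged
#>  reagent_06 -0.9988776 6.477984e-64 1.962829e-61    TRUE
#>  reagent_10 -0.9985714 1.867605e-61 2.829422e-59    TRUE
#>  ...
```

All 20 flagged taxa are the planted reagent contaminants: their share of
each library shrinks as sequencing depth grows. Next, guilt by
association around the dominant human-skin contaminant, then beta
diversity on the cleaned table:

```r
cooc <- cooccurrence_network(counts, n_null = 999, seed = 43)
removal <- expand_contaminants(cooc, "Cutibacterium_acnes")
cleaned <- apply_removal(counts, unique(c(removal, ft$taxon[ft$flagged])))

rel <- tss_normalize(genome_size_normalize(cleaned$counts, sim$genome_sizes))
d   <- community_distance(rel, "bray_curtis")
ord <- pcoa(d)
ord
#> PCoA: 49 samples, 37 positive axes
#>   variation explained: Axis1 40.9%, Axis2 11.9%, Axis3 7.9%, Axis4 5.5%
#>   11 negative eigenvalues (min -0.0522)

md <- sim$metadata
md$log_lib <- log10(colSums(cleaned$counts)[md$sample])
permanova(d, md, c("log_lib", "group"), n_perm = 999, seed = 44)
#> PERMANOVA (sequential SS, 999 permutations)
#>      term df     F     r2     p
#>   log_lib  1 3.790 0.0691 0.006
#>     group  4 2.009 0.1466 0.009
#>  Residual 43    NA 0.7843    NA
#>     Total 48    NA 1.0000    NA
```

After controlling for library size, host group explains ~15% of
community variance (p = 0.009) — the planted group effect. The driving
taxa on the first two axes recover the planted diatom-associated block:

```r
driving_taxa(taxon_loadings(ord, rel))
#> [1] "Tenacibaculum_dicentrarchi" "algae_04"  "algae_06"  "algae_02"
#> [5] "core_187"  "core_155"  "human_13"  "human_04"
```

Source attribution of a sink drawn 60/30/10 from three disjoint sources:

```r
ss <- generate_source_sink(mixing = c(0.6, 0.3, 0.1), seed = 45)
fit_source_mixture(ss$sinks[, 1], ss$sources, seed = 46)
#> Source attribution (posterior mean +/- sd):
#>   source_1              0.558 +/- 0.010
#>   source_2              0.293 +/- 0.003
#>   source_3              0.109 +/- 0.001
#>   Unknown               0.040 +/- 0.010
```

The whole chain, from generation through networks, attribution and the
diatom GLMs, runs from one call: `run_pipeline(synthetic_scenario(),
outdir = "out", seed = 1)` (or pass a YAML scenario file).

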