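# barcodeval

Evaluation of candidate DNA barcode markers for species identification in
multi-marker plant datasets.

DNA barcoding identifies a specimen by comparing a short standardized DNA
region against a reference library of sequences from vouchered, expertly
identified individuals. Before a marker (or marker combination) can be
trusted for that job — for example to recognize protected timber species in
seized wood shipments — it has to be *evaluated* on a reference dataset:
How variable is it? Do intraspecific and interspecific divergences
separate (a "barcoding gap")? How often does the closest reference sequence
identify the right species? Do conspecific individuals form supported
clusters on a tree? `barcodeval` implements that whole evaluation battery
for aligned multi-FASTA inputs with specimen metadata, plus a seeded
coalescent simulator so every stage can be exercised and tested without any
external download.

## What it computes

* **Marker variability** (`diversity_stats()`): alignment length, sites with
  gaps/missing data, and — over gap-free columns only (complete deletion) —
  the number of polymorphic sites *S*, parsimony-informative sites,
  nucleotide diversity
  π = (2 / n(n−1)) Σ_{i<j} d_ij (mean pairwise proportion of differing
  sites), and the number of distinct haplotypes.
* **Distances and the barcoding gap** (`pairwise_matrix()`,
  `gap_summary()`): uncorrected p-distances p = mismatches / comparable
  sites under pairwise deletion (sites with `-`, `N` or `?` in either
  sequence are excluded per pair), partitioned into intra- and
  interspecific sets, with relative-frequency histograms, strict tail
  fractions at a threshold x, and an overlap flag
  (max intra ≥ min inter).
* **Best close match** (`bcm_summary()`): the classic leave-one-out
  identification test. A threshold t is the smallest observed intraspecific
  distance covering ≥95% of all intraspecific distances; each query's
  candidates are all other specimens within t, and the nearest-candidate
  tie set classifies the query as `correct` (all conspecific), `ambiguous`
  (mixed), `incorrect` (none conspecific) or `no_match` (no candidate).
* **Trees and species-specific clusters** (`neighbor_joining()`,
  `bootstrap_support()`, `root_tree()`, `species_specific_clusters()`):
  Saitou–Nei neighbor joining on the p-distance matrix, nonparametric
  bootstrap over alignment columns with bipartition-matched support on the
  full-data topology, outgroup rooting, and the percentage of
  multi-specimen species forming monophyletic clades with support at or
  above a cutoff (default 70%). The cluster scorer accepts any rooted,
  support-annotated newick tree, so externally built ML/MP trees can be
  scored too.
* **Marker combinations** (`concatenate_markers()`): supermatrices under
  combination schemes (e.g. keep specimens with at least 2 of 3 regions;
  fill absent blocks with `?`), with a retained block map.
* **Simulator** (`sim_config()`, `simulate_dataset()`): Yule species tree,
  within-species coalescents (plastid markers share one genealogy, the
  nuclear marker draws its own), Jukes–Cantor substitution, species-level
  spacer indels, and per-(specimen, marker) dropout — all reproducible from
  one seed.
* **Orchestration** (`run_pipeline()`): runs everything per marker and per
  scheme and writes a CSV/newick bundle that is byte-identical under a
  fixed config and seed.

Results are tibbles or small S3 objects with broom-style `tidy()` /
`glance()` methods and ggplot2 `autoplot()` for the gap histograms and
identification bar charts.

## Worked example

```r
library(barcodeval)

cfg <- sim_config(n_species = 8, individuals_per_species = 3, seed = 42)
sim <- simulate_dataset(cfg)

aln <- sim$alignments$ITS
aln
#> <marker_alignment> ITS: 16 sequences x 650 bp, 8 species

m <- pairwise_matrix(aln)
gap_summary(m)
#> <gap_summary> 10 intra / 110 inter pairs; at x = 0.05: 90.9% inter > x,
#>  100.0% intra < x; gap absent (overlap)

glance(bcm_summary(m))
#>   marker n_queries n_singleton_queries threshold ... pct_correct pct_no_match
#> 1 ITS           16                   2    0.0466 ...        87.5         12.5

tr <- bootstrap_support(aln, n_reps = 100, seed = 42)
og <- intersect(sim$metadata$specimen_id[sim$metadata$family == "Family_01"],
                aln$ids)[1]
species_specific_clusters(root_tree(tr, og), sim$metadata)
#> <cluster_report> 4/6 multi-specimen species supported at >= 70% (66.7%)

diversity_stats(aln)
#> 16 sequences, 650 bp aligned, 360 gap sites, 149 polymorphic sites,
#> 102 parsimony-informative, pi = 0.161, 14 haplotypes
```

Reading them: of 16 simulated ITS sequences (two specimens were lost to the
configured dropout), 90.9% of interspecific distances exceed 0.05 while
every intraspecific distance sits below it; the best-close-match test
identifies 87.5% of queries correctly (the two singleton-species queries
can never be "correct" and here fall outside the 0.0466 threshold, giving
`no_match`); and 4 of the 6 species with ≥2 surviving specimens form
monophyletic clusters with ≥70% bootstrap support.

For real data, read each aligned marker with
`read_alignment("ITS.fasta", metadata)` (metadata CSV:
`specimen_id,species,genus,family`) and run the same calls, or configure
`run_pipeline()` to produce the full CSV bundle for all markers and
combination schemes at once.

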