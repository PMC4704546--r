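---
title: "Evaluating DNA barcode markers: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating DNA barcode markers: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeval)
```

`barcodeval` evaluates candidate DNA barcode markers — typically a panel
such as *rbcL*, *matK*, *trnH-psbA* and nrITS in plants — on a reference
collection of aligned sequences from vouchered specimens. This vignette
explains the statistics it computes, the assumptions behind them, the
tunable parameters, the simulator used for testing, and the places where
the design was genuinely open and a choice had to be made.

## Distance model

All distance-based analyses use the **uncorrected p-distance**: the
proportion of differing sites among the sites comparable between two
aligned sequences. No substitution-model correction is applied — barcode
evaluation conventionally works on raw divergences, and at the shallow
depths involved corrections change little.

Missing data are handled in two deliberately different ways:

* **Pairwise deletion** for distances: a site is dropped for a pair when
  either sequence carries `-`, `N` or `?` there. Spacer alignments are
  gap-rich, and complete deletion would discard most of their signal; each
  pair keeps every site at which both sequences are informative. Pairs with
  *zero* comparable sites have an undefined distance: they are excluded
  from every summary and counted in a diagnostics field rather than being
  silently imputed, because an undefined distance carries no evidence of
  either proximity or divergence. All three symbols are treated alike:
  ambiguity cannot evidence a mismatch, so `N` and `?` behave exactly like
  a gap.
* **Complete deletion** for the variability statistics (polymorphic sites,
  parsimony-informative sites, nucleotide diversity, haplotypes): any
  column containing a gap/missing symbol in any row is excluded for all
  rows. This matches the convention of the population-genetics software
  these statistics come from and keeps them comparable across rows: every
  sequence is summarized over the same set of columns.

Nucleotide diversity is the mean over unordered sequence pairs of the
per-site difference proportion over usable columns; it therefore equals the
mean off-diagonal of a p-distance matrix restricted to usable columns, and
the test suite verifies this identity. Haplotypes collapse sequences that
are identical over usable columns, numbered by first occurrence; ambiguity
codes beyond `N` are rejected at read time so the collapsing is
deterministic. Because published marker tables report a single "length"
column whose printed values are often non-integer (and so cannot be a
median of integer sequence lengths), `length_stats()` reports both the mean
and the median of the unaligned lengths.

## The barcoding gap

`gap_summary()` bins intra- and interspecific distances into
relative-frequency histograms on a common grid (default bin width 0.01,
which resolves the 0–0.2 range typical of plant spacers), and reports the
fraction of interspecific distances **strictly greater** than a threshold
x and of intraspecific distances **strictly lower** than x (default
x = 0.05). The strict inequalities follow the usual phrasing of these
summaries ("greater than", "lower than"); values exactly at x count toward
neither tail. A clean barcoding gap is flagged when
max(intra) < min(inter).

## Best close match

The identification test is leave-one-out: each specimen in turn is a query
against all remaining specimens.

1. **Threshold.** The threshold is the smallest *observed* intraspecific
   distance t such that at least 95% (configurable) of all intraspecific
   distances are ≤ t — an empirical-quantile convention on observed values,
   computed separately for each matrix (marker or combination), since each
   matrix has its own intraspecific distribution.
2. **Classification.** Candidates are the other specimens at a defined
   distance ≤ t. No candidate → `no_match`. Otherwise the tie set contains
   the candidates within `tie_tol` of the minimum candidate distance:
   all conspecific → `correct`; mixed → `ambiguous`; none conspecific →
   `incorrect`.

Two open points were resolved as follows. First, the historical
description of this test names a fourth category for queries whose nearest
sequences lie outside the threshold; the only reading consistent with the
threshold logic is "no candidate within the limit", implemented here as
`no_match`. Second, queries from singleton species (no conspecific exists
anywhere in the matrix) are classified by the same rules — they can never
be `correct`, only `incorrect` or `no_match` — and are counted in
`n_singleton_queries`; category percentages are reported both over all
queries and excluding singletons, so either denominator convention can be
read off directly. `tie_tol` defaults to 0 (exact ties only), which keeps
the rule deterministic; a positive tolerance is available because the
original implementations compare distances at limited precision.

## Trees and species-specific clusters

`neighbor_joining()` implements the Saitou–Nei agglomeration with the
standard Q-criterion. Two numerical conventions make it deterministic and
robust:

* **Tie-breaking**: when several pairs minimize Q exactly, the pair whose
  cluster representatives (the smallest original leaf label in each
  cluster) are lexicographically smallest is joined. Exact Q ties occur
  readily in barcode matrices full of identical sequences.
* **Negative branch lengths** are clamped to zero, with the deficit
  transferred to the sibling edge so that the path length between the two
  joined clusters is preserved; downstream newick consumers reject
  negative lengths.

`bootstrap_support()` resamples alignment columns with replacement,
rebuilds the NJ tree per replicate, and annotates each internal edge of the
**full-data topology** with the percentage of replicates containing the
same bipartition. Support is mapped onto the full-data tree rather than a
majority-rule consensus because evaluation reports conventionally present
one topology with support under its branches. Replicates in which some pair
loses all comparable sites are dropped and counted. The resampling is
seeded, so a fixed seed reproduces the supports exactly.

`species_specific_clusters()` works on a *rooted* tree — monophyly is not
well defined on an unrooted one — and requires an explicit outgroup for
`root_tree()` (which errors if the outgroup is not a bipartition of the
tree). For each species with at least two specimens it asks whether some
clade contains exactly that species' specimens and whether that clade's
support meets the cutoff (default 70%). The headline percentage divides by
the number of multi-specimen species, since a singleton cannot form a
cluster; the all-species denominator is also reported because both
conventions appear in the literature. The scorer reads any
support-annotated newick, so trees from external ML or MP searches (which
this package deliberately does not implement) can be scored with the same
criterion.

## Marker combinations

`concatenate_markers()` builds supermatrices under a
`combination_scheme()`: the marker list, the minimum number of those
markers a specimen must possess, and the fill character for absent blocks.
Filtering is at the **specimen** level: published combination rules are
phrased per species ("species with sequences from at least two regions"),
but distances and trees operate on specimens, and a specimen-level rule is
the only interpretation that yields a well-formed supermatrix; species
counts can then be derived from the surviving specimens. The fill character
defaults to `?`, which every downstream comparison treats as missing — so
gap-filling is neutral with respect to pairwise-deletion distances, and
dropped-versus-filled behaviour is fully controlled by
`min_markers_required`. A block map (marker → column range) is attached to
the result.

## The simulator

The generator exists so that every analysis stage is testable against known
truth, with defaults chosen once to mirror a realistic multi-marker woody
plant survey: 30 species × 4 individuals (≈120 specimens), and a
four-marker panel whose lengths (570–800 bp), relative substitution rates
(conserved coding genes; fast spacers), spacer indel rates and
per-marker dropout (5–35%) echo the completeness and variability ordering
reported in published surveys of this kind.

Its structure:

* **Species tree**: pure-birth (Yule), rescaled so the *mean pairwise*
  distance between species tips equals `2 * interspecific_depth`
  substitutions/site. With this convention the closed-form expected
  interspecific p-distance of a unit-rate marker is
  `expected_p_distance(2 * interspecific_depth)` (Jukes–Cantor:
  0.75(1 − e^(−4d/3))), which makes calibration exact on average. Scaling
  the root-to-tip depth instead would bias the mean pairwise divergence
  below the calibration target, because most species pairs coalesce below
  the root. Note the expectation is slightly concave in the path length
  (Jensen), so the recovered mean sits a fraction of a percent below the
  target for strongly dispersed trees.
* **Within-species genealogies**: each species tip carries a standard
  neutral coalescent over its individuals, scaled so the expected pairwise
  path equals `intraspecific_theta`, and grafted so individual tips sit
  exactly at the species-tip depth (the terminal branch is shortened by the
  subtree height, clamped at zero). Interspecific paths therefore equal
  the species-tree paths exactly. All plastid markers share one genealogy
  draw per dataset — uniparental inheritance links them — while the
  nuclear marker draws an independent one; this mirrors the biology that
  motivates combining plastid and nuclear markers.
* **Zero-divergence limit**: `interspecific_depth = 0` means a single
  panmictic population, so the genealogy is one coalescent over *all*
  individuals and species labels carry no phylogenetic structure. (Grafting
  per-species coalescents onto a zero-length star would still cluster
  conspecifics, which is not what "no divergence" means.)
* **Sequences** evolve by Jukes–Cantor along the genealogy (via
  `phangorn::simSeq()`), each marker's branch lengths multiplied by its
  `rate_scale`. Richer substitution models would buy nothing here: the
  analyses use uncorrected distances.
* **Indels** are simulated as species-level deletions (geometric lengths,
  mean `indel_length_mean`) for markers with `indel_rate > 0`. Only
  deletions are modelled and the true alignment is retained, because the
  package never aligns — indels exist purely to exercise the gap-handling
  paths (pairwise vs complete deletion).
* **Dropout** removes whole (specimen, marker) sequences with probability
  `missing_rate`, emulating amplification/sequencing failure.

One master seed fans out to per-stage sub-seeds (species tree, per-genome
coalescents, per-marker mutation/indel/dropout), so a fixed seed gives
byte-identical datasets while stages remain independently reproducible.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: alignment error (inputs are true alignments),
hybridization/introgression, ITS paralogy and intra-individual ambiguity,
rate variation across sites and lineages, and non-neutral or structured
populations. Real spacer alignments across distant families are far harder
than anything generated here; results on simulated data bound what the
*statistics* do, not what field data will look like.

## Pipeline and reproducibility

`run_pipeline()` analyses every marker and every combination scheme,
writing per-unit CSVs (diversity, distance matrix, gap summary and
histogram, per-query and summary identification tables, haplotype
assignments, cluster reports) plus a bootstrap-annotated newick per unit.
Trees are rooted on the first configured outgroup specimen present in each
alignment — a deterministic single-leaf rooting that cannot fail on
non-monophyletic outgroups; a family name can be given instead of explicit
ids. Schemes that retain no specimen are skipped with a logged warning.
With a fixed config and seed the data files are byte-identical across
runs; the run log also records per-stage timings, which are naturally not
covered by that guarantee.

Problem sizes used in the shipped tests and acceptance script — chosen as
comfortable desk-scale versions of the analyses: oracle equivalence on 200
random small alignments and 100 random additive matrices of 4–6 taxa
(against exhaustive topology enumeration with least-squares fits);
calibration recovery over 20 simulated datasets of 10 species × 4
individuals × 500 bp; and a full study-scale pipeline determinism run of
30 species × 4 individuals × 4 markers with 100 bootstrap replicates. For
real analyses, 1000 bootstrap replicates (the `run_pipeline()` default) is
conventional.

## Known limitations

* NJ is O(n³) in pure R; matrices beyond a few hundred specimens will be
  slow with large bootstrap counts.
* Undefined distances (zero comparable sites) abort tree building rather
  than being imputed; the error message says which choice to make.
* ML/MP tree inference, model-corrected distances, alignment and
  chromatogram handling are out of scope by design; external trees can be
  scored, pre-aligned matrices are expected as input.
* The best-close-match `ambiguous` category depends on exact distance ties
  when `tie_tol = 0`; with long alignments ties are rare and most
  borderline cases fall to `correct`/`incorrect` instead.
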