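# Marker variability statistics: site classes under complete deletion,
# polymorphic and parsimony-informative sites, nucleotide diversity,
# haplotype collapsing, and sequence-length summaries.

#' Classify alignment columns into gap and usable sites
#'
#' A column is a gap site when any row carries `-`, `N` or `?`; the usable
#' sites are the complement (complete deletion). All diversity statistics in
#' this module are computed over usable sites only.
#'
#' @param aln A [marker_alignment()] with at least two rows.
#' @return List with integer column-index vectors `gap_sites` and
#'   `usable_sites`.
#' @export
site_classes <- function(aln) {
  if (n_seq(aln) < 2) abort_bv("need at least 2 sequences.", "input")
  M <- as.matrix(aln)
  has_gap <- colSums(matrix(M %in% MISSING_CHARS, nrow = nrow(M))) > 0
  list(gap_sites = which(has_gap), usable_sites = which(!has_gap))
}

usable_matrix <- function(aln) {
  as.matrix(aln)[, site_classes(aln)$usable_sites, drop = FALSE]
}

#' Polymorphic and parsimony-informative site counts
#'
#' Over usable sites only (complete deletion): a site is polymorphic when at
#' least two distinct bases are present; parsimony-informative when at least
#' two distinct bases are each present in at least two rows.
#'
#' @param aln A [marker_alignment()].
#' @return List with `n_polymorphic` and `n_pic` (integers).
#' @export
polymorphic_pic <- function(aln) {
  Mu <- usable_matrix(aln)
  if (ncol(Mu) == 0) return(list(n_polymorphic = 0L, n_pic = 0L))
  counts <- vapply(BASES, function(b) colSums(Mu == b),
                   numeric(ncol(Mu)))
  counts <- matrix(counts, ncol = 4)
  n_poly <- sum(rowSums(counts > 0) >= 2)
  n_pic <- sum(rowSums(counts >= 2) >= 2)
  list(n_polymorphic = as.integer(n_poly), n_pic = as.integer(n_pic))
}

#' Nucleotide diversity (pi)
#'
#' Average over all unordered row pairs of the proportion of differing
#' usable sites (complete deletion), as in the classic per-site diversity
#' statistic.
#'
#' @param aln A [marker_alignment()] with at least two rows and at least one
#'   usable site.
#' @return Numeric pi in `[0, 1]`.
#' @export
nucleotide_diversity <- function(aln) {
  Mu <- usable_matrix(aln)
  if (ncol(Mu) == 0) {
    abort_bv("no usable (gap-free) sites; pi is undefined.", "input")
  }
  cc <- dist_counts(Mu)
  mm <- cc$mismatches[upper.tri(cc$mismatches)]
  mean(mm) / ncol(Mu)
}

#' Collapse sequences into haplotypes
#'
#' Rows identical over usable sites (complete deletion) share a haplotype;
#' haplotypes are numbered by first occurrence in row order.
#'
#' @param aln A [marker_alignment()].
#' @return List with `n_haplotypes` and `assignment`, a tibble with columns
#'   `specimen_id`, `species`, `haplotype`.
#' @export
haplotypes <- function(aln) {
  if (n_seq(aln) < 1) abort_bv("empty alignment.", "input")
  if (n_seq(aln) == 1) {
    keys <- ""
  } else {
    Mu <- usable_matrix(aln)
    keys <- apply(Mu, 1, paste, collapse = "")
  }
  hap <- match(keys, unique(keys))
  list(n_haplotypes = length(unique(hap)),
       assignment = tibble::tibble(specimen_id = aln$ids,
                                   species = aln$species,
                                   haplotype = hap))
}

#' Haplotype sharing across species
#'
#' Groups the [haplotypes()] assignment per haplotype and reports which
#' species each haplotype occurs in; haplotypes spanning more than one
#' species flag taxa a marker cannot separate.
#'
#' @param aln A [marker_alignment()].
#' @return Tibble with columns `haplotype`, `n_specimens`, `n_species`,
#'   `species` (semicolon-joined sorted labels), `shared`.
#' @export
haplotype_sharing <- function(aln) {
  asg <- haplotypes(aln)$assignment
  asg |>
    dplyr::group_by(.data$haplotype) |>
    dplyr::summarise(
      n_specimens = dplyr::n(),
      n_species = dplyr::n_distinct(.data$species),
      species = paste(sort(unique(.data$species)), collapse = ";"),
      .groups = "drop") |>
    dplyr::mutate(shared = .data$n_species > 1)
}

#' Sequence-length summary
#'
#' Mean and median of unaligned sequence lengths. Both are reported because
#' published per-marker length columns are sometimes mean-like despite a
#' "median" heading.
#'
#' @param x Character vector of unaligned sequences, or a
#'   [marker_alignment()] whose rows are degapped (`-` and `?` removed)
#'   before measuring.
#' @return Tibble with `n`, `mean_length`, `median_length`.
#' @export
length_stats <- function(x) {
  if (inherits(x, "marker_alignment")) x <- gsub("[-?]", "", x$seqs)
  if (length(x) < 1) abort_bv("no sequences.", "input")
  lens <- nchar(x)
  tibble::tibble(n = length(lens), mean_length = mean(lens),
                 median_length = stats::median(lens))
}

#' Per-marker variability statistics
#'
#' One row of the standard marker-comparison table: sample size, sequence
#' lengths, alignment length, gap/usable site counts, polymorphic and
#' parsimony-informative sites, nucleotide diversity and haplotype count.
#'
#' @param aln A [marker_alignment()].
#' @param raw Optional character vector of unaligned (raw) sequences for the
#'   length summary; when `NULL` the aligned rows are degapped instead.
#' @return A one-row tibble.
#' @export
diversity_stats <- function(aln, raw = NULL) {
  sc <- site_classes(aln)
  pp <- polymorphic_pic(aln)
  pi_val <- if (length(sc$usable_sites) == 0) NA_real_ else nucleotide_diversity(aln)
  ls <- length_stats(if (is.null(raw)) aln else raw)
  tibble::tibble(
    marker = aln$marker,
    n_sequences = n_seq(aln),
    n_species = length(unique(aln$species)),
    mean_length = ls$mean_length,
    median_length = ls$median_length,
    alignment_length = aln$length,
    n_gap_sites = length(sc$gap_sites),
    n_usable_sites = length(sc$usable_sites),
    n_polymorphic = pp$n_polymorphic,
    n_pic = pp$n_pic,
    pi = pi_val,
    n_haplotypes = haplotypes(aln)$n_haplotypes)
}
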