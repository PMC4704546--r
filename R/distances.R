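# Uncorrected p-distances with pairwise deletion, intra/interspecific
# partitioning, and barcoding-gap summaries.

#' Uncorrected p-distance between two aligned sequences
#'
#' Sites where either sequence carries `-`, `N` or `?` are excluded
#' (pairwise deletion); the distance is the proportion of mismatches among
#' the remaining comparable sites. With zero comparable sites the distance
#' is undefined (`NA`).
#'
#' @param a,b Aligned sequences of equal length (strings or character
#'   vectors of single residues).
#' @return List with elements `distance` (proportion in `[0,1]` or `NA`)
#'   and `comparable_sites` (integer).
#' @export
p_distance <- function(a, b) {
  ca <- if (length(a) == 1) strsplit(toupper(a), "", fixed = TRUE)[[1]] else toupper(a)
  cb <- if (length(b) == 1) strsplit(toupper(b), "", fixed = TRUE)[[1]] else toupper(b)
  if (length(ca) != length(cb)) {
    abort_bv("sequences must have equal aligned length.", "alignment")
  }
  valid <- ca %in% BASES & cb %in% BASES
  n <- sum(valid)
  d <- if (n == 0) NA_real_ else sum(ca[valid] != cb[valid]) / n
  list(distance = d, comparable_sites = as.integer(n))
}

# mismatch/comparable-site counts for a character matrix, via base-indicator
# cross-products (exact integer counts, BLAS-fast for bootstrap use)
dist_counts <- function(M) {
  V <- matrix(as.numeric(M %in% BASES), nrow = nrow(M))
  comp <- tcrossprod(V)
  same <- matrix(0, nrow(M), nrow(M))
  for (b in BASES) {
    Ib <- matrix(as.numeric(M == b), nrow = nrow(M))
    same <- same + tcrossprod(Ib)
  }
  list(comparable = comp, mismatches = comp - same)
}

#' Pairwise p-distance matrix for an alignment
#'
#' Computes [p_distance()] for every unordered specimen pair under pairwise
#' deletion. Entries with zero comparable sites are `NA`.
#'
#' @param aln A [marker_alignment()] with at least two rows.
#' @return An object of class `p_dist_matrix`: fields `labels`, `species`,
#'   `d` (symmetric matrix, diagonal 0 where defined) and
#'   `comparable_sites` (integer matrix).
#' @export
pairwise_matrix <- function(aln) {
  if (n_seq(aln) < 2) abort_bv("need at least 2 sequences.", "input")
  M <- as.matrix(aln)
  cc <- dist_counts(M)
  d <- cc$mismatches / cc$comparable
  d[cc$comparable == 0] <- NA_real_
  dimnames(d) <- list(aln$ids, aln$ids)
  dimnames(cc$comparable) <- dimnames(d)
  structure(
    list(marker = aln$marker, labels = aln$ids,
         species = stats::setNames(aln$species, aln$ids),
         d = d,
         comparable_sites = matrix(as.integer(cc$comparable),
                                   nrow = nrow(d), dimnames = dimnames(d))),
    class = "p_dist_matrix")
}

#' @export
print.p_dist_matrix <- function(x, ...) {
  nd <- sum(is.na(x$d[upper.tri(x$d)]))
  cat(sprintf("<p_dist_matrix> %s: %d specimens, %d pairs (%d undefined)\n",
              x$marker, length(x$labels), choose(length(x$labels), 2), nd))
  invisible(x)
}

#' @describeIn pairwise_matrix Long tibble of unordered pairs with species
#'   labels and an intra/inter flag.
#' @param x A `p_dist_matrix`.
#' @param ... Unused.
#' @method tidy p_dist_matrix
#' @export
tidy.p_dist_matrix <- function(x, ...) {
  ut <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble::tibble(
    id1 = x$labels[ut[, 1]], id2 = x$labels[ut[, 2]],
    species1 = unname(x$species[ut[, 1]]),
    species2 = unname(x$species[ut[, 2]]),
    distance = x$d[ut],
    comparable_sites = x$comparable_sites[ut],
    type = ifelse(x$species[ut[, 1]] == x$species[ut[, 2]],
                  "intraspecific", "interspecific"))
}

#' Split pairwise distances into intra- and interspecific sets
#'
#' Each defined unordered pair is assigned to the intraspecific set when the
#' two specimens share a species label, otherwise to the interspecific set.
#' Undefined pairs (zero comparable sites) are excluded and counted.
#'
#' @param m A `p_dist_matrix`.
#' @return List with numeric vectors `intra` and `inter` and the count
#'   `n_undefined_pairs`.
#' @export
partition_distances <- function(m) {
  tt <- tidy.p_dist_matrix(m)
  list(intra = tt$distance[tt$type == "intraspecific" & !is.na(tt$distance)],
       inter = tt$distance[tt$type == "interspecific" & !is.na(tt$distance)],
       n_undefined_pairs = sum(is.na(tt$distance)))
}

#' Barcoding-gap summary
#'
#' Relative-frequency histograms of intra- and interspecific p-distances on
#' a common binning, the fraction of interspecific distances strictly above
#' a threshold and of intraspecific distances strictly below it, and an
#' overlap flag (`max(intra) >= min(inter)`; `FALSE` indicates a clean
#' barcoding gap).
#'
#' @param intra Numeric vector of intraspecific distances, or a
#'   `p_dist_matrix` (then `inter` is ignored and both sets are derived via
#'   [partition_distances()]).
#' @param inter Numeric vector of interspecific distances.
#' @param bin_width Histogram bin width in p-distance units.
#' @param threshold_x Threshold distance for the tail fractions.
#' @return An object of class `gap_summary`.
#' @export
gap_summary <- function(intra, inter = NULL, bin_width = 0.01,
                        threshold_x = 0.05) {
  n_undef <- 0L
  if (inherits(intra, "p_dist_matrix")) {
    part <- partition_distances(intra)
    inter <- part$inter
    n_undef <- part$n_undefined_pairs
    intra <- part$intra
  }
  intra <- intra[!is.na(intra)]
  inter <- inter[!is.na(inter)]
  if (length(intra) + length(inter) == 0) {
    abort_bv("both distance sets are empty.", "input")
  }
  maxd <- max(c(intra, inter))
  nb <- max(1L, ceiling(maxd / bin_width - 1e-9))
  breaks <- seq(0, nb * bin_width, by = bin_width)
  rel_hist <- function(x) {
    if (length(x) == 0) return(rep(NA_real_, nb))
    idx <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), nb)
    tabulate(idx, nbins = nb) / length(x)
  }
  structure(
    list(intra = intra, inter = inter,
         bin_width = bin_width, breaks = breaks,
         intra_hist = rel_hist(intra), inter_hist = rel_hist(inter),
         threshold_x = threshold_x,
         frac_inter_above_x = if (length(inter)) mean(inter > threshold_x) else NA_real_,
         frac_intra_below_x = if (length(intra)) mean(intra < threshold_x) else NA_real_,
         max_intra = if (length(intra)) max(intra) else NA_real_,
         min_inter = if (length(inter)) min(inter) else NA_real_,
         overlap = if (length(intra) && length(inter)) max(intra) >= min(inter) else NA,
         n_undefined_pairs = n_undef),
    class = "gap_summary")
}

#' @export
print.gap_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<gap_summary> %d intra / %d inter pairs; at x = %g: %.1f%% inter > x,",
    " %.1f%% intra < x; gap %s\n"),
    length(x$intra), length(x$inter), x$threshold_x,
    100 * x$frac_inter_above_x, 100 * x$frac_intra_below_x,
    if (isTRUE(x$overlap)) "absent (overlap)" else "present"))
  invisible(x)
}

#' @describeIn gap_summary Binned relative frequencies as a tibble.
#' @param x A `gap_summary`.
#' @param ... Unused.
#' @method tidy gap_summary
#' @export
tidy.gap_summary <- function(x, ...) {
  nb <- length(x$intra_hist)
  tibble::tibble(
    bin_lower = x$breaks[seq_len(nb)],
    bin_upper = x$breaks[seq_len(nb) + 1L],
    bin_mid = (x$breaks[seq_len(nb)] + x$breaks[seq_len(nb) + 1L]) / 2,
    intra_freq = x$intra_hist,
    inter_freq = x$inter_hist)
}

#' @describeIn gap_summary One-row summary tibble.
#' @method glance gap_summary
#' @export
glance.gap_summary <- function(x, ...) {
  tibble::tibble(
    n_intra = length(x$intra), n_inter = length(x$inter),
    threshold_x = x$threshold_x,
    frac_inter_above_x = x$frac_inter_above_x,
    frac_intra_below_x = x$frac_intra_below_x,
    max_intra = x$max_intra, min_inter = x$min_inter,
    overlap = x$overlap, n_undefined_pairs = x$n_undefined_pairs)
}

#' @describeIn gap_summary Paired histogram of intra- and interspecific
#'   divergences (intraspecific dark, interspecific light).
#' @param object A `gap_summary`.
#' @method autoplot gap_summary
#' @export
autoplot.gap_summary <- function(object, ...) {
  df <- tidy.gap_summary(object)
  long <- tidyr::pivot_longer(df, c("intra_freq", "inter_freq"),
                              names_to = "set", values_to = "freq")
  long$set <- factor(long$set, c("intra_freq", "inter_freq"),
                     c("intraspecific", "interspecific"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin_mid, y = .data$freq,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge", width = object$bin_width * 0.9) +
    ggplot2::scale_fill_manual(values = c(intraspecific = "grey20",
                                          interspecific = "grey85"),
                               name = NULL) +
    ggplot2::geom_vline(xintercept = object$threshold_x, linetype = 2) +
    ggplot2::labs(x = "p-distance", y = "relative frequency") +
    ggplot2::theme_minimal()
}

#' Write a square distance matrix as CSV
#'
#' First column and header row carry the specimen ids.
#'
#' @param m A `p_dist_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(m, path) {
  df <- tibble::as_tibble(m$d, rownames = "specimen_id")
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Write a square distance matrix in PHYLIP format
#' @param m A `p_dist_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dist_phylip <- function(m, path) {
  n <- length(m$labels)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste0(formatC(m$labels[i], width = -10),
                      paste(sprintf("%.6f", m$d[i, ]), collapse = " "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
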