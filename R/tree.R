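# Neighbor-joining from p-distances, nonparametric bootstrap support,
# outgroup rooting, and species-specific cluster scoring.

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei agglomeration with the standard Q-criterion. Q ties are broken
#' deterministically by the lexicographically smallest pair of cluster
#' representative labels (the smallest original leaf label in each cluster).
#' Negative branch lengths arising at a join are clamped to zero with the
#' deficit transferred to the sibling edge, preserving the path length
#' between the joined clusters. The returned tree is unrooted.
#'
#' @param m A `p_dist_matrix`, a `dist`, or a labelled square numeric
#'   matrix with at least three taxa and no undefined entries.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(m) {
  if (inherits(m, "p_dist_matrix")) {
    D <- m$d
  } else if (inherits(m, "dist")) {
    D <- as.matrix(m)
  } else {
    D <- as.matrix(m)
  }
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(D)))
  n <- nrow(D)
  if (n < 3) abort_bv("neighbor joining needs at least 3 taxa.", "input")
  offdiag <- D[upper.tri(D)]
  if (anyNA(offdiag)) {
    abort_bv(paste0("distance matrix has undefined entries; impute them or ",
                    "remove the affected specimens before tree building."),
             "input")
  }
  frag <- labs          # newick fragment per active cluster
  repmin <- labs        # smallest original leaf label per cluster
  fmt <- function(x) sprintf("%.15g", x)
  while (n > 3) {
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    hits <- which(Q == qmin, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    if (nrow(hits) > 1) {
      keys <- apply(hits, 1, function(h) {
        p <- sort(c(repmin[h[1]], repmin[h[2]]))
        paste(p, collapse = "\r")
      })
      hits <- hits[order(keys)[1], , drop = FALSE]
    }
    i <- hits[1, 1]; j <- hits[1, 2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(li + lj, 0); lj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    others <- setdiff(seq_len(n), c(i, j))
    dnew <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D <- D[others, others, drop = FALSE]
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    frag <- c(frag[others], newfrag)
    repmin <- c(repmin[others], min(repmin[c(i, j)]))
    n <- n - 1
  }
  la <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  lb <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  lc <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(la), frag[2], fmt(lb), frag[3], fmt(lc))
  ape::read.tree(text = nwk)
}

# canonical keys for the non-trivial bipartitions of an unrooted tree,
# relative to a fixed reference label order; named by internal node number
tree_bipartitions <- function(tree, ref_labels) {
  ntip <- length(tree$tip.label)
  idx <- match(tree$tip.label, ref_labels)
  all_idx <- sort(idx)
  desc <- phangorn::Descendants(tree, seq_len(ntip + tree$Nnode), "tips")
  inner <- setdiff(seq_len(ntip + tree$Nnode), seq_len(ntip))
  keys <- vapply(inner, function(nd) {
    side <- sort(idx[desc[[nd]]])
    if (length(side) <= 1 || length(side) >= ntip - 1) return(NA_character_)
    if (1 %in% side) side <- setdiff(all_idx, side)
    paste(side, collapse = ",")
  }, "")
  stats::setNames(keys, inner)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the full-data NJ tree from the alignment's pairwise p-distances,
#' then resamples alignment columns with replacement `n_reps` times, rebuilds
#' the NJ tree for each replicate, and annotates each internal edge of the
#' full-data tree with the percentage of replicate trees containing the same
#' bipartition. Replicates whose resampled matrix has undefined distances
#' (zero comparable sites for some pair) are dropped and counted.
#'
#' @param aln A [marker_alignment()] with at least three rows.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Optional integer seed for the column resampling.
#' @return An unrooted `phylo` whose `node.label` holds support percentages
#'   (empty for the basal node), with attributes `n_replicates_used` and
#'   `n_replicates_dropped`.
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = NULL) {
  if (aln$length < 1) abort_bv("alignment has no columns.", "input")
  if (n_reps < 1) abort_bv("n_reps must be >= 1.", "input")
  m_full <- pairwise_matrix(aln)
  tree <- neighbor_joining(m_full)
  M <- as.matrix(aln)
  if (!is.null(seed)) set.seed(seed)
  counts <- new.env(parent = emptyenv())
  used <- 0L
  dropped <- 0L
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
    cc <- dist_counts(M[, cols, drop = FALSE])
    if (any(cc$comparable[upper.tri(cc$comparable)] == 0)) {
      dropped <- dropped + 1L
      next
    }
    d <- cc$mismatches / cc$comparable
    dimnames(d) <- list(aln$ids, aln$ids)
    rt <- neighbor_joining(d)
    used <- used + 1L
    for (k in unique(stats::na.omit(tree_bipartitions(rt, aln$ids)))) {
      assign(k, get0(k, envir = counts, ifnotfound = 0L) + 1L, envir = counts)
    }
  }
  if (used == 0L) {
    abort_bv("all bootstrap replicates had undefined distances.", "input")
  }
  full_keys <- tree_bipartitions(tree, aln$ids)
  ntip <- length(tree$tip.label)
  labels <- vapply(as.character(seq_len(tree$Nnode) + ntip), function(nd) {
    k <- full_keys[[nd]]
    if (is.na(k)) return("")
    sup <- 100 * get0(k, envir = counts, ifnotfound = 0L) / used
    formatC(sup, format = "fg", digits = 4)
  }, "")
  tree$node.label <- unname(labels)
  attr(tree, "n_replicates_used") <- used
  attr(tree, "n_replicates_dropped") <- dropped
  tree
}

#' Root a tree on an outgroup
#'
#' Roots on the edge subtending the smallest clade containing the outgroup
#' labels. Internal-node labels are treated as edge (support) labels so they
#' stay attached to the correct bipartition across the re-rooting.
#'
#' @param tree A `phylo`.
#' @param outgroup Character vector of leaf labels (a single leaf or a
#'   monophyletic set in the unrooted tree).
#' @return A rooted `phylo`.
#' @export
root_tree <- function(tree, outgroup) {
  miss <- setdiff(outgroup, tree$tip.label)
  if (length(miss) > 0) {
    abort_bv(paste0("outgroup labels not in tree: ",
                    paste(miss, collapse = ", ")), "lookup")
  }
  out <- tryCatch(
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
              edgelabel = TRUE),
    error = function(e) {
      abort_bv(paste0(
        "outgroup {", paste(outgroup, collapse = ", "),
        "} is not a bipartition of the unrooted tree; ",
        "pick a monophyletic set or a single leaf."), "input")
    })
  out
}

#' Score species-specific clusters on a support-annotated tree
#'
#' For every species with at least two specimens, tests whether some clade
#' of the rooted tree contains exactly that species' specimens
#' (monophyly) and whether that clade's support meets the cutoff. The
#' headline percentage uses multi-specimen species as the denominator
#' (singletons cannot form a cluster); an all-species variant is also
#' reported. Works on any rooted tree whose internal-node labels are
#' bootstrap percentages, including externally built newick trees.
#'
#' @param tree A rooted `phylo` with support values in `node.label`.
#' @param species Named character vector mapping tip label to species, or a
#'   metadata data frame with `specimen_id` and `species` columns.
#' @param cutoff Support cutoff in percent (default 70).
#' @return An object of class `cluster_report`.
#' @export
species_specific_clusters <- function(tree, species, cutoff = 70) {
  if (!ape::is.rooted(tree)) {
    abort_bv("tree must be rooted (see root_tree()).", "input")
  }
  if (is.data.frame(species)) {
    species <- stats::setNames(species$species, species$specimen_id)
  }
  miss <- setdiff(tree$tip.label, names(species))
  if (length(miss) > 0) {
    abort_bv(paste0("tips without a species label: ",
                    paste(miss, collapse = ", ")), "metadata")
  }
  sp_of_tip <- unname(species[tree$tip.label])
  ntip <- length(tree$tip.label)
  root_node <- ntip + 1L
  sup_of_node <- function(nd) {
    if (is.null(tree$node.label) || nd == root_node) return(NA_real_)
    suppressWarnings(as.numeric(tree$node.label[nd - ntip]))
  }
  per <- purrr::map_dfr(sort(unique(sp_of_tip)), function(sp) {
    tips <- which(sp_of_tip == sp)
    k <- length(tips)
    if (k < 2) {
      return(tibble::tibble(species = sp, n_specimens = k, counted = FALSE,
                            monophyletic = NA, support = NA_real_,
                            supported = NA))
    }
    mrca <- ape::getMRCA(tree, tips)
    desc <- phangorn::Descendants(tree, mrca, "tips")[[1]]
    mono <- length(desc) == k
    sup <- if (mono) sup_of_node(mrca) else NA_real_
    tibble::tibble(species = sp, n_specimens = k, counted = TRUE,
                   monophyletic = mono, support = sup,
                   supported = mono && !is.na(sup) && sup >= cutoff)
  })
  n_counted <- sum(per$counted)
  n_ok <- sum(per$supported, na.rm = TRUE)
  structure(
    list(per_species = per, cutoff = cutoff,
         n_species = nrow(per), n_counted = n_counted,
         n_supported = n_ok,
         percent_species_specific =
           if (n_counted > 0) 100 * n_ok / n_counted else NA_real_,
         percent_species_specific_all_species =
           if (nrow(per) > 0) 100 * n_ok / nrow(per) else NA_real_),
    class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  pct <- if (is.na(x$percent_species_specific)) "not applicable"
         else sprintf("%.1f%%", x$percent_species_specific)
  cat(sprintf(
    "<cluster_report> %d/%d multi-specimen species supported at >= %g%% (%s)\n",
    x$n_supported, x$n_counted, x$cutoff, pct))
  invisible(x)
}

#' @describeIn species_specific_clusters Per-species verdicts as a tibble.
#' @param x A `cluster_report`.
#' @param ... Unused.
#' @method tidy cluster_report
#' @export
tidy.cluster_report <- function(x, ...) x$per_species

#' @describeIn species_specific_clusters One-row summary tibble.
#' @method glance cluster_report
#' @export
glance.cluster_report <- function(x, ...) {
  tibble::tibble(
    n_species = x$n_species, n_counted = x$n_counted,
    n_supported = x$n_supported, cutoff = x$cutoff,
    percent_species_specific = x$percent_species_specific,
    percent_species_specific_all_species =
      x$percent_species_specific_all_species)
}
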