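# Fixtures and independent oracles used across the test files. Oracles are
# deliberately written as plain site-by-site / enumeration code, independent
# of the package's vectorised implementations.

make_aln <- function(seqs, species, marker = "test", ids = NULL) {
  if (is.null(ids)) ids <- paste0("q", seq_along(seqs))
  marker_alignment(stats::setNames(seqs, ids), species, marker = marker)
}

# hand-made p_dist_matrix for rule-level BCM tests
make_pdm <- function(d, species, marker = "hand") {
  labs <- rownames(d)
  structure(list(marker = marker, labels = labs,
                 species = stats::setNames(species, labs), d = d,
                 comparable_sites = matrix(1L, nrow(d), ncol(d),
                                           dimnames = dimnames(d))),
            class = "p_dist_matrix")
}

rand_sym_matrix <- function(labs) {
  n <- length(labs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  vals <- runif(n * (n - 1) / 2, 0.001, 0.4)
  d[upper.tri(d)] <- vals
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

# --- independent p-distance oracle: explicit per-site loop -----------------

oracle_p_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  comp <- 0L
  mism <- 0L
  for (s in seq_along(ca)) {
    x <- ca[s]
    y <- cb[s]
    if (x %in% c("A", "C", "G", "T") && y %in% c("A", "C", "G", "T")) {
      comp <- comp + 1L
      if (x != y) mism <- mism + 1L
    }
  }
  list(distance = if (comp == 0) NA_real_ else mism / comp,
       comparable_sites = comp)
}

random_test_alignment <- function(max_rows = 8, max_cols = 20) {
  n <- sample(2:max_rows, 1)
  L <- sample(4:max_cols, 1)
  chars <- c("A", "C", "G", "T", "N", "-", "?")
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(chars, L, replace = TRUE,
                 prob = c(rep(0.2, 4), 0.07, 0.07, 0.06)), collapse = "")
  }, "")
  make_aln(seqs, species = paste0("sp", rep_len(1:3, n)))
}

# --- NJ oracle: exhaustive topology enumeration + least-squares fit --------

# canonical non-trivial splits of a tree, independent of package internals
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  ref <- sort(labs)[1]
  keys <- vapply(pp, function(cl) {
    side <- labs[cl]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) <= 1 || length(side) >= ntip - 1) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, "")
  sort(unique(keys[!is.na(keys)]))
}

# pairs x edges incidence matrix (1 if the edge lies on the tip-pair path)
path_matrix <- function(tree) {
  labs <- sort(tree$tip.label)
  pairs <- t(utils::combn(labs, 2))
  A <- matrix(0, nrow(pairs), nrow(tree$edge))
  for (p in seq_len(nrow(pairs))) {
    i <- which(tree$tip.label == pairs[p, 1])
    j <- which(tree$tip.label == pairs[p, 2])
    np <- ape::nodepath(tree, i, j)
    for (k in seq_len(length(np) - 1)) {
      e <- which((tree$edge[, 1] == np[k] & tree$edge[, 2] == np[k + 1]) |
                   (tree$edge[, 1] == np[k + 1] & tree$edge[, 2] == np[k]))
      A[p, e] <- 1
    }
  }
  list(A = A, pairs = pairs)
}

# all unrooted topologies for these labels, with cached path matrices
ls_topology_bank <- local({
  cache <- list()
  function(labs) {
    key <- paste(labs, collapse = ",")
    if (is.null(cache[[key]])) {
      tops <- phangorn::allTrees(length(labs), rooted = FALSE,
                                 tip.label = labs)
      cache[[key]] <<- lapply(tops, function(tr) {
        pm <- path_matrix(tr)
        list(tree = tr, A = pm$A, pairs = pm$pairs, qr = qr(pm$A))
      })
    }
    cache[[key]]
  }
})

# splits of the least-squares-best topology for a distance matrix
ls_best_splits <- function(D) {
  labs <- sort(rownames(D))
  bank <- ls_topology_bank(labs)
  dvec_for <- function(pairs) D[cbind(pairs[, 1], pairs[, 2])]
  rss <- vapply(bank, function(b) {
    sum(qr.resid(b$qr, dvec_for(b$pairs))^2)
  }, 0)
  best <- which.min(rss)
  list(splits = tree_splits(bank[[best]]$tree), rss = rss[best],
       n_topologies = length(bank))
}

random_additive_tree <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE, tip.label = paste0("t", seq_len(n)))
  tr$edge.length <- runif(length(tr$edge.length), 0.05, 1)
  tr
}

# plain nearest-neighbour + threshold oracle (all distances distinct)
oracle_classify <- function(q, d, species, tval) {
  dd <- d[q, ]
  dd <- dd[names(dd) != q]
  if (min(dd) > tval) return("no_match")
  nn <- names(dd)[which.min(dd)]
  if (species[nn] == species[q]) "correct" else "incorrect"
}
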