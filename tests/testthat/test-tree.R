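test_that("NJ solves the three-taxon closed form and simple additive cases", {
  labs <- c("A", "B", "C")
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, dimnames = list(labs, labs))
  tr <- neighbor_joining(d)
  expect_equal(ape::Ntip(tr), 3)
  coph <- ape::cophenetic.phylo(tr)[labs, labs]
  expect_equal(coph, d, tolerance = 1e-12)
  # closed-form tip edges: la = (dAB + dAC - dBC)/2 = 1
  la <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "A")]
  expect_equal(la, 1)

  labs4 <- c("A", "B", "C", "D")
  d4 <- matrix(3, 4, 4, dimnames = list(labs4, labs4))
  diag(d4) <- 0
  d4["A", "B"] <- d4["B", "A"] <- 2
  d4["C", "D"] <- d4["D", "C"] <- 2
  tr4 <- neighbor_joining(d4)
  expect_true("A|B" %in% tree_splits(tr4) || "C|D" %in% tree_splits(tr4))
  expect_equal(ape::cophenetic.phylo(tr4)[labs4, labs4], d4, tolerance = 1e-12)
  # internal edge length 1, tip edges 1
  expect_equal(sort(tr4$edge.length), c(1, 1, 1, 1, 1))

  expect_error(neighbor_joining(d4[1:2, 1:2]), class = "barcodeval_error_input")
  d4["A", "C"] <- d4["C", "A"] <- NA
  expect_error(neighbor_joining(d4), class = "barcodeval_error_input")
})

test_that("NJ matches an ultrametric pair-of-cherries and an independent implementation", {
  labs <- c("a", "b", "c", "d")
  d <- matrix(0.4, 4, 4, dimnames = list(labs, labs))
  diag(d) <- 0
  d["a", "b"] <- d["b", "a"] <- 0.1
  d["c", "d"] <- d["d", "c"] <- 0.1
  expect_setequal(tree_splits(neighbor_joining(d)),
                  tree_splits(ape::read.tree(text = "((a,b),(c,d));")))

  set.seed(77)
  for (rep in 1:20) {
    tr0 <- random_additive_tree(sample(5:8, 1))
    D <- ape::cophenetic.phylo(tr0)
    mine <- neighbor_joining(D)
    ref <- ape::nj(D)
    expect_setequal(tree_splits(mine), tree_splits(ref))
    expect_equal(sort(mine$edge.length), sort(ref$edge.length),
                 tolerance = 1e-8)
  }
})

test_that("clamped NJ branch lengths stay non-negative", {
  labs <- paste0("t", 1:5)
  set.seed(12)
  for (rep in 1:20) {
    d <- rand_sym_matrix(labs)
    tr <- neighbor_joining(d)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("bootstrap gives full support to a clean split and is seed-reproducible", {
  seqs <- c(a1 = strrep("A", 100), a2 = strrep("A", 100),
            b1 = strrep("T", 100), b2 = strrep("T", 100))
  aln <- marker_alignment(seqs, c("A", "A", "B", "B"))
  tr <- bootstrap_support(aln, n_reps = 10, seed = 1)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
  expect_equal(attr(tr, "n_replicates_used"), 10L)

  mk <- tibble::tibble(name = "locus", length = 200L, genome = "plastid",
                       rate_scale = 1, indel_rate = 0, missing_rate = 0)
  sim <- simulate_dataset(sim_config(n_species = 5, individuals_per_species = 2,
                                     markers = mk, seed = 4))
  a <- sim$alignments$locus
  t1 <- bootstrap_support(a, n_reps = 30, seed = 9)
  t2 <- bootstrap_support(a, n_reps = 30, seed = 9)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))

  # support values are invariant to input row order
  idx <- rev(seq_len(n_seq(a)))
  a_rev <- marker_alignment(stats::setNames(a$seqs[idx], a$ids[idx]),
                            a$species[idx], marker = a$marker)
  t3 <- bootstrap_support(a_rev, n_reps = 30, seed = 9)
  sup_by_split <- function(tr) {
    keys <- vapply(seq_len(tr$Nnode), function(k) {
      cl <- phangorn::Descendants(tr, length(tr$tip.label) + k, "tips")[[1]]
      side <- sort(tr$tip.label[cl])
      if (a$ids[1] %in% side || length(side) >= length(tr$tip.label) - 1)
        return(NA_character_)
      paste(side, collapse = "|")
    }, "")
    ok <- !is.na(keys) & tr$node.label != ""
    stats::setNames(tr$node.label[ok], keys[ok])
  }
  s1 <- sup_by_split(t1)
  s3 <- sup_by_split(t3)
  common <- intersect(names(s1), names(s3))
  expect_gt(length(common), 0)
  expect_equal(s1[common], s3[common])
})

test_that("rooting places the outgroup correctly and rejects scattered outgroups", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);")
  r1 <- root_tree(tr, "e")
  expect_true(ape::is.rooted(r1))
  kids <- phangorn::Descendants(r1, ape::Ntip(r1) + 1, "children")
  expect_true("e" %in% r1$tip.label[kids[kids <= ape::Ntip(r1)]])

  r2 <- root_tree(tr, c("c", "d"))
  cd <- ape::getMRCA(r2, c("c", "d"))
  expect_setequal(r2$tip.label[phangorn::Descendants(r2, cd, "tips")[[1]]],
                  c("c", "d"))

  expect_error(root_tree(tr, c("a", "c")), class = "barcodeval_error_input")
  expect_error(root_tree(tr, "zz"), class = "barcodeval_error_lookup")
})

test_that("cluster scoring combines monophyly and support at the cutoff", {
  tr <- ape::read.tree(text = "((A1:1,A2:1)95:1,((B1:1,B2:1)60:1,Out:1):1);")
  sp <- stats::setNames(c("A", "A", "B", "B", "O"),
                        c("A1", "A2", "B1", "B2", "Out"))
  cr <- species_specific_clusters(tr, sp, cutoff = 70)
  tt <- tidy(cr)
  expect_true(tt$supported[tt$species == "A"])
  expect_true(tt$monophyletic[tt$species == "B"])
  expect_false(tt$supported[tt$species == "B"])
  expect_false(tt$counted[tt$species == "O"])
  expect_equal(cr$percent_species_specific, 50)
  g <- glance(cr)
  expect_equal(g$n_counted, 2L)
  expect_equal(g$percent_species_specific_all_species, 100 / 3)

  # all-singleton tree: denominator empty, percentage not applicable
  tr1 <- ape::read.tree(text = "((x:1,y:1)90:1,z:1);")
  cr1 <- species_specific_clusters(
    tr1, stats::setNames(c("X", "Y", "Z"), c("x", "y", "z")))
  expect_true(is.na(cr1$percent_species_specific))

  # species split across two clades is never monophyletic
  tr2 <- ape::read.tree(text = "(((A1:1,B1:1)99:1,A2:1)99:1,B2:1);")
  cr2 <- species_specific_clusters(
    tr2, stats::setNames(c("A", "B", "A", "B"), c("A1", "B1", "A2", "B2")))
  expect_false(any(tidy(cr2)$monophyletic))

  expect_error(
    species_specific_clusters(ape::unroot(tr), sp),
    class = "barcodeval_error_input")
})

test_that("a tree of fully supported cherries scores 100 percent", {
  tr <- ape::read.tree(
    text = "(((a1:1,a2:1)100:1,(b1:1,b2:1)100:1)100:1,(c1:1,c2:1)100:1);")
  sp <- stats::setNames(rep(c("A", "B", "C"), each = 2),
                        c("a1", "a2", "b1", "b2", "c1", "c2"))
  expect_equal(species_specific_clusters(tr, sp)$percent_species_specific, 100)
})
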