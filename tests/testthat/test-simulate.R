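test_that("the Jukes-Cantor p-distance map and its inverse are consistent", {
  expect_equal(expected_p_distance(0), 0)
  expect_equal(expected_p_distance(1e6), 0.75)
  expect_equal(expected_p_distance(0.1), 0.0937, tolerance = 1e-3)
  for (p in c(0.001, 0.05, 0.2, 0.5)) {
    expect_equal(expected_p_distance(divergence_for_p(p)), p, tolerance = 1e-12)
  }
  expect_error(divergence_for_p(0.8), class = "barcodeval_error_input")
})

test_that("species trees are scaled to the requested divergence and are seeded", {
  cfg2 <- sim_config(n_species = 2, interspecific_depth = 0.07, seed = 5)
  tr2 <- simulate_species_tree(cfg2)
  # two tips: the single pairwise path is 2 * depth, each tip at depth
  expect_equal(ape::cophenetic.phylo(tr2)[1, 2], 0.14, tolerance = 1e-12)

  cfg <- sim_config(n_species = 12, interspecific_depth = 0.05, seed = 8)
  tr <- simulate_species_tree(cfg)
  pw <- ape::cophenetic.phylo(tr)
  expect_equal(mean(pw[upper.tri(pw)]), 0.1, tolerance = 1e-12)
  expect_identical(ape::write.tree(simulate_species_tree(cfg)),
                   ape::write.tree(tr))

  cfg0 <- sim_config(n_species = 4, interspecific_depth = 0, seed = 1)
  tr0 <- simulate_species_tree(cfg0)
  expect_true(all(tr0$edge.length == 0))
})

test_that("datasets are byte-identical under a fixed seed", {
  cfg <- sim_config(n_species = 5, individuals_per_species = 3, seed = 21)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  for (mk in names(s1$alignments)) {
    expect_identical(s1$alignments[[mk]]$seqs, s2$alignments[[mk]]$seqs)
    expect_identical(s1$alignments[[mk]]$ids, s2$alignments[[mk]]$ids)
  }
  expect_identical(s1$metadata, s2$metadata)
})

test_that("theta 0 with positive depth gives zero intra and positive inter distances", {
  mk <- tibble::tibble(name = "locus", length = 500L, genome = "plastid",
                       rate_scale = 1, indel_rate = 0, missing_rate = 0)
  cfg <- sim_config(n_species = 6, individuals_per_species = 3, markers = mk,
                    interspecific_depth = 0.3, intraspecific_theta = 0,
                    seed = 17)
  part <- partition_distances(
    pairwise_matrix(simulate_dataset(cfg)$alignments$locus))
  expect_true(all(part$intra == 0))
  expect_true(all(part$inter > 0))
})

test_that("dropout empties a marker at rate 1 and tracks the rate otherwise", {
  mk <- tibble::tibble(name = c("gone", "kept"), length = c(100L, 100L),
                       genome = c("plastid", "plastid"), rate_scale = c(1, 1),
                       indel_rate = c(0, 0), missing_rate = c(1, 0.3))
  cfg <- sim_config(n_species = 15, individuals_per_species = 4, markers = mk,
                    seed = 33)
  sim <- simulate_dataset(cfg)
  expect_equal(n_seq(sim$alignments$gone), 0L)
  n_total <- nrow(sim$metadata)
  n_miss <- n_total - n_seq(sim$alignments$kept)
  ci <- stats::qbinom(c(0.0005, 0.9995), n_total, 0.3)
  expect_gte(n_miss, ci[1])
  expect_lte(n_miss, ci[2])
})

test_that("plastid markers share one genealogy; the nuclear draw is independent", {
  cfg <- sim_config(n_species = 5, individuals_per_species = 3, seed = 13)
  tr <- simulate_species_tree(cfg)
  g1 <- barcodeval:::simulate_genealogy(cfg, tr, "plastid")
  g2 <- barcodeval:::simulate_genealogy(cfg, tr, "plastid")
  gn <- barcodeval:::simulate_genealogy(cfg, tr, "nuclear")
  expect_identical(ape::write.tree(g1), ape::write.tree(g2))
  expect_false(identical(ape::write.tree(g1), ape::write.tree(gn)))

  # with theta 0 the haplotype partition of every plastid marker collapses to
  # the species partition, so linked markers agree exactly
  mk <- tibble::tibble(name = c("p1", "p2"), length = c(400L, 400L),
                       genome = "plastid", rate_scale = c(1, 1),
                       indel_rate = c(0, 0), missing_rate = c(0, 0))
  cfg0 <- sim_config(n_species = 6, individuals_per_species = 3, markers = mk,
                     interspecific_depth = 0.08, intraspecific_theta = 0,
                     seed = 19)
  sim <- simulate_dataset(cfg0)
  partition_of <- function(aln) {
    asg <- haplotypes(aln)$assignment
    unname(split(asg$specimen_id, asg$haplotype))
  }
  canon <- function(p) sort(vapply(p, function(g) paste(sort(g), collapse = ","), ""))
  expect_identical(canon(partition_of(sim$alignments$p1)),
                   canon(partition_of(sim$alignments$p2)))
})

test_that("spacer-like indels create gap columns but keep the matrix aligned", {
  mk <- tibble::tibble(name = "spacer", length = 400L, genome = "plastid",
                       rate_scale = 1, indel_rate = 0.03, missing_rate = 0)
  cfg <- sim_config(n_species = 6, individuals_per_species = 3, markers = mk,
                    seed = 29)
  aln <- simulate_dataset(cfg)$alignments$spacer
  expect_true(all(nchar(aln$seqs) == aln$length))
  expect_gt(length(site_classes(aln)$gap_sites), 0)
  # deletions are species-level: all individuals of a species share gaps
  M <- as.matrix(aln) == "-"
  for (sp in unique(aln$species)) {
    rows <- M[aln$species == sp, , drop = FALSE]
    expect_true(all(apply(rows, 2, function(col) all(col) || !any(col))))
  }
})

test_that("simulated datasets can be written to plain-text files", {
  cfg <- sim_config(n_species = 4, individuals_per_species = 2, seed = 2)
  sim <- simulate_dataset(cfg)
  out <- withr::local_tempdir()
  write_dataset(sim, out)
  expect_true(file.exists(file.path(out, "metadata.csv")))
  expect_true(file.exists(file.path(out, "species_tree.nwk")))
  expect_true(file.exists(file.path(out, "ITS_aligned.fasta")))
  meta <- read_specimen_metadata(file.path(out, "metadata.csv"))
  aln <- read_alignment(file.path(out, "ITS_aligned.fasta"), meta,
                        marker = "ITS")
  expect_identical(aln$seqs, unname(sim$alignments$ITS$seqs))
})
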