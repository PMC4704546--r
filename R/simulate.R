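# Seeded simulator of multi-species, multi-individual, multi-marker
# sequence datasets: a Yule species tree carrying within-species coalescent
# genealogies, Jukes-Cantor substitution along the combined genealogy,
# deletion-style indels for spacer-like markers, and per-(specimen, marker)
# dropout. All plastid markers share one within-species genealogy per
# dataset (uniparental linkage); the nuclear marker draws its own.

#' Default marker panel for the simulator
#'
#' Four markers emulating a typical plant-barcoding panel: two conserved
#' plastid coding genes, one indel-rich plastid spacer, and a fast nuclear
#' spacer. `rate_scale` multiplies the genealogy's branch lengths for that
#' marker; `indel_rate` is the per-site probability that a deletion event
#' starts in a given species; `missing_rate` is the per-(specimen, marker)
#' dropout probability.
#'
#' @return Tibble with columns `name`, `length`, `genome`, `rate_scale`,
#'   `indel_rate`, `missing_rate`.
#' @export
default_markers <- function() {
  tibble::tibble(
    name = c("rbcL", "matK", "trnH-psbA", "ITS"),
    length = c(570L, 800L, 480L, 650L),
    genome = c("plastid", "plastid", "plastid", "nuclear"),
    rate_scale = c(0.4, 0.8, 1.5, 2.0),
    indel_rate = c(0, 0, 0.02, 0.015),
    missing_rate = c(0.05, 0.35, 0.2, 0.25))
}

#' Simulation configuration
#'
#' @param n_species Number of species (>= 2).
#' @param individuals_per_species Scalar or per-species integer vector.
#' @param markers Marker table as in [default_markers()].
#' @param interspecific_depth Expected substitutions/site such that the mean
#'   pairwise path between tips of different species equals
#'   `2 * interspecific_depth` (so the expected interspecific p-distance is
#'   `expected_p_distance(2 * interspecific_depth * rate_scale)`).
#' @param intraspecific_theta Expected pairwise substitutions/site between
#'   two individuals of the same species.
#' @param indel_length_mean Mean deletion length (geometric), in bp.
#' @param seed Integer master seed; every stochastic stage derives its own
#'   sub-seed from it, so a fixed seed gives byte-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_species = 30, individuals_per_species = 4,
                       markers = default_markers(),
                       interspecific_depth = 0.05,
                       intraspecific_theta = 0.005,
                       indel_length_mean = 6, seed = 1) {
  if (n_species < 2) abort_bv("need at least 2 species.", "input")
  k <- individuals_per_species
  if (length(k) == 1) k <- rep(as.integer(k), n_species)
  if (length(k) != n_species || any(k < 1)) {
    abort_bv("individuals_per_species must be a positive scalar or one value per species.",
             "input")
  }
  need <- c("name", "length", "genome", "rate_scale", "indel_rate",
            "missing_rate")
  if (!all(need %in% names(markers))) {
    abort_bv(paste0("marker table needs columns: ",
                    paste(need, collapse = ", ")), "input")
  }
  if (interspecific_depth < 0 || intraspecific_theta < 0 ||
      any(markers$rate_scale < 0) || any(markers$indel_rate < 0) ||
      any(markers$missing_rate < 0 | markers$missing_rate > 1)) {
    abort_bv("rates must be non-negative (missing_rate in [0,1]).", "input")
  }
  structure(list(n_species = as.integer(n_species),
                 individuals_per_species = k,
                 markers = tibble::as_tibble(markers),
                 interspecific_depth = interspecific_depth,
                 intraspecific_theta = intraspecific_theta,
                 indel_length_mean = indel_length_mean,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# stable sub-seed derivation: one master seed fans out per stage/tag
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

#' Expected p-distance under Jukes-Cantor divergence
#'
#' Closed form `0.75 * (1 - exp(-4 d / 3))` for a path of `d` expected
#' substitutions per site; saturates at 0.75.
#'
#' @param d Expected substitutions per site (>= 0).
#' @return Expected proportion of differing sites.
#' @export
expected_p_distance <- function(d) 0.75 * (1 - exp(-4 * d / 3))

#' Jukes-Cantor divergence giving a target p-distance
#'
#' Inverse of [expected_p_distance()]; handy for calibrating simulation
#' depths to a target observed p-distance.
#'
#' @param p Target p-distance in `[0, 0.75)`.
#' @return Expected substitutions per site.
#' @export
divergence_for_p <- function(p) {
  if (any(p < 0 | p >= 0.75)) abort_bv("p must be in [0, 0.75).", "input")
  -0.75 * log(1 - 4 * p / 3)
}

species_labels <- function(n) {
  sprintf("s%0*d", max(2L, nchar(n)), seq_len(n))
}

#' Simulate a species tree
#'
#' Pure-birth (Yule) topology over `n_species`, rescaled so that the mean
#' pairwise path between species tips equals `2 * interspecific_depth`
#' (hence the expected interspecific p-distance for a unit-rate marker is
#' `expected_p_distance(2 * interspecific_depth)`). A zero depth yields a
#' star of zero-length edges.
#'
#' @param cfg A [sim_config()].
#' @return An ultrametric `phylo` with tips `s01, s02, ...`.
#' @export
simulate_species_tree <- function(cfg) {
  n <- cfg$n_species
  set.seed(derive_seed(cfg$seed, "species_tree"))
  if (cfg$interspecific_depth == 0) {
    tr <- ape::stree(n, type = "star")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else {
    tr <- ape::rphylo(n, birth = 1, death = 0)
    pw <- ape::cophenetic.phylo(tr)
    meanpair <- mean(pw[upper.tri(pw)])
    tr$edge.length <- tr$edge.length * (2 * cfg$interspecific_depth / meanpair)
  }
  tr$tip.label <- species_labels(n)
  tr
}

# one genealogy over all individuals: within-species coalescent subtrees
# grafted onto the species tree so individual tips sit exactly at the
# species-tip depth (terminal branch shortened by the subtree height,
# clamped at zero). `genome` selects the shared plastid draw or the
# independent nuclear draw.
simulate_genealogy <- function(cfg, species_tree, genome) {
  set.seed(derive_seed(cfg$seed, paste0("coal_", genome)))
  if (cfg$interspecific_depth == 0) {
    # zero divergence is a single panmictic population: one coalescent over
    # every individual, regardless of species label
    ids <- unlist(lapply(seq_len(cfg$n_species), function(i) {
      paste0(species_tree$tip.label[i], "_",
             seq_len(cfg$individuals_per_species[i]))
    }))
    if (cfg$intraspecific_theta == 0) {
      star <- ape::stree(length(ids), type = "star", tip.label = ids)
      star$edge.length <- rep(0, nrow(star$edge))
      return(star)
    }
    ct <- ape::rcoal(length(ids), tip.label = ids)
    ct$edge.length <- ct$edge.length * (cfg$intraspecific_theta / 2)
    return(ct)
  }
  nwk <- ape::write.tree(species_tree)
  fmt <- function(x) sprintf("%.12g", x)
  for (i in seq_len(cfg$n_species)) {
    sp <- species_tree$tip.label[i]
    k <- cfg$individuals_per_species[i]
    ids <- paste0(sp, "_", seq_len(k))
    pat <- paste0(sp, ":[0-9.eE+-]+")
    hit <- regexpr(pat, nwk)
    blen <- as.numeric(sub(paste0(sp, ":"), "", regmatches(nwk, hit)))
    if (k == 1) {
      repl <- paste0(ids, ":", fmt(blen))
    } else {
      ct <- ape::rcoal(k, tip.label = ids)
      ct$edge.length <- ct$edge.length * (cfg$intraspecific_theta / 2)
      h <- max(ape::node.depth.edgelength(ct))
      core <- sub(";$", "", ape::write.tree(ct))
      repl <- paste0(core, ":", fmt(max(blen - h, 0)))
    }
    regmatches(nwk, hit) <- repl
  }
  ape::read.tree(text = nwk)
}

#' Simulate one marker alignment
#'
#' Evolves Jukes-Cantor sequences along the dataset genealogy for the
#' marker's genome class (all plastid markers share one genealogy; the
#' nuclear marker has its own), applies species-level deletions for markers
#' with `indel_rate > 0` (the true alignment is retained, so the output is
#' aligned), and drops whole specimens at `missing_rate`.
#'
#' @param cfg A [sim_config()].
#' @param species_tree Tree from [simulate_species_tree()].
#' @param marker_name Name present in `cfg$markers`.
#' @return A [marker_alignment()]; specimens lost to dropout are absent.
#' @export
simulate_marker <- function(cfg, species_tree, marker_name) {
  row <- cfg$markers[cfg$markers$name == marker_name, ]
  if (nrow(row) != 1) {
    abort_bv(sprintf("marker '%s' not in the configuration.", marker_name),
             "lookup")
  }
  gen <- simulate_genealogy(cfg, species_tree, row$genome)
  set.seed(derive_seed(cfg$seed, paste0("seq_", marker_name)))
  dat <- phangorn::simSeq(gen, l = row$length, rate = row$rate_scale)
  M <- toupper(as.character(dat))
  meta <- sim_metadata(cfg, species_tree)
  M <- M[meta$specimen_id, , drop = FALSE]
  if (row$indel_rate > 0) {
    set.seed(derive_seed(cfg$seed, paste0("indel_", marker_name)))
    for (i in seq_len(cfg$n_species)) {
      sp <- species_tree$tip.label[i]
      starts <- which(stats::runif(row$length) < row$indel_rate)
      for (s in starts) {
        len <- stats::rgeom(1, 1 / cfg$indel_length_mean) + 1L
        cols <- s:min(s + len - 1L, row$length)
        M[meta$species_label == sp, cols] <- "-"
      }
    }
  }
  keep <- rep(TRUE, nrow(M))
  if (row$missing_rate > 0) {
    set.seed(derive_seed(cfg$seed, paste0("miss_", marker_name)))
    keep <- stats::runif(nrow(M)) >= row$missing_rate
  }
  if (!any(keep)) {
    return(structure(list(marker = marker_name, ids = character(0),
                          species = character(0), seqs = character(0),
                          length = row$length),
                     class = "marker_alignment"))
  }
  seqs <- apply(M[keep, , drop = FALSE], 1, paste, collapse = "")
  marker_alignment(seqs, meta$species[keep], marker = marker_name)
}

# specimen metadata implied by a config + species tree; genus groups pairs
# of adjacent tips, families are the clades stemming from the root (pure
# bookkeeping so that family-level outgroup selection is exercisable)
sim_metadata <- function(cfg, species_tree) {
  n <- cfg$n_species
  sp_labels <- species_tree$tip.label
  ntip <- n
  root <- ntip + 1L
  fam_of_sp <- integer(n)
  kids <- species_tree$edge[species_tree$edge[, 1] == root, 2]
  for (j in seq_along(kids)) {
    tips <- if (kids[j] <= ntip) kids[j]
            else phangorn::Descendants(species_tree, kids[j], "tips")[[1]]
    fam_of_sp[tips] <- j
  }
  genus_of_sp <- ceiling(seq_len(n) / 2)
  purrr::map_dfr(seq_len(n), function(i) {
    k <- cfg$individuals_per_species[i]
    tibble::tibble(
      specimen_id = paste0(sp_labels[i], "_", seq_len(k)),
      species = paste0("Species_", sub("^s", "", sp_labels[i])),
      genus = sprintf("Genus_%02d", genus_of_sp[i]),
      family = sprintf("Family_%02d", fam_of_sp[i]),
      species_label = sp_labels[i])
  })
}

#' Simulate a complete multi-marker dataset
#'
#' @param cfg A [sim_config()].
#' @return List with `alignments` (named list of [marker_alignment()]),
#'   `metadata` (tibble: specimen_id, species, genus, family),
#'   `species_tree` (`phylo`) and `config`.
#' @export
simulate_dataset <- function(cfg) {
  tr <- simulate_species_tree(cfg)
  meta <- sim_metadata(cfg, tr)
  alns <- stats::setNames(
    lapply(cfg$markers$name, function(mk) simulate_marker(cfg, tr, mk)),
    cfg$markers$name)
  list(alignments = alns,
       metadata = meta[, c("specimen_id", "species", "genus", "family")],
       species_tree = tr, config = cfg)
}

#' Write a simulated dataset to disk
#'
#' Emits per-marker aligned FASTA, degapped raw FASTA, the metadata CSV,
#' the true species tree (newick) and a config echo (YAML).
#'
#' @param sim Result of [simulate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  safe <- function(x) gsub("[^A-Za-z0-9_.]+", "_", x)
  for (mk in names(sim$alignments)) {
    aln <- sim$alignments[[mk]]
    write_alignment(aln, file.path(out_dir, paste0(safe(mk), "_aligned.fasta")))
    raw <- gsub("[-?]", "", aln$seqs)
    ss <- Biostrings::BStringSet(stats::setNames(raw, aln$ids))
    Biostrings::writeXStringSet(ss, file.path(out_dir,
                                              paste0(safe(mk), "_raw.fasta")))
  }
  readr::write_csv(sim$metadata, file.path(out_dir, "metadata.csv"),
                   progress = FALSE)
  ape::write.tree(sim$species_tree, file.path(out_dir, "species_tree.nwk"))
  cfg <- sim$config
  yaml::write_yaml(list(
    n_species = cfg$n_species,
    individuals_per_species = cfg$individuals_per_species,
    interspecific_depth = cfg$interspecific_depth,
    intraspecific_theta = cfg$intraspecific_theta,
    indel_length_mean = cfg$indel_length_mean,
    seed = cfg$seed,
    markers = as.data.frame(cfg$markers)),
    file.path(out_dir, "sim_config.yaml"))
  invisible(out_dir)
}
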