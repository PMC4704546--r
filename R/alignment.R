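# Data model for aligned marker matrices and specimen metadata.
# Allowed residue alphabet: A,C,G,T plus N (ambiguous), '-' (gap) and '?'
# (missing). All three non-base symbols are treated as missing downstream.

MISSING_CHARS <- c("-", "N", "?")
BASES <- c("A", "C", "G", "T")

abort_bv <- function(msg, class) {
  rlang::abort(msg, class = paste0("barcodeval_error_", class))
}

#' Construct a marker alignment
#'
#' A `marker_alignment` holds equal-length aligned sequences for one marker
#' (or a concatenation of markers), together with the specimen-to-species
#' mapping needed by every downstream analysis.
#'
#' @param seqs Named character vector of aligned sequences; names are
#'   specimen ids. Alphabet restricted to `A,C,G,T,N,-,?` (case-insensitive);
#'   all sequences must have identical length.
#' @param species Character vector of species labels, same length/order as
#'   `seqs`, or a metadata data frame with columns `specimen_id` and
#'   `species` in which the ids are looked up.
#' @param marker Marker name (e.g. `"ITS"`, `"trnH-psbA"`, or a combination
#'   label such as `"trnH-psbA+ITS"`).
#' @return An object of class `marker_alignment` with fields `marker`,
#'   `ids`, `species`, `seqs` (uppercase strings) and `length` (columns).
#' @export
marker_alignment <- function(seqs, species, marker = "marker") {
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    abort_bv("`seqs` must be a named character vector (names = specimen ids).",
             "metadata")
  }
  if (anyDuplicated(ids)) {
    abort_bv("specimen ids must be unique within an alignment.", "metadata")
  }
  if (is.data.frame(species)) {
    meta <- species
    miss <- setdiff(ids, meta$specimen_id)
    if (length(miss) > 0) {
      abort_bv(paste0("specimen ids absent from metadata: ",
                      paste(miss, collapse = ", ")), "metadata")
    }
    species <- meta$species[match(ids, meta$specimen_id)]
  }
  if (length(species) != length(seqs)) {
    abort_bv("`species` must match `seqs` in length.", "metadata")
  }
  seqs <- toupper(unname(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    abort_bv(sprintf(
      "aligned sequences must have identical length (saw lengths %s).",
      paste(sort(unique(lens)), collapse = ", ")), "alignment")
  }
  if (any(!grepl("^[ACGTN?-]*$", seqs))) {
    bad <- ids[!grepl("^[ACGTN?-]*$", seqs)]
    abort_bv(paste0("sequences contain characters outside {A,C,G,T,N,-,?}: ",
                    paste(bad, collapse = ", ")), "alignment")
  }
  structure(
    list(marker = marker, ids = ids, species = as.character(species),
         seqs = seqs, length = lens[1]),
    class = "marker_alignment")
}

#' @export
print.marker_alignment <- function(x, ...) {
  cat(sprintf("<marker_alignment> %s: %d sequences x %d bp, %d species\n",
              x$marker, length(x$ids), x$length,
              length(unique(x$species))))
  invisible(x)
}

#' Number of sequences in an alignment
#' @param aln A `marker_alignment`.
#' @return Integer count of rows.
#' @export
n_seq <- function(aln) length(aln$ids)

#' @export
as.matrix.marker_alignment <- function(x, ...) {
  m <- matrix("", nrow = length(x$ids), ncol = x$length,
              dimnames = list(x$ids, NULL))
  if (x$length > 0) {
    m[] <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  }
  m
}

#' Read specimen metadata
#'
#' Reads a CSV with columns `specimen_id`, `species` and (optionally)
#' `genus`, `family`. `genus` defaults to the first word of the species
#' binomial when absent.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `specimen_id`, `species`, `genus`, `family`.
#' @export
read_specimen_metadata <- function(path) {
  meta <- readr::read_csv(path, show_col_types = FALSE,
                          progress = FALSE, col_types = readr::cols(
                            .default = readr::col_character()))
  need <- c("specimen_id", "species")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    abort_bv(paste0("metadata lacks required columns: ",
                    paste(miss, collapse = ", ")), "metadata")
  }
  if (anyDuplicated(meta$specimen_id)) {
    abort_bv("duplicated specimen_id in metadata.", "metadata")
  }
  if (any(is.na(meta$species) | meta$species == "")) {
    abort_bv("species must be non-empty for every specimen.", "metadata")
  }
  if (!"genus" %in% names(meta)) {
    meta$genus <- vapply(strsplit(meta$species, "[ _]"), `[`, "", 1)
  }
  if (!"family" %in% names(meta)) meta$family <- NA_character_
  tibble::as_tibble(meta[, c("specimen_id", "species", "genus", "family")])
}

#' Read an aligned FASTA into a marker alignment
#'
#' FASTA ids must equal `specimen_id` values in the metadata exactly (no
#' description parsing); rows keep FASTA order and sequences are uppercased.
#'
#' @param fasta_path Path to an aligned multi-FASTA file.
#' @param metadata Data frame with `specimen_id` and `species` columns
#'   (see [read_specimen_metadata()]).
#' @param marker Marker name; defaults to the file name without extension.
#' @return A [marker_alignment()].
#' @export
read_alignment <- function(fasta_path, metadata, marker = NULL) {
  if (is.null(marker)) {
    marker <- sub("\\.[^.]*$", "", basename(fasta_path))
  }
  ss <- Biostrings::readBStringSet(fasta_path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  marker_alignment(seqs, metadata, marker = marker)
}

#' Write a marker alignment to FASTA
#' @param aln A `marker_alignment`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(stats::setNames(aln$seqs, aln$ids))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Define a marker-combination scheme
#'
#' A scheme names the markers to concatenate, how many of them a specimen
#' must possess to be retained in the supermatrix, and which character fills
#' the blocks of absent markers.
#'
#' @param markers Character vector of marker names, in concatenation order.
#' @param min_markers_required Integer in `[1, length(markers)]`; a specimen
#'   survives only if it has sequences for at least this many of the
#'   scheme's markers.
#' @param fill_char One of `"?"` or `"N"`; both are treated as missing by
#'   all downstream site comparisons.
#' @return An object of class `combination_scheme`.
#' @export
combination_scheme <- function(markers, min_markers_required = length(markers),
                               fill_char = "?") {
  stopifnot(is.character(markers), length(markers) >= 1)
  if (!fill_char %in% c("?", "N")) {
    abort_bv("fill_char must be '?' or 'N'.", "input")
  }
  min_markers_required <- as.integer(min_markers_required)
  if (min_markers_required < 1 || min_markers_required > length(markers)) {
    abort_bv("min_markers_required must be between 1 and the number of markers.",
             "input")
  }
  structure(list(markers = markers,
                 min_markers_required = min_markers_required,
                 fill_char = fill_char),
            class = "combination_scheme")
}

#' Concatenate marker alignments into a supermatrix
#'
#' Builds a multi-marker supermatrix under a [combination_scheme()]: a
#' specimen is retained when it has sequences for at least
#' `min_markers_required` of the scheme's markers; its absent marker blocks
#' are filled with `fill_char` for the full marker width. Column blocks
#' follow the scheme's marker order and the block layout is retained as the
#' `block_map` attribute.
#'
#' @param alignments List of `marker_alignment` objects covering the
#'   scheme's markers (matched by their `marker` field).
#' @param scheme A [combination_scheme()].
#' @return A `marker_alignment` whose `marker` is the `+`-joined scheme
#'   label, with attribute `block_map` (tibble: marker, start, end).
#' @export
concatenate_markers <- function(alignments, scheme) {
  by_marker <- stats::setNames(alignments,
                               vapply(alignments, `[[`, "", "marker"))
  miss <- setdiff(scheme$markers, names(by_marker))
  if (length(miss) > 0) {
    abort_bv(paste0("scheme markers not supplied: ",
                    paste(miss, collapse = ", ")), "input")
  }
  use <- by_marker[scheme$markers]
  widths <- vapply(use, `[[`, 0L, "length")
  # specimens in order of first appearance across the scheme's alignments
  all_ids <- unique(unlist(lapply(use, `[[`, "ids")))
  have <- vapply(use, function(a) all_ids %in% a$ids,
                 logical(length(all_ids)))
  have <- matrix(have, nrow = length(all_ids))
  keep <- rowSums(have) >= scheme$min_markers_required
  if (!any(keep)) {
    abort_bv("no specimen has enough markers for this scheme.", "filter")
  }
  ids <- all_ids[keep]
  species <- rep(NA_character_, length(ids))
  for (a in use) {
    hit <- match(ids, a$ids)
    species[!is.na(hit)] <- a$species[hit[!is.na(hit)]]
  }
  rows <- vapply(seq_along(ids), function(i) {
    paste0(vapply(seq_along(use), function(j) {
      a <- use[[j]]
      k <- match(ids[i], a$ids)
      if (is.na(k)) strrep(scheme$fill_char, widths[j]) else a$seqs[k]
    }, ""), collapse = "")
  }, "")
  ends <- cumsum(widths)
  bm <- tibble::tibble(marker = scheme$markers,
                       start = ends - widths + 1L, end = ends)
  out <- marker_alignment(stats::setNames(rows, ids), species,
                          marker = paste(scheme$markers, collapse = "+"))
  attr(out, "block_map") <- bm
  out
}

#' Block layout of a concatenated alignment
#' @param aln A supermatrix built by [concatenate_markers()].
#' @return Tibble with columns `marker`, `start`, `end` (1-based, inclusive).
#' @export
block_map <- function(aln) {
  bm <- attr(aln, "block_map")
  if (is.null(bm)) {
    abort_bv("alignment has no block map (not a concatenation).", "input")
  }
  bm
}

#' Write a tabular report to CSV
#'
#' Writes any of the package's report objects (or a plain data frame) as a
#' CSV with a header row and stable column order; report objects are passed
#' through their `tidy()` method first. Round-trips through [read_tables()].
#'
#' @param report A data frame or an object with a `tidy()` method.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tables <- function(report, path) {
  df <- if (is.data.frame(report)) report else generics::tidy(report)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_tables()]
#' @param path CSV path.
#' @return A tibble.
#' @export
read_tables <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
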