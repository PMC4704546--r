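# 'Best close match' identification test: empirical 95% threshold on the
# intraspecific distance distribution, then leave-one-out classification of
# every specimen as correct / ambiguous / incorrect / no_match.

BCM_CATEGORIES <- c("correct", "ambiguous", "incorrect", "no_match")

#' Best-close-match distance threshold
#'
#' The threshold is the smallest observed intraspecific distance `d` such
#' that at least `percentile` of all intraspecific distances are `<= d`
#' (empirical-quantile convention on observed values).
#'
#' @param intra Non-empty numeric vector of intraspecific p-distances.
#' @param percentile Coverage proportion, default 0.95.
#' @return An object of class `bcm_threshold` with fields `value`,
#'   `percentile`, `n_intra_pairs`.
#' @export
bcm_threshold <- function(intra, percentile = 0.95) {
  intra <- intra[!is.na(intra)]
  if (length(intra) == 0) {
    abort_bv("no intraspecific distances; cannot set a threshold.", "input")
  }
  s <- sort(intra)
  ecdf_vals <- seq_along(s) / length(s)
  value <- s[which(ecdf_vals >= percentile)[1]]
  structure(list(value = value, percentile = percentile,
                 n_intra_pairs = length(intra)),
            class = "bcm_threshold")
}

#' @export
print.bcm_threshold <- function(x, ...) {
  cat(sprintf("<bcm_threshold> %.6g (%.0f%% of %d intraspecific pairs)\n",
              x$value, 100 * x$percentile, x$n_intra_pairs))
  invisible(x)
}

#' Classify one query specimen by best close match
#'
#' Candidates are all other specimens whose (defined) distance to the query
#' is at or below the threshold. With no candidate the query is `no_match`;
#' otherwise the tie set holds the candidates within `tie_tol` of the
#' minimum candidate distance: all conspecific gives `correct`, a mixture
#' gives `ambiguous`, none conspecific gives `incorrect`.
#'
#' @param query_id Specimen id present in `m`.
#' @param m A `p_dist_matrix` with at least two specimens.
#' @param threshold A [bcm_threshold()] or a bare numeric distance.
#' @param tie_tol Non-negative distance within which candidate distances are
#'   considered tied with the minimum (default 0, exact ties only).
#' @return One-row tibble: `specimen_id`, `species`, `category`,
#'   `best_match_id`, `best_match_species`, `best_match_distance`.
#' @export
classify_query <- function(query_id, m, threshold, tie_tol = 0) {
  if (!query_id %in% m$labels) {
    abort_bv(sprintf("query '%s' not in distance matrix.", query_id), "lookup")
  }
  tval <- if (inherits(threshold, "bcm_threshold")) threshold$value else threshold
  d <- m$d[query_id, ]
  d <- d[names(d) != query_id]
  sp <- m$species[names(d)]
  qsp <- unname(m$species[query_id])
  defined <- !is.na(d)
  cand <- defined & d <= tval
  # nearest defined specimen, for reporting (ties broken by id order)
  nn <- if (any(defined)) {
    dd <- d[defined]
    names(sort(dd))[1]
  } else NA_character_
  if (!any(cand)) {
    category <- "no_match"
    best <- nn
  } else {
    dmin <- min(d[cand])
    tie <- names(d)[cand & d <= dmin + tie_tol]
    consp <- sp[tie] == qsp
    category <- if (all(consp)) "correct" else if (any(consp)) "ambiguous" else "incorrect"
    # report the closest tie-set member, preferring a conspecific one
    ord <- tie[order(!consp, d[tie], tie)]
    best <- ord[1]
  }
  tibble::tibble(
    specimen_id = query_id, species = qsp, category = category,
    best_match_id = best,
    best_match_species = if (is.na(best)) NA_character_ else unname(sp[best]),
    best_match_distance = if (is.na(best)) NA_real_ else unname(d[best]))
}

#' Best-close-match identification report
#'
#' Runs the full leave-one-out test: the threshold is computed from all
#' intraspecific distances of the matrix, then every specimen is queried
#' against all others and classified. Category percentages are reported both
#' over all queries and excluding singleton-species queries (which can never
#' be `correct` since no conspecific exists).
#'
#' @param x A [marker_alignment()] or a `p_dist_matrix`; at least two
#'   species must be represented.
#' @param percentile Threshold coverage proportion (default 0.95).
#' @param tie_tol Tie tolerance passed to [classify_query()].
#' @return An object of class `bcm_report` with fields `per_query`,
#'   `summary`, `threshold`, `n_queries`, `n_singleton_queries`.
#' @export
bcm_summary <- function(x, percentile = 0.95, tie_tol = 0) {
  m <- if (inherits(x, "p_dist_matrix")) x else pairwise_matrix(x)
  if (length(unique(m$species)) < 2) {
    abort_bv("need at least 2 species for an identification test.", "input")
  }
  part <- partition_distances(m)
  thr <- bcm_threshold(part$intra, percentile)
  per_query <- purrr::map_dfr(m$labels, classify_query,
                              m = m, threshold = thr, tie_tol = tie_tol)
  sp_counts <- table(m$species)
  per_query$singleton_species <- as.vector(sp_counts[per_query$species] == 1)
  n_all <- nrow(per_query)
  n_single <- sum(per_query$singleton_species)
  summary <- tibble::tibble(category = factor(BCM_CATEGORIES, BCM_CATEGORIES)) |>
    dplyr::left_join(
      per_query |>
        dplyr::group_by(category = factor(.data$category, BCM_CATEGORIES)) |>
        dplyr::summarise(
          n = dplyr::n(),
          n_excl_singletons = sum(!.data$singleton_species),
          .groups = "drop"),
      by = "category") |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      n_excl_singletons = dplyr::coalesce(.data$n_excl_singletons, 0L),
      pct = 100 * .data$n / n_all,
      pct_excl_singletons =
        if (n_all - n_single > 0) 100 * .data$n_excl_singletons / (n_all - n_single)
        else NA_real_)
  structure(list(per_query = per_query, summary = summary, threshold = thr,
                 n_queries = n_all, n_singleton_queries = n_single,
                 marker = m$marker),
            class = "bcm_report")
}

#' @export
print.bcm_report <- function(x, ...) {
  cat(sprintf("<bcm_report> %s: %d queries (%d singleton-species), threshold %.6g\n",
              x$marker, x$n_queries, x$n_singleton_queries, x$threshold$value))
  print(x$summary)
  invisible(x)
}

#' @describeIn bcm_summary Per-query classifications as a tibble.
#' @method tidy bcm_report
#' @export
tidy.bcm_report <- function(x, ...) x$per_query

#' @describeIn bcm_summary One-row summary with category percentages and the
#'   threshold used.
#' @method glance bcm_report
#' @export
glance.bcm_report <- function(x, ...) {
  pct <- stats::setNames(x$summary$pct, paste0("pct_", x$summary$category))
  dplyr::bind_cols(
    tibble::tibble(marker = x$marker, n_queries = x$n_queries,
                   n_singleton_queries = x$n_singleton_queries,
                   threshold = x$threshold$value,
                   threshold_percentile = x$threshold$percentile),
    tibble::as_tibble(as.list(pct)))
}

#' @describeIn bcm_summary Bar chart of identification-category percentages.
#' @param object A `bcm_report`.
#' @method autoplot bcm_report
#' @export
autoplot.bcm_report <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$category, y = .data$pct)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = NULL, y = "% of queries",
                  title = object$marker) +
    ggplot2::theme_minimal()
}
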