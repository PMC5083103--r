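# Gene-set over-representation for a significant-protein list: Fisher's
# exact test with odds ratio per set, the reporting filter used for the
# pathway tables (overlap > 1 in >= 1 age data set, p < 0.05, optional
# named exclusions), and the conservative EASE variant (one success
# jackknifed out of the overlap cell).

.enrichOne <- function(query, set, universe, alternative) {
  set <- intersect(set, universe)
  a <- length(intersect(query, set))
  b <- length(query) - a
  cc <- length(set) - a
  dd <- length(universe) - length(query) - cc
  ft <- fisherExactTest(rbind(c(a, b), c(cc, dd)), alternative = alternative)
  list(overlap = a, set_size = length(set), p = ft$p.value,
       odds_ratio = ft$odds.ratio, or_flagged = ft$or.flagged)
}

#' Gene-set over-representation by Fisher's exact test
#'
#' Per set, builds the 2x2 table (in query & in set, in query & not, not in
#' query & in set, neither) over the measured universe and applies
#' \link{fisherExactTest}. The default one-sided ("greater") alternative
#' tests over-representation; set \code{alternative = "two.sided"} for the
#' symmetric test. Sets are intersected with the universe first; sets
#' disjoint from it are skipped with a warning.
#'
#' @param query character vector of significant proteins (must be a subset
#'   of \code{universe}).
#' @param sets named list of member vectors (e.g. from \link{readGmt}).
#' @param universe all quantified proteins (the default measured-universe
#'   convention; supply a broader universe to change it).
#' @param alternative sidedness of the Fisher test.
#' @return data.frame sorted by p: \code{set}, \code{overlap},
#'   \code{set_size}, \code{query_size}, \code{universe_size}, \code{p},
#'   \code{odds_ratio}, \code{or_flagged}, \code{minus_log10_p}.
#' @export
enrich <- function(query, sets, universe,
                   alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  query <- unique(query)
  if (!length(universe)) .stopf("universe is empty")
  extra <- setdiff(query, universe)
  if (length(extra)) {
    .stopf("query protein(s) outside the universe: %s",
           paste(head(extra, 5), collapse = ", "))
  }
  keep <- vapply(sets, function(s) length(intersect(s, universe)) > 0,
                 logical(1))
  if (any(!keep)) {
    .warnf("skipping %d set(s) disjoint from the universe", sum(!keep))
  }
  sets <- sets[keep]
  rows <- lapply(names(sets), function(nm) {
    r <- .enrichOne(query, unique(sets[[nm]]), universe, alternative)
    data.frame(set = nm, overlap = r$overlap, set_size = r$set_size,
               query_size = length(query), universe_size = length(universe),
               p = r$p, odds_ratio = r$odds_ratio,
               or_flagged = r$or_flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$minus_log10_p <- -log10(out$p)
  out[order(out$p, out$set), , drop = FALSE]
}

#' Pathway-table reporting filter
#'
#' Keeps sets represented by more than one protein in at least one age
#' data set and with p < \code{pCut}; an optional name list (e.g.
#' disease-specific pathways) is excluded. When per-age overlap columns
#' (\code{overlap_newborn}, \code{overlap_adult}) are present the overlap
#' rule checks their maximum, otherwise the single \code{overlap} column.
#'
#' @param results data.frame from \link{enrich} (optionally with per-age
#'   overlap columns).
#' @param pCut p-value cutoff (default 0.05).
#' @param minOverlap minimal overlap in at least one age set (default 2,
#'   i.e. "more than one protein").
#' @param exclude character vector of set names to drop.
#' @return filtered data.frame.
#' @export
table3Filter <- function(results, pCut = 0.05, minOverlap = 2,
                         exclude = NULL) {
  ageCols <- intersect(c("overlap_newborn", "overlap_adult"),
                       colnames(results))
  ov <- if (length(ageCols)) {
    do.call(pmax, results[ageCols])
  } else {
    results$overlap
  }
  keep <- ov >= minOverlap & results$p < pCut
  if (!is.null(exclude)) keep <- keep & !(results$set %in% exclude)
  results[keep, , drop = FALSE]
}

#' EASE-score over-representation (jackknifed Fisher)
#'
#' The conservative DAVID-style variant: one success is removed from the
#' overlap cell before the one-sided Fisher test, so single-protein
#' overlaps can never be significant. EASE p >= Fisher p on every table.
#'
#' @inheritParams enrich
#' @param alpha significance threshold on the EASE score (default 0.05).
#' @return data.frame as \link{enrich} plus \code{significant} at
#'   \code{alpha}.
#' @export
easeVariant <- function(query, sets, universe, alpha = 0.05) {
  universe <- unique(universe)
  query <- unique(query)
  extra <- setdiff(query, universe)
  if (length(extra)) {
    .stopf("query protein(s) outside the universe: %s",
           paste(head(extra, 5), collapse = ", "))
  }
  keep <- vapply(sets, function(s) length(intersect(s, universe)) > 0,
                 logical(1))
  sets <- sets[keep]
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    a <- length(intersect(query, set))
    b <- length(query) - a
    cc <- length(set) - a
    dd <- length(universe) - length(query) - cc
    aj <- max(0, a - 1)
    ft <- fisherExactTest(rbind(c(aj, b), c(cc, dd)),
                          alternative = "greater")
    data.frame(set = nm, overlap = a, set_size = length(set),
               query_size = length(query), universe_size = length(universe),
               p = ft$p.value, odds_ratio = ft$odds.ratio,
               or_flagged = ft$or.flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$minus_log10_p <- -log10(out$p)
  out$significant <- out$p < alpha
  out[order(out$p, out$set), , drop = FALSE]
}
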