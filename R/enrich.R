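#' Build a region-set enrichment catalogue
#'
#' A catalogue is a named list of `RegionSet`s with optional metadata and a
#' universe region set defining the enrichment background. Enrichment is
#' counted at the level of universe regions.
#'
#' @param sets Named list of `RegionSet` objects.
#' @param universe A `RegionSet` giving the background regions.
#' @param meta Optional `data.frame` with columns `name`, `collection`,
#'   `description` (row per catalogue entry).
#' @return An object of class `EnrichmentCatalog`.
#' @export
enrichment_catalog <- function(sets, universe, meta = NULL) {
  if (length(sets) == 0L) stop_mw("empty catalogue")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- vapply(sets, `[[`, "", "name")
  lapply(sets, function(s) {
    if (!inherits(s, "RegionSet")) stop_mw("catalogue entries must be RegionSets")
  })
  if (!inherits(universe, "RegionSet") || length(universe) == 0L)
    stop_mw("universe must be a nonempty RegionSet")
  if (is.null(meta))
    meta <- data.frame(name = names(sets), collection = "default",
                       description = "", stringsAsFactors = FALSE)
  structure(list(sets = sets, universe = universe, meta = meta),
            class = "EnrichmentCatalog")
}

#' Load an enrichment catalogue from a directory
#'
#' Expects an `index.tsv` with columns `file`, `name`, `collection`,
#' `description`, one BED file per entry, and a `universe.bed`.
#'
#' @param dir Catalogue directory.
#' @return An `EnrichmentCatalog`.
#' @export
load_catalog <- function(dir) {
  idx <- utils::read.table(file.path(dir, "index.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  sets <- lapply(seq_len(nrow(idx)), function(i)
    load_region_set(file.path(dir, idx$file[i]), name = idx$name[i]))
  names(sets) <- idx$name
  enrichment_catalog(sets,
                     universe = load_region_set(file.path(dir, "universe.bed"),
                                                name = "universe"),
                     meta = idx[, c("name", "collection", "description")])
}

#' One-sided enrichment p-value of a 2x2 overlap table
#'
#' The one-sided Fisher exact test for enrichment of a 2x2 contingency
#' table equals the hypergeometric upper tail: with `N` universe regions of
#' which `K` are in the catalogue set, a query of `n` regions, and `a`
#' query regions in the set, the p-value is `P(X >= a)` for
#' `X ~ Hypergeometric(N, K, n)`.
#'
#' @param a Overlap count (query regions in the set).
#' @param K Set size within the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return The enrichment p-value in (0, 1].
#' @export
fisher_enrichment_p <- function(a, K, n, N) {
  stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
}

#' Region-set enrichment of a query against a catalogue
#'
#' LOLA-style enrichment: counts universe regions by membership in the
#' query (any base-pair overlap with a query region) and in each catalogue
#' set, tests each 2x2 table with the one-sided Fisher exact test
#' (enrichment direction; two-sided optional), computes the odds ratio with
#' a 0.5 Haldane correction when any cell is zero, and ranks entries by the
#' worst (maximum) of their p-value rank, odds-ratio rank, and support
#' rank. Query regions that do not overlap the universe are dropped (count
#' reported in the `"n_query_dropped"` attribute).
#'
#' @param query A `RegionSet` of regions of interest (e.g. DMRs or DVRs).
#' @param catalog An `EnrichmentCatalog`.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return A `data.frame` of class `EnrichmentResult`, one row per
#'   catalogue entry with columns `name`, `collection`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `log_odds`, `fisher_p`, `rank_p`, `rank_or`,
#'   `rank_support`, `max_rank`, ordered by `max_rank`.
#' @export
region_enrichment <- function(query, catalog,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  uni <- regions_to_granges(catalog$universe)
  qgr <- regions_to_granges(query)
  q_hit <- suppressWarnings(IRanges::overlapsAny(qgr, uni))
  n_dropped <- sum(!q_hit)
  if (!any(q_hit))
    stop_mw("no query region overlaps the universe")
  in_query <- suppressWarnings(IRanges::overlapsAny(uni, qgr[q_hit]))
  N <- length(uni)
  n_query <- sum(in_query)
  res <- lapply(names(catalog$sets), function(nm) {
    in_set <- suppressWarnings(
      IRanges::overlapsAny(uni, regions_to_granges(catalog$sets[[nm]])))
    a <- sum(in_query & in_set)
    b <- n_query - a
    cc <- sum(!in_query & in_set)
    d <- N - a - b - cc
    p <- if (alternative == "greater") {
      fisher_enrichment_p(a, a + cc, n_query, N)
    } else {
      stats::fisher.test(matrix(c(a, b, cc, d), 2L), alternative = "two.sided")$p.value
    }
    hald <- if (any(c(a, b, cc, d) == 0L)) 0.5 else 0
    or <- ((a + hald) * (d + hald)) / ((b + hald) * (cc + hald))
    data.frame(name = nm, a = a, b = b, c = cc, d = d,
               odds_ratio = or, log_odds = log2(or), fisher_p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$collection <-
    catalog$meta$collection[match(out$name, catalog$meta$name)]
  out$rank_p <- rank(out$fisher_p, ties.method = "min")
  out$rank_or <- rank(-out$odds_ratio, ties.method = "min")
  out$rank_support <- rank(-out$a, ties.method = "min")
  out$max_rank <- pmax(out$rank_p, out$rank_or, out$rank_support)
  out <- out[order(out$max_rank, out$fisher_p, seq_len(nrow(out))), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  attr(out, "n_query_dropped") <- n_dropped
  attr(out, "universe_size") <- N
  attr(out, "query_size") <- n_query
  out
}
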