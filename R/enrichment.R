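#' Hypergeometric term enrichment
#'
#' Local replacement for a web-based over-representation service: for each
#' term, the upper-tail hypergeometric probability of observing at least
#' the seen overlap between the query gene list and the term, drawn from a
#' finite gene universe. With population N = |universe|, successes
#' K = |term ∩ universe|, draws n = |query ∩ universe| and observed
#' k = |query ∩ term ∩ universe|, p = P[X >= k]. P-values are adjusted by
#' Benjamini-Hochberg across all tested terms, and the ratio of
#' intersection size to term size is reported for ranking
#' (see [rankTerms()]).
#'
#' Query symbols outside the universe are dropped with a message; terms
#' with no member in the universe are skipped (also with a message).
#'
#' @param queryGenes character vector of gene symbols (e.g. the filtered
#'   hotspot gene list).
#' @param terms named list of member-symbol vectors, as from [readGmt()].
#' @param universeGenes the gene universe; by convention, all annotation
#'   genes after family filtering.
#' @return `data.frame` with columns `term_id`, `term_name`, `term_size`,
#'   `intersection_size`, `ratio`, `p_value`, `p_adjusted`, one row per
#'   tested term.
#' @export
hypergeometricEnrichment <- function(queryGenes, terms, universeGenes) {
    universe <- unique(as.character(universeGenes))
    if (!length(universe)) stop("empty gene universe")
    query <- unique(as.character(queryGenes))
    outside <- setdiff(query, universe)
    if (length(outside))
        message(length(outside),
                " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
    if (!length(query))
        stop("no query genes remain after intersecting with the universe")
    desc <- attr(terms, "description")
    N <- length(universe)
    n <- length(query)
    rows <- lapply(names(terms), function(id) {
        members <- intersect(unique(terms[[id]]), universe)
        K <- length(members)
        if (K == 0) return(NULL)
        k <- length(intersect(members, query))
        p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(term_id = id,
                   term_name = if (!is.null(desc)) unname(desc[id]) else id,
                   term_size = K, intersection_size = k,
                   ratio = k / K, p_value = p,
                   stringsAsFactors = FALSE)
    })
    skipped <- sum(vapply(rows, is.null, logical(1)))
    if (skipped)
        message(skipped, " term(s) with no member in the universe skipped")
    res <- do.call(rbind, rows)
    if (is.null(res)) stop("no testable terms")
    res$p_adjusted <- p.adjust(res$p_value, method = "BH")
    rownames(res) <- NULL
    res
}

#' Rank enriched terms by intersection ratio
#'
#' Filters to significant terms (adjusted p below `alpha`), sorts by the
#' ratio of intersection size to term size, descending, and keeps the top
#' `topK` (default 10) — the selection rule used for the bubble-graph
#' summary. Ties are broken by smaller p-value, then term id.
#'
#' @param results `data.frame` from [hypergeometricEnrichment()].
#' @param topK number of terms to keep (default 10).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return the selected rows, in rank order (possibly fewer than `topK`).
#' @export
rankTerms <- function(results, topK = 10, alpha = 0.05) {
    stopifnot(topK >= 1)
    sig <- results[results$p_adjusted < alpha, , drop = FALSE]
    ord <- order(-sig$ratio, sig$p_value, sig$term_id)
    out <- head(sig[ord, , drop = FALSE], topK)
    rownames(out) <- NULL
    out
}
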