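#' @include AllGenerics.R
NULL

#' HotspotSet: windows in the top tail of the SCNA recurrence rate
#'
#' Result container produced by [callHotspots()]. Holds the full per-window
#' \eqn{\hat\lambda} table and the subset of windows called hotspots, ranked
#' by decreasing \eqn{\hat\lambda} (rank 1 = largest; ties at the cut broken
#' by genome order, i.e. smaller window index wins). After
#' [annotateGenes()] each hotspot carries its overlapping gene symbols
#' (`genes_all`) and, after family filtering, `genes_filtered`.
#'
#' @slot windows `GRanges` of every window with metadata columns
#'   `window_index`, `n_samples`, `lambda_hat`, `log2_lambda`, `is_hotspot`
#'   and `rank` (NA for non-hotspots).
#' @slot hotspots `GRanges` of the called hotspots in rank order.
#' @slot fraction numeric, the tail fraction used (default 0.05).
#' @slot minLambda numeric, the minimum \eqn{\hat\lambda} among hotspots —
#'   the natural Manhattan-plot threshold line.
#' @seealso [callHotspots()], [annotateGenes()], [filterGeneList()]
#' @export
setClass("HotspotSet",
    representation(windows = "GRanges", hotspots = "GRanges",
                   fraction = "numeric", minLambda = "numeric"))

setValidity("HotspotSet", function(object) {
    msg <- NULL
    if (object@fraction <= 0 || object@fraction >= 1)
        msg <- c(msg, "fraction must be in (0, 1)")
    hs <- object@hotspots
    if (length(hs)) {
        if (is.null(mcols(hs)$lambda_hat) || is.null(mcols(hs)$rank))
            msg <- c(msg, "hotspots must carry lambda_hat and rank")
        else if (is.unsorted(mcols(hs)$rank))
            msg <- c(msg, "hotspots must be in rank order")
    }
    if (is.null(msg)) TRUE else msg
})

#' @describeIn HotspotSet the called hotspot windows (`GRanges`, rank order).
#' @param x a `HotspotSet`.
#' @export
setMethod("hotspots", "HotspotSet", function(x) x@hotspots)

#' @describeIn HotspotSet the full per-window rate table as a `data.frame`
#'   (chrom, start, end, window_index, n_samples, lambda_hat, log2_lambda,
#'   is_hotspot, rank) ready for [writeTable()].
#' @export
setMethod("lambdaTable", "HotspotSet", function(x) {
    w <- x@windows
    data.frame(chrom = as.character(seqnames(w)),
               start = start(w), end = end(w),
               window_index = mcols(w)$window_index,
               n_samples = mcols(w)$n_samples,
               lambda_hat = mcols(w)$lambda_hat,
               log2_lambda = mcols(w)$log2_lambda,
               is_hotspot = mcols(w)$is_hotspot,
               rank = mcols(w)$rank,
               stringsAsFactors = FALSE)
})

setMethod("show", "HotspotSet", function(object) {
    cat("HotspotSet:", length(object@hotspots), "hotspots from",
        length(object@windows), "windows",
        sprintf("(top %.1f%%)\n", 100 * object@fraction))
    cat("  minimum hotspot lambda:", format(object@minLambda, digits = 4), "\n")
    ga <- mcols(object@hotspots)$genes_all
    if (!is.null(ga)) {
        gf <- mcols(object@hotspots)$genes_filtered
        cat("  annotated genes:", length(unique(unlist(ga))),
            "before /", length(unique(unlist(gf))), "after family filtering\n")
    }
})

#' Minimum lambda among called hotspots
#'
#' The smallest \eqn{\hat\lambda} of any hotspot: the decision boundary of
#' the top-tail rule and the threshold line drawn on Manhattan plots.
#'
#' @param x a [HotspotSet].
#' @return a single numeric value.
#' @export
minHotspotLambda <- function(x) {
    stopifnot(is(x, "HotspotSet"))
    x@minLambda
}

#' Annotate hotspots with overlapping genes
#'
#' A gene is assigned to a hotspot when its interval overlaps the hotspot
#' window under the same strict-inequality half-open semantics used for
#' segment counting (any shared base; abutting intervals do not overlap).
#' Gene symbols are then passed through [filterGeneList()] to remove
#' hyper-polymorphic families, populating `genes_filtered`.
#'
#' @param x a [HotspotSet].
#' @param genes `GRanges` of gene intervals with a `symbol` metadata column,
#'   as returned by [readBedGenes()].
#' @param extraExclude optional character vector of additional symbols to
#'   exclude during filtering (e.g. a curated HLA list).
#' @return `x` with `genes_all` and `genes_filtered` (both `CharacterList`)
#'   on its hotspot ranges.
#' @export
setMethod("annotateGenes", "HotspotSet", function(x, genes, extraExclude = NULL) {
    stopifnot(is(genes, "GRanges"), !is.null(mcols(genes)$symbol))
    hs <- x@hotspots
    ov <- findOverlaps(genes, hs, ignore.strand = TRUE)
    all_list <- vector("list", length(hs))
    for (i in seq_along(hs)) all_list[[i]] <- character(0)
    sp <- split(as.character(mcols(genes)$symbol[S4Vectors::queryHits(ov)]),
                factor(S4Vectors::subjectHits(ov), levels = seq_along(hs)))
    all_list <- lapply(sp, function(g) sort(unique(g)))
    mcols(hs)$genes_all <- CharacterList(all_list)
    mcols(hs)$genes_filtered <- CharacterList(
        lapply(all_list, filterGeneList, extraExclude = extraExclude))
    x@hotspots <- hs
    x
})

#' Hotspot-gene table
#'
#' Long-format export of an annotated [HotspotSet]: one row per
#' (hotspot, gene) pair, with a column flagging genes that survived the
#' family filter.
#'
#' @param x an annotated [HotspotSet].
#' @return a `data.frame` (chrom, start, end, window_index, rank,
#'   lambda_hat, symbol, retained).
#' @export
hotspotGeneTable <- function(x) {
    stopifnot(is(x, "HotspotSet"))
    hs <- hotspots(x)
    if (is.null(mcols(hs)$genes_all))
        stop("hotspots are not annotated; call annotateGenes() first")
    rows <- lapply(seq_along(hs), function(i) {
        g <- mcols(hs)$genes_all[[i]]
        if (!length(g)) return(NULL)
        data.frame(chrom = as.character(seqnames(hs))[i],
                   start = start(hs)[i], end = end(hs)[i],
                   window_index = mcols(hs)$window_index[i],
                   rank = mcols(hs)$rank[i],
                   lambda_hat = mcols(hs)$lambda_hat[i],
                   symbol = g,
                   retained = g %in% mcols(hs)$genes_filtered[[i]],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(chrom = character(), start = integer(),
                          end = integer(), window_index = integer(),
                          rank = integer(), lambda_hat = numeric(),
                          symbol = character(), retained = logical())
    out
}
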