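#' @include AllGenerics.R
NULL

#' WindowCounts: per-window, per-sample SCNA overlap counts
#'
#' A `WindowCounts` is a [SummarizedExperiment::RangedSummarizedExperiment]
#' whose rows are genomic windows (see [tileWindows()]), whose columns are
#' cohort samples, and whose single assay `"counts"` holds the number of
#' SCNA segments of each sample overlapping each window. Samples with no
#' segments at all appear as all-zero columns, so that the Poisson rate
#' \eqn{\lambda} is estimated over the full cohort. The width class the
#' counts were computed on (`"all"`, `"set1"` or `"set2"`) is carried in
#' `metadata(x)$widthClass`.
#'
#' @slot .. inherits all slots from `RangedSummarizedExperiment`.
#' @seealso [countWindowOverlaps()], [estimateLambda()], [callHotspots()]
#' @aliases WindowCounts
#' @export
setClass("WindowCounts", contains = "RangedSummarizedExperiment")

setValidity("WindowCounts", function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(cnt != round(cnt))) msg <- c(msg, "counts must be integers")
    }
    if (is.null(mcols(rowRanges(object))$window_index))
        msg <- c(msg, "rowRanges must carry a 'window_index' column")
    if (is.null(msg)) TRUE else msg
})

#' Construct a WindowCounts object
#'
#' Usually produced by [countWindowOverlaps()]; the constructor is exported
#' for programmatic assembly (e.g. from simulated count matrices).
#'
#' @param counts integer matrix, windows x samples.
#' @param windows `GRanges` of windows with a `window_index` metadata
#'   column, one range per row of `counts`.
#' @param widthClass which segment width class the counts describe:
#'   `"all"`, `"set1"` (> threshold) or `"set2"` (<= threshold).
#' @return A [WindowCounts] object.
#' @export
WindowCounts <- function(counts, windows, widthClass = "all") {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    se <- SummarizedExperiment(assays = list(counts = counts),
                               rowRanges = windows)
    metadata(se)$widthClass <- widthClass
    new("WindowCounts", se)
}

#' @describeIn WindowCounts the width class label the counts were computed on.
#' @param x a `WindowCounts` object.
#' @export
setMethod("widthClass", "WindowCounts", function(x) metadata(x)$widthClass)

setMethod("show", "WindowCounts", function(object) {
    cnt <- SummarizedExperiment::assay(object, "counts")
    cat("WindowCounts:", nrow(object), "windows x", ncol(object), "samples",
        sprintf("(width class: %s)\n", widthClass(object)))
    cat("  total counted overlaps:", sum(cnt), "\n")
    if (!is.null(rowData(object)$lambda_hat))
        cat("  lambda estimated; max lambda_hat =",
            format(max(rowData(object)$lambda_hat), digits = 4), "\n")
})
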