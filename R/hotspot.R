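#' @include windowCounts-class.R hotspotSet-class.R
NULL

#' Classify segments by width
#'
#' Splits segments at the width threshold used throughout the analysis:
#' Set1 holds large-scale SCNAs with width strictly greater than the
#' threshold (default 100 kb), Set2 those with width less than or equal to
#' it. The two sets partition the input and are analysed as independent
#' runs of the same pipeline.
#'
#' @param segments `GRanges` of segments (see [readSeg()]).
#' @param thresholdBp width threshold in bp (default 1e5).
#' @return a list with elements `set1` and `set2` (`GRanges`).
#' @examples
#' gr <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(1, c(100000, 100001)))
#' gr$sample_id <- c("a", "a")
#' lengths(classifyByWidth(gr))  # set1 = 1, set2 = 1
#' @export
classifyByWidth <- function(segments, thresholdBp = 1e5) {
    stopifnot(thresholdBp > 0)
    big <- width(segments) > thresholdBp
    message(sum(big), " segment(s) in Set1 (> ", thresholdBp, " bp), ",
            sum(!big), " in Set2 (<= ", thresholdBp, " bp)")
    list(set1 = segments[big], set2 = segments[!big])
}

#' Count segment-window overlaps per sample
#'
#' Builds the Poisson data: a windows x samples matrix in which entry
#' (w, s) is the number of segments of sample s overlapping window w. A
#' segment overlaps a window when its start lies before the window end and
#' its end after the window start (equivalently: the intervals share at
#' least one base; abutting half-open intervals do not count). A segment
#' spanning k windows contributes 1 to each of them.
#'
#' @param segments `GRanges` with a `sample_id` metadata column.
#' @param windows `GRanges` from [tileWindows()].
#' @param samples the cohort sample set (columns of the result). Defaults
#'   to the sorted unique sample ids present in `segments`; pass the full
#'   cohort explicitly so that samples whose segments were all filtered out
#'   still appear as all-zero columns.
#' @param widthClass label recorded on the result (`"all"`, `"set1"`,
#'   `"set2"`).
#' @return a [WindowCounts] object.
#' @export
countWindowOverlaps <- function(segments, windows,
                                samples = NULL, widthClass = "all") {
    if (is.null(mcols(segments)$sample_id))
        stop("segments need a 'sample_id' metadata column")
    if (is.null(samples))
        samples <- sort(unique(as.character(mcols(segments)$sample_id)))
    samples <- as.character(samples)
    if (!length(samples)) stop("empty sample set")
    ov <- findOverlaps(segments, windows, ignore.strand = TRUE)
    si <- match(as.character(mcols(segments)$sample_id)[S4Vectors::queryHits(ov)],
                samples)
    wi <- S4Vectors::subjectHits(ov)
    keep <- !is.na(si)
    counts <- matrix(0L, nrow = length(windows), ncol = length(samples),
                     dimnames = list(NULL, samples))
    if (any(keep)) {
        tab <- table(factor(wi[keep], levels = seq_along(windows)),
                     factor(si[keep], levels = seq_along(samples)))
        counts[] <- as.integer(tab)
    }
    WindowCounts(counts, windows, widthClass = widthClass)
}

#' Poisson log-likelihood of a rate given window counts
#'
#' \eqn{\ell(\lambda) = \sum_s [x_s \log\lambda - \lambda - \log(x_s!)]},
#' the function maximized by [estimateLambdaMLE()].
#'
#' @param lambda candidate rate (> 0).
#' @param counts non-negative integer counts, one per sample.
#' @return the log-likelihood value.
#' @export
poissonLogLik <- function(lambda, counts) {
    sum(counts * log(lambda) - lambda - lfactorial(counts))
}

#' Maximum-likelihood Poisson rate for one window
#'
#' Estimates the per-sample SCNA rate \eqn{\lambda} of a window from its
#' cohort counts. The closed-form maximizer of the Poisson log-likelihood
#' is the sample mean; `method = "numeric"` instead maximizes
#' [poissonLogLik()] with [stats::optimize()], and the two routes agree to
#' within 1e-6 relative. All cohort samples enter the estimate, including
#' zero-count ones — dropping them would bias \eqn{\hat\lambda} upward.
#'
#' @param counts non-negative integer counts, one per sample.
#' @param method `"closed"` (sample mean, default) or `"numeric"`.
#' @return the estimated rate (>= 0); exactly 0 for all-zero counts.
#' @examples
#' estimateLambdaMLE(c(1, 2, 3))  # 2
#' @export
estimateLambdaMLE <- function(counts, method = c("closed", "numeric")) {
    method <- match.arg(method)
    if (!length(counts)) stop("at least one sample is required")
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be non-negative integers")
    m <- mean(counts)
    if (method == "closed" || m == 0) return(m)
    upper <- max(counts) + 1
    opt <- optimize(poissonLogLik, interval = c(1e-12, upper),
                    counts = counts, maximum = TRUE, tol = 1e-10)
    opt$maximum
}

#' Estimate lambda for every window
#'
#' Adds `lambda_hat` (the per-window MLE over all cohort samples) and
#' `log2_lambda` (NA where `lambda_hat` is 0; zero-rate windows are dropped
#' from log-scale summaries rather than pseudo-counted) to the row data of
#' a [WindowCounts] object.
#'
#' @param x a [WindowCounts].
#' @param method passed to [estimateLambdaMLE()] (`"closed"` by default;
#'   the numeric route exists as a cross-check and is equivalent).
#' @return `x` with `lambda_hat`, `log2_lambda` and `n_samples` row data.
#' @export
setMethod("estimateLambda", "WindowCounts", function(x, method = "closed") {
    cnt <- SummarizedExperiment::assay(x, "counts")
    lam <- if (method == "closed") rowMeans(cnt)
           else apply(cnt, 1, estimateLambdaMLE, method = "numeric")
    rowData(x)$lambda_hat <- lam
    rowData(x)$log2_lambda <- ifelse(lam > 0, log2(lam), NA_real_)
    rowData(x)$n_samples <- ncol(cnt)
    x
})

.nHotspots <- function(n, fraction) {
    # round half up, so 144.85 -> 145 and exact .5 cases go to the larger set
    k <- floor(fraction * n + 0.5)
    if (fraction * n < 1) {
        warning("fraction * N < 1; returning a single hotspot")
        k <- 1
    }
    as.integer(k)
}

#' Call hotspots from per-window rate estimates
#'
#' Selects the windows whose \eqn{\hat\lambda} lies in the top tail
#' (default 5\%) genome-wide. The number of hotspots is
#' round-half-up(fraction x N) — 145 of 2,897 windows at 5\% — and ties at
#' the cut are broken by genome order (smaller window index wins). The
#' minimum \eqn{\hat\lambda} among the called hotspots is recorded as the
#' decision threshold.
#'
#' @param x a [WindowCounts] (lambda is estimated on the fly if absent).
#' @param fraction tail fraction in (0, 1); default 0.05.
#' @return a [HotspotSet].
#' @export
setMethod("callHotspots", "WindowCounts", function(x, fraction = 0.05) {
    if (is.null(rowData(x)$lambda_hat)) x <- estimateLambda(x)
    w <- rowRanges(x)
    mcols(w)$lambda_hat <- rowData(x)$lambda_hat
    mcols(w)$log2_lambda <- rowData(x)$log2_lambda
    mcols(w)$n_samples <- rowData(x)$n_samples
    callHotspots(w, fraction = fraction)
})

#' @describeIn callHotspots on a `GRanges` of windows carrying
#'   `window_index` and `lambda_hat` metadata columns.
#' @export
setMethod("callHotspots", "GRanges", function(x, fraction = 0.05) {
    stopifnot(length(x) > 0, fraction > 0, fraction < 1,
              !is.null(mcols(x)$lambda_hat),
              !is.null(mcols(x)$window_index))
    n <- length(x)
    k <- .nHotspots(n, fraction)
    lam <- mcols(x)$lambda_hat
    if (is.null(mcols(x)$log2_lambda))
        mcols(x)$log2_lambda <- ifelse(lam > 0, log2(lam), NA_real_)
    ord <- order(-lam, mcols(x)$window_index)
    sel <- ord[seq_len(k)]
    mcols(x)$is_hotspot <- seq_len(n) %in% sel
    rk <- rep(NA_integer_, n)
    rk[sel] <- seq_len(k)
    mcols(x)$rank <- rk
    if (is.null(mcols(x)$n_samples)) mcols(x)$n_samples <- NA_integer_
    hs <- x[sel]
    new("HotspotSet", windows = x, hotspots = hs,
        fraction = fraction, minLambda = min(lam[sel]))
})

## Hyper-polymorphic family patterns excluded before enrichment: olfactory
## receptors (OR + family digit(s) + subfamily letter(s) + member, so ORC1 /
## ORAI1 survive), taste receptors TAS1R*/TAS2R*, immunoglobulin heavy /
## kappa / lambda loci, and HLA-*.
.FAMILY_PATTERNS <- c("^OR[0-9]+[A-Z]+[0-9]+", "^TAS[12]R",
                      "^IGH", "^IGK", "^IGL", "^HLA-")

#' Filter hyper-polymorphic gene families from a symbol list
#'
#' Removes genes whose population-level variability would swamp a term
#' enrichment: olfactory receptors (OR nomenclature), taste receptors
#' (TAS1R/TAS2R), immunoglobulin heavy/kappa/lambda genes and the HLA
#' locus, plus any user-supplied exclusion list. Matching is anchored and
#' case-sensitive: `ORC1` and `ORAI1` are retained.
#'
#' @param symbols character vector of gene symbols.
#' @param extraExclude optional character vector of exact symbols to drop
#'   in addition to the family patterns.
#' @return the retained symbols, in input order.
#' @examples
#' filterGeneList(c("TP53", "HLA-A", "OR4F5", "IGHG1", "TAS2R38"))  # "TP53"
#' @export
filterGeneList <- function(symbols, extraExclude = NULL) {
    if (!length(symbols)) return(character(0))
    drop <- Reduce(`|`, lapply(.FAMILY_PATTERNS, grepl, x = symbols))
    if (!is.null(extraExclude)) drop <- drop | symbols %in% extraExclude
    symbols[!drop]
}

#' Data for a log2(lambda) histogram
#'
#' Returns the finite log2 rates of a called [HotspotSet] (or estimated
#' [WindowCounts]); windows with \eqn{\hat\lambda = 0} are dropped with a
#' message rather than pseudo-counted.
#'
#' @param x a [HotspotSet].
#' @return `data.frame` with columns `window_index` and `log2_lambda`.
#' @export
lambdaHistogramData <- function(x) {
    tab <- lambdaTable(x)
    nzero <- sum(is.na(tab$log2_lambda))
    if (nzero)
        message(nzero, " window(s) with lambda = 0 dropped from the ",
                "log2 histogram")
    tab <- tab[!is.na(tab$log2_lambda), c("window_index", "log2_lambda")]
    rownames(tab) <- NULL
    tab
}

#' Data for a Manhattan plot of lambda
#'
#' Per-window \eqn{\hat\lambda} with genome-wide position and hotspot flag;
#' the natural threshold line is [minHotspotLambda()].
#'
#' @param x a [HotspotSet].
#' @return `data.frame` (chrom, start, window_index, lambda_hat,
#'   is_hotspot).
#' @export
manhattanData <- function(x) {
    tab <- lambdaTable(x)
    tab[, c("chrom", "start", "window_index", "lambda_hat", "is_hotspot")]
}

#' Render a Manhattan plot of window rates
#'
#' Simple base-graphics rendering with hotspots in red and a horizontal
#' line at the minimum hotspot lambda. All plotted values are available as
#' data via [manhattanData()]; rendering is an optional convenience.
#'
#' @param x a [HotspotSet].
#' @param path optional PNG path; when NULL, plots to the active device.
#' @return invisibly, the plotted `data.frame`.
#' @export
plotManhattan <- function(x, path = NULL) {
    tab <- manhattanData(x)
    if (!is.null(path)) {
        png(path, width = 1400, height = 500)
        on.exit(dev.off())
    }
    chroms <- unique(tab$chrom)
    col <- (match(tab$chrom, chroms) %% 2) + 1
    plot(tab$window_index, tab$lambda_hat, pch = 16, cex = 0.5,
         col = c("grey40", "steelblue")[col],
         xlab = "window index (genome order)",
         ylab = expression(hat(lambda)))
    points(tab$window_index[tab$is_hotspot],
           tab$lambda_hat[tab$is_hotspot], pch = 16, cex = 0.6, col = "red")
    abline(h = minHotspotLambda(x), lty = 2, col = "red")
    invisible(tab)
}

#' Render a histogram of log2(lambda)
#'
#' @param x a [HotspotSet].
#' @param path optional PNG path.
#' @return invisibly, the histogram data.
#' @export
plotLambdaHistogram <- function(x, path = NULL) {
    dat <- lambdaHistogramData(x)
    if (!is.null(path)) {
        png(path, width = 700, height = 500)
        on.exit(dev.off())
    }
    hist(dat$log2_lambda, breaks = 40, col = "grey70",
         xlab = expression(log[2](hat(lambda))), main = "")
    invisible(dat)
}
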