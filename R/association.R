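#' Per-sample SCNA burden
#'
#' Burden is the number of SCNA segments a sample carries, optionally
#' restricted to one width class. Samples listed in `samples` but carrying
#' no segments get burden 0, so the table always covers the full cohort.
#'
#' @param segments `GRanges` with a `sample_id` column.
#' @param samples the cohort sample set; defaults to the ids present in
#'   `segments`.
#' @param set which segments to count: `"all"` (default), `"set1"` or
#'   `"set2"`.
#' @param thresholdBp width threshold used when `set` is not `"all"`.
#' @return `data.frame` with columns `sample_id` and `burden`.
#' @export
computeBurden <- function(segments, samples = NULL,
                          set = c("all", "set1", "set2"),
                          thresholdBp = 1e5) {
    set <- match.arg(set)
    if (set != "all") {
        cls <- classifyByWidth(segments, thresholdBp)
        segments <- cls[[set]]
    }
    ids <- as.character(mcols(segments)$sample_id)
    if (is.null(samples)) samples <- sort(unique(ids))
    samples <- as.character(samples)
    tab <- table(factor(ids, levels = samples))
    data.frame(sample_id = samples, burden = as.integer(tab),
               stringsAsFactors = FALSE)
}

#' Split a cohort at the median burden
#'
#' Samples are sorted by burden (ties by sample id) and the lower half is
#' labelled Low, the upper half High; with an odd cohort the middle sample
#' goes to Low. On even cohorts the two groups are exactly equal in size.
#'
#' @param burdens `data.frame` from [computeBurden()] (or any table with
#'   `sample_id` and `burden`).
#' @return `burdens` with an added `median_group` factor (Low/High).
#' @export
splitByMedian <- function(burdens) {
    n <- nrow(burdens)
    if (n < 2) stop("median split needs at least 2 samples")
    ord <- order(burdens$burden, burdens$sample_id)
    nLow <- ceiling(n / 2)
    grp <- rep(NA_character_, n)
    grp[ord[seq_len(nLow)]] <- "Low"
    grp[ord[(nLow + 1):n]] <- "High"
    burdens$median_group <- factor(grp, levels = c("Low", "High"))
    burdens
}

#' Label samples Mutant/Wild for one gene
#'
#' A sample is Mutant when at least one of its SCNA segments overlaps the
#' gene interval — segment start before the gene end and segment end after
#' the gene start, the same strict-inequality rule used for window
#' counting — and Wild otherwise.
#'
#' @param segments `GRanges` with a `sample_id` column.
#' @param gene a single-range `GRanges` (the gene interval).
#' @param samples cohort sample set; defaults to ids present in `segments`.
#' @return `data.frame` with columns `sample_id` and `status`
#'   (factor Wild/Mutant).
#' @export
classifyMutantWild <- function(segments, gene, samples = NULL) {
    stopifnot(is(gene, "GRanges"), length(gene) == 1)
    ids <- as.character(mcols(segments)$sample_id)
    if (is.null(samples)) samples <- sort(unique(ids))
    samples <- as.character(samples)
    hit <- S4Vectors::queryHits(findOverlaps(segments, gene,
                                             ignore.strand = TRUE))
    mut <- unique(ids[hit])
    data.frame(sample_id = samples,
               status = factor(ifelse(samples %in% mut, "Mutant", "Wild"),
                               levels = c("Wild", "Mutant")),
               stringsAsFactors = FALSE)
}

#' Two-group t-test on a continuous variable
#'
#' Welch's unequal-variance t-test by default (Student's by
#' `varEqual = TRUE`). Degenerate inputs — a group with fewer than two
#' values, or essentially constant pooled data — do not raise; the result
#' is flagged untestable with NA statistics, so genome-wide sweeps never
#' abort on a single bad gene.
#'
#' @param values1,values2 numeric vectors for the two groups.
#' @param varEqual use the pooled-variance (Student) test.
#' @return a one-row `data.frame`: `mean1`, `mean2`, `t`, `p_value`, `n1`,
#'   `n2`, `testable`.
#' @export
groupTTest <- function(values1, values2, varEqual = FALSE) {
    values1 <- values1[!is.na(values1)]
    values2 <- values2[!is.na(values2)]
    base <- data.frame(mean1 = if (length(values1)) mean(values1) else NA_real_,
                       mean2 = if (length(values2)) mean(values2) else NA_real_,
                       t = NA_real_, p_value = NA_real_,
                       n1 = length(values1), n2 = length(values2),
                       testable = FALSE)
    if (length(values1) < 2 || length(values2) < 2) return(base)
    res <- tryCatch(t.test(values1, values2, var.equal = varEqual),
                    error = function(e) NULL)
    if (is.null(res)) return(base)  # e.g. data essentially constant
    base$t <- unname(res$statistic)
    base$p_value <- res$p.value
    base$testable <- TRUE
    base
}

#' Rank-based tertile grouping
#'
#' Sorts samples by a continuous variable (ties by sample id) and cuts the
#' order into three contiguous groups — Low, Median, High — of sizes as
#' equal as possible, remainders assigned from Low upward (n = 10 gives
#' 4/3/3; n = 332 gives 111/111/110). Rank-based cutting guarantees
#' near-equal group sizes even with heavily tied values.
#'
#' @param values numeric vector.
#' @param ids sample ids used for deterministic tie-breaking; defaults to
#'   the element order.
#' @return a factor with levels Low, Median, High, aligned with `values`.
#' @export
tertileGroups <- function(values, ids = NULL) {
    n <- length(values)
    if (n < 3) stop("tertile grouping needs at least 3 samples")
    if (is.null(ids)) ids <- seq_len(n)
    ord <- order(values, ids)
    q <- n %/% 3
    r <- n %% 3
    sizes <- q + as.integer(seq_len(3) <= r)
    lab <- rep(c("Low", "Median", "High"), times = sizes)
    grp <- character(n)
    grp[ord] <- lab
    factor(grp, levels = c("Low", "Median", "High"))
}

#' Kaplan-Meier curves and log-rank test across groups
#'
#' Fits the Kaplan-Meier estimator per group and tests equality of the
#' survival curves with the k-group log-rank statistic (chi-square on
#' k - 1 degrees of freedom). With no events anywhere the log-rank test is
#' undefined; the result is flagged rather than raising.
#'
#' @param time survival times (>= 0).
#' @param event event indicator (1 = death observed, 0 = censored).
#' @param group factor of group labels; every level must be non-empty.
#' @return a list: `curves` (`data.frame` group/time/n_risk/n_event/
#'   survival), `chisq`, `df`, `p_value`, `group_sizes`, `testable`.
#' @export
kmLogrank <- function(time, event, group) {
    group <- droplevels(as.factor(group))
    stopifnot(length(time) == length(event), length(time) == length(group))
    if (any(time < 0)) stop("survival times must be >= 0")
    if (nlevels(group) < 2) stop("need at least 2 non-empty groups")
    if (any(table(group) == 0)) stop("a group has zero subjects")
    fit <- survival::survfit(survival::Surv(time, event) ~ group)
    strata <- rep(names(fit$strata), fit$strata)
    curves <- data.frame(group = sub("^group=", "", strata),
                         time = fit$time, n_risk = fit$n.risk,
                         n_event = fit$n.event, survival = fit$surv,
                         stringsAsFactors = FALSE)
    out <- list(curves = curves, chisq = NA_real_,
                df = nlevels(group) - 1L, p_value = NA_real_,
                group_sizes = as.integer(table(group)), testable = FALSE)
    if (sum(event) == 0) {
        message("no events observed; log-rank test undefined")
        return(out)
    }
    lr <- survival::survdiff(survival::Surv(time, event) ~ group)
    out$chisq <- unname(lr$chisq)
    out$p_value <- pchisq(lr$chisq, df = out$df, lower.tail = FALSE)
    out$testable <- TRUE
    out
}
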