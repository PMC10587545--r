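#' Configuration for a synthetic SCNA cohort
#'
#' Bundles and validates every parameter of the generator. The defaults
#' describe a compact cohort with the statistical structure the pipeline
#' assumes: 300 samples on three 10 Mb toy chromosomes tiled at 1 Mb
#' (30 windows), a background segment-placement rate of 0.2 events per
#' sample per window with two planted hotspots at rate 2.0, a width
#' mixture straddling the 100 kb classification threshold, expression
#' shifted additively for the high-burden half of the cohort at designated
#' genes, and exponential survival with hazard decreasing across burden
#' tertiles (hazard ratio 2 between Low and High, mirroring the direction
#' in which higher SCNA burden associates with better outcome).
#'
#' @param nSamples cohort size.
#' @param chromSizes named vector of chromosome lengths; default three
#'   10 Mb toy chromosomes (pass [hg19ChromSizes()] for a full-genome run).
#' @param windowSize tiling width in bp.
#' @param backgroundLambda segment-placement rate per sample per window.
#' @param hotspotSpec `data.frame` with columns `window` (1-based global
#'   window index) and `lambda` (placement rate there).
#' @param widthMixture list: `prop_small` (fraction of segments drawn from
#'   the small class), `small_range` and `large_range` (bp ranges of the
#'   two log-uniform width classes; the small class sits at or below the
#'   100 kb threshold, the large class above it).
#' @param expressionSpec list: `n_genes`, `baseline_mean`, `baseline_sd`
#'   (expression scale, log2-like units), `n_affected` (genes whose
#'   expression responds to burden) and `effect` (additive shift applied
#'   to high-burden samples at affected genes).
#' @param survivalSpec list: `baseline_hazard` (events/day),
#'   `hazard_multipliers` (length-3, Low/Median/High burden tertiles) and
#'   `censor_rate` (independent exponential censoring, events/day).
#' @param seed master seed; each output stratum (segments, genes,
#'   expression, survival) draws from its own stream derived from it, so
#'   adding one output never perturbs another's draws.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nSamples = 300,
                             chromSizes = c(chr1 = 1e7, chr2 = 1e7,
                                            chr3 = 1e7),
                             windowSize = 1e6,
                             backgroundLambda = 0.2,
                             hotspotSpec = data.frame(window = c(5L, 17L),
                                                      lambda = c(2, 2)),
                             widthMixture = list(
                                 prop_small = 0.6,
                                 small_range = c(1e3, 1e5),
                                 large_range = c(1e5, 1e6)),
                             expressionSpec = list(
                                 n_genes = 60, baseline_mean = 8,
                                 baseline_sd = 1, n_affected = 6,
                                 effect = 0.5),
                             survivalSpec = list(
                                 baseline_hazard = 1 / 730,
                                 hazard_multipliers = c(Low = 1,
                                                        Median = 0.75,
                                                        High = 0.5),
                                 censor_rate = 1 / 1825),
                             seed = 1) {
    cfg <- list(nSamples = nSamples, chromSizes = chromSizes,
                windowSize = windowSize,
                backgroundLambda = backgroundLambda,
                hotspotSpec = hotspotSpec, widthMixture = widthMixture,
                expressionSpec = expressionSpec,
                survivalSpec = survivalSpec, seed = as.integer(seed))
    stopifnot(nSamples >= 1, windowSize > 0, all(chromSizes > 0),
              backgroundLambda >= 0,
              widthMixture$prop_small >= 0, widthMixture$prop_small <= 1,
              widthMixture$small_range[1] > 0,
              diff(widthMixture$small_range) >= 0,
              diff(widthMixture$large_range) >= 0,
              expressionSpec$baseline_sd > 0,
              survivalSpec$baseline_hazard > 0,
              length(survivalSpec$hazard_multipliers) == 3,
              all(survivalSpec$hazard_multipliers > 0),
              survivalSpec$censor_rate >= 0)
    nw <- length(tileWindows(chromSizes, windowSize))
    if (nrow(hotspotSpec) &&
        (any(hotspotSpec$window < 1) || any(hotspotSpec$window > nw)))
        stop("hotspotSpec window index out of range (1..", nw, ")")
    if (any(hotspotSpec$lambda < 0)) stop("hotspot lambda must be >= 0")
    class(cfg) <- "SimulationConfig"
    cfg
}

## Per-window placement rates (background with planted hotspots).
.plantedLambda <- function(config) {
    windows <- tileWindows(config$chromSizes, config$windowSize)
    lam <- rep(config$backgroundLambda, length(windows))
    if (nrow(config$hotspotSpec))
        lam[config$hotspotSpec$window] <- config$hotspotSpec$lambda
    lam
}

## integral_0^t P(W > u) du for W ~ LogUniform(a, b); closed form.
.survIntegral <- function(t, a, b) {
    if (t <= 0) return(0)
    if (b <= a) return(min(t, a))  # degenerate point mass at a
    if (t <= a) return(t)
    t <- min(t, b)
    lab <- log(b / a)
    a + (t * log(b) - (t * log(t) - t) - a * log(b) + (a * log(a) - a)) / lab
}

## P(a segment placed uniformly in a window of width L, with width from the
## mixture, overlaps a window starting d bp downstream); d = 0 gives 1.
.pOverlap <- function(d, L, mix) {
    Gm <- function(t) {
        if (t <= 0) return(0)
        mix$prop_small * .survIntegral(t, mix$small_range[1],
                                       mix$small_range[2]) +
            (1 - mix$prop_small) * .survIntegral(t, mix$large_range[1],
                                                 mix$large_range[2])
    }
    lo <- d - L
    (max(0, -lo) + Gm(d) - Gm(max(0, lo))) / L
}

#' Expected per-window overlap rates under a simulation config
#'
#' Segments are placed by window but may extend across window boundaries,
#' so the rate of segments *overlapping* a window exceeds the rate
#' *placed* in it: every upstream window contributes its placement rate
#' times the probability that a segment starting there reaches this far.
#' This function computes that expected overlap rate in closed form
#' (integrating the log-uniform width mixture), giving the exact target
#' against which \eqn{\hat\lambda} recovery is scored.
#'
#' @param config a [simulationConfig()].
#' @return numeric vector, one expected overlap rate per window (genome
#'   order).
#' @export
expectedWindowRates <- function(config) {
    windows <- tileWindows(config$chromSizes, config$windowSize)
    lam <- .plantedLambda(config)
    chrom <- as.character(seqnames(windows))
    st <- start(windows)
    L <- width(windows)
    out <- numeric(length(windows))
    for (w in seq_along(windows)) {
        ups <- which(chrom == chrom[w] & st <= st[w])
        out[w] <- sum(vapply(ups, function(u) {
            lam[u] * .pOverlap(st[w] - st[u], L[u], config$widthMixture)
        }, numeric(1)))
    }
    out
}

.drawWidths <- function(n, mix) {
    if (!n) return(numeric(0))
    small <- runif(n) < mix$prop_small
    rng <- function(r, m) exp(runif(m, log(r[1]), log(r[2])))
    w <- numeric(n)
    w[small] <- rng(mix$small_range, sum(small))
    w[!small] <- rng(mix$large_range, sum(!small))
    pmax(1, round(w))
}

#' Simulate a synthetic SCNA cohort
#'
#' Draws a full cohort under the Poisson recurrence model: for every
#' (window, sample) pair a segment count is drawn Poisson(\eqn{\lambda_w}),
#' each segment starts uniformly inside its window with a width from the
#' configured mixture (truncated at the chromosome end), so segments
#' deliberately cross window boundaries and exercise the multi-window
#' counting semantics. Gene intervals are placed uniformly (plus four
#' decoy symbols from the hyper-polymorphic families the filter removes);
#' expression at affected genes is shifted additively for the high-burden
#' half of the cohort; survival times are exponential with the burden
#' tertile's hazard and independently exponentially censored. Identical
#' config and seed give bit-identical output; each stratum uses its own
#' RNG stream.
#'
#' @param config a [simulationConfig()].
#' @return a list: `segments` (`GRanges` with `sample_id`), `genes`
#'   (`GRanges` with `symbol`), `expression` (matrix), `clinical`
#'   (`data.frame`), `burden` (`data.frame`), and `config`.
#' @export
simulateCohort <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    windows <- tileWindows(config$chromSizes, config$windowSize)
    lam <- .plantedLambda(config)
    n <- config$nSamples
    sampleIds <- sprintf("S%04d", seq_len(n))
    chromLen <- config$chromSizes

    ## --- segments stream ---------------------------------------------
    set.seed(config$seed + 1L)
    W <- length(windows)
    cellCounts <- rpois(W * n, rep(lam, times = n))
    evWin <- rep(rep(seq_len(W), times = n), times = cellCounts)
    evSample <- rep(rep(seq_len(n), each = W), times = cellCounts)
    nev <- length(evWin)
    wStart <- start(windows)[evWin]
    wWidth <- width(windows)[evWin]
    evChrom <- as.character(seqnames(windows))[evWin]
    segStart <- wStart + floor(runif(nev) * wWidth)
    segWidth <- .drawWidths(nev, config$widthMixture)
    segEnd <- pmin(segStart + segWidth - 1, chromLen[evChrom])
    segments <- GRanges(evChrom, IRanges(segStart, segEnd))
    mcols(segments)$sample_id <- sampleIds[evSample]
    mcols(segments)$segment_mean <- 0
    segments <- segments[order(match(evChrom, names(chromLen)),
                               segStart, segEnd)]

    ## --- gene annotation stream --------------------------------------
    set.seed(config$seed + 2L)
    es <- config$expressionSpec
    geneSymbols <- sprintf("G%03d", seq_len(es$n_genes))
    decoys <- c("OR4F5", "HLA-A", "IGHG1", "TAS2R38")
    allSymbols <- c(geneSymbols, decoys)
    ng <- length(allSymbols)
    gChrom <- sample(names(chromLen), ng, replace = TRUE,
                     prob = chromLen / sum(chromLen))
    gWidth <- pmax(1, round(exp(runif(ng, log(1e4), log(1e5)))))
    gStart <- floor(runif(ng) * (chromLen[gChrom] - gWidth)) + 1
    genes <- GRanges(gChrom, IRanges(gStart, gStart + gWidth - 1))
    mcols(genes)$symbol <- allSymbols
    genes <- GenomeInfoDb::sortSeqlevels(genes)
    genes <- genes[order(as.integer(seqnames(genes)), start(genes))]

    burden <- computeBurden(segments, samples = sampleIds)

    ## --- expression stream -------------------------------------------
    set.seed(config$seed + 3L)
    affected <- geneSymbols[seq_len(es$n_affected)]
    highHalf <- splitByMedian(burden)$median_group == "High"
    expr <- matrix(rnorm(ng * n, es$baseline_mean, es$baseline_sd),
                   nrow = ng, dimnames = list(allSymbols, sampleIds))
    expr[affected, highHalf] <- expr[affected, highHalf] + es$effect
    expr <- pmax(expr, 0)

    ## --- survival stream ---------------------------------------------
    set.seed(config$seed + 4L)
    ss <- config$survivalSpec
    tert <- tertileGroups(burden$burden, burden$sample_id)
    hz <- ss$baseline_hazard * ss$hazard_multipliers[as.integer(tert)]
    tEvent <- rexp(n, rate = hz)
    tCens <- if (ss$censor_rate > 0) rexp(n, rate = ss$censor_rate)
             else rep(Inf, n)
    clinical <- data.frame(sample_id = sampleIds,
                           time = round(pmin(tEvent, tCens), 2),
                           event = as.integer(tEvent <= tCens),
                           stringsAsFactors = FALSE)

    list(segments = segments, genes = genes, expression = expr,
         clinical = clinical, burden = burden, config = config)
}

#' Planted-truth table for a simulation config
#'
#' Emits the parameters the generator planted, for recovery scoring:
#' per-window placement and expected overlap rates (see
#' [expectedWindowRates()] for why the two differ), per-gene expression
#' effects, and per-tertile hazard multipliers.
#'
#' @param config a [simulationConfig()].
#' @return a list of three `data.frame`s: `windows`, `genes`, `survival`.
#' @export
truthTable <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    windows <- tileWindows(config$chromSizes, config$windowSize)
    es <- config$expressionSpec
    geneSymbols <- sprintf("G%03d", seq_len(es$n_genes))
    list(
        windows = data.frame(
            chrom = as.character(seqnames(windows)),
            start = start(windows), end = end(windows),
            window_index = mcols(windows)$window_index,
            lambda_placed = .plantedLambda(config),
            lambda_effective = expectedWindowRates(config),
            stringsAsFactors = FALSE),
        genes = data.frame(
            symbol = geneSymbols,
            true_effect = ifelse(seq_along(geneSymbols) <= es$n_affected,
                                 es$effect, 0),
            stringsAsFactors = FALSE),
        survival = data.frame(
            group = c("Low", "Median", "High"),
            hazard_multiplier = unname(config$survivalSpec$hazard_multipliers),
            stringsAsFactors = FALSE))
}

#' Write a simulated cohort to disk
#'
#' Emits the cohort in the pipeline's input formats — SEG (1-based),
#' BED4 genes, expression TSV, clinical TSV — plus the three truth TSVs.
#'
#' @param cohort result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named character vector of the written paths.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(segments = file.path(dir, "segments.seg"),
               genes = file.path(dir, "genes.bed"),
               expression = file.path(dir, "expression.tsv"),
               clinical = file.path(dir, "clinical.tsv"),
               chrom_sizes = file.path(dir, "chrom.sizes"),
               truth_windows = file.path(dir, "truth_windows.tsv"),
               truth_genes = file.path(dir, "truth_genes.tsv"),
               truth_survival = file.path(dir, "truth_survival.tsv"))
    writeSeg(cohort$segments, paths["segments"])
    writeBedGenes(cohort$genes, paths["genes"])
    writeExpression(cohort$expression, paths["expression"])
    writeClinical(cohort$clinical, paths["clinical"])
    write.table(data.frame(names(cohort$config$chromSizes),
                           unname(cohort$config$chromSizes)),
                paths["chrom_sizes"], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    tt <- truthTable(cohort$config)
    writeTable(tt$windows, paths["truth_windows"])
    writeTable(tt$genes, paths["truth_genes"])
    writeTable(tt$survival, paths["truth_survival"])
    invisible(paths)
}
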