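#' Run configuration for the end-to-end pipeline
#'
#' Collects input paths and analysis parameters. Defaults reproduce the
#' published analysis settings: 1 Mb windows, 100 kb width threshold,
#' top-5\% hotspot calling, enrichment at adjusted p < 0.05 with the top
#' 10 terms by ratio. The configuration is serialized into the output
#' directory for provenance.
#'
#' @param seg path to the SEG segment table (required).
#' @param genesBed path to the BED4 gene annotation (required).
#' @param expression path to the expression matrix TSV (optional; enables
#'   the association stage).
#' @param clinical path to the clinical TSV (optional; enables survival).
#' @param gmt path to a GMT term file (optional; enables enrichment).
#' @param chromSizes path to a chrom.sizes file, or NULL for the bundled
#'   hg19 autosomes.
#' @param outDir output directory.
#' @param segDialect `"1based"` (TCGA SEG convention) or `"0based"`.
#' @param windowSize window width in bp.
#' @param widthThreshold Set1/Set2 width threshold in bp.
#' @param hotspotFraction top tail fraction for hotspot calling.
#' @param enrichAlpha adjusted-p threshold for term ranking.
#' @param enrichTopK number of top terms to keep.
#' @param burdenSet segments counted into burden: `"all"`, `"set1"`,
#'   `"set2"`.
#' @param survivalVariable `"burden"` or a gene symbol whose expression
#'   defines the tertiles.
#' @param assocGenes gene symbols for the association t-tests; NULL means
#'   all filtered hotspot genes present in the expression matrix.
#' @param mutantWildGenes gene symbols for Mutant/Wild overlap tests;
#'   NULL means the same default as `assocGenes`.
#' @param plots also render PNG figures (data TSVs are always written).
#' @return a validated list of class `RunConfig`.
#' @export
runConfig <- function(seg, genesBed, expression = NULL, clinical = NULL,
                      gmt = NULL, chromSizes = NULL, outDir = "scnaScan_out",
                      segDialect = "1based", windowSize = 1e6,
                      widthThreshold = 1e5, hotspotFraction = 0.05,
                      enrichAlpha = 0.05, enrichTopK = 10,
                      burdenSet = "all", survivalVariable = "burden",
                      assocGenes = NULL, mutantWildGenes = NULL,
                      plots = FALSE) {
    cfg <- as.list(environment())
    class(cfg) <- "RunConfig"
    validateRunConfig(cfg)
    cfg
}

#' Validate a run configuration (fail fast)
#'
#' Checks file existence and internal consistency before any computation,
#' so misconfigured runs fail at once rather than mid-pipeline.
#'
#' @param config a `RunConfig` (see [runConfig()]) or a list read from
#'   YAML via [readRunConfig()].
#' @return invisibly TRUE; errors otherwise.
#' @export
validateRunConfig <- function(config) {
    need <- function(p, what) {
        if (!is.null(p) && !file.exists(p))
            stop(what, " file not found: ", p, call. = FALSE)
    }
    if (is.null(config$seg)) stop("a SEG input is required")
    need(config$seg, "SEG")
    if (is.null(config$genesBed)) stop("a gene annotation BED is required")
    need(config$genesBed, "gene BED")
    need(config$expression, "expression")
    need(config$clinical, "clinical")
    need(config$gmt, "GMT")
    need(config$chromSizes, "chrom.sizes")
    stopifnot(config$windowSize > 0, config$widthThreshold > 0,
              config$hotspotFraction > 0, config$hotspotFraction < 1,
              config$enrichAlpha > 0, config$enrichTopK >= 1)
    if (!config$burdenSet %in% c("all", "set1", "set2"))
        stop("burdenSet must be all, set1 or set2")
    if (!identical(config$survivalVariable, "burden") &&
        is.null(config$expression))
        stop("survival on gene expression requires an expression matrix")
    if (!is.null(config$clinical) && is.null(config$expression) &&
        !identical(config$survivalVariable, "burden"))
        stop("survival on gene expression requires an expression matrix")
    invisible(TRUE)
}

#' Read a YAML run configuration
#'
#' Keys mirror the arguments of [runConfig()] (snake_case accepted).
#'
#' @param path YAML file.
#' @return a `RunConfig`.
#' @export
readRunConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    toCamel <- function(x) gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
    names(raw) <- toCamel(names(raw))
    do.call(runConfig, raw)
}

.runOneSet <- function(segments, windows, samples, genes, config, setLabel,
                       outDir) {
    wc <- countWindowOverlaps(segments, windows, samples = samples,
                              widthClass = setLabel)
    wc <- estimateLambda(wc)
    hs <- callHotspots(wc, fraction = config$hotspotFraction)
    hs <- annotateGenes(hs, genes)
    prefix <- file.path(outDir, setLabel)
    writeTable(lambdaTable(hs), paste0(prefix, "_lambda.tsv"))
    writeTable(hotspotGeneTable(hs), paste0(prefix, "_hotspot_genes.tsv"))
    writeTable(lambdaHistogramData(hs), paste0(prefix, "_log2_lambda_hist.tsv"))
    writeTable(manhattanData(hs), paste0(prefix, "_manhattan.tsv"))
    if (isTRUE(config$plots)) {
        plotManhattan(hs, paste0(prefix, "_manhattan.png"))
        plotLambdaHistogram(hs, paste0(prefix, "_log2_lambda_hist.png"))
    }
    hs
}

#' Run the full hotspot analysis pipeline
#'
#' Executes every stage on files on disk: read and classify segments,
#' tile the genome, count window overlaps, estimate \eqn{\lambda}, call
#' and annotate hotspots (independently for Set1 and Set2, and for the
#' unclassified segment set), filter gene families, then — when the
#' corresponding inputs are present — term enrichment, burden association
#' t-tests, Mutant/Wild tests, and tertile Kaplan-Meier survival. Every
#' stage writes a TSV; a JSON manifest records parameters, input hashes
#' and row counts. The pipeline is deterministic: identical inputs and
#' configuration give byte-identical outputs.
#'
#' @param config a [runConfig()].
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
    validateRunConfig(config)
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(package = "scnaScan",
                     version = as.character(packageVersion("scnaScan")),
                     parameters = config[!vapply(config, is.null,
                                                 logical(1))],
                     inputs = list(), stages = list())
    hash <- function(p) unname(tools::md5sum(p))
    for (f in c("seg", "genesBed", "expression", "clinical", "gmt"))
        if (!is.null(config[[f]]))
            manifest$inputs[[f]] <- list(path = config[[f]],
                                         md5 = hash(config[[f]]))

    sizes <- if (is.null(config$chromSizes)) hg19ChromSizes()
             else readChromSizes(config$chromSizes)
    segments <- readSeg(config$seg, dialect = config$segDialect)
    genes <- readBedGenes(config$genesBed)
    samples <- sort(unique(mcols(segments)$sample_id))
    windows <- tileWindows(sizes, config$windowSize)
    manifest$stages$input <- list(n_segments = length(segments),
                                  n_samples = length(samples),
                                  n_genes = length(genes),
                                  n_windows = length(windows))

    sets <- classifyByWidth(segments, config$widthThreshold)
    hsList <- list()
    for (lab in c("all", "set1", "set2")) {
        segs <- if (lab == "all") segments else sets[[lab]]
        if (!length(segs)) {
            message("no segments in ", lab, "; stage skipped")
            next
        }
        hsList[[lab]] <- .runOneSet(segs, windows, samples, genes, config,
                                    lab, config$outDir)
        manifest$stages[[lab]] <- list(
            n_hotspots = length(hotspots(hsList[[lab]])),
            min_hotspot_lambda = minHotspotLambda(hsList[[lab]]),
            n_genes_all = length(unique(unlist(
                mcols(hotspots(hsList[[lab]]))$genes_all))),
            n_genes_filtered = length(unique(unlist(
                mcols(hotspots(hsList[[lab]]))$genes_filtered))))
    }

    hotGenes <- unique(unlist(mcols(hotspots(hsList[["all"]]))$genes_filtered))
    universe <- filterGeneList(unique(mcols(genes)$symbol))

    if (!length(hotGenes))
        message("no genes overlap the called hotspots; ",
                "enrichment and association defaults will be empty")

    if (!is.null(config$gmt) && length(hotGenes)) {
        terms <- readGmt(config$gmt)
        enr <- hypergeometricEnrichment(hotGenes, terms, universe)
        top <- rankTerms(enr, topK = config$enrichTopK,
                         alpha = config$enrichAlpha)
        writeTable(enr, file.path(config$outDir, "enrichment.tsv"))
        writeTable(top, file.path(config$outDir, "enrichment_top.tsv"))
        manifest$stages$enrichment <- list(n_terms = nrow(enr),
                                           n_top = nrow(top))
    }

    burden <- computeBurden(segments, samples = samples,
                            set = config$burdenSet,
                            thresholdBp = config$widthThreshold)
    burden <- splitByMedian(burden)
    burden$tertile_group <- tertileGroups(burden$burden, burden$sample_id)
    writeTable(burden, file.path(config$outDir, "burden.tsv"))
    manifest$stages$burden <- list(n_samples = nrow(burden),
                                   median_burden = median(burden$burden))

    if (!is.null(config$expression)) {
        expr <- readExpression(config$expression)
        common <- intersect(colnames(expr), burden$sample_id)
        testGenes <- config$assocGenes
        if (is.null(testGenes))
            testGenes <- intersect(hotGenes, rownames(expr))
        rows <- lapply(testGenes, function(g) {
            grp <- burden$median_group[match(common, burden$sample_id)]
            tt <- groupTTest(expr[g, common][grp == "High"],
                             expr[g, common][grp == "Low"])
            cbind(data.frame(gene = g, grouping = "median-burden"), tt)
        })
        mwGenes <- config$mutantWildGenes
        if (is.null(mwGenes)) mwGenes <- testGenes
        mwGenes <- intersect(mwGenes, mcols(genes)$symbol)
        mwRows <- lapply(mwGenes, function(g) {
            gi <- genes[mcols(genes)$symbol == g][1]
            mw <- classifyMutantWild(segments, gi, samples = samples)
            b <- burden$burden[match(mw$sample_id, burden$sample_id)]
            tt <- groupTTest(b[mw$status == "Mutant"],
                             b[mw$status == "Wild"])
            cbind(data.frame(gene = g, grouping = "mutant-wild"), tt)
        })
        assoc <- do.call(rbind, c(rows, mwRows))
        if (!is.null(assoc)) {
            writeTable(assoc, file.path(config$outDir, "association.tsv"))
            manifest$stages$association <- list(
                n_tests = nrow(assoc),
                n_significant = sum(assoc$p_value < 0.05, na.rm = TRUE))
        }
    }

    if (!is.null(config$clinical)) {
        clin <- readClinical(config$clinical)
        common <- intersect(clin$sample_id, burden$sample_id)
        clin <- clin[match(common, clin$sample_id), ]
        if (identical(config$survivalVariable, "burden")) {
            values <- burden$burden[match(common, burden$sample_id)]
        } else {
            expr <- readExpression(config$expression)
            if (!config$survivalVariable %in% rownames(expr))
                stop("survival variable gene not in expression matrix: ",
                     config$survivalVariable)
            values <- expr[config$survivalVariable,
                           match(common, colnames(expr))]
        }
        grp <- tertileGroups(values, common)
        km <- kmLogrank(clin$time, clin$event, grp)
        writeTable(km$curves, file.path(config$outDir, "km_curves.tsv"))
        writeTable(data.frame(variable = config$survivalVariable,
                              chisq = km$chisq, df = km$df,
                              p_value = km$p_value,
                              n_low = km$group_sizes[1],
                              n_median = km$group_sizes[2],
                              n_high = km$group_sizes[3]),
                   file.path(config$outDir, "logrank.tsv"))
        manifest$stages$survival <- list(variable = config$survivalVariable,
                                         p_value = km$p_value)
    }

    jsonlite::write_json(manifest,
                         file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    invisible(manifest)
}
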