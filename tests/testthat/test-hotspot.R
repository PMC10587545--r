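test_that("width classification uses a strict > threshold and partitions", {
    gr <- GRanges("chr1", IRanges(1, c(100000, 100001, 50000, 2000000)))
    mcols(gr)$sample_id <- "s"
    cls <- suppressMessages(classifyByWidth(gr, 1e5))
    expect_equal(width(cls$set2), c(100000, 50000))   # boundary goes to Set2
    expect_equal(width(cls$set1), c(100001, 2000000))

    set.seed(3)
    gr <- randomSegmentsGR(1000, c(chr1 = 5e6), 10)
    cls <- suppressMessages(classifyByWidth(gr))
    expect_equal(length(cls$set1) + length(cls$set2), 1000)
    expect_true(all(width(cls$set1) > 1e5))
    expect_true(all(width(cls$set2) <= 1e5))
})

test_that("overlap counting follows the strict half-open inequality rule", {
    win <- tileWindows(c(chr1 = 300), 100)  # [0,100) [100,200) [200,300)
    # half-open [150, 250) overlaps [100, 200); [200, 300) abuts and does not
    seg <- GRanges("chr1", IRanges(c(151, 201), c(250, 300)))
    mcols(seg)$sample_id <- c("a", "b")
    wc <- countWindowOverlaps(seg, win)
    cnt <- SummarizedExperiment::assay(wc, "counts")
    expect_equal(cnt[, "a"], c(0, 1, 1))  # spans windows 2 and 3
    expect_equal(cnt[, "b"], c(0, 0, 1))  # does NOT touch window 2
})

test_that("count matrix equals the brute-force nested-loop oracle", {
    set.seed(101)
    sizes <- c(chr1 = 6e6, chr2 = 4e6)
    win <- tileWindows(sizes, 333333)  # 31 ragged windows
    seg <- randomSegmentsGR(200, sizes, nSamples = 12)
    samples <- sort(unique(mcols(seg)$sample_id))
    wc <- countWindowOverlaps(seg, win, samples = samples)
    oracle <- oracleCountMatrix(grToHalfOpen(seg, mcols(seg)$sample_id),
                                grToHalfOpen(win), samples)
    expect_equal(unname(SummarizedExperiment::assay(wc, "counts")),
                 unname(oracle))
})

test_that("overlap counting is order-independent and conserves totals", {
    set.seed(55)
    sizes <- c(chr1 = 5e6)
    win <- tileWindows(sizes, 1e6)
    seg <- randomSegmentsGR(150, sizes, nSamples = 6)
    samples <- sort(unique(mcols(seg)$sample_id))
    wc1 <- countWindowOverlaps(seg, win, samples = samples)
    wc2 <- countWindowOverlaps(seg[sample(length(seg))], win,
                               samples = samples)
    expect_equal(SummarizedExperiment::assay(wc1), SummarizedExperiment::assay(wc2))

    # per-sample column sums equal the arithmetic span count of each segment
    spans <- floor((end(seg) - 1) / 1e6) - floor((start(seg) - 1) / 1e6) + 1
    colTotals <- colSums(SummarizedExperiment::assay(wc1))
    expect_equal(unname(colTotals),
                 as.vector(tapply(spans, mcols(seg)$sample_id, sum)[samples]))
})

test_that("lambda MLE: closed form, numeric maximizer and edge cases agree", {
    expect_identical(estimateLambdaMLE(c(0, 0, 0, 0)), 0)
    expect_equal(estimateLambdaMLE(c(1, 2, 3)), 2)
    # grid search of the log-likelihood confirms the maximum at the mean
    grid <- seq(0.01, 10, by = 0.01)
    ll <- vapply(grid, poissonLogLik, numeric(1), counts = c(1, 2, 3))
    expect_equal(grid[which.max(ll)], 2)
    expect_equal(estimateLambdaMLE(c(4, 4, 4, 4)), 4)
    expect_error(estimateLambdaMLE(c(-1, 2)), "non-negative")
    expect_error(estimateLambdaMLE(c(0.5, 2)), "integers")

    set.seed(9)
    for (i in 1:200) {
        x <- rpois(sample(2:40, 1), runif(1, 0.05, 8))
        if (mean(x) == 0) next
        expect_equal(estimateLambdaMLE(x, "numeric"), mean(x),
                     tolerance = 1e-6)
    }
})

test_that("estimateLambda stores per-window rates with NA log2 at zero", {
    win <- tileWindows(c(chr1 = 3e6), 1e6)
    counts <- rbind(c(2L, 4L), c(0L, 0L), c(1L, 0L))
    wc <- estimateLambda(WindowCounts(counts, win))
    expect_equal(rowData(wc)$lambda_hat, c(3, 0, 0.5))
    expect_equal(rowData(wc)$log2_lambda, c(log2(3), NA, -1))
    expect_equal(rowData(wc)$n_samples, rep(2L, 3))
})

test_that("top-5% of 2,897 lambda values yields exactly 145 hotspots", {
    set.seed(2)
    win <- tileWindows(hg19ChromSizes(), 1e6)
    mcols(win)$lambda_hat <- rexp(length(win))
    hs <- callHotspots(win, fraction = 0.05)
    expect_identical(length(hotspots(hs)), 145L)
    expect_equal(sum(lambdaTable(hs)$is_hotspot), 145)
    tab <- lambdaTable(hs)
    expect_true(min(tab$lambda_hat[tab$is_hotspot]) >=
                max(tab$lambda_hat[!tab$is_hotspot]))
    expect_equal(minHotspotLambda(hs), min(tab$lambda_hat[tab$is_hotspot]))
})

test_that("small cohorts return a single max-lambda hotspot", {
    win <- tileWindows(c(chr1 = 2e7), 1e6)  # 20 windows
    mcols(win)$lambda_hat <- c(5, 1:19 / 10)
    hs <- callHotspots(win, fraction = 0.05)  # 20 * 0.05 = 1 slot
    expect_equal(length(hotspots(hs)), 1)
    expect_equal(mcols(hotspots(hs))$lambda_hat, 5)

    # fraction * N < 1 warns and still returns the max-lambda window
    win10 <- win[1:10]
    expect_warning(hs10 <- callHotspots(win10, fraction = 0.05),
                   "single hotspot")
    expect_equal(mcols(hotspots(hs10))$window_index, 1)
})

test_that("ties at the hotspot cut resolve by genome order", {
    win <- tileWindows(c(chr1 = 2e7), 1e6)
    lam <- c(5, 4, 4, seq(3.9, 0.1, length.out = 17))
    mcols(win)$lambda_hat <- lam
    hs <- callHotspots(win, fraction = 0.10)  # 2 slots, tie at 4
    # brute-force enumeration of the rule: sort by (-lambda, index)
    oracle <- order(-lam, seq_along(lam))[1:2]
    expect_equal(mcols(hotspots(hs))$window_index, oracle)
    expect_equal(mcols(hotspots(hs))$rank, 1:2)

    # selection size is always round-half-up(fraction * N)
    for (frac in c(0.05, 0.1, 0.125, 0.33)) {
        hs <- suppressWarnings(callHotspots(win, fraction = frac))
        expect_equal(length(hotspots(hs)),
                     max(1, floor(frac * 20 + 0.5)))
    }
})

test_that("gene annotation shares the overlap semantics of counting", {
    win <- tileWindows(c(chr1 = 1e6, chr2 = 1e6), 5e5)
    mcols(win)$lambda_hat <- c(4, 3, 2, 1)
    hs <- callHotspots(win, fraction = 0.5)  # windows 1 and 2 of chr1
    genes <- GRanges(c("chr1", "chr1", "chr1", "chr2"),
                     IRanges(c(1000, 500001, 499901, 1),
                             c(2000, 500100, 500000, 100)))
    mcols(genes)$symbol <- c("INSIDE", "NEXTWIN", "ABUT", "OFFCHROM")
    hs <- annotateGenes(hs, genes)
    ga <- mcols(hotspots(hs))$genes_all
    expect_equal(ga[[1]], c("ABUT", "INSIDE"))   # window 1: [0, 5e5)
    expect_equal(ga[[2]], "NEXTWIN")             # ABUT does not reach window 2
})

test_that("annotation matches the nested-loop oracle on random input", {
    set.seed(77)
    sizes <- c(chr1 = 5e6, chr2 = 5e6)
    win <- tileWindows(sizes, 1e6)
    mcols(win)$lambda_hat <- runif(10)
    hs <- callHotspots(win, fraction = 0.999)  # nearly all windows kept
    genes <- randomSegmentsGR(100, sizes, 1, maxWidth = 3e5)
    mcols(genes)$sample_id <- NULL
    mcols(genes)$symbol <- sprintf("G%03d", 1:100)
    hs <- annotateGenes(hs, genes)
    oracle <- oracleCountMatrix(
        cbind(grToHalfOpen(genes), sample = mcols(genes)$symbol),
        grToHalfOpen(hotspots(hs)), mcols(genes)$symbol)
    for (i in seq_along(hotspots(hs))) {
        expect_equal(mcols(hotspots(hs))$genes_all[[i]],
                     sort(colnames(oracle)[oracle[i, ] > 0]))
    }
})

test_that("gene-family filtering removes the hyper-polymorphic families only", {
    expect_equal(filterGeneList(c("TP53", "HLA-A", "OR4F5", "IGHG1",
                                  "TAS2R38")),
                 "TP53")
    # non-olfactory OR*/TAS*/HLA-like symbols are retained
    expect_equal(filterGeneList(c("ORC1", "ORAI1", "TAS", "HLAX", "IGF1R")),
                 c("ORC1", "ORAI1", "TAS", "HLAX", "IGF1R"))
    expect_equal(filterGeneList(c("A", "B"), extraExclude = "B"), "A")
    expect_equal(filterGeneList(character(0)), character(0))

    # 50 symbols, 12 family members; regex-free handwritten exclusion list
    family <- c("OR4F5", "OR2T8", "OR51A2", "TAS1R1", "TAS2R38", "IGHG1",
                "IGHM", "IGKC", "IGLL1", "HLA-A", "HLA-DRB1", "OR5AC2")
    keepers <- sprintf("KEEP%02d", 1:38)
    pool <- sample(c(family, keepers))
    expect_setequal(filterGeneList(pool), keepers)
    expect_equal(length(filterGeneList(pool)), 38)
})

test_that("log2 histogram drops zero-rate windows with a message", {
    win <- tileWindows(c(chr1 = 4e6), 1e6)
    mcols(win)$lambda_hat <- c(2, 0, 1, 4)
    hs <- callHotspots(win, fraction = 0.25)
    expect_message(dat <- lambdaHistogramData(hs), "1 window")
    expect_equal(nrow(dat), 3)
    expect_false(any(is.na(dat$log2_lambda)))
    man <- manhattanData(hs)
    expect_equal(nrow(man), 4)
    expect_equal(sum(man$is_hotspot), 1)
})
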