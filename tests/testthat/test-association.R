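segsFor <- function(tab, sizes = c(chr1 = 1e7)) {
    gr <- GRanges(tab$chrom, IRanges(tab$start, tab$end))
    mcols(gr)$sample_id <- tab$sample
    gr
}

test_that("burden counts segments per sample, zero-segment samples included", {
    seg <- segsFor(data.frame(sample = c("a", "a", "a", "b"),
                              chrom = "chr1",
                              start = c(1, 100, 5000, 10),
                              end = c(50, 900, 9000, 20)))
    b <- computeBurden(seg, samples = c("a", "b", "c"))
    expect_equal(b$burden[match(c("a", "b", "c"), b$sample_id)], c(3, 1, 0))

    set.seed(12)
    seg <- randomSegmentsGR(500, c(chr1 = 1e7), 20)
    b <- computeBurden(seg)
    expect_equal(sum(b$burden), 500)  # conservation
})

test_that("median split halves the cohort with the declared odd-n rule", {
    b332 <- data.frame(sample_id = sprintf("P%03d", 1:332),
                       burden = rpois(332, 500))
    sp <- splitByMedian(b332)
    expect_equal(as.vector(table(sp$median_group)), c(166, 166))

    b5 <- data.frame(sample_id = sprintf("P%d", 1:5), burden = c(9, 2, 5, 7, 1))
    sp <- splitByMedian(b5)
    expect_equal(sum(sp$median_group == "Low"), 3)   # middle sample -> Low
    expect_equal(sum(sp$median_group == "High"), 2)
    expect_setequal(sp$sample_id[sp$median_group == "High"], c("P1", "P4"))

    set.seed(44)
    for (i in 1:5) {
        n <- sample(4:40, 1)
        bb <- data.frame(sample_id = sprintf("S%02d", 1:n),
                         burden = rpois(n, 4))
        sp <- splitByMedian(bb)
        expect_lte(max(sp$burden[sp$median_group == "Low"]),
                   min(sp$burden[sp$median_group == "High"]))
    }
    expect_error(splitByMedian(b5[1, , drop = FALSE]), "at least 2")
})

test_that("Mutant/Wild labels follow the gene-overlap rule", {
    gene <- GRanges("chr1", IRanges(1000, 2000))
    seg <- segsFor(data.frame(sample = c("a", "b", "c"),
                              chrom = c("chr1", "chr1", "chr2"),
                              start = c(500, 2001, 900),
                              end = c(2500, 3000, 2100)))
    mw <- classifyMutantWild(seg, gene, samples = c("a", "b", "c", "d"))
    lbl <- setNames(as.character(mw$status), mw$sample_id)
    expect_equal(unname(lbl["a"]), "Mutant")  # segment contains the gene
    expect_equal(unname(lbl["b"]), "Wild")    # starts just past the gene end
    expect_equal(unname(lbl["c"]), "Wild")    # other chromosome
    expect_equal(unname(lbl["d"]), "Wild")    # no segments at all

    set.seed(66)
    sizes <- c(chr1 = 5e6, chr2 = 5e6)
    seg <- randomSegmentsGR(300, sizes, 25)
    gene <- GRanges("chr1", IRanges(2.2e6, 2.4e6))
    samples <- sort(unique(mcols(seg)$sample_id))
    mw <- classifyMutantWild(seg, gene, samples = samples)
    # nested-loop oracle on half-open coordinates
    segHO <- grToHalfOpen(seg, mcols(seg)$sample_id)
    geneHO <- grToHalfOpen(gene)
    oracleMut <- unique(segHO$sample[segHO$chrom == geneHO$chrom &
                                     segHO$start0 < geneHO$end0 &
                                     segHO$end0 > geneHO$start0])
    expect_setequal(mw$sample_id[mw$status == "Mutant"], oracleMut)
    # invariant to segment order
    mw2 <- classifyMutantWild(seg[sample(length(seg))], gene,
                              samples = samples)
    expect_equal(mw, mw2)
})

test_that("Welch t-test matches the from-scratch formula and handles edges", {
    expect_equal(groupTTest(c(1, 2, 3), c(1, 2, 3))$t, 0)
    expect_equal(groupTTest(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

    jitter <- c(1e-6, -1e-6, 2e-6, -2e-6)
    res <- groupTTest(0 + jitter, 5 + jitter)
    expect_lt(res$p_value, 1e-4)

    set.seed(19)
    for (i in 1:50) {
        x <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 2))
        y <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
        got <- groupTTest(x, y)
        ref <- welchOracle(x, y)
        expect_equal(got$t, ref$t, tolerance = 1e-10)
        expect_equal(got$p_value, ref$p, tolerance = 1e-10)
    }

    # degenerate groups flagged untestable, never an exception
    expect_false(groupTTest(c(1, 1, 1), c(1, 1, 1))$testable)
    expect_false(groupTTest(1, c(2, 3, 4))$testable)
    expect_true(is.na(groupTTest(1, c(2, 3, 4))$p_value))
})

test_that("tertile grouping cuts ranks into near-equal thirds", {
    expect_equal(as.vector(table(tertileGroups(rnorm(9)))), c(3, 3, 3))
    expect_equal(as.vector(table(tertileGroups(rnorm(10)))), c(4, 3, 3))
    expect_equal(as.vector(table(tertileGroups(rnorm(332)))),
                 c(111, 111, 110))
    # ordering respected: every Low value <= every High value
    set.seed(4)
    v <- rpois(50, 3)
    g <- tertileGroups(v, sprintf("s%02d", 1:50))
    expect_lte(max(v[g == "Low"]), min(v[g == "High"]))
    expect_error(tertileGroups(c(1, 2)), "at least 3")
})

test_that("KM curves and log-rank match the 6-subject hand calculation", {
    # subjects: times 1..6, events 1,1,0,1,0,1; group A = {1,3,5}, B = {2,4,6}
    time <- 1:6
    event <- c(1, 1, 0, 1, 0, 1)
    group <- rep(c("A", "B"), 3)
    km <- kmLogrank(time, event, group)

    curvA <- km$curves[km$curves$group == "A", ]
    curvB <- km$curves[km$curves$group == "B", ]
    # hand KM: A drops to 2/3 at t=1 then is flat (censored at 3 and 5)
    expect_equal(curvA$survival[curvA$time == 1], 2 / 3, tolerance = 1e-10)
    expect_equal(curvA$survival[curvA$time == 5], 2 / 3, tolerance = 1e-10)
    # hand KM: B = 2/3, 1/3, 0 at t = 2, 4, 6
    expect_equal(curvB$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-10)
    # hand log-rank: O-E = -7/30, V = 641/900, chisq = 49/641
    expect_equal(km$chisq, 49 / 641, tolerance = 1e-10)
    expect_equal(km$p_value, pchisq(49 / 641, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
    expect_equal(km$df, 1L)
})

test_that("KM invariants: starts at 1, non-increasing, empirical when uncensored", {
    set.seed(23)
    time <- round(rexp(40, 1 / 100), 1)
    event <- rep(1L, 40)
    group <- rep(c("g1", "g2"), each = 20)
    km <- kmLogrank(time, event, group)
    for (g in c("g1", "g2")) {
        cv <- km$curves[km$curves$group == g, ]
        expect_true(all(cv$survival >= 0 & cv$survival <= 1))
        expect_true(all(diff(cv$survival) <= 1e-12))
        expect_lte(cv$survival[1], 1)
        # no censoring: KM equals the empirical survival function
        tg <- time[group == g]
        emp <- vapply(cv$time, function(t) mean(tg > t), numeric(1))
        expect_equal(cv$survival, emp, tolerance = 1e-12)
    }
})

test_that("log-rank degenerate cases: no events flagged, identical groups p=1", {
    expect_message(
        km <- kmLogrank(1:6, rep(0, 6), rep(c("a", "b"), 3)),
        "no events")
    expect_false(km$testable)
    expect_true(all(km$curves$survival == 1))

    # two identical groups: statistic 0, p 1
    time <- c(5, 10, 15, 5, 10, 15)
    event <- c(1, 0, 1, 1, 0, 1)
    km <- kmLogrank(time, event, rep(c("a", "b"), each = 3))
    expect_equal(km$chisq, 0, tolerance = 1e-12)
    expect_equal(km$p_value, 1, tolerance = 1e-12)

    # two-group chi-square equals the squared standardized O-E statistic
    set.seed(37)
    time <- rexp(30); event <- rbinom(30, 1, 0.7)
    group <- rep(c("a", "b"), 15)
    km <- kmLogrank(time, event, group)
    lr <- survival::survdiff(survival::Surv(time, event) ~ group)
    z2 <- (lr$obs[1] - lr$exp[1])^2 / lr$var[1, 1]
    expect_equal(km$chisq, unname(z2), tolerance = 1e-10)

    expect_error(kmLogrank(1:3, c(1, 1, 1), c("a", "a", "a")), "2 non-empty")
})
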