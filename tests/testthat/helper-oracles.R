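## Independent oracles: deliberately naive implementations used to verify
## the package's vectorised/GRanges-based code paths.

# Brute-force overlap counting on the stated inequality rule, applied to
# 0-based half-open coordinates (seg.start < win.end && seg.end > win.start).
# segDf/winDf: data.frames with chrom, start0, end0 (+ sample for segDf).
oracleCountMatrix <- function(segDf, winDf, samples) {
    m <- matrix(0L, nrow = nrow(winDf), ncol = length(samples),
                dimnames = list(NULL, samples))
    for (i in seq_len(nrow(segDf))) {
        for (w in seq_len(nrow(winDf))) {
            if (segDf$chrom[i] == winDf$chrom[w] &&
                segDf$start0[i] < winDf$end0[w] &&
                segDf$end0[i] > winDf$start0[w]) {
                s <- match(segDf$sample[i], samples)
                m[w, s] <- m[w, s] + 1L
            }
        }
    }
    m
}

# GRanges (1-based closed) -> half-open data.frame for the oracle.
grToHalfOpen <- function(gr, sample = NULL) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start0 = GenomicRanges::start(gr) - 1,
                     end0 = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE)
    if (!is.null(sample)) df$sample <- sample
    df
}

randomSegmentsGR <- function(n, sizes, nSamples, maxWidth = 2e6) {
    chrom <- sample(names(sizes), n, replace = TRUE)
    w <- pmax(1, round(runif(n, 1, maxWidth)))
    s <- floor(runif(n) * pmax(1, sizes[chrom] - w)) + 1
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, s + w - 1))
    S4Vectors::mcols(gr)$sample_id <- sprintf("S%02d", sample.int(nSamples, n,
                                                                  replace = TRUE))
    gr
}

# Welch's t from the textbook formula, no stats:: shortcuts.
welchOracle <- function(x, y) {
    m1 <- sum(x) / length(x); m2 <- sum(y) / length(y)
    v1 <- sum((x - m1)^2) / (length(x) - 1)
    v2 <- sum((y - m2)^2) / (length(y) - 1)
    se2 <- v1 / length(x) + v2 / length(y)
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / length(x))^2 / (length(x) - 1) +
                   (v2 / length(y))^2 / (length(y) - 1))
    p <- 2 * pt(-abs(t), df)
    list(t = t, df = df, p = p)
}

# Upper-tail hypergeometric by exhaustive enumeration of all C(N, n) draws.
hyperEnumOracle <- function(N, K, n, k) {
    draws <- combn(N, n)
    hits <- colSums(draws <= K)  # successes are items 1..K
    mean(hits >= k)
}
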