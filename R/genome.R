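## Bundled hg19 autosome lengths (UCSC chromInfo). X and Y are excluded from
## the default analysis set; widen via readChromSizes() on a custom file.
.HG19_AUTOSOMES <- c(
    chr1 = 249250621L, chr2 = 243199373L, chr3 = 198022430L,
    chr4 = 191154276L, chr5 = 180915260L, chr6 = 171115067L,
    chr7 = 159138663L, chr8 = 146364022L, chr9 = 141213431L,
    chr10 = 135534747L, chr11 = 135006516L, chr12 = 133851895L,
    chr13 = 115169878L, chr14 = 107349540L, chr15 = 102531392L,
    chr16 = 90354753L, chr17 = 81195210L, chr18 = 78077248L,
    chr19 = 59128983L, chr20 = 63025520L, chr21 = 48129895L,
    chr22 = 51304566L)

#' hg19 autosome lengths
#'
#' The bundled UCSC hg19 chromosome lengths for chr1-chr22. Sex chromosomes
#' are excluded from the default analysis set; supply a custom sizes table
#' via [readChromSizes()] to widen it.
#'
#' @return a named integer vector, chromosome name to length in bp.
#' @examples
#' sum(ceiling(hg19ChromSizes() / 1e6))  # 2897 one-megabase windows
#' @export
hg19ChromSizes <- function() .HG19_AUTOSOMES

#' Read a UCSC-style chrom.sizes file
#'
#' Two-column TSV (chromosome name, length), no header, as in UCSC
#' chromInfo exports.
#'
#' @param path file path.
#' @param autosomesOnly drop chrX/chrY and non-canonical contigs
#'   (default TRUE, matching the analysis set of the pipeline).
#' @return named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path, autosomesOnly = TRUE) {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("chrom.sizes must have two columns: name, length")
    sizes <- setNames(as.integer(tab[[2]]), as.character(tab[[1]]))
    if (anyNA(sizes) || any(sizes <= 0))
        stop("all chromosome lengths must be positive integers")
    if (anyDuplicated(names(sizes)))
        stop("duplicated chromosome names in ", path)
    if (autosomesOnly) {
        keep <- grepl("^(chr)?[0-9]+$", names(sizes))
        dropped <- sum(!keep)
        if (dropped) message(dropped, " non-autosomal chromosome(s) dropped")
        sizes <- sizes[keep]
    }
    if (!length(sizes)) stop("no chromosomes left after filtering")
    sizes
}

#' Tile a genome into fixed-width windows
#'
#' Partitions every chromosome into contiguous, non-overlapping windows of
#' `windowSize` bp. The last window of each chromosome is kept even when
#' shorter, so each chromosome contributes `ceiling(length / windowSize)`
#' windows and the windows cover it exactly. With the bundled hg19
#' autosomes at 1 Mb this yields 2,897 windows.
#'
#' @param sizes named vector of chromosome lengths (default
#'   [hg19ChromSizes()]).
#' @param windowSize window width in bp (default 1e6).
#' @return a `GRanges` with one range per window, ordered by chromosome then
#'   start, carrying a `window_index` column (1..N genome-wide).
#' @examples
#' length(tileWindows())  # 2897
#' @export
tileWindows <- function(sizes = hg19ChromSizes(), windowSize = 1e6) {
    if (!length(sizes)) stop("empty chromosome sizes table")
    if (windowSize <= 0) stop("windowSize must be positive")
    tiles <- tileGenome(seqlengths = sizes, tilewidth = windowSize,
                        cut.last.tile.in.chrom = TRUE)
    mcols(tiles)$window_index <- seq_along(tiles)
    tiles
}

#' Export windows as BED3+1
#'
#' Writes windows in BED convention (0-based half-open starts) with the
#' window index in the name column.
#'
#' @param windows `GRanges` from [tileWindows()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
exportWindowsBed <- function(windows, path) {
    df <- data.frame(chrom = as.character(seqnames(windows)),
                     start = start(windows) - 1L,
                     end = end(windows),
                     name = mcols(windows)$window_index)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
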