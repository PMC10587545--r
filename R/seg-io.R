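## Readers and writers for the on-disk formats the pipeline consumes:
## SEG segment tables, BED4 gene annotations, expression matrices,
## clinical tables and GMT term files. All coordinates are normalised to
## the internal GRanges (1-based, closed) convention at this boundary.

.normChrom <- function(x) {
    x <- as.character(x)
    ifelse(grepl("^chr", x), x, paste0("chr", x))
}

.isAutosome <- function(x) grepl("^chr[0-9]+$", x)

#' Harmonize sample identifiers
#'
#' Truncates TCGA-style dash-separated barcodes to a fixed number of leading
#' fields (default 3 = patient level, e.g. `TCGA-BR-4183-01A` ->
#' `TCGA-BR-4183`) so that segment, expression and clinical tables join on
#' the same key. Identifiers with fewer fields pass through unchanged; the
#' operation is idempotent.
#'
#' @param ids character vector of sample identifiers.
#' @param nFields number of dash-separated fields to keep.
#' @return character vector of harmonized identifiers.
#' @export
harmonizeSampleIds <- function(ids, nFields = 3) {
    vapply(strsplit(as.character(ids), "-", fixed = TRUE), function(f) {
        paste(f[seq_len(min(length(f), nFields))], collapse = "-")
    }, character(1))
}

#' Read a SEG segment table
#'
#' Expects a header and at least the columns sample, chromosome, start, end,
#' optionally followed by probe count and segment mean (the TCGA SNP6
#' column order). Coordinates are declared via `dialect`: `"1based"`
#' (TCGA convention, default) means 1-based inclusive start and end;
#' `"0based"` means 0-based half-open. Rows on chrX/chrY or non-canonical
#' contigs are dropped with a message, as are rows whose interval is empty
#' after normalisation; if more than half of all rows are rejected the read
#' aborts, on the assumption of a systematic dialect mismatch.
#'
#' @param path SEG file path.
#' @param dialect `"1based"` or `"0based"`.
#' @param harmonize truncate sample barcodes via [harmonizeSampleIds()]
#'   (set to 0 to disable).
#' @return a `GRanges` with metadata columns `sample_id`, and when present
#'   `num_probes` and `segment_mean`.
#' @export
readSeg <- function(path, dialect = c("1based", "0based"), harmonize = 3) {
    dialect <- match.arg(dialect)
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (ncol(tab) < 4)
        stop("SEG file needs at least 4 columns (sample, chrom, start, end): ",
             path)
    n0 <- nrow(tab)
    if (!n0) stop("empty SEG file: ", path)
    sample_id <- as.character(tab[[1]])
    chrom <- .normChrom(tab[[2]])
    start <- suppressWarnings(as.numeric(tab[[3]]))
    end <- suppressWarnings(as.numeric(tab[[4]]))
    bad <- !complete.cases(start, end) | is.na(sample_id) | sample_id == ""
    if (any(bad)) {
        if (sum(bad) > 0.5 * n0)
            stop("more than half of the SEG rows are malformed; ",
                 "first bad line: ", which(bad)[1] + 1L)
        message(sum(bad), " malformed SEG row(s) rejected (lines ",
                paste(head(which(bad) + 1L, 5), collapse = ", "), " ...)")
    }
    # to 1-based closed
    if (dialect == "0based") start <- start + 1
    offchrom <- !.isAutosome(chrom) & !bad
    if (any(offchrom))
        message(sum(offchrom),
                " segment(s) on excluded chromosomes dropped")
    empty <- !bad & !offchrom & end < start
    if (any(empty))
        message(sum(empty), " empty segment(s) rejected (end <= start)")
    keep <- !(bad | offchrom | empty)
    if (!any(keep)) stop("no usable segments in ", path)
    if (harmonize > 0) sample_id <- harmonizeSampleIds(sample_id, harmonize)
    gr <- GRanges(chrom[keep], IRanges(start[keep], end[keep]))
    mcols(gr)$sample_id <- sample_id[keep]
    # optional columns matched by header name, falling back to the TCGA
    # positional order (5 = probe count, 6 = segment mean)
    extra <- setdiff(seq_len(ncol(tab)), 1:4)
    probeCol <- extra[grepl("probe", names(tab)[extra], ignore.case = TRUE)][1]
    meanCol <- extra[grepl("mean", names(tab)[extra], ignore.case = TRUE)][1]
    if (is.na(probeCol) && is.na(meanCol)) {
        probeCol <- if (ncol(tab) >= 5) 5L else NA_integer_
        meanCol <- if (ncol(tab) >= 6) 6L else NA_integer_
    }
    if (!is.na(probeCol)) mcols(gr)$num_probes <- suppressWarnings(
        as.integer(tab[[probeCol]][keep]))
    if (!is.na(meanCol)) mcols(gr)$segment_mean <- suppressWarnings(
        as.numeric(tab[[meanCol]][keep]))
    gr
}

#' Write segments as a SEG table
#'
#' Inverse of [readSeg()]; emits the TCGA column order with coordinates in
#' the requested dialect.
#'
#' @param segments `GRanges` with a `sample_id` column.
#' @param path output path.
#' @param dialect `"1based"` (default) or `"0based"`.
#' @return invisibly, the path.
#' @export
writeSeg <- function(segments, path, dialect = c("1based", "0based")) {
    dialect <- match.arg(dialect)
    s <- start(segments)
    if (dialect == "0based") s <- s - 1L
    df <- data.frame(Sample = mcols(segments)$sample_id,
                     Chromosome = as.character(seqnames(segments)),
                     Start = s, End = end(segments))
    if (!is.null(mcols(segments)$num_probes))
        df$Num_Probes <- mcols(segments)$num_probes
    if (!is.null(mcols(segments)$segment_mean))
        df$Segment_Mean <- mcols(segments)$segment_mean
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a BED4 gene annotation
#'
#' BED is 0-based half-open; records are converted to the internal 1-based
#' closed convention. Records on excluded chromosomes are dropped and exact
#' duplicates (same symbol, same interval) collapsed.
#'
#' @param path BED4 file (chrom, start, end, symbol; no header).
#' @return `GRanges` with a `symbol` metadata column.
#' @export
readBedGenes <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(mcols(gr)$name) || any(is.na(mcols(gr)$name)) ||
        any(mcols(gr)$name == ""))
        stop("BED gene annotation needs a symbol in column 4: ", path)
    chrom <- .normChrom(as.character(seqnames(gr)))
    keep <- .isAutosome(chrom)
    if (any(!keep))
        message(sum(!keep), " gene record(s) on excluded chromosomes dropped")
    gr <- gr[keep]
    out <- GRanges(.normChrom(as.character(seqnames(gr))),
                   IRanges(start(gr), end(gr)))
    mcols(out)$symbol <- as.character(mcols(gr)$name)
    dup <- duplicated(paste(seqnames(out), start(out), end(out),
                            mcols(out)$symbol))
    out[!dup]
}

#' Write genes as BED4
#' @param genes `GRanges` with a `symbol` column.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeBedGenes <- function(genes, path) {
    df <- data.frame(chrom = as.character(seqnames(genes)),
                     start = start(genes) - 1L, end = end(genes),
                     name = mcols(genes)$symbol)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a GMT gene-set file
#'
#' One term per line: term id, description, then member symbols, all
#' tab-separated. Terms with no members are rejected.
#'
#' @param path GMT file.
#' @return a named list of character vectors (member symbols), with the
#'   term descriptions in `attr(, "description")`.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(fields) < 3
    if (any(bad))
        stop("GMT line(s) without members: ",
             paste(head(which(bad), 5), collapse = ", "))
    ids <- vapply(fields, `[[`, character(1), 1)
    if (anyDuplicated(ids)) stop("duplicated term ids in ", path)
    genes <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(genes) <- ids
    attr(genes, "description") <- setNames(
        vapply(fields, `[[`, character(1), 2), ids)
    genes
}

#' Write a GMT gene-set file
#' @param terms named list as returned by [readGmt()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeGmt <- function(terms, path) {
    desc <- attr(terms, "description")
    if (is.null(desc)) desc <- setNames(names(terms), names(terms))
    lines <- vapply(names(terms), function(id) {
        paste(c(id, desc[[id]], terms[[id]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read an expression matrix
#'
#' Genes x samples TSV with gene symbols in the first column and sample ids
#' in the header. Duplicated gene symbols are an error.
#'
#' @param path TSV file.
#' @param harmonize barcode truncation depth for column names (0 disables).
#' @return numeric matrix, rownames = gene symbols.
#' @export
readExpression <- function(path, harmonize = 3) {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    genes <- as.character(tab[[1]])
    if (anyDuplicated(genes))
        stop("duplicated gene symbol(s) in expression matrix: ",
             paste(unique(genes[duplicated(genes)])[1:3], collapse = ", "))
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
    if (harmonize > 0)
        colnames(m) <- harmonizeSampleIds(colnames(m), harmonize)
    if (anyDuplicated(colnames(m)))
        stop("sample ids collide after harmonization in ", path)
    m
}

#' Write an expression matrix
#' @param mat numeric matrix with gene rownames.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeExpression <- function(mat, path) {
    df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a clinical (overall survival) table
#'
#' TSV with a header and columns sample id, survival time (days) and event
#' indicator (1 = death observed, 0 = censored). Duplicated sample ids are
#' an error.
#'
#' @param path TSV file.
#' @param harmonize barcode truncation depth (0 disables).
#' @return `data.frame` with columns `sample_id`, `time`, `event`.
#' @export
readClinical <- function(path, harmonize = 3) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (ncol(tab) < 3)
        stop("clinical table needs 3 columns (sample, time, event): ", path)
    out <- data.frame(sample_id = as.character(tab[[1]]),
                      time = as.numeric(tab[[2]]),
                      event = as.integer(tab[[3]]),
                      stringsAsFactors = FALSE)
    if (harmonize > 0)
        out$sample_id <- harmonizeSampleIds(out$sample_id, harmonize)
    if (anyDuplicated(out$sample_id))
        stop("duplicated sample id(s) in clinical table: ", path)
    if (any(is.na(out$time)) || any(out$time < 0))
        stop("survival times must be >= 0")
    if (!all(out$event %in% c(0L, 1L)))
        stop("event indicator must be 0 or 1")
    out
}

#' Write a clinical table
#' @param clinical `data.frame` as from [readClinical()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeClinical <- function(clinical, path) {
    write.table(clinical[, c("sample_id", "time", "event")], path,
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a result table as TSV
#'
#' All pipeline result tables go through this writer: tab-separated, header,
#' no quoting, no row names — a fixed, diff-friendly on-disk form.
#'
#' @param records a `data.frame`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTable <- function(records, path) {
    write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
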