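#' @importFrom Biostrings writeXStringSet readDNAStringSet
#' @importFrom utils read.delim write.table
#' @importFrom jsonlite toJSON fromJSON
NULL

#' Read and write gene annotations
#'
#' The TSV dialect is 0-based half-open with columns `gene_id`, `chrom`,
#' `start`, `end`, `strand`, `biotype`, `target_class`; GFF3 (via
#' rtracklayer) is 1-based inclusive with `ID`, `biotype` and
#' `target_class` attributes on `gene` features. Both round-trip the
#' internal `GRanges` representation.
#'
#' @param annotation `GRanges` named by gene id with `biotype` and
#'   `target_class` metadata columns.
#' @param path File path.
#' @return Readers return the annotation `GRanges`; writers return `path`
#'   invisibly.
#' @name annotation-io
NULL

#' @rdname annotation-io
#' @export
writeAnnotationTsv <- function(annotation, path) {
    df <- data.frame(
        gene_id = names(annotation),
        chrom = as.character(GenomeInfoDb::seqnames(annotation)),
        start = start(annotation) - 1L,           # 0-based half-open
        end = end(annotation),
        strand = as.character(strand(annotation)),
        biotype = mcols(annotation)$biotype,
        target_class = mcols(annotation)$target_class)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname annotation-io
#' @export
readAnnotationTsv <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                  strand = df$strand, biotype = df$biotype,
                  target_class = df$target_class)
    names(gr) <- df$gene_id
    gr
}

#' @rdname annotation-io
#' @export
writeAnnotationGff3 <- function(annotation, path) {
    gr <- annotation
    mcols(gr) <- DataFrame(source = "smallRNAtools", type = "gene",
                           ID = names(gr),
                           biotype = mcols(annotation)$biotype,
                           target_class = mcols(annotation)$target_class)
    rtracklayer::export(gr, path, format = "gff3")
    invisible(path)
}

#' @rdname annotation-io
#' @export
readAnnotationGff3 <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    out <- GRanges(GenomeInfoDb::seqnames(gr), IRanges(start(gr), end(gr)),
                   strand = strand(gr),
                   biotype = as.character(mcols(gr)$biotype),
                   target_class = as.character(mcols(gr)$target_class))
    names(out) <- as.character(mcols(gr)$ID)
    out
}

#' Read and write aligned records
#'
#' The canonical TSV dialect has columns `read_id`, `chrom`, `pos0`
#' (0-based leftmost), `strand`, `length`, `seq`, `n_hits`. The SAM writer
#' emits a minimal valid single-end SAM (1-based POS, FLAG 16 for
#' minus-strand reads, `<n>M` CIGAR, `NH:i` tag, SEQ on the reference
#' forward strand as SAM requires); the SAM reader goes through
#' Rsamtools (SAM -> BAM -> records) and restores the read-strand
#' sequence.
#'
#' @param records `GRanges` with `read_id`, `seq`, `n_hits` metadata
#'   columns; strand = read strand.
#' @param path File path.
#' @param seqlens Named vector of chromosome lengths for the SAM header
#'   (defaults to `seqlengths(records)`).
#' @return Readers return the records `GRanges`; writers return `path`
#'   invisibly.
#' @name alignment-io
NULL

#' @rdname alignment-io
#' @export
writeAlignmentsTsv <- function(records, path) {
    df <- data.frame(
        read_id = mcols(records)$read_id,
        chrom = as.character(GenomeInfoDb::seqnames(records)),
        pos0 = start(records) - 1L,
        strand = as.character(strand(records)),
        length = width(records),
        seq = mcols(records)$seq,
        n_hits = mcols(records)$n_hits)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname alignment-io
#' @export
readAlignmentsTsv <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    gr <- GRanges(df$chrom, IRanges(df$pos0 + 1L, width = df$length),
                  strand = df$strand)
    mcols(gr)$read_id <- df$read_id
    mcols(gr)$seq <- df$seq
    mcols(gr)$n_hits <- as.integer(df$n_hits)
    gr
}

#' @rdname alignment-io
#' @export
writeSam <- function(records, path, seqlens = NULL) {
    if (is.null(seqlens)) seqlens <- seqlengths(records)
    if (any(is.na(seqlens)))
        stop("chromosome lengths required for the SAM header", call. = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("@HD\tVN:1.6\tSO:unknown", con)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), seqlens), con)
    if (length(records)) {
        neg <- as.character(strand(records)) == "-"
        seqs <- mcols(records)$seq
        # SAM stores SEQ on the reference forward strand
        if (any(neg))
            seqs[neg] <- as.character(reverseComplement(DNAStringSet(seqs[neg])))
        writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d",
                           mcols(records)$read_id, ifelse(neg, 16L, 0L),
                           as.character(GenomeInfoDb::seqnames(records)),
                           start(records), width(records), seqs,
                           mcols(records)$n_hits), con)
    }
    invisible(path)
}

#' @rdname alignment-io
#' @export
readSam <- function(path) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    p <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "strand", "seq"),
        tag = "NH")
    x <- Rsamtools::scanBam(bam, param = p)[[1L]]
    keep <- !is.na(x$pos)
    st <- as.character(x$strand)[keep]
    seqs <- as.character(x$seq)[keep]
    neg <- st == "-"
    if (any(neg))   # restore read-strand sequence
        seqs[neg] <- as.character(reverseComplement(DNAStringSet(seqs[neg])))
    gr <- GRanges(as.character(x$rname)[keep],
                  IRanges(x$pos[keep], width = nchar(seqs)), strand = st)
    mcols(gr)$read_id <- x$qname[keep]
    mcols(gr)$seq <- seqs
    nh <- x$tag$NH[keep]
    mcols(gr)$n_hits <- if (is.null(nh)) rep(1L, sum(keep))
                        else ifelse(is.na(nh), 1L, nh)
    unlink(paste0(bam, c("", ".bai")))
    gr
}

#' Read and write CountTables as TSV with a JSON parameter header
#'
#' The file starts with `#` lines carrying a JSON object (sample id, class
#' filter, normalisation mode and total) followed by a
#' `gene_id/count/rpm` table, so each table records how it was produced.
#'
#' @param x A [CountTable-class].
#' @param path File path.
#' @return `readCountTableTsv` returns a [CountTable-class];
#'   `writeCountTableTsv` returns `path` invisibly.
#' @name counttable-io
NULL

#' @rdname counttable-io
#' @export
writeCountTableTsv <- function(x, path) {
    hdr <- toJSON(list(sample_id = x@sampleId, class_filter = x@classFilter,
                       norm_mode = x@normMode, total = x@total),
                  auto_unbox = TRUE, digits = NA)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", hdr), con)
    write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' @rdname counttable-io
#' @export
readCountTableTsv <- function(path) {
    lines <- readLines(path)
    hdrLine <- grep("^# ", lines)[1L]
    hdr <- fromJSON(sub("^# ", "", lines[hdrLine]))
    df <- read.delim(text = lines[-seq_len(hdrLine)],
                     stringsAsFactors = FALSE)
    obj <- new("CountTable", sampleId = hdr$sample_id,
               counts = stats::setNames(as.integer(df$count), df$gene_id),
               rpm = stats::setNames(df$rpm, df$gene_id),
               total = hdr$total, classFilter = hdr$class_filter,
               normMode = hdr$norm_mode)
    validObject(obj)
    obj
}

#' Export a coverage track as bedGraph
#'
#' @param track A [CoverageTrack-class].
#' @param annotation Gene `GRanges` (for genomic placement).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(track, annotation, path) {
    g <- annotation[track@geneId]
    v <- track@values
    gr <- GRanges(GenomeInfoDb::seqnames(g),
                  IRanges(start(g) + seq_along(v) - 1L, width = 1L),
                  score = v)
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}

#' Write a simulated world to disk
#'
#' Emits the genome FASTA, the annotation (both GFF3 and TSV dialects) and
#' a truth sidecar TSV of per-gene baseline abundances with target class
#' and planted memberships, into `dir`.
#'
#' @param sim Output of [buildTruth()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
writeSimData <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "genome.fa")
    writeXStringSet(sim$genome, fa)
    tsv <- writeAnnotationTsv(sim$annotation, file.path(dir, "genes.tsv"))
    gff <- writeAnnotationGff3(sim$annotation, file.path(dir, "genes.gff3"))
    truth <- sim$truth
    planted <- lapply(truth@ipTargets, `[[`, "genes")
    df <- data.frame(gene_id = names(truth@abundance),
                     abundance = unname(truth@abundance))
    for (b in names(planted))
        df[[paste0("ip_target_", gsub("[^A-Za-z0-9]", "_", b))]] <-
            df$gene_id %in% planted[[b]]
    tpath <- file.path(dir, "truth.tsv")
    write.table(df, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(genome = fa, genes_tsv = tsv, genes_gff3 = gff,
                truth = tpath))
}
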