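# Shared fixtures: hand-built annotations/reads for oracle tests, and a
# small simulated world for integration-style tests.

library(GenomicRanges)
library(S4Vectors)

# IRanges also exports a `members` generic (Grouping API) and masks ours
# once GenomicRanges attaches; pin the accessors the tests mean.
members <- smallRNAtools::members
rpm <- smallRNAtools::rpm

# A tiny hand-laid annotation: two plus-strand mRNAs, one minus-strand
# mRNA, a piRNA locus nested inside geneA, and a miRNA locus.
tinyAnnotation <- function() {
    gr <- GRanges("chrI",
        IRanges(start = c(101L, 401L, 701L, 151L, 901L),
                end   = c(300L, 600L, 900L, 171L, 922L)),
        strand = c("+", "+", "-", "+", "+"),
        biotype = c("mRNA", "mRNA", "mRNA", "piRNA", "miRNA"),
        target_class = c("WAGO", "CSR1", "none", "none", "none"))
    names(gr) <- c("geneA", "geneB", "geneC", "pir1", "mir1")
    gr
}

# Build an aligned-record GRanges from a compact spec.
makeReads <- function(start, width, strand, seq = NULL, n_hits = 1L,
                      chrom = "chrI") {
    n <- length(start)
    gr <- GRanges(chrom, IRanges(start, width = rep(width, length.out = n)),
                  strand = strand)
    mcols(gr)$read_id <- sprintf("r%03d", seq_len(n))
    mcols(gr)$seq <- if (is.null(seq))
        vapply(BiocGenerics::width(gr), function(w)
            paste(rep("A", w), collapse = ""), "") else seq
    mcols(gr)$n_hits <- rep(as.integer(n_hits), length.out = n)
    gr
}

# Brute-force per-read tally: the independent oracle for quantify.
# Re-implements the counting rules one read at a time with plain loops.
naiveQuantify <- function(records, annotation, classFilter = "22G") {
    ids <- names(annotation)
    counts <- setNames(rep(0L, length(ids)), ids)
    for (i in seq_along(records)) {
        rec <- records[i]
        lab <- as.character(classifyReads(rec, annotation)$label)
        g <- classifyReads(rec, annotation)$gene_id
        if (!is.na(g) && lab == classFilter)
            counts[g] <- counts[g] + 1L
    }
    counts
}

# Small simulated world shared across tests (built once per test run).
smallWorldConfig <- function(...) {
    simConfig(nMrna = 60L, nPirna = 8L, nMirna = 4L, nWago = 15L,
              nCsr1 = 20L,
              ipTargets = list("WAGO-1" = list(class = "WAGO", n = 10L,
                                               e = 4)),
              ...)
}
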