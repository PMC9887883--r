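#' @importFrom GenomicRanges findOverlaps pintersect
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Classification rules for small-RNA reads
#'
#' The defaults implement the standard 22G extraction: a read is 22G iff
#' it maps uniquely (`n_hits == 1`), is exactly 22 nt long and lies
#' antisense to an mRNA gene. The 5'-G check is off by default — the class
#' is defined operationally by length, strand and uniqueness — and can be
#' switched on. piRNA calls require sense overlap of a piRNA locus, with
#' optional 21-nt length and 5'-U checks. Overlapping loci are resolved
#' with precedence piRNA > miRNA > mRNA.
#'
#' @param g22Length Required 22G read length. Default 22.
#' @param require5primeG Also require the read to start with G. Default
#'   `FALSE`.
#' @param requireUnique Require `n_hits == 1` for 22G calls. Default `TRUE`.
#' @param pirnaLength Required piRNA length, or `NA` to skip the check.
#'   Default `NA`.
#' @param require5primeU Require piRNA reads to start with U/T. Default
#'   `FALSE`.
#' @param minOverlap Minimum overlap (nt) to assign a read to a gene.
#'   Default 1.
#' @return Named list of rules, for [classifyReads()].
#' @export
classifyRules <- function(g22Length = 22L, require5primeG = FALSE,
                          requireUnique = TRUE, pirnaLength = NA_integer_,
                          require5primeU = FALSE, minOverlap = 1L) {
    list(g22Length = as.integer(g22Length), require5primeG = require5primeG,
         requireUnique = requireUnique, pirnaLength = as.integer(pirnaLength),
         require5primeU = require5primeU, minOverlap = as.integer(minOverlap))
}

# Largest-overlap gene assignment within one biotype; ties to the
# lexicographically smallest gene_id (deterministic, order-independent).
.assignByOverlap <- function(records, anno, sameStrand = NA) {
    # reads on chromosomes unknown to the annotation simply never overlap
    hits <- suppressWarnings(findOverlaps(records, anno,
                                          ignore.strand = TRUE,
                                          minoverlap = 1L))
    if (!length(hits))
        return(rep(NA_character_, length(records)))
    q <- queryHits(hits); s <- subjectHits(hits)
    if (!is.na(sameStrand)) {
        same <- as.character(strand(records))[q] ==
            as.character(strand(anno))[s]
        keep <- if (sameStrand) same else !same
        q <- q[keep]; s <- s[keep]
    }
    out <- rep(NA_character_, length(records))
    if (!length(q)) return(out)
    ow <- width(pintersect(GRanges(records[q]), anno[s],
                           ignore.strand = TRUE))
    gid <- names(anno)[s]
    o <- order(q, -ow, gid)             # per read: biggest overlap, then id
    q <- q[o]; gid <- gid[o]
    first <- !duplicated(q)
    out[q[first]] <- gid[first]
    out
}

#' Classify aligned reads into small-RNA classes
#'
#' Assigns each record one label in `{22G, piRNA, miRNA, other,
#' unassigned}` plus (where applicable) a source gene. Precedence for reads
#' overlapping several biotypes is piRNA > miRNA > mRNA. 22G calls require
#' unique mapping, the configured length and antisense orientation to an
#' mRNA gene; reads overlapping an mRNA that fail those checks are labelled
#' `other` (still gene-assigned); reads overlapping nothing are
#' `unassigned`. Gene assignment among overlapping same-biotype genes goes
#' to the larger overlap, ties to the lexicographically smallest gene id.
#'
#' @param records `GRanges` of aligned reads with metadata columns `seq`
#'   and `n_hits` (missing `n_hits` treated as 1); strand = read strand.
#' @param annotation `GRanges` named by gene_id with metadata columns
#'   `biotype` and (optionally) `target_class`.
#' @param rules List from [classifyRules()].
#' @return [S4Vectors::DataFrame] with columns `label` and `gene_id`
#'   (NA when unassigned), one row per record.
#' @export
classifyReads <- function(records, annotation, rules = classifyRules()) {
    n <- length(records)
    lab <- rep("unassigned", n)
    gene <- rep(NA_character_, n)
    if (n == 0L)
        return(DataFrame(label = character(), gene_id = character()))
    nh <- mcols(records)$n_hits
    if (is.null(nh)) nh <- rep(1L, n)
    rlen <- width(records)
    seqs <- mcols(records)$seq

    biotype <- mcols(annotation)$biotype
    pAnno <- annotation[biotype == "piRNA"]
    miAnno <- annotation[biotype == "miRNA"]
    mAnno <- annotation[biotype == "mRNA"]

    # precedence piRNA (sense) > miRNA (any strand) > mRNA
    pGene <- .assignByOverlap(records, pAnno, sameStrand = TRUE)
    isP <- !is.na(pGene)
    if (!is.na(rules$pirnaLength)) isP <- isP & rlen == rules$pirnaLength
    if (rules$require5primeU && !is.null(seqs))
        isP <- isP & substr(seqs, 1L, 1L) %in% c("T", "U")
    lab[isP] <- "piRNA"; gene[isP] <- pGene[isP]

    rest <- which(!isP)
    miGene <- .assignByOverlap(records[rest], miAnno, sameStrand = NA)
    isMi <- !is.na(miGene)
    lab[rest[isMi]] <- "miRNA"; gene[rest[isMi]] <- miGene[isMi]

    rest2 <- rest[!isMi]
    # antisense mRNA assignment for 22G; sense/failed checks fall to other
    asGene <- .assignByOverlap(records[rest2], mAnno, sameStrand = FALSE)
    sGene <- .assignByOverlap(records[rest2], mAnno, sameStrand = TRUE)
    ok22 <- !is.na(asGene) & rlen[rest2] == rules$g22Length
    if (rules$requireUnique) ok22 <- ok22 & nh[rest2] == 1L
    if (rules$require5primeG && !is.null(seqs))
        ok22 <- ok22 & substr(seqs[rest2], 1L, 1L) == "G"
    lab[rest2[ok22]] <- "22G"; gene[rest2[ok22]] <- asGene[ok22]
    # overlapping an mRNA without qualifying as 22G -> other
    oth <- !ok22 & (!is.na(asGene) | !is.na(sGene))
    gOth <- ifelse(!is.na(sGene), sGene, asGene)
    lab[rest2[oth]] <- "other"; gene[rest2[oth]] <- gOth[oth]

    DataFrame(label = lab, gene_id = gene)
}

#' Quantify reads per gene and normalise to RPM
#'
#' Sums reads of the requested class per gene and normalises to reads per
#' million. The default denominator is the total number of mapped records
#' in the sample (`normMode = "all_mapped"`, matching normalisation by each
#' sample's total read count); `"class"` divides by the counted class
#' total instead, and `"unique_mapped"` by the number of uniquely mapping
#' records. The normalisation total, mode and class filter are recorded in
#' the returned table.
#'
#' @param records `GRanges` of aligned reads (see [classifyReads()]).
#' @param annotation Gene `GRanges` (defines the gene universe: all genes
#'   appear in the output, zero-filled).
#' @param classFilter Which reads to count per gene: `"22G"`, `"piRNA"`,
#'   `"miRNA"`, `"sense"` (any-gene sense overlap, no uniqueness — CLIP
#'   quantification) or `"all"` (any gene-assigned read). Default `"22G"`.
#' @param normMode `"all_mapped"`, `"class"` or `"unique_mapped"`.
#' @param rules Classification rules, see [classifyRules()].
#' @param sampleId Label recorded in the table.
#' @return A [CountTable-class].
#' @examples
#' # 3 reads on geneA and 1 on geneB with total 4 give RPM 750,000/250,000
#' @export
quantifySmallRNA <- function(records, annotation, classFilter = "22G",
                             normMode = c("all_mapped", "class",
                                          "unique_mapped"),
                             rules = classifyRules(),
                             sampleId = "sample") {
    normMode <- match.arg(normMode)
    ids <- names(annotation)
    counts <- stats::setNames(rep(0L, length(ids)), ids)
    if (length(records)) {
        if (classFilter == "sense") {
            gene <- .assignByOverlap(records, annotation, sameStrand = TRUE)
            sel <- !is.na(gene)
        } else {
            cls <- classifyReads(records, annotation, rules)
            sel <- if (classFilter == "all") !is.na(cls$gene_id)
                   else cls$label == classFilter & !is.na(cls$gene_id)
            gene <- cls$gene_id
        }
        if (any(sel)) {
            tab <- table(factor(gene[sel], levels = ids))
            counts <- stats::setNames(as.integer(tab), ids)
        }
    }
    nh <- mcols(records)$n_hits
    if (is.null(nh)) nh <- rep(1L, length(records))
    total <- switch(normMode,
        all_mapped = length(records),
        class = sum(counts),
        unique_mapped = sum(nh == 1L))
    rpmv <- if (total > 0) counts / total * 1e6 else counts * 0
    obj <- new("CountTable", sampleId = sampleId, counts = counts,
               rpm = rpmv, total = as.numeric(total),
               classFilter = classFilter, normMode = normMode)
    validObject(obj)
    obj
}
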