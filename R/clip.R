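#' @importFrom IRanges coverage Views restrict
#' @importFrom stats approx
NULL

#' Per-class read composition of a library
#'
#' Classifies every mapped record (precedence piRNA > miRNA > mRNA) and
#' reports the percentage of reads per RNA class, i.e. the per-class sum
#' of mapped reads divided by the total mapped read count. For CLIP
#' libraries the mRNA class counts sense fragments; classification rules
#' can be relaxed via `rules` (by default no length/uniqueness constraints
#' are imposed on the mRNA class here — any gene-overlapping read counts
#' toward its biotype).
#'
#' @param records `GRanges` of mapped reads.
#' @param annotation Gene `GRanges` with a `biotype` metadata column.
#' @return `data.frame` with columns `class` (`mRNA`, `piRNA`, `miRNA`,
#'   `other`), `reads` and `percent` (sums to 100 up to rounding); zero
#'   mapped reads give a zero-row frame with attribute `empty = TRUE`.
#' @export
classComposition <- function(records, annotation) {
    if (!length(records)) {
        out <- data.frame(class = character(), reads = integer(),
                          percent = numeric())
        attr(out, "empty") <- TRUE
        return(out)
    }
    biotype <- mcols(annotation)$biotype
    pGene <- .assignByOverlap(records, annotation[biotype == "piRNA"],
                              sameStrand = TRUE)
    miGene <- .assignByOverlap(records, annotation[biotype == "miRNA"],
                               sameStrand = NA)
    mGene <- .assignByOverlap(records, annotation[biotype == "mRNA"],
                              sameStrand = NA)
    cls <- ifelse(!is.na(pGene), "piRNA",
           ifelse(!is.na(miGene), "miRNA",
           ifelse(!is.na(mGene), "mRNA", "other")))
    lev <- c("mRNA", "piRNA", "miRNA", "other")
    tab <- table(factor(cls, levels = lev))
    data.frame(class = lev, reads = as.integer(tab),
               percent = as.numeric(tab) / length(records) * 100)
}

#' Per-base coverage track for one gene
#'
#' Piles up read intervals over the gene span and scales per-base depth to
#' RPM units using the sample total (`scale = 1e6 / total`); with
#' `total = NULL` raw depth is returned.
#'
#' @param records `GRanges` of aligned reads.
#' @param annotation Gene `GRanges` (named by gene id).
#' @param gene Gene id present in `annotation`.
#' @param total Normalisation total (reads), or `NULL` for raw depth.
#' @param senseOnly Count only reads on the gene's strand (`TRUE`), only
#'   antisense reads (`FALSE`) or all reads (`NA`, default).
#' @return A [CoverageTrack-class] whose `values` run over the gene span
#'   in genomic (left-to-right) order.
#' @export
coverageTrack <- function(records, annotation, gene, total = NULL,
                          senseOnly = NA) {
    if (!gene %in% names(annotation))
        stop("gene '", gene, "' not in the annotation", call. = FALSE)
    g <- annotation[gene]
    if (!is.na(senseOnly)) {
        same <- as.character(strand(records)) == as.character(strand(g))
        records <- records[if (senseOnly) same else !same]
    }
    sel <- records[as.character(GenomeInfoDb::seqnames(records)) ==
                   as.character(GenomeInfoDb::seqnames(g))]
    L <- width(g)
    vals <- rep(0, L)
    if (length(sel)) {
        cov <- coverage(IRanges(start(sel), end(sel)),
                        width = max(end(g), max(end(sel))))
        vals <- as.numeric(Views(cov, start(g), end(g))[[1L]])
    }
    if (!is.null(total) && total > 0) vals <- vals * 1e6 / total
    new("CoverageTrack", geneId = gene, values = vals,
        strand = as.character(strand(g)))
}

# Exact fractional binning of a per-base vector into `bins` bins.
# Cumulative coverage is piecewise linear in position, so evaluating it at
# fractional bin boundaries conserves mass exactly.
.binVector <- function(v, bins = 100L) {
    L <- length(v)
    if (L == 0L) return(rep(0, bins))
    cs <- c(0, cumsum(v))
    bounds <- seq(0, L, length.out = bins + 1L)
    diff(approx(0:L, cs, xout = bounds)$y)
}

#' 100-bin 5'-to-3' metagene profile over a gene set
#'
#' For each gene in the set, per-base coverage (RPM units when `total` is
#' given) over the annotated gene span is oriented 5' to 3' (reversed for
#' minus-strand genes) and mapped onto `bins` equal-width bins of 1% of
#' the gene length each, by exact fractional overlap, so per-gene bin mass
#' equals per-gene coverage mass. Gene profiles are then aggregated across
#' the set by `mean` (default — each gene weighted equally) or `sum`.
#'
#' @param records `GRanges` of aligned reads.
#' @param geneSet Character vector of gene ids (must all be annotated).
#' @param annotation Gene `GRanges` named by gene id.
#' @param bins Number of bins. Default 100.
#' @param mode `"mean"` or `"sum"`.
#' @param total Normalisation total; default `length(records)`.
#' @param senseOnly Strand filter passed to [coverageTrack()].
#' @param geneSetId,sampleId Labels recorded in the profile.
#' @return A [MetageneProfile-class].
#' @export
metageneProfile <- function(records, geneSet, annotation, bins = 100L,
                            mode = c("mean", "sum"),
                            total = length(records), senseOnly = NA,
                            geneSetId = "set", sampleId = "sample") {
    mode <- match.arg(mode)
    geneSet <- unique(geneSet)
    missing <- setdiff(geneSet, names(annotation))
    if (length(missing) == length(geneSet) || !length(geneSet))
        stop("gene set is empty or disjoint from the annotation",
             call. = FALSE)
    if (length(missing))
        stop("genes absent from the annotation: ",
             paste(utils::head(missing, 10L), collapse = ", "),
             call. = FALSE)
    # one coverage pass per strand selection, then per-gene views
    scale <- if (!is.null(total) && total > 0) 1e6 / total else 1
    covFor <- function(sel) {
        if (!length(sel)) return(NULL)
        coverage(GRanges(GenomeInfoDb::seqnames(sel),
                         IRanges(start(sel), end(sel))))
    }
    gstr <- stats::setNames(as.character(strand(annotation)),
                            names(annotation))
    covs <- list()
    if (is.na(senseOnly)) {
        covs[["+"]] <- covs[["-"]] <- covFor(records)
    } else {
        same <- as.character(strand(records))
        covs[["+"]] <- covFor(records[same == (if (senseOnly) "+" else "-")])
        covs[["-"]] <- covFor(records[same == (if (senseOnly) "-" else "+")])
    }
    mat <- vapply(geneSet, function(g) {
        ganno <- annotation[g]
        cv <- covs[[gstr[[g]]]]
        chr <- as.character(GenomeInfoDb::seqnames(ganno))
        v <- if (is.null(cv) || !chr %in% names(cv) ||
                 length(cv[[chr]]) < start(ganno)) {
            rep(0, width(ganno))
        } else {
            rle <- cv[[chr]]
            e <- min(end(ganno), length(rle))
            c(as.numeric(IRanges::Views(rle, start(ganno), e)[[1L]]),
              rep(0, end(ganno) - e))
        }
        v <- v * scale
        if (gstr[[g]] == "-") v <- rev(v)   # orient 5' -> 3'
        .binVector(v, bins)
    }, numeric(bins))
    agg <- if (mode == "mean") rowMeans(mat) else rowSums(mat)
    obj <- new("MetageneProfile", geneSetId = geneSetId,
               sampleId = sampleId, bins = pmax(agg, 0), mode = mode,
               nGenes = length(geneSet))
    validObject(obj)
    obj
}
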