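#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom Biostrings extractAt
#' @importFrom GenomeInfoDb seqlengths seqlengths<-
#' @importFrom stats rlnorm rmultinom rbeta runif
NULL

.withSeed <- function(seed, expr) {
    # deterministic across sessions: pin generator kinds, restore state after
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
    expr
}

#' Derive a per-sample random seed from the master seed
#'
#' Stable polynomial hash of the sample id combined with the master seed,
#' reduced modulo 2^31 - 1, so each library gets a reproducible but
#' distinct random stream.
#'
#' @param masterSeed Integer master seed.
#' @param sampleId Character scalar.
#' @return Integer seed in `[1, 2^31 - 1)`.
#' @export
sampleSeed <- function(masterSeed, sampleId) {
    p <- 2147483647
    h <- 0
    for (code in utf8ToInt(sampleId)) h <- (h * 31 + code) %% p
    as.integer((h + (as.numeric(masterSeed) %% p) + 1) %% p)
}

#' Default simulation parameters
#'
#' Returns the configuration list consumed by [buildTruth()]. The defaults
#' describe a desk-scale C. elegans-like germline: 1000 mRNAs of 500-2000
#' nt (150 in the WAGO target class, 200 in the CSR-1 class), 30 discrete
#' 21-nt piRNA loci, 20 miRNA loci; small-RNA libraries that are 70%
#' 22G-RNAs, 15% piRNAs, 5% miRNAs, 10% other; one planted Argonaute bait
#' ("WAGO-1") whose 100 target genes carry a 4-fold IP enrichment factor;
#' and CLIP fragments of 18-40 nt whose start positions are 3'-skewed with
#' bias parameter 4.
#'
#' Because library depth is fixed, enriching a planted set renormalises
#' every gene's read share: a planted set holding weight fraction `f` of
#' its class sees an observed IP/input fold of `e / (1 + (e-1) f)` rather
#' than `e`. The default universe keeps planted sets near `f ~ 0.1` so a
#' planted `e = 4` is observable as roughly 3-fold, comfortably above a
#' 2-fold calling threshold; per-gene abundances are log-normal with
#' `sdlog = 0.5` (about a 10-fold dynamic range) so that desk-scale depths
#' leave even low-abundance genes with tens of reads.
#'
#' @param ... Named overrides of any default listed below.
#' @return Named list of parameters:
#' \describe{
#'   \item{nMrna,nPirna,nMirna}{gene counts per biotype}
#'   \item{abundanceSdlog}{sdlog of the log-normal baseline abundances}
#'   \item{mrnaLen}{length-2 range of mRNA lengths (nt)}
#'   \item{pirnaLen,mirnaLen}{locus lengths (nt)}
#'   \item{nWago,nCsr1,nBoth}{mRNAs assigned to each Argonaute target class}
#'   \item{ipTargets}{named list per bait:
#'     `list(class=, n=, e=)` — planted target-set source class, size and
#'     IP enrichment factor}
#'   \item{conditions}{named list per genotype:
#'     `list(from=, n=, multiplier=)` (or `genes=`) — planted per-gene
#'     multiplier on small-RNA rates}
#'   \item{classMix,clipMix}{read-class mixtures (sum to 1)}
#'   \item{beta}{CLIP 3' positional bias (0 = uniform)}
#'   \item{clipLenRange}{CLIP fragment length range (nt)}
#'   \item{sitesPerGene}{designated 22G start sites per mRNA}
#'   \item{gap}{intergenic gap between simulated genes (nt)}
#'   \item{multimapFraction}{fraction of reads emitted with n_hits = 2}
#' }
#' @export
simConfig <- function(...) {
    cfg <- list(
        nMrna = 1000L, nPirna = 30L, nMirna = 20L,
        mrnaLen = c(500L, 2000L), pirnaLen = 21L, mirnaLen = 22L,
        nWago = 150L, nCsr1 = 200L, nBoth = 0L,
        abundanceSdlog = 0.5,
        ipTargets = list("WAGO-1" = list(class = "WAGO", n = 100L, e = 4)),
        conditions = list(),
        classMix = c(g22 = 0.70, piRNA = 0.15, miRNA = 0.05, other = 0.10),
        clipMix = c(mRNA = 0.80, piRNA = 0.10, miRNA = 0.02, other = 0.08),
        beta = 4, clipLenRange = c(18L, 40L),
        sitesPerGene = 50L, gap = 100L, multimapFraction = 0
    )
    dots <- list(...)
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad))
        stop("unknown simConfig parameter(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    cfg[names(dots)] <- dots
    cfg
}

# sample() that never falls into the 1:x surprise for length-1 pools
.sampleFrom <- function(x, n, replace = FALSE, prob = NULL) {
    x[sample.int(length(x), n, replace = replace, prob = prob)]
}

.pickClassGenes <- function(pool, n, what) {
    if (n > length(pool))
        stop(sprintf(
            "configuration error: %s requests %d genes but only %d of the requested class exist",
            what, n, length(pool)), call. = FALSE)
    .sampleFrom(pool, n)
}

#' Build a simulated annotation, genome and ground truth
#'
#' Lays the configured genes end to end (with intergenic gaps) on a single
#' chromosome, draws log-normal baseline abundances, assigns Argonaute
#' target classes, plants the configured IP target sets and condition
#' multipliers, designates per-mRNA 22G start sites, and generates an
#' i.i.d. ACGT genome in which the base under each designated 22G (or
#' piRNA) 5' position is forced so that emitted 22G reads begin with G and
#' piRNA reads with U. Deterministic in `(config, seed)`.
#'
#' @param config Parameter list from [simConfig()].
#' @param seed Integer master seed.
#' @return List with elements `annotation` (a
#'   [GenomicRanges::GRanges] named by gene_id with metadata columns
#'   `biotype` and `target_class`), `genome` (a
#'   [Biostrings::DNAStringSet]) and `truth` (a [GroundTruth-class]).
#' @examples
#' sim <- buildTruth(simConfig(nMrna = 20L, nPirna = 5L, nMirna = 2L,
#'                             nWago = 6L, nCsr1 = 8L,
#'                             ipTargets = list("WAGO-1" = list(
#'                               class = "WAGO", n = 5L, e = 4))), seed = 1L)
#' sim$annotation
#' sim$truth
#' @export
buildTruth <- function(config = simConfig(), seed = 1L) {
    .withSeed(seed, {
        cfg <- config
        nM <- cfg$nMrna; nP <- cfg$nPirna; nMi <- cfg$nMirna
        lens <- c(
            if (nM) .sampleFrom(seq(cfg$mrnaLen[1], cfg$mrnaLen[2]), nM,
                                replace = TRUE) else integer(),
            rep(cfg$pirnaLen, nP), rep(cfg$mirnaLen, nMi))
        biotype <- c(rep("mRNA", nM), rep("piRNA", nP), rep("miRNA", nMi))
        ids <- c(sprintf("mg%04d", seq_len(nM)),
                 sprintf("pir%03d", seq_len(nP)),
                 sprintf("mir%03d", seq_len(nMi)))
        strandv <- sample(c("+", "-"), length(ids), replace = TRUE)
        starts <- cfg$gap + cumsum(c(0L, (lens + cfg$gap)[-length(lens)])) + 1L
        ends <- starts + lens - 1L
        genomeLen <- max(ends) + cfg$gap

        # Argonaute target classes among mRNAs
        target_class <- rep("none", length(ids))
        mIdx <- which(biotype == "mRNA")
        picked <- .sampleFrom(mIdx, min(cfg$nWago + cfg$nCsr1 + cfg$nBoth, nM))
        if (cfg$nWago + cfg$nCsr1 + cfg$nBoth > nM)
            stop("configuration error: more target-class genes than mRNAs",
                 call. = FALSE)
        target_class[picked[seq_len(cfg$nWago)]] <- "WAGO"
        target_class[picked[cfg$nWago + seq_len(cfg$nCsr1)]] <- "CSR1"
        if (cfg$nBoth)
            target_class[picked[cfg$nWago + cfg$nCsr1 +
                                seq_len(cfg$nBoth)]] <- "both"

        anno <- GRanges("chrI", IRanges(starts, ends), strand = strandv,
                        biotype = biotype, target_class = target_class)
        names(anno) <- ids
        seqlengths(anno) <- c(chrI = genomeLen)

        abundance <- stats::setNames(rlnorm(length(ids), 0, cfg$abundanceSdlog),
                                     ids)

        classPool <- function(cl) switch(cl,
            WAGO = ids[target_class %in% c("WAGO", "both")],
            CSR1 = ids[target_class %in% c("CSR1", "both")],
            mRNA = ids[biotype == "mRNA"],
            stop("unknown gene class: ", cl, call. = FALSE))

        one <- stats::setNames(rep(1, length(ids)), ids)
        conditions <- list(WT = one)
        plantedGenes <- list()
        for (cn in names(cfg$conditions)) {
            spec <- cfg$conditions[[cn]]
            genes <- if (!is.null(spec$genes)) {
                spec$genes
            } else if (!is.null(spec$fromCondition)) {
                # reuse another condition's planted set (e.g. a double
                # mutant sharing the single mutant's ectopic genes)
                if (is.null(plantedGenes[[spec$fromCondition]]))
                    stop("configuration error: conditions[", cn,
                         "] references unknown condition '",
                         spec$fromCondition, "'", call. = FALSE)
                plantedGenes[[spec$fromCondition]]
            } else {
                .pickClassGenes(classPool(spec$from), spec$n,
                                paste0("conditions[", cn, "]"))
            }
            mult <- one
            mult[genes] <- spec$multiplier
            if (!is.null(spec$suppressN) && spec$suppressN > 0) {
                # a second depletion restores a subset to baseline
                supp <- .sampleFrom(genes, min(spec$suppressN, length(genes)))
                mult[supp] <- 1
            }
            plantedGenes[[cn]] <- genes
            conditions[[cn]] <- mult
        }

        # IP bait target sets (after conditions, so a bait can pick up or
        # drop another planting — e.g. a WAGO bait that additionally loads
        # the ectopic genes of a mutant condition)
        ipTargets <- lapply(names(cfg$ipTargets), function(b) {
            spec <- cfg$ipTargets[[b]]
            genes <- if (!is.null(spec$genes)) {
                if (!all(spec$genes %in% ids))
                    stop("configuration error: planted IP genes outside annotation",
                         call. = FALSE)
                spec$genes
            } else .pickClassGenes(classPool(spec$class), spec$n,
                                   paste0("ipTargets[", b, "]"))
            if (!is.null(spec$plusCondition)) {
                if (is.null(plantedGenes[[spec$plusCondition]]))
                    stop("configuration error: ipTargets[", b,
                         "] references unknown condition '",
                         spec$plusCondition, "'", call. = FALSE)
                genes <- union(genes, plantedGenes[[spec$plusCondition]])
            }
            if (!is.null(spec$minusCondition)) {
                if (is.null(plantedGenes[[spec$minusCondition]]))
                    stop("configuration error: ipTargets[", b,
                         "] references unknown condition '",
                         spec$minusCondition, "'", call. = FALSE)
                genes <- setdiff(genes, plantedGenes[[spec$minusCondition]])
            }
            list(genes = genes, e = spec$e)
        })
        names(ipTargets) <- names(cfg$ipTargets)

        # designated antisense 22G start sites per mRNA (genomic 1-based)
        sites22G <- stats::setNames(vector("list", nM), ids[seq_len(nM)])
        for (i in seq_len(nM)) {
            L <- lens[i]
            k <- min(cfg$sitesPerGene, L - 21L)
            off <- sort(sample.int(L - 21L, k))  # offsets 1..L-21
            sites22G[[i]] <- starts[i] + off - 1L
        }

        genome <- sample(c("A", "C", "G", "T"), genomeLen, replace = TRUE)
        # force 22G reads to start with G: the read 5' base maps to the
        # genome base at the far end of the antisense slice
        for (i in seq_len(nM)) {
            s <- sites22G[[i]]
            if (strandv[i] == "+") genome[s + 21L] <- "C" else genome[s] <- "G"
        }
        # force piRNA (21U) and miRNA 5' bases
        for (i in which(biotype == "piRNA")) {
            if (strandv[i] == "+") genome[starts[i]] <- "T"
            else genome[ends[i]] <- "A"
        }
        genomeSet <- DNAStringSet(paste(genome, collapse = ""))
        names(genomeSet) <- "chrI"

        truth <- new("GroundTruth",
            abundance = abundance, conditions = conditions,
            ipTargets = ipTargets, beta = cfg$beta,
            classMix = cfg$classMix, clipMix = cfg$clipMix,
            sites22G = sites22G,
            clipLenRange = as.integer(cfg$clipLenRange),
            multimapFraction = cfg$multimapFraction,
            seed = as.integer(seed))
        validObject(truth)
        list(annotation = anno, genome = genomeSet, truth = truth)
    })
}

#' Construct a SampleSpec
#'
#' @param sampleId Unique library label.
#' @param genotype Condition name known to the ground truth
#'   (default `"WT"`).
#' @param fraction `"input"`, `"IP"`, `"CLIP"` or `"CLIP-control"`.
#' @param bait Bait protein for IP/tagged-CLIP libraries; `NULL` for input
#'   and untagged controls.
#' @param depth Number of aligned records to emit.
#' @param beta CLIP bias override; `NA` uses the truth default for tagged
#'   CLIP and 0 for untagged controls.
#' @return A [SampleSpec-class].
#' @export
sampleSpec <- function(sampleId, genotype = "WT", fraction = "input",
                       bait = NULL, depth = 1e5, beta = NA_real_) {
    obj <- new("SampleSpec", sampleId = sampleId, genotype = genotype,
               fraction = fraction, bait = bait, depth = as.integer(depth),
               beta = as.numeric(beta))
    validObject(obj)
    obj
}

.drawGeneCounts <- function(n, weights) {
    if (n == 0L || sum(weights) == 0) return(stats::setNames(rep(0L, length(weights)),
                                                             names(weights)))
    stats::setNames(rmultinom(1L, n, weights)[, 1L], names(weights))
}

#' Simulate one aligned-read library
#'
#' Emits exactly `depth` aligned records with the planted statistical
#' structure: per-gene read counts are multinomial with probabilities
#' proportional to baseline abundance x condition multiplier (x the bait's
#' IP enrichment factor `e` for planted targets in IP and tagged-CLIP
#' fractions). 22G-class reads are 22-nt, antisense to their source mRNA
#' and begin with G; piRNA-class reads are 21-nt, sense to a piRNA locus
#' and begin with U; "other" reads fall in intergenic space. CLIP fragments
#' have lengths in the configured range and transcript-relative start
#' positions drawn as `1 - Beta(1, 1 + beta)`, which is uniform at
#' `beta = 0` and increasingly 3'-skewed as `beta` grows. The per-sample
#' random stream is derived from `(master seed, sampleId)` via
#' [sampleSeed()].
#'
#' @param sim Output of [buildTruth()].
#' @param spec A [SampleSpec-class] from [sampleSpec()].
#' @return List with `records` (a [GenomicRanges::GRanges] with metadata
#'   columns `read_id`, `seq`, `n_hits`; strand is the read strand) and
#'   `sidecar` (named integer truth counts per gene, with `"*"` for
#'   intergenic reads; sums to `depth`).
#' @export
simulateLibrary <- function(sim, spec) {
    anno <- sim$annotation
    truth <- sim$truth
    stopifnot(is(truth, "GroundTruth"), is(spec, "SampleSpec"))
    if (!spec@genotype %in% names(truth@conditions))
        stop("configuration error: unknown condition '", spec@genotype, "'",
             call. = FALSE)
    isIP <- spec@fraction == "IP"
    isCLIP <- spec@fraction %in% c("CLIP", "CLIP-control")
    if ((isIP || spec@fraction == "CLIP") && !is.null(spec@bait) &&
        !spec@bait %in% names(truth@ipTargets))
        stop("configuration error: unknown bait '", spec@bait, "'",
             call. = FALSE)

    .withSeed(sampleSeed(truth@seed, spec@sampleId), {
        ids <- names(anno)
        biotype <- mcols(anno)$biotype
        geneStrand <- as.character(strand(anno))
        gstart <- start(anno); gend <- end(anno)
        cond <- truth@conditions[[spec@genotype]]
        mix <- if (isCLIP) truth@clipMix else truth@classMix

        mIds <- ids[biotype == "mRNA"]
        pIds <- ids[biotype == "piRNA"]
        miIds <- ids[biotype == "miRNA"]

        # drop mixture mass for classes with no source loci, renormalise
        pool <- c(length(mIds), length(pIds), length(miIds), 1L)
        mix[pool == 0L] <- 0
        mix <- mix / sum(mix)
        nClass <- .drawGeneCounts(spec@depth, mix)

        wM <- truth@abundance[mIds] * cond[mIds]
        if ((isIP || spec@fraction == "CLIP") && !is.null(spec@bait)) {
            tg <- truth@ipTargets[[spec@bait]]
            hit <- intersect(tg$genes, mIds)
            wM[hit] <- wM[hit] * tg$e
        }

        accS <- list(); accW <- list(); accT <- list(); accG <- list()
        put <- function(st, w, sd, g) {
            k <- length(accS) + 1L
            accS[[k]] <<- as.integer(st); accW[[k]] <<- as.integer(w)
            accT[[k]] <<- sd; accG[[k]] <<- g
        }

        # mRNA-derived reads: 22G antisense (small-RNA) or CLIP fragments
        nMr <- if (isCLIP) nClass[["mRNA"]] else nClass[["g22"]]
        cM <- .drawGeneCounts(nMr, wM)
        for (g in mIds[cM > 0]) {
            n <- cM[[g]]
            gi <- match(g, ids)
            if (isCLIP) {
                L <- gend[gi] - gstart[gi] + 1L
                beta <- if (!is.na(spec@beta)) spec@beta
                        else if (spec@fraction == "CLIP") truth@beta else 0
                len <- pmin(.sampleFrom(seq(truth@clipLenRange[1],
                                            truth@clipLenRange[2]),
                                        n, replace = TRUE), L)
                frac <- 1 - rbeta(n, 1, 1 + beta)   # mass toward 3' for beta>0
                off5 <- floor(frac * (L - len + 1L))
                off5 <- pmin(pmax(off5, 0L), L - len)  # 5'-relative offset
                st <- if (geneStrand[gi] == "+") gstart[gi] + off5
                      else gend[gi] - off5 - len + 1L
                put(st, len, rep(geneStrand[gi], n), rep(g, n))
            } else {
                st <- .sampleFrom(truth@sites22G[[g]], n, replace = TRUE)
                put(st, rep(22L, n),
                    rep(if (geneStrand[gi] == "+") "-" else "+", n),
                    rep(g, n))
            }
        }

        # piRNA-locus reads: the sense 21-mer of the locus
        cP <- .drawGeneCounts(nClass[["piRNA"]],
                              truth@abundance[pIds] * cond[pIds])
        for (g in pIds[cP > 0]) {
            n <- cP[[g]]
            gi <- match(g, ids)
            put(rep(gstart[gi], n),
                rep(min(21L, gend[gi] - gstart[gi] + 1L), n),
                rep(geneStrand[gi], n), rep(g, n))
        }

        # miRNA reads: sense 22-mer at the locus start
        cMi <- .drawGeneCounts(nClass[["miRNA"]],
                               truth@abundance[miIds] * cond[miIds])
        for (g in miIds[cMi > 0]) {
            n <- cMi[[g]]
            gi <- match(g, ids)
            put(rep(gstart[gi], n),
                rep(min(22L, gend[gi] - gstart[gi] + 1L), n),
                rep(geneStrand[gi], n), rep(g, n))
        }

        # "other": intergenic 22-mers on a random strand
        nO <- nClass[["other"]]
        if (nO > 0L) {
            gaps <- .intergenicRanges(anno)
            gapIdx <- sample.int(length(gaps$start), nO, replace = TRUE,
                                 prob = gaps$width)
            pos <- gaps$start[gapIdx] +
                floor(runif(nO) * (gaps$width[gapIdx] - 21L))
            put(pos, rep(22L, nO), sample(c("+", "-"), nO, replace = TRUE),
                rep("*", nO))
        }

        recStart <- unlist(accS); recWidth <- unlist(accW)
        recStrand <- unlist(accT); gene <- unlist(accG)
        nRec <- length(recStart)
        nHits <- rep(1L, nRec)
        if (truth@multimapFraction > 0 && nRec > 0) {
            nMM <- round(truth@multimapFraction * nRec)
            if (nMM > 0) nHits[sample.int(nRec, nMM)] <- 2L
        }
        gr <- GRanges("chrI", IRanges(recStart, width = recWidth),
                      strand = recStrand)
        seqs <- as.character(extractAt(sim$genome[[1L]],
                                       IRanges(recStart, width = recWidth)))
        neg <- recStrand == "-"
        if (any(neg))
            seqs[neg] <- as.character(reverseComplement(DNAStringSet(seqs[neg])))
        ord <- sample.int(nRec)   # shuffle so record order carries no signal
        gr <- gr[ord]; seqs <- seqs[ord]; gene <- gene[ord]
        mcols(gr)$read_id <- sprintf("%s_r%07d", spec@sampleId, seq_len(nRec))
        mcols(gr)$seq <- seqs
        mcols(gr)$n_hits <- nHits
        seqlengths(gr) <- seqlengths(anno)

        sidecar <- table(factor(gene, levels = c(ids, "*")))
        sidecar <- stats::setNames(as.integer(sidecar), names(sidecar))
        list(records = gr, sidecar = sidecar)
    })
}

.intergenicRanges <- function(anno) {
    glen <- unname(seqlengths(anno)[1L])
    s <- sort(start(anno)); e <- sort(end(anno))
    # genes are non-overlapping by construction; gaps between/around them
    gapStart <- c(1L, e + 1L)
    gapEnd <- c(s - 1L, glen)
    w <- gapEnd - gapStart + 1L
    keep <- w >= 30L
    list(start = gapStart[keep], end = gapEnd[keep], width = w[keep])
}
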