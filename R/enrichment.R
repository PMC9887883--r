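.checkUniverse <- function(a, b, whatA = "first", whatB = "second") {
    ga <- geneIds(a); gb <- geneIds(b)
    if (!identical(sort(ga), sort(gb))) {
        d <- union(setdiff(ga, gb), setdiff(gb, ga))
        stop(sprintf(
            "gene universes of the %s and %s tables differ; symmetric difference: %s",
            whatA, whatB,
            paste(utils::head(d, 10L), collapse = ", ")), call. = FALSE)
    }
    ga
}

.foldRatio <- function(num, den) {
    # +Inf when den == 0 and num > 0; NaN for 0/0
    ifelse(den > 0, num / den, ifelse(num > 0, Inf, NaN))
}

#' Call genes enriched in an Argonaute IP over input
#'
#' A gene enters the set iff its IP RPM is at least `minRpm` and the
#' IP/input RPM ratio exceeds `fold` ("more than" — strictly greater by
#' default; set `strict = FALSE` for an at-least rule). A gene detected in
#' the IP (above the floor) but absent from the input is enriched with
#' fold `+Inf`; genes absent from both (0/0) are excluded. Defaults follow
#' the small-RNA IP scoring rule: minimal 1 RPM and more than 2-fold
#' enrichment over the corresponding input.
#'
#' @param ip,input [CountTable-class] objects over the same gene universe.
#' @param fold Fold threshold. Default 2.
#' @param minRpm RPM floor applied to the IP sample. Default 1.
#' @param strict Strictly-greater comparison. Default `TRUE`.
#' @return An [EnrichedSet-class].
#' @examples
#' # ip 10 RPM vs input 4 RPM -> fold 2.5, enriched;
#' # ip 2 vs input 1 -> fold exactly 2, excluded under the strict rule
#' @export
ipEnrichment <- function(ip, input, fold = 2, minRpm = 1, strict = TRUE) {
    ids <- .checkUniverse(ip, input, "IP", "input")
    ri <- rpm(ip)[ids]; rr <- rpm(input)[ids]
    fc <- .foldRatio(ri, rr)
    pass <- ri >= minRpm & !is.nan(fc) &
        (if (strict) fc > fold else fc >= fold)
    obj <- new("EnrichedSet", ipSample = ip@sampleId,
               refSample = input@sampleId, fold = fold, strict = strict,
               minRpm = minRpm, members = fc[pass])
    validObject(obj)
    obj
}

#' Call CLIP targets against an untagged background
#'
#' A gene is a CLIP target iff its tagged-CLIP RPM is at least `minRpm`
#' and the tagged/untagged RPM ratio is at least `fold` (non-strict,
#' "at least two-fold"). Defaults follow the CLIP target scoring rule:
#' at least two-fold enrichment over untagged input and minimal 5 RPM.
#' Tables should be built from reads passing the 15-nt post-trim floor.
#'
#' @param tagged,untagged [CountTable-class] objects over the same
#'   universe.
#' @param fold Fold threshold. Default 2.
#' @param minRpm RPM floor on the tagged sample. Default 5.
#' @return An [EnrichedSet-class].
#' @export
clipTargets <- function(tagged, untagged, fold = 2, minRpm = 5) {
    ipEnrichment(tagged, untagged, fold = fold, minRpm = minRpm,
                 strict = FALSE)
}

#' Categorise per-gene differential small-RNA abundance
#'
#' Compares two samples gene by gene on the RPM scale: `up` iff
#' `test >= fold * ref` with test RPM above `floorRpm`; `down` iff
#' `ref >= fold * test` with reference RPM above the floor (the floor is
#' applied on the higher side, as in a "2-fold reduction and >5 RPM"
#' rule); `below_floor` when both samples sit at or under the floor;
#' otherwise `unchanged`. Comparisons are non-strict ("at least
#' `fold`-fold").
#'
#' @param test,ref [CountTable-class] objects over the same universe.
#' @param fold Fold threshold. Default 2.
#' @param floorRpm RPM floor. Default 0 (a 0/0 gene is then below_floor).
#' @return A [DifferentialResult-class].
#' @export
differentialSmallRNA <- function(test, ref, fold = 2, floorRpm = 0) {
    if (floorRpm < 0)
        stop("configuration error: floorRpm must be non-negative",
             call. = FALSE)
    ids <- .checkUniverse(test, ref, "test", "reference")
    rt <- rpm(test)[ids]; rr <- rpm(ref)[ids]
    up <- rt >= fold * rr & rt > floorRpm
    down <- rr >= fold * rt & rr > floorRpm
    # a gene can satisfy both only when one side is 0; resolve by magnitude
    both <- up & down
    up[both] <- rt[both] > rr[both]
    down[both] <- rr[both] > rt[both]
    cat <- rep("unchanged", length(ids))
    cat[up] <- "up"
    cat[down] <- "down"
    cat[!up & !down & rt <= floorRpm & rr <= floorRpm] <- "below_floor"
    obj <- new("DifferentialResult", testSample = test@sampleId,
               refSample = ref@sampleId, fold = fold, floorRpm = floorRpm,
               category = stats::setNames(cat, ids),
               foldChange = .foldRatio(rt, rr))
    validObject(obj)
    obj
}

#' Cross-tabulate two gene sets within a universe
#'
#' @param A,B Character vectors of gene ids, both subsets of `universe`.
#' @param universe Character vector, the shared gene universe.
#' @return List with `nA`, `nB`, `nIntersect`, `nUnion`,
#'   `jaccard` (`|A n B| / |A u B|`), `fracAShared`, `fracBShared`
#'   (shared fraction of each set) and the member vectors `intersect` and
#'   `union`.
#' @export
setCrosstab <- function(A, B, universe) {
    A <- unique(A); B <- unique(B)
    out <- setdiff(c(A, B), universe)
    if (length(out))
        stop("set members outside the universe: ",
             paste(utils::head(out, 10L), collapse = ", "), call. = FALSE)
    i <- intersect(A, B); u <- union(A, B)
    list(nA = length(A), nB = length(B),
         nIntersect = length(i), nUnion = length(u),
         jaccard = if (length(u)) length(i) / length(u) else NA_real_,
         fracAShared = if (length(A)) length(i) / length(A) else NA_real_,
         fracBShared = if (length(B)) length(i) / length(B) else NA_real_,
         intersect = i, union = u)
}

#' Detect ectopic WAGO 22G-RNA targets among CSR-1 target genes
#'
#' Returns the genes that (a) belong to the supplied CSR-1 target list,
#' (b) show increased 22G-RNA levels in the differential comparison
#' (category `up`), (c) are enriched in at least one WAGO-family IP and
#' (d) are not enriched in the CSR-1 IP — the signature of WAGO small RNAs
#' appearing ectopically on genes normally protected by CSR-1.
#'
#' @param diff A [DifferentialResult-class] (mutant vs wild type).
#' @param csr1List Character vector of CSR-1 target gene ids.
#' @param ipSets Named list of [EnrichedSet-class] objects; names starting
#'   with `"WAGO"` are treated as the WAGO family and an element named
#'   `"CSR-1"` (or `"CSR1"`) as the CSR-1 IP. Both kinds must be present.
#' @return Character vector of ectopic target gene ids.
#' @export
ectopicTargets <- function(diff, csr1List, ipSets) {
    wagoNames <- grep("^WAGO", names(ipSets), value = TRUE)
    csrName <- intersect(c("CSR-1", "CSR1"), names(ipSets))
    if (!length(wagoNames) || !length(csrName))
        stop("configuration error: ipSets must include at least one WAGO-family set and the CSR-1 set",
             call. = FALSE)
    up <- names(categories(diff))[categories(diff) == "up"]
    inWago <- unique(unlist(lapply(ipSets[wagoNames], members)))
    inCsr <- members(ipSets[[csrName[1L]]])
    sort(setdiff(intersect(intersect(csr1List, up), inWago), inCsr))
}

#' Score suppression of ectopic 22G-RNAs by a second depletion
#'
#' For each ectopic target gene, asks whether depleting an additional
#' factor reduced its 22G-RNA level: under the default `"half"` criterion
#' a gene is suppressed iff its RPM in the double mutant is at most
#' `1/fold` of its RPM in the single mutant; the alternative `"wt"`
#' criterion instead requires the double-mutant RPM to return to within
#' `fold`-fold of wild type (needs `wt`).
#'
#' @param ectopic Character vector of ectopic target gene ids.
#' @param mutant,double [CountTable-class] objects over a shared universe
#'   containing `ectopic`.
#' @param fold Fold threshold. Default 2.
#' @param criterion `"half"` (default) or `"wt"`.
#' @param wt Wild-type [CountTable-class], required for
#'   `criterion = "wt"`.
#' @return List with `suppressed` (gene ids), `nSuppressed`, `nTotal`.
#' @export
suppressionCall <- function(ectopic, mutant, double, fold = 2,
                            criterion = c("half", "wt"), wt = NULL) {
    criterion <- match.arg(criterion)
    if (!length(ectopic))
        return(list(suppressed = character(), nSuppressed = 0L,
                    nTotal = 0L))
    ids <- .checkUniverse(mutant, double, "mutant", "double mutant")
    missing <- setdiff(ectopic, ids)
    if (length(missing))
        stop("ectopic genes outside the count-table universe: ",
             paste(utils::head(missing, 10L), collapse = ", "),
             call. = FALSE)
    rm_ <- rpm(mutant)[ectopic]; rd <- rpm(double)[ectopic]
    supp <- if (criterion == "half") {
        rd <= rm_ / fold
    } else {
        if (is.null(wt))
            stop("criterion 'wt' requires the wild-type count table",
                 call. = FALSE)
        rw <- rpm(wt)[ectopic]
        rd <= fold * rw
    }
    list(suppressed = ectopic[supp], nSuppressed = sum(supp),
         nTotal = length(ectopic))
}

#' Union of differential categories across comparisons, with overlap
#'
#' `compositeUnion()` collects the genes carrying the requested category
#' (default `down`) in any of the supplied differential results — e.g.
#' summing the genes depleted at least 2-fold in each double mutant versus
#' wild type. `overlapFraction()` reports what fraction of such a
#' composite is contained in a reference set.
#'
#' @param diffs List of [DifferentialResult-class] objects (may be empty).
#' @param category Category to collect. Default `"down"`.
#' @return `compositeUnion`: character vector of gene ids.
#' @export
compositeUnion <- function(diffs, category = "down") {
    if (!length(diffs)) return(character())
    sort(unique(unlist(lapply(diffs, function(d)
        names(categories(d))[categories(d) == category]))))
}

#' @rdname compositeUnion
#' @param composite,reference Character vectors of gene ids.
#' @return `overlapFraction`: `|composite n reference| / |composite|`
#'   (NA for an empty composite).
#' @export
overlapFraction <- function(composite, reference) {
    if (!length(composite)) return(NA_real_)
    length(intersect(composite, reference)) / length(unique(composite))
}

#' Call proteins enriched in an IP-MS experiment over background
#'
#' A protein is enriched iff its relative peptide level in the IP is at
#' least `fold` times its level in the background control (non-strict,
#' "at-least two fold"); proteins detected in the IP but absent from the
#' background are enriched.
#'
#' @param ip,background Data frames with columns `protein_id` and `level`
#'   (relative peptide level, non-negative). Proteins missing from one
#'   table are treated as level 0 there.
#' @param fold Fold threshold. Default 2.
#' @return Character vector of enriched protein ids (sorted).
#' @export
proteinEnrichment <- function(ip, background, fold = 2) {
    stopifnot(all(c("protein_id", "level") %in% names(ip)),
              all(c("protein_id", "level") %in% names(background)))
    if (any(ip$level < 0) || any(background$level < 0))
        stop("peptide levels must be non-negative", call. = FALSE)
    ids <- union(ip$protein_id, background$protein_id)
    li <- stats::setNames(rep(0, length(ids)), ids)
    lb <- li
    li[ip$protein_id] <- ip$level
    lb[background$protein_id] <- background$level
    sort(ids[li > 0 & li >= fold * lb])
}
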