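#' @rdname accessors
setMethod("geneIds", "CountTable", function(x) names(x@counts))

#' @rdname accessors
setMethod("geneIds", "EnrichedSet", function(x) names(x@members))

#' @rdname accessors
setMethod("geneIds", "DifferentialResult", function(x) names(x@category))

#' @rdname accessors
setMethod("geneIds", "GroundTruth", function(x) names(x@abundance))

#' @rdname accessors
setMethod("rpm", "CountTable", function(x) x@rpm)

#' @rdname accessors
setMethod("rawCounts", "CountTable", function(x) x@counts)

#' @rdname accessors
setMethod("normTotal", "CountTable", function(x) x@total)

#' @rdname accessors
setMethod("members", "EnrichedSet", function(x) names(x@members))

#' @rdname accessors
setMethod("memberFolds", "EnrichedSet", function(x) x@members)

#' @rdname accessors
setMethod("categories", "DifferentialResult", function(x) x@category)

#' @rdname accessors
setMethod("profileBins", "MetageneProfile", function(x) x@bins)

#' @rdname accessors
setMethod("centerOfMass", "MetageneProfile", function(x) {
    tot <- sum(x@bins)
    if (tot == 0) return(NA_real_)
    sum(x@bins * seq_len(100L)) / tot
})

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth for", length(object@abundance), "genes\n")
    cat("  conditions:", paste(names(object@conditions), collapse = ", "), "\n")
    cat("  IP baits:  ",
        if (length(object@ipTargets))
            paste(sprintf("%s (n=%d, e=%g)", names(object@ipTargets),
                          vapply(object@ipTargets, function(t) length(t$genes), 1L),
                          vapply(object@ipTargets, function(t) t$e, 1.0)),
                  collapse = ", ")
        else "none", "\n")
    cat("  CLIP 3' bias beta:", object@beta,
        " class mix:", paste(sprintf("%s=%.2f", names(object@classMix),
                                     object@classMix), collapse = " "), "\n")
    cat("  master seed:", object@seed, "\n")
})

setMethod("show", "CountTable", function(object) {
    cat(sprintf("CountTable '%s' (%s, norm %s): %d genes, total %g reads\n",
                object@sampleId, object@classFilter, object@normMode,
                length(object@counts), object@total))
    nz <- sum(object@counts > 0)
    cat(sprintf("  %d genes with nonzero counts; top RPM %.1f\n",
                nz, if (length(object@rpm)) max(object@rpm) else 0))
})

setMethod("show", "EnrichedSet", function(object) {
    cat(sprintf(
        "EnrichedSet: %d genes with %s %g-fold (IP '%s' vs '%s', IP RPM >= %g)\n",
        length(object@members), if (object@strict) ">" else ">=",
        object@fold, object@ipSample, object@refSample, object@minRpm))
})

setMethod("show", "DifferentialResult", function(object) {
    tab <- table(factor(object@category,
                        c("up", "down", "unchanged", "below_floor")))
    cat(sprintf("DifferentialResult '%s' vs '%s' (fold %g, floor %g RPM)\n",
                object@testSample, object@refSample, object@fold,
                object@floorRpm))
    cat(sprintf("  up %d | down %d | unchanged %d | below_floor %d\n",
                tab[["up"]], tab[["down"]], tab[["unchanged"]],
                tab[["below_floor"]]))
})

setMethod("show", "MetageneProfile", function(object) {
    cat(sprintf(
        "MetageneProfile '%s' / sample '%s': 100 bins (%s over %d genes)\n",
        object@geneSetId, object@sampleId, object@mode, object@nGenes))
    cat(sprintf("  total %.3g, centre of mass bin %.1f\n",
                sum(object@bins), centerOfMass(object)))
})

setMethod("show", "CoverageTrack", function(object) {
    cat(sprintf("CoverageTrack '%s' (%s): %d bases, max %.3g, total %.3g\n",
                object@geneId, object@strand, length(object@values),
                if (length(object@values)) max(object@values) else 0,
                sum(object@values)))
})

#' Convert a CountTable to a data.frame
#'
#' @param x A [CountTable-class].
#' @param row.names,optional Ignored (base signature).
#' @param ... Ignored.
#' @return `data.frame` with columns `gene_id`, `count`, `rpm`.
#' @export
as.data.frame.CountTable <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
    data.frame(gene_id = names(x@counts), count = unname(x@counts),
               rpm = unname(x@rpm), stringsAsFactors = FALSE)
}

#' Convert a DifferentialResult to a data.frame
#'
#' @param x A [DifferentialResult-class].
#' @param row.names,optional Ignored (base signature).
#' @param ... Ignored.
#' @return `data.frame` with columns `gene_id`, `category`, `fold_change`.
#' @export
as.data.frame.DifferentialResult <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
    data.frame(gene_id = names(x@category), category = unname(x@category),
               fold_change = unname(x@foldChange), stringsAsFactors = FALSE)
}
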