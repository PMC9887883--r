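#' Accessors for smallRNAtools classes
#'
#' `geneIds()` returns the gene universe of an object; `rpm()` and
#' `rawCounts()` the per-gene RPM/count vectors of a [CountTable-class];
#' `normTotal()` its normalisation denominator; `members()` the gene ids in
#' an [EnrichedSet-class]; `memberFolds()` their per-gene folds;
#' `categories()` the per-gene category vector of a
#' [DifferentialResult-class]; `profileBins()` the 100 bin values of a
#' [MetageneProfile-class]; `centerOfMass()` its positional centre of mass
#' on the bin scale (1 = 5', 100 = 3').
#'
#' @param x An object of the relevant class.
#' @return A named vector (or scalar for `normTotal`/`centerOfMass`).
#' @name accessors
#' @aliases geneIds rpm rawCounts normTotal members memberFolds categories
#'   profileBins centerOfMass
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("rpm", function(x) standardGeneric("rpm"))

#' @rdname accessors
#' @export
setGeneric("rawCounts", function(x) standardGeneric("rawCounts"))

#' @rdname accessors
#' @export
setGeneric("normTotal", function(x) standardGeneric("normTotal"))

#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname accessors
#' @export
setGeneric("memberFolds", function(x) standardGeneric("memberFolds"))

#' @rdname accessors
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))

#' @rdname accessors
#' @export
setGeneric("profileBins", function(x) standardGeneric("profileBins"))

#' @rdname accessors
#' @export
setGeneric("centerOfMass", function(x) standardGeneric("centerOfMass"))
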