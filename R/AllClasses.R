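#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom BiocGenerics start end strand width
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Planted ground truth for a simulated small-RNA study
#'
#' Holds everything the synthetic-data generator decided about a simulated
#' genome: per-gene baseline abundances, per-condition multipliers (e.g. a
#' planted glh-1-null condition that raises 22G-RNA rates on a chosen gene
#' set), per-bait IP enrichment factors, the CLIP 3' positional-bias
#' parameter, class mixture proportions and the master seed. Downstream
#' recovery tests compare analysis output against these planted values.
#'
#' @slot abundance Named non-negative numeric; baseline expected read rate
#'   per gene (arbitrary units, normalised internally).
#' @slot conditions Named list; each element a full named multiplier vector
#'   over genes (a genotype's per-gene fold effect on small-RNA rates).
#'   Always contains `"WT"` (all 1).
#' @slot ipTargets Named list keyed by bait (e.g. `"WAGO-1"`); each element
#'   `list(genes = <character>, e = <positive scalar>)` — the planted target
#'   set and its IP enrichment factor.
#' @slot beta Non-negative scalar; CLIP start-position bias (0 = uniform
#'   along the transcript, larger = more 3'-skewed).
#' @slot classMix Named numeric over `c("g22","piRNA","miRNA","other")`
#'   summing to 1; read-class mixture of small-RNA libraries.
#' @slot clipMix Named numeric over `c("mRNA","piRNA","miRNA","other")`
#'   summing to 1; read-class mixture of CLIP libraries.
#' @slot sites22G Named list; per-mRNA integer vector of designated genomic
#'   start positions (1-based) for 22-nt antisense reads.
#' @slot clipLenRange Integer length-2; CLIP fragment length range (nt).
#' @slot multimapFraction Fraction of reads emitted with mapping
#'   multiplicity 2 (exercises the unique-mapper filter); default 0.
#' @slot seed Integer master seed.
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
    abundance    = "numeric",
    conditions   = "list",
    ipTargets    = "list",
    beta         = "numeric",
    classMix     = "numeric",
    clipMix      = "numeric",
    sites22G     = "list",
    clipLenRange = "integer",
    multimapFraction = "numeric",
    seed         = "integer"
))

setValidity("GroundTruth", function(object) {
    msg <- character()
    if (any(object@abundance < 0))
        msg <- c(msg, "abundances must be non-negative")
    if (is.null(names(object@abundance)))
        msg <- c(msg, "abundance must be named by gene_id")
    if (abs(sum(object@classMix) - 1) > 1e-8)
        msg <- c(msg, "classMix proportions must sum to 1")
    if (abs(sum(object@clipMix) - 1) > 1e-8)
        msg <- c(msg, "clipMix proportions must sum to 1")
    if (!"WT" %in% names(object@conditions))
        msg <- c(msg, "conditions must include 'WT'")
    for (b in names(object@ipTargets)) {
        tg <- object@ipTargets[[b]]
        if (!all(tg$genes %in% names(object@abundance)))
            msg <- c(msg, sprintf("ipTargets[%s]: genes outside annotation", b))
        if (tg$e <= 0)
            msg <- c(msg, sprintf("ipTargets[%s]: enrichment factor must be > 0", b))
    }
    if (length(msg)) msg else TRUE
})

#' Sample specification for one simulated library
#'
#' @slot sampleId Character scalar, unique library label.
#' @slot genotype Character scalar naming a condition known to the truth.
#' @slot fraction One of `"input"`, `"IP"`, `"CLIP"`, `"CLIP-control"`.
#' @slot bait Bait protein for IP/CLIP fractions, or `NULL` for an untagged
#'   control.
#' @slot depth Positive integer, number of aligned records to emit.
#' @slot beta CLIP bias override, or `NA` to use the truth default.
#' @exportClass SampleSpec
setClass("SampleSpec", representation(
    sampleId = "character",
    genotype = "character",
    fraction = "character",
    bait     = "characterOrNULL",
    depth    = "integer",
    beta     = "numeric"
))

setValidity("SampleSpec", function(object) {
    msg <- character()
    if (object@depth <= 0L) msg <- c(msg, "depth must be > 0")
    if (!object@fraction %in% c("input", "IP", "CLIP", "CLIP-control"))
        msg <- c(msg, "fraction must be input, IP, CLIP or CLIP-control")
    if (object@fraction == "IP" && is.null(object@bait))
        msg <- c(msg, "IP fraction requires a bait")
    if (length(msg)) msg else TRUE
})

#' Per-gene counts and RPM for one sample
#'
#' Raw per-gene read counts together with reads-per-million values
#' (`count / total * 1e6`), the normalisation total and the class filter
#' that produced them, so every downstream threshold call is auditable.
#'
#' @slot sampleId Character scalar.
#' @slot counts Named non-negative integer vector (gene universe).
#' @slot rpm Named numeric vector, same names as `counts`.
#' @slot total Non-negative integer, the normalisation denominator.
#' @slot classFilter Character scalar, e.g. `"22G"`.
#' @slot normMode Character scalar, `"all_mapped"` or `"class"`.
#' @exportClass CountTable
setClass("CountTable", representation(
    sampleId    = "character",
    counts      = "numeric",
    rpm         = "numeric",
    total       = "numeric",
    classFilter = "character",
    normMode    = "character"
))

setValidity("CountTable", function(object) {
    msg <- character()
    if (is.null(names(object@counts)))
        msg <- c(msg, "counts must be named by gene_id")
    if (!identical(names(object@counts), names(object@rpm)))
        msg <- c(msg, "counts and rpm must share names")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
    if (object@total < 0) msg <- c(msg, "total must be non-negative")
    if (object@total > 0) {
        expect <- object@counts / object@total * 1e6
        if (max(abs(expect - object@rpm)) > 1e-6)
            msg <- c(msg, "rpm must equal counts / total * 1e6")
    } else if (any(object@rpm != 0)) {
        msg <- c(msg, "rpm must be all zero when total is zero")
    }
    if (length(msg)) msg else TRUE
})

#' A gene set called by a fold-enrichment rule
#'
#' Genes whose small-RNA (or CLIP) RPM in an IP library exceeds the matched
#' input/background library by a fold threshold, subject to a minimum-RPM
#' floor on the IP side. The rule parameters are carried with the set.
#'
#' @slot ipSample,refSample Character sample labels.
#' @slot fold Fold threshold.
#' @slot strict Logical; `TRUE` means strictly greater than `fold`
#'   ("more than"), `FALSE` means at-least.
#' @slot minRpm RPM floor applied to the IP sample.
#' @slot members Named numeric; per-gene fold (may be `Inf` when the
#'   reference RPM is 0 and the IP RPM is positive).
#' @exportClass EnrichedSet
setClass("EnrichedSet", representation(
    ipSample  = "character",
    refSample = "character",
    fold      = "numeric",
    strict    = "logical",
    minRpm    = "numeric",
    members   = "numeric"
))

setValidity("EnrichedSet", function(object) {
    msg <- character()
    m <- object@members
    if (length(m) && is.null(names(m)))
        msg <- c(msg, "members must be named by gene_id")
    if (length(m) && any(m <= 0))
        msg <- c(msg, "member folds must be positive")
    if (length(msg)) msg else TRUE
})

#' Per-gene differential categories between two samples
#'
#' @slot testSample,refSample Character sample labels.
#' @slot fold Fold threshold (non-strict: at-least).
#' @slot floorRpm RPM floor; applies to the test sample for up-calls and to
#'   the reference for down-calls.
#' @slot category Named character over
#'   `c("up","down","unchanged","below_floor")`, exhaustive over the universe.
#' @slot foldChange Named numeric test/ref RPM ratio (`Inf`, `NaN` for 0/0).
#' @exportClass DifferentialResult
setClass("DifferentialResult", representation(
    testSample = "character",
    refSample  = "character",
    fold       = "numeric",
    floorRpm   = "numeric",
    category   = "character",
    foldChange = "numeric"
))

setValidity("DifferentialResult", function(object) {
    msg <- character()
    ok <- c("up", "down", "unchanged", "below_floor")
    if (!all(object@category %in% ok))
        msg <- c(msg, "categories must be up/down/unchanged/below_floor")
    if (!identical(names(object@category), names(object@foldChange)))
        msg <- c(msg, "category and foldChange must share names")
    if (length(msg)) msg else TRUE
})

#' 100-bin 5'-to-3' metagene profile
#'
#' Aggregate positional coverage over a gene set in transcript-relative
#' coordinates: each bin is 1% of a transcript's length, bin 1 at the 5'
#' end and bin 100 at the 3' end (minus-strand genes are reversed before
#' binning).
#'
#' @slot geneSetId,sampleId Character labels.
#' @slot bins Numeric length-100 vector of non-negative bin values.
#' @slot mode `"mean"` (average across genes) or `"sum"`.
#' @slot nGenes Number of genes aggregated.
#' @exportClass MetageneProfile
setClass("MetageneProfile", representation(
    geneSetId = "character",
    sampleId  = "character",
    bins      = "numeric",
    mode      = "character",
    nGenes    = "integer"
))

setValidity("MetageneProfile", function(object) {
    msg <- character()
    if (length(object@bins) != 100L)
        msg <- c(msg, "a metagene profile has exactly 100 bins")
    if (any(object@bins < -1e-9))
        msg <- c(msg, "bin values must be non-negative")
    if (!object@mode %in% c("mean", "sum"))
        msg <- c(msg, "mode must be mean or sum")
    if (length(msg)) msg else TRUE
})

#' Per-base coverage track over one gene
#'
#' @slot geneId Character scalar.
#' @slot values Numeric per-base density over `[start, end)` of the gene,
#'   in RPM units when a sample total was supplied.
#' @slot strand Gene strand, `"+"` or `"-"`.
#' @exportClass CoverageTrack
setClass("CoverageTrack", representation(
    geneId = "character",
    values = "numeric",
    strand = "character"
))

setValidity("CoverageTrack", function(object) {
    if (any(object@values < 0)) "coverage values must be non-negative" else TRUE
})
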