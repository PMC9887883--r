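#' Demo run configuration: a planted ectopic-target study
#'
#' Builds a [runPipeline()] configuration that emulates the full study
#' design at desk scale: a wild-type and a "glh-1-null"-like mutant in
#' which 50 CSR-1-class genes gain 4-fold 22G-RNA levels (the planted
#' ectopic set), a double mutant in which a second depletion suppresses
#' 35 of those 50 genes back to baseline, WAGO-1 and CSR-1 IP libraries
#' from the mutant (the WAGO-1 bait additionally enriches the ectopic
#' genes 4-fold; the CSR-1 bait enriches the remaining CSR-1 targets),
#' and a tagged + untagged CLIP pair with 3'-biased binding on the WAGO-1
#' target set.
#'
#' @param seed Master seed.
#' @param depth Reads per library. Default 1e5.
#' @return A configuration list for [runPipeline()].
#' @export
demoRunConfig <- function(seed = 1L, depth = 1e5) {
    sim <- simConfig(
        conditions = list(
            "glh-1-null" = list(from = "CSR1", n = 50L, multiplier = 4),
            "glh-1-null;glh-4-degron" = list(fromCondition = "glh-1-null",
                                             multiplier = 4,
                                             suppressN = 35L)),
        ipTargets = list(
            "WAGO-1" = list(class = "WAGO", n = 100L, e = 6,
                            plusCondition = "glh-1-null"),
            "CSR-1" = list(class = "CSR1", n = 150L, e = 6,
                           minusCondition = "glh-1-null")))
    list(
        sim = sim, seed = as.integer(seed),
        samples = list(
            list(sampleId = "wt_input", genotype = "WT",
                 fraction = "input", depth = depth),
            list(sampleId = "mut_input", genotype = "glh-1-null",
                 fraction = "input", depth = depth),
            list(sampleId = "double_input",
                 genotype = "glh-1-null;glh-4-degron",
                 fraction = "input", depth = depth),
            list(sampleId = "mut_wago1_ip", genotype = "glh-1-null",
                 fraction = "IP", bait = "WAGO-1", depth = depth),
            list(sampleId = "mut_csr1_ip", genotype = "glh-1-null",
                 fraction = "IP", bait = "CSR-1", depth = depth),
            list(sampleId = "clip_tagged", genotype = "WT",
                 fraction = "CLIP", bait = "WAGO-1", depth = depth),
            list(sampleId = "clip_untagged", genotype = "WT",
                 fraction = "CLIP-control", depth = depth)),
        thresholds = list(
            ip = list(fold = 2, minRpm = 1, strict = TRUE),
            diff = list(fold = 2, floorRpm = 0),
            clip = list(fold = 2, minRpm = 5),
            suppression = list(fold = 2, criterion = "half"),
            metagene = list(bins = 100L)),
        ipPairs = list(
            "WAGO-1" = list(ip = "mut_wago1_ip", input = "mut_input"),
            "CSR-1" = list(ip = "mut_csr1_ip", input = "mut_input")),
        diffPairs = list(
            mut_vs_wt = list(test = "mut_input", ref = "wt_input"),
            double_vs_wt = list(test = "double_input", ref = "wt_input")),
        clipPair = list(tagged = "clip_tagged", untagged = "clip_untagged"),
        suppression = list(mutant = "mut_input", double = "double_input"),
        composite = list(diffs = c("double_vs_wt"), category = "down")
    )
}

.stage <- function(report, name, expr) {
    res <- tryCatch(list(ok = TRUE, value = expr, error = NULL),
                    error = function(e)
                        list(ok = FALSE, value = NULL,
                             error = conditionMessage(e)))
    if (!res$ok)
        message("[pipeline] stage '", name, "' failed: ", res$error)
    report$status[[name]] <- if (res$ok) "ok" else paste("failed:", res$error)
    report$values[[name]] <- res$value
    report
}

#' Run the full simulation-to-report pipeline
#'
#' Orchestrates simulation, 22G quantification, IP enrichment,
#' differential calling, ectopic-target detection, suppression scoring,
#' composite union, IP cross-tabulation, CLIP target calling, class
#' composition and metagene profiling, from a single configuration with
#' one master seed. Stages that fail are reported in `$status` and their
#' dependents skipped; two runs with identical config and seed produce
#' identical outputs. When `outDir` is given, every table is written as
#' TSV/JSON with its thresholds, plus a JSON run manifest with the seed,
#' thresholds and md5 digests of all written files.
#'
#' @param config Configuration list, see [demoRunConfig()].
#' @param outDir Output directory, or `NULL` to skip writing.
#' @return List with `sim`, `tables` (CountTables), `enriched`,
#'   `diffs`, `ectopic`, `suppression`, `composite`, `crosstab`,
#'   `clipTargets`, `composition`, `metagene`, `status` and (if written)
#'   `manifest`.
#' @export
runPipeline <- function(config, outDir = NULL) {
    th <- config$thresholds
    rep <- list(status = list(), values = list())

    rep <- .stage(rep, "simulate", {
        sim <- buildTruth(config$sim, config$seed)
        libs <- lapply(config$samples, function(s)
            simulateLibrary(sim, sampleSpec(
                sampleId = s$sampleId, genotype = s$genotype,
                fraction = s$fraction, bait = s$bait, depth = s$depth,
                beta = if (is.null(s$beta)) NA_real_ else s$beta)))
        names(libs) <- vapply(config$samples, `[[`, "", "sampleId")
        list(sim = sim, libs = libs)
    })
    simv <- rep$values$simulate
    if (is.null(simv)) return(c(rep["status"], list(failed = TRUE)))
    sim <- simv$sim; libs <- simv$libs
    fractions <- stats::setNames(
        vapply(config$samples, `[[`, "", "fraction"),
        names(libs))

    rep <- .stage(rep, "quantify", {
        tabs <- lapply(names(libs), function(sid) {
            cf <- if (fractions[[sid]] %in% c("CLIP", "CLIP-control"))
                "sense" else "22G"
            quantifySmallRNA(libs[[sid]]$records, sim$annotation,
                             classFilter = cf, sampleId = sid)
        })
        stats::setNames(tabs, names(libs))
    })
    tables <- rep$values$quantify

    rep <- .stage(rep, "ip_enrichment", {
        lapply(config$ipPairs, function(p)
            ipEnrichment(tables[[p$ip]], tables[[p$input]],
                         fold = th$ip$fold, minRpm = th$ip$minRpm,
                         strict = th$ip$strict))
    })
    enriched <- rep$values$ip_enrichment

    rep <- .stage(rep, "differential", {
        lapply(config$diffPairs, function(p)
            differentialSmallRNA(tables[[p$test]], tables[[p$ref]],
                                 fold = th$diff$fold,
                                 floorRpm = th$diff$floorRpm))
    })
    diffs <- rep$values$differential

    rep <- .stage(rep, "crosstab", {
        if (length(enriched) >= 2L) {
            setCrosstab(members(enriched[[1L]]), members(enriched[[2L]]),
                        names(sim$annotation))
        } else NULL
    })

    rep <- .stage(rep, "ectopic", {
        csr1List <- names(sim$annotation)[
            mcols(sim$annotation)$target_class %in% c("CSR1", "both")]
        ectopicTargets(diffs[[1L]], csr1List, enriched)
    })
    ectopic <- rep$values$ectopic

    rep <- .stage(rep, "suppression", {
        if (is.null(ectopic)) stop("skipped: ectopic stage failed")
        suppressionCall(ectopic, tables[[config$suppression$mutant]],
                        tables[[config$suppression$double]],
                        fold = th$suppression$fold,
                        criterion = th$suppression$criterion,
                        wt = tables[["wt_input"]])
    })

    rep <- .stage(rep, "composite", {
        comp <- compositeUnion(diffs[config$composite$diffs],
                               category = config$composite$category)
        refSet <- if (!is.null(ectopic)) ectopic else character()
        list(genes = comp,
             overlapWithEctopic = overlapFraction(comp, refSet))
    })

    rep <- .stage(rep, "clip_targets", {
        clipTargets(tables[[config$clipPair$tagged]],
                    tables[[config$clipPair$untagged]],
                    fold = th$clip$fold, minRpm = th$clip$minRpm)
    })

    rep <- .stage(rep, "composition", {
        clipIds <- names(libs)[fractions %in% c("CLIP", "CLIP-control")]
        stats::setNames(lapply(clipIds, function(sid)
            classComposition(libs[[sid]]$records, sim$annotation)), clipIds)
    })

    rep <- .stage(rep, "metagene", {
        tgt <- sim$truth@ipTargets[[1L]]$genes
        ctrl <- setdiff(names(sim$annotation)[
            mcols(sim$annotation)$biotype == "mRNA"], tgt)
        clipIds <- names(libs)[fractions %in% c("CLIP", "CLIP-control")]
        out <- list()
        for (sid in clipIds) {
            recs <- libs[[sid]]$records
            out[[paste0("target_", sid)]] <- metageneProfile(
                recs, tgt, sim$annotation, geneSetId = "target",
                sampleId = sid, senseOnly = TRUE)
            out[[paste0("control_", sid)]] <- metageneProfile(
                recs, ctrl, sim$annotation, geneSetId = "control",
                sampleId = sid, senseOnly = TRUE)
        }
        out
    })

    result <- list(sim = sim, libs = libs, tables = tables,
                   enriched = enriched, diffs = diffs,
                   crosstab = rep$values$crosstab, ectopic = ectopic,
                   suppression = rep$values$suppression,
                   composite = rep$values$composite,
                   clipTargets = rep$values$clip_targets,
                   composition = rep$values$composition,
                   metagene = rep$values$metagene,
                   status = rep$status)
    if (!is.null(outDir))
        result$manifest <- .writeReportBundle(result, config, outDir)
    result
}

.writeEnrichedTsv <- function(es, path) {
    hdr <- toJSON(list(ip = es@ipSample, ref = es@refSample,
                       fold = es@fold, strict = es@strict,
                       min_rpm = es@minRpm), auto_unbox = TRUE)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste0("# ", hdr), con)
    df <- data.frame(gene_id = names(es@members),
                     fold = unname(es@members))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

.writeDiffTsv <- function(d, path) {
    hdr <- toJSON(list(test = d@testSample, ref = d@refSample,
                       fold = d@fold, floor_rpm = d@floorRpm),
                  auto_unbox = TRUE)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste0("# ", hdr), con)
    write.table(as.data.frame(d), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    path
}

.writeReportBundle <- function(result, config, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- character()
    simPaths <- writeSimData(result$sim, file.path(outDir, "sim"))
    paths <- c(paths, simPaths)
    for (sid in names(result$tables))
        paths <- c(paths, writeCountTableTsv(
            result$tables[[sid]],
            file.path(outDir, sprintf("counts_%s.tsv", sid))))
    for (nm in names(result$enriched))
        paths <- c(paths, .writeEnrichedTsv(
            result$enriched[[nm]],
            file.path(outDir, sprintf("enriched_%s.tsv",
                                      gsub("[^A-Za-z0-9]", "_", nm)))))
    for (nm in names(result$diffs))
        paths <- c(paths, .writeDiffTsv(
            result$diffs[[nm]],
            file.path(outDir, sprintf("diff_%s.tsv", nm))))
    if (!is.null(result$clipTargets))
        paths <- c(paths, .writeEnrichedTsv(
            result$clipTargets, file.path(outDir, "clip_targets.tsv")))
    ej <- file.path(outDir, "sets.json")
    jsonlite::write_json(list(
        ectopic = result$ectopic,
        suppression = result$suppression[c("suppressed", "nSuppressed",
                                           "nTotal")],
        composite = result$composite,
        crosstab = result$crosstab[c("nA", "nB", "nIntersect", "nUnion",
                                     "jaccard", "fracAShared",
                                     "fracBShared")]),
        ej, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, ej)
    for (nm in names(result$metagene)) {
        p <- file.path(outDir, sprintf("metagene_%s.tsv", nm))
        write.table(data.frame(bin = 1:100,
                               value = profileBins(result$metagene[[nm]])),
                    p, sep = "\t", quote = FALSE, row.names = FALSE)
        paths <- c(paths, p)
    }
    for (nm in names(result$composition)) {
        p <- file.path(outDir, sprintf("composition_%s.tsv", nm))
        write.table(result$composition[[nm]], p, sep = "\t",
                    quote = FALSE, row.names = FALSE)
        paths <- c(paths, p)
    }
    manifest <- list(
        package = "smallRNAtools",
        version = as.character(utils::packageVersion("smallRNAtools")),
        seed = config$seed,
        thresholds = config$thresholds,
        status = result$status,
        files = as.list(stats::setNames(
            unname(tools::md5sum(unlist(paths))), basename(unlist(paths)))))
    mf <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
    manifest
}
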