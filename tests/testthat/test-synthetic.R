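test_that("identical config and seed give identical truth and annotation", {
    cfg <- smallWorldConfig()
    a <- buildTruth(cfg, seed = 42L)
    b <- buildTruth(cfg, seed = 42L)
    expect_identical(a$annotation, b$annotation)
    expect_identical(as.character(a$genome), as.character(b$genome))
    expect_identical(a$truth, b$truth)
    # and a different seed gives a different world
    d <- buildTruth(cfg, seed = 43L)
    expect_false(identical(a$truth@abundance, d$truth@abundance))
})

test_that("simulated libraries are deterministic and distinct per sample id", {
    sim <- buildTruth(smallWorldConfig(), seed = 42L)
    l1 <- simulateLibrary(sim, sampleSpec("x", depth = 2000))
    l2 <- simulateLibrary(sim, sampleSpec("x", depth = 2000))
    expect_identical(l1, l2)
    l3 <- simulateLibrary(sim, sampleSpec("y", depth = 2000))
    expect_false(identical(l1$sidecar, l3$sidecar))
    expect_true(sampleSeed(42L, "x") != sampleSeed(42L, "y"))
    expect_identical(sampleSeed(42L, "x"), sampleSeed(42L, "x"))
})

test_that("configured biotype counts and planted set sizes are honoured", {
    sim0 <- buildTruth(smallWorldConfig(nPirna = 0L), seed = 1L)
    expect_false(any(mcols(sim0$annotation)$biotype == "piRNA"))
    cfg <- simConfig(nMrna = 200L, nPirna = 5L, nMirna = 2L, nWago = 50L,
                     nCsr1 = 20L,
                     ipTargets = list("WAGO-1" = list(class = "WAGO",
                                                      n = 50L, e = 4)))
    sim <- buildTruth(cfg, seed = 2L)
    expect_equal(sum(mcols(sim$annotation)$target_class == "WAGO"), 50L)
    expect_equal(length(sim$truth@ipTargets[["WAGO-1"]]$genes), 50L)
    expect_true(all(sim$truth@ipTargets[["WAGO-1"]]$genes %in%
                    names(sim$annotation)))
})

test_that("a planted set larger than its source class is a configuration error", {
    cfg <- smallWorldConfig(
        ipTargets = list("WAGO-1" = list(class = "WAGO", n = 50L, e = 4)))
    expect_error(buildTruth(cfg, seed = 1L), "configuration error")
    expect_error(simulateLibrary(buildTruth(smallWorldConfig(), 1L),
                                 sampleSpec("z", genotype = "nope",
                                            depth = 10)),
                 "unknown condition")
    expect_error(simulateLibrary(buildTruth(smallWorldConfig(), 1L),
                                 sampleSpec("z", fraction = "IP",
                                            bait = "nope", depth = 10)),
                 "unknown bait")
})

test_that("libraries emit exactly the requested depth and conserve it in the sidecar", {
    sim <- buildTruth(smallWorldConfig(), seed = 7L)
    for (fr in c("input", "CLIP")) {
        lib <- simulateLibrary(sim, sampleSpec(
            paste0("d_", fr), fraction = fr,
            bait = if (fr == "CLIP") "WAGO-1" else NULL, depth = 10000))
        expect_length(lib$records, 10000L)
        expect_equal(sum(lib$sidecar), 10000L)
    }
})

test_that("emitted 22G reads are 22-nt, antisense, unique and G-starting; piRNAs are 21-nt U-starting", {
    sim <- buildTruth(smallWorldConfig(), seed = 8L)
    lib <- simulateLibrary(sim, sampleSpec("rt", depth = 20000))
    cls <- classifyReads(lib$records, sim$annotation)
    g22 <- lib$records[cls$label == "22G"]
    expect_true(all(width(g22) == 22L))
    expect_true(all(substr(mcols(g22)$seq, 1, 1) == "G"))
    gs <- setNames(as.character(strand(sim$annotation)),
                   names(sim$annotation))
    expect_true(all(as.character(strand(g22)) !=
                    gs[cls$gene_id[cls$label == "22G"]]))
    pir <- lib$records[cls$label == "piRNA"]
    expect_true(all(width(pir) == 21L))
    expect_true(all(substr(mcols(pir)$seq, 1, 1) == "T"))
    # round trip: simulator 22G truth counts match the classifier's view
    mIds <- names(sim$annotation)[mcols(sim$annotation)$biotype == "mRNA"]
    expect_equal(sum(lib$sidecar[mIds]), sum(cls$label == "22G"))
})

test_that("read sequences come from the genome (antisense reads are reverse complements)", {
    sim <- buildTruth(smallWorldConfig(), seed = 9L)
    lib <- simulateLibrary(sim, sampleSpec("seqcheck", depth = 500))
    rec <- lib$records
    slice <- as.character(Biostrings::extractAt(
        sim$genome[[1]], IRanges(start(rec), end(rec))))
    neg <- as.character(strand(rec)) == "-"
    expect_identical(mcols(rec)$seq[!neg], slice[!neg])
    expect_identical(
        mcols(rec)$seq[neg],
        as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(slice[neg]))))
})

test_that("an e=4 IP doubles down on the planted gene per the multinomial expectation", {
    # two equal-abundance genes, e=4 on one: expected IP share 4/5 = 0.8
    cfg <- simConfig(nMrna = 2L, nPirna = 0L, nMirna = 0L, nWago = 1L,
                     nCsr1 = 0L, abundanceSdlog = 0,
                     classMix = c(g22 = 1, piRNA = 0, miRNA = 0, other = 0),
                     ipTargets = list("WAGO-1" = list(class = "WAGO", n = 1L,
                                                      e = 4)))
    sim <- buildTruth(cfg, seed = 21L)
    tgt <- sim$truth@ipTargets[["WAGO-1"]]$genes
    depth <- 1e5
    lib <- simulateLibrary(sim, sampleSpec("share", fraction = "IP",
                                           bait = "WAGO-1", depth = depth))
    share <- lib$sidecar[[tgt]] / depth
    sd3 <- 3 * sqrt(0.8 * 0.2 / depth)
    expect_lt(abs(share - 0.8), sd3)
})

test_that("beta = 0 CLIP start positions are uniform along the transcript", {
    # chi-square goodness of fit on 20 bins must pass in >= 95% of
    # seeded replicates at alpha = 0.01
    cfg <- simConfig(nMrna = 1L, nPirna = 0L, nMirna = 0L, nWago = 1L,
                     nCsr1 = 0L, abundanceSdlog = 0, beta = 0,
                     mrnaLen = c(1000L, 1000L),
                     clipLenRange = c(20L, 20L),
                     clipMix = c(mRNA = 1, piRNA = 0, miRNA = 0, other = 0),
                     ipTargets = list("WAGO-1" = list(class = "WAGO", n = 1L,
                                                      e = 1)))
    pass <- logical(100)
    for (i in seq_len(100)) {
        sim <- buildTruth(cfg, seed = 1000L + i)
        lib <- simulateLibrary(sim, sampleSpec("u", fraction = "CLIP",
                                               bait = "WAGO-1",
                                               depth = 5000))
        g <- sim$annotation[mcols(sim$annotation)$biotype == "mRNA"]
        # 5' start offsets within the transcript (981 possible positions)
        off <- if (as.character(strand(g)) == "+")
            start(lib$records) - start(g)
        else end(g) - end(lib$records)
        h <- table(cut(off, breaks = seq(0, 981, length.out = 21),
                       include.lowest = TRUE))
        pass[i] <- suppressWarnings(chisq.test(h)$p.value) > 0.01
    }
    expect_gte(mean(pass), 0.95)
})

test_that("a configured multimapper fraction is emitted and excluded from 22G", {
    sim <- buildTruth(smallWorldConfig(multimapFraction = 0.2), seed = 30L)
    lib <- simulateLibrary(sim, sampleSpec("mm", depth = 5000))
    expect_equal(mean(mcols(lib$records)$n_hits > 1L), 0.2, tolerance = 0.01)
    cls <- classifyReads(lib$records, sim$annotation)
    expect_true(all(mcols(lib$records)$n_hits[cls$label == "22G"] == 1L))
})
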