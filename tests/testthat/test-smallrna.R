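test_that("22G calls require length 22, unique mapping and antisense orientation", {
    anno <- tinyAnnotation()
    # geneA is plus-strand: a minus-strand 22-mer inside it is 22G
    r <- makeReads(200, 22, "-")
    out <- classifyReads(r, anno)
    expect_identical(as.character(out$label), "22G")
    expect_identical(out$gene_id, "geneA")
    # sense read of the same length is not
    expect_identical(as.character(classifyReads(
        makeReads(200, 22, "+"), anno)$label), "other")
    # wrong length
    expect_identical(as.character(classifyReads(
        makeReads(200, 23, "-"), anno)$label), "other")
    # multimapper
    expect_identical(as.character(classifyReads(
        makeReads(200, 22, "-", n_hits = 2L), anno)$label), "other")
    # minus-strand gene: the antisense read is plus-strand
    out2 <- classifyReads(makeReads(750, 22, "+"), anno)
    expect_identical(as.character(out2$label), "22G")
    expect_identical(out2$gene_id, "geneC")
})

test_that("a read on a chromosome absent from the annotation is unassigned, not an error", {
    out <- classifyReads(makeReads(200, 22, "-", chrom = "chrX"),
                         tinyAnnotation())
    expect_identical(as.character(out$label), "unassigned")
    expect_true(is.na(out$gene_id))
})

test_that("piRNA takes precedence over the mRNA it is nested in, and strands matter", {
    anno <- tinyAnnotation()   # pir1 (+) sits inside geneA (+)
    sense <- classifyReads(makeReads(151, 21, "+"), anno)
    expect_identical(as.character(sense$label), "piRNA")
    expect_identical(sense$gene_id, "pir1")
    # antisense to the piRNA locus: falls through to 22G logic on geneA
    anti <- classifyReads(makeReads(151, 22, "-"), anno)
    expect_identical(as.character(anti$label), "22G")
    expect_identical(anti$gene_id, "geneA")
})

test_that("every record receives exactly one label", {
    sim <- buildTruth(smallWorldConfig(), seed = 14L)
    lib <- simulateLibrary(sim, sampleSpec("part", depth = 3000))
    out <- classifyReads(lib$records, sim$annotation)
    expect_length(out$label, 3000L)
    expect_true(all(out$label %in%
                    c("22G", "piRNA", "miRNA", "other", "unassigned")))
})

test_that("overlapping-gene assignment goes to the larger overlap, ties lexicographic", {
    gr <- GRanges("chrI", IRanges(c(100, 150), c(200, 400)),
                  strand = c("+", "+"),
                  biotype = "mRNA", target_class = "none")
    names(gr) <- c("zzz", "aaa")
    # read 160..181 overlaps zzz by 41nt and aaa fully (22nt)... construct
    # overlap sizes explicitly: read at 180, width 22 -> zzz 21nt, aaa 22nt
    out <- classifyReads(makeReads(180, 22, "-"), gr)
    expect_identical(out$gene_id, "aaa")
    # read fully inside both -> equal overlap -> lexicographically first
    out2 <- classifyReads(makeReads(160, 22, "-"), gr)
    expect_identical(out2$gene_id, "aaa")
    gr2 <- gr; names(gr2) <- c("aaa", "zzz")
    out3 <- classifyReads(makeReads(160, 22, "-"), gr2)
    expect_identical(out3$gene_id, "aaa")
})

test_that("RPM arithmetic matches counts / total x 1e6 and survives empty input", {
    anno <- tinyAnnotation()
    r <- makeReads(c(200, 210, 220, 450), 22, c("-", "-", "-", "-"))
    ct <- quantifySmallRNA(r, anno, sampleId = "toy")
    expect_equal(unname(rawCounts(ct)[c("geneA", "geneB")]), c(3L, 1L))
    expect_equal(normTotal(ct), 4)
    expect_equal(unname(rpm(ct)[c("geneA", "geneB")]), c(750000, 250000))
    empty <- quantifySmallRNA(r[0], anno, sampleId = "none")
    expect_true(all(rawCounts(empty) == 0))
    expect_true(all(rpm(empty) == 0))
    expect_equal(normTotal(empty), 0)
})

test_that("the RPM of fully assigned reads sums to one million under class normalisation", {
    anno <- tinyAnnotation()
    r <- makeReads(seq(180, 280, by = 10), 22, "-")   # all 22G on geneA
    ct <- quantifySmallRNA(r, anno, normMode = "class")
    expect_equal(sum(rpm(ct)), 1e6)
    # with the whole-sample denominator the sum never exceeds 1e6
    sim <- buildTruth(smallWorldConfig(), seed = 15L)
    lib <- simulateLibrary(sim, sampleSpec("rpmcap", depth = 4000))
    ct2 <- quantifySmallRNA(lib$records, sim$annotation)
    expect_lte(sum(rpm(ct2)), 1e6 + 1e-6)
})

test_that("quantify equals a brute-force per-read tally on a mixed fixture", {
    sim <- buildTruth(smallWorldConfig(), seed = 16L)
    lib <- simulateLibrary(sim, sampleSpec("oracle", depth = 400))
    for (cf in c("22G", "piRNA")) {
        fast <- rawCounts(quantifySmallRNA(lib$records, sim$annotation,
                                           classFilter = cf))
        slow <- naiveQuantify(lib$records, sim$annotation, classFilter = cf)
        expect_equal(fast, slow)
    }
})

test_that("the normalisation denominator honours the configured mode", {
    anno <- tinyAnnotation()
    r <- c(makeReads(200, 22, "-"),                      # 22G
           makeReads(450, 22, "-", n_hits = 2L),         # multimapper
           makeReads(50, 22, "+"))                       # intergenic
    ctAll <- quantifySmallRNA(r, anno, normMode = "all_mapped")
    expect_equal(normTotal(ctAll), 3)
    ctUniq <- quantifySmallRNA(r, anno, normMode = "unique_mapped")
    expect_equal(normTotal(ctUniq), 2)
    ctClass <- quantifySmallRNA(r, anno, normMode = "class")
    expect_equal(normTotal(ctClass), 1)
})
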