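ct <- function(rpmv, id = "s", total = 1e6) {
    counts <- round(rpmv * total / 1e6)
    new("CountTable", sampleId = id,
        counts = setNames(as.numeric(counts), names(rpmv)),
        rpm = setNames(counts / total * 1e6, names(rpmv)),
        total = total, classFilter = "22G", normMode = "all_mapped")
}

test_that("IP enrichment applies the strict more-than-2-fold rule with a 1-RPM floor", {
    ip <- ct(c(a = 10, b = 2, c = 5, d = 0.5, e = 0), "ip")
    input <- ct(c(a = 4, b = 1, c = 0, d = 0.1, e = 0), "in")
    es <- ipEnrichment(ip, input)
    expect_setequal(members(es), c("a", "c"))
    expect_equal(unname(memberFolds(es)["a"]), 2.5)  # 10/4
    expect_equal(unname(memberFolds(es)["c"]), Inf)  # detected only in IP
    # fold exactly 2.0 fails the strict rule but passes non-strict
    expect_true("b" %in% members(ipEnrichment(ip, input, strict = FALSE)))
    # the floor keeps low-RPM genes out even at high fold ('d': fold 5)
    expect_false("d" %in% members(es))
    # 0/0 genes are never members
    expect_false("e" %in% members(es))
})

test_that("mismatched gene universes are rejected with the offending genes named", {
    expect_error(ipEnrichment(ct(c(a = 1, b = 1)), ct(c(a = 1, z = 1))),
                 "symmetric difference.*[bz]")
})

test_that("enrichment is monotone in the IP count at fixed totals", {
    set.seed(31)
    input <- ct(setNames(runif(50, 0, 50), sprintf("g%02d", 1:50)), "in")
    for (i in 1:10) {
        base <- setNames(runif(50, 0, 50), sprintf("g%02d", 1:50))
        esLo <- ipEnrichment(ct(base, "ip"), input)
        g <- sample(names(base), 1)
        base[g] <- base[g] + 30
        esHi <- ipEnrichment(ct(base, "ip"), input)
        if (g %in% members(esLo)) expect_true(g %in% members(esHi))
        expect_true(all(setdiff(members(esLo), g) %in% members(esHi)))
    }
})

test_that("differential categories follow the at-least-2-fold rule with the floor on the higher side", {
    test <- ct(c(a = 8, b = 1, c = 3, d = 0, e = 12), "mut")
    ref <- ct(c(a = 2, b = 10, c = 2, d = 0, e = 4), "wt")
    d0 <- differentialSmallRNA(test, ref)
    expect_identical(unname(categories(d0)[c("a", "b", "c", "d", "e")]),
                     c("up", "down", "unchanged", "below_floor", "up"))
    # floor 5: the 1-vs-10 gene is still down (reference side above floor)
    d5 <- differentialSmallRNA(test, ref, floorRpm = 5)
    expect_identical(unname(categories(d5)[["b"]]), "down")
    # an 8-vs-2 up call needs the test side above the floor; with both
    # sides under the floor the gene is below_floor, not unchanged
    d9 <- differentialSmallRNA(test, ref, floorRpm = 9)
    expect_identical(unname(categories(d9)[["a"]]), "below_floor")
    expect_identical(unname(categories(d9)[["e"]]), "up")
    expect_error(differentialSmallRNA(test, ref, floorRpm = -1),
                 "configuration error")
})

test_that("swapping samples swaps up and down for genes above floor in both", {
    set.seed(32)
    ids <- sprintf("g%02d", 1:80)
    a <- ct(setNames(round(runif(80, 0, 40), 1), ids), "A")
    b <- ct(setNames(round(runif(80, 0, 40), 1), ids), "B")
    fwd <- categories(differentialSmallRNA(a, b, floorRpm = 2))
    rev <- categories(differentialSmallRNA(b, a, floorRpm = 2))
    above <- names(which(rpm(a) > 2 & rpm(b) > 2))
    expect_identical(fwd[above] == "up", rev[above] == "down")
    expect_identical(fwd[above] == "down", rev[above] == "up")
})

test_that("cross-tabulation reports overlap counts and fractions in range", {
    u <- letters[1:10]
    xt <- setCrosstab(c("a", "b", "c"), c("b", "c", "d"), u)
    expect_equal(xt$nIntersect, 2L)
    expect_equal(xt$nUnion, 4L)
    expect_equal(xt$jaccard, 0.5)
    expect_equal(xt$fracAShared, 2 / 3)
    same <- setCrosstab(c("a", "b"), c("a", "b"), u)
    expect_equal(same$jaccard, 1)
    disj <- setCrosstab(c("a"), c("b"), u)
    expect_equal(disj$nIntersect, 0L)
    expect_error(setCrosstab(c("a", "zz"), "b", u), "outside the universe")
    # invariants on random sets
    set.seed(33)
    for (i in 1:10) {
        A <- sample(u, sample(0:10, 1))
        B <- sample(u, sample(0:10, 1))
        x <- setCrosstab(A, B, u)
        expect_lte(x$nIntersect, min(x$nA, x$nB))
        fr <- c(x$jaccard, x$fracAShared, x$fracBShared)
        fr <- fr[!is.na(fr)]
        expect_true(all(fr >= 0 & fr <= 1))
    }
})

test_that("ectopic targets are up-regulated CSR-1 genes in WAGO but not CSR-1 IPs", {
    ids <- sprintf("g%02d", 1:20)
    csr1List <- ids[1:10]
    test <- ct(setNames(c(rep(40, 6), rep(5, 14)), ids), "mut")
    ref <- ct(setNames(rep(5, 20), ids), "wt")
    d <- differentialSmallRNA(test, ref)           # g01..g06 up
    mk <- function(memberIds, ipId)
        new("EnrichedSet", ipSample = ipId, refSample = "in", fold = 2,
            strict = TRUE, minRpm = 1,
            members = setNames(rep(3, length(memberIds)), memberIds))
    ipSets <- list("WAGO-1" = mk(c("g01", "g02", "g03", "g15"), "w1"),
                   "WAGO-9" = mk(c("g04"), "w9"),
                   "CSR-1" = mk(c("g02", "g08"), "c1"))
    out <- ectopicTargets(d, csr1List, ipSets)
    # g01,g03 via WAGO-1; g04 via WAGO-9; g02 excluded (CSR-1-enriched);
    # g05,g06 up but in no WAGO IP; g15 WAGO-enriched but not a CSR-1 target
    expect_setequal(out, c("g01", "g03", "g04"))
    expect_error(ectopicTargets(d, csr1List, ipSets["WAGO-1"]),
                 "configuration error")
    noUp <- differentialSmallRNA(ref, ref)
    expect_length(ectopicTargets(noUp, csr1List, ipSets), 0L)
})

test_that("suppression counts genes whose double-mutant level falls to half the mutant level", {
    ids <- c("x", "y", "z", "w")
    mutant <- ct(setNames(c(20, 20, 10, 20), ids), "mut")
    double <- ct(setNames(c(5, 8, 2, 15), ids), "dbl")
    # enumerated against the criterion double <= mutant / 2:
    # 5 <= 10 yes, 8 <= 10 yes, 2 <= 5 yes, 15 <= 10 no
    out <- suppressionCall(ids, mutant, double)
    expect_setequal(out$suppressed, c("x", "y", "z"))
    expect_equal(c(out$nSuppressed, out$nTotal), c(3L, 4L))
    # empty set is not an error
    none <- suppressionCall(character(), mutant, double)
    expect_equal(c(none$nSuppressed, none$nTotal), c(0L, 0L))
    # alternative criterion: returned to within 2-fold of wild type
    wt <- ct(setNames(c(5, 3, 2, 20), ids), "wt")
    alt <- suppressionCall(ids, mutant, double, criterion = "wt", wt = wt)
    expect_setequal(alt$suppressed, c("x", "z", "w"))  # 5<=10, 8>6, 2<=4, 15<=40
})

test_that("composite union collects one category across comparisons", {
    ids <- c("a", "b", "c", "d")
    mk <- function(downIds) {
        cat <- setNames(rep("unchanged", 4), ids)
        cat[downIds] <- "down"
        new("DifferentialResult", testSample = "t", refSample = "r",
            fold = 2, floorRpm = 0, category = cat,
            foldChange = setNames(rep(1, 4), ids))
    }
    comp <- compositeUnion(list(mk(c("a", "b")), mk(c("b", "c"))))
    expect_identical(comp, c("a", "b", "c"))
    expect_identical(compositeUnion(list()), character())
    expect_equal(overlapFraction(comp, c("b", "c", "d")), 2 / 3)
    expect_true(is.na(overlapFraction(character(), ids)))
})

test_that("protein enrichment uses the non-strict at-least rule and handles absent background", {
    ip <- data.frame(protein_id = c("P1", "P2", "P3", "P4"),
                     level = c(4.0, 1.9, 2.0, 0.7))
    bg <- data.frame(protein_id = c("P1", "P2", "P3"),
                     level = c(1.5, 1.0, 1.0))
    out <- proteinEnrichment(ip, bg)
    expect_setequal(out, c("P1", "P3", "P4"))   # 2.67x, exactly 2x, absent bg
    expect_false("P2" %in% out)                  # 1.9x misses at-least 2
    expect_error(proteinEnrichment(
        data.frame(protein_id = "P1", level = -1), bg), "non-negative")
})
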