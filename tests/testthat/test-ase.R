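## ASE pipeline: eligibility and filter cascades, the two cross-comparison
## tests against brute-force oracles, downsampling behaviour, and
## permutation enrichment.

makeAseRows <- function(snp, tissue, refL, altL, refS, altS, gene = "g1",
                        exonic = TRUE, pos = 100) {
    nL <- length(refL); nS <- length(refS)
    data.frame(snp = snp, chrom = "chrI", pos = pos, gene = gene,
               exonic = exonic,
               cross = rep(c("MarineXLong", "MarineXShort"), c(nL, nS)),
               tissue = tissue,
               library = sprintf("%s_%s_%d", tissue,
                                 rep(c("L", "S"), c(nL, nS)),
                                 c(seq_len(nL), seq_len(nS))),
               individual = sprintf("%s_%d", rep(c("L", "S"), c(nL, nS)),
                                    c(seq_len(nL), seq_len(nS))),
               ref = c(refL, refS), alt = c(altL, altS), fwAllele = "ref")
}

test_that("eligibility requires enough informative individuals", {
    ## 24 individuals all at (10, 10): kept
    mk <- function(refs, alts) {
        AseCountTable(data.frame(
            snp = "s1", chrom = "chrI", pos = 1, gene = "g", exonic = TRUE,
            cross = rep(c("MarineXLong", "MarineXShort"), each = 12),
            tissue = "DS", library = sprintf("L%02d", 1:24),
            individual = sprintf("F%02d", 1:24),
            ref = refs, alt = alts, fwAllele = "ref"))
    }
    expect_identical(filterEligibleSnps(mk(rep(10, 24), rep(10, 24))), "s1")

    ## only 19 informative of 24: dropped (19 < 20)
    refs <- c(rep(10, 19), rep(0, 5)); alts <- c(rep(10, 19), rep(1, 5))
    expect_length(filterEligibleSnps(mk(refs, alts)), 0)

    ## (100, 3): 3 reads but < 5% of total, so that fish is uninformative
    ## and only 19 of 24 remain -> dropped
    refs <- c(rep(10, 19), 100, rep(1, 4))
    alts <- c(rep(10, 19), 3, rep(1, 4))
    expect_length(filterEligibleSnps(mk(refs, alts)), 0)
    ## same fish at (50, 3): 3/53 > 5%, now informative -> 20 of 24 -> kept
    refs[20] <- 50
    expect_identical(filterEligibleSnps(mk(refs, alts)), "s1")
})

test_that("downsampling thins to the group median and preserves ratios", {
    df <- makeAseRows("s1", "DS", refL = c(25, 25, 50), altL = c(25, 25, 50),
                      refS = c(25, 25, 25), altS = c(25, 25, 25))
    tab <- AseCountTable(df)
    out <- downsampleToMedian(tab, seed = 1)
    tot <- out$ref + out$alt
    ## median per (cross, tissue): Long group totals 50,50,100 -> median 50
    expect_true(all(tot[out$cross == "MarineXLong"] == 50))
    ## at-median libraries unchanged
    expect_identical(out$ref[1:2], c(25L, 25L))
    ## never increases counts
    expect_true(all(out$ref <= tab$ref & out$alt <= tab$alt))
    ## equal-depth group is untouched
    expect_identical(out$ref[out$cross == "MarineXShort"],
                     tab$ref[tab$cross == "MarineXShort"])

    ## thinning preserves the expected allelic fraction (3-SE band over
    ## independent seeds)
    fr <- vapply(1:2000, function(s) downsampleToMedian(tab, seed = s)$ref[3] / 50, 0)
    expect_lt(abs(mean(fr) - 0.5), 3 * sd(fr) / sqrt(length(fr)))
})

test_that("pooled Fisher test matches the hypergeometric oracle", {
    df <- makeAseRows("s1", "DS", refL = c(3, 2), altL = c(3, 2),
                      refS = c(2, 3), altS = c(2, 3))
    tab <- AseCountTable(df)
    expect_equal(pooledFisher(tab, "s1", "DS"), 1.0)
    expect_equal(pooledFisher(tab, "s1", "PF"), NA_real_)

    df2 <- makeAseRows("s2", "PS", refL = 12, altL = 2, refS = 3, altS = 11)
    tab2 <- AseCountTable(df2)
    m <- rbind(c(12, 2), c(3, 11))
    expect_equal(pooledFisher(tab2, "s2", "PS"), oracleFisher2x2(m),
                 tolerance = 1e-10)

    ## random tables against the oracle
    set.seed(5)
    for (i in 1:50) {
        m <- matrix(sample(0:12, 4, TRUE), 2)
        if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
        expect_equal(fisher.test(m)$p.value, oracleFisher2x2(m),
                     tolerance = 1e-9)
    }
})

test_that("log ratios follow the zero-count pseudocount rule", {
    expect_equal(aseLogRatio(8, 2), 2)
    expect_equal(aseLogRatio(4, 4), 0)
    expect_equal(aseLogRatio(10, 0), log2(21))
    expect_equal(aseLogRatio(0, 10), -log2(21))
    expect_true(is.na(aseLogRatio(0, 0)))
    expect_equal(aseLogRatio(c(8, 10), c(2, 0)), c(2, log2(21)))
})

test_that("Mann-Whitney reciprocal test matches the exhaustive permutation oracle", {
    same <- mwuReciprocal(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$p, 1.0)
    expect_equal(same$diffAse, 0)

    r <- mwuReciprocal(c(1, 2, 3), c(4, 5, 6))
    expect_equal(r$p, 0.1)
    expect_equal(r$p, oracleMwuExact(c(1, 2, 3), c(4, 5, 6)))
    expect_equal(r$diffAse, -3)

    set.seed(9)
    for (i in 1:20) {
        n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
        v <- sample(1000, n1 + n2)   # distinct values, no ties
        x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
        expect_equal(mwuReciprocal(x, y)$p, oracleMwuExact(x, y),
                     tolerance = 1e-12)
    }
    expect_error(mwuReciprocal(numeric(0), 1:3), "at least one")
})

test_that("binomial allele test matches exact enumeration", {
    expect_equal(binomialAlleleTest(5, 5), 1.0)
    expect_equal(binomialAlleleTest(9, 1), 22 / 1024)
    expect_equal(binomialAlleleTest(0, 20), 2 * 0.5^20)
    set.seed(3)
    for (i in 1:20) {
        n <- sample(1:30, 1); k <- sample(0:n, 1)
        expect_equal(binomialAlleleTest(k, n - k), oracleBinomTwoSided(k, n),
                     tolerance = 1e-12)
    }
})

test_that("spine-candidate filter applies all criteria", {
    mkRes <- function(psDiff = 1.2, totalReads = 3000, exonic = TRUE) {
        S4Vectors::DataFrame(
            snp = "s1", gene = "g1", exonic = exonic,
            tissue = c("DS", "PS", "PF", "H"),
            fisherP = c(0.001, 0.001, 0.5, 0.5),
            mwuP = c(0.01, 0.02, 0.4, 0.6),
            diffAse = c(1.5, psDiff, 0.1, -0.2),
            meanLogRatioLong = 1, meanLogRatioShort = -1,
            binomPLong = 0.01, binomPShort = 0.01,
            tissueReads = totalReads / 4, totalReads = totalReads)
    }
    expect_identical(spineCandidateFilter(mkRes()), "s1")
    expect_length(spineCandidateFilter(mkRes(psDiff = -1.2)), 0)  # discordant
    expect_length(spineCandidateFilter(mkRes(totalReads = 6000)), 0)
    expect_length(spineCandidateFilter(mkRes(exonic = FALSE)), 0)

    ## control-tissue violation: significant PF
    bad <- mkRes(); bad$mwuP[3] <- 0.01
    expect_length(spineCandidateFilter(bad), 0)
    ## control-tissue violation: large differential ASE in H
    bad2 <- mkRes(); bad2$diffAse[4] <- 1.4
    expect_length(spineCandidateFilter(bad2), 0)
    ## missing tissue: excluded
    expect_length(spineCandidateFilter(mkRes()[1:3, ]), 0)
})

test_that("reciprocal-gene filter recovers planted genes and counts SNP support", {
    sim <- generateAseCounts(AseEffectSpec(nGenes = 12L, fracReciprocal = 0.25,
                                           seed = 31))
    res <- snpAseTest(sim$counts, seed = 31)
    calls <- reciprocalGeneFilter(res)
    planted <- sim$truth$gene[sim$truth$reciprocal]
    expect_setequal(calls$gene, planted)
    expect_true(all(calls$passes1Snp))
    expect_true(all(calls$passes2Snp))   # 3 planted SNPs per gene
    expect_true(all(calls$nSnps >= 2))

    ## a gene with a single passing SNP passes 1-SNP but not 2-SNP support
    one <- S4Vectors::DataFrame(
        snp = "s9", gene = "g9", exonic = TRUE, tissue = "DS",
        fisherP = 1e-6, mwuP = 0.001, diffAse = 2,
        meanLogRatioLong = 1, meanLogRatioShort = -1,
        binomPLong = 1e-4, binomPShort = 1e-4,
        tissueReads = 500, totalReads = 2000)
    g <- reciprocalGeneFilter(one)
    expect_true(g$passes1Snp)
    expect_false(g$passes2Snp)
})

test_that("proximity enrichment has correct degenerate and enriched behaviour", {
    genes <- GenomicRanges::GRanges("chrI",
                                    IRanges::IRanges(seq(1e5, 3e7, by = 1e5),
                                                     width = 1000))
    names(genes) <- sprintf("g%03d", seq_along(genes))

    ## saturated: every gene near a region
    all <- GenomicRanges::GRanges("chrI", IRanges::IRanges(1, 3.2e7))
    e <- proximityEnrichment(names(genes)[1:10], genes, all, nPerm = 200,
                             seed = 1)
    expect_identical(e$observed, 10L)
    expect_equal(e$p, 1.0)

    ## no regions at all
    e0 <- proximityEnrichment(names(genes)[1:10], genes,
                              GenomicRanges::GRanges(), nPerm = 200, seed = 1)
    expect_identical(e0$observed, 0L)
    expect_equal(e0$p, 1.0)

    ## called set drawn entirely from near-region genes (10% of universe)
    near <- genes[1:30]
    regions <- GenomicRanges::resize(near, 1, fix = "center")
    called <- names(near)[1:20]
    er <- proximityEnrichment(called, genes, regions, nPerm = 2000, seed = 2)
    expect_lt(er$p, 0.001)
    expect_lt(er$expected, er$observed)

    ## permutation p is invariant to universe order given the seed
    perm <- sample(seq_along(genes))
    er2 <- proximityEnrichment(called, genes[perm], regions, nPerm = 2000,
                               seed = 2)
    expect_identical(er$p, er2$p)

    expect_error(proximityEnrichment(c(names(genes), "zzz"), genes, regions),
                 "larger than")
})
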