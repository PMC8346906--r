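## Triallelic scan: window tiling, PCA filter, cluster-gain filter,
## merging/intersection, and end-to-end parameter recovery.

makeClusteredMatrix <- function(nSites, groupSizes, divergence = 0.9,
                                noiseSd = 0, seed = 1) {
    ## sites x samples matrix with each group's per-site mean drawn
    ## independently at 0.5 +/- divergence/2 (general-position clusters)
    set.seed(seed)
    k <- length(groupSizes)
    cl <- rep(seq_len(k), groupSizes)
    means <- matrix(0.5 + sample(c(-1, 1), nSites * k, TRUE) * divergence / 2,
                    nSites, k)
    f <- means[, cl] + matrix(rnorm(nSites * sum(groupSizes), 0, noiseSd),
                              nSites)
    pmin(pmax(f, 0), 1)
}

test_that("window tiling covers each chromosome from the origin to its last SNP", {
    sites <- GenomicRanges::GRanges("chrI",
                                    IRanges::IRanges(c(1, 2600, 5000), width = 1))
    w <- tileWindows(sites, 2500, 500)
    expect_identical(GenomicRanges::start(w), seq(1L, 5000L, by = 500L))
    expect_true(all(GenomicRanges::width(w) == 2500))

    expect_length(tileWindows(GenomicRanges::GRanges(), 2500, 500), 0)

    ## non-overlapping tiling: window count equals direct enumeration
    set.seed(1)
    for (span in c(3000, 9999, 20000)) {
        s2 <- GenomicRanges::GRanges("chrII", IRanges::IRanges(
            c(1, sort(sample.int(span, 5)), span), width = 1))
        w2 <- tileWindows(s2, 2500, 2500)
        expect_identical(length(w2), length(seq(1, span, by = 2500)))
        expect_true(all(diff(GenomicRanges::start(w2)) == 2500))
    }
})

test_that("window PCA matches a dense eigensolver and has the expected structure", {
    ## rank-1 two-group separation: PC1 = 100
    f <- cbind(matrix(0, 10, 3), matrix(1, 10, 3))
    p <- windowPca(f)
    expect_equal(p$pve[1], 100, tolerance = 1e-9)
    expect_equal(sum(p$pve), 100, tolerance = 1e-9)

    ## three equidistant clusters: PC1 ~ PC2 ~ 50, and the full spectrum
    ## equals an independent eigendecomposition of the covariance matrix
    f3 <- makeClusteredMatrix(200, c(4, 4, 4), divergence = 1, seed = 2)
    p3 <- windowPca(f3)
    expect_equal(p3$pve[1], 50, tolerance = 5)
    expect_equal(p3$pve[2], 50, tolerance = 5)
    x <- scale(t(f3), scale = FALSE)
    ev <- eigen(cov(x), symmetric = TRUE, only.values = TRUE)$values
    ev <- ev[ev > 1e-12]
    expect_equal(p3$pve[seq_along(ev)], 100 * ev / sum(ev), tolerance = 1e-8)

    ## duplicating every sample leaves the PVE spectrum unchanged
    pd <- windowPca(cbind(f3, f3))
    expect_equal(pd$pve[1:5], p3$pve[1:5], tolerance = 1e-8)

    ## constant window is degenerate
    expect_null(windowPca(matrix(0.5, 5, 6)))
})

test_that("PCA filter applies inclusive thresholds to PC2 and PC1+PC2", {
    expect_true(pcaFilter(c(55, 20, 25)))
    expect_false(pcaFilter(c(80, 10, 10)))
    expect_false(pcaFilter(c(40, 30, 30)))
})

test_that("cluster gain separates 3-group structure and matches the exhaustive optimum", {
    ## three internally identical groups: perfect separation
    f <- makeClusteredMatrix(30, c(3, 3, 3), divergence = 1, seed = 3)
    g <- clusterGain(f, seed = 1)
    expect_equal(g$s3, 0)
    expect_equal(g$reductionK3, 1)
    expect_equal(g$transitionGain, 1)
    expect_true(kmeansFilter(g))

    ## two identical groups: no k=3 gain
    f2 <- makeClusteredMatrix(30, c(4, 4), divergence = 1, seed = 4)
    g2 <- clusterGain(f2, seed = 1)
    expect_equal(g2$s2, 0)
    expect_equal(g2$transitionGain, 0)
    expect_false(kmeansFilter(g2))

    ## random matrices, n <= 8: best-of-restarts equals the exhaustive
    ## partition optimum for both k = 2 and k = 3
    for (seed in 1:4) {
        set.seed(100 + seed)
        n <- sample(5:8, 1)
        f <- matrix(runif(12 * n), 12, n)
        g <- clusterGain(f, restarts = 20, seed = seed)
        dmat <- squaredDistMatrix(t(f))
        expect_equal(g$s2, oracleBestS(dmat, 2), tolerance = 1e-12)
        expect_equal(g$s3, oracleBestS(dmat, 3), tolerance = 1e-12)
        expect_true(g$s1 >= g$s2 && g$s2 >= g$s3)
    }
})

test_that("cluster gain errors with fewer than three samples", {
    expect_error(clusterGain(matrix(runif(10), 5, 2)), ">= 3 samples")
})

test_that("k-means filter uses strict thresholds", {
    mk <- function(r, t) list(reductionK3 = r, transitionGain = t)
    expect_true(kmeansFilter(mk(0.66, 0.21)))
    expect_false(kmeansFilter(mk(0.65, 0.5)))
    expect_false(kmeansFilter(mk(0.9, 0.1)))
    expect_false(kmeansFilter(mk(0.9, 0.2)))
})

test_that("merging bridges gaps up to the limit and is a fixed point", {
    gr <- GenomicRanges::GRanges("chrI",
                                 IRanges::IRanges(c(1001, 13001), c(3500, 15500)))
    m <- mergeWithin(gr, 10000)   # gap is 9500 <= 10000
    expect_length(m, 1)
    expect_identical(GenomicRanges::start(m), 1001L)
    expect_identical(GenomicRanges::end(m), 15500L)
    expect_length(mergeWithin(gr, 9000), 2)   # gap exceeds limit

    single <- GenomicRanges::GRanges("chrI", IRanges::IRanges(5, 10))
    expect_equal(mergeWithin(single, 1000), GenomicRanges::granges(single))

    ## random sets: merging again changes nothing, and all residual gaps
    ## exceed the limit
    set.seed(7)
    for (i in 1:5) {
        rnd <- GenomicRanges::GRanges(
            sample(c("chrI", "chrII"), 12, TRUE),
            IRanges::IRanges(sample.int(5e4, 12), width = sample.int(4000, 12)))
        m1 <- mergeWithin(rnd, 2000)
        expect_equal(mergeWithin(m1, 2000), m1)
        for (ch in c("chrI", "chrII")) {
            mm <- m1[GenomicRanges::seqnames(m1) == ch]
            if (length(mm) > 1)
                expect_true(all(GenomicRanges::start(mm)[-1] -
                                GenomicRanges::end(mm)[-length(mm)] - 1 > 2000))
        }
    }
})

test_that("track intersection equals per-base membership", {
    a <- GenomicRanges::GRanges("chrI", IRanges::IRanges(1, 100))
    b <- GenomicRanges::GRanges("chrI", IRanges::IRanges(51, 150))
    expect_identical(GenomicRanges::start(intersectTracks(a, b)), 51L)
    expect_identical(GenomicRanges::end(intersectTracks(a, b)), 100L)

    disj <- GenomicRanges::GRanges("chrI", IRanges::IRanges(200, 300))
    expect_length(intersectTracks(a, disj), 0)

    ## brute-force per-base oracle on a 10-kb toy chromosome
    set.seed(11)
    for (i in 1:4) {
        mk <- function() mergeWithin(GenomicRanges::GRanges(
            "chrT", IRanges::IRanges(sample.int(9000, 6),
                                     width = sample.int(1500, 6))), 0)
        ra <- mk(); rb <- mk()
        res <- intersectTracks(ra, rb)
        inA <- inB <- logical(12000)
        for (j in seq_along(ra))
            inA[GenomicRanges::start(ra)[j]:GenomicRanges::end(ra)[j]] <- TRUE
        for (j in seq_along(rb))
            inB[GenomicRanges::start(rb)[j]:GenomicRanges::end(rb)[j]] <- TRUE
        inRes <- logical(12000)
        for (j in seq_along(res))
            inRes[GenomicRanges::start(res)[j]:GenomicRanges::end(res)[j]] <- TRUE
        expect_identical(inRes, inA & inB)
    }
})

test_that("the scan recovers a planted 3-cluster window and nothing else", {
    w3 <- GenomicRanges::GRanges("chrI", IRanges::IRanges(30001, 32500),
                                 nClusters = 3L, divergence = 0.9)
    w2 <- GenomicRanges::GRanges("chrI", IRanges::IRanges(60001, 62500),
                                 nClusters = 2L, divergence = 0.9)
    spec <- LandscapeSpec(nMarine = 4L, nFreshwater = 8L,
                          chromLengths = c(chrI = 1e5), windows = c(w3, w2),
                          noiseSd = 0.05, seed = 21)
    sim <- generateGenotypeLandscape(spec)
    res <- scanTriallelic(sim$genotypes, seed = 21)
    calls <- triallelicCalls(res)
    expect_true(all(IRanges::overlapsAny(w3, calls)))
    expect_false(any(IRanges::overlapsAny(w2, calls)))
    rec <- scanRecovery(res, sim$truth, sim$genotypes)
    expect_equal(rec$sensitivity, 1)
    expect_equal(rec$falseCallRate, 0)

    ## the final call set is contained in both merged tracks
    ov <- GenomicRanges::intersect(res@pcaTrack, res@kmeansTrack)
    expect_true(all(IRanges::overlapsAny(calls, res@pcaTrack)))
    expect_equal(sum(GenomicRanges::width(calls)), sum(GenomicRanges::width(ov)))
})

test_that("a marine/freshwater (2-cluster) landscape yields an empty call set", {
    w2 <- GenomicRanges::GRanges("chrI",
                                 IRanges::IRanges(c(20001, 50001), c(22500, 52500)),
                                 nClusters = 2L, divergence = 0.9)
    spec <- LandscapeSpec(nMarine = 4L, nFreshwater = 8L,
                          chromLengths = c(chrI = 8e4), windows = w2,
                          noiseSd = 0.05, seed = 22)
    sim <- generateGenotypeLandscape(spec)
    res <- scanTriallelic(sim$genotypes, seed = 22)
    expect_length(triallelicCalls(res), 0)
})

test_that("an all-constant genome yields an empty call set", {
    sites <- GenomicRanges::GRanges("chrI",
                                    IRanges::IRanges(seq(1, 2e4, by = 100),
                                                     width = 1),
                                    ref = "A", alt = "T")
    gt <- GenotypeTable(sites, matrix(0.5, length(sites), 8),
                        ecotype = "unknown",
                        sampleNames = sprintf("s%d", 1:8))
    res <- scanTriallelic(gt, seed = 1)
    expect_length(triallelicCalls(res), 0)
    expect_true(all(windowStats(res)$skipped == "no_variance"))
})

test_that("scan output is invariant to sample order and chromosome order", {
    w3 <- GenomicRanges::GRanges("chrI", IRanges::IRanges(20001, 22500),
                                 nClusters = 3L, divergence = 0.9)
    spec <- LandscapeSpec(nMarine = 4L, nFreshwater = 8L,
                          chromLengths = c(chrI = 5e4), windows = w3,
                          noiseSd = 0.05, seed = 23)
    sim <- generateGenotypeLandscape(spec)
    gt <- sim$genotypes
    res <- scanTriallelic(gt, seed = 5)

    ## permute samples
    perm <- c(5, 12, 1, 8, 3, 10, 2, 7, 11, 4, 9, 6)
    gtp <- GenotypeTable(rowRanges(gt), freqMatrix(gt)[, perm],
                         ecotype = ecotype(gt)[perm],
                         sampleNames = colnames(gt)[perm])
    resp <- scanTriallelic(gtp, seed = 5)
    expect_equal(triallelicCalls(res), triallelicCalls(resp))

    ## present chromosomes in reversed input order (constructor sorts)
    sites2 <- suppressWarnings(
        c(GenomicRanges::GRanges("chrB",
                                 IRanges::IRanges(seq(1, 1e4, 100),
                                                  width = 1),
                                 ref = "A", alt = "T"),
          rowRanges(gt)))
    seqnames2 <- as.character(GenomicRanges::seqnames(sites2))
    f2 <- rbind(matrix(0.5, sum(seqnames2 == "chrB"), 12), freqMatrix(gt))
    gt2a <- GenotypeTable(sites2, f2, ecotype(gt), colnames(gt))
    o <- rev(seq_along(sites2))
    gt2b <- GenotypeTable(sites2[o], f2[o, ], ecotype(gt), colnames(gt))
    expect_equal(triallelicCalls(scanTriallelic(gt2a, seed = 5)),
                 triallelicCalls(scanTriallelic(gt2b, seed = 5)))
})
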