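## Triallelic genome scan: sliding 2.5-kb windows are tested by two
## independent filters -- a window-PCA variance filter and a k-means
## cluster-gain filter -- whose merged tracks are intersected into the
## final call set.

#' Tile sliding windows over the sites of a chromosome
#'
#' Windows of width `windowBp` start every `stepBp` bp from position 1 and
#' tile each chromosome up to its last site; chromosomes without sites get
#' no windows.
#'
#' @param sites a `GRanges` of sites (or a [GenotypeTable-class]).
#' @param windowBp,stepBp window width and step in bp (defaults 2500/500).
#' @return A `GRanges` of windows, chromosomes in alphabetical order.
#' @export
tileWindows <- function(sites, windowBp = 2500, stepBp = 500) {
    if (is(sites, "GenotypeTable")) sites <- rowRanges(sites)
    stopifnot(windowBp > 0, stepBp > 0)
    chroms <- sort(unique(as.character(seqnames(sites))))
    starts <- lapply(chroms, function(ch)
        seq(1L, max(start(sites[seqnames(sites) == ch])), by = stepBp))
    GRanges(rep(chroms, lengths(starts)),
            IRanges(unlist(c(starts, list(integer(0)))), width = windowBp))
}

.imputeRows <- function(freqs) {
    ## mean-impute missing frequencies per site within the window
    miss <- is.na(freqs)
    if (any(miss)) {
        rm <- rowMeans(freqs, na.rm = TRUE)
        freqs[miss] <- rm[row(freqs)[miss]]
        freqs[is.na(freqs)] <- 0    # site entirely missing
    }
    freqs
}

#' Percent variance explained by window PCA
#'
#' PCA of one window's site-by-sample frequency matrix with samples as
#' observations and sites as (centred, unscaled) variables; the PVE vector
#' is the eigenvalue spectrum of the sample covariance matrix, scaled to
#' sum to 100.  Missing values are mean-imputed per site.
#'
#' @param freqs numeric matrix, sites x samples.
#' @return A list with `pve` (numeric, sums to 100), `nSites`; or `NULL`
#'   for a degenerate (all-constant) window.
#' @export
windowPca <- function(freqs) {
    freqs <- .imputeRows(as.matrix(freqs))
    if (ncol(freqs) < 2) stop("window PCA needs >= 2 samples")
    x <- t(freqs)
    x <- sweep(x, 2, colMeans(x))
    if (all(abs(x) < 1e-12)) return(NULL)
    ev <- svd(x, nu = 0, nv = 0)$d^2
    list(pve = 100 * ev / sum(ev), nSites = nrow(freqs))
}

#' PCA variance filter
#'
#' A window is a triallelic candidate on the PCA track when substantial
#' variance lies on *both* of the first two axes: `PC2 >= pc2Min` and
#' `PC1 + PC2 >= pc12Min` (percent variance explained, inclusive
#' thresholds).
#'
#' @param pca result of [windowPca()] (or a bare PVE vector).
#' @param pc2Min,pc12Min thresholds in PVE points (defaults 20 and 75).
#' @return `TRUE`/`FALSE`.
#' @export
pcaFilter <- function(pca, pc2Min = 20, pc12Min = 75) {
    pve <- if (is.list(pca)) pca$pve else pca
    if (is.null(pve) || length(pve) < 2) return(FALSE)
    pve[2] >= pc2Min && (pve[1] + pve[2]) >= pc12Min
}

.sOfPartition <- function(dmat, cl) {
    ## sum over clusters of the mean pairwise distance within the cluster;
    ## singleton clusters contribute 0
    s <- 0
    for (k in unique(cl)) {
        i <- which(cl == k)
        if (length(i) > 1) s <- s + mean(dmat[i, i][lower.tri(dmat[i, i])])
    }
    s
}

#' k-means cluster-gain statistic for one window
#'
#' Samples (frequency-vector columns) are clustered with k-means at
#' k = 2 and k = 3, and the sum `s` of average intracluster genetic
#' distances is computed for each k (`s1` puts all samples in one
#' cluster).  The genetic distance between two samples is, by default
#' (`metric = "squared"`), the mean squared per-site frequency difference
#' -- the same squared-deviation scale the k-means objective minimises,
#' which keeps the within-cluster noise floor far below the
#' between-cluster signal.  `"euclidean"` (per-site RMS difference) and
#' `"manhattan"` (per-site mean absolute difference) are available as
#' options.  For nine or fewer samples the best partition at each k is
#' found by exhaustive enumeration; otherwise it is the best over
#' `restarts` seeded k-means starts, two deterministic hierarchical starts
#' (average and complete linkage cuts), and all single-sample "donation"
#' splits of the best (k-1)-partition, "best" meaning lowest `s` with ties
#' broken by start index.  The donation candidates guarantee
#' `s1 >= s2 >= s3`, and the whole search is invariant to sample order.
#'
#' @param freqs numeric matrix, sites x samples (>= 3 samples).
#' @param metric `"squared"` (default), `"euclidean"` or `"manhattan"`.
#' @param restarts number of random k-means starts (default 20).
#' @param seed integer seed for the restarts.
#' @return list with `s1`, `s2`, `s3`, `reductionK3` (`1 - s3/s1`),
#'   `transitionGain` (`1 - s3/s2`, defined as 0 when `s2 == 0`), and
#'   `nSites`.
#' @export
clusterGain <- function(freqs, metric = c("squared", "euclidean", "manhattan"),
                        restarts = 20, seed = 1) {
    metric <- match.arg(metric)
    freqs <- .imputeRows(as.matrix(freqs))
    nS <- ncol(freqs)
    if (nS < 3) stop("cluster gain needs >= 3 samples")
    x <- t(freqs)
    dmat <- as.matrix(dist(x))
    n <- nrow(freqs)
    dmat <- switch(metric,
                   squared = dmat^2 / n,
                   euclidean = dmat / sqrt(n),
                   manhattan = as.matrix(dist(x, method = "manhattan")) / n)
    s1 <- mean(dmat[lower.tri(dmat)])
    p2 <- .bestPartition(x, dmat, 2, restarts, seed, prev = rep(1L, nS))
    p3 <- .bestPartition(x, dmat, 3, restarts, seed, prev = p2$cl)
    list(s1 = s1, s2 = p2$s, s3 = p3$s,
         reductionK3 = if (s1 > 0) 1 - p3$s / s1 else NA_real_,
         transitionGain = if (p2$s > 0) 1 - p3$s / p2$s else 0,
         nSites = n)
}

.donationSplits <- function(cl) {
    ## all partitions obtained by splitting one member out of a
    ## multi-member cluster into its own new cluster
    out <- list()
    for (i in which(tabulate(cl)[cl] > 1)) {
        cl2 <- cl
        cl2[i] <- max(cl) + 1L
        out[[length(out) + 1L]] <- cl2
    }
    out
}

.allKPartitions <- function(n, k) {
    ## every partition of n items into exactly k non-empty blocks,
    ## as restricted growth strings
    out <- vector("list", 0)
    rec <- function(labels, nextLab) {
        i <- length(labels) + 1L
        if (i > n) {
            if (nextLab - 1L == k) out[[length(out) + 1L]] <<- labels
            return()
        }
        for (lab in seq_len(min(nextLab, k)))
            rec(c(labels, lab), max(nextLab, lab + 1L))
    }
    rec(integer(0), 1L)
    out
}

.bestPartition <- function(x, dmat, k, restarts, seed, prev = NULL) {
    if (nrow(x) <= 9) {
        ## small windows: the global s-optimum by exhaustive enumeration
        cand <- .allKPartitions(nrow(x), k)
        if (!length(cand)) {
            grp <- seq_len(nrow(x))
            return(list(cl = grp, s = .sOfPartition(dmat, grp)))
        }
        ss <- vapply(cand, function(cl) .sOfPartition(dmat, cl), 0)
        best <- which.min(ss)
        return(list(cl = cand[[best]], s = ss[best]))
    }
    ## canonical ordering of the distinct sample profiles makes the seeded
    ## center draws independent of input sample order
    key <- apply(round(x, 10), 1, paste, collapse = ",")
    ux <- x[!duplicated(key), , drop = FALSE]
    uo <- order(apply(round(ux, 10), 1, paste, collapse = ","))
    ux <- ux[uo, , drop = FALSE]
    grp <- match(key, apply(round(ux, 10), 1, paste, collapse = ","))
    if (nrow(ux) <= k)                 # fewer distinct profiles than k
        return(list(cl = grp, s = .sOfPartition(dmat, grp)))
    cand <- list()
    for (r in seq_len(restarts)) {
        set.seed(seed * 1000L + r)
        centers <- ux[sample.int(nrow(ux), k), , drop = FALSE]
        km <- tryCatch(suppressWarnings(
            kmeans(x, centers = centers, iter.max = 50)),
            error = function(e) NULL)
        if (!is.null(km)) cand[[length(cand) + 1L]] <- km$cluster
    }
    cand[[length(cand) + 1L]] <- cutree(hclust(stats::as.dist(dmat),
                                               method = "average"), k)
    cand[[length(cand) + 1L]] <- cutree(hclust(stats::as.dist(dmat),
                                               method = "complete"), k)
    if (!is.null(prev) && length(unique(prev)) == k - 1L)
        cand <- c(cand, .donationSplits(prev))
    cand <- Filter(function(cl) length(unique(cl)) == k, cand)
    ss <- vapply(cand, function(cl) .sOfPartition(dmat, cl), 0)
    best <- which.min(ss)
    list(cl = cand[[best]], s = ss[best])
}

#' k-means cluster-gain filter
#'
#' A window is a triallelic candidate on the k-means track when three
#' clusters explain most of the genetic distance structure: more than
#' `k3Min` reduction in `s` for k = 3 relative to the unclustered baseline
#' *and* more than `transitionMin` further reduction from k = 2 to k = 3
#' (both strict inequalities).
#'
#' @param gain result of [clusterGain()].
#' @param k3Min,transitionMin thresholds (defaults 0.65 and 0.20).
#' @return `TRUE`/`FALSE` (`FALSE` for a degenerate window with `s1 = 0`).
#' @export
kmeansFilter <- function(gain, k3Min = 0.65, transitionMin = 0.20) {
    if (is.null(gain) || !is.finite(gain$reductionK3)) return(FALSE)
    gain$reductionK3 > k3Min && gain$transitionGain > transitionMin
}

#' Merge candidate windows within a gap
#'
#' Intervals on the same chromosome separated by at most `gapBp` bp are
#' unioned; the output is sorted with all pairwise gaps > `gapBp`.
#'
#' @param intervals a `GRanges`.
#' @param gapBp maximum gap to bridge (bp).
#' @return A merged, sorted `GRanges`.
#' @export
mergeWithin <- function(intervals, gapBp) {
    reduce(GenomicRanges::sort(intervals), min.gapwidth = gapBp + 1)
}

#' Intersect the PCA and k-means candidate tracks
#'
#' The final triallelic call set is the base-pair intersection of the two
#' merged tracks; empty intersections are dropped.
#'
#' @param pcaRegions,kmeansRegions merged `GRanges` tracks.
#' @return A `GRanges` with metadata columns `passedPca` and
#'   `passedKmeans` (both `TRUE` by construction).
#' @export
intersectTracks <- function(pcaRegions, kmeansRegions) {
    calls <- GenomicRanges::intersect(pcaRegions, kmeansRegions)
    mcols(calls)$passedPca <- rep(TRUE, length(calls))
    mcols(calls)$passedKmeans <- rep(TRUE, length(calls))
    calls
}

#' TriallelicScanResult
#'
#' Container for [scanTriallelic()] output: the final call set, the two
#' merged candidate tracks, per-window diagnostics and the parameters
#' used.
#'
#' @slot calls final call `GRanges` (intersection of the tracks).
#' @slot pcaTrack,kmeansTrack merged candidate `GRanges` per filter.
#' @slot windowStats `DataFrame` of per-window diagnostics (PC1/PC2 PVE,
#'   s-values, filter flags).
#' @slot params list of scan parameters.
#' @export
setClass("TriallelicScanResult",
         representation(calls = "GRanges", pcaTrack = "GRanges",
                        kmeansTrack = "GRanges", windowStats = "DFrame",
                        params = "list"))

setMethod("show", "TriallelicScanResult", function(object) {
    cat(sprintf(
        "TriallelicScanResult: %d final region(s) spanning %d bp\n",
        length(object@calls), sum(width(object@calls))))
    cat(sprintf("  PCA track: %d region(s); k-means track: %d region(s); %d window(s) analyzed\n",
                length(object@pcaTrack), length(object@kmeansTrack),
                nrow(object@windowStats)))
    invisible(NULL)
})

#' @describeIn scanTriallelic final call set (`GRanges`)
#' @param x a `TriallelicScanResult`
#' @export
triallelicCalls <- function(x) x@calls

#' @describeIn scanTriallelic per-window diagnostics (`DataFrame`)
#' @export
windowStats <- function(x) x@windowStats

#' Triallelic genome scan
#'
#' Slides 2.5-kb windows (500-bp step) across a population
#' allele-frequency matrix and flags windows by two independent filters:
#' [pcaFilter()] on the window-PCA variance spectrum (PC2 >= 20 PVE and
#' PC1 + PC2 >= 75 PVE) and [kmeansFilter()] on the k-means cluster-gain
#' statistic (> 65% reduction in the intracluster-distance sum `s` at
#' k = 3, > 20% reduction from k = 2 to k = 3).  Candidate windows on the
#' PCA track are merged within 10 kb, on the k-means track within 5 kb,
#' and the intersection of the two merged tracks is the final call set.
#' Windows with fewer than `minSites` SNPs or no variance are skipped.
#'
#' @param gt a [GenotypeTable-class] (samples are populations represented
#'   by alternate-allele frequencies; per-individual dosage matrices work
#'   identically).
#' @param windowBp,stepBp window width and step (2500/500).
#' @param pc2Min,pc12Min PCA-filter thresholds (20/75, inclusive).
#' @param k3Min,transitionMin k-means-filter thresholds (0.65/0.20,
#'   strict).
#' @param mergePcaBp,mergeKmeansBp per-track merge gaps (10000/5000).
#' @param minSites minimum SNPs per analyzable window (3).
#' @param metric genetic distance metric, see [clusterGain()].
#' @param restarts,seed k-means restarts per window and base seed.
#' @return A [TriallelicScanResult-class].
#' @examples
#' w <- GenomicRanges::GRanges("chrI", IRanges::IRanges(40001, 42500),
#'                             nClusters = 3L, divergence = 0.9)
#' sim <- generateGenotypeLandscape(LandscapeSpec(
#'     chromLengths = c(chrI = 1e5), windows = w, seed = 2))
#' res <- scanTriallelic(sim$genotypes, seed = 2)
#' triallelicCalls(res)
#' @export
scanTriallelic <- function(gt, windowBp = 2500, stepBp = 500,
                           pc2Min = 20, pc12Min = 75,
                           k3Min = 0.65, transitionMin = 0.20,
                           mergePcaBp = 10000, mergeKmeansBp = 5000,
                           minSites = 3, metric = "squared",
                           restarts = 20, seed = 1) {
    stopifnot(is(gt, "GenotypeTable"))
    windows <- tileWindows(gt, windowBp, stepBp)
    freq <- freqMatrix(gt)
    hits <- findOverlaps(windows, rowRanges(gt))
    rows <- split(subjectHits(hits), factor(queryHits(hits),
                                            levels = seq_along(windows)))
    stats <- vector("list", length(windows))
    for (i in seq_along(windows)) {
        idx <- rows[[i]]
        rec <- list(chrom = as.character(seqnames(windows))[i],
                    start = start(windows)[i], end = end(windows)[i],
                    nSites = length(idx), pc1 = NA_real_, pc2 = NA_real_,
                    s1 = NA_real_, s2 = NA_real_, s3 = NA_real_,
                    reductionK3 = NA_real_, transitionGain = NA_real_,
                    passedPca = FALSE, passedKmeans = FALSE,
                    skipped = "")
        if (length(idx) < minSites) {
            rec$skipped <- "too_few_sites"
        } else {
            f <- freq[idx, , drop = FALSE]
            pca <- windowPca(f)
            if (is.null(pca)) {
                rec$skipped <- "no_variance"
            } else {
                rec$pc1 <- pca$pve[1]
                rec$pc2 <- if (length(pca$pve) > 1) pca$pve[2] else 0
                rec$passedPca <- pcaFilter(pca, pc2Min, pc12Min)
                g <- clusterGain(f, metric = metric, restarts = restarts,
                                 seed = seed + i)
                rec[c("s1", "s2", "s3", "reductionK3", "transitionGain")] <-
                    g[c("s1", "s2", "s3", "reductionK3", "transitionGain")]
                rec$passedKmeans <- kmeansFilter(g, k3Min, transitionMin)
            }
        }
        stats[[i]] <- rec
    }
    ws <- DataFrame(do.call(rbind, lapply(stats, as.data.frame)))
    pcaTrack <- mergeWithin(windows[ws$passedPca], mergePcaBp)
    kmTrack <- mergeWithin(windows[ws$passedKmeans], mergeKmeansBp)
    new("TriallelicScanResult", calls = intersectTracks(pcaTrack, kmTrack),
        pcaTrack = pcaTrack, kmeansTrack = kmTrack, windowStats = ws,
        params = list(windowBp = windowBp, stepBp = stepBp, pc2Min = pc2Min,
                      pc12Min = pc12Min, k3Min = k3Min,
                      transitionMin = transitionMin, mergePcaBp = mergePcaBp,
                      mergeKmeansBp = mergeKmeansBp, minSites = minSites,
                      metric = metric, restarts = restarts, seed = seed))
}

#' Sensitivity and specificity of a scan against a planted truth set
#'
#' A planted 3-cluster window counts as recovered when it overlaps a final
#' call.  Specificity is measured on background tiles: non-overlapping
#' `windowBp`-wide tiles at least `bufferBp` away from any planted
#' 3-cluster window; the false-call rate is the fraction of those tiles
#' touched by a call.
#'
#' @param result a [TriallelicScanResult-class].
#' @param truth planted-window `GRanges` with an `nClusters` column (as
#'   returned by [generateGenotypeLandscape()]).
#' @param sites the scanned sites (`GRanges` or [GenotypeTable-class]),
#'   used to lay background tiles.
#' @param bufferBp exclusion buffer around planted 3-cluster windows
#'   (default 10000, the PCA-track merge distance).
#' @return list with `sensitivity`, `falseCallRate`, `nTrue`,
#'   `nBackground`.
#' @export
scanRecovery <- function(result, truth, sites, bufferBp = 10000) {
    calls <- triallelicCalls(result)
    tri <- truth[mcols(truth)$nClusters == 3L]
    sens <- if (length(tri))
        mean(IRanges::overlapsAny(tri, calls)) else NA_real_
    w <- result@params$windowBp
    tiles <- tileWindows(sites, windowBp = w, stepBp = w)
    if (length(tri))
        tiles <- tiles[!IRanges::overlapsAny(
            tiles, GenomicRanges::resize(tri, width(tri) + 2 * bufferBp,
                                         fix = "center"))]
    fcr <- if (length(tiles))
        mean(IRanges::overlapsAny(tiles, calls)) else NA_real_
    list(sensitivity = sens, falseCallRate = fcr,
         nTrue = length(tri), nBackground = length(tiles))
}
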