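## Seeded generators of synthetic inputs with known planted structure.
## These emulate the statistical structure the analyses assume -- ancestral
## haplotype clusters in population allele frequencies, reciprocal allelic
## imbalance in F1 read counts, and covariate-dependent spine lengths --
## so that every downstream stage can be validated by parameter recovery.

#' LandscapeSpec: design of a synthetic genotype landscape
#'
#' Describes a population allele-frequency matrix containing windows with
#' 1, 2 or 3 ancestral haplotype clusters.  In a 3-cluster window the
#' marine populations form one cluster and the freshwater populations are
#' split into two classes (as for a triallelic locus); a 2-cluster window
#' is ordinary marine/freshwater differentiation; elsewhere all samples
#' share a common frequency plus jitter.  Within a planted window, each
#' cluster's per-SNP mean frequency sits at `0.5 +/- divergence/2`, the
#' side drawn independently per cluster and per SNP, so clusters are
#' mutually equidistant and in general position (expected per-site
#' frequency difference between two clusters is `divergence` at half the
#' sites).
#'
#' @slot nMarine,nFreshwater integer population counts.
#' @slot chromLengths named numeric: chromosome lengths in bp.
#' @slot snpDensity SNPs per bp.
#' @slot windows `GRanges` of planted windows with metadata columns
#'   `nClusters` (1, 2 or 3) and `divergence` (in \[0, 1\]).
#' @slot noiseSd within-cluster per-sample frequency jitter (SD).
#' @slot seed integer RNG seed.
#' @export
setClass("LandscapeSpec",
         representation(nMarine = "integer", nFreshwater = "integer",
                        chromLengths = "numeric", snpDensity = "numeric",
                        windows = "GRanges", noiseSd = "numeric",
                        seed = "integer"))

setValidity("LandscapeSpec", function(object) {
    msg <- character()
    if (object@snpDensity <= 0) msg <- c(msg, "snpDensity must be > 0")
    w <- object@windows
    if (length(w)) {
        if (!all(mcols(w)$nClusters %in% 1:3))
            msg <- c(msg, "nClusters must be 1, 2 or 3")
        if (any(mcols(w)$divergence < 0 | mcols(w)$divergence > 1))
            msg <- c(msg, "divergence must lie in [0, 1]")
        if (length(GenomicRanges::findOverlaps(w, drop.self = TRUE,
                                               drop.redundant = TRUE)))
            msg <- c(msg, "planted windows must not overlap")
        if (!all(as.character(seqnames(w)) %in% names(object@chromLengths)))
            msg <- c(msg, "planted windows must lie on named chromosomes")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname LandscapeSpec-class
#' @param nMarine,nFreshwater population counts (defaults mirror a
#'   69-population survey with a one-third marine share).
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param snpDensity SNPs per bp (default 0.01, i.e. ~25 SNPs per 2.5-kb
#'   window).
#' @param windows planted-window `GRanges` (metadata `nClusters`,
#'   `divergence`).
#' @param noiseSd within-cluster jitter SD (default 0.05).
#' @param seed RNG seed.
#' @export
LandscapeSpec <- function(nMarine = 23L, nFreshwater = 46L,
                          chromLengths = c(chrI = 1e6), snpDensity = 0.01,
                          windows = GRanges(), noiseSd = 0.05, seed = 1L) {
    new("LandscapeSpec", nMarine = as.integer(nMarine),
        nFreshwater = as.integer(nFreshwater), chromLengths = chromLengths,
        snpDensity = snpDensity, windows = windows, noiseSd = noiseSd,
        seed = as.integer(seed))
}

#' Cluster membership implied by a LandscapeSpec
#'
#' The deterministic partition used inside planted windows: marine samples
#' form cluster 1; for 3-cluster windows the freshwater samples are split
#' in half into clusters 2 and 3, for 2-cluster windows they form a single
#' cluster 2.
#'
#' @param spec a [LandscapeSpec-class].
#' @param nClusters 1, 2 or 3.
#' @return integer vector of cluster indices, one per sample (marine
#'   samples first).
#' @export
landscapeClusters <- function(spec, nClusters) {
    nM <- spec@nMarine; nF <- spec@nFreshwater
    if (nClusters == 1L) rep(1L, nM + nF)
    else if (nClusters == 2L) rep(1:2, c(nM, nF))
    else rep(1:3, c(nM, ceiling(nF / 2), floor(nF / 2)))
}

#' Generate a synthetic genotype landscape
#'
#' @param spec a [LandscapeSpec-class].
#' @return A list with elements `genotypes` (a [GenotypeTable-class],
#'   marine samples first) and `truth` (the planted-window `GRanges` with
#'   an added list-column `assignment` giving each sample's cluster).
#'   Identical spec (including seed) gives bitwise-identical output.
#' @examples
#' w <- GenomicRanges::GRanges("chrI", IRanges::IRanges(50001, 52500),
#'                             nClusters = 3L, divergence = 0.9)
#' sim <- generateGenotypeLandscape(LandscapeSpec(windows = w, seed = 7))
#' sim$genotypes
#' @export
generateGenotypeLandscape <- function(spec) {
    validObject(spec)
    set.seed(spec@seed)
    nS <- spec@nMarine + spec@nFreshwater
    eco <- rep(c("marine", "freshwater"), c(spec@nMarine, spec@nFreshwater))
    nm <- sprintf("pop%02d", seq_len(nS))
    chromList <- lapply(sort(names(spec@chromLengths)), function(ch) {
        L <- spec@chromLengths[[ch]]
        n <- round(L * spec@snpDensity)
        pos <- sort(sample.int(L, n))
        base <- runif(n, 0.1, 0.9)
        freq <- matrix(base, n, nS)
        w <- spec@windows[seqnames(spec@windows) == ch]
        for (i in seq_along(w)) {
            idx <- which(pos >= start(w)[i] & pos <= end(w)[i])
            if (!length(idx)) next
            k <- mcols(w)$nClusters[i]
            d <- mcols(w)$divergence[i]
            cl <- landscapeClusters(spec, k)
            if (k == 1L) {
                freq[idx, ] <- runif(length(idx), 0.1, 0.9)
            } else {
                ## per SNP, each cluster independently sits at 0.5 +/- d/2;
                ## for k = 2 the two clusters always take opposite sides
                for (j in idx) {
                    side <- if (k == 2L) {
                        s1 <- sample(c(-1, 1), 1); c(s1, -s1)
                    } else sample(c(-1, 1), k, replace = TRUE)
                    freq[j, ] <- 0.5 + side[cl] * d / 2
                }
            }
        }
        if (spec@noiseSd > 0)
            freq <- freq + matrix(rnorm(length(freq), 0, spec@noiseSd),
                                  nrow(freq))
        freq <- pmin(pmax(freq, 0), 1)
        list(chrom = rep(ch, length(pos)), pos = pos, freq = freq)
    })
    sites <- GRanges(unlist(lapply(chromList, `[[`, "chrom")),
                     IRanges(unlist(lapply(chromList, `[[`, "pos")),
                             width = 1L),
                     ref = "A", alt = "T")
    freq <- do.call(rbind, lapply(chromList, `[[`, "freq"))
    truth <- spec@windows
    if (length(truth))
        mcols(truth)$assignment <- lapply(mcols(truth)$nClusters,
                                          landscapeClusters, spec = spec)
    list(genotypes = GenotypeTable(sites, freq, ecotype = eco,
                                   sampleNames = nm),
         truth = truth)
}

#' AseEffectSpec: design of a synthetic ASE experiment
#'
#' Two F1 crosses sharing a marine parent (Marine x Long, Marine x Short)
#' are profiled in four tissues: dorsal spine (DS), pelvic spine (PS), and
#' the control tissues pectoral fin (PF) and heart (H).  For a planted
#' reciprocal gene the freshwater-allele read fraction in the spine
#' tissues is `pSpine["MarineXShort"]` (default 0.73, i.e. the Short
#' allele up 0.73/0.27 = 2.7-fold relative to marine) and
#' `pSpine["MarineXLong"]` (default 0.36, the Long allele down 1.8-fold);
#' control tissues and non-reciprocal genes sit at 0.5.  Read depth per
#' SNP per library is negative-binomial; the freshwater-allele count is
#' binomial given depth.
#'
#' @slot pSpine named numeric(2): planted freshwater-allele fraction in
#'   spine tissues per cross.
#' @slot depthMean,depthSize negative-binomial mean and size of per-SNP,
#'   per-library total depth.
#' @slot nLibraries named integer: libraries per tissue *per cross*
#'   (default DS 12, PS 12, PF 6, H 6).
#' @slot nSnpsPerGene,nGenes integers.
#' @slot fracReciprocal fraction of genes with a planted reciprocal
#'   effect.
#' @slot pJitterSd optional per-library jitter (SD, logit-free, applied to
#'   p and clipped) modelling ratio overdispersion; default 0.
#' @slot seed integer RNG seed.
#' @export
setClass("AseEffectSpec",
         representation(pSpine = "numeric", depthMean = "numeric",
                        depthSize = "numeric", nLibraries = "integer",
                        nSnpsPerGene = "integer", nGenes = "integer",
                        fracReciprocal = "numeric", pJitterSd = "numeric",
                        seed = "integer"))

setValidity("AseEffectSpec", function(object) {
    msg <- character()
    if (!all(sort(names(object@pSpine)) == sort(CROSSES)))
        msg <- c(msg, "pSpine must be named by the two crosses")
    if (any(object@pSpine <= 0 | object@pSpine >= 1))
        msg <- c(msg, "pSpine values must lie in (0, 1)")
    if (object@depthMean < 0) msg <- c(msg, "depthMean must be >= 0")
    if (!all(sort(names(object@nLibraries)) == sort(TISSUES)))
        msg <- c(msg, "nLibraries must be named by the four tissues")
    if (object@fracReciprocal < 0 || object@fracReciprocal > 1)
        msg <- c(msg, "fracReciprocal must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @rdname AseEffectSpec-class
#' @param pSpine,depthMean,depthSize,nLibraries,nSnpsPerGene,nGenes,fracReciprocal,pJitterSd,seed
#'   see slots.
#' @export
AseEffectSpec <- function(pSpine = c(MarineXShort = 0.73, MarineXLong = 0.36),
                          depthMean = 60, depthSize = 8,
                          nLibraries = c(DS = 12L, PS = 12L, PF = 6L, H = 6L),
                          nSnpsPerGene = 3L, nGenes = 50L,
                          fracReciprocal = 0.2, pJitterSd = 0, seed = 1L) {
    new("AseEffectSpec", pSpine = pSpine, depthMean = depthMean,
        depthSize = depthSize,
        nLibraries = setNames(as.integer(nLibraries), names(nLibraries)),
        nSnpsPerGene = as.integer(nSnpsPerGene), nGenes = as.integer(nGenes),
        fracReciprocal = fracReciprocal, pJitterSd = pJitterSd,
        seed = as.integer(seed))
}

#' Generate a synthetic ASE count table
#'
#' Library-to-individual mapping follows the study design: within each
#' cross, spine library `i` (DS or PS) comes from individual `i`
#' (1..nLibraries), and control library `i` (PF or H) from individual `i`;
#' with the default 12 spine libraries per cross this yields 12
#' individuals per cross, 24 in total.
#'
#' @param spec an [AseEffectSpec-class].
#' @return A list with `counts` (an [AseCountTable-class]) and `truth`
#'   (`DataFrame` of `gene`, `reciprocal` flag).
#' @examples
#' sim <- generateAseCounts(AseEffectSpec(nGenes = 5L, seed = 3))
#' sim$counts
#' @export
generateAseCounts <- function(spec) {
    validObject(spec)
    set.seed(spec@seed)
    genes <- sprintf("gene%03d", seq_len(spec@nGenes))
    nRec <- round(spec@fracReciprocal * spec@nGenes)
    rec <- genes %in% sample(genes, nRec)
    snpGene <- rep(genes, each = spec@nSnpsPerGene)
    snpRec <- rep(rec, each = spec@nSnpsPerGene)
    nSnps <- length(snpGene)
    ## genes laid 20 kb apart on one synthetic chromosome, SNPs 300 bp apart
    pos <- (match(snpGene, genes) - 1L) * 20000L + 1000L +
        (seq_len(nSnps) - 1L) %% spec@nSnpsPerGene * 300L
    snp <- sprintf("chrA:%d", pos)
    fwAllele <- sample(c("ref", "alt"), nSnps, replace = TRUE)

    libs <- do.call(rbind, lapply(CROSSES, function(cr)
        do.call(rbind, lapply(TISSUES, function(ti)
            data.frame(cross = cr, tissue = ti,
                       library = sprintf("%s_%s_%02d", cr, ti,
                                         seq_len(spec@nLibraries[[ti]])),
                       individual = sprintf("%s_F%02d", cr,
                                            seq_len(spec@nLibraries[[ti]])))))))
    grid <- cbind(libs[rep(seq_len(nrow(libs)), each = nSnps), ],
                  snpIdx = rep(seq_len(nSnps), nrow(libs)))
    n <- nrow(grid)
    depth <- if (spec@depthMean == 0) integer(n)
             else rnbinom(n, mu = spec@depthMean, size = spec@depthSize)
    p <- rep(0.5, n)
    planted <- snpRec[grid$snpIdx] & grid$tissue %in% c("DS", "PS")
    p[planted] <- spec@pSpine[grid$cross[planted]]
    if (spec@pJitterSd > 0)
        p <- pmin(pmax(p + rnorm(n, 0, spec@pJitterSd), 0.01), 0.99)
    fw <- rbinom(n, depth, p)
    isRef <- fwAllele[grid$snpIdx] == "ref"
    counts <- AseCountTable(data.frame(
        snp = snp[grid$snpIdx], chrom = "chrA", pos = pos[grid$snpIdx],
        gene = snpGene[grid$snpIdx], exonic = TRUE,
        cross = grid$cross, tissue = grid$tissue,
        library = grid$library, individual = grid$individual,
        ref = ifelse(isRef, fw, depth - fw),
        alt = ifelse(isRef, depth - fw, fw),
        fwAllele = fwAllele[grid$snpIdx]))
    list(counts = counts, truth = DataFrame(gene = genes, reciprocal = rec))
}

#' PhenotypeSpec: design of synthetic spine-length phenotypes
#'
#' Spine lengths are generated as
#' `intercept + betaSL * SL + betaSex * (sex == "M") + gamma[genotype] + e`
#' with genotypes at a biallelic locus (classes SS, SL, LL by count of the
#' Long allele) drawn under Hardy-Weinberg at the given Long-allele
#' frequency.  The full genotype effect applies to the major spines (DS1,
#' DS2, PS); DS3 and the anal spine receive half of it.
#'
#' @slot nFish integer.
#' @slot intercept,betaSL,betaSex numeric model coefficients (mm; `betaSL`
#'   per mm of standard length).
#' @slot gamma named numeric(3): genotype-class effects for SS, SL, LL.
#' @slot residSd residual SD (mm).
#' @slot alleleFreq frequency of the Long allele.
#' @slot meanSL,sdSL standard-length distribution (mm).
#' @slot seed integer RNG seed.
#' @export
setClass("PhenotypeSpec",
         representation(nFish = "integer", intercept = "numeric",
                        betaSL = "numeric", betaSex = "numeric",
                        gamma = "numeric", residSd = "numeric",
                        alleleFreq = "numeric", meanSL = "numeric",
                        sdSL = "numeric", seed = "integer"))

setValidity("PhenotypeSpec", function(object) {
    msg <- character()
    if (object@nFish < 1) msg <- c(msg, "nFish must be positive")
    if (object@residSd < 0) msg <- c(msg, "residSd must be >= 0")
    if (!identical(sort(names(object@gamma)), sort(c("SS", "SL", "LL"))))
        msg <- c(msg, "gamma must be named SS, SL, LL")
    if (object@alleleFreq < 0 || object@alleleFreq > 1)
        msg <- c(msg, "alleleFreq must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @rdname PhenotypeSpec-class
#' @param nFish,intercept,betaSL,betaSex,gamma,residSd,alleleFreq,meanSL,sdSL,seed
#'   see slots.
#' @export
PhenotypeSpec <- function(nFish = 700L, intercept = 1, betaSL = 0.1,
                          betaSex = 0.3,
                          gamma = c(SS = 0, SL = 0.5, LL = 1),
                          residSd = 0.5, alleleFreq = 0.5,
                          meanSL = 45, sdSL = 6, seed = 1L) {
    new("PhenotypeSpec", nFish = as.integer(nFish), intercept = intercept,
        betaSL = betaSL, betaSex = betaSex, gamma = gamma, residSd = residSd,
        alleleFreq = alleleFreq, meanSL = meanSL, sdSL = sdSL,
        seed = as.integer(seed))
}

#' Per-allele effect size for a target percent variance explained
#'
#' For an additive genotype effect `gamma = (0, d, 2d)` under
#' Hardy-Weinberg at Long-allele frequency `p`, the genotype variance is
#' `2 p (1 - p) d^2`; solving
#' `PVE = 100 * varG / (varG + residSd^2)` for `d` gives the per-allele
#' effect needed to plant a given PVE.
#'
#' @param pve target percent variance explained (0-100).
#' @param alleleFreq Long-allele frequency.
#' @param residSd residual SD.
#' @return the per-allele effect `d`.
#' @examples
#' d <- spineEffectForPve(30, 0.5, 1)
#' 100 * 2 * .25 * d^2 / (2 * .25 * d^2 + 1)   # 30
#' @export
spineEffectForPve <- function(pve, alleleFreq = 0.5, residSd = 1) {
    v <- pve / 100
    het <- 2 * alleleFreq * (1 - alleleFreq)
    residSd * sqrt(v / (1 - v) / het)
}

#' Generate synthetic phenotypes and genotypes
#'
#' @param spec a [PhenotypeSpec-class].
#' @return A list with `phenotypes` (data.frame: `fish`, `population`,
#'   `sex`, `standardLength`, `DS1`, `DS2`, `DS3`, `anal`, `PS`) and
#'   `genotypes` (character vector of SS/SL/LL, named by fish).
#' @export
generatePhenotypes <- function(spec) {
    validObject(spec)
    set.seed(spec@seed)
    n <- spec@nFish
    fish <- sprintf("fish%04d", seq_len(n))
    sex <- sample(c("M", "F"), n, replace = TRUE)
    sl <- rnorm(n, spec@meanSL, spec@sdSL)
    nL <- rbinom(n, 2, spec@alleleFreq)
    geno <- c("SS", "SL", "LL")[nL + 1L]
    base <- spec@intercept + spec@betaSL * sl + spec@betaSex * (sex == "M")
    g <- spec@gamma[geno]
    mk <- function(scale) base + scale * g + rnorm(n, 0, spec@residSd)
    ph <- data.frame(fish = fish, population = "simulated", sex = sex,
                     standardLength = sl,
                     DS1 = mk(1), DS2 = mk(1), DS3 = mk(0.5),
                     anal = mk(0.5), PS = mk(1))
    list(phenotypes = ph, genotypes = setNames(geno, fish))
}
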