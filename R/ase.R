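## Reciprocal allele-specific expression between two F1 crosses sharing a
## marine parent.  Per SNP and tissue, two tests compare the crosses: a
## Fisher exact test on pooled (optionally depth-downsampled) allele
## counts, and a Mann-Whitney U test on per-library log2 allelic ratios.
## Filter cascades then call spine candidates and reciprocally expressed
## genes, and a permutation test measures enrichment of called genes near
## triallelic regions.

#' Log2 allelic ratio with zero-count pseudocount
#'
#' `log2(ref/alt)`, with a Haldane-Anscombe pseudocount (default 0.5)
#' added to both counts only when either count is zero, keeping the ratio
#' finite without biasing nonzero cases.  Samples with both counts zero
#' are `NA` (excluded from that SNP).
#'
#' @param ref,alt non-negative counts (vectorized).
#' @param pseudocount added to both counts when a zero is present.
#' @return numeric vector of log2 ratios.
#' @examples
#' aseLogRatio(8, 2)    # 2
#' aseLogRatio(10, 0)   # log2(10.5/0.5)
#' @export
aseLogRatio <- function(ref, alt, pseudocount = 0.5) {
    stopifnot(all(ref >= 0), all(alt >= 0))
    zero <- ref == 0 | alt == 0
    out <- ifelse(zero,
                  log2((ref + pseudocount) / (alt + pseudocount)),
                  log2(ref / alt))
    out[ref == 0 & alt == 0] <- NA_real_
    out
}

#' Eligibility filter for ASE SNPs
#'
#' Keeps SNPs informative in enough fish: counts are first aggregated per
#' individual (summing each individual's libraries across tissues), and a
#' SNP is kept when at least `ceiling(minFracIndividuals * nIndividuals)`
#' individuals have at least `minReads` reads for *each* allele and each
#' allele carries at least `minAlleleFrac` of that individual's total.
#' With the default 20/24 fraction and the study's 24 fish this is the
#' "20 of 24 fish with >= 3 reads per allele (minimum 5% of total)" rule.
#'
#' @param counts an [AseCountTable-class].
#' @param minFracIndividuals required fraction of informative individuals
#'   (default 20/24).
#' @param minReads minimum reads per allele per individual (default 3).
#' @param minAlleleFrac minimum per-allele fraction of the individual's
#'   total (default 0.05).
#' @return character vector of eligible SNP ids.
#' @export
filterEligibleSnps <- function(counts, minFracIndividuals = 20 / 24,
                               minReads = 3, minAlleleFrac = 0.05) {
    if (any(is.na(counts$individual)))
        stop("library-to-individual mapping is incomplete; supply an ",
             "explicit 'individual' column")
    nInd <- length(unique(counts$individual))
    need <- ceiling(minFracIndividuals * nInd)
    key <- paste(counts$snp, counts$individual, sep = "\r")
    ref <- rowsum(counts$ref, key)
    alt <- rowsum(counts$alt, key)
    tot <- ref + alt
    ok <- ref >= minReads & alt >= minReads &
        ref >= minAlleleFrac * tot & alt >= minAlleleFrac * tot
    snpOf <- sub("\r.*", "", rownames(ref))
    nOk <- rowsum(as.integer(ok), snpOf)
    sort(rownames(nOk)[nOk[, 1] >= need])
}

#' Downsample libraries to the median depth of their cross x tissue group
#'
#' For each (cross, tissue) group the median total depth over (SNP,
#' library) entries is computed; entries above the median are thinned to
#' exactly the median total by drawing that many reads without
#' replacement from the entry's read pool
#' (`ref' ~ Hypergeometric(ref, alt, median)`, `alt' = median - ref'`).
#' Subsampling reads this way preserves the allelic-ratio distribution
#' exactly: if the original reference count is Binomial(total, p), the
#' thinned count is Binomial(median, p).  Entries at or below the median
#' are unchanged.
#'
#' @param counts an [AseCountTable-class].
#' @param seed integer seed.
#' @return A thinned [AseCountTable-class].
#' @export
downsampleToMedian <- function(counts, seed = 1) {
    set.seed(seed)
    df <- as.data.frame(counts)
    tot <- df$ref + df$alt
    grp <- paste(df$cross, df$tissue)
    med <- stats::ave(tot, grp, FUN = median)
    med <- as.integer(round(med))
    over <- which(tot > med & tot > 0)
    if (length(over)) {
        newRef <- stats::rhyper(length(over), df$ref[over], df$alt[over],
                                med[over])
        df$ref[over] <- newRef
        df$alt[over] <- med[over] - newRef
    }
    AseCountTable(df)
}

#' Pooled Fisher exact test between crosses
#'
#' Reference and alternate reads are summed within each cross for one SNP
#' and tissue, and the resulting 2 x 2 table (rows = crosses, columns =
#' ref/alt) is tested with a two-sided Fisher exact test.
#'
#' @param counts an [AseCountTable-class].
#' @param snp,tissue the SNP id and tissue to test.
#' @return two-sided p-value, or `NA` if either cross has zero total.
#' @export
pooledFisher <- function(counts, snp, tissue) {
    i <- counts$snp == snp & counts$tissue == tissue
    if (!any(i)) return(NA_real_)
    m <- .pooledMatrix(counts[i, , drop = FALSE])
    if (any(rowSums(m) == 0)) return(NA_real_)
    fisher.test(m)$p.value
}

.pooledMatrix <- function(rows) {
    m <- rbind(
        c(sum(rows$ref[rows$cross == "MarineXLong"]),
          sum(rows$alt[rows$cross == "MarineXLong"])),
        c(sum(rows$ref[rows$cross == "MarineXShort"]),
          sum(rows$alt[rows$cross == "MarineXShort"])))
    dimnames(m) <- list(c("MarineXLong", "MarineXShort"), c("ref", "alt"))
    m
}

#' Mann-Whitney U test on per-library log ratios, with differential ASE
#'
#' Compares log2 allelic ratios of Marine x Long libraries against
#' Marine x Short libraries (two-sided; exact when the combined sample
#' size is <= 20 and there are no ties, tie-corrected normal approximation
#' otherwise).  `diffAse`, the per-SNP effect size, is the difference of
#' cross-mean log2 ratios (Long cross minus Short cross).
#'
#' @param longRatios,shortRatios numeric vectors of per-library log2
#'   ratios (NAs dropped; each cross needs >= 1 value).
#' @return list with `p` and `diffAse`.
#' @export
mwuReciprocal <- function(longRatios, shortRatios) {
    longRatios <- longRatios[!is.na(longRatios)]
    shortRatios <- shortRatios[!is.na(shortRatios)]
    if (!length(longRatios) || !length(shortRatios))
        stop("both crosses need at least one informative library")
    exact <- length(longRatios) + length(shortRatios) <= 20 &&
        !anyDuplicated(c(longRatios, shortRatios))
    p <- suppressWarnings(wilcox.test(longRatios, shortRatios,
                                      exact = exact)$p.value)
    list(p = p, diffAse = mean(longRatios) - mean(shortRatios))
}

#' Exact two-sided binomial test of allelic balance
#'
#' Tests `ref` successes in `ref + alt` trials against 0.5, summing the
#' probabilities of all outcomes at most as probable as the observed one.
#'
#' @param ref,alt non-negative counts with `ref + alt >= 1`.
#' @return two-sided p-value.
#' @export
binomialAlleleTest <- function(ref, alt) {
    stopifnot(ref + alt >= 1)
    binom.test(ref, ref + alt, p = 0.5)$p.value
}

#' Per-SNP, per-tissue ASE statistics
#'
#' Runs the full per-SNP battery for every (SNP, tissue): pooled Fisher
#' exact test between crosses (after optional per-group median
#' downsampling), Mann-Whitney U on per-library log2 ratios with the
#' `diffAse` effect size, per-cross mean log2 ratios, per-cross pooled
#' binomial allelic-balance tests, and read totals.
#'
#' @param counts an [AseCountTable-class].
#' @param downsample logical; downsample to group medians before the
#'   pooled Fisher test (default `TRUE`).  The Mann-Whitney test always
#'   uses the raw per-library ratios.
#' @param seed seed for the downsampling.
#' @return A `DataFrame` with one row per (SNP, tissue): `snp`, `gene`,
#'   `exonic`, `tissue`, `fisherP`, `mwuP`, `diffAse`, `meanLogRatioLong`,
#'   `meanLogRatioShort`, `binomPLong`, `binomPShort`, `tissueReads`,
#'   `totalReads` (all-tissue total for the SNP).
#' @export
snpAseTest <- function(counts, downsample = TRUE, seed = 1) {
    pooled <- if (downsample) downsampleToMedian(counts, seed) else counts
    df <- as.data.frame(counts)
    pf <- as.data.frame(pooled)
    totBySnp <- rowsum(df$ref + df$alt, df$snp)
    keys <- unique(df[, c("snp", "gene", "exonic", "tissue")])
    splitKey <- function(d) paste(d$snp, d$tissue, sep = "\r")
    rawSplit <- split(df, splitKey(df))
    pooSplit <- split(pf, splitKey(pf))
    out <- lapply(seq_len(nrow(keys)), function(i) {
        k <- keys[i, ]
        raw <- rawSplit[[paste(k$snp, k$tissue, sep = "\r")]]
        poo <- pooSplit[[paste(k$snp, k$tissue, sep = "\r")]]
        m <- .pooledMatrix(poo)
        fisherP <- if (any(rowSums(m) == 0)) NA_real_
                   else fisher.test(m)$p.value
        lr <- aseLogRatio(raw$ref, raw$alt)
        lrL <- lr[raw$cross == "MarineXLong"]
        lrS <- lr[raw$cross == "MarineXShort"]
        mwu <- if (all(is.na(lrL)) || all(is.na(lrS)))
            list(p = NA_real_, diffAse = NA_real_)
        else mwuReciprocal(lrL, lrS)
        mRaw <- .pooledMatrix(raw)
        data.frame(
            snp = k$snp, gene = k$gene, exonic = k$exonic, tissue = k$tissue,
            fisherP = fisherP, mwuP = mwu$p, diffAse = mwu$diffAse,
            meanLogRatioLong = mean(lrL, na.rm = TRUE),
            meanLogRatioShort = mean(lrS, na.rm = TRUE),
            binomPLong = if (sum(mRaw[1, ]) >= 1)
                binomialAlleleTest(mRaw[1, 1], mRaw[1, 2]) else NA_real_,
            binomPShort = if (sum(mRaw[2, ]) >= 1)
                binomialAlleleTest(mRaw[2, 1], mRaw[2, 2]) else NA_real_,
            tissueReads = sum(raw$ref + raw$alt),
            totalReads = totBySnp[k$snp, 1])
    })
    DataFrame(do.call(rbind, out))
}

#' Spine-candidate SNP filter
#'
#' Keeps SNPs behaving as expected for a gene controlling spine length:
#' located in an annotated exon; not an extreme depth outlier (total reads
#' `< maxReads`); significant differential ASE in the same direction in
#' *both* spine tissues (DS and PS, Mann-Whitney unadjusted `p < alpha`);
#' and no differential ASE in either control tissue (PF and H:
#' `p > alpha` and `-aseBound < diffAse < aseBound`).  SNPs missing any of
#' the four tissues are excluded.
#'
#' @param results output of [snpAseTest()].
#' @param maxReads depth-outlier cutoff (default 5000).
#' @param alpha significance level (default 0.05).
#' @param aseBound control-tissue differential-ASE bound (default 1).
#' @return character vector of passing SNP ids.
#' @export
spineCandidateFilter <- function(results, maxReads = 5000, alpha = 0.05,
                                 aseBound = 1) {
    res <- as.data.frame(results)
    keep <- vapply(split(res, res$snp), function(r) {
        if (!all(c("DS", "PS", "PF", "H") %in% r$tissue)) return(FALSE)
        ds <- r[r$tissue == "DS", ]; ps <- r[r$tissue == "PS", ]
        ctrl <- r[r$tissue %in% c("PF", "H"), ]
        isTRUE(ds$exonic[1]) && r$totalReads[1] < maxReads &&
            !is.na(ds$mwuP) && !is.na(ps$mwuP) &&
            ds$mwuP < alpha && ps$mwuP < alpha &&
            sign(ds$diffAse) == sign(ps$diffAse) &&
            all(!is.na(ctrl$mwuP) & ctrl$mwuP > alpha &
                abs(ctrl$diffAse) < aseBound)
    }, TRUE)
    sort(names(keep)[keep])
}

#' Reciprocal-expression gene calls
#'
#' A SNP shows a reciprocal expression pattern when, in at least one
#' tissue, both freshwater alleles are significantly differentially
#' expressed relative to marine (pooled binomial test `p < alpha` in each
#' cross separately) and relative to each other (both Mann-Whitney and
#' Fisher `p < alpha`), with at least a `foldMin`-fold expression change
#' between the two freshwater alleles (`|diffAse| >= log2(foldMin)`).
#' Exonic SNPs below the depth cutoff are considered; genes are called at
#' 1-SNP and 2-SNP support stringencies.
#'
#' @param results output of [snpAseTest()].
#' @param foldMin minimum fold change between the freshwater alleles
#'   (default 2).
#' @param alpha significance level (default 0.05).
#' @param maxReads depth-outlier cutoff (default 5000).
#' @return A `DataFrame` with one row per gene carrying a passing SNP:
#'   `gene`, `nSnps` (passing SNPs), `directionLong`, `directionShort`
#'   (majority sign of the cross-mean log ratios among passing SNPs),
#'   `passes1Snp`, `passes2Snp`.
#' @export
reciprocalGeneFilter <- function(results, foldMin = 2, alpha = 0.05,
                                 maxReads = 5000) {
    res <- as.data.frame(results)
    res <- res[res$exonic & res$totalReads < maxReads, ]
    pass <- !is.na(res$binomPLong) & !is.na(res$binomPShort) &
        !is.na(res$mwuP) & !is.na(res$fisherP) &
        res$binomPLong < alpha & res$binomPShort < alpha &
        res$mwuP < alpha & res$fisherP < alpha &
        abs(res$diffAse) >= log2(foldMin)
    hits <- res[pass, ]
    hits <- hits[!is.na(hits$gene), ]
    passingSnps <- unique(hits[, c("snp", "gene")])
    if (!nrow(passingSnps))
        return(DataFrame(gene = character(), nSnps = integer(),
                         directionLong = integer(), directionShort = integer(),
                         passes1Snp = logical(), passes2Snp = logical()))
    byGene <- split(hits, hits$gene)
    DataFrame(do.call(rbind, lapply(byGene, function(h) data.frame(
        gene = h$gene[1],
        nSnps = length(unique(h$snp)),
        directionLong = sign(median(h$meanLogRatioLong)),
        directionShort = sign(median(h$meanLogRatioShort)),
        passes1Snp = TRUE,
        passes2Snp = length(unique(h$snp)) >= 2))),
        row.names = NULL)
}

#' Permutation enrichment of called genes near genomic regions
#'
#' Counts how many called genes lie within `windowBp` of any region, and
#' compares against a null distribution from `nPerm` equal-size draws of
#' genes from the universe (without replacement).  The p-value is
#' `(1 + #{null >= observed}) / (nPerm + 1)`.
#'
#' @param calledGenes character vector of called gene ids (must be a
#'   subset of `names(geneRanges)`).
#' @param geneRanges named `GRanges`: the gene universe.
#' @param regions `GRanges` of (triallelic) regions.
#' @param windowBp proximity window (default 50000).
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list with `observed`, `expected` (mean null count) and `p`.
#' @export
proximityEnrichment <- function(calledGenes, geneRanges, regions,
                                windowBp = 50000, nPerm = 10000, seed = 1) {
    if (is.null(names(geneRanges)))
        stop("geneRanges must be named by gene id")
    if (length(calledGenes) > length(geneRanges))
        stop("called set larger than gene universe")
    if (!all(calledGenes %in% names(geneRanges)))
        stop("called genes missing from the universe")
    ## canonical order: results depend only on the seed, not input order
    geneRanges <- geneRanges[order(names(geneRanges))]
    near <- if (length(regions)) {
        d <- distanceToNearest(geneRanges, regions)
        flags <- logical(length(geneRanges))
        flags[queryHits(d)] <- mcols(d)$distance <= windowBp
        flags
    } else logical(length(geneRanges))
    observed <- sum(near[match(sort(calledGenes), names(geneRanges))])
    k <- length(calledGenes)
    set.seed(seed)
    null <- vapply(seq_len(nPerm),
                   function(i) sum(near[sample.int(length(near), k)]), 0L)
    list(observed = observed, expected = mean(null),
         p = (1 + sum(null >= observed)) / (nPerm + 1))
}
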