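## Windowed recombination rates from a genetic map, and contrasts between
## windows that do and do not overlap triallelic regions, within one
## species and between species via a synteny pairing.

#' Windowed recombination rates from a genetic map
#'
#' The genome is tiled with non-overlapping `windowBp` windows; the
#' genetic position (cM) at each window edge is obtained by linear
#' interpolation of the marker map, and the window's rate is
#' `(cM at end - cM at start) / (window length in Mb)`.  Windows not fully
#' inside the map span of their chromosome are dropped; chromosomes with
#' fewer than two markers are skipped.
#'
#' @param map a [GeneticMap-class].
#' @param windowBp tile width in bp (default 1e5).
#' @param regions optional `GRanges`; windows overlapping any region are
#'   flagged `overlapsTriallelic`.
#' @param species optional species label stored on the result.
#' @return A `GRanges` of windows with metadata columns `rate` (cM/Mb),
#'   `overlapsTriallelic` and `species`.
#' @export
windowedRates <- function(map, windowBp = 1e5, regions = NULL,
                          species = NA_character_) {
    stopifnot(is(map, "GeneticMap"))
    out <- lapply(sort(unique(map$chrom)), function(ch) {
        m <- map[map$chrom == ch, ]
        if (nrow(m) < 2) return(NULL)
        lo <- min(m$bp); hi <- max(m$bp)
        starts <- seq(1, hi, by = windowBp)
        starts <- starts[starts >= lo & starts + windowBp - 1 <= hi]
        if (!length(starts)) return(NULL)
        cmAt <- function(x) approx(m$bp, m$cM, xout = x, ties = "ordered")$y
        rate <- (cmAt(starts + windowBp - 1) - cmAt(starts)) /
            ((windowBp - 1) / 1e6)
        data.frame(chrom = ch, start = starts, rate = rate)
    })
    df <- do.call(rbind, out)
    gr <- if (is.null(df)) GRanges() else
        GRanges(df$chrom, IRanges(df$start, width = windowBp),
                rate = df$rate)
    mcols(gr)$overlapsTriallelic <- if (is.null(regions))
        rep(FALSE, length(gr)) else IRanges::overlapsAny(gr, regions)
    mcols(gr)$species <- rep(species, length(gr))
    gr
}

#' Compare recombination rates of triallelic vs. background windows
#'
#' Two-sided Mann-Whitney U test of window rates between windows that
#' overlap triallelic regions and those that do not, with group means and
#' standard errors.
#'
#' @param rates `GRanges` from [windowedRates()] (metadata `rate`,
#'   `overlapsTriallelic`), or any vector/flag pair via `rate` and
#'   `overlap` columns.
#' @return list with `meanOverlap`, `semOverlap`, `meanBackground`,
#'   `semBackground`, `p`, `nOverlap`, `nBackground`.
#' @export
recombGroupCompare <- function(rates) {
    r <- mcols(rates)$rate
    f <- mcols(rates)$overlapsTriallelic
    if (!any(f) || all(f)) stop("both groups must be non-empty")
    a <- r[f]; b <- r[!f]
    p <- if (length(unique(r)) == 1) 1    # all rates tied: no evidence
         else suppressWarnings(wilcox.test(a, b)$p.value)
    list(meanOverlap = mean(a), semOverlap = sd(a) / sqrt(length(a)),
         meanBackground = mean(b), semBackground = sd(b) / sqrt(length(b)),
         p = p, nOverlap = length(a), nBackground = length(b))
}

#' Cross-species recombination-rate ratios over syntenic windows
#'
#' Pairs windows of species A with syntenic windows of species B, forms
#' the per-pair ratio `rateA / rateB` (pairs with zero denominator are
#' dropped, with the count reported), and compares ratios of
#' triallelic-overlap pairs against background pairs as in
#' [recombGroupCompare()].  The triallelic flag of the species-A window
#' classifies the pair.  With a single valid pair the ratio is reported
#' descriptively (no test, `p = NA`).
#'
#' @param ratesA,ratesB `GRanges` from [windowedRates()] for the two
#'   species.
#' @param synteny two-column data.frame of window indices (`idxA`,
#'   `idxB`) pairing `ratesA` rows with `ratesB` rows.
#' @return list with `ratios`, `flags`, `nDroppedZero`, and (when both
#'   groups are populated) `meanOverlap`, `meanBackground`, `p`.
#' @export
crossSpeciesRatio <- function(ratesA, ratesB, synteny) {
    stopifnot(all(c("idxA", "idxB") %in% colnames(synteny)))
    ra <- mcols(ratesA)$rate[synteny$idxA]
    rb <- mcols(ratesB)$rate[synteny$idxB]
    fl <- mcols(ratesA)$overlapsTriallelic[synteny$idxA]
    valid <- rb > 0
    if (!any(valid)) stop("no valid window pairs (all zero denominators)")
    out <- list(ratios = ra[valid] / rb[valid], flags = fl[valid],
                nDroppedZero = sum(!valid))
    if (length(out$ratios) >= 2 && any(out$flags) && !all(out$flags)) {
        a <- out$ratios[out$flags]; b <- out$ratios[!out$flags]
        out$meanOverlap <- mean(a)
        out$meanBackground <- mean(b)
        out$p <- if (length(unique(out$ratios)) == 1) 1
                 else suppressWarnings(wilcox.test(a, b)$p.value)
    } else {
        out$meanOverlap <- if (any(out$flags)) mean(out$ratios[out$flags]) else NA_real_
        out$meanBackground <- if (any(!out$flags)) mean(out$ratios[!out$flags]) else NA_real_
        out$p <- NA_real_
    }
    out
}
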