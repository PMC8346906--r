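## Central S4 containers.  Genomic coordinates follow the Bioconductor
## convention throughout (1-based, closed intervals, as in GRanges); BED
## input/output converts to/from the 0-based half-open convention at the
## file boundary.

ECOTYPES <- c("marine", "freshwater", "unknown")
CROSSES  <- c("MarineXLong", "MarineXShort")
TISSUES  <- c("DS", "PS", "PF", "H")

#' GenotypeTable: population-by-site allele-frequency matrix
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose single assay
#' `"freq"` holds the alternate-allele frequency (in \[0, 1\], `NA` for
#' missing) at each genomic site (rows) in each population or individual
#' (columns).  Row ranges are width-1 [GenomicRanges::GRanges] with metadata
#' columns `ref` and `alt`; column data carry an `ecotype` label
#' (`"marine"`, `"freshwater"` or `"unknown"`).  Sites are kept sorted by
#' (chromosome, position) with chromosomes in alphabetical order, so all
#' window operations are invariant to the order in which data arrived.
#'
#' @export
setClass("GenotypeTable", contains = "RangedSummarizedExperiment")

setValidity("GenotypeTable", function(object) {
    msg <- character()
    if (!"freq" %in% assayNames(object))
        msg <- c(msg, "assay 'freq' is required")
    else {
        f <- assay(object, "freq")
        bad <- f[!is.na(f)]
        if (length(bad) && (min(bad) < 0 || max(bad) > 1))
            msg <- c(msg, "frequencies must lie in [0, 1] or be NA")
    }
    if (!"ecotype" %in% colnames(colData(object)))
        msg <- c(msg, "colData column 'ecotype' is required")
    else if (!all(object$ecotype %in% ECOTYPES))
        msg <- c(msg, sprintf("ecotype labels must be in {%s}",
                              paste(ECOTYPES, collapse = ", ")))
    rr <- rowRanges(object)
    if (length(rr)) {
        if (!all(c("ref", "alt") %in% colnames(mcols(rr))))
            msg <- c(msg, "rowRanges need 'ref' and 'alt' metadata columns")
        o <- order(as.character(seqnames(rr)), start(rr))
        if (!identical(o, seq_along(rr)))
            msg <- c(msg, "sites must be sorted by (chrom, position)")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeTable
#'
#' @param sites width-1 `GRanges` with metadata columns `ref` and `alt`
#'   (single-character alleles), one per genomic site.
#' @param freq numeric matrix, sites x samples, of alternate-allele
#'   frequencies in \[0, 1\] (`NA` = missing).
#' @param ecotype character vector of per-sample labels, one of
#'   `"marine"`, `"freshwater"`, `"unknown"`; recycled if length 1.
#' @param sampleNames sample identifiers; default `colnames(freq)`.
#' @return A [GenotypeTable-class] object, sites sorted by position.
#' @examples
#' sites <- GenomicRanges::GRanges("chrI", IRanges::IRanges(c(100, 200), width = 1),
#'                                 ref = "A", alt = "T")
#' gt <- GenotypeTable(sites, matrix(c(0, 1, 0.5, 0.5), 2, 2),
#'                     ecotype = c("marine", "freshwater"),
#'                     sampleNames = c("pop1", "pop2"))
#' freqMatrix(gt)
#' @export
GenotypeTable <- function(sites, freq, ecotype = "unknown",
                          sampleNames = colnames(freq)) {
    freq <- as.matrix(freq)
    if (length(sites) != nrow(freq))
        stop("nrow(freq) must equal length(sites)")
    if (is.null(sampleNames))
        sampleNames <- paste0("sample", seq_len(ncol(freq)))
    ecotype <- rep_len(as.character(ecotype), ncol(freq))
    o <- order(as.character(seqnames(sites)), start(sites))
    sites <- sites[o]
    freq <- freq[o, , drop = FALSE]
    dimnames(freq) <- list(NULL, sampleNames)
    se <- SummarizedExperiment(
        assays = list(freq = freq), rowRanges = sites,
        colData = DataFrame(ecotype = ecotype, row.names = sampleNames))
    new("GenotypeTable", se)
}

#' @describeIn GenotypeTable the site-by-sample frequency matrix
#' @param x,object a `GenotypeTable`
#' @export
freqMatrix <- function(x) assay(x, "freq")

#' @describeIn GenotypeTable per-sample ecotype labels
#' @export
ecotype <- function(x) x$ecotype

setMethod("show", "GenotypeTable", function(object) {
    cat(sprintf("GenotypeTable: %d sites x %d samples (%s)\n",
                nrow(object), ncol(object),
                paste(sprintf("%d %s", table(object$ecotype)[unique(object$ecotype)],
                              unique(object$ecotype)), collapse = ", ")))
    chr <- table(as.character(seqnames(rowRanges(object))))
    cat("  chromosomes:", paste(sprintf("%s (%d)", names(chr), chr),
                                collapse = ", "), "\n")
    invisible(NULL)
})

#' AseCountTable: per-SNP, per-library allele-specific read counts
#'
#' A [S4Vectors::DataFrame] subclass with one row per (SNP, library) pair
#' and columns `snp`, `chrom`, `pos`, `gene` (`NA` if intergenic), `exonic`
#' (logical), `cross` (`"MarineXLong"` or `"MarineXShort"`), `tissue`
#' (`"DS"` dorsal spine, `"PS"` pelvic spine, `"PF"` pectoral fin, `"H"`
#' heart), `library`, `individual`, `ref`, `alt` (non-negative read
#' counts) and `fwAllele` (`"ref"` or `"alt"`: which physical allele is the
#' freshwater one at this SNP).
#'
#' @export
setClass("AseCountTable", contains = "DFrame")

.ASE_COLS <- c("snp", "chrom", "pos", "gene", "exonic", "cross", "tissue",
               "library", "individual", "ref", "alt", "fwAllele")

setValidity("AseCountTable", function(object) {
    msg <- character()
    miss <- setdiff(.ASE_COLS, colnames(object))
    if (length(miss))
        return(paste("missing columns:", paste(miss, collapse = ", ")))
    if (any(object$ref < 0) || any(object$alt < 0))
        msg <- c(msg, "read counts must be non-negative")
    if (!all(object$cross %in% CROSSES))
        msg <- c(msg, sprintf("cross labels must be in {%s}",
                              paste(CROSSES, collapse = ", ")))
    if (!all(object$tissue %in% TISSUES))
        msg <- c(msg, sprintf("tissue labels must be in {%s}",
                              paste(TISSUES, collapse = ", ")))
    if (!all(object$fwAllele %in% c("ref", "alt")))
        msg <- c(msg, "fwAllele must be 'ref' or 'alt'")
    if (anyDuplicated(paste(object$snp, object$library)))
        msg <- c(msg, "each (snp, library) pair may appear only once")
    if (length(msg)) msg else TRUE
})

#' Construct an AseCountTable from a data.frame
#'
#' @param df data.frame (or DataFrame) with the columns documented in
#'   [AseCountTable-class].
#' @return A validated `AseCountTable`.
#' @export
AseCountTable <- function(df) {
    df <- as(as.data.frame(df), "DataFrame")
    miss <- setdiff(.ASE_COLS, colnames(df))
    if (length(miss))
        stop("missing columns: ", paste(miss, collapse = ", "))
    df$ref <- as.integer(df$ref)
    df$alt <- as.integer(df$alt)
    df$exonic <- as.logical(df$exonic)
    new("AseCountTable", df[, .ASE_COLS])
}

setMethod("show", "AseCountTable", function(object) {
    cat(sprintf(
        "AseCountTable: %d rows | %d SNPs, %d genes, %d libraries, crosses: %s\n",
        nrow(object), length(unique(object$snp)),
        length(unique(object$gene[!is.na(object$gene)])),
        length(unique(object$library)),
        paste(unique(object$cross), collapse = "/")))
    invisible(NULL)
})

#' GeneticMap: physical-to-genetic marker map
#'
#' A [S4Vectors::DataFrame] subclass with columns `chrom`, `bp` (physical
#' position, 1-based) and `cM` (genetic position).  Within each chromosome
#' physical positions must be strictly increasing and genetic positions
#' non-decreasing.
#'
#' @export
setClass("GeneticMap", contains = "DFrame")

setValidity("GeneticMap", function(object) {
    if (!all(c("chrom", "bp", "cM") %in% colnames(object)))
        return("columns 'chrom', 'bp', 'cM' are required")
    for (ch in unique(object$chrom)) {
        i <- object$chrom == ch
        if (is.unsorted(object$bp[i], strictly = TRUE))
            return(sprintf("physical positions not strictly increasing on %s", ch))
        if (is.unsorted(object$cM[i]))
            return(sprintf("genetic positions not non-decreasing on %s", ch))
    }
    TRUE
})

#' Construct a GeneticMap
#' @param chrom,bp,cM marker chromosome, physical position (bp, 1-based)
#'   and genetic position (cM); markers are sorted by (chrom, bp).
#' @return A validated `GeneticMap`.
#' @export
GeneticMap <- function(chrom, bp, cM) {
    o <- order(chrom, bp)
    new("GeneticMap", DataFrame(chrom = as.character(chrom)[o],
                                bp = as.numeric(bp)[o], cM = as.numeric(cM)[o]))
}

setMethod("show", "GeneticMap", function(object) {
    cat(sprintf("GeneticMap: %d markers on %d chromosome(s), %.1f cM total\n",
                nrow(object), length(unique(object$chrom)),
                sum(vapply(split(object$cM, object$chrom),
                           function(z) max(z) - min(z), 0))))
    invisible(NULL)
})

#' DistanceTriple: pairwise substitution rates among the three alleles
#'
#' Substitutions per aligned site between the cloned Long, Short and Marine
#' alleles: `dLS` (Long-Short), `dSM` (Short-Marine), `dLM` (Long-Marine).
#'
#' @slot dLS,dSM,dLM numeric rates in \[0, 1\].
#' @export
setClass("DistanceTriple",
         representation(dLS = "numeric", dSM = "numeric", dLM = "numeric"))

setValidity("DistanceTriple", function(object) {
    d <- c(object@dLS, object@dSM, object@dLM)
    if (any(!is.finite(d)) || any(d < 0) || any(d > 1))
        "distances must be finite and in [0, 1]" else TRUE
})

#' @rdname DistanceTriple-class
#' @param dLS,dSM,dLM pairwise substitution rates (substitutions per
#'   aligned site) for Long-Short, Short-Marine and Long-Marine.
#' @export
DistanceTriple <- function(dLS, dSM, dLM)
    new("DistanceTriple", dLS = dLS, dSM = dSM, dLM = dLM)

setMethod("show", "DistanceTriple", function(object) {
    cat(sprintf("DistanceTriple: Long-Short %.4g, Short-Marine %.4g, Long-Marine %.4g\n",
                object@dLS, object@dSM, object@dLM))
    invisible(NULL)
})

#' ThreeTaxonTree: imputed tree for the three alleles
#'
#' The unrooted three-taxon tree implied by a [DistanceTriple-class] under
#' the three-point formula: terminal branch lengths
#' `b_X = (d_XY + d_XZ - d_YZ)/2`, sister pair = the pair with the smallest
#' pairwise distance.  Reconstructed pairwise distances equal the inputs
#' exactly (additivity).
#'
#' @slot sister character(2): taxon names of the sister pair.
#' @slot branches named numeric(3): terminal branch lengths for Long,
#'   Short, Marine.
#' @slot distances the input [DistanceTriple-class].
#' @export
setClass("ThreeTaxonTree",
         representation(sister = "character", branches = "numeric",
                        distances = "DistanceTriple"))

setMethod("show", "ThreeTaxonTree", function(object) {
    cat(sprintf("ThreeTaxonTree: sister pair (%s); branches %s\n",
                paste(object@sister, collapse = ", "),
                paste(sprintf("%s=%.5g", names(object@branches),
                              object@branches), collapse = ", ")))
    cat(" ", treeNewick(object), "\n")
    invisible(NULL)
})
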