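## File formats.  All on-disk genomic coordinates are 1-based inclusive
## (matching VCF and printed coordinates) except BED, which is 0-based
## half-open; conversion happens inside the readers/writers and nowhere
## else.

#' Read a genotype / allele-frequency table
#'
#' Reads a population-by-site table of alternate-allele frequencies into a
#' [GenotypeTable-class].  Two formats are supported:
#' \describe{
#'   \item{`tsv`}{columns `chrom`, `pos` (1-based), `ref`, `alt`, then one
#'     column per sample.  A sample column may be named `"name:ecotype"`
#'     (e.g. `"BearPaw:freshwater"`) to attach its ecotype label; plain
#'     names get ecotype `"unknown"`.  Missing frequencies are `NA`.}
#'   \item{`vcf`}{a minimal VCF subset: biallelic SNP rows with per-sample
#'     `GT` fields; the frequency is the fraction of alternate alleles
#'     among called alleles (0/0.5/1 for a diploid individual).
#'     Multi-allelic rows are skipped with a warning.}
#' }
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @param ecotypes optional named character vector overriding per-sample
#'   ecotype labels.
#' @return A [GenotypeTable-class].
#' @seealso [writeGenotypeTable()]
#' @export
readGenotypeTable <- function(path, format = c("tsv", "vcf"), ecotypes = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    gt <- if (format == "tsv") .readGenotypeTsv(path) else .readGenotypeVcf(path)
    if (!is.null(ecotypes)) {
        i <- match(colnames(gt), names(ecotypes))
        gt$ecotype[!is.na(i)] <- ecotypes[i[!is.na(i)]]
        validObject(gt)
    }
    gt
}

.readGenotypeTsv <- function(path) {
    df <- read.delim(path, check.names = FALSE, colClasses = "character")
    fixed <- c("chrom", "pos", "ref", "alt")
    if (!all(fixed %in% colnames(df)))
        stop("genotype TSV needs columns: ", paste(fixed, collapse = ", "))
    sampcols <- setdiff(colnames(df), fixed)
    if (!length(sampcols)) stop("genotype TSV has no sample columns")
    pos <- suppressWarnings(as.numeric(df$pos))
    bad <- which(is.na(pos) | pos < 1 | pos != round(pos))
    if (length(bad))
        stop(sprintf("malformed position at line %d of %s", bad[1] + 1L, path))
    freq <- matrix(NA_real_, nrow(df), length(sampcols))
    for (j in seq_along(sampcols)) {
        v <- df[[sampcols[j]]]
        x <- suppressWarnings(as.numeric(v))
        bad <- which(is.na(x) & !(is.na(v) | v %in% c("NA", ".", "")))
        if (length(bad))
            stop(sprintf("malformed frequency at line %d of %s", bad[1] + 1L, path))
        freq[, j] <- x
    }
    out <- which(!is.na(freq) & (freq < 0 | freq > 1), arr.ind = TRUE)
    if (nrow(out))
        stop(sprintf("frequency outside [0, 1] at line %d of %s",
                     out[1, 1] + 1L, path))
    parts <- strsplit(sampcols, ":", fixed = TRUE)
    nm <- vapply(parts, `[`, "", 1L)
    eco <- vapply(parts, function(p) if (length(p) > 1) p[2] else "unknown", "")
    sites <- GRanges(df$chrom, IRanges(pos, width = 1L),
                     ref = df$ref, alt = df$alt)
    GenotypeTable(sites, freq, ecotype = eco, sampleNames = nm)
}

.readGenotypeVcf <- function(path) {
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    alt <- VariantAnnotation::alt(vcf)
    multi <- lengths(alt) != 1L
    if (any(multi)) {
        warning(sprintf("skipping %d multi-allelic row(s) in %s",
                        sum(multi), path))
        vcf <- vcf[!multi]
        alt <- alt[!multi]
    }
    gtm <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gtm)) stop("VCF has no GT field")
    freq <- apply(gtm, 2, function(g) {
        al <- strsplit(g, "[/|]")
        vapply(al, function(a) {
            a <- a[a %in% c("0", "1")]
            if (!length(a)) NA_real_ else mean(a == "1")
        }, 0)
    })
    freq <- matrix(freq, nrow = nrow(gtm), ncol = ncol(gtm),
                   dimnames = dimnames(gtm))
    rr <- SummarizedExperiment::rowRanges(vcf)
    sites <- GRanges(seqnames(rr), IRanges(start(rr), width = 1L),
                     ref = as.character(VariantAnnotation::ref(vcf)),
                     alt = vapply(as.list(alt), function(a) as.character(a[[1]]), ""))
    GenotypeTable(sites, freq, ecotype = "unknown", sampleNames = colnames(gtm))
}

#' Write a GenotypeTable as TSV
#'
#' Inverse of [readGenotypeTable()] (`format = "tsv"`); sample columns are
#' written as `"name:ecotype"` so the label round-trips.
#'
#' @param gt a [GenotypeTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenotypeTable <- function(gt, path) {
    rr <- rowRanges(gt)
    df <- data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
                     ref = mcols(rr)$ref, alt = mcols(rr)$alt,
                     check.names = FALSE)
    f <- freqMatrix(gt)
    colnames(f) <- paste(colnames(gt), gt$ecotype, sep = ":")
    write.table(cbind(df, f), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Write genomic regions as BED
#'
#' Writes a `GRanges` (1-based, closed) as standard BED (0-based,
#' half-open), sorted by (chrom, start).  Metadata columns `name` and
#' `score` are written when present; overlapping intervals are permitted
#' and written as-is.
#'
#' @param regions a `GRanges`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(regions, path) {
    o <- order(as.character(seqnames(regions)), start(regions))
    regions <- regions[o]
    df <- data.frame(chrom = as.character(seqnames(regions)),
                     start = start(regions) - 1L, end = end(regions))
    if (!is.null(mcols(regions)$name)) {
        df$name <- mcols(regions)$name
        if (!is.null(mcols(regions)$score)) df$score <- mcols(regions)$score
    }
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a BED file into GRanges
#'
#' 0-based half-open BED intervals become 1-based closed `GRanges`.
#' Columns 4 and 5, when present, become metadata columns `name` and
#' `score`.
#'
#' @param path BED file path.
#' @return A `GRanges` (empty for an empty file).
#' @export
readBed <- function(path) {
    if (file.size(path) == 0) return(GRanges())
    gr <- rtracklayer::import.bed(path)
    strand(gr) <- "*"
    gr
}

#' Read / write allele-specific read-count tables
#'
#' TSV with the columns of [AseCountTable-class]; validation (negative
#' counts, unknown cross/tissue labels, duplicated (snp, library) pairs)
#' happens on read.
#'
#' @param path file path.
#' @return `readAseCounts`: an [AseCountTable-class].
#' @export
readAseCounts <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, check.names = FALSE)
    AseCountTable(df)
}

#' @rdname readAseCounts
#' @param counts an [AseCountTable-class].
#' @export
writeAseCounts <- function(counts, path) {
    write.table(as.data.frame(counts), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read a genetic map
#'
#' TSV with columns `chrom`, `bp` (physical position), `cM` (genetic
#' position).  Non-monotone genetic positions within a chromosome are a
#' validation error.
#'
#' @param path file path.
#' @return A [GeneticMap-class].
#' @export
readGeneticMap <- function(path) {
    df <- read.delim(path)
    if (!all(c("chrom", "bp", "cM") %in% colnames(df)))
        stop("genetic map needs columns chrom, bp, cM")
    GeneticMap(df$chrom, df$bp, df$cM)
}

#' Read a gene annotation BED
#'
#' BED file whose name column holds the gene identifier; returns a named
#' `GRanges` usable as the gene universe for [proximityEnrichment()].
#'
#' @param path BED file path.
#' @return A named `GRanges`.
#' @export
readGeneAnnotation <- function(path) {
    gr <- readBed(path)
    if (is.null(mcols(gr)$name))
        stop("gene annotation BED needs a name column (gene id)")
    names(gr) <- mcols(gr)$name
    gr
}
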