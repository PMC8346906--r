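## Three-taxon distance phylogeny of the cloned Long, Short and Marine
## alleles, and molecular-clock dating under a user-supplied calibration
## rate.

#' Pairwise substitution rate between two allele sequences
#'
#' Globally aligns the two sequences (affine gaps: match 1, mismatch -1,
#' gap open 5, gap extend 1) and returns the raw p-distance: mismatched
#' aligned base pairs divided by aligned base pairs, excluding gap columns
#' and positions where either sequence has an ambiguous base.  Symmetric
#' in its arguments; no multiple-hit correction is applied (distances of a
#' few percent make the correction negligible).
#'
#' @param seqA,seqB `DNAString`/character sequences.
#' @return substitutions per aligned site.
#' @examples
#' substitutionRate("ACGTACGT", "ACGTACCT")  # 1/8
#' @export
substitutionRate <- function(seqA, seqB) {
    a <- DNAString(as.character(seqA))
    b <- DNAString(as.character(seqB))
    mat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                        baseOnly = FALSE)
    aln <- pairwiseAlignment(a, b, type = "global", substitutionMatrix = mat,
                             gapOpening = 5, gapExtension = 1)
    p <- strsplit(as.character(alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(alignedSubject(aln)), "")[[1]]
    ok <- p %in% c("A", "C", "G", "T") & s %in% c("A", "C", "G", "T")
    if (!any(ok)) stop("no aligned unambiguous bases between the sequences")
    sum(p[ok] != s[ok]) / sum(ok)
}

#' Distance triple from a three-allele FASTA
#'
#' Computes all three pairwise substitution rates among records named
#' `Long`, `Short` and `Marine` (matching is by name prefix,
#' case-insensitive).
#'
#' @param alleles a named `DNAStringSet` or path to a three-record FASTA.
#' @return A [DistanceTriple-class].
#' @export
alleleDistances <- function(alleles) {
    if (is.character(alleles)) alleles <- readDNAStringSet(alleles)
    nm <- names(alleles)
    pick <- function(lbl) {
        i <- grep(paste0("^", lbl), nm, ignore.case = TRUE)
        if (length(i) != 1)
            stop("need exactly one record named '", lbl, "'")
        alleles[[i]]
    }
    L <- pick("Long"); S <- pick("Short"); M <- pick("Marine")
    DistanceTriple(dLS = substitutionRate(L, S),
                   dSM = substitutionRate(S, M),
                   dLM = substitutionRate(L, M))
}

#' Impute the three-taxon tree from a distance triple
#'
#' The sister pair is the pair with the smallest pairwise distance (ties
#' broken lexicographically by pair name); terminal branch lengths follow
#' the three-point formula `b_X = (d_XY + d_XZ - d_YZ)/2`, under which the
#' reconstructed pairwise distances equal the inputs exactly.  A negative
#' implied branch (triple violating the three-point condition) is clamped
#' to zero with a warning.
#'
#' @param d a [DistanceTriple-class].
#' @return A [ThreeTaxonTree-class].
#' @examples
#' tr <- threeTaxonTree(DistanceTriple(0.0148, 0.0211, 0.0171))
#' tr@sister            # Long, Short
#' tr@branches          # 0.0054, 0.0094, 0.0117
#' @export
threeTaxonTree <- function(d) {
    validObject(d)
    dd <- c("Long-Short" = d@dLS, "Long-Marine" = d@dLM,
            "Short-Marine" = d@dSM)
    sisterName <- names(dd)[order(dd, names(dd))][1]
    b <- c(Long   = (d@dLS + d@dLM - d@dSM) / 2,
           Short  = (d@dLS + d@dSM - d@dLM) / 2,
           Marine = (d@dSM + d@dLM - d@dLS) / 2)
    if (any(b < 0)) {
        warning("three-point condition violated; clamping negative branch(es) to 0")
        b <- pmax(b, 0)
    }
    new("ThreeTaxonTree", sister = strsplit(sisterName, "-")[[1]],
        branches = b, distances = d)
}

#' Newick string / ape phylo for a ThreeTaxonTree
#'
#' The three terminal branches radiate from the single internal node of
#' the unrooted three-taxon tree.
#'
#' @param tree a [ThreeTaxonTree-class].
#' @return `treeNewick`: a Newick string; `treePhylo`: an [ape] `phylo`.
#' @export
treeNewick <- function(tree) {
    b <- tree@branches
    sprintf("(Long:%g,Short:%g,Marine:%g);", b["Long"], b["Short"],
            b["Marine"])
}

#' @rdname treeNewick
#' @export
treePhylo <- function(tree) read.tree(text = treeNewick(tree))

#' Molecular-clock divergence times
#'
#' Converts pairwise distances to divergence times under a constant
#' per-lineage substitution rate: `t(X, Y) = d_XY / (2 * rate)`.  The
#' sister-split time uses the sister pair's distance; the deeper-split
#' time is the mean of the two distances crossing the deeper node.  The
#' calibration rate is a required user input (e.g. derived from the
#' Japanese marine / Japan Sea stickleback divergence).
#'
#' @param tree a [ThreeTaxonTree-class].
#' @param ratePerLineage substitutions per site per My, per lineage
#'   (> 0).
#' @return list with `sisterSplitMya`, `deeperSplitMya`, and `pairwiseMya`
#'   (named vector of per-pair times).
#' @export
clockDates <- function(tree, ratePerLineage) {
    if (!is.numeric(ratePerLineage) || ratePerLineage <= 0)
        stop("ratePerLineage must be > 0")
    d <- tree@distances
    dd <- c("Long-Short" = d@dLS, "Long-Marine" = d@dLM,
            "Short-Marine" = d@dSM)
    times <- dd / (2 * ratePerLineage)
    sisterName <- paste(sort(tree@sister), collapse = "-")
    sisterName <- names(dd)[match(sisterName, vapply(
        strsplit(names(dd), "-"), function(p) paste(sort(p), collapse = "-"),
        ""))]
    list(sisterSplitMya = unname(times[sisterName]),
         deeperSplitMya = mean(times[setdiff(names(dd), sisterName)]),
         pairwiseMya = times)
}
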