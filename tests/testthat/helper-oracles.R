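## Independent brute-force oracles used to validate the package's
## statistics.  These deliberately avoid the code paths they check.

## Two-sided Fisher exact p for a 2x2 table by direct hypergeometric
## enumeration: sum the probabilities of all tables with the observed
## margins whose probability does not exceed the observed table's.
oracleFisher2x2 <- function(m) {
    a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
    r1 <- a + b; c1 <- a + cc; n <- a + b + cc + d
    support <- max(0, r1 + c1 - n):min(r1, c1)
    probs <- stats::dhyper(support, c1, n - c1, r1)
    pObs <- stats::dhyper(a, c1, n - c1, r1)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

## Two-sided exact Mann-Whitney p by exhaustive enumeration of all
## assignments of the pooled values to the two groups (no ties assumed).
## The U distribution is symmetric, so the doubling definition equals the
## symmetric-tail count.
oracleMwuExact <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    pool <- c(x, y)
    r <- rank(pool)
    uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mid <- n1 * n2 / 2
    sets <- utils::combn(n1 + n2, n1)
    us <- apply(sets, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
    mean(abs(us - mid) >= abs(uObs - mid) - 1e-9)
}

## Exact two-sided binomial p against 0.5 by enumeration of tail masses.
oracleBinomTwoSided <- function(k, n) {
    probs <- stats::dbinom(0:n, n, 0.5)
    sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

## All partitions of n items into exactly k non-empty blocks (restricted
## growth strings); returns a list of integer label vectors.
allPartitions <- function(n, k) {
    out <- list()
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

## Intracluster-distance sum s for a labelled partition (mean pairwise
## distance within each cluster; singletons contribute 0).
oracleS <- function(dmat, cl) {
    s <- 0
    for (k in unique(cl)) {
        i <- which(cl == k)
        if (length(i) > 1) {
            sub <- dmat[i, i]
            s <- s + mean(sub[lower.tri(sub)])
        }
    }
    s
}

## Minimum s over all exact-k partitions (exhaustive; n <= 8).
oracleBestS <- function(dmat, k) {
    min(vapply(allPartitions(nrow(dmat), k), function(cl) oracleS(dmat, cl), 0))
}

## Squared-distance matrix matching the scan's default genetic metric.
squaredDistMatrix <- function(x) as.matrix(stats::dist(x))^2 / ncol(x)

## One-sided Kolmogorov-Smirnov check that p-values are uniform or
## super-uniform (i.e. not enriched for small values).
ksUniformOk <- function(p, alpha = 0.01) {
    suppressWarnings(stats::ks.test(p, "punif",
                                    alternative = "greater")$p.value) > alpha
}
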