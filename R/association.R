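## Spine-length association statistics.  Spine lengths scale with body
## size and differ between sexes, so every test operates on residuals of
## an ordinary least-squares regression of the trait on standard length
## and sex.

#' Residualize a spine trait on body-size covariates
#'
#' OLS residuals of `trait ~ intercept + standardLength + sex` (or any
#' subset of those covariates).  Residuals sum to zero and are orthogonal
#' to each covariate.  Fish with a missing trait or covariate get `NA`.
#' If a covariate is collinear (e.g. a single-sex sample) it is dropped
#' with a warning.
#'
#' @param phenos data.frame with columns `fish`, the trait, and the
#'   covariates (`standardLength`, `sex`).
#' @param trait trait column name (e.g. `"DS1"`).
#' @param covariates subset of `c("standardLength", "sex")`.
#' @return named numeric vector of residuals (names = fish ids), `NA`
#'   where incomplete.
#' @export
residualizeTrait <- function(phenos, trait,
                             covariates = c("standardLength", "sex")) {
    stopifnot(trait %in% colnames(phenos),
              all(covariates %in% colnames(phenos)))
    keep <- covariates
    if ("sex" %in% keep && length(unique(stats::na.omit(phenos$sex))) < 2) {
        warning("covariate 'sex' is constant; dropping it")
        keep <- setdiff(keep, "sex")
    }
    dat <- phenos[, c(trait, keep), drop = FALSE]
    cc <- complete.cases(dat)
    if (sum(cc) < length(keep) + 2)
        stop("too few complete records to residualize")
    fml <- stats::reformulate(if (length(keep)) keep else "1",
                              response = trait)
    fit <- lm(fml, data = phenos[cc, , drop = FALSE])
    out <- rep(NA_real_, nrow(phenos))
    out[cc] <- residuals(fit)
    setNames(out, phenos$fish)
}

#' Combined major-spine residuals
#'
#' Each major-spine trait (DS1, DS2, PS by default) is residualized
#' separately on the covariates, and the per-fish residuals are summed;
#' fish missing any trait get `NA`.
#'
#' @inheritParams residualizeTrait
#' @param traits trait columns to combine.
#' @return named numeric vector of summed residuals.
#' @export
combinedSpineResiduals <- function(phenos, traits = c("DS1", "DS2", "PS"),
                                   covariates = c("standardLength", "sex")) {
    mats <- vapply(traits, function(tr)
        residualizeTrait(phenos, tr, covariates), numeric(nrow(phenos)))
    setNames(rowSums(mats), phenos$fish)
}

#' Quintile genome scan
#'
#' Fish are ranked by residual spine length and the first and last
#' quintiles (`floor(n/5)` fish each) are compared at every site by a
#' Fisher exact test on the 2 x 2 allele-count table (allele count =
#' 2 x homozygotes + heterozygotes per quintile).  Monomorphic sites get
#' p = 1.
#'
#' @param residuals named numeric vector (fish ids) of trait residuals.
#' @param siteGenotypes matrix or data.frame, sites x fish, of genotype
#'   strings `"AA"`, `"AB"`, `"BB"` (NA = missing); columns named by fish.
#' @return named numeric vector of per-site p-values.
#' @export
quintileScan <- function(residuals, siteGenotypes) {
    residuals <- residuals[!is.na(residuals)]
    if (length(residuals) < 10) stop("need >= 10 fish with residuals")
    siteGenotypes <- as.matrix(siteGenotypes)
    fish <- intersect(names(residuals), colnames(siteGenotypes))
    residuals <- sort(residuals[fish])
    q <- floor(length(residuals) / 5)
    lowFish <- names(residuals)[seq_len(q)]
    highFish <- names(residuals)[seq(length(residuals) - q + 1,
                                     length(residuals))]
    alleleCounts <- function(g) {
        g <- g[!is.na(g)]
        c(A = 2 * sum(g == "AA") + sum(g == "AB"),
          B = 2 * sum(g == "BB") + sum(g == "AB"))
    }
    apply(siteGenotypes, 1, function(g) {
        m <- rbind(low = alleleCounts(g[lowFish]),
                   high = alleleCounts(g[highFish]))
        if (any(colSums(m) == 0)) return(1)
        fisher.test(m)$p.value
    })
}

#' One-way ANOVA F-test of marker genotype on residuals
#'
#' Residual spine lengths are compared across genotype classes (unordered
#' factor) by a one-way ANOVA F-test with (g - 1, n - g) degrees of
#' freedom.  Fish with missing residual or genotype are dropped pairwise.
#'
#' @param residuals named numeric vector of residuals.
#' @param genotypes named character vector of genotype classes (same fish
#'   ids).
#' @return list with `F`, `p`, `df1`, `df2`, `n`; `F`/`p` are `NA` when
#'   fewer than two classes remain.
#' @export
markerFtest <- function(residuals, genotypes) {
    fish <- intersect(names(residuals)[!is.na(residuals)],
                      names(genotypes)[!is.na(genotypes)])
    y <- residuals[fish]
    g <- factor(genotypes[fish])
    if (nlevels(g) < 2 || length(y) - nlevels(g) < 1)
        return(list(F = NA_real_, p = NA_real_, df1 = NA_integer_,
                    df2 = NA_integer_, n = length(y)))
    a <- anova(lm(y ~ g))
    list(F = a$`F value`[1], p = a$`Pr(>F)`[1],
         df1 = a$Df[1], df2 = a$Df[2], n = length(y))
}

#' Conditional marker association
#'
#' Residuals are first regressed on the genotype classes of a control
#' marker (typically the most significant one); the one-way F-test is then
#' applied to those second-stage residuals at every other marker.  The
#' control marker itself is skipped (`NA`).
#'
#' @param residuals named numeric vector of residuals.
#' @param markerGenotypes matrix or data.frame, markers x fish, of
#'   genotype class strings (rownames = marker ids, colnames = fish ids).
#' @param controlMarker row name of the control marker.
#' @return named numeric vector of conditional p-values per marker.
#' @export
conditionalFtest <- function(residuals, markerGenotypes, controlMarker) {
    markerGenotypes <- as.matrix(markerGenotypes)
    stopifnot(controlMarker %in% rownames(markerGenotypes))
    ctrl <- markerGenotypes[controlMarker, ]
    fish <- intersect(names(residuals)[!is.na(residuals)],
                      names(ctrl)[!is.na(ctrl)])
    y <- residuals[fish]
    g <- factor(ctrl[fish])
    stage2 <- if (nlevels(g) < 2) y else residuals(lm(y ~ g))
    names(stage2) <- fish
    vapply(rownames(markerGenotypes), function(mk) {
        if (mk == controlMarker) return(NA_real_)
        markerFtest(stage2, markerGenotypes[mk, ])$p
    }, 0)
}

#' Percent variance explained by genotype class
#'
#' `100 * SS_between / SS_total` of the residuals grouped by genotype
#' class -- the one-way ANOVA R-squared, in \[0, 100\].
#'
#' @inheritParams markerFtest
#' @return percent variance explained (`NA` if total variance is zero or
#'   fewer than two classes).
#' @export
pveGenotype <- function(residuals, genotypes) {
    fish <- intersect(names(residuals)[!is.na(residuals)],
                      names(genotypes)[!is.na(genotypes)])
    y <- residuals[fish]
    g <- factor(genotypes[fish])
    sst <- sum((y - mean(y))^2)
    if (sst == 0 || nlevels(g) < 2) return(NA_real_)
    fit <- lm(y ~ g)
    100 * (1 - sum(residuals(fit)^2) / sst)
}

#' Select fish with extreme residual spine lengths
#'
#' The `nLow` lowest-residual and `nHigh` highest-residual fish, ties
#' broken deterministically by fish id.
#'
#' @param residuals named numeric vector of residuals.
#' @param nLow,nHigh set sizes.
#' @return list with character vectors `low` and `high`.
#' @export
selectExtremes <- function(residuals, nLow, nHigh) {
    residuals <- residuals[!is.na(residuals)]
    stopifnot(nLow + nHigh <= length(residuals))
    ## one shared ordering so that low and high never overlap even when a
    ## tie spans the selection boundary
    o <- order(residuals, names(residuals))
    list(low = names(residuals)[o][seq_len(nLow)],
         high = rev(names(residuals)[o])[seq_len(nHigh)])
}
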