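#' Group-mean imputation of missing genotypes
#'
#' Each missing cell is replaced by the mean genotype value at that locus
#' over the non-missing individuals of the same group. When a locus is
#' entirely missing within a group, the global (all-individual) locus mean
#' is used instead, with a warning. Non-missing cells are never altered.
#'
#' @param x a [HybridGenotypes-class] object with group assignments.
#' @return numeric matrix (loci x individuals) with no missing values.
#' @export
imputeGroupMean <- function(x) {
    gt <- genotypes(x)
    grp <- colData(x)$group
    if (any(is.na(grp)))
        stop("every individual needs a group assignment")
    out <- matrix(as.numeric(gt), nrow(gt), ncol(gt), dimnames = dimnames(gt))
    globalMean <- rowMeans(out, na.rm = TRUE)
    nFallback <- 0L
    for (g in unique(grp)) {
        cols <- which(grp == g)
        sub <- out[, cols, drop = FALSE]
        gm <- rowMeans(sub, na.rm = TRUE)
        fallback <- is.nan(gm)
        nFallback <- nFallback + sum(fallback & rowSums(is.na(sub)) > 0)
        gm[fallback] <- globalMean[fallback]
        miss <- is.na(sub)
        sub[miss] <- gm[row(sub)[miss]]
        out[, cols] <- sub
    }
    if (nFallback > 0L)
        warning(nFallback, " locus-group combination(s) entirely missing; ",
                "global locus mean used")
    out
}

#' Patterson normalization of an imputed genotype matrix
#'
#' Scales each locus by its estimated binomial standard deviation: with
#' locus mean \eqn{\mu_j} and allele-frequency estimate
#' \eqn{p_j = \mu_j / 2}, each cell becomes
#' \eqn{(g - \mu_j) / \sqrt{p_j (1 - p_j)}}. Loci monomorphic after
#' imputation (\eqn{p_j \in \{0, 1\}}) carry no information and are dropped;
#' the count is stored in `attr(,"droppedMonomorphic")`.
#'
#' @param m complete numeric matrix (loci x individuals) with values in
#'   \[0, 2\], e.g. from [imputeGroupMean()].
#' @return normalized matrix with monomorphic loci removed.
#' @export
pattersonNormalize <- function(m) {
    stopifnot(!anyNA(m), all(m >= 0), all(m <= 2))
    mu <- rowMeans(m)
    p <- mu / 2
    keep <- p > 0 & p < 1
    out <- (m[keep, , drop = FALSE] - mu[keep]) / sqrt(p[keep] * (1 - p[keep]))
    attr(out, "droppedMonomorphic") <- sum(!keep)
    out
}

## Tracy-Widom (beta = 1) upper-tail probability, via the shifted-gamma
## closed-form approximation (accurate to ~1e-4; the 5% point is 0.9793).
.twShape <- 46.44604884387132
.twScale <- 0.18605402228279955
.twShift <- 9.848007781128567

#' @rdname runAdmixturePCA
#' @param q quantile / statistic value.
#' @return `ptw()`: upper-tail probability of the Tracy-Widom (beta = 1)
#'   distribution; `qtw()`: the statistic value with upper-tail
#'   probability `p`.
#' @export
ptw <- function(q) pgamma(q + .twShift, shape = .twShape, scale = .twScale,
                          lower.tail = FALSE)

#' @rdname runAdmixturePCA
#' @param p upper-tail probability.
#' @export
qtw <- function(p) qgamma(p, shape = .twShape, scale = .twScale,
                          lower.tail = FALSE) - .twShift

## Sequential Tracy-Widom axis test on the eigenvalues of the sample
## covariance: for each leading axis, estimate the effective marker count
## by the moment estimator, centre/scale the largest remaining eigenvalue
## and refer it to TW1; then drop it and repeat with m - 1 samples.
## The effective marker count is estimated from the null spectrum -- the
## eigenvalues EXCLUDING the one under test -- because an outlying
## structured eigenvalue dominates the moment sums and collapses the
## estimate (destroying power). The moment estimator also needs more
## eigenvalue dispersion than independent markers produce (its
## denominator is negative in expectation when markers outnumber
## samples^2); when invalid or larger than the actual marker count, the
## actual count is used (the trace normalization of the statistic makes
## that scale-consistent).
.twAxisTest <- function(eigenvalues, nAxes, nMarkers = Inf) {
    twStat <- twP <- rep(NA_real_, nAxes)
    lambda <- eigenvalues
    m <- length(lambda)
    for (k in seq_len(nAxes)) {
        if (m < 3L || sum(lambda) <= 0) break
        S1 <- sum(lambda[-1L]); S2 <- sum(lambda[-1L]^2)
        mm <- m - 1L
        nEff <- ((mm + 1) * S1^2) / ((mm - 1) * S2 - S1^2)
        if (!is.finite(nEff) || nEff <= 1 || nEff > nMarkers)
            nEff <- nMarkers
        if (!is.finite(nEff) || nEff <= 1) break
        mu <- (sqrt(nEff - 1) + sqrt(m))^2 / nEff
        sig <- ((sqrt(nEff - 1) + sqrt(m)) / nEff) *
            (1 / sqrt(nEff - 1) + 1 / sqrt(m))^(1 / 3)
        l1 <- m * lambda[1L] / sum(lambda)
        twStat[k] <- (l1 - mu) / sig
        twP[k] <- ptw(twStat[k])
        lambda <- lambda[-1L]
        m <- m - 1L
    }
    list(stat = twStat, p = twP)
}

#' PCA of genomic composition with Tracy-Widom axis significance
#'
#' Imputes missing genotypes by group means, applies Patterson
#' normalization, and eigendecomposes the individual x individual
#' covariance of the normalized matrix. Axis significance follows the
#' Patterson procedure: the effective marker count is estimated from the
#' eigenvalue moments, the scaled largest eigenvalue is referred to the
#' Tracy-Widom (beta = 1) distribution, and the test is applied
#' sequentially to successive axes.
#'
#' On a two-species cross the first axis captures the interspecific split:
#' parental groups sit at the extremes, F1 hybrids near the midpoint,
#' backcrosses between F1 and the recurrent parent.
#'
#' @param x a [HybridGenotypes-class] object.
#' @param panelOnly use only panel loci when `rowData(x)$inPanel` exists
#'   (default TRUE).
#' @param nAxes number of axes to test (default 10, capped by rank).
#' @return An [AdmixtureSummary-class] object.
#' @export
runAdmixturePCA <- function(x, panelOnly = TRUE, nAxes = 10L) {
    rd <- rowData(x)
    if (panelOnly && !is.null(rd$inPanel))
        x <- x[rd$inPanel, ]
    if (nrow(x) < 2L || ncol(x) < 3L)
        stop("need at least 2 loci and 3 individuals")
    imp <- imputeGroupMean(x)
    norm <- pattersonNormalize(imp)
    nLoci <- nrow(norm)
    C <- crossprod(norm) / nLoci          # individuals x individuals
    eig <- eigen(C, symmetric = TRUE)
    ev <- pmax(eig$values, 0)
    nPos <- sum(ev > max(ev) * 1e-12)
    axisVariance <- ev / sum(ev)
    scores <- eig$vectors * rep(sqrt(ev), each = nrow(C))
    rownames(scores) <- colnames(x)
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
    nAxes <- min(as.integer(nAxes), max(nPos - 1L, 1L))
    tw <- .twAxisTest(ev[seq_len(nPos)], nAxes, nMarkers = nLoci)
    hi <- hybridIndex(x, panelOnly = FALSE)
    new("AdmixtureSummary", pcScores = scores,
        axisVariance = axisVariance, twStats = tw$stat, axisP = tw$p,
        hybridIndex = hi, nLoci = as.integer(nLoci))
}

#' Per-individual hybrid index
#'
#' Fraction of an individual's panel alleles derived from the parental_B
#' species: the sum of its non-missing (polarized) genotype values divided
#' by twice their count. 0 means fully parental_A-like, 1 fully
#' parental_B-like; obligate F1 heterozygotes score 0.5 and first-generation
#' backcrosses to parental_A score 0.25 in expectation. An in-package
#' surrogate for model-based admixture proportions.
#'
#' @param x a polarized [HybridGenotypes-class] object.
#' @param panelOnly restrict to panel loci when available (default TRUE).
#' @return data.frame with `individual`, `group`, `role`, `index`
#'   (NA when every panel genotype is missing) and `n` (loci used).
#' @export
hybridIndex <- function(x, panelOnly = TRUE) {
    rd <- rowData(x)
    if (panelOnly && !is.null(rd$inPanel))
        x <- x[rd$inPanel, ]
    gt <- genotypes(x)
    n <- colSums(!is.na(gt))
    idx <- ifelse(n > 0, colSums(gt, na.rm = TRUE) / (2 * n), NA_real_)
    if (any(n == 0))
        warning(sum(n == 0), " individual(s) with no non-missing panel ",
                "genotype; hybrid index undefined")
    data.frame(individual = colnames(gt), group = colData(x)$group,
               role = colData(x)$role, index = unname(idx), n = unname(n),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Export genotypes in STRUCTURE format
#'
#' Writes the two-row-per-individual STRUCTURE input (alleles 0/1 per
#' locus, -9 for missing), with individual id and numeric group code as
#' leading columns, for external model-based clustering runs.
#'
#' @param x a [HybridGenotypes-class] object.
#' @param file output path.
#' @return The file path, invisibly.
#' @export
exportStructure <- function(x, file) {
    gt <- genotypes(x)
    grp <- as.integer(factor(colData(x)$group))
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(paste(rownames(gt), collapse = "\t"), con)
    for (j in seq_len(ncol(gt))) {
        g <- gt[, j]
        a1 <- ifelse(is.na(g), -9L, ifelse(g >= 1L, 1L, 0L))
        a2 <- ifelse(is.na(g), -9L, ifelse(g == 2L, 1L, 0L))
        writeLines(paste(c(colnames(gt)[j], grp[j], a1), collapse = "\t"), con)
        writeLines(paste(c(colnames(gt)[j], grp[j], a2), collapse = "\t"), con)
    }
    invisible(file)
}
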