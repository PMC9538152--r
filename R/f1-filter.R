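## Per-locus one-sample statistics of genotype values against mu = 1
## (the obligate-heterozygote / Mendelian-F2 expectation).
## sd = 0 rules: mean == 1 -> p = 1 (null holds exactly);
##               mean != 1 -> p = 0 (deterministic deviation);
## n == 1 -> t and p undefined (NA).
.rowGenotypeTest <- function(gt) {
    n <- rowSums(!is.na(gt))
    s <- rowSums(gt, na.rm = TRUE)
    s2 <- rowSums(gt * gt, na.rm = TRUE)
    m <- ifelse(n > 0, s / n, NA_real_)
    v <- ifelse(n > 1, pmax(s2 - n * m^2, 0) / (n - 1), NA_real_)
    sdv <- sqrt(v)
    t <- ifelse(n > 1 & sdv > 0, (m - 1) / (sdv / sqrt(n)), NA_real_)
    p <- ifelse(n > 1 & sdv > 0, 2 * pt(-abs(t), df = n - 1), NA_real_)
    zeroSd <- !is.na(sdv) & sdv == 0 & n > 1
    p[zeroSd & m == 1] <- 1
    t[zeroSd & m == 1] <- 0
    p[zeroSd & m != 1] <- 0
    t[zeroSd & m != 1] <- sign(m[zeroSd & m != 1] - 1) * Inf
    data.frame(n = unname(n), mean = unname(m), sd = unname(sdv),
               t = unname(t), p = unname(p))
}

#' Mendelian validation of panel SNPs in F1 hybrids (volcano statistics)
#'
#' At a truly species-discriminant locus every F1 hybrid is an obligate
#' heterozygote, so the mean F1 genotype value is 1 with standard deviation
#' 0. `f1Volcano()` computes, for every panel locus, the mean and standard
#' deviation of the non-missing F1 genotypes together with a one-sample
#' two-sided t-test of H0: mean = 1, and a decision:
#' \describe{
#'   \item{`drop-missing`}{no F1 genotyped at the locus;}
#'   \item{`drop-deviant`}{mean deviates significantly from 1
#'     (p < `alpha`), or deterministically (sd = 0, mean != 1);}
#'   \item{`keep`}{otherwise. Loci with a single genotyped F1 are kept
#'     with a warning (test undefined).}
#' }
#' The missing-loci drop is applied before testing, so the reported
#' denominators chain (panel -> non-missing -> t-pass).
#'
#' @param x a [HybridGenotypes-class] object with `inPanel` in `rowData`
#'   (see [classifyPanel()]) and F1 individuals.
#' @param alpha type-I error for the t-test (default 0.05, uncorrected).
#' @param fdr if TRUE, apply Benjamini-Hochberg correction to the t-test
#'   p-values before thresholding (off by default).
#' @param panelOnly restrict to panel loci (default TRUE).
#' @return data.frame with one row per tested locus: `locus`, `n`, `mean`,
#'   `sd`, `t`, `p`, `decision`. Suitable for a volcano (mean vs sd) plot.
#' @export
f1Volcano <- function(x, alpha = 0.05, fdr = FALSE, panelOnly = TRUE) {
    idsF1 <- .assertRolePresent(x, "F1")
    rd <- rowData(x)
    loci <- if (panelOnly) {
        if (is.null(rd$inPanel)) stop("run classifyPanel() first")
        rownames(x)[rd$inPanel]
    } else rownames(x)
    gt <- genotypes(x)[loci, idsF1, drop = FALSE]
    st <- .rowGenotypeTest(gt)
    decision <- rep("keep", nrow(st))
    decision[st$n == 0L] <- "drop-missing"
    pAdj <- st$p
    if (fdr) pAdj <- p.adjust(st$p, method = "BH")
    deviant <- st$n > 1L & !is.na(pAdj) & pAdj < alpha
    decision[deviant & decision == "keep"] <- "drop-deviant"
    if (any(st$n == 1L))
        warning(sum(st$n == 1L), " locus/loci with a single genotyped F1; ",
                "kept (t-test undefined)")
    data.frame(locus = loci, st, decision = decision,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname f1Volcano
#' @param stats the data.frame returned by `f1Volcano()`.
#' @return `applyF1Filter()`: `x` restricted to loci that pass, with
#'   `dropReason` updated (`"f1-missing"`, `"f1-deviant"`) and the dropped
#'   loci recorded in `metadata(x)$f1Dropped`.
#' @export
applyF1Filter <- function(x, stats) {
    dropMissing <- stats$locus[stats$decision == "drop-missing"]
    dropDeviant <- stats$locus[stats$decision == "drop-deviant"]
    rd <- rowData(x)
    if (!is.null(rd$dropReason)) {
        rd$dropReason[rownames(x) %in% dropMissing] <- "f1-missing"
        rd$dropReason[rownames(x) %in% dropDeviant] <- "f1-deviant"
        rd$inPanel <- rd$inPanel & !rownames(x) %in% c(dropMissing, dropDeviant)
        rowData(x) <- rd
    }
    keep <- !rownames(x) %in% c(dropMissing, dropDeviant)
    out <- x[keep, ]
    metadata(out)$f1Dropped <- list(missing = dropMissing,
                                    deviant = dropDeviant)
    out
}
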