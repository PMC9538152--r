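#' Polarize alleles to the parental_A reference
#'
#' Orients every locus so that genotype code 0 is homozygous for the allele
#' with the highest frequency among `parental_A` individuals. When the
#' current orientation has that allele on the alternate side, all genotypes
#' at the locus are recoded `g -> 2 - g` (for every individual). Loci where
#' the two alleles are equally frequent in `parental_A`, or where all
#' `parental_A` genotypes are missing, are flagged `"ambiguous"` and left
#' as-is. Polarizing an already-polarized matrix changes nothing.
#'
#' @param x a [HybridGenotypes-class] object with `parental_A` individuals.
#' @return `x` with recoded genotypes and a `polarity` column
#'   (`"as-is"`, `"flipped"`, `"ambiguous"`) in `rowData`.
#' @export
polarizeGenotypes <- function(x) {
    idsA <- .assertRolePresent(x, "parental_A")
    gt <- genotypes(x)
    ga <- gt[, idsA, drop = FALSE]
    nCalled <- rowSums(!is.na(ga))
    ## frequency of the current reference allele in parental_A
    refFreq <- rowSums(2L - ga, na.rm = TRUE) / (2 * nCalled)
    polarity <- rep("as-is", nrow(gt))
    polarity[nCalled > 0 & refFreq < 0.5] <- "flipped"
    ambiguous <- nCalled == 0 | abs(refFreq - 0.5) < .Machine$double.eps^0.5
    polarity[ambiguous] <- "ambiguous"
    if (any(nCalled == 0))
        warning(sum(nCalled == 0),
                " locus/loci with all parental_A genotypes missing; ",
                "polarity set to ambiguous")
    flip <- polarity == "flipped"
    gt[flip, ] <- 2L - gt[flip, , drop = FALSE]
    assay(x, "GT") <- gt
    rowData(x)$polarity <- polarity
    x
}

#' Diagnostic / discriminant SNP score
#'
#' For each (polarized) locus the score is the mean of two proportions: the
#' proportion of homozygous-reference genotypes (code 0) among non-missing
#' `parental_A` individuals, and the proportion of homozygous-alternate
#' genotypes (code 2) among non-missing `parental_B` individuals:
#' \deqn{s = \tfrac12\left(\hat p_{A}(g{=}0) + \hat p_{B}(g{=}2)\right)}
#' The score lies in \[0, 1\] and equals 1 exactly for a diagnostic SNP
#' (the two species fixed for alternative homozygous states). Heterozygotes
#' count against both proportions. A locus with one parental side entirely
#' missing gets an `NA` score.
#'
#' @param x a polarized [HybridGenotypes-class] object.
#' @return `x` with a `score` column in `rowData`.
#' @seealso [classifyPanel()]
#' @export
discriminantScores <- function(x) {
    idsA <- .assertRolePresent(x, "parental_A")
    idsB <- .assertRolePresent(x, "parental_B")
    gt <- genotypes(x)
    ga <- gt[, idsA, drop = FALSE]
    gb <- gt[, idsB, drop = FALSE]
    nA <- rowSums(!is.na(ga))
    nB <- rowSums(!is.na(gb))
    pA <- rowSums(ga == 0L, na.rm = TRUE) / nA
    pB <- rowSums(gb == 2L, na.rm = TRUE) / nB
    score <- (pA + pB) / 2
    score[nA == 0 | nB == 0] <- NA_real_
    rowData(x)$score <- unname(score)
    x
}

#' Classify loci into the discriminant panel
#'
#' Score-based classes: `diagnostic` (score exactly 1), `discriminant`
#' (score strictly greater than `threshold`), `semi-diagnostic`
#' (0.5 < score <= threshold), `non-diagnostic` (score <= 0.5). The panel
#' initially contains the loci with score strictly above the threshold
#' whose polarity is not ambiguous; diagnostic loci are discriminant by
#' construction. Excluded loci carry a `dropReason` (`"low-score"`,
#' `"ambiguous-polarity"`, `"side-missing"`).
#'
#' @param x a [HybridGenotypes-class] object with `score` (and optionally
#'   `polarity`) in `rowData`.
#' @param threshold strict lower bound for panel membership, in (0, 1);
#'   default 0.9.
#' @return `x` with `class`, `inPanel` and `dropReason` columns in
#'   `rowData`.
#' @export
classifyPanel <- function(x, threshold = 0.9) {
    if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
        stop("threshold must lie strictly between 0 and 1")
    rd <- rowData(x)
    if (is.null(rd$score))
        stop("run discriminantScores() first")
    s <- rd$score
    cls <- rep(NA_character_, length(s))
    cls[!is.na(s) & s <= 0.5] <- "non-diagnostic"
    cls[!is.na(s) & s > 0.5 & s <= threshold] <- "semi-diagnostic"
    cls[!is.na(s) & s > threshold] <- "discriminant"
    cls[!is.na(s) & s == 1] <- "diagnostic"
    ambiguous <- if (is.null(rd$polarity)) rep(FALSE, length(s)) else
        rd$polarity == "ambiguous"
    inPanel <- !is.na(s) & s > threshold & !ambiguous
    dropReason <- rep(NA_character_, length(s))
    dropReason[!is.na(s) & s <= threshold] <- "low-score"
    dropReason[ambiguous & is.na(dropReason)] <- "ambiguous-polarity"
    dropReason[is.na(s)] <- "side-missing"
    rowData(x)$class <- cls
    rowData(x)$inPanel <- inPanel
    rowData(x)$dropReason <- dropReason
    x
}

#' Chromosome enrichment of discriminant SNPs
#'
#' Pearson chi-square test of homogeneity on the 2 x K table of panel
#' vs non-panel locus counts per chromosome (K chromosomes with at least
#' one mapped SNP; unmapped loci, chromosome `"NA"`, are excluded).
#' Standardized residuals identify chromosomes enriched or depleted in
#' discriminant SNPs.
#'
#' @param x a [HybridGenotypes-class] object with `inPanel` in `rowData`
#'   and chromosome annotation.
#' @return list with `statistic`, `df`, `p.value`, `table` and the
#'   standardized residuals (`stdres`, panel row).
#' @export
chromosomeEnrichment <- function(x) {
    rd <- rowData(x)
    if (is.null(rd$inPanel))
        stop("run classifyPanel() first")
    mapped <- !is.na(rd$chrom) & rd$chrom != "NA"
    chrom <- rd$chrom[mapped]
    inPanel <- rd$inPanel[mapped]
    if (length(unique(chrom)) < 2L)
        stop("need at least 2 chromosomes with mapped SNPs")
    tab <- table(panel = factor(inPanel, c(TRUE, FALSE)), chrom = chrom)
    if (any(colSums(tab) == 0L))
        tab <- tab[, colSums(tab) > 0L, drop = FALSE]
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    if (any(ct$expected < 1))
        warning("expected count below 1 in some cell(s); chi-square ",
                "approximation may be poor (df = ", unname(ct$parameter), ")")
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p.value = ct$p.value, table = tab, stdres = ct$stdres["TRUE", ])
}
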