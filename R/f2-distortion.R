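#' Exact Hardy-Weinberg test
#'
#' Two-sided exact test of Hardy-Weinberg proportions for a biallelic
#' locus. Conditional on the observed allele counts, the heterozygote
#' count under random union of gametes follows the Levene distribution
#' \deqn{P(n_1 = h) = \frac{2^h\, n!\, n_A!\, n_B!}{
#'   \left(\frac{n_A-h}{2}\right)!\, h!\, \left(\frac{n_B-h}{2}\right)!\,(2n)!}}
#' over heterozygote counts h compatible with the allele counts (same
#' parity as \eqn{n_A}). The p-value is the sum of the probabilities of all
#' outcomes no more probable than the observed one (the conventional
#' two-sided exact test); `midp = TRUE` subtracts half the probability of
#' the observed outcome.
#'
#' Monomorphic tables (one allele absent) return p = 1 by convention.
#'
#' @param n0,n1,n2 vectors of genotype counts (homozygous reference,
#'   heterozygous, homozygous alternate); recycled to a common length.
#' @param midp use the mid-p variant (default FALSE).
#' @return numeric vector of exact p-values.
#' @examples
#' hwExactTest(25, 50, 25)   # exact HW proportions
#' hwExactTest(50, 0, 50)    # extreme heterozygote deficit
#' @export
hwExactTest <- function(n0, n1, n2, midp = FALSE) {
    len <- max(length(n0), length(n1), length(n2))
    n0 <- rep_len(as.integer(n0), len)
    n1 <- rep_len(as.integer(n1), len)
    n2 <- rep_len(as.integer(n2), len)
    vapply(seq_len(len), function(i) .hwExactOne(n0[i], n1[i], n2[i], midp),
           numeric(1))
}

## Levene log-probabilities of all heterozygote counts compatible with the
## allele counts (nA alleles of type A among 2n); h has the parity of nA.
.leveneLogProb <- function(n, nA) {
    nB <- 2L * n - nA
    h <- seq.int(nA %% 2L, min(nA, nB), by = 2L)
    lp <- h * log(2) + lfactorial(n) - lfactorial((nA - h) / 2) -
        lfactorial(h) - lfactorial((nB - h) / 2) +
        lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
    names(lp) <- h
    lp
}

.hwExactOne <- function(n0, n1, n2, midp = FALSE) {
    stopifnot(n0 >= 0, n1 >= 0, n2 >= 0)
    n <- n0 + n1 + n2
    if (n < 1L) return(NA_real_)
    nA <- 2L * n0 + n1
    if (nA == 0L || nA == 2L * n) return(1)
    lp <- .leveneLogProb(n, nA)
    pr <- exp(lp - max(lp))
    pr <- pr / sum(pr)
    pObs <- pr[as.character(n1)]
    p <- sum(pr[pr <= pObs * (1 + 1e-9)])
    if (midp) p <- p - pObs / 2
    min(p, 1)
}

#' Heterozygote-excess D statistic
#'
#' Half the difference between the observed and Hardy-Weinberg-expected
#' heterozygote counts: \eqn{D = (n_1 - 2 n \hat p \hat q) / 2} with
#' \eqn{\hat p = (2 n_0 + n_1) / 2n}. Positive D indicates heterozygote
#' excess, negative D heterozygote deficit (homozygote excess). The
#' `homExcess` column reports, for use when D < 0, which homozygote class
#' exceeds its HW expectation: `"A"` (reference, parental_A side), `"B"`,
#' `"both"`, or `"none"`.
#'
#' Sign convention: D > 0 = heterozygote excess (conventions differ across
#' software; this matches the heterozygote-centred chi-square
#' decomposition).
#'
#' @inheritParams hwExactTest
#' @return data.frame with columns `D` and `homExcess`.
#' @export
hwDStatistic <- function(n0, n1, n2) {
    len <- max(length(n0), length(n1), length(n2))
    n0 <- rep_len(as.numeric(n0), len)
    n1 <- rep_len(as.numeric(n1), len)
    n2 <- rep_len(as.numeric(n2), len)
    n <- n0 + n1 + n2
    p <- (2 * n0 + n1) / (2 * n)
    q <- 1 - p
    e1 <- 2 * n * p * q
    D <- (n1 - e1) / 2
    excessA <- n0 > n * p^2
    excessB <- n2 > n * q^2
    homExcess <- rep("none", len)
    homExcess[excessA & !excessB] <- "A"
    homExcess[!excessA & excessB] <- "B"
    homExcess[excessA & excessB] <- "both"
    data.frame(D = D, homExcess = homExcess, stringsAsFactors = FALSE)
}

.CATEGORIES <- c("NEUTRAL", "HET_EXCESS_BALANCED", "HOM_EXCESS_BOTH",
                 "A_SHIFT_HWE", "A_SHIFT_HET_EXCESS", "A_SHIFT_A_HOM_EXCESS",
                 "B_SHIFT_HWE", "B_SHIFT_HET_EXCESS")

#' Eight-way segregation-distortion category
#'
#' Deterministic mapping from the transmission direction, the HW test
#' outcome and the sign of D to one of eight locus categories:
#' \tabular{lll}{
#'   direction \tab HW \tab category \cr
#'   none \tab pass \tab `NEUTRAL` \cr
#'   none \tab fail, D > 0 \tab `HET_EXCESS_BALANCED` \cr
#'   none \tab fail, D < 0 \tab `HOM_EXCESS_BOTH` \cr
#'   toward_A \tab pass \tab `A_SHIFT_HWE` \cr
#'   toward_A \tab fail, D > 0 \tab `A_SHIFT_HET_EXCESS` \cr
#'   toward_A \tab fail, D < 0 \tab `A_SHIFT_A_HOM_EXCESS` \cr
#'   toward_B \tab pass \tab `B_SHIFT_HWE` \cr
#'   toward_B \tab fail, D > 0 \tab `B_SHIFT_HET_EXCESS` \cr
#' }
#' Combinations outside the table (a toward_B shift with homozygote
#' excess, or an A-shift whose homozygote excess is not on the A side) are
#' assigned the nearest category and flagged as anomalies.
#'
#' @param direction character vector in `{"none", "toward_A", "toward_B"}`.
#' @param hwFail logical vector: HW test rejected at alpha.
#' @param D numeric vector of D statistics.
#' @param homExcess character vector from [hwDStatistic()].
#' @return data.frame with columns `category` (factor over the eight
#'   levels) and `anomaly` (logical).
#' @export
classifyDistortion <- function(direction, hwFail, D, homExcess) {
    len <- length(direction)
    stopifnot(length(hwFail) == len, length(D) == len,
              length(homExcess) == len)
    category <- rep(NA_character_, len)
    anomaly <- rep(FALSE, len)
    hetSide <- D >= 0
    idx <- direction == "none"
    category[idx & !hwFail] <- "NEUTRAL"
    category[idx & hwFail & hetSide] <- "HET_EXCESS_BALANCED"
    category[idx & hwFail & !hetSide] <- "HOM_EXCESS_BOTH"
    idx <- direction == "toward_A"
    category[idx & !hwFail] <- "A_SHIFT_HWE"
    category[idx & hwFail & hetSide] <- "A_SHIFT_HET_EXCESS"
    category[idx & hwFail & !hetSide] <- "A_SHIFT_A_HOM_EXCESS"
    anomaly[idx & hwFail & !hetSide & homExcess != "A"] <- TRUE
    idx <- direction == "toward_B"
    category[idx & !hwFail] <- "B_SHIFT_HWE"
    category[idx & hwFail & hetSide] <- "B_SHIFT_HET_EXCESS"
    ## no B-homozygote-excess class: nearest category, flagged
    category[idx & hwFail & !hetSide] <- "B_SHIFT_HWE"
    anomaly[idx & hwFail & !hetSide] <- TRUE
    data.frame(category = factor(category, levels = .CATEGORIES),
               anomaly = anomaly)
}

#' Per-locus segregation-distortion analysis of an F2 cohort
#'
#' For every locus, over the non-missing genotypes of the cohort:
#' \enumerate{
#'   \item transmission test (H0: mean genotype = 1) -- one-sample
#'     two-sided t-test; rejection with mean < 1 is a shift toward the
#'     parental_A alleles (`toward_A`), mean > 1 `toward_B`;
#'   \item exact Hardy-Weinberg test ([hwExactTest()]) of the genotype
#'     counts;
#'   \item heterozygote-excess statistic D ([hwDStatistic()]);
#'   \item eight-way category ([classifyDistortion()]).
#' }
#' Loci with fewer than 2 non-missing genotypes are marked unanalyzable
#' (`analyzable = FALSE`) and excluded from category counts.
#'
#' @param x a polarized [HybridGenotypes-class] object.
#' @param cohort character vector of individual ids forming the cohort;
#'   default: all individuals with role `"F2"`.
#' @param alpha shared type-I error for both tests (default 0.05).
#' @param fdr apply Benjamini-Hochberg correction to both p-value sets
#'   before thresholding (off by default; the raw-alpha tallies match the
#'   uncorrected convention).
#' @param panelOnly restrict to panel loci when available (default TRUE).
#' @return data.frame with one row per locus: `locus`, `chrom`, `pos`,
#'   `n`, `n0`, `n1`, `n2`, `mean`, `t`, `p_t`, `direction`, `p_hw`, `D`,
#'   `homExcess`, `category`, `anomaly`, `analyzable`.
#' @export
f2Distortion <- function(x, cohort = NULL, alpha = 0.05, fdr = FALSE,
                         panelOnly = TRUE) {
    rd <- rowData(x)
    if (panelOnly && !is.null(rd$inPanel))
        x <- x[rd$inPanel, ]
    if (is.null(cohort)) {
        cohort <- .assertRolePresent(x, "F2")
    } else {
        missing <- setdiff(cohort, colnames(x))
        if (length(missing))
            stop("cohort id(s) absent from matrix: ",
                 paste(head(missing, 5L), collapse = ", "))
    }
    gt <- genotypes(x)[, cohort, drop = FALSE]
    n0 <- rowSums(gt == 0L, na.rm = TRUE)
    n1 <- rowSums(gt == 1L, na.rm = TRUE)
    n2 <- rowSums(gt == 2L, na.rm = TRUE)
    st <- .rowGenotypeTest(gt)
    analyzable <- st$n >= 2L

    pT <- st$p
    pHW <- hwExactTest(n0, n1, n2)
    if (fdr) {
        pT <- p.adjust(pT, method = "BH")
        pHW <- p.adjust(pHW, method = "BH")
    }
    direction <- rep("none", nrow(st))
    sigT <- analyzable & !is.na(pT) & pT < alpha
    direction[sigT & st$mean < 1] <- "toward_A"
    direction[sigT & st$mean > 1] <- "toward_B"
    dStat <- hwDStatistic(n0, n1, n2)
    hwFail <- !is.na(pHW) & pHW < alpha
    cls <- classifyDistortion(direction, hwFail, dStat$D, dStat$homExcess)
    cls$category[!analyzable] <- NA
    rdx <- lociInfo(x)
    out <- data.frame(locus = rownames(gt),
                      chrom = as.character(rdx$chrom),
                      pos = rdx$pos,
                      n = st$n, n0 = n0, n1 = n1, n2 = n2,
                      mean = st$mean, t = st$t, p_t = pT,
                      direction = direction, p_hw = pHW,
                      D = dStat$D, homExcess = dStat$homExcess,
                      category = cls$category, anomaly = cls$anomaly,
                      analyzable = analyzable,
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "alpha") <- alpha
    out
}

#' Cohort summary of distortion categories
#'
#' Category counts and percentages (2 decimals, denominator = analyzable
#' loci) plus per-test tallies: loci significant by the transmission
#' t-test, loci failing the HW test, loci with heterozygote excess among
#' the HW failures.
#'
#' @param results data.frame from [f2Distortion()].
#' @param label optional cohort label carried into the output.
#' @return list with `label`, `nLoci`, `nAnalyzable`, `categories`
#'   (data.frame: category, count, pct), `nSigT`, `nHWFail`, `nHetExcess`.
#' @export
cohortSummary <- function(results, label = "F2") {
    alpha <- attr(results, "alpha")
    if (is.null(alpha)) alpha <- 0.05
    ok <- results$analyzable
    nA <- sum(ok)
    counts <- table(results$category[ok])
    pct <- if (nA > 0) formatPercentage(as.integer(counts), nA) else
        rep(NA_real_, length(counts))
    list(label = label,
         nLoci = nrow(results),
         nAnalyzable = nA,
         categories = data.frame(category = names(counts),
                                 count = as.integer(counts), pct = pct,
                                 stringsAsFactors = FALSE),
         nSigT = sum(results$direction[ok] != "none"),
         nHWFail = sum(results$p_hw[ok] < alpha, na.rm = TRUE),
         nHetExcess = sum(results$p_hw[ok] < alpha & results$D[ok] > 0,
                          na.rm = TRUE))
}

#' Per-chromosome track of transmission statistics
#'
#' Orders the per-locus t statistics along each chromosome for plotting
#' (transmission-distortion profile). Unmapped loci are routed to an
#' `"NA"` track.
#'
#' @param results data.frame from [f2Distortion()].
#' @return data.frame ordered by chromosome and position with columns
#'   `chrom`, `pos`, `locus`, `t`, `direction`, `significant`.
#' @export
chromosomeProfile <- function(results) {
    chrom <- results$chrom
    chrom[is.na(chrom)] <- "NA"
    num <- suppressWarnings(as.integer(sub("^[Cc]hr", "", chrom)))
    ord <- order(is.na(num), num, chrom, results$pos)
    data.frame(chrom = chrom[ord], pos = results$pos[ord],
               locus = results$locus[ord], t = results$t[ord],
               direction = results$direction[ord],
               significant = results$direction[ord] != "none",
               row.names = NULL, stringsAsFactors = FALSE)
}
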