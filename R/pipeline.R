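#' Ratio-to-percentage formatter
#'
#' Formats a count ratio as a percentage the way analysis reports print
#' them: `digits = 2` with half-up rounding by default (76.99 for
#' 475/617), a whole-percent variant (`digits = 0`: 17 for 908/5289), and
#' a truncation mode (66.66 for 12/18).
#'
#' @param k numerator count(s), `0 <= k <= n`.
#' @param n denominator count(s), `n > 0` (`n = 0` yields `NA` with a
#'   warning).
#' @param digits decimal places (default 2; use 0 for whole percent).
#' @param method `"half-up"` (default) or `"truncate"`.
#' @return numeric percentage(s).
#' @examples
#' formatPercentage(475, 617)              # 76.99
#' formatPercentage(908, 5289, digits = 0) # 17
#' formatPercentage(12, 18, method = "truncate") # 66.66
#' @export
formatPercentage <- function(k, n, digits = 2L,
                             method = c("half-up", "truncate")) {
    method <- match.arg(method)
    if (any(k < 0) || any(k > n & n > 0))
        stop("counts must satisfy 0 <= k <= n")
    bad <- n == 0
    if (any(bad))
        warning("percentage undefined for zero denominator")
    scale <- 10^digits
    raw <- 100 * k / n
    out <- switch(method,
                  "half-up" = floor(raw * scale + 0.5 + 1e-9) / scale,
                  "truncate" = floor(raw * scale + 1e-9) / scale)
    out[bad] <- NA_real_
    out
}

#' Run the full hybrid-porosity analysis pipeline
#'
#' Orchestrates the analysis stages in order: locus/individual missingness
#' filters, replicate detection and deduplication, allele polarization,
#' discriminant scoring and panel classification, F1 Mendelian validation,
#' admixture PCA with hybrid index, and per-cohort F2 segregation
#' distortion. Produces a cascade report whose stage in/out counts chain
#' and whose percentages are recomputed from the integer counts.
#'
#' @param x a [HybridGenotypes-class] object with complete group and role
#'   assignments.
#' @param lociR per-group and overall call-rate threshold
#'   (see [filterLociByMissingness()]; default 0.7).
#' @param indMaxNA individual missingness cutoff (default 0.8, strict).
#' @param scoreThreshold strict discriminant-score cutoff (default 0.9).
#' @param alpha shared type-I error for the F1 and F2 tests (default 0.05).
#' @param declaredReplicates optional data.frame (`id1`, `id2`) of known
#'   replicate pairs.
#' @param replicateThreshold optional manual replicate distance threshold;
#'   default: KDE valley ([detectReplicateThreshold()]).
#' @param cohorts named list of individual-id vectors to analyze as F2
#'   cohorts; default: one cohort of all F2 individuals. When no F2
#'   individuals exist the distortion stage is skipped and noted.
#' @return A list of class `"CascadeReport"`: `stages` (data.frame with
#'   per-stage in/out counts), `panel` (locus panel table), `f1` (volcano
#'   table), `admixture` ([AdmixtureSummary-class]), `cohorts` (named list
#'   of [cohortSummary()] lists), `distortion` (named list of per-locus
#'   tables), `genotypes` (the final filtered object).
#' @export
runFullPipeline <- function(x, lociR = 0.7, indMaxNA = 0.8,
                            scoreThreshold = 0.9, alpha = 0.05,
                            declaredReplicates = NULL,
                            replicateThreshold = NULL, cohorts = NULL) {
    cd <- colData(x)
    if (any(is.na(cd$group)) || any(is.na(cd$role)))
        stop("every individual needs a group and role before running ",
             "the pipeline")

    stages <- list()
    note <- function(stage, xin, xout, detail = "")
        data.frame(stage = stage,
                   lociIn = nrow(xin), lociOut = nrow(xout),
                   indIn = ncol(xin), indOut = ncol(xout),
                   detail = detail, stringsAsFactors = FALSE)

    ## 1. locus call-rate filter
    x1 <- filterLociByMissingness(x, r = lociR)
    stages$loci <- note("locus_callrate", x, x1,
                        sprintf("r=%.2f, dropped=%d", lociR,
                                length(metadata(x1)$droppedLoci)))

    ## 2. replicate QC
    gd <- pairwiseGenotypeDistance(x1)
    thr <- if (is.null(replicateThreshold))
        detectReplicateThreshold(gd) else replicateThreshold
    rep <- resolveReplicates(x1, gd, thr, declared = declaredReplicates)
    x2 <- dropReplicates(x1, rep)
    stages$replicates <- note("replicate_qc", x1, x2,
                              sprintf("threshold=%.3g, removed=%d", thr,
                                      length(rep@removed)))

    ## 3. individual missingness
    x3 <- filterIndividualsByMissingness(x2, maxNA = indMaxNA)
    stages$individuals <- note("individual_missingness", x2, x3,
                               sprintf("maxNA=%.2f, removed=%d", indMaxNA,
                                       length(metadata(x3)$removedIndividuals)))

    ## 4. polarization, score, panel
    x4 <- classifyPanel(discriminantScores(polarizeGenotypes(x3)),
                        threshold = scoreThreshold)
    x5 <- x4[rowData(x4)$inPanel, ]
    stages$panel <- note("discriminant_panel", x4, x5,
                         sprintf("threshold=%.2f", scoreThreshold))

    ## 5. F1 Mendelian validation
    f1 <- f1Volcano(x5, alpha = alpha)
    x6 <- applyF1Filter(x5, f1)
    stages$f1 <- note("f1_validation", x5, x6,
                      sprintf("drop-missing=%d, drop-deviant=%d",
                              sum(f1$decision == "drop-missing"),
                              sum(f1$decision == "drop-deviant")))

    ## 6. admixture
    adm <- runAdmixturePCA(x6)

    ## 7. F2 distortion per cohort
    f2ids <- .idsOfRole(x6, "F2")
    distortion <- list()
    summaries <- list()
    if (is.null(cohorts))
        cohorts <- if (length(f2ids)) list(F2 = f2ids) else list()
    if (!length(cohorts)) {
        stages$distortion <- note("f2_distortion", x6, x6,
                                  "skipped: no F2 individuals")
    } else {
        for (nm in names(cohorts)) {
            ids <- intersect(cohorts[[nm]], colnames(x6))
            res <- f2Distortion(x6, cohort = ids, alpha = alpha)
            distortion[[nm]] <- res
            summaries[[nm]] <- cohortSummary(res, label = nm)
        }
        stages$distortion <- note("f2_distortion", x6, x6,
                                  sprintf("cohorts=%s",
                                          paste(names(cohorts),
                                                collapse = ",")))
    }

    report <- list(stages = do.call(rbind, unname(stages)),
                   panel = as.data.frame(rowData(x4)),
                   f1 = f1, admixture = adm, cohorts = summaries,
                   distortion = distortion,
                   replicateReport = rep, genotypes = x6,
                   params = list(lociR = lociR, indMaxNA = indMaxNA,
                                 scoreThreshold = scoreThreshold,
                                 alpha = alpha))
    class(report) <- "CascadeReport"
    report
}

#' @export
print.CascadeReport <- function(x, ...) {
    cat("Hybrid-porosity analysis cascade\n")
    st <- x$stages
    for (i in seq_len(nrow(st)))
        cat(sprintf("  %-24s loci %5d -> %5d | individuals %4d -> %4d  (%s)\n",
                    st$stage[i], st$lociIn[i], st$lociOut[i],
                    st$indIn[i], st$indOut[i], st$detail[i]))
    for (nm in names(x$cohorts)) {
        s <- x$cohorts[[nm]]
        cat(sprintf("  cohort %s: %d analyzable loci\n", nm, s$nAnalyzable))
        tab <- s$categories[s$categories$count > 0, ]
        for (i in seq_len(nrow(tab)))
            cat(sprintf("    %-22s %5d/%d (%.2f%%)\n", tab$category[i],
                        tab$count[i], s$nAnalyzable, tab$pct[i]))
    }
    invisible(x)
}
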