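#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   rowData colData rowData<- colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats density pgamma pt qgamma setNames chisq.test
#'   p.adjust runif rbinom
#' @importFrom utils read.table write.table head
NULL

## genotype coding: 0 = homozygous for the parental_A-side allele (after
## polarization), 1 = heterozygous, 2 = homozygous parental_B; NA = missing.
.GT_CODES <- c(0L, 1L, 2L)

.ROLES <- c("parental_A", "parental_B", "F1", "F2", "backcross")

#' Container for a biallelic genotype matrix with population metadata
#'
#' `HybridGenotypes` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds a loci x individuals matrix of genotype codes in a `"GT"` assay
#' (0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#' `NA` = missing). After [polarizeGenotypes()], code 0 is homozygous for the
#' majority allele of the `parental_A` species. Per-individual metadata
#' (`group`, `role`) live in `colData`; per-locus annotation (`chrom`, `pos`,
#' `gene`, and panel columns added by scoring) in `rowData`.
#'
#' @slot .
#'   See [SummarizedExperiment::SummarizedExperiment] for inherited slots.
#'
#' @seealso [HybridGenotypes()] for construction, [genotypes()],
#'   [sampleGroups()], [sampleRoles()] for access.
#' @export
setClass("HybridGenotypes", contains = "SummarizedExperiment")

.validHybridGenotypes <- function(object) {
    msg <- character()
    if (!"GT" %in% names(assays(object)))
        msg <- c(msg, "assay 'GT' is required")
    else {
        gt <- assay(object, "GT")
        bad <- !(gt %in% .GT_CODES | is.na(gt))
        if (any(bad))
            msg <- c(msg, sprintf("%d genotype values outside {0, 1, 2, NA}",
                                  sum(bad)))
    }
    cd <- colData(object)
    if (!all(c("group", "role") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'group' and 'role'")
    else {
        role <- cd$role
        badRole <- !is.na(role) & !(role %in% .ROLES)
        if (any(badRole))
            msg <- c(msg, sprintf("invalid role(s): %s",
                                  paste(unique(role[badRole]), collapse = ", ")))
    }
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "individual ids must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "locus ids must be unique")
    if (length(msg)) msg else TRUE
}

setValidity("HybridGenotypes", .validHybridGenotypes)

#' Construct a HybridGenotypes object
#'
#' @param gt integer matrix of genotype codes (loci in rows, individuals in
#'   columns), values in \{0, 1, 2, NA\}. Dimnames are used as locus and
#'   individual ids; defaults are generated when absent.
#' @param group character vector (one per individual) of group labels.
#' @param role character vector of roles, one per individual or one per group
#'   when `group` is given and `role` is named by group. Valid roles:
#'   `"parental_A"`, `"parental_B"`, `"F1"`, `"F2"`, `"backcross"`.
#' @param chrom,pos,gene optional per-locus annotation (chromosome label,
#'   1-based position, gene id). Unmapped loci use chromosome `"NA"`.
#'
#' @return A [HybridGenotypes-class] object.
#' @examples
#' gt <- matrix(c(0L, 1L, 2L, NA), nrow = 2,
#'              dimnames = list(c("L1", "L2"), c("ind1", "ind2")))
#' hg <- HybridGenotypes(gt, group = c("popA", "popB"),
#'                       role = c("parental_A", "parental_B"))
#' hg
#' @export
HybridGenotypes <- function(gt, group = NULL, role = NULL,
                            chrom = NULL, pos = NULL, gene = NULL) {
    gt <- as.matrix(gt)
    storage.mode(gt) <- "integer"
    if (is.null(rownames(gt)))
        rownames(gt) <- sprintf("L%05d", seq_len(nrow(gt)))
    if (is.null(colnames(gt)))
        colnames(gt) <- sprintf("ind%04d", seq_len(ncol(gt)))
    n <- ncol(gt)
    if (is.null(group)) group <- rep(NA_character_, n)
    if (is.null(role)) {
        role <- rep(NA_character_, n)
    } else if (!is.null(names(role)) && length(role) != n) {
        ## role named by group label
        role <- unname(role[group])
    }
    stopifnot(length(group) == n, length(role) == n)
    cd <- DataFrame(group = as.character(group), role = as.character(role),
                    row.names = colnames(gt))
    rd <- DataFrame(row.names = rownames(gt))
    rd$chrom <- if (is.null(chrom)) rep("NA", nrow(gt)) else as.character(chrom)
    rd$pos <- if (is.null(pos)) rep(NA_integer_, nrow(gt)) else as.integer(pos)
    if (!is.null(gene)) rd$gene <- as.character(gene)
    new("HybridGenotypes",
        SummarizedExperiment(assays = list(GT = gt), rowData = rd, colData = cd))
}

setMethod("show", "HybridGenotypes", function(object) {
    gt <- assay(object, "GT")
    cat(sprintf("HybridGenotypes: %d loci x %d individuals\n",
                nrow(object), ncol(object)))
    role <- colData(object)$role
    if (any(!is.na(role))) {
        tab <- table(factor(role, levels = .ROLES))
        cat("roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
            "\n")
    }
    cat(sprintf("missing: %.1f%%\n", 100 * mean(is.na(gt))))
    rd <- rowData(object)
    if (!is.null(rd$inPanel))
        cat(sprintf("panel loci: %d\n", sum(rd$inPanel, na.rm = TRUE)))
    invisible(NULL)
})

## ---- generics ----

#' Accessors for HybridGenotypes
#'
#' `genotypes()` returns the loci x individuals genotype code matrix;
#' `sampleGroups()` and `sampleRoles()` the per-individual group / role
#' (named by individual id); `lociInfo()` the per-locus annotation
#' `DataFrame`.
#'
#' @param x a [HybridGenotypes-class] object.
#' @return See description.
#' @examples
#' hg <- simulateHybridCross(simConfig(nLoci = 50), seed = 1)$genotypes
#' dim(genotypes(hg))
#' table(sampleRoles(hg))
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname genotypes
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname genotypes
#' @export
setGeneric("sampleRoles", function(x) standardGeneric("sampleRoles"))

#' @rdname genotypes
#' @export
setGeneric("lociInfo", function(x) standardGeneric("lociInfo"))

#' @rdname genotypes
setMethod("genotypes", "HybridGenotypes", function(x) assay(x, "GT"))

#' @rdname genotypes
setMethod("sampleGroups", "HybridGenotypes", function(x)
    setNames(colData(x)$group, colnames(x)))

#' @rdname genotypes
setMethod("sampleRoles", "HybridGenotypes", function(x)
    setNames(colData(x)$role, colnames(x)))

#' @rdname genotypes
setMethod("lociInfo", "HybridGenotypes", function(x) rowData(x))

## individuals of a given role (helper, internal)
.idsOfRole <- function(x, role) {
    colnames(x)[!is.na(colData(x)$role) & colData(x)$role == role]
}

.assertRolePresent <- function(x, role) {
    ids <- .idsOfRole(x, role)
    if (!length(ids))
        stop("no individuals with role '", role, "' in the population map")
    ids
}

#' Pairwise genotype distances between individuals
#'
#' Holds the symmetric matrix of missingness-rescaled Euclidean genotype
#' distances produced by [pairwiseGenotypeDistance()], together with the
#' number of loci non-missing in both members of each pair.
#'
#' @slot distance numeric symmetric matrix of distances (NA where no shared
#'   loci).
#' @slot nShared integer matrix of shared (pairwise-complete) locus counts.
#' @slot nLoci total number of loci the distances were computed over.
#' @export
setClass("GenotypeDistances",
         representation(distance = "matrix", nShared = "matrix",
                        nLoci = "integer"))

setValidity("GenotypeDistances", function(object) {
    d <- object@distance
    if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
        return("distance matrix must be symmetric")
    if (any(diag(d) != 0))
        return("self-distances must be zero")
    if (any(d < 0, na.rm = TRUE))
        return("distances must be nonnegative")
    TRUE
})

setMethod("show", "GenotypeDistances", function(object) {
    n <- nrow(object@distance)
    cat(sprintf("GenotypeDistances: %d individuals, %d pairs (%d loci)\n",
                n, n * (n - 1) / 2, object@nLoci))
    dd <- object@distance[upper.tri(object@distance)]
    cat(sprintf("range: %.3f - %.3f\n", min(dd, na.rm = TRUE),
                max(dd, na.rm = TRUE)))
    invisible(NULL)
})

#' @rdname pairwiseGenotypeDistance
#' @export
setGeneric("distanceMatrix", function(x) standardGeneric("distanceMatrix"))

#' @rdname pairwiseGenotypeDistance
setMethod("distanceMatrix", "GenotypeDistances", function(x) x@distance)

#' @rdname pairwiseGenotypeDistance
#' @export
setGeneric("distancePairs", function(x) standardGeneric("distancePairs"))

#' @rdname pairwiseGenotypeDistance
setMethod("distancePairs", "GenotypeDistances", function(x) {
    d <- x@distance
    idx <- which(upper.tri(d), arr.ind = TRUE)
    data.frame(id1 = rownames(d)[idx[, 1]], id2 = colnames(d)[idx[, 2]],
               distance = d[idx], nShared = x@nShared[idx],
               stringsAsFactors = FALSE)
})

#' Replicate-detection report
#'
#' Result of [resolveReplicates()]: clusters of individuals whose pairwise
#' distance falls below the replicate threshold, the representative kept per
#' cluster, below-threshold pairs with no declared replicate label
#' (contamination candidates), and declared replicate pairs that sit above
#' the threshold but are mutual nearest neighbours.
#'
#' @slot threshold distance threshold used.
#' @slot clusters list of character vectors (individual ids).
#' @slot kept representative kept per cluster.
#' @slot removed ids removed from the matrix.
#' @slot flaggedContaminants data.frame of suspicious below-threshold pairs.
#' @slot mutualNearest data.frame of above-threshold declared pairs that are
#'   mutually nearest.
#' @export
setClass("ReplicateReport",
         representation(threshold = "numeric", clusters = "list",
                        kept = "character", removed = "character",
                        flaggedContaminants = "data.frame",
                        mutualNearest = "data.frame"))

setValidity("ReplicateReport", function(object) {
    if (length(object@clusters) != length(object@kept))
        return("one kept representative per cluster is required")
    TRUE
})

setMethod("show", "ReplicateReport", function(object) {
    cat(sprintf("ReplicateReport: threshold %.4g\n", object@threshold))
    cat(sprintf("  %d cluster(s), %d individual(s) removed\n",
                length(object@clusters), length(object@removed)))
    cat(sprintf("  %d contamination-candidate pair(s)\n",
                nrow(object@flaggedContaminants)))
    cat(sprintf("  %d mutual-nearest declared pair(s) above threshold\n",
                nrow(object@mutualNearest)))
    invisible(NULL)
})

#' Admixture summary (PCA scores, axis tests, hybrid index)
#'
#' @slot pcScores individuals x axes matrix of principal-component scores.
#' @slot axisVariance fraction of variance per axis (non-increasing).
#' @slot twStats Tracy-Widom statistic per tested axis.
#' @slot axisP axis significance (upper-tail TW p-value) per tested axis.
#' @slot hybridIndex data.frame with per-individual hybrid index.
#' @slot nLoci number of loci retained after normalization.
#' @export
setClass("AdmixtureSummary",
         representation(pcScores = "matrix", axisVariance = "numeric",
                        twStats = "numeric", axisP = "numeric",
                        hybridIndex = "data.frame", nLoci = "integer"))

setMethod("show", "AdmixtureSummary", function(object) {
    cat(sprintf("AdmixtureSummary: %d individuals, %d loci\n",
                nrow(object@pcScores), object@nLoci))
    k <- min(3L, length(object@axisVariance))
    cat("axis variance:",
        paste(sprintf("%.2f%%", 100 * object@axisVariance[seq_len(k)]),
              collapse = " "), "...\n")
    k2 <- min(3L, length(object@axisP))
    cat("axis p (TW):",
        paste(sprintf("%.3g", object@axisP[seq_len(k2)]), collapse = " "), "\n")
    invisible(NULL)
})
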