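#' Read a biallelic SNP genotype matrix from VCF
#'
#' Reads a VCF 4.x file and converts diploid GT fields to genotype codes:
#' `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`, any half or no call
#' (`./.`, `0/.`) `-> NA`. Phased separators (`|`) are accepted and treated
#' as unphased. Records that are not biallelic SNPs are skipped and counted
#' (see `metadata(x)$skippedRecords`). Coordinates are taken from CHROM/POS
#' (1-based).
#'
#' @param file path to a VCF file (plain or gzipped).
#' @param popmap optional data.frame with columns `individual`, `group`,
#'   `role`, as returned by [readPopulationMap()].
#' @return A [HybridGenotypes-class] object (loci x individuals).
#' @export
readGenotypeVcf <- function(file, popmap = NULL) {
    if (!file.exists(file))
        stop("cannot read VCF file: ", file)
    vcf <- vcfR::read.vcfR(file, verbose = FALSE)
    if (nrow(vcf@fix) == 0L)
        stop("VCF contains no records")
    fix <- vcf@fix
    ref <- fix[, "REF"]
    alt <- fix[, "ALT"]
    keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
        ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
    nSkipped <- sum(!keep)
    if (!any(keep))
        stop("VCF contains no biallelic SNP records")
    if (nSkipped > 0L)
        message(nSkipped, " non-biallelic-SNP record(s) skipped")
    gtChar <- vcfR::extract.gt(vcf[keep, ], element = "GT")
    gt <- .decodeDiploidGT(gtChar)
    ids <- fix[keep, "ID"]
    noId <- is.na(ids) | ids == "."
    ids[noId] <- paste0(fix[keep, "CHROM"][noId], ":", fix[keep, "POS"][noId])
    rownames(gt) <- make.unique(ids)
    x <- HybridGenotypes(gt, chrom = fix[keep, "CHROM"],
                         pos = as.integer(fix[keep, "POS"]))
    if (!is.null(popmap))
        x <- applyPopulationMap(x, popmap)
    metadata(x)$skippedRecords <- nSkipped
    x
}

## "0/0","0|1","1/0","./.","0/." ... -> 0/1/2/NA
.decodeDiploidGT <- function(gtChar) {
    g <- gsub("|", "/", gtChar, fixed = TRUE)
    out <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = dimnames(g))
    out[g %in% "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% "1/1"] <- 2L
    out
}

#' Read / write a plain genotype table
#'
#' The table format is tab-delimited with individuals in rows and loci in
#' columns; the first column holds the individual id and the header the locus
#' ids. Cells are `0`, `1`, `2` or `NA` (empty also reads as missing).
#'
#' @param file path to the table.
#' @param popmap optional popmap data.frame (see [readPopulationMap()]).
#' @return `readGenotypeTable()`: a [HybridGenotypes-class] object.
#' @export
readGenotypeTable <- function(file, popmap = NULL) {
    if (!file.exists(file))
        stop("cannot read genotype table: ", file)
    tab <- read.table(file, header = TRUE, sep = "\t", row.names = NULL,
                      colClasses = "character", check.names = FALSE)
    if (nrow(tab) == 0L || ncol(tab) < 2L)
        stop("genotype table is empty")
    ids <- tab[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate individual id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(tab[, -1L, drop = FALSE])
    m[m == "" | m == "NA"] <- NA
    bad <- which(!(is.na(m) | m %in% c("0", "1", "2")), arr.ind = TRUE)
    if (nrow(bad) > 0L)
        stop(sprintf("invalid genotype '%s' for individual '%s', locus '%s'",
                     m[bad[1L, , drop = FALSE]], ids[bad[1L, 1L]],
                     colnames(m)[bad[1L, 2L]]))
    gt <- t(matrix(as.integer(m), nrow(m), ncol(m),
                   dimnames = list(ids, colnames(m))))
    x <- HybridGenotypes(gt)
    if (!is.null(popmap))
        x <- applyPopulationMap(x, popmap)
    x
}

#' @rdname readGenotypeTable
#' @param x a [HybridGenotypes-class] object.
#' @return `writeGenotypeTable()`: the file path, invisibly.
#' @export
writeGenotypeTable <- function(x, file) {
    gt <- t(genotypes(x))
    tab <- data.frame(individual = rownames(gt), gt, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Write genotypes as a minimal VCF
#'
#' Emits a minimal VCF 4.2 text file with placeholder REF/ALT alleles (A/C)
#' and diploid GT fields (`0/0`, `0/1`, `1/1`, `./.`). Chromosome and
#' position come from the locus annotation; unplaced loci are written with
#' CHROM `NA` and increasing positions.
#'
#' @param x a [HybridGenotypes-class] object.
#' @param file output path.
#' @return The file path, invisibly.
#' @export
writeGenotypeVcf <- function(x, file) {
    gt <- genotypes(x)
    rd <- lociInfo(x)
    chrom <- as.character(rd$chrom)
    pos <- rd$pos
    pos[is.na(pos)] <- seq_len(nrow(gt))[is.na(pos)]
    gtStr <- matrix("./.", nrow(gt), ncol(gt))
    gtStr[!is.na(gt) & gt == 0L] <- "0/0"
    gtStr[!is.na(gt) & gt == 1L] <- "0/1"
    gtStr[!is.na(gt) & gt == 2L] <- "1/1"
    header <- c("##fileformat=VCFv4.2",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
    body <- paste(chrom, pos, rownames(gt), "A", "C", ".", ".", ".", "GT",
                  apply(gtStr, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(header, body), file)
    invisible(file)
}

#' Read a population map and attach it to a genotype matrix
#'
#' The popmap is a two-column tab-delimited file (`individual<TAB>group`,
#' no header) in the style of Stacks; roles are supplied either as a YAML
#' file mapping each group label to one of `parental_A`, `parental_B`,
#' `F1`, `F2`, `backcross`, or as a named character vector.
#'
#' @param file path to the popmap TSV.
#' @param roles named character vector (`group -> role`) or path to a YAML
#'   file with the same mapping.
#' @return data.frame with columns `individual`, `group`, `role`.
#' @export
readPopulationMap <- function(file, roles) {
    tab <- read.table(file, header = FALSE, sep = "\t",
                      colClasses = "character")
    if (ncol(tab) < 2L)
        stop("popmap must have two columns: individual<TAB>group")
    names(tab)[1:2] <- c("individual", "group")
    if (is.character(roles) && length(roles) == 1L && file.exists(roles))
        roles <- unlist(yaml::read_yaml(roles))
    if (is.null(names(roles)))
        stop("roles must map group labels to roles")
    bad <- setdiff(unique(roles), .ROLES)
    if (length(bad))
        stop("invalid role(s): ", paste(bad, collapse = ", "))
    miss <- setdiff(unique(tab$group), names(roles))
    if (length(miss))
        stop("group(s) with no role assignment: ", paste(miss, collapse = ", "))
    tab$role <- unname(roles[tab$group])
    tab[, c("individual", "group", "role")]
}

#' @rdname readPopulationMap
#' @param x a [HybridGenotypes-class] object.
#' @param popmap data.frame with columns `individual`, `group`, `role`.
#' @return `applyPopulationMap()`: `x` with updated `colData`.
#' @export
applyPopulationMap <- function(x, popmap) {
    stopifnot(all(c("individual", "group", "role") %in% colnames(popmap)))
    idx <- match(colnames(x), popmap$individual)
    if (anyNA(idx))
        stop("individual(s) missing from popmap: ",
             paste(head(colnames(x)[is.na(idx)], 5L), collapse = ", "))
    colData(x)$group <- popmap$group[idx]
    colData(x)$role <- popmap$role[idx]
    validObject(x)
    x
}

#' Missingness filters
#'
#' `filterLociByMissingness()` retains exactly the loci genotyped in at
#' least a fraction `r` of the individuals of every group *and* at least
#' `r` of all individuals overall (the call-rate rule applied to the
#' genotype matrix, with Stacks `-r` >= semantics).
#' `filterIndividualsByMissingness()` removes individuals whose missing
#' fraction strictly exceeds `maxNA`.
#'
#' Dropped locus / individual ids are recorded in
#' `metadata(x)$droppedLoci` / `metadata(x)$removedIndividuals`.
#'
#' @param x a [HybridGenotypes-class] object with group assignments.
#' @param r minimum per-group and overall call-rate fraction (0 < r <= 1).
#' @return The filtered [HybridGenotypes-class] object.
#' @examples
#' hg <- simulateHybridCross(simConfig(nLoci = 100), seed = 1)$genotypes
#' hg2 <- filterLociByMissingness(hg, r = 0.7)
#' hg3 <- filterIndividualsByMissingness(hg2, maxNA = 0.8)
#' @export
filterLociByMissingness <- function(x, r = 0.7) {
    stopifnot(r > 0, r <= 1)
    grp <- colData(x)$group
    if (any(is.na(grp)))
        stop("every individual needs a group assignment")
    if (any(table(grp) == 0L))
        stop("group with zero individuals")
    gt <- genotypes(x)
    called <- !is.na(gt)
    ok <- rowMeans(called) >= r
    for (g in unique(grp)) {
        cols <- grp == g
        ok <- ok & rowMeans(called[, cols, drop = FALSE]) >= r
    }
    dropped <- rownames(x)[!ok]
    x <- x[ok, ]
    metadata(x)$droppedLoci <- dropped
    x
}

#' @rdname filterLociByMissingness
#' @param maxNA maximum tolerated missing fraction per individual; removal
#'   uses strict inequality (an individual at exactly `maxNA` is kept).
#' @export
filterIndividualsByMissingness <- function(x, maxNA = 0.8) {
    stopifnot(maxNA >= 0, maxNA <= 1)
    naFrac <- colMeans(is.na(genotypes(x)))
    drop <- naFrac > maxNA
    removed <- colnames(x)[drop]
    x <- x[, !drop]
    metadata(x)$removedIndividuals <- removed
    x
}
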