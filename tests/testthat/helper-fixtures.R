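## Small deterministic genotype object: 3 parental_A + 3 parental_B
## + 2 F1 + 4 F2 individuals, 4 loci with known structure.
toyGenotypes <- function() {
    gt <- rbind(
        L1 = c(0L, 0L, 0L,  2L, 2L, 2L,  1L, 1L,  0L, 1L, 1L, 2L),
        L2 = c(0L, 0L, 1L,  2L, 2L, 2L,  1L, 1L,  0L, 2L, 1L, 1L),
        L3 = c(2L, 2L, 2L,  0L, 0L, 0L,  1L, 1L,  2L, 1L, 0L, 1L),
        L4 = c(0L, 1L, NA,  1L, 2L, 2L,  1L, NA,  1L, 1L, 0L, 2L))
    colnames(gt) <- c(paste0("A", 1:3), paste0("B", 1:3),
                      paste0("H", 1:2), paste0("X", 1:4))
    HybridGenotypes(gt,
                    group = rep(c("popA", "popB", "f1", "f2"), c(3, 3, 2, 4)),
                    role = rep(c("parental_A", "parental_B", "F1", "F2"),
                               c(3, 3, 2, 4)),
                    chrom = c("Chr1", "Chr1", "Chr2", "NA"),
                    pos = c(100L, 200L, 50L, NA))
}

## Brute-force pairwise-complete rescaled Euclidean distance.
bruteDistance <- function(gt) {
    n <- ncol(gt); L <- nrow(gt)
    d <- matrix(0, n, n, dimnames = list(colnames(gt), colnames(gt)))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        ok <- !is.na(gt[, i]) & !is.na(gt[, j])
        d[i, j] <- if (!any(ok)) NA_real_ else
            sqrt(sum((gt[ok, i] - gt[ok, j])^2) * L / sum(ok))
    }
    diag(d) <- 0
    d
}

## Independent exact-HW oracle: enumerate every genotype configuration
## with the observed allele counts and sum the conditional multinomial
## probabilities of outcomes no more probable than the observed one.
hwOracle <- function(n0, n1, n2) {
    n <- n0 + n1 + n2
    nA <- 2L * n0 + n1
    if (nA == 0L || nA == 2L * n) return(1)
    cfg <- expand.grid(m0 = 0:n, m1 = 0:n)
    cfg$m2 <- n - cfg$m0 - cfg$m1
    cfg <- cfg[cfg$m2 >= 0 & 2L * cfg$m0 + cfg$m1 == nA, ]
    logw <- lfactorial(n) - lfactorial(cfg$m0) - lfactorial(cfg$m1) -
        lfactorial(cfg$m2) + cfg$m1 * log(2)
    w <- exp(logw - max(logw))
    pr <- w / sum(w)
    pObs <- pr[cfg$m1 == n1]
    sum(pr[pr <= pObs * (1 + 1e-9)])
}

## Same oracle for larger n: the heterozygote count is enumerated directly
## and weighted by the conditional multinomial probability at p = q = 1/2
## (the allele frequency cancels under the conditioning), normalized
## explicitly. O(n) per table.
hwOracleLarge <- function(n0, n1, n2) {
    n <- n0 + n1 + n2
    nA <- 2L * n0 + n1
    if (nA == 0L || nA == 2L * n) return(1)
    m1 <- seq.int(nA %% 2L, min(nA, 2L * n - nA), by = 2L)
    m0 <- (nA - m1) / 2
    m2 <- n - m0 - m1
    logw <- lfactorial(n) - lfactorial(m0) - lfactorial(m1) -
        lfactorial(m2) + m1 * log(2)
    w <- exp(logw - max(logw))
    pr <- w / sum(w)
    pObs <- pr[m1 == n1]
    sum(pr[pr <= pObs * (1 + 1e-9)])
}

## write a small VCF text fixture, return the path
writeToyVcf <- function(lines, path = tempfile(fileext = ".vcf")) {
    writeLines(lines, path)
    path
}
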