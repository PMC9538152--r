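noiseCfg <- function(...) {
    defaults <- list(nLoci = 400, nParentalA = 10, nParentalB = 10,
                     nF1 = 10, nF2 = 60, nBackcross = 10,
                     missingRates = c(0, 0), nReplicates = 0,
                     nContaminants = 0, distortedBlocks = list())
    over <- list(...)
    defaults[names(over)] <- over
    do.call(simConfig, defaults)
}

test_that("simulation is deterministic under a fixed seed", {
    s1 <- simulateHybridCross(simConfig(nLoci = 300), seed = 11)
    s2 <- simulateHybridCross(simConfig(nLoci = 300), seed = 11)
    expect_identical(genotypes(s1$genotypes), genotypes(s2$genotypes))
    expect_identical(s1$truth, s2$truth)
    s3 <- simulateHybridCross(simConfig(nLoci = 300), seed = 12)
    expect_false(identical(genotypes(s1$genotypes), genotypes(s3$genotypes)))
})

test_that("diagnostic loci are fixed in parents and heterozygous in F1", {
    sim <- simulateHybridCross(noiseCfg(dFrac = 1, semiFrac = 0), seed = 21)
    x <- sim$genotypes
    role <- sampleRoles(x)
    flip <- sim$truth$loci$flipped
    gt <- genotypes(x)
    gt[flip, ] <- 2L - gt[flip, , drop = FALSE]   # undo orientation
    expect_true(all(gt[, role == "parental_A"] == 0L))
    expect_true(all(gt[, role == "parental_B"] == 2L))
    expect_true(all(gt[, role == "F1"] == 1L))
    ## backcross to parental_A never carries two B alleles
    expect_true(all(gt[, role == "backcross"] != 2L))
})

test_that("Mendelian F2 genotype frequencies at unbiased diagnostic loci", {
    sim <- simulateHybridCross(noiseCfg(dFrac = 1, semiFrac = 0, nF2 = 150),
                               seed = 22)
    x <- sim$genotypes
    gt <- genotypes(x)[, sampleRoles(x) == "F2"]
    flip <- sim$truth$loci$flipped
    gt[flip, ] <- 2L - gt[flip, , drop = FALSE]
    freq <- table(gt) / length(gt)
    n <- length(gt)
    for (k in c("0", "1", "2")) {
        expected <- ifelse(k == "1", 0.5, 0.25)
        ## pooled cells are not independent (shared gametes are not used
        ## here: no blocks), 3 binomial sd band
        expect_lt(abs(freq[[k]] - expected),
                  3 * sqrt(expected * (1 - expected) / n))
    }
})

test_that("transmission bias g shifts the F2 mean toward parental_A", {
    sim <- simulateHybridCross(noiseCfg(dFrac = 1, semiFrac = 0, g = 0.7,
                                        nF2 = 200), seed = 23)
    x <- sim$genotypes
    gt <- genotypes(x)[, sampleRoles(x) == "F2"]
    flip <- sim$truth$loci$flipped
    gt[flip, ] <- 2L - gt[flip, , drop = FALSE]
    ## E[genotype] = 2 (1 - g) = 0.6
    expect_lt(abs(mean(gt) - 0.6), 0.02)
})

test_that("heterozygote-advantage viability inflates het frequency and D", {
    sim <- simulateHybridCross(noiseCfg(dFrac = 1, semiFrac = 0,
                                        viability = c(1, 2, 1), nF2 = 200),
                               seed = 24)
    x <- sim$genotypes
    gt <- genotypes(x)[, sampleRoles(x) == "F2"]
    ## expected het frequency (1/2 * 2) / (1/4 + 1/2 * 2 + 1/4) = 2/3
    hetFreq <- mean(gt == 1L)
    expect_lt(abs(hetFreq - 2 / 3), 0.02)
    n0 <- rowSums(gt == 0L); n1 <- rowSums(gt == 1L); n2 <- rowSums(gt == 2L)
    expect_gt(mean(hwDStatistic(n0, n1, n2)$D > 0), 0.95)
})

test_that("missingness honours the per-run rates", {
    sim0 <- simulateHybridCross(noiseCfg(), seed = 25)
    expect_false(anyNA(genotypes(sim0$genotypes)))
    cfg <- simConfig(nLoci = 2000, nParentalA = 10, nParentalB = 10,
                     nF1 = 5, nF2 = 30, nBackcross = 5,
                     missingRates = c(run1 = 0.5, run2 = 0.1), pRun1 = 0.5,
                     nReplicates = 0, nContaminants = 0,
                     distortedBlocks = list())
    sim <- simulateHybridCross(cfg, seed = 26)
    naByInd <- colMeans(is.na(genotypes(sim$genotypes)))
    run <- sim$truth$runClass[names(naByInd)]
    for (r in c("run1", "run2")) {
        rate <- cfg$missingRates[[r]]
        tol <- 4 * sqrt(rate * (1 - rate) / 2000)
        expect_true(all(abs(naByInd[run == r] - rate) < tol))
    }
})

test_that("replicates are exact copies at zero discordance, pre-masking", {
    sim <- simulateHybridCross(
        simConfig(nLoci = 300, nParentalA = 8, nParentalB = 8, nF1 = 5,
                  nF2 = 20, nBackcross = 4, missingRates = c(0, 0),
                  nReplicates = 10, errorRate = 0, nContaminants = 0,
                  distortedBlocks = list()),
        seed = 27)
    gt <- genotypes(sim$genotypes)
    rp <- sim$truth$replicatePairs
    expect_identical(nrow(rp), 10L)
    for (i in seq_len(nrow(rp)))
        expect_identical(gt[, rp$id1[i]], gt[, rp$id2[i]],
                         ignore_attr = TRUE)
    ## with discordance, copies differ at roughly the requested rate
    sim2 <- simulateHybridCross(
        simConfig(nLoci = 2000, nParentalA = 8, nParentalB = 8, nF1 = 5,
                  nF2 = 20, nBackcross = 4, missingRates = c(0, 0),
                  nReplicates = 5, errorRate = 0.05, nContaminants = 0,
                  distortedBlocks = list()),
        seed = 28)
    gt2 <- genotypes(sim2$genotypes)
    rp2 <- sim2$truth$replicatePairs
    disc <- mean(gt2[, rp2$id1[1]] != gt2[, rp2$id2[1]])
    expect_lt(abs(disc - 0.05), 0.02)
})

test_that("block ranges are validated and contaminants recorded", {
    expect_error(simulateHybridCross(
        noiseCfg(distortedBlocks = list(list(chrom = "Chr99", g = 0.7))),
        seed = 29), "unknown")
    sim <- simulateHybridCross(
        simConfig(nLoci = 300, nParentalA = 8, nParentalB = 8, nF1 = 5,
                  nF2 = 30, nBackcross = 4, missingRates = c(0, 0),
                  nReplicates = 0, nContaminants = 2,
                  distortedBlocks = list()),
        seed = 30)
    expect_identical(nrow(sim$truth$contaminants), 2L)
    expect_true(all(sim$truth$contaminants$id %in%
                    colnames(sim$genotypes)))
})

test_that("sim bundle writes readable VCF, popmap, roles and truth", {
    sim <- simulateHybridCross(simConfig(nLoci = 50, nParentalA = 4,
                                         nParentalB = 4, nF1 = 3, nF2 = 6,
                                         nBackcross = 2, nReplicates = 2,
                                         nContaminants = 0,
                                         distortedBlocks = list()),
                               seed = 31)
    dir <- tempfile()
    writeSimBundle(sim, dir)
    map <- readPopulationMap(file.path(dir, "popmap.tsv"),
                             file.path(dir, "roles.yaml"))
    x <- readGenotypeVcf(file.path(dir, "genotypes.vcf"), popmap = map)
    expect_identical(unname(genotypes(x)),
                     unname(genotypes(sim$genotypes)))
    expect_identical(unname(sampleRoles(x)),
                     unname(sampleRoles(sim$genotypes)))
})
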