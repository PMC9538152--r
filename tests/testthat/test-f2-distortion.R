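test_that("exact HW test matches hand-enumerated Levene cases", {
    ## (0,2,0): het counts {0,2} have P(2) = 2/3 >= P(0) = 1/3, obs = 2 -> 1
    expect_equal(hwExactTest(0, 2, 0), 1)
    ## (1,0,1): observed het 0 has P 1/3 < P(2) = 2/3 -> p = 1/3
    expect_equal(hwExactTest(1, 0, 1), 1 / 3)
    ## modal expectation at n = 100
    expect_gte(hwExactTest(25, 50, 25), 0.99)
    ## monomorphic convention
    expect_equal(hwExactTest(10, 0, 0), 1)
    expect_equal(hwExactTest(0, 0, 7), 1)
    ## mid-p is smaller but at most the standard p
    expect_lt(hwExactTest(3, 10, 3, midp = TRUE), hwExactTest(3, 10, 3))
})

test_that("exact HW test equals the configuration-enumeration oracle", {
    set.seed(91)
    for (i in 1:60) {
        n <- sample(2:40, 1)
        n1 <- sample(0:n, 1)
        n0 <- sample(0:(n - n1), 1)
        n2 <- n - n1 - n0
        expect_equal(hwExactTest(n0, n1, n2), hwOracle(n0, n1, n2),
                     tolerance = 1e-10,
                     label = sprintf("counts (%d,%d,%d)", n0, n1, n2))
    }
})

test_that("Levene probabilities sum to one over compatible het counts", {
    set.seed(92)
    for (i in 1:30) {
        n <- sample(1:500, 1)
        nA <- sample(0:(2 * n), 1)
        lp <- introscan:::.leveneLogProb(n, nA)
        expect_equal(sum(exp(lp)), 1, tolerance = 1e-10)
    }
})

test_that("D statistic and homozygote-excess flags follow the definitions", {
    d <- hwDStatistic(c(25, 0, 50), c(50, 100, 0), c(25, 0, 50))
    expect_equal(d$D, c(0, 25, -25))
    expect_identical(d$homExcess[3], "both")
    ## single-sided homozygote excess
    d2 <- hwDStatistic(60, 20, 20)   # p = 0.7: E(n0) = 49, E(n2) = 9
    expect_lt(d2$D, 0)
    expect_identical(d2$homExcess, "both")
    d3 <- hwDStatistic(36, 48, 16)   # exact HW at p 0.6
    expect_equal(d3$D, 0)
    expect_identical(d3$homExcess, "none")
})

.f2Fixture <- function(...) {
    rows <- list(...)
    gt <- do.call(rbind, rows)
    rownames(gt) <- paste0("L", seq_along(rows))
    colnames(gt) <- paste0("x", seq_len(ncol(gt)))
    HybridGenotypes(gt, group = rep("f2", ncol(gt)),
                    role = rep("F2", ncol(gt)))
}

test_that("transmission test direction and degenerate rules", {
    x <- .f2Fixture(c(0L, 2L, 0L, 2L),
                    c(0L, 0L, 0L, 0L),
                    c(2L, 2L, 2L, 1L),
                    c(2L, 2L, 2L, 2L))
    res <- f2Distortion(x)
    expect_equal(res$mean, c(1, 0, 1.75, 2))
    expect_equal(res$t[1], 0)
    expect_equal(res$p_t[1], 1)
    expect_identical(res$direction, c("none", "toward_A", "none", "toward_B"))
    expect_equal(res$p_t[3], 2 * pt(-3, 3), tolerance = 1e-9)
    ## unanalyzable locus: fewer than 2 genotypes
    x2 <- .f2Fixture(c(1L, NA, NA, NA))
    res2 <- f2Distortion(x2)
    expect_false(res2$analyzable)
    expect_true(is.na(res2$category))
})

test_that("category mapping is total, deterministic, and matches the defined cases", {
    grid <- expand.grid(direction = c("none", "toward_A", "toward_B"),
                        hwFail = c(FALSE, TRUE),
                        D = c(-3, 3),
                        homExcess = c("none", "A", "B", "both"),
                        stringsAsFactors = FALSE)
    cls <- classifyDistortion(grid$direction, grid$hwFail, grid$D,
                              grid$homExcess)
    expect_false(anyNA(cls$category))
    ## deterministic: same input, same output
    cls2 <- classifyDistortion(grid$direction, grid$hwFail, grid$D,
                               grid$homExcess)
    expect_identical(cls, cls2)
    one <- function(dir, hw, D, hom = "none")
        as.character(classifyDistortion(dir, hw, D, hom)$category)
    expect_identical(one("none", FALSE, 2), "NEUTRAL")
    expect_identical(one("toward_A", FALSE, 1), "A_SHIFT_HWE")
    expect_identical(one("none", TRUE, 12), "HET_EXCESS_BALANCED")
    expect_identical(one("none", TRUE, -5, "both"), "HOM_EXCESS_BOTH")
    expect_identical(one("toward_A", TRUE, -4, "A"), "A_SHIFT_A_HOM_EXCESS")
    expect_identical(one("toward_B", TRUE, 4), "B_SHIFT_HET_EXCESS")
    ## off-table combination maps to nearest category with anomaly flag
    odd <- classifyDistortion("toward_B", TRUE, -4, "B")
    expect_identical(as.character(odd$category), "B_SHIFT_HWE")
    expect_true(odd$anomaly)
    oddA <- classifyDistortion("toward_A", TRUE, -4, "B")
    expect_identical(as.character(oddA$category), "A_SHIFT_A_HOM_EXCESS")
    expect_true(oddA$anomaly)
})

test_that("cohort summary counts, tallies and percentage bookkeeping", {
    x <- .f2Fixture(c(0L, 2L, 0L, 2L, 1L, 1L),
                    c(1L, 1L, 1L, 1L, 1L, 1L),
                    c(0L, 0L, 0L, 0L, 0L, 0L),
                    c(NA, NA, NA, NA, NA, 1L))
    res <- f2Distortion(x)
    s <- cohortSummary(res, label = "toy")
    expect_identical(s$nAnalyzable, 3L)
    expect_equal(sum(s$categories$pct), 100, tolerance = 0.05)
    expect_identical(s$nSigT,
                     sum(res$direction != "none" & res$analyzable))
    ## all-HW-pass data yields no HW-derived categories
    expect_identical(
        sum(s$categories$count[s$categories$category %in%
            c("HET_EXCESS_BALANCED", "HOM_EXCESS_BOTH")]), 0L)
})

test_that("chromosome profile orders loci and routes unmapped to NA track", {
    res <- data.frame(locus = c("a", "b", "c", "d"),
                      chrom = c("Chr2", "Chr1", NA, "Chr1"),
                      pos = c(10L, 500L, 7L, 20L),
                      t = c(0, 0, 0, 0),
                      direction = rep("none", 4),
                      analyzable = TRUE)
    prof <- chromosomeProfile(res)
    expect_identical(prof$locus, c("d", "b", "a", "c"))
    expect_identical(prof$chrom[4], "NA")
    expect_false(any(prof$significant))
})

test_that("a transmission-biased block concentrates significant loci", {
    sim <- simulateHybridCross(
        simConfig(nLoci = 1500, dFrac = 0.4, semiFrac = 0.2,
                  nParentalA = 15, nParentalB = 15, nF1 = 8, nF2 = 80,
                  nBackcross = 2, missingRates = c(0, 0),
                  nReplicates = 0, nContaminants = 0,
                  distortedBlocks = list(list(chrom = "Chr3", g = 0.75))),
        seed = 303)
    x <- classifyPanel(discriminantScores(polarizeGenotypes(sim$genotypes)))
    res <- f2Distortion(x)
    onBlock <- res$chrom == "Chr3"
    sig <- res$direction == "toward_A"
    expect_gt(mean(sig[onBlock]), 0.9)
    ## permutation test of positional enrichment of significant loci
    obs <- sum(sig & onBlock)
    set.seed(1)
    perm <- replicate(999, sum(sample(sig) & onBlock))
    pPerm <- (1 + sum(perm >= obs)) / 1000
    expect_lt(pPerm, 0.05)
})
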