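test_that("polarization orients each locus to the parental_A major allele", {
    ## L1 already A-major (freq 5/6); L2 needs flipping (ref freq 1/6);
    ## L3 tied (ambiguous)
    gt <- rbind(L1 = c(0L, 0L, 1L, 0L),
                L2 = c(2L, 2L, 1L, 0L),
                L3 = c(1L, 1L, NA, 2L))
    colnames(gt) <- c("a1", "a2", "a3", "b1")
    x <- HybridGenotypes(gt, group = c("A", "A", "A", "B"),
                         role = c(rep("parental_A", 3), "parental_B"))
    p <- polarizeGenotypes(x)
    expect_identical(rowData(p)$polarity, c("as-is", "flipped", "ambiguous"))
    expect_identical(unname(genotypes(p)["L1", ]), c(0L, 0L, 1L, 0L))
    ## flipped locus recodes everyone, parental_B's 0 becomes 2
    expect_identical(unname(genotypes(p)["L2", ]), c(0L, 0L, 1L, 2L))
    ## tied allele frequencies: orientation kept as-is
    expect_identical(unname(genotypes(p)["L3", ]), c(1L, 1L, NA, 2L))
})

test_that("polarizing an already-polarized matrix changes nothing", {
    set.seed(41)
    gt <- matrix(sample(c(0:2, NA), 200, TRUE, c(.4, .2, .3, .1)), nrow = 20)
    colnames(gt) <- paste0("i", 1:10)
    x <- HybridGenotypes(gt, group = rep(c("A", "B"), each = 5),
                         role = rep(c("parental_A", "parental_B"), each = 5))
    p1 <- suppressWarnings(polarizeGenotypes(x))
    p2 <- suppressWarnings(polarizeGenotypes(p1))
    expect_identical(genotypes(p2), genotypes(p1))
    expect_identical(rowData(p2)$polarity == "ambiguous",
                     rowData(p1)$polarity == "ambiguous")
})

.scoreFixture <- function(gA, gB) {
    gt <- rbind(L1 = c(gA, gB))
    colnames(gt) <- paste0("i", seq_along(c(gA, gB)))
    x <- HybridGenotypes(gt,
                         group = rep(c("A", "B"), c(length(gA), length(gB))),
                         role = rep(c("parental_A", "parental_B"),
                                    c(length(gA), length(gB))))
    rowData(x)$score <- NULL
    discriminantScores(x)
}

test_that("discriminant score is the mean of the two homozygote proportions", {
    expect_equal(rowData(.scoreFixture(c(0L, 0L, 0L), c(2L, 2L, 2L)))$score, 1)
    expect_equal(rowData(.scoreFixture(c(0L, 0L, 1L, 1L),
                                       c(2L, 2L, 2L, 2L)))$score, 0.75)
    expect_equal(rowData(.scoreFixture(c(0L, 0L, 0L, 1L),
                                       c(2L, 2L, 2L, 2L)))$score, 0.875)
    ## missing genotypes use non-missing denominators only
    expect_equal(rowData(.scoreFixture(c(0L, 0L, NA, NA),
                                       c(2L, NA, 2L, 2L)))$score, 1)
    ## a fully-missing parental side yields NA
    expect_true(is.na(rowData(.scoreFixture(c(NA, NA), c(2L, 2L)))$score))
})

test_that("score is invariant to individual order and to flipping", {
    set.seed(43)
    gA <- sample(c(0:2, NA), 12, TRUE, c(.6, .2, .1, .1))
    gB <- sample(c(0:2, NA), 12, TRUE, c(.1, .2, .6, .1))
    s1 <- rowData(.scoreFixture(gA, gB))$score
    perm <- sample(12)
    s2 <- rowData(.scoreFixture(gA[perm], gB[perm]))$score
    expect_equal(s1, s2)
    ## score computed on flipped codes with swapped sides is identical
    s3 <- rowData(.scoreFixture(2L - gB, 2L - gA))$score
    expect_equal(s1, s3)
})

test_that("panel classification uses strict threshold and polarity", {
    gt <- matrix(rep(c(0L, 2L), c(4, 4)), nrow = 1,
                 dimnames = list("L1", paste0("i", 1:8)))
    x <- HybridGenotypes(gt, group = rep(c("A", "B"), each = 4),
                         role = rep(c("parental_A", "parental_B"), each = 4))
    x <- discriminantScores(polarizeGenotypes(x))
    scores <- c(1, 0.95, 0.9, 0.75, 0.5, 0.4)
    cls <- vapply(scores, function(s) {
        rowData(x)$score <- s
        rowData(classifyPanel(x, 0.9))$class
    }, character(1))
    expect_identical(cls, c("diagnostic", "discriminant", "semi-diagnostic",
                            "semi-diagnostic", "non-diagnostic",
                            "non-diagnostic"))
    inPanel <- vapply(scores, function(s) {
        rowData(x)$score <- s
        rowData(classifyPanel(x, 0.9))$inPanel
    }, logical(1))
    expect_identical(inPanel, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
    expect_error(classifyPanel(x, 1.2), "between 0 and 1")
    ## ambiguous polarity is excluded from the panel even with score 1
    rowData(x)$score <- 1
    rowData(x)$polarity <- "ambiguous"
    expect_false(rowData(classifyPanel(x, 0.9))$inPanel)
})

test_that("chromosome enrichment matches the Pearson chi-square oracle", {
    mk <- function(chrom, inPanel) {
        gt <- matrix(0L, length(chrom), 2,
                     dimnames = list(NULL, c("a", "b")))
        x <- HybridGenotypes(gt, group = c("A", "B"),
                             role = c("parental_A", "parental_B"),
                             chrom = chrom, pos = seq_along(chrom))
        rowData(x)$inPanel <- inPanel
        x
    }
    ## identical panel proportion on every chromosome -> chi2 0, p 1
    x0 <- mk(rep(c("Chr1", "Chr2"), each = 10),
             rep(c(TRUE, FALSE), times = 10))
    e0 <- chromosomeEnrichment(x0)
    expect_equal(e0$statistic, 0)
    expect_equal(e0$p.value, 1)
    ## 2 x 2 table (10, 90) vs (30, 70): Pearson chi-square 12.5, df 1
    x1 <- mk(rep(c("Chr1", "Chr2"), each = 100),
             c(rep(c(TRUE, FALSE), c(10, 90)), rep(c(TRUE, FALSE), c(30, 70))))
    e1 <- chromosomeEnrichment(x1)
    expect_equal(e1$statistic, 12.5, tolerance = 1e-9)
    expect_identical(unname(e1$df), 1L)
    ## a single chromosome is not analyzable
    expect_error(chromosomeEnrichment(mk(rep("Chr1", 10), rep(TRUE, 10))),
                 "at least 2 chromosomes")
})

test_that("diagnostic fraction converges to the simulated d_frac", {
    for (seed in 1:3) {
        sim <- simulateHybridCross(
            simConfig(nLoci = 600, dFrac = 0.3, semiFrac = 0.2,
                      nParentalA = 25, nParentalB = 25, nF1 = 5, nF2 = 5,
                      nBackcross = 2, missingRates = c(0, 0),
                      nReplicates = 0, nContaminants = 0,
                      distortedBlocks = list()),
            seed = seed)
        x <- classifyPanel(discriminantScores(polarizeGenotypes(
            sim$genotypes)))
        dObs <- mean(rowData(x)$class == "diagnostic")
        ## binomial 3-sigma band around 0.3 at 600 loci
        expect_lt(abs(dObs - 0.3), 3 * sqrt(0.3 * 0.7 / 600))
        ## simulated diagnostic loci always score 1 without noise
        truthD <- sim$truth$loci$class == "diagnostic"
        expect_true(all(rowData(x)$score[truthD] == 1))
    }
})
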