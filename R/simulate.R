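#' Configuration for the synthetic two-species cross simulator
#'
#' Builds a validated configuration list for [simulateHybridCross()]. The
#' defaults emulate the design of a two-species laboratory cross panel:
#' two wild parental sides (split into two populations each), one F1
#' family bred from one genitor per side, an F1 x F1 intercross (F2) and a
#' backcross to parental_A; a genome of `nChrom` chromosomes; a mixture of
#' fixed inter-species differences (diagnostic loci), partially diverged
#' loci and shared polymorphism; two sequencing-run missingness regimes;
#' and injected technical replicates and contaminated samples.
#'
#' @param nLoci number of biallelic SNP loci (default 5000).
#' @param dFrac fraction of diagnostic loci (fixed inter-species
#'   differences; default 0.12).
#' @param semiFrac fraction of partially diverged loci, with side-specific
#'   major-allele frequencies drawn from Uniform(0.8, 1) (default 0.25).
#'   The remainder is shared polymorphism at a common frequency.
#' @param nParentalA,nParentalB,nF1,nF2,nBackcross group sizes
#'   (defaults 20, 20, 19, 166, 15).
#' @param g baseline gametic transmission probability of the
#'   parental_A-derived haplotype in F1 gametes (0.5 = Mendelian).
#' @param viability zygotic viability weights `(w0, w1, w2)` per genotype
#'   (default `c(1, 1, 1)`); selection by rejection sampling, so genotype
#'   frequencies are proportional to Mendelian expectation times weight.
#' @param distortedBlocks list of blocks, each a list with `chrom` and
#'   optional `start`/`end` (indices among the chromosome's loci; default
#'   whole chromosome), and a `g` and/or `viability` override. Loci of a
#'   block with a `g` override share one crossover-free gamete per meiosis
#'   (complete linkage). The default places a transmission-biased region
#'   (g = 0.7) on Chr5 and Chr20.
#' @param missingRates per-run missingness rates (default
#'   `c(run1 = 0.5, run2 = 0.1)`, the two sequencing-depth regimes).
#' @param pRun1 probability an individual belongs to the shallow run.
#' @param nReplicates number of individuals duplicated as technical
#'   replicates (default 30).
#' @param errorRate per-locus genotype discordance between an individual
#'   and its replicate (default 0).
#' @param genotypeErrorRate per-cell miscall probability applied to every
#'   individual's genotypes (uniform over the two wrong codes; default 0).
#' @param nContaminants number of injected contaminated samples, each a
#'   random union of gametes from two same-group individuals (default 2).
#' @param nChrom number of chromosomes (default 25).
#' @return A list of class `"SimConfig"`.
#' @export
simConfig <- function(nLoci = 5000L, dFrac = 0.12, semiFrac = 0.25,
                      nParentalA = 20L, nParentalB = 20L, nF1 = 19L,
                      nF2 = 166L, nBackcross = 15L,
                      g = 0.5, viability = c(1, 1, 1),
                      distortedBlocks = list(
                          list(chrom = "Chr5", g = 0.7),
                          list(chrom = "Chr20", g = 0.7)),
                      missingRates = c(run1 = 0.5, run2 = 0.1),
                      pRun1 = 0.2, nReplicates = 30L, errorRate = 0,
                      genotypeErrorRate = 0, nContaminants = 2L,
                      nChrom = 25L) {
    stopifnot(nLoci >= 1, dFrac >= 0, semiFrac >= 0, dFrac + semiFrac <= 1,
              g >= 0, g <= 1, length(viability) == 3L, all(viability >= 0),
              any(viability > 0), all(missingRates >= 0),
              all(missingRates <= 1), errorRate >= 0, errorRate <= 1,
              genotypeErrorRate >= 0, genotypeErrorRate <= 1,
              pRun1 >= 0, pRun1 <= 1)
    if (length(missingRates) != 2L || is.null(names(missingRates)))
        names(missingRates) <- c("run1", "run2")
    cfg <- list(nLoci = as.integer(nLoci), dFrac = dFrac, semiFrac = semiFrac,
                nParentalA = as.integer(nParentalA),
                nParentalB = as.integer(nParentalB),
                nF1 = as.integer(nF1), nF2 = as.integer(nF2),
                nBackcross = as.integer(nBackcross),
                g = g, viability = as.numeric(viability),
                distortedBlocks = distortedBlocks,
                missingRates = missingRates, pRun1 = pRun1,
                nReplicates = as.integer(nReplicates), errorRate = errorRate,
                genotypeErrorRate = genotypeErrorRate,
                nContaminants = as.integer(nContaminants),
                nChrom = as.integer(nChrom))
    class(cfg) <- "SimConfig"
    cfg
}

#' Simulate a two-species cross SNP dataset with known truth
#'
#' Generates wild parental populations, F1 hybrids (one genitor per side),
#' an F2 intercross with optional gametic transmission bias and zygotic
#' viability selection, a backcross to parental_A, and then injects
#' technical replicates, contaminated samples and run-dependent
#' missingness. Locus orientation is randomized, so downstream
#' polarization has real work to do. Output is fully deterministic given
#' `seed`.
#'
#' Genetics: each F1 carries one parental_A-derived and one
#' parental_B-derived haplotype per locus. An F1 gamete transmits the
#' A-derived haplotype with probability `g` (0.5 = Mendelian; at
#' diagnostic loci this is a bias toward the parental_A allele). Blocks
#' with a `g` override are transmitted as one crossover-free unit.
#' Viability selection accepts each zygote genotype with probability
#' `w[genotype] / max(w)` and redraws rejections per locus.
#'
#' @param config a [simConfig()] list.
#' @param seed integer random seed (sets the R RNG).
#' @return list with elements
#' \describe{
#'   \item{`genotypes`}{a [HybridGenotypes-class] object (all individuals,
#'     missingness applied);}
#'   \item{`truth`}{ground truth: `loci` (per-locus class, orientation,
#'     allele frequencies, g, viability, block membership),
#'     `replicatePairs`, `contaminants`, `runClass`;}
#'   \item{`config`}{the configuration used.}
#' }
#' @examples
#' sim <- simulateHybridCross(simConfig(nLoci = 200, nF2 = 40), seed = 7)
#' sim$genotypes
#' head(sim$truth$loci)
#' @export
simulateHybridCross <- function(config = simConfig(), seed = 1L) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(seed)
    cfg <- config
    L <- cfg$nLoci

    ## ---- genome ----
    chrom <- paste0("Chr", sample.int(cfg$nChrom, L, replace = TRUE))
    pos <- sample.int(5e7L, L, replace = TRUE)
    ord <- order(as.integer(sub("Chr", "", chrom)), pos)
    chrom <- chrom[ord]; pos <- pos[ord]
    locusIds <- sprintf("L%05d", seq_len(L))
    gene <- sprintf("gene%05d", cumsum(c(1L, rbinom(L - 1L, 1L, 0.85))))

    ## ---- locus classes and side allele frequencies (B-allele freq) ----
    classes <- sample(c("diagnostic", "semi", "shared"), L, replace = TRUE,
                      prob = c(cfg$dFrac, cfg$semiFrac,
                               1 - cfg$dFrac - cfg$semiFrac))
    pB_A <- pB_B <- numeric(L)                 # B-allele freq per side
    isD <- classes == "diagnostic"
    isS <- classes == "semi"
    isC <- classes == "shared"
    pB_A[isD] <- 0;                 pB_B[isD] <- 1
    pB_A[isS] <- runif(sum(isS), 0, 0.2)
    pB_B[isS] <- runif(sum(isS), 0.8, 1)
    f <- runif(sum(isC), 0.05, 0.95)
    pB_A[isC] <- f;                 pB_B[isC] <- f

    ## ---- per-locus transmission bias and viability ----
    gLoc <- rep(cfg$g, L)
    wLoc <- matrix(cfg$viability, nrow = 3L, ncol = L)
    inBlock <- rep(FALSE, L)
    blockId <- rep(NA_integer_, L)
    linked <- rep(FALSE, L)
    for (b in seq_along(cfg$distortedBlocks)) {
        blk <- cfg$distortedBlocks[[b]]
        onChrom <- which(chrom == blk$chrom)
        if (!length(onChrom))
            stop("distorted block on unknown/empty chromosome: ", blk$chrom)
        from <- if (is.null(blk$start)) 1L else blk$start
        to <- if (is.null(blk$end)) length(onChrom) else blk$end
        if (from < 1L || to > length(onChrom) || from > to)
            stop("block range outside the locus set on ", blk$chrom)
        loci <- onChrom[from:to]
        inBlock[loci] <- TRUE
        blockId[loci] <- b
        if (!is.null(blk$g)) {
            gLoc[loci] <- blk$g
            linked[loci] <- TRUE
        }
        if (!is.null(blk$viability))
            wLoc[, loci] <- blk$viability
    }

    ## ---- wild parental populations (HW draws per side) ----
    drawSide <- function(pB, nInd)
        matrix(rbinom(L * nInd, 2L, rep(pB, nInd)), nrow = L)
    gtA <- drawSide(pB_A, cfg$nParentalA)
    gtB <- drawSide(pB_B, cfg$nParentalB)

    ## ---- genitors (haplotypes) and F1 family ----
    drawHap <- function(pB) rbinom(L, 1L, pB)
    genitorA <- cbind(drawHap(pB_A), drawHap(pB_A))   # F1 sire, A side
    genitorB <- cbind(drawHap(pB_B), drawHap(pB_B))   # F1 dam, B side
    bcDamA <- cbind(drawHap(pB_A), drawHap(pB_A))     # backcross dam, A side
    pickHap <- function(haps) {
        sel <- rbinom(L, 1L, 0.5)
        ifelse(sel == 1L, haps[, 1L], haps[, 2L])
    }
    hapA_F1 <- matrix(0L, L, cfg$nF1)     # parental_A-derived haplotype
    hapB_F1 <- matrix(0L, L, cfg$nF1)
    for (j in seq_len(cfg$nF1)) {
        hapA_F1[, j] <- pickHap(genitorA)
        hapB_F1[, j] <- pickHap(genitorB)
    }
    gtF1 <- hapA_F1 + hapB_F1

    ## F1 gamete with transmission bias and block linkage
    blockLoci <- split(which(linked), blockId[linked])
    f1Gamete <- function(parent) {
        choiceA <- rbinom(L, 1L, gLoc)    # 1 = transmit A-derived haplotype
        for (loci in blockLoci)
            choiceA[loci] <- rbinom(1L, 1L, gLoc[loci[1L]])
        ifelse(choiceA == 1L, hapA_F1[, parent], hapB_F1[, parent])
    }

    ## ---- F2 intercross with viability selection ----
    nGenitorsF2 <- min(8L, cfg$nF1)
    gtF2 <- matrix(0L, L, cfg$nF2)
    moF2 <- faF2 <- integer(cfg$nF2)
    for (j in seq_len(cfg$nF2)) {
        pair <- sample.int(nGenitorsF2, 2L)
        moF2[j] <- pair[1L]; faF2[j] <- pair[2L]
        gtF2[, j] <- f1Gamete(pair[1L]) + f1Gamete(pair[2L])
    }
    selected <- which(apply(wLoc, 2L, function(w) length(unique(w)) > 1L))
    if (length(selected) && cfg$nF2 > 0L) {
        wMax <- apply(wLoc, 2L, max)
        ## per-cell rejection sampling: each proposal is tested once and,
        ## if rejected, both transmitted alleles at that cell are redrawn
        pend <- cbind(li = rep(selected, times = cfg$nF2),
                      jj = rep(seq_len(cfg$nF2), each = length(selected)))
        repeat {
            g <- gtF2[pend]
            acc <- runif(nrow(pend)) <
                wLoc[cbind(g + 1L, pend[, 1L])] / wMax[pend[, 1L]]
            pend <- pend[!acc, , drop = FALSE]
            if (!nrow(pend)) break
            li <- pend[, 1L]; jj <- pend[, 2L]
            gm <- ifelse(rbinom(nrow(pend), 1L, gLoc[li]) == 1L,
                         hapA_F1[cbind(li, moF2[jj])],
                         hapB_F1[cbind(li, moF2[jj])])
            gf <- ifelse(rbinom(nrow(pend), 1L, gLoc[li]) == 1L,
                         hapA_F1[cbind(li, faF2[jj])],
                         hapB_F1[cbind(li, faF2[jj])])
            gtF2[cbind(li, jj)] <- gm + gf
        }
    }

    ## ---- backcross to parental_A ----
    gtBC <- matrix(0L, L, cfg$nBackcross)
    for (j in seq_len(cfg$nBackcross)) {
        sire <- sample.int(cfg$nF1, 1L)
        gtBC[, j] <- pickHap(bcDamA) + f1Gamete(sire)
    }

    ## ---- assemble, randomize orientation ----
    gt <- cbind(gtA, gtB, gtF1, gtF2, gtBC)
    halfA <- ceiling(cfg$nParentalA / 2)
    halfB <- ceiling(cfg$nParentalB / 2)
    group <- c(rep(c("A_pop1", "A_pop2"),
                   c(halfA, cfg$nParentalA - halfA)),
               rep(c("B_pop1", "B_pop2"),
                   c(halfB, cfg$nParentalB - halfB)),
               rep("F1_lab", cfg$nF1), rep("F2_lab", cfg$nF2),
               rep("BC_lab", cfg$nBackcross))
    role <- c(rep("parental_A", cfg$nParentalA),
              rep("parental_B", cfg$nParentalB),
              rep("F1", cfg$nF1), rep("F2", cfg$nF2),
              rep("backcross", cfg$nBackcross))
    ids <- paste0(group, "_", unlist(lapply(rle(group)$lengths, seq_len)))
    colnames(gt) <- ids
    rownames(gt) <- locusIds

    flipped <- rbinom(L, 1L, 0.5) == 1L
    gt[flipped, ] <- 2L - gt[flipped, , drop = FALSE]

    ## ---- genotyping error (uniform miscall to one of the other codes) ----
    if (cfg$genotypeErrorRate > 0) {
        err <- matrix(rbinom(length(gt), 1L, cfg$genotypeErrorRate) == 1L,
                      nrow(gt))
        shift <- matrix(sample.int(2L, length(gt), replace = TRUE), nrow(gt))
        gt[err] <- (gt[err] + shift[err]) %% 3L
    }

    ## ---- replicates ----
    repPairs <- data.frame(id1 = character(), id2 = character(),
                           stringsAsFactors = FALSE)
    if (cfg$nReplicates > 0L) {
        src <- sample(ids, min(cfg$nReplicates, length(ids)))
        repGt <- gt[, src, drop = FALSE]
        if (cfg$errorRate > 0) {
            err <- matrix(rbinom(length(repGt), 1L, cfg$errorRate) == 1L,
                          nrow(repGt))
            err[is.na(repGt)] <- FALSE
            shift <- matrix(sample.int(2L, length(repGt), replace = TRUE),
                            nrow(repGt))
            repGt[err] <- (repGt[err] + shift[err]) %% 3L
        }
        colnames(repGt) <- paste0(src, "_rep")
        gt <- cbind(gt, repGt)
        group <- c(group, group[match(src, ids)])
        role <- c(role, role[match(src, ids)])
        repPairs <- data.frame(id1 = src, id2 = colnames(repGt),
                               stringsAsFactors = FALSE)
        ids <- colnames(gt)
    }

    ## ---- contaminated samples (random union of two individuals' gametes) --
    contaminants <- data.frame(id = character(), source1 = character(),
                               source2 = character(), stringsAsFactors = FALSE)
    if (cfg$nContaminants > 0L) {
        baseIds <- setdiff(ids, repPairs$id2)
        grpOf <- setNames(group[match(baseIds, ids)], baseIds)
        ## contamination happens between co-housed samples; the chance a
        ## pair collides scales with cohort size, so draw sources from the
        ## largest group
        gsel <- names(which.max(table(grpOf)))
        for (k in seq_len(cfg$nContaminants)) {
            uv <- sample(baseIds[grpOf[baseIds] == gsel], 2L)
            g1 <- gt[, uv[1L]]; g2 <- gt[, uv[2L]]
            a1 <- rbinom(L, 1L, ifelse(is.na(g1), 0.5, g1 / 2))
            a2 <- rbinom(L, 1L, ifelse(is.na(g2), 0.5, g2 / 2))
            mixId <- paste0("MIX_", k)
            gt <- cbind(gt, setNames(data.frame(a1 + a2), mixId)[[1L]])
            colnames(gt)[ncol(gt)] <- mixId
            group <- c(group, gsel)
            role <- c(role, role[match(uv[1L], ids)])
            contaminants <- rbind(contaminants, data.frame(
                id = mixId, source1 = uv[1L], source2 = uv[2L],
                stringsAsFactors = FALSE))
            ids <- colnames(gt)
        }
    }

    ## ---- run classes and missingness ----
    runClass <- ifelse(rbinom(ncol(gt), 1L, cfg$pRun1) == 1L, "run1", "run2")
    names(runClass) <- colnames(gt)
    rate <- cfg$missingRates[runClass]
    if (any(rate > 0)) {
        mask <- matrix(rbinom(length(gt), 1L, rep(rate, each = nrow(gt))) == 1L,
                       nrow(gt))
        gt[mask] <- NA_integer_
    }

    x <- HybridGenotypes(gt, group = group, role = role,
                         chrom = chrom, pos = pos, gene = gene)
    truth <- list(
        loci = data.frame(locus = locusIds, chrom = chrom, pos = pos,
                          class = classes, flipped = flipped,
                          pB_A = pB_A, pB_B = pB_B, g = gLoc,
                          w0 = wLoc[1L, ], w1 = wLoc[2L, ], w2 = wLoc[3L, ],
                          inBlock = inBlock, blockId = blockId,
                          stringsAsFactors = FALSE),
        replicatePairs = repPairs,
        contaminants = contaminants,
        runClass = runClass)
    metadata(x)$simTruth <- truth
    list(genotypes = x, truth = truth, config = cfg)
}

#' Write a simulated dataset bundle to disk
#'
#' Writes the VCF, a Stacks-style popmap, a group-to-role YAML and the
#' ground-truth tables of a [simulateHybridCross()] result into a
#' directory.
#'
#' @param sim result of [simulateHybridCross()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeSimBundle <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    x <- sim$genotypes
    writeGenotypeVcf(x, file.path(dir, "genotypes.vcf"))
    write.table(data.frame(colnames(x), colData(x)$group),
                file.path(dir, "popmap.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    cd <- colData(x)
    roles <- tapply(as.character(cd$role), cd$group, function(r) r[1L])
    yaml::write_yaml(as.list(roles), file.path(dir, "roles.yaml"))
    write.table(sim$truth$loci, file.path(dir, "truth_loci.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sim$truth$replicatePairs,
                file.path(dir, "truth_replicates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}
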