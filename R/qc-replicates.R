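#' Pairwise genotype distance between individuals
#'
#' Euclidean distance on genotype codes: for individuals i and j,
#' \deqn{d_{ij} = \sqrt{ \frac{L}{n_{ij}} \sum_{\ell \in S_{ij}}
#'   (g_{i\ell} - g_{j\ell})^2 }}
#' where the sum runs over the loci non-missing in both individuals
#' (pairwise-complete), \eqn{n_{ij}} is the number of such loci and L the
#' total locus count. The \eqn{L/n_{ij}} rescaling keeps distances comparable
#' across pairs with different completeness. Pairs sharing no locus get an
#' `NA` distance.
#'
#' On complete data this is the plain Euclidean distance on genotype values
#' and satisfies the metric axioms. Technical replicates (identical DNA)
#' concentrate near zero, producing the low mode of the distance
#' distribution exploited by [detectReplicateThreshold()].
#'
#' @param x a [HybridGenotypes-class] object with at least 2 individuals.
#' @return A [GenotypeDistances-class] object.
#' @seealso [detectReplicateThreshold()], [resolveReplicates()]
#' @export
pairwiseGenotypeDistance <- function(x) {
    gt <- genotypes(x)
    if (ncol(gt) < 2L)
        stop("need at least 2 individuals")
    L <- nrow(gt)
    M <- !is.na(gt)                       # loci x ind indicator
    X <- gt; X[!M] <- 0L
    X <- matrix(as.numeric(X), nrow(gt), ncol(gt))
    Mn <- matrix(as.numeric(M), nrow(gt), ncol(gt))
    S <- X * X
    ## sum over shared loci of gi^2 + gj^2 - 2 gi gj
    cross <- crossprod(X)                 # sum gi gj over all loci (0-filled)
    sq1 <- crossprod(S, Mn)               # sum gi^2 over loci where j called
    ss <- sq1 + t(sq1) - 2 * cross
    nShared <- crossprod(Mn)
    d <- sqrt(pmax(ss, 0) * L / nShared)  # NaN where nShared == 0
    d[nShared == 0] <- NA_real_
    diag(d) <- 0
    dimnames(d) <- list(colnames(gt), colnames(gt))
    storage.mode(nShared) <- "integer"
    dimnames(nShared) <- dimnames(d)
    new("GenotypeDistances", distance = d, nShared = nShared,
        nLoci = as.integer(L))
}

#' Replicate distance threshold from the multimodal distance distribution
#'
#' Technical replicates produce a distinct low mode in the distribution of
#' pairwise genotype distances. The default method fits a Gaussian kernel
#' density (Silverman bandwidth) to the distances and returns the distance
#' at the first local minimum after the first mode (the valley separating
#' replicate pairs from unrelated pairs). Two overrides are available:
#' a manual threshold, and a lowest-k rule that flags exactly the k smallest
#' distances.
#'
#' @param gd a [GenotypeDistances-class] object with at least 10 pairs.
#' @param method `"valley"` (default), `"lowestK"` or `"manual"`.
#' @param k for `"lowestK"`: number of smallest distances to flag; the
#'   threshold is placed halfway between the k-th and (k+1)-th smallest.
#' @param threshold for `"manual"`: the threshold itself.
#' @return A single numeric distance threshold. Pairs strictly below it are
#'   treated as replicate candidates. A unimodal distribution with no valley
#'   yields 0 with a warning (nothing flagged).
#' @export
detectReplicateThreshold <- function(gd, method = c("valley", "lowestK",
                                                    "manual"),
                                     k = NULL, threshold = NULL) {
    method <- match.arg(method)
    d <- distanceMatrix(gd)
    dd <- sort(d[upper.tri(d)])
    dd <- dd[!is.na(dd)]
    if (length(dd) < 10L)
        stop("need at least 10 pairwise distances")
    switch(method,
           manual = {
               stopifnot(is.numeric(threshold), threshold >= 0)
               threshold
           },
           lowestK = {
               stopifnot(is.numeric(k), k >= 1, k < length(dd))
               (dd[k] + dd[k + 1L]) / 2
           },
           valley = {
               if (max(dd) - min(dd) < .Machine$double.eps^0.5) {
                   warning("degenerate distance distribution; threshold 0")
                   return(0)
               }
               dens <- density(dd, bw = "nrd0")
               y <- dens$y
               n <- length(y)
               isMin <- c(FALSE, y[2:(n - 1)] < y[1:(n - 2)] &
                                 y[2:(n - 1)] <= y[3:n], FALSE)
               isMax <- c(y[1] > y[2],
                          y[2:(n - 1)] > y[1:(n - 2)] &
                          y[2:(n - 1)] >= y[3:n], FALSE)
               firstMax <- which(isMax)[1L]
               valley <- which(isMin & seq_len(n) > firstMax)[1L]
               if (is.na(valley)) {
                   warning("unimodal distance distribution; threshold 0 ",
                           "(no replicates detected)")
                   return(0)
               }
               dens$x[valley]
           })
}

#' Detect and deduplicate technical replicates
#'
#' Pairs with distance strictly below the threshold are clustered by
#' transitive closure. Within each cluster the individual with the least
#' missingness is kept (ties broken by lexicographic id) and the others
#' removed. Clusters containing no declared replicate pair are reported as
#' contamination candidates (genetically near-identical samples that should
#' not be) but are still deduplicated. Declared replicate pairs lying above
#' the threshold are checked for mutual-nearest-neighbour status and
#' reported; both members are kept.
#'
#' @param x the [HybridGenotypes-class] object the distances were computed
#'   from.
#' @param gd a [GenotypeDistances-class] object.
#' @param threshold replicate distance threshold (see
#'   [detectReplicateThreshold()]).
#' @param declared optional data.frame with columns `id1`, `id2` listing
#'   known replicate pairs (DNA or tissue replicates).
#' @return A [ReplicateReport-class] object; apply it with
#'   [dropReplicates()].
#' @export
resolveReplicates <- function(x, gd, threshold, declared = NULL) {
    d <- distanceMatrix(gd)
    ids <- rownames(d)
    if (!is.null(declared)) {
        stopifnot(all(c("id1", "id2") %in% colnames(declared)))
        missing <- setdiff(c(declared$id1, declared$id2), ids)
        if (length(missing))
            stop("declared replicate id(s) absent from matrix: ",
                 paste(missing, collapse = ", "))
    }
    below <- which(upper.tri(d) & !is.na(d) & d < threshold, arr.ind = TRUE)
    ## transitive closure via union-find
    parent <- seq_along(ids)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (r in seq_len(nrow(below))) {
        a <- find(below[r, 1L]); b <- find(below[r, 2L])
        if (a != b) parent[max(a, b)] <- min(a, b)
    }
    comp <- vapply(seq_along(ids), find, integer(1))
    clusters <- split(ids, comp)
    clusters <- unname(clusters[lengths(clusters) >= 2L])

    naFrac <- colMeans(is.na(genotypes(x)))[ids]
    kept <- vapply(clusters, function(cl) {
        cl[order(naFrac[cl], cl)][1L]
    }, character(1))
    removed <- as.character(setdiff(unlist(clusters), kept))

    pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    declaredKeys <- if (is.null(declared)) character() else
        pairKey(declared$id1, declared$id2)

    flagged <- data.frame(id1 = character(), id2 = character(),
                          distance = numeric(), stringsAsFactors = FALSE)
    if (nrow(below)) {
        b1 <- ids[below[, 1L]]; b2 <- ids[below[, 2L]]
        isDecl <- pairKey(b1, b2) %in% declaredKeys
        flagged <- data.frame(id1 = pmin(b1, b2)[!isDecl],
                              id2 = pmax(b1, b2)[!isDecl],
                              distance = d[below][!isDecl],
                              stringsAsFactors = FALSE)
    }

    mutual <- data.frame(id1 = character(), id2 = character(),
                         distance = numeric(), stringsAsFactors = FALSE)
    if (!is.null(declared) && nrow(declared)) {
        dNoSelf <- d; diag(dNoSelf) <- NA
        nearest <- ids[apply(dNoSelf, 1L, which.min)]
        names(nearest) <- ids
        for (r in seq_len(nrow(declared))) {
            a <- declared$id1[r]; b <- declared$id2[r]
            dist <- d[a, b]
            if (!is.na(dist) && dist >= threshold &&
                identical(nearest[[a]], b) && identical(nearest[[b]], a)) {
                mutual <- rbind(mutual, data.frame(
                    id1 = min(a, b), id2 = max(a, b), distance = dist,
                    stringsAsFactors = FALSE))
            }
        }
    }
    new("ReplicateReport", threshold = threshold, clusters = clusters,
        kept = kept, removed = removed, flaggedContaminants = flagged,
        mutualNearest = mutual)
}

#' @rdname resolveReplicates
#' @param report a [ReplicateReport-class] object.
#' @return `dropReplicates()`: `x` without the removed individuals.
#' @export
dropReplicates <- function(x, report) {
    x <- x[, !colnames(x) %in% report@removed]
    metadata(x)$replicateReport <- report
    x
}
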