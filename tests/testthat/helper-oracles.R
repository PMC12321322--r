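# Independent oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and, where possible, the
# library calls) they are checking.

# Pearson chi-square by the definitional formula sum((O - E)^2 / E);
# Yates continuity correction subtracts min(0.5, |O - E|) for 2x2 tables.
oracleChisq <- function(tab, yates = FALSE) {
    tab <- as.matrix(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (yates && all(dim(tab) == 2L)) {
        d <- abs(tab - E)
        sum((d - pmin(0.5, d))^2 / E)
    } else {
        sum((tab - E)^2 / E)
    }
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# choose(n, nA) group labelings (valid without ties).
oracleMwuExact <- function(a, b) {
    pooled <- c(a, b)
    nA <- length(a)
    r <- rank(pooled)
    uObs <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
    labelings <- utils::combn(length(pooled), nA)
    uAll <- apply(labelings, 2L, function(idx)
        sum(r[idx]) - nA * (nA + 1) / 2)
    pLess <- mean(uAll <= uObs)
    pMore <- mean(uAll >= uObs)
    list(u = uObs, p = min(1, 2 * min(pLess, pMore)))
}

# Jaccard of two gene-id sets by direct set arithmetic.
oracleJaccard <- function(s1, s2) {
    u <- union(s1, s2)
    if (length(u) == 0L) return(0)
    length(intersect(s1, s2)) / length(u)
}

# 0-based half-open interval overlap by arithmetic on a pair of rows.
oracleOverlap <- function(chromA, startA, endA, chromB, startB, endB) {
    chromA == chromB && max(startA, startB) < min(endA, endB)
}

# Small association-table fixture builder.
makeAssoc <- function(variant, gene, tissue, p, slope = 0.5) {
    data.frame(variant_id = variant, gene_id = gene, tissue = tissue,
               nominal_p = p, slope = slope, stringsAsFactors = FALSE)
}

# Random GRanges on a small genome (0-based half-open inputs).
randomIntervals <- function(n, chroms = c("chr1", "chr2")) {
    start0 <- sample.int(1000L, n, replace = TRUE)
    len <- sample.int(200L, n, replace = TRUE)
    GenomicRanges::GRanges(sample(chroms, n, replace = TRUE),
                           IRanges::IRanges(start0 + 1L, start0 + len))
}

# Tiny simulated dataset shared by several tests (built once per run).
tinySim <- function(seed = 5L) {
    simulateDataset(simulationConfig(
        seed = seed, nGenes = 150L, nTissues = 6L, nSamplesPerTissue = 8L,
        nNullPairs = 10L))
}
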