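.seFromMedians <- function(med, nSamples = 3L) {
    # builds an experiment whose per-tissue medians equal `med` exactly:
    # each tissue gets nSamples identical columns
    tpm <- med[, rep(seq_len(ncol(med)), each = nSamples), drop = FALSE]
    tissue <- rep(colnames(med), each = nSamples)
    sample_id <- rep(sprintf("s%d", seq_len(nSamples)), times = ncol(med))
    colnames(tpm) <- paste(tissue, sample_id, sep = ".")
    SummarizedExperiment::SummarizedExperiment(
        assays = list(tpm = tpm),
        colData = S4Vectors::DataFrame(tissue = tissue, sample_id = sample_id))
}

test_that("expressed tissue counts threshold the per-tissue median TPM", {
    med <- matrix(c(5, 0.05, 2), 1, dimnames = list("g1", c("T1", "T2", "T3")))
    se <- .seFromMedians(med)
    expect_equal(unname(expressedTissueCounts(se, 0.1)), 2L)
    expect_equal(unname(expressedTissueCounts(se, 0)), 3L)
    expect_warning(counts <- expressedTissueCounts(se, 0.1,
                                                   allGenes = c("g1", "gX")),
                   "absent")
    expect_equal(unname(counts["gX"]), 0L)

    # random fixture: counts match a brute-force recount
    set.seed(2)
    med2 <- matrix(runif(60, 0, 2), 10, 6,
                   dimnames = list(sprintf("g%02d", 1:10), sprintf("T%d", 1:6)))
    se2 <- .seFromMedians(med2)
    got <- expressedTissueCounts(se2, 0.5)
    want <- apply(med2, 1L, function(r) sum(r > 0.5))
    expect_equal(unname(got), unname(as.integer(want)))
})

test_that("affected proportions divide by expressed count and cap at 1", {
    m <- matrix(FALSE, 3, 12,
                dimnames = list(c("g1", "g2", "g3"), sprintf("T%02d", 1:12)))
    m["g1", 1:2] <- TRUE
    m["g3", 1:12] <- TRUE
    gtm <- new("GeneTissueMatrix", affected = m, mode = "bonferroni")
    expressed <- c(g1 = 10L, g2 = 10L, g3 = 10L, g4 = 0L)
    props <- affectedProportions(gtm, expressed)
    expect_equal(props$affected_proportion[props$gene_id == "g1"], 0.2)
    expect_equal(props$affected_proportion[props$gene_id == "g2"], 0)
    # affected in 12 tissues but expressed in 10 -> capped at 1
    expect_equal(props$affected_proportion[props$gene_id == "g3"], 1)
    expect_false("g4" %in% props$gene_id)
})

test_that("broad-breadth threshold implements the top-fraction rule", {
    # breadths 1..100: fraction >= 91 is exactly 10/100
    expect_equal(breadthQuantileThreshold(1:100, 0.10), 91L)
    # degenerate: all single-tissue eQTLs, nothing qualifies as broad
    expect_equal(breadthQuantileThreshold(rep(1L, 50), 0.10), 2L)
    expect_error(breadthQuantileThreshold(integer(), 0.1), "empty")
    # reducing the top fraction never lowers the threshold
    set.seed(4)
    br <- sample(1:48, 500, replace = TRUE, prob = 0.85^(1:48))
    fr <- c(0.5, 0.25, 0.1, 0.05, 0.01)
    thr <- vapply(fr, function(f) breadthQuantileThreshold(br, f), 1L)
    expect_true(all(diff(thr) >= 0L))
})

test_that("focal and broad flags distinguish many narrow eQTLs from one broad", {
    panel <- sprintf("T%02d", 1:20)
    # g1: 14 single-tissue eQTLs; g2: one 14-tissue eQTL; g3: 13 tissues
    a1 <- makeAssoc(sprintf("v%02d", 1:14), "g1", panel[1:14], 1e-8)
    a2 <- makeAssoc(rep("w1", 14), "g2", panel[1:14], 1e-8)
    a3 <- makeAssoc(rep("x1", 13), "g3", panel[1:13], 1e-8)
    cs <- bonferroniCalls(rbind(a1, a2, a3), nTissues = 20, tissuePanel = panel)
    gtm <- geneTissueMatrix(cs, genes = c("g1", "g2", "g3"), tissues = panel)
    fc <- focalBroadClassification(cs, gtm, threshold = 14L)
    expect_equal(fc$in_focal_set, c(TRUE, TRUE, FALSE))
    expect_equal(fc$broad_affected, c(FALSE, TRUE, FALSE))
    # broad_affected implies focal membership when cutoffs agree
    expect_true(all(!fc$broad_affected | fc$in_focal_set))
})

test_that("Jaccard matrix equals brute-force set arithmetic", {
    m <- matrix(FALSE, 4, 2, dimnames = list(c("A", "B", "C", "D"),
                                             c("T1", "T2")))
    m[c("A", "B", "C"), "T1"] <- TRUE
    m[c("B", "C", "D"), "T2"] <- TRUE
    gtm <- new("GeneTissueMatrix", affected = m, mode = "bonferroni")
    jm <- jaccardMatrix(gtm, rownames(m), "all")
    expect_equal(jaccardValues(jm)["T1", "T2"], 0.5)  # 2 / 4
    expect_equal(unname(diag(jaccardValues(jm))), c(1, 1))

    set.seed(8)
    m2 <- matrix(runif(35 * 5) < 0.3, 35, 5,
                 dimnames = list(sprintf("g%02d", 1:35), sprintf("T%d", 1:5)))
    stratum <- sample(rownames(m2), 20)
    gtm2 <- new("GeneTissueMatrix", affected = m2, mode = "bonferroni")
    jm2 <- jaccardMatrix(gtm2, stratum, "s")
    v <- jaccardValues(jm2)
    sets <- lapply(colnames(m2), function(t)
        intersect(rownames(m2)[m2[, t]], stratum))
    for (i in 1:5) for (j in 1:5)
        expect_equal(v[i, j], oracleJaccard(sets[[i]], sets[[j]]))
    # symmetry and range hold by construction
    expect_equal(v, t(v))
    expect_true(all(v >= 0 & v <= 1))
    # identical sets -> 1; disjoint -> 0 (checked via a constructed pair)
    m3 <- cbind(T1 = c(TRUE, TRUE, FALSE), T2 = c(TRUE, TRUE, FALSE),
                T3 = c(FALSE, FALSE, TRUE))
    rownames(m3) <- c("a", "b", "c")
    jm3 <- jaccardMatrix(new("GeneTissueMatrix", affected = m3,
                             mode = "bonferroni"), rownames(m3))
    expect_equal(jaccardValues(jm3)["T1", "T2"], 1)
    expect_equal(jaccardValues(jm3)["T1", "T3"], 0)
})

test_that("pairwise distributions have choose(n, 2) values per stratum", {
    set.seed(13)
    for (nT in c(3L, 48L)) {
        m <- matrix(runif(40 * nT) < 0.25, 40, nT,
                    dimnames = list(sprintf("g%02d", 1:40),
                                    sprintf("T%02d", seq_len(nT))))
        gtm <- new("GeneTissueMatrix", affected = m, mode = "bonferroni")
        ja <- jaccardMatrix(gtm, rownames(m)[1:20], "a")
        jb <- jaccardMatrix(gtm, rownames(m)[21:40], "b")
        d <- jaccardPairwiseDistributions(ja, jb)
        expect_length(d$a, choose(nT, 2))
        expect_length(d$b, choose(nT, 2))
    }
    # 48 tissues give exactly 1,128 unordered pairs
    expect_equal(choose(48, 2), 1128)
})
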