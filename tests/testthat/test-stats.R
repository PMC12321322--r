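test_that("chi-square matches the definitional formula on random tables", {
    # perfectly independent table: statistic 0, p 1
    res <- chi2Enrichment(matrix(c(10, 10, 10, 10), 2), nTests = 1)
    expect_equal(res$statistic, 0)
    expect_equal(res$p_raw, 1)
    expect_equal(res$df, 1)

    set.seed(6)
    for (i in 1:40) {
        tab <- matrix(rpois(6, lambda = 40) + 1L, 2, 3)
        got <- chi2Enrichment(tab, nTests = 3)
        expect_equal(got$statistic, oracleChisq(tab), tolerance = 1e-10)
        expect_equal(got$df, 2)
        expect_equal(got$p_adjusted, min(1, got$p_raw * 3))
        tab2 <- matrix(rpois(4, lambda = 30) + 1L, 2, 2)
        gotY <- chi2Enrichment(tab2, yates = TRUE)
        expect_equal(gotY$statistic, oracleChisq(tab2, yates = TRUE),
                     tolerance = 1e-10)
        gotN <- chi2Enrichment(tab2, yates = FALSE)
        expect_equal(gotN$statistic, oracleChisq(tab2), tolerance = 1e-10)
    }
    expect_warning(chi2Enrichment(matrix(c(1, 1, 1, 200), 2)), "below 1")
})

test_that("Mann-Whitney agrees with exhaustive permutation enumeration", {
    # {1,2,3} vs {4,5,6}: U = 0 for the first group, exact two-sided p = 0.1
    res <- mwuCompare(c(1, 2, 3), c(4, 5, 6))
    expect_equal(unname(res$u_statistic), 0)
    expect_equal(res$p_raw, 0.1)
    oracle <- oracleMwuExact(c(1, 2, 3), c(4, 5, 6))
    expect_equal(res$p_raw, oracle$p)

    set.seed(15)
    for (i in 1:20) {
        nA <- sample(2:5, 1); nB <- sample(2:5, 1)
        x <- sample(seq(0.1, 50, by = 0.1), nA + nB)  # distinct values
        a <- x[seq_len(nA)]; b <- x[-seq_len(nA)]
        got <- mwuCompare(a, b)
        want <- oracleMwuExact(a, b)
        expect_equal(unname(got$u_statistic), want$u)
        expect_equal(got$p_raw, want$p, tolerance = 1e-12)
    }
    # strongly shifted large samples: tiny p, direction via medians
    set.seed(16)
    big <- mwuCompare(rnorm(500), rnorm(500, 2), nTests = 2)
    expect_lt(big$p_adjusted, 1e-6)
    expect_lt(big$medians[1], big$medians[2])
    expect_error(mwuCompare(numeric(), 1), "non-empty")
})

test_that("CV is sd over mean of log-transformed TPM", {
    # log2(TPM + 1) of {1, 3, 7} is {1, 2, 3}: sd 1, mean 2 -> CV 0.5
    tpm <- matrix(c(1, 3, 7), 1, 3,
                  dimnames = list("g1", c("s1", "s2", "s3")))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(tpm = tpm),
        colData = S4Vectors::DataFrame(tissue = rep("T1", 3),
                                       sample_id = colnames(tpm)))
    cv <- cvPerGene(se)
    expect_equal(cv$cv, 0.5)

    # constant expression -> CV 0
    tpm2 <- matrix(5, 1, 3, dimnames = list("g1", c("s1", "s2", "s3")))
    se2 <- SummarizedExperiment::SummarizedExperiment(
        assays = list(tpm = tpm2),
        colData = S4Vectors::DataFrame(tissue = rep("T1", 3),
                                       sample_id = colnames(tpm2)))
    expect_equal(cvPerGene(se2)$cv, 0)

    # the log transform is non-linear: doubling TPM changes the CV
    tpm3 <- tpm * 2
    se3 <- SummarizedExperiment::SummarizedExperiment(
        assays = list(tpm = tpm3),
        colData = S4Vectors::DataFrame(tissue = rep("T1", 3),
                                       sample_id = colnames(tpm3)))
    expect_false(isTRUE(all.equal(cvPerGene(se3)$cv, 0.5)))

    # single-sample tissue is an error
    se4 <- SummarizedExperiment::SummarizedExperiment(
        assays = list(tpm = tpm[, 1, drop = FALSE]),
        colData = S4Vectors::DataFrame(tissue = "T1", sample_id = "s1"))
    expect_error(cvPerGene(se4), "fewer than 2 samples")
})

test_that("BH adjustment matches the step-up formula and is monotone", {
    # hand computation: {0.01, 0.02, 0.03, 0.04} over 4 tests -> all 0.04
    expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
    set.seed(17)
    p <- runif(30)
    adj <- p.adjust(p, "BH")
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("per-tissue CV comparisons detect a planted low-CV class", {
    set.seed(18)
    nG <- 120; nS <- 12; tissues <- c("T1", "T2", "T3")
    genes <- sprintf("g%03d", 1:nG)
    status <- rep(c("ohnolog", "ssd"), each = nG / 2)
    sigma <- ifelse(status == "ohnolog", 0.2, 0.7)
    tpmList <- lapply(tissues, function(t) {
        x <- matrix(rnorm(nG * nS, mean = 4, sd = sigma), nG, nS)
        m <- pmax(2^x - 1, 0); rownames(m) <- genes
        colnames(m) <- sprintf("s%02d", 1:nS); m
    })
    tpm <- do.call(cbind, tpmList)
    colnames(tpm) <- paste(rep(tissues, each = nS), colnames(tpm), sep = ".")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(tpm = tpm),
        colData = S4Vectors::DataFrame(
            tissue = rep(tissues, each = nS),
            sample_id = rep(sprintf("s%02d", 1:nS), 3)))
    classTable <- data.frame(
        gene_id = genes, duplication_status = status,
        cnvr_member = NA, cnv_affected = "unknown", pli = NA,
        haplo_class = "unknown", ccn = FALSE, stringsAsFactors = FALSE)
    cv <- cvPerGene(se)
    res <- cvGroupTestsBH(cv, classTable, axis = "duplication")
    expect_equal(nrow(res), 3L)  # one pair x three tissues
    expect_true(all(res$p_bh < 0.05))
    expect_true(all(res$median_a < res$median_b))  # ohnolog CV lower
})

test_that("expression bins are equal-size, remainder-low and deterministic", {
    x <- setNames(runif(100), sprintf("g%03d", 1:100))
    bins <- expressionDecileBins(x, 10)
    expect_equal(as.vector(table(bins)), rep(10L, 10))
    # lowest-expression genes land in bin 1
    expect_equal(unname(bins[which.min(x)]), 1L)
    expect_equal(unname(bins[which.max(x)]), 10L)

    x101 <- setNames(runif(101), sprintf("g%03d", 1:101))
    t101 <- table(expressionDecileBins(x101, 10))
    expect_equal(sort(as.vector(t101), decreasing = TRUE),
                 c(11L, rep(10L, 9)))

    # all-equal values: assignment still deterministic via id tie-break
    xeq <- setNames(rep(1, 30), sprintf("g%02d", 30:1))
    b1 <- expressionDecileBins(xeq, 3)
    b2 <- expressionDecileBins(xeq[sample(30)], 3)
    expect_identical(b1[sort(names(b1))], b2[sort(names(b2))])
    expect_error(expressionDecileBins(setNames(1:5, letters[1:5]), 10),
                 "fewer genes")
})

test_that("logistic model recovers planted status effects and degrades sanely", {
    rec <- simulateEqtlStatusRecords(20000, orSsd = 1.8, orSingleton = 1.0,
                                     seed = 19)
    fit <- fitEqtlLogistic(rec)
    expect_equal(unname(fit$odds_ratios["duplication_statusssd"]), 1.8,
                 tolerance = 0.12)
    expect_equal(fit$reference_level, "ohnolog")
    expect_equal(unname(exp(fit$coefficients$estimate)),
                 unname(fit$odds_ratios))

    # balanced null data: odds ratios near 1
    nullRec <- simulateEqtlStatusRecords(20000, orSsd = 1, orSingleton = 1,
                                         seed = 20)
    nullFit <- fitEqtlLogistic(nullRec)
    ors <- nullFit$odds_ratios[grep("duplication_status",
                                    names(nullFit$odds_ratios))]
    expect_true(all(abs(ors - 1) < 0.15))

    # all-identical predictors -> intercept-only fit
    degen <- data.frame(affected = c(TRUE, FALSE, TRUE, FALSE),
                        median_expression = 1,
                        duplication_status = "ohnolog")
    dfit <- fitEqtlLogistic(degen)
    expect_equal(dfit$coefficients$term, "(Intercept)")
})
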