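test_that("Bonferroni calling applies the tissue-count correction strictly", {
    panel <- c("T1", "T2", "T3")
    # 0.001 x 48 = 0.048 < 0.05 significant; 0.002 x 48 = 0.096 not
    a <- makeAssoc(c("v1", "v1"), c("g1", "g1"), c("T1", "T2"),
                   c(0.001, 0.002))
    cs <- bonferroniCalls(a, nTissues = 48, alpha = 0.05, tissuePanel = panel)
    expect_equal(length(cs), 1L)
    expect_equal(as.character(eqtlCalls(cs)$tissues[[1]]), "T1")

    # pair significant in T1 and T3 only -> one call with breadth 2
    b <- makeAssoc(rep("v2", 3), rep("g2", 3), c("T1", "T2", "T3"),
                   c(1e-6, 0.5, 1e-5))
    cs2 <- bonferroniCalls(b, nTissues = 48, tissuePanel = panel)
    expect_equal(length(cs2), 1L)
    expect_equal(eqtlTissueBreadth(cs2), 2L)
    expect_setequal(as.character(eqtlCalls(cs2)$tissues[[1]]), c("T1", "T3"))

    # no significant tissue -> no call emitted
    cs3 <- bonferroniCalls(makeAssoc("v3", "g3", "T1", 0.5),
                           nTissues = 48, tissuePanel = panel)
    expect_equal(length(cs3), 0L)
    expect_error(bonferroniCalls(a, alpha = 1.5), "alpha")
})

test_that("posterior calling uses a strict m-value threshold", {
    mv <- data.frame(variant_id = rep("v1", 3), gene_id = rep("g1", 3),
                     tissue = c("T1", "T2", "T3"),
                     m_value = c(0.95, 0.92, 0.10))
    cs <- posteriorCalls(mv, threshold = 0.9,
                         tissuePanel = c("T1", "T2", "T3"))
    expect_equal(eqtlTissueBreadth(cs), 2L)
    # exactly 0.90 is excluded; 0.91 included
    mv2 <- data.frame(variant_id = c("v1", "v2"), gene_id = c("g1", "g2"),
                      tissue = "T1", m_value = c(0.90, 0.91))
    cs2 <- posteriorCalls(mv2, tissuePanel = "T1")
    expect_equal(eqtlCalls(cs2)$variant_id, "v2")
})

test_that("breadths equal brute-force recounts on random call fixtures", {
    set.seed(3)
    panel <- sprintf("T%02d", 1:10)
    n <- 400L
    a <- makeAssoc(sprintf("v%03d", sample(100, n, TRUE)),
                   sprintf("g%03d", sample(60, n, TRUE)),
                   sample(panel, n, TRUE),
                   runif(n)^4)
    a <- a[!duplicated(a[c("variant_id", "gene_id", "tissue")]), ]
    cs <- bonferroniCalls(a, nTissues = 10, alpha = 0.05, tissuePanel = panel)
    # brute force: recount significant tissues per (variant, gene)
    sig <- a[a$nominal_p * 10 < 0.05, ]
    key <- paste(sig$variant_id, sig$gene_id)
    want <- sort(table(key))
    calls <- eqtlCalls(cs)
    got <- sort(setNames(calls$breadth,
                         paste(calls$variant_id, calls$gene_id)))
    expect_equal(as.integer(got), as.integer(want))
    expect_equal(names(got)[order(names(got))], names(want)[order(names(want))])
    expect_true(all(eqtlTissueBreadth(cs) >= 1L))
})

test_that("lowering alpha never adds a significant tissue (monotonicity)", {
    set.seed(9)
    panel <- sprintf("T%02d", 1:8)
    n <- 300L
    a <- makeAssoc(sprintf("v%02d", sample(40, n, TRUE)),
                   sprintf("g%02d", sample(30, n, TRUE)),
                   sample(panel, n, TRUE), runif(n)^3)
    a <- a[!duplicated(a[c("variant_id", "gene_id", "tissue")]), ]
    loose <- bonferroniCalls(a, nTissues = 8, alpha = 0.05, tissuePanel = panel)
    strict <- bonferroniCalls(a, nTissues = 8, alpha = 0.005, tissuePanel = panel)
    lc <- eqtlCalls(loose); sc <- eqtlCalls(strict)
    lkey <- paste(lc$variant_id, lc$gene_id)
    skey <- paste(sc$variant_id, sc$gene_id)
    expect_true(all(skey %in% lkey))
    for (i in seq_along(skey)) {
        tl <- as.character(lc$tissues[[match(skey[i], lkey)]])
        ts <- as.character(sc$tissues[[i]])
        expect_true(all(ts %in% tl))
    }
})

test_that("gene x tissue matrix is the union over calls and brute force agrees", {
    panel <- c("T1", "T2", "T3")
    a <- makeAssoc(c("v1", "v2", "v3"), c("g1", "g1", "g2"),
                   c("T1", "T2", "T3"), rep(1e-6, 3))
    cs <- bonferroniCalls(a, nTissues = 3, tissuePanel = panel)
    gtm <- geneTissueMatrix(cs, genes = c("g1", "g2", "g3"), tissues = panel)
    m <- affectedMatrix(gtm)
    expect_equal(unname(m["g1", ]), c(TRUE, TRUE, FALSE))
    expect_equal(unname(m["g2", ]), c(FALSE, FALSE, TRUE))
    expect_equal(unname(m["g3", ]), c(FALSE, FALSE, FALSE))  # no calls

    set.seed(21)
    n <- 200L
    panel <- sprintf("T%02d", 1:6)
    b <- makeAssoc(sprintf("v%03d", sample(80, n, TRUE)),
                   sprintf("g%02d", sample(25, n, TRUE)),
                   sample(panel, n, TRUE), runif(n)^3)
    b <- b[!duplicated(b[c("variant_id", "gene_id", "tissue")]), ]
    cs2 <- bonferroniCalls(b, nTissues = 6, tissuePanel = panel)
    genes <- sprintf("g%02d", 1:25)
    got <- affectedMatrix(geneTissueMatrix(cs2, genes, panel))
    sig <- b[b$nominal_p * 6 < 0.05, ]
    want <- matrix(FALSE, length(genes), length(panel),
                   dimnames = list(genes, panel))
    for (i in seq_len(nrow(sig)))
        want[sig$gene_id[i], sig$tissue[i]] <- TRUE
    expect_identical(got, want)
    # per-tissue totals never exceed the pooled affected count
    expect_true(all(colSums(got) <= sum(rowSums(got) > 0L)))
})

test_that("top eQTL per gene and tissue is the argmin with lexicographic ties", {
    panel <- "T1"
    a <- makeAssoc(c("v_b", "v_a"), c("g1", "g1"), "T1", c(1e-8, 1e-6))
    cs <- bonferroniCalls(a, nTissues = 1, tissuePanel = panel)
    top <- topEqtlPerGeneTissue(a, cs)
    expect_equal(top$variant_id, "v_b")  # smaller p wins
    # exact tie -> lexicographically smallest variant id
    b <- makeAssoc(c("chr1_200", "chr1_100"), c("g1", "g1"), "T1",
                   c(1e-8, 1e-8))
    top2 <- topEqtlPerGeneTissue(b, bonferroniCalls(b, 1, tissuePanel = panel))
    expect_equal(top2$variant_id, "chr1_100")

    # random fixture equals a brute-force argmin scan
    set.seed(14)
    n <- 300L
    panel <- sprintf("T%02d", 1:5)
    d <- makeAssoc(sprintf("v%03d", sample(120, n, TRUE)),
                   sprintf("g%02d", sample(20, n, TRUE)),
                   sample(panel, n, TRUE), runif(n)^4)
    d <- d[!duplicated(d[c("variant_id", "gene_id", "tissue")]), ]
    cs3 <- bonferroniCalls(d, nTissues = 5, tissuePanel = panel)
    got <- topEqtlPerGeneTissue(d, cs3)
    sig <- d[d$nominal_p * 5 < 0.05, ]
    for (k in split(seq_len(nrow(sig)),
                    paste(sig$gene_id, sig$tissue))) {
        rows <- sig[k, ]
        best <- rows[order(rows$nominal_p, rows$variant_id)[1], ]
        hit <- got[got$gene_id == best$gene_id & got$tissue == best$tissue, ]
        expect_equal(hit$variant_id, best$variant_id)
    }
    expect_false(any(duplicated(paste(got$gene_id, got$tissue))))
})
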