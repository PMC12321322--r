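#' @importFrom stats chisq.test wilcox.test p.adjust sd glm binomial coef
#'   plogis setNames
NULL

#' Chi-square enrichment test with Bonferroni adjustment
#'
#' Pearson chi-square test of independence on an r x c contingency table,
#' with optional Yates continuity correction for 2 x 2 tables (on by
#' default, matching R's own default) and a Bonferroni multiple-testing
#' adjustment (p_adjusted = min(1, p_raw x nTests)).
#'
#' @param table Matrix of non-negative integer counts (no all-zero row or
#'   column).
#' @param nTests Bonferroni correction count (default 1).
#' @param yates Apply the continuity correction for 2 x 2 tables?
#' @return List of class \code{ContingencyResult}: \code{table},
#'   \code{statistic}, \code{df}, \code{p_raw}, \code{p_adjusted},
#'   \code{n_tests}, \code{expected}, \code{low_expected_warning}.
#' @examples
#' chi2Enrichment(matrix(c(10, 10, 10, 10), 2))$p_raw  # exactly 1
#' @export
chi2Enrichment <- function(table, nTests = 1L, yates = TRUE) {
    table <- as.matrix(table)
    if (any(table < 0)) stop("counts must be non-negative")
    if (any(rowSums(table) == 0) || any(colSums(table) == 0))
        stop("table has an all-zero row or column")
    res <- suppressWarnings(chisq.test(table, correct = yates))
    lowExp <- any(res$expected < 1)
    if (lowExp) warning("expected cell count below 1; chi-square unreliable")
    structure(list(
        table = table,
        statistic = unname(res$statistic),
        df = unname(res$parameter),
        p_raw = unname(res$p.value),
        p_adjusted = min(1, unname(res$p.value) * nTests),
        n_tests = nTests,
        expected = res$expected,
        low_expected_warning = lowExp
    ), class = "ContingencyResult")
}

#' @export
print.ContingencyResult <- function(x, ...) {
    cat("Chi-square test: X2 =", signif(x$statistic, 4), ", df =", x$df,
        ", p_raw =", format(x$p_raw, digits = 3),
        ", p_adjusted =", format(x$p_adjusted, digits = 3),
        "(x", x$n_tests, "tests)\n")
    invisible(x)
}

#' Two-sided Mann-Whitney U comparison with Bonferroni adjustment
#'
#' Wilcoxon rank-sum test between two groups. For small groups (both sizes
#' at most 8) with no ties the exact null distribution is used; otherwise the
#' tie-corrected normal approximation with continuity correction. The U
#' statistic reported is for the first group.
#'
#' @param valuesA,valuesB Non-empty numeric vectors.
#' @param nTests Bonferroni correction count (default 1).
#' @param labels Group labels for reporting.
#' @return List of class \code{GroupComparisonResult}: \code{group_labels},
#'   \code{group_sizes}, \code{medians}, \code{u_statistic}, \code{p_raw},
#'   \code{p_adjusted}.
#' @export
mwuCompare <- function(valuesA, valuesB, nTests = 1L,
                       labels = c("a", "b")) {
    if (length(valuesA) == 0L || length(valuesB) == 0L)
        stop("both groups must be non-empty")
    exact <- length(valuesA) <= 8L && length(valuesB) <= 8L &&
        !anyDuplicated(c(valuesA, valuesB))
    res <- suppressWarnings(
        wilcox.test(valuesA, valuesB, alternative = "two.sided", exact = exact)
    )
    structure(list(
        group_labels = labels,
        group_sizes = c(length(valuesA), length(valuesB)),
        medians = c(stats::median(valuesA), stats::median(valuesB)),
        u_statistic = unname(res$statistic),
        p_raw = res$p.value,
        p_adjusted = min(1, res$p.value * nTests)
    ), class = "GroupComparisonResult")
}

#' @export
print.GroupComparisonResult <- function(x, ...) {
    cat("Mann-Whitney U:", x$group_labels[1], "(n =", x$group_sizes[1],
        ", median", signif(x$medians[1], 3), ") vs", x$group_labels[2],
        "(n =", x$group_sizes[2], ", median", signif(x$medians[2], 3),
        "); U =", x$u_statistic, ", p_adjusted =",
        format(x$p_adjusted, digits = 3), "\n")
    invisible(x)
}

#' Coefficient of variation of log-transformed expression per gene
#'
#' For every tissue, TPM values are transformed as log_b(x + pseudocount)
#' (default log2(TPM + 1)) and the per-gene coefficient of variation
#' CV = standard deviation / mean is computed across samples (sample sd,
#' n - 1 denominator). Genes whose mean transformed expression is not
#' strictly positive in a tissue are dropped there, with the dropped count
#' recorded in attribute \code{"n_dropped"}.
#'
#' @param se A \code{SummarizedExperiment} of TPM values.
#' @param logBase Logarithm base for the transform (default 2).
#' @param pseudocount Added before the log (default 1).
#' @return data.frame with columns \code{tissue}, \code{gene_id}, \code{cv}.
#' @export
cvPerGene <- function(se, logBase = 2, pseudocount = 1) {
    tpm <- assay(se, "tpm")
    tissue <- colData(se)$tissue
    out <- lapply(unique(tissue), function(t) {
        m <- tpm[, tissue == t, drop = FALSE]
        if (ncol(m) < 2L)
            stop("tissue ", t, " has fewer than 2 samples; CV undefined")
        lx <- log(m + pseudocount, base = logBase)
        mu <- rowMeans(lx)
        s <- apply(lx, 1L, sd)
        keep <- mu > 0
        data.frame(tissue = t, gene_id = rownames(m)[keep],
                   cv = s[keep] / mu[keep], stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "n_dropped") <-
        length(unique(tissue)) * nrow(tpm) - nrow(res)
    res
}

#' Per-tissue rank-sum tests of CV between gene classes, BH-adjusted
#'
#' Within every tissue, compares the CV distributions of each unordered pair
#' of groups on the chosen dosage-sensitivity axis with a Wilcoxon rank-sum
#' test; p-values are Benjamini-Hochberg adjusted across all tests of the
#' axis (tissues x group pairs).
#'
#' @param cvTable data.frame from \code{\link{cvPerGene}}.
#' @param classTable data.frame from \code{\link{assembleClassTable}}.
#' @param axis Class axis passed to \code{\link{classAxisGroups}}.
#' @return data.frame with columns \code{tissue}, \code{group_a},
#'   \code{group_b}, \code{n_a}, \code{n_b}, \code{median_a},
#'   \code{median_b}, \code{p_raw}, \code{p_bh}.
#' @export
cvGroupTestsBH <- function(cvTable, classTable, axis = "duplication") {
    groups <- classAxisGroups(classTable, axis)
    g <- groups[cvTable$gene_id]
    keep <- !is.na(g)
    cvTable <- cvTable[keep, , drop = FALSE]
    g <- g[keep]
    levs <- sort(unique(g))
    if (length(levs) < 2L) stop("need at least 2 classes on axis ", axis)
    pairs <- utils::combn(levs, 2L)
    rows <- list()
    for (t in unique(cvTable$tissue)) {
        inT <- cvTable$tissue == t
        for (k in seq_len(ncol(pairs))) {
            a <- cvTable$cv[inT & g == pairs[1L, k]]
            b <- cvTable$cv[inT & g == pairs[2L, k]]
            if (length(a) < 2L || length(b) < 2L) next
            p <- suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
            rows[[length(rows) + 1L]] <- data.frame(
                tissue = t, group_a = pairs[1L, k], group_b = pairs[2L, k],
                n_a = length(a), n_b = length(b),
                median_a = stats::median(a), median_b = stats::median(b),
                p_raw = p, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    out$p_bh <- p.adjust(out$p_raw, method = "BH")
    out
}

#' Equal-size rank bins of genes by expression
#'
#' Splits genes into \code{nBins} rank-based bins of (near-)equal size by a
#' numeric value (e.g. median tissue expression); bin sizes differ by at most
#' one, with the remainder assigned to the lowest bins. Ties in the value are
#' broken deterministically by gene id, so the assignment is stable across
#' runs.
#'
#' @param x Named numeric vector (names are gene ids).
#' @param nBins Number of bins (default 10 for deciles).
#' @return Named integer vector of bin indices (1 = lowest expression).
#' @export
expressionDecileBins <- function(x, nBins = 10L) {
    n <- length(x)
    if (n < nBins) stop("fewer genes (", n, ") than bins (", nBins, ")")
    o <- order(x, names(x), method = "radix")
    sizes <- rep(n %/% nBins, nBins)
    rem <- n %% nBins
    if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    bins <- integer(n)
    bins[o] <- rep(seq_len(nBins), times = sizes)
    names(bins) <- names(x)
    bins
}

#' Logistic model of per-tissue eQTL status
#'
#' Fits affected ~ expression + duplication_status (+ their interaction) by
#' binomial GLM with ohnolog as the reference level, and reports per-term
#' odds ratios (exp of the estimate). The expression covariate is
#' mean-centered by default so that, in the presence of the interaction, the
#' status main effects (and their odds ratios) are evaluated at the mean
#' expression level rather than extrapolated to zero TPM. With a single
#' duplication class or constant predictors the model degrades gracefully to
#' the terms that remain identifiable (ultimately intercept-only).
#'
#' @param records data.frame with columns \code{affected} (logical),
#'   \code{median_expression} (numeric) and \code{duplication_status}.
#' @param interaction Include the expression x status interaction?
#' @param center Mean-center the expression covariate before fitting?
#' @return List of class \code{LogisticModelResult}: \code{coefficients}
#'   (data.frame term/estimate/se/p), \code{odds_ratios},
#'   \code{reference_level}, \code{converged}, \code{separation_flag}.
#' @export
fitEqtlLogistic <- function(records, interaction = TRUE, center = TRUE) {
    stopifnot(all(c("affected", "median_expression", "duplication_status")
                  %in% names(records)))
    status <- factor(records$duplication_status)
    if ("ohnolog" %in% levels(status))
        status <- stats::relevel(status, ref = "ohnolog")
    expr <- records$median_expression
    if (center) expr <- expr - mean(expr)
    useStatus <- nlevels(droplevels(status)) >= 2L
    useExpr <- length(unique(expr)) >= 2L
    terms <- c(if (useExpr) "median_expression",
               if (useStatus) "duplication_status",
               if (useExpr && useStatus && interaction)
                   "median_expression:duplication_status")
    fml <- stats::as.formula(paste("affected ~",
        if (length(terms)) paste(terms, collapse = " + ") else "1"))
    d <- data.frame(affected = as.logical(records$affected),
                    median_expression = expr,
                    duplication_status = droplevels(status))
    fit <- glm(fml, data = d, family = binomial())
    if (!fit$converged)
        stop("logistic model did not converge after ", fit$iter, " iterations")
    est <- summary(fit)$coefficients
    sep <- any(abs(est[, "Estimate"]) > 15)
    if (sep) warning("possible complete separation: extreme coefficient(s)")
    coefs <- data.frame(
        term = rownames(est),
        estimate = est[, "Estimate"],
        se = est[, "Std. Error"],
        p = est[, "Pr(>|z|)"],
        stringsAsFactors = FALSE, row.names = NULL
    )
    structure(list(
        coefficients = coefs,
        odds_ratios = stats::setNames(exp(coefs$estimate), coefs$term),
        reference_level = "ohnolog",
        converged = fit$converged,
        separation_flag = sep
    ), class = "LogisticModelResult")
}

#' @export
print.LogisticModelResult <- function(x, ...) {
    cat("Logistic model of eQTL status (reference:", x$reference_level, ")\n")
    df <- x$coefficients
    df$odds_ratio <- x$odds_ratios[df$term]
    print(df, digits = 4)
    invisible(x)
}
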