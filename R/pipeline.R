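#' @importFrom tools md5sum
NULL

#' Configuration for the end-to-end analysis
#'
#' Collects the input paths and tunable parameters of the full analysis. The
#' default path layout matches \code{\link{writeSimulatedData}}; every path
#' can be overridden individually, so real per-tissue association tables and
#' class lists can be supplied in the same shapes.
#'
#' @param inputDir Directory holding the input files.
#' @param annotations,cnvrs,associations,mvalues,ohnologs,paralogs,
#'   cnvAffected,cnvAssayed,ccn,pli,tissues Individual input paths
#'   (defaults under \code{inputDir}).
#' @param expressionGlob Glob for per-tissue expression TSVs; tissue label is
#'   taken from the file name (\code{expr_<tissue>.tsv}).
#' @param alpha Significance level after Bonferroni correction (default 0.05).
#' @param posteriorThreshold Posterior-probability cutoff (default 0.9).
#' @param tableTests Bonferroni correction count for the pooled-enrichment
#'   table (default 10: five gene-group splits x two eQTL call sets).
#' @param tpmThreshold Median-TPM expression threshold (default 0.1).
#' @param topFraction Upper-tail fraction defining broad tissue breadth
#'   (default 0.10).
#' @param logBase,pseudocount CV transform settings (default log2(TPM + 1)).
#' @param seed RNG seed for any resampling step (the core pipeline is
#'   deterministic).
#' @return List of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(inputDir,
                           annotations = file.path(inputDir, "annotations.tsv"),
                           cnvrs = file.path(inputDir, "cnvrs.bed"),
                           associations = file.path(inputDir, "associations.tsv"),
                           mvalues = file.path(inputDir, "mvalues.tsv"),
                           ohnologs = file.path(inputDir, "ohnologs.txt"),
                           paralogs = file.path(inputDir, "paralogs.tsv"),
                           cnvAffected = file.path(inputDir, "cnv_affected.txt"),
                           cnvAssayed = file.path(inputDir, "cnv_assayed.txt"),
                           ccn = file.path(inputDir, "ccn.txt"),
                           pli = file.path(inputDir, "pli.tsv"),
                           tissues = file.path(inputDir, "tissues.txt"),
                           expressionGlob = file.path(inputDir, "expr_*.tsv"),
                           alpha = 0.05, posteriorThreshold = 0.9,
                           tableTests = 10L, tpmThreshold = 0.1,
                           topFraction = 0.10, logBase = 2, pseudocount = 1,
                           seed = 1L) {
    cfg <- list(annotations = annotations, cnvrs = cnvrs,
                associations = associations, mvalues = mvalues,
                ohnologs = ohnologs, paralogs = paralogs,
                cnvAffected = cnvAffected, cnvAssayed = cnvAssayed,
                ccn = ccn, pli = pli, tissues = tissues,
                expressionGlob = expressionGlob,
                alpha = alpha, posteriorThreshold = posteriorThreshold,
                tableTests = as.integer(tableTests),
                tpmThreshold = tpmThreshold, topFraction = topFraction,
                logBase = logBase, pseudocount = pseudocount,
                seed = as.integer(seed))
    paths <- unlist(cfg[c("annotations", "cnvrs", "associations", "mvalues",
                          "ohnologs", "paralogs", "cnvAffected", "cnvAssayed",
                          "ccn", "pli", "tissues")])
    missing <- paths[!file.exists(paths)]
    if (length(missing))
        stop("input path(s) do not exist: ", paste(missing, collapse = ", "))
    structure(cfg, class = "PipelineConfig")
}

.axes <- c("cnvr", "cnv", "duplication", "ccn", "haplo")

.pooledEnrichmentTable <- function(classTable, affectedByMode, tableTests) {
    rows <- list()
    for (mode in names(affectedByMode)) {
        affected <- affectedByMode[[mode]]
        for (axis in .axes) {
            g <- classAxisGroups(classTable, axis)
            keep <- !is.na(g) & names(g) %in% names(affected)
            gg <- g[keep]
            aa <- affected[names(gg)]
            tab <- table(gg, factor(aa, levels = c(TRUE, FALSE)))
            res <- chi2Enrichment(unclass(tab), nTests = tableTests)
            for (lev in rownames(tab)) {
                n <- sum(tab[lev, ])
                rows[[length(rows) + 1L]] <- data.frame(
                    mode = mode, axis = axis, group = lev, n = n,
                    pct_affected = 100 * tab[lev, "TRUE"] / n,
                    chi2 = res$statistic, p_raw = res$p_raw,
                    p_adjusted = res$p_adjusted, stringsAsFactors = FALSE)
            }
        }
    }
    do.call(rbind, rows)
}

.perTissueTable <- function(classTable, gtms) {
    rows <- list()
    for (mode in names(gtms)) {
        aff <- affectedMatrix(gtms[[mode]])
        g <- classAxisGroups(classTable, "duplication2")
        g <- g[rownames(aff)]
        nT <- ncol(aff)
        for (t in colnames(aff)) {
            tab <- table(factor(g[!is.na(g)],
                                levels = c("ohnolog", "nonohnolog")),
                         factor(aff[!is.na(g), t], levels = c(TRUE, FALSE)))
            res <- chi2Enrichment(unclass(tab), nTests = nT)
            rows[[length(rows) + 1L]] <- data.frame(
                mode = mode, tissue = t,
                prop_ohnolog = tab["ohnolog", "TRUE"] / sum(tab["ohnolog", ]),
                prop_nonohnolog = tab["nonohnolog", "TRUE"] /
                    sum(tab["nonohnolog", ]),
                p_adjusted = res$p_adjusted, stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}

.jaccardSummaryTable <- function(classTable, gtms) {
    rows <- list()
    for (mode in names(gtms)) {
        gtm <- gtms[[mode]]
        g <- classAxisGroups(classTable, "duplication2")
        jo <- jaccardMatrix(gtm, names(g)[!is.na(g) & g == "ohnolog"],
                            "ohnolog")
        jn <- jaccardMatrix(gtm, names(g)[!is.na(g) & g == "nonohnolog"],
                            "nonohnolog")
        dist <- jaccardPairwiseDistributions(jo, jn)
        cmp <- mwuCompare(dist$a, dist$b, nTests = 1L, labels = dist$labels)
        rows[[length(rows) + 1L]] <- data.frame(
            mode = mode, n_pairs = length(dist$a),
            median_ohnolog = stats::median(dist$a),
            median_nonohnolog = stats::median(dist$b),
            p_adjusted = cmp$p_adjusted, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}

.breadthComparisonTable <- function(classTable, gtms, expressed) {
    axes2 <- c("cnvr", "cnv", "duplication2", "ccn", "haplo")
    rows <- list()
    for (mode in names(gtms)) {
        props <- affectedProportions(gtms[[mode]], expressed)
        # restrict to eQTL-affected genes, as in the proportion distributions
        props <- props[props$n_affected_tissues > 0L, ]
        pr <- stats::setNames(props$affected_proportion, props$gene_id)
        for (axis in axes2) {
            g <- classAxisGroups(classTable, axis)
            g <- g[names(pr)]
            levs <- sort(unique(g[!is.na(g)]))
            if (length(levs) < 2L) next
            pairs <- utils::combn(levs, 2L)
            for (k in seq_len(ncol(pairs))) {
                a <- pr[!is.na(g) & g == pairs[1L, k]]
                b <- pr[!is.na(g) & g == pairs[2L, k]]
                cmp <- mwuCompare(a, b, nTests = length(axes2),
                                  labels = pairs[, k])
                rows[[length(rows) + 1L]] <- data.frame(
                    mode = mode, axis = axis,
                    group_a = pairs[1L, k], group_b = pairs[2L, k],
                    n_a = length(a), n_b = length(b),
                    median_a = cmp$medians[1], median_b = cmp$medians[2],
                    p_adjusted = cmp$p_adjusted, stringsAsFactors = FALSE)
            }
        }
    }
    do.call(rbind, rows)
}

.broadDepletionTable <- function(classTable, callsets, gtms, topFraction) {
    rows <- list()
    for (mode in names(callsets)) {
        cs <- callsets[[mode]]
        gtm <- gtms[[mode]]
        thr <- breadthQuantileThreshold(eqtlTissueBreadth(cs), topFraction)
        fc <- focalBroadClassification(cs, gtm, thr)
        affected <- rowSums(affectedMatrix(gtm)) > 0L
        fc <- fc[affected[fc$gene_id], ]
        broad <- stats::setNames(fc$broad_affected, fc$gene_id)
        for (axis in .axes) {
            g <- classAxisGroups(classTable, axis)
            g <- g[names(broad)]
            keep <- !is.na(g)
            tab <- table(g[keep], factor(broad[keep], levels = c(TRUE, FALSE)))
            if (nrow(tab) < 2L || any(colSums(tab) == 0)) next
            res <- chi2Enrichment(unclass(tab), nTests = length(.axes))
            for (lev in rownames(tab)) {
                n <- sum(tab[lev, ])
                rows[[length(rows) + 1L]] <- data.frame(
                    mode = mode, axis = axis, breadth_threshold = thr,
                    group = lev, n = n,
                    pct_broad = 100 * tab[lev, "TRUE"] / n,
                    p_adjusted = res$p_adjusted, stringsAsFactors = FALSE)
            }
        }
    }
    do.call(rbind, rows)
}

.effectSizeTable <- function(classTable, assoc, callset, alpha, nTissues) {
    sig <- pmin(1, assoc$nominal_p * nTissues) < alpha
    sigAssoc <- assoc[sig, , drop = FALSE]
    top <- topEqtlPerGeneTissue(assoc, callset)
    sets <- list(all = sigAssoc, top = top)
    axes2 <- c("cnvr", "cnv", "duplication2", "ccn", "haplo")
    rows <- list()
    for (setName in names(sets)) {
        d <- sets[[setName]]
        absSlope <- abs(d$slope)
        for (axis in axes2) {
            g <- classAxisGroups(classTable, axis)
            gg <- g[d$gene_id]
            levs <- sort(unique(gg[!is.na(gg)]))
            if (length(levs) < 2L) next
            pairs <- utils::combn(levs, 2L)
            for (k in seq_len(ncol(pairs))) {
                a <- absSlope[!is.na(gg) & gg == pairs[1L, k]]
                b <- absSlope[!is.na(gg) & gg == pairs[2L, k]]
                cmp <- mwuCompare(a, b, nTests = length(axes2),
                                  labels = pairs[, k])
                rows[[length(rows) + 1L]] <- data.frame(
                    eqtl_set = setName, axis = axis,
                    group_a = pairs[1L, k], group_b = pairs[2L, k],
                    n_a = length(a), n_b = length(b),
                    median_a = cmp$medians[1], median_b = cmp$medians[2],
                    p_adjusted = cmp$p_adjusted, stringsAsFactors = FALSE)
            }
        }
    }
    do.call(rbind, rows)
}

.logisticTable <- function(classTable, gtm, medTpm) {
    g <- classAxisGroups(classTable, "duplication")
    genes <- intersect(rownames(affectedMatrix(gtm)),
                       names(g)[!is.na(g)])
    genes <- intersect(genes, rownames(medTpm))
    aff <- affectedMatrix(gtm)[genes, , drop = FALSE]
    med <- medTpm[genes, colnames(aff), drop = FALSE]
    records <- data.frame(
        affected = as.vector(aff),
        median_expression = as.vector(med),
        duplication_status = rep(g[genes], times = ncol(aff)),
        stringsAsFactors = FALSE)
    fit <- fitEqtlLogistic(records, interaction = TRUE)
    out <- fit$coefficients
    out$odds_ratio <- unname(fit$odds_ratios[out$term])
    out
}

#' Run the full analysis end-to-end
#'
#' Reads all inputs, classifies genes, builds the eQTL call set(s), and
#' computes the seven report tables: pooled enrichment by gene group,
#' per-tissue affected proportions (ohnolog vs nonohnolog), Jaccard overlap
#' summaries, affected-tissue-proportion comparisons, broad-breadth
#' depletion, effect-size comparisons, and the logistic model of per-tissue
#' eQTL status. Deterministic given inputs and configuration.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @param mode Which call sets to build: \code{"both"} (default),
#'   \code{"bonferroni"} or \code{"posterior"}. Effect-size and logistic
#'   tables require the Bonferroni set (slopes live in the association
#'   table) and are present only when it is included.
#' @return A \code{\link{ReportBundle}}.
#' @export
runFullAnalysis <- function(config, mode = c("both", "bonferroni", "posterior")) {
    stopifnot(inherits(config, "PipelineConfig"))
    mode <- match.arg(mode)
    modes <- if (mode == "both") c("bonferroni", "posterior") else mode
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    panel <- stage("tissues", readLines(config$tissues))
    if (length(panel) < 2L) stop("tissue panel must have >= 2 tissues")
    ann <- stage("annotations", readGeneAnnotations(config$annotations, "tsv"))
    cnvrs <- stage("cnvrs", readCnvRegions(config$cnvrs))
    genes <- ann$gene_id
    message("inputs: ", length(genes), " genes, ", length(panel), " tissues, ",
            length(cnvrs), " CNV regions")
    paralogDf <- stage("paralogs",
        read.delim(config$paralogs, stringsAsFactors = FALSE))
    classTable <- stage("classify", suppressMessages(assembleClassTable(
        genes = genes,
        ohnologIds = readGeneList(config$ohnologs),
        paralogMap = stats::setNames(as.logical(paralogDf$has_paralog),
                                     stripGeneVersion(paralogDf$gene_id)),
        annotations = ann, cnvrs = cnvrs,
        cnvAffectedIds = readGeneList(config$cnvAffected),
        cnvAssayedIds = readGeneList(config$cnvAssayed),
        pliScores = readPliScores(config$pli),
        ccnIds = readGeneList(config$ccn))))
    exprFiles <- Sys.glob(config$expressionGlob)
    if (length(exprFiles) == 0L) stop("no expression tables found")
    tissueOf <- sub("^expr_", "", sub("\\.tsv$", "", basename(exprFiles)))
    se <- stage("expression",
        readExpressionTables(stats::setNames(exprFiles, tissueOf)))
    message("expression: ", nrow(se), " genes x ", ncol(se), " samples")

    callsets <- list(); gtms <- list()
    if ("bonferroni" %in% modes) {
        assoc <- stage("associations",
            readAssociations(config$associations, panel))
        message("associations: ", nrow(assoc), " rows")
        callsets$bonferroni <- stage("call-bonferroni",
            bonferroniCalls(assoc, nTissues = length(panel),
                            alpha = config$alpha, tissuePanel = panel))
        message("bonferroni calls: ", length(callsets$bonferroni))
    }
    if ("posterior" %in% modes) {
        mv <- stage("mvalues", readMValues(config$mvalues, panel))
        callsets$posterior <- stage("call-posterior",
            posteriorCalls(mv, threshold = config$posteriorThreshold,
                           tissuePanel = panel))
        message("posterior calls: ", length(callsets$posterior))
    }
    for (m in names(callsets))
        gtms[[m]] <- geneTissueMatrix(callsets[[m]], genes = genes,
                                      tissues = panel)
    expressed <- stage("breadth",
        expressedTissueCounts(se, config$tpmThreshold, allGenes = genes))
    medTpm <- medianTpmByTissue(se)

    affectedByMode <- lapply(gtms, function(g)
        rowSums(affectedMatrix(g)) > 0L)
    tables <- list()
    tables$table1_analog <- stage("stats-pooled",
        .pooledEnrichmentTable(classTable, affectedByMode, config$tableTests))
    tables$per_tissue_affected <- stage("stats-per-tissue",
        .perTissueTable(classTable, gtms))
    tables$jaccard_summaries <- stage("jaccard",
        .jaccardSummaryTable(classTable, gtms))
    tables$breadth_comparisons <- stage("breadth-compare",
        .breadthComparisonTable(classTable, gtms, expressed))
    tables$broad_depletion <- stage("broad-depletion",
        .broadDepletionTable(classTable, callsets, gtms, config$topFraction))
    if ("bonferroni" %in% modes) {
        tables$effect_sizes <- stage("effect-sizes",
            .effectSizeTable(classTable, assoc, callsets$bonferroni,
                             config$alpha, length(panel)))
        tables$logistic <- stage("logistic",
            .logisticTable(classTable, gtms$bonferroni, medTpm))
    }
    new("ReportBundle", tables = tables, mode = mode)
}

#' Write the report tables of a bundle as TSVs with a manifest
#'
#' One TSV per bundle table plus \code{manifest.tsv} listing each file, its
#' row count and its MD5 checksum. Fails before writing anything if the
#' directory cannot be created or written.
#'
#' @param bundle A \code{\link{ReportBundle}}.
#' @param outdir Output directory.
#' @return Invisibly, the manifest data.frame.
#' @export
writeReportTables <- function(bundle, outdir) {
    stopifnot(is(bundle, "ReportBundle"))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (file.access(outdir, 2L) != 0L)
        stop("output directory is not writable: ", outdir)
    files <- character()
    for (nm in names(bundle@tables)) {
        f <- file.path(outdir, paste0(nm, ".tsv"))
        writeTsv(bundle@tables[[nm]], f)
        files <- c(files, f)
    }
    manifest <- data.frame(
        file = basename(files),
        rows = vapply(bundle@tables, nrow, 1L),
        md5 = unname(md5sum(files)),
        stringsAsFactors = FALSE)
    writeTsv(manifest, file.path(outdir, "manifest.tsv"))
    invisible(manifest)
}
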