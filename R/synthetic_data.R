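#' @importFrom stats rnorm runif rlnorm rpois rbinom rbeta rgeom pgeom qgeom
#'   qlogis
NULL

#' Configuration for the synthetic multi-tissue eQTL dataset
#'
#' Defines the study conditions the generator plants: class mixing weights,
#' class-dependent eQTL incidence, tissue-breadth distributions (truncated
#' geometric), effect-size distributions (log-normal |slope| with random
#' sign), baseline expression, class-dependent expression dispersion and
#' allele-frequency model. Defaults emulate the qualitative structure of a
#' multi-tissue eQTL resource at desk scale: dosage-sensitive (ohnolog) genes
#' get a higher chance of carrying at least one eQTL but markedly narrower
#' per-eQTL tissue breadth, smaller absolute slopes and lower expression
#' dispersion; the other proxy axes are sampled correlated with ohnolog
#' status.
#'
#' @param seed RNG seed (mandatory).
#' @param nGenes Number of genes (default 2000).
#' @param nTissues Number of tissues in the panel (default 48).
#' @param nSamplesPerTissue Samples per tissue expression matrix (default 30).
#' @param classProportions Mixing weights of duplication classes.
#' @param eqtlIncidence Per-class probability that a gene carries >= 1 eQTL.
#' @param extraEqtlRate Per-class Poisson rate of additional eQTLs beyond the
#'   first.
#' @param breadthModel Per-class success probability of the truncated
#'   geometric tissue-breadth distribution on [1, nTissues]; larger values
#'   mean narrower eQTLs.
#' @param slopeModel Per-class \code{c(meanlog, sdlog)} of the log-normal
#'   |slope| distribution.
#' @param expressionModel \code{c(meanlog, sdlog)} of the log-normal baseline
#'   median TPM across genes.
#' @param cvMultiplier Per-class multiplier on the expression noise sd
#'   (log2 scale).
#' @param baseSigma Baseline expression noise sd on the log2(TPM + 1) scale.
#' @param tissueRestrictedFraction Fraction of genes expressed in only a
#'   random subset of tissues (others are near-silent, 0.01 TPM).
#' @param mafModel \code{c(shape1, shape2)} of the Beta distribution of minor
#'   allele frequency (scaled to [0, 0.5]).
#' @param axisProbs Conditional probabilities tying the other proxy axes to
#'   ohnolog status (see source; all overridable).
#' @param pliMissingRate Fraction of genes with no pLI score.
#' @param nNullPairs Number of non-eQTL (variant, gene) pairs receiving
#'   uniform p-values in every tissue.
#' @param alpha Significance level the planted p-values are scaled to: a
#'   planted eQTL draws nominal p below alpha/nTissues in its planted tissues
#'   and above it elsewhere.
#' @return Validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed,
                             nGenes = 2000L,
                             nTissues = 48L,
                             nSamplesPerTissue = 30L,
                             classProportions = c(ohnolog = 0.35, ssd = 0.35,
                                                  singleton = 0.30),
                             eqtlIncidence = c(ohnolog = 0.90, ssd = 0.72,
                                               singleton = 0.75),
                             extraEqtlRate = c(ohnolog = 0.8, ssd = 0.3,
                                               singleton = 0.3),
                             breadthModel = c(ohnolog = 0.5, ssd = 0.125,
                                              singleton = 0.125),
                             slopeModel = list(
                                 ohnolog = c(meanlog = log(0.30), sdlog = 0.35),
                                 ssd = c(meanlog = log(0.45), sdlog = 0.35),
                                 singleton = c(meanlog = log(0.45), sdlog = 0.35)),
                             expressionModel = c(meanlog = 2.1, sdlog = 1.0),
                             cvMultiplier = c(ohnolog = 0.8, ssd = 1.2,
                                              singleton = 1.0),
                             baseSigma = 0.5,
                             tissueRestrictedFraction = 0.2,
                             mafModel = c(shape1 = 1.5, shape2 = 8),
                             axisProbs = c(pCcnOhno = 0.60, pCcnOther = 0.25,
                                           pHiOhno = 0.35, pHiOther = 0.12,
                                           pCnvrOhno = 0.25, pCnvrOther = 0.45,
                                           pCnvAffOhno = 0.80, pCnvAffOther = 0.90,
                                           pCnvAssayed = 0.95),
                             pliMissingRate = 0.10,
                             nNullPairs = 200L,
                             alpha = 0.05) {
    if (missing(seed)) stop("seed is mandatory")
    cfg <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
                nTissues = as.integer(nTissues),
                nSamplesPerTissue = as.integer(nSamplesPerTissue),
                classProportions = classProportions,
                eqtlIncidence = eqtlIncidence,
                extraEqtlRate = extraEqtlRate,
                breadthModel = breadthModel, slopeModel = slopeModel,
                expressionModel = expressionModel,
                cvMultiplier = cvMultiplier, baseSigma = baseSigma,
                tissueRestrictedFraction = tissueRestrictedFraction,
                mafModel = mafModel, axisProbs = axisProbs,
                pliMissingRate = pliMissingRate,
                nNullPairs = as.integer(nNullPairs), alpha = alpha)
    bad <- character()
    classes <- c("ohnolog", "ssd", "singleton")
    for (nm in c("classProportions", "eqtlIncidence", "extraEqtlRate",
                 "breadthModel", "cvMultiplier"))
        if (!all(classes %in% names(cfg[[nm]]))) bad <- c(bad, nm)
    if (!all(classes %in% names(slopeModel))) bad <- c(bad, "slopeModel")
    if (any(eqtlIncidence < 0 | eqtlIncidence > 1)) bad <- c(bad, "eqtlIncidence")
    if (any(breadthModel <= 0 | breadthModel > 1)) bad <- c(bad, "breadthModel")
    if (abs(sum(classProportions) - 1) > 1e-8) bad <- c(bad, "classProportions")
    if (alpha <= 0 || alpha >= 1) bad <- c(bad, "alpha")
    if (nGenes < 1 || nTissues < 2 || nSamplesPerTissue < 2)
        bad <- c(bad, "nGenes/nTissues/nSamplesPerTissue")
    if (tissueRestrictedFraction < 0 || tissueRestrictedFraction > 1)
        bad <- c(bad, "tissueRestrictedFraction")
    if (pliMissingRate < 0 || pliMissingRate > 1) bad <- c(bad, "pliMissingRate")
    if (length(bad))
        stop("invalid simulation config field(s): ",
             paste(unique(bad), collapse = ", "))
    structure(cfg, class = "SimulationConfig")
}

# truncated geometric on [1, max]: breadth of a planted eQTL
.rtruncgeom <- function(n, prob, max) {
    u <- runif(n) * pgeom(max - 1L, prob)
    as.integer(qgeom(u, prob) + 1L)
}

#' Simulate a complete multi-tissue eQTL dataset
#'
#' Generates gene annotations and CNV regions, per-gene class labels on all
#' five dosage-sensitivity axes, per-tissue TPM expression matrices, a nominal
#' association table, a posterior (m-value) table, and the planted truth.
#' Planted eQTLs receive nominal p-values strictly below alpha/nTissues in
#' their planted tissues and above it elsewhere, and m-values above 0.9 in
#' exactly their planted tissues; null (variant, gene) pairs receive uniform
#' p-values in every tissue. Deterministic given the seed.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return A \code{\link{SimulatedEqtlData}}.
#' @export
simulateDataset <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    nG <- config$nGenes; nT <- config$nTissues; nS <- config$nSamplesPerTissue
    genes <- sprintf("ENSG%08d", seq_len(nG))
    tissues <- sprintf("Tissue%02d", seq_len(nT))
    classes <- c("ohnolog", "ssd", "singleton")
    status <- sample(classes, nG, replace = TRUE,
                     prob = config$classProportions[classes])
    isO <- status == "ohnolog"
    ap <- config$axisProbs
    ccn <- runif(nG) < ifelse(isO, ap["pCcnOhno"], ap["pCcnOther"])
    hi <- runif(nG) < ifelse(isO, ap["pHiOhno"], ap["pHiOther"])
    cnvrIn <- runif(nG) < ifelse(isO, ap["pCnvrOhno"], ap["pCnvrOther"])
    assayed <- runif(nG) < ap["pCnvAssayed"]
    cnvAff <- assayed & (runif(nG) <
                         ifelse(isO, ap["pCnvAffOhno"], ap["pCnvAffOther"]))
    pli <- ifelse(hi, runif(nG, 0.905, 0.999), runif(nG, 0.001, 0.895))
    pli[runif(nG) < config$pliMissingRate] <- NA_real_

    # non-overlapping gene intervals; a CNVR wraps each planted inside-gene
    geneLen <- 2000L; gap <- 10000L
    chroms <- paste0("chr", 1L + (seq_len(nG) - 1L) %% 4L)
    idxOnChrom <- stats::ave(seq_len(nG), chroms, FUN = seq_along)
    starts0 <- (idxOnChrom - 1L) * (geneLen + gap) + 1000L   # 0-based
    annotations <- GRanges(chroms, IRanges(starts0 + 1L, starts0 + geneLen),
                           strand = sample(c("+", "-"), nG, replace = TRUE))
    annotations$gene_id <- genes
    annotations$biotype <- "protein_coding"
    cnvrs <- GRanges(chroms[cnvrIn],
                     IRanges(starts0[cnvrIn] + 1L - 1000L,
                             starts0[cnvrIn] + geneLen + 1000L))
    cnvrs$name <- sprintf("cnvr%05d", seq_len(sum(cnvrIn)))

    # expression: per-gene baseline median TPM; restricted genes near-silent
    # outside their expressed tissues; class-dependent dispersion on log2 scale
    baseTpm <- rlnorm(nG, config$expressionModel["meanlog"],
                      config$expressionModel["sdlog"])
    restricted <- runif(nG) < config$tissueRestrictedFraction
    nExpressed <- ifelse(restricted,
                         sample(5:nT, nG, replace = TRUE), nT)
    exprMask <- matrix(TRUE, nG, nT)
    for (g in which(restricted))
        exprMask[g, sample.int(nT, nT - nExpressed[g])] <- FALSE
    sigma <- config$baseSigma * config$cvMultiplier[status]
    tpmList <- vector("list", nT)
    for (t in seq_len(nT)) {
        mu <- log2(ifelse(exprMask[, t], baseTpm, 0.01) + 1)
        x <- matrix(rnorm(nG * nS, mean = mu, sd = sigma), nG, nS)
        tpm <- pmax(2^x - 1, 0)
        colnames(tpm) <- sprintf("S%03d", seq_len(nS))
        rownames(tpm) <- genes
        tpmList[[t]] <- tpm
    }
    tpmAll <- do.call(cbind, tpmList)
    colTissue <- rep(tissues, each = nS)
    colSample <- rep(sprintf("S%03d", seq_len(nS)), times = nT)
    colnames(tpmAll) <- paste(colTissue, colSample, sep = ".")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(tpm = tpmAll),
        colData = S4Vectors::DataFrame(tissue = colTissue,
                                       sample_id = colSample))

    # planted eQTLs: class-dependent incidence, count, breadth and slope
    hasEqtl <- runif(nG) < config$eqtlIncidence[status]
    nEqtl <- ifelse(hasEqtl, 1L + rpois(nG, config$extraEqtlRate[status]), 0L)
    geneIdx <- rep(seq_len(nG), nEqtl)
    nE <- length(geneIdx)
    eClass <- status[geneIdx]
    breadth <- integer(nE)
    for (cl in classes) {
        sel <- eClass == cl
        breadth[sel] <- .rtruncgeom(sum(sel), config$breadthModel[cl], nT)
    }
    slopeAbs <- numeric(nE)
    for (cl in classes) {
        sel <- eClass == cl
        sm <- config$slopeModel[[cl]]
        slopeAbs[sel] <- rlnorm(sum(sel), sm["meanlog"], sm["sdlog"])
    }
    slope <- slopeAbs * sample(c(-1, 1), nE, replace = TRUE)
    eqtlIdxInGene <- unlist(lapply(nEqtl[nEqtl > 0L], seq_len), use.names = FALSE)
    variant <- sprintf("%s_%s_v%02d", chroms[geneIdx],
                       formatC(starts0[geneIdx], width = 9, flag = "0"),
                       eqtlIdxInGene)
    plantedTissues <- lapply(seq_len(nE), function(i)
        sort(sample(tissues, breadth[i])))
    maf <- 0.5 * rbeta(nE, config$mafModel["shape1"], config$mafModel["shape2"])

    # one association row per eQTL x tissue, built as long vectors
    pSig <- config$alpha / nT
    N <- nE * nT
    inSet <- if (nE > 0L)
        unlist(lapply(plantedTissues, function(ts) tissues %in% ts),
               use.names = FALSE) else logical(0)
    p <- numeric(N)
    p[inSet] <- runif(sum(inSet), 0, pSig * 0.999)
    p[!inSet] <- runif(sum(!inSet), pSig, 1)
    sl <- rep(slope, each = nT)
    sl[!inSet] <- rnorm(sum(!inSet), 0, 0.05)
    m <- numeric(N)
    m[inSet] <- runif(sum(inSet), 0.905, 0.9999)
    m[!inSet] <- runif(sum(!inSet), 0, 0.9)
    associations <- data.frame(
        variant_id = rep(variant, each = nT),
        gene_id = rep(genes[geneIdx], each = nT),
        tissue = rep(tissues, times = nE),
        nominal_p = p, slope = sl, maf = rep(maf, each = nT),
        stringsAsFactors = FALSE)
    mvalues <- data.frame(
        variant_id = rep(variant, each = nT),
        gene_id = rep(genes[geneIdx], each = nT),
        tissue = rep(tissues, times = nE),
        m_value = m, stringsAsFactors = FALSE)

    # null variant-gene pairs: uniform p everywhere (false calls expected at
    # rate alpha/nTissues per variant-tissue pair), sub-threshold m-values
    nNull <- config$nNullPairs
    if (nNull > 0L) {
        nullGene <- sample.int(nG, nNull, replace = TRUE)
        nullVar <- sprintf("%s_%s_null%04d", chroms[nullGene],
                           formatC(starts0[nullGene], width = 9, flag = "0"),
                           seq_len(nNull))
        nullMaf <- 0.5 * rbeta(nNull, config$mafModel["shape1"],
                               config$mafModel["shape2"])
        associations <- rbind(associations, data.frame(
            variant_id = rep(nullVar, each = nT),
            gene_id = rep(genes[nullGene], each = nT),
            tissue = rep(tissues, times = nNull),
            nominal_p = runif(nNull * nT),
            slope = rnorm(nNull * nT, 0, 0.05),
            maf = rep(nullMaf, each = nT), stringsAsFactors = FALSE))
        mvalues <- rbind(mvalues, data.frame(
            variant_id = rep(nullVar, each = nT),
            gene_id = rep(genes[nullGene], each = nT),
            tissue = rep(tissues, times = nNull),
            m_value = runif(nNull * nT, 0, 0.9), stringsAsFactors = FALSE))
    }
    rownames(associations) <- NULL
    rownames(mvalues) <- NULL

    truth <- data.frame(
        variant_id = variant, gene_id = genes[geneIdx],
        duplication_status = eClass, breadth = breadth,
        tissues = vapply(plantedTissues, paste, "", collapse = ";"),
        slope = slope, stringsAsFactors = FALSE)

    classTable <- suppressMessages(assembleClassTable(
        genes = genes,
        ohnologIds = genes[status == "ohnolog"],
        paralogMap = stats::setNames(status != "singleton", genes),
        annotations = annotations, cnvrs = cnvrs,
        cnvAffectedIds = genes[cnvAff],
        cnvAssayedIds = genes[assayed],
        pliScores = stats::setNames(pli, genes),
        ccnIds = genes[ccn]))

    new("SimulatedEqtlData", classTable = classTable,
        annotations = annotations, cnvrs = cnvrs, expression = se,
        associations = associations, mvalues = mvalues, truth = truth,
        config = unclass(config))
}

#' Write a simulated dataset as the plain-text files the readers consume
#'
#' Emits: gene annotation TSV, CNV-region BED, one expression TSV per tissue,
#' association and m-value TSVs, one-column gene lists (ohnologs,
#' CNV-affected, CNV-assayed, CCN), a paralogy map, a pLI table, the tissue
#' panel, the planted truth table and the resolved configuration as
#' key-value text.
#'
#' @param ds A \code{\link{SimulatedEqtlData}}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the written paths.
#' @export
writeSimulatedData <- function(ds, dir) {
    stopifnot(is(ds, "SimulatedEqtlData"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(...) file.path(dir, ...)
    ann <- data.frame(
        chrom = as.character(seqnames(ds@annotations)),
        start = GenomicRanges::start(ds@annotations) - 1L,  # back to 0-based
        end = GenomicRanges::end(ds@annotations),
        gene_id = ds@annotations$gene_id,
        strand = as.character(strand(ds@annotations)),
        biotype = ds@annotations$biotype, stringsAsFactors = FALSE)
    writeTsv(ann, p("annotations.tsv"))
    bed <- data.frame(
        chrom = as.character(seqnames(ds@cnvrs)),
        start = GenomicRanges::start(ds@cnvrs) - 1L,
        end = GenomicRanges::end(ds@cnvrs),
        name = ds@cnvrs$name, stringsAsFactors = FALSE)
    write.table(bed, p("cnvrs.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    tpm <- assay(ds@expression, "tpm")
    cd <- colData(ds@expression)
    for (t in unique(cd$tissue)) {
        m <- tpm[, cd$tissue == t, drop = FALSE]
        df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                         stringsAsFactors = FALSE)
        names(df)[-1] <- cd$sample_id[cd$tissue == t]
        writeTsv(df, p(paste0("expr_", t, ".tsv")))
    }
    writeAssociations(ds@associations, p("associations.tsv"))
    writeTsv(ds@mvalues, p("mvalues.tsv"))
    ct <- ds@classTable
    writeLines(ct$gene_id[ct$duplication_status == "ohnolog"], p("ohnologs.txt"))
    writeLines(ct$gene_id[ct$cnv_affected == "affected"], p("cnv_affected.txt"))
    writeLines(ct$gene_id[ct$cnv_affected != "unknown"], p("cnv_assayed.txt"))
    writeLines(ct$gene_id[ct$ccn], p("ccn.txt"))
    writeTsv(data.frame(gene_id = ct$gene_id,
                        has_paralog = ct$duplication_status != "singleton"),
             p("paralogs.tsv"))
    pliDf <- data.frame(gene_id = ct$gene_id, pli = ct$pli)
    writeTsv(pliDf[!is.na(pliDf$pli), ], p("pli.tsv"))
    writeLines(unique(colData(ds@expression)$tissue), p("tissues.txt"))
    writeTsv(ds@truth, p("truth.tsv"))
    cfg <- ds@config
    flat <- unlist(cfg)
    writeLines(paste0(names(flat), "=", vapply(flat, format, "")),
               p("config.txt"))
    files <- list.files(dir, full.names = TRUE)
    invisible(stats::setNames(files, basename(files)))
}

#' Compare recovered eQTL calls with the planted truth
#'
#' @param ds A \code{\link{SimulatedEqtlData}}.
#' @param callset An \code{\link{EqtlCallSet}} computed from the dataset's
#'   association (or m-value) table.
#' @return List: \code{n_planted}, \code{n_called}, \code{sensitivity}
#'   (fraction of planted (variant, gene) pairs recovered),
#'   \code{false_calls} (significant variant-gene-tissue triples not
#'   planted), \code{breadth_match} (fraction of recovered pairs whose
#'   breadth equals the planted breadth).
#' @export
plantedTruthCheck <- function(ds, callset) {
    stopifnot(is(ds, "SimulatedEqtlData"), is(callset, "EqtlCallSet"))
    truth <- ds@truth
    calls <- callset@calls
    tKey <- .callKey(truth$variant_id, truth$gene_id)
    cKey <- .callKey(calls$variant_id, calls$gene_id)
    recovered <- tKey %in% cKey
    truthTriples <- unlist(lapply(seq_len(nrow(truth)), function(i)
        paste(tKey[i], strsplit(truth$tissues[i], ";", fixed = TRUE)[[1]],
              sep = "\r")))
    callTriples <- paste(rep(cKey, lengths(calls$tissues)),
                         unlist(calls$tissues, use.names = FALSE), sep = "\r")
    falseCalls <- sum(!callTriples %in% truthTriples)
    breadthMatch <- if (any(recovered)) {
        called <- calls$breadth[match(tKey[recovered], cKey)]
        mean(called == truth$breadth[recovered])
    } else NA_real_
    list(n_planted = nrow(truth), n_called = nrow(calls),
         sensitivity = if (nrow(truth)) mean(recovered) else NA_real_,
         false_calls = falseCalls, breadth_match = breadthMatch)
}

#' Simulate per-(gene, tissue) eQTL-status records with planted odds ratios
#'
#' Generates rows of (affected, median_expression, duplication_status) for
#' \code{\link{fitEqtlLogistic}} parameter-recovery checks: status log-odds
#' offsets log(orSsd) and log(orSingleton) relative to ohnologs, plus an
#' optional linear expression effect on the log-odds.
#'
#' @param n Number of rows.
#' @param orSsd,orSingleton Planted odds ratios vs the ohnolog reference.
#' @param baseProb Affected probability for an ohnolog (at expression effect
#'   zero).
#' @param exprEffect Log-odds slope per TPM of median expression (default 0).
#' @param seed RNG seed.
#' @return data.frame with the three model columns.
#' @export
simulateEqtlStatusRecords <- function(n, orSsd = 1.4, orSingleton = 1.4,
                                      baseProb = 0.3, exprEffect = 0,
                                      seed = 1L) {
    set.seed(seed)
    status <- sample(c("ohnolog", "ssd", "singleton"), n, replace = TRUE)
    expr <- rlnorm(n, meanlog = 2, sdlog = 0.5)
    eta <- qlogis(baseProb) +
        log(orSsd) * (status == "ssd") +
        log(orSingleton) * (status == "singleton") +
        exprEffect * expr
    data.frame(affected = runif(n) < plogis(eta),
               median_expression = expr,
               duplication_status = status, stringsAsFactors = FALSE)
}

#' Simulate null variant-tissue association rows
#'
#' Rows carry uniform nominal p-values and near-zero slopes: the false-call
#' behaviour of \code{\link{bonferroniCalls}} on such rows is binomial with
#' per-row success probability alpha/nTissues.
#'
#' @param n Number of variant-tissue rows.
#' @param tissues Tissue panel to draw labels from.
#' @param seed RNG seed.
#' @return data.frame of association rows (one distinct variant-gene pair
#'   per row).
#' @export
simulateNullAssociations <- function(n, tissues, seed = 1L) {
    set.seed(seed)
    data.frame(
        variant_id = sprintf("null_v%06d", seq_len(n)),
        gene_id = sprintf("NULLG%06d", seq_len(n)),
        tissue = sample(tissues, n, replace = TRUE),
        nominal_p = runif(n),
        slope = rnorm(n, 0, 0.05),
        stringsAsFactors = FALSE)
}
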