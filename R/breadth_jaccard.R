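#' @importFrom SummarizedExperiment assay colData
NULL

#' Per-tissue median TPM matrix
#'
#' @param se A \code{SummarizedExperiment} with assay \code{"tpm"} and
#'   \code{colData} column \code{tissue}.
#' @return Numeric gene x tissue matrix of median TPM across the samples of
#'   each tissue.
#' @export
medianTpmByTissue <- function(se) {
    tpm <- assay(se, "tpm")
    tissue <- colData(se)$tissue
    tissues <- unique(tissue)
    out <- vapply(tissues, function(t) {
        apply(tpm[, tissue == t, drop = FALSE], 1L, stats::median)
    }, numeric(nrow(tpm)))
    if (is.null(dim(out))) out <- matrix(out, nrow = nrow(tpm))
    dimnames(out) <- list(rownames(tpm), tissues)
    out
}

#' Count the tissues in which each gene is expressed
#'
#' A gene counts as expressed in a tissue when its median TPM across that
#' tissue's samples is strictly above \code{tpmThreshold} (default 0.1 TPM,
#' a conventional detectability floor; configurable).
#'
#' @param se A \code{SummarizedExperiment} of TPM values (see
#'   \code{\link{readExpressionTables}}).
#' @param tpmThreshold Expression threshold on the median TPM.
#' @param allGenes Optional gene universe; genes absent from the expression
#'   experiment get count 0 with a warning.
#' @return Named integer vector of expressed-tissue counts.
#' @export
expressedTissueCounts <- function(se, tpmThreshold = 0.1, allGenes = NULL) {
    med <- medianTpmByTissue(se)
    counts <- as.integer(rowSums(med > tpmThreshold))
    names(counts) <- rownames(med)
    if (!is.null(allGenes)) {
        missing <- setdiff(allGenes, names(counts))
        if (length(missing)) {
            warning(length(missing),
                    " gene(s) absent from all expression tables; count 0")
            add <- integer(length(missing)); names(add) <- missing
            counts <- c(counts, add)[allGenes]
        } else counts <- counts[allGenes]
    }
    counts
}

#' Per-gene eQTL-affected tissue proportions
#'
#' For each gene, the number of eQTL-affected tissues (row sum of the
#' gene x tissue matrix), the number of expressed tissues, and their ratio.
#' The proportion is capped at 1: an eQTL can be detected in a tissue whose
#' median expression sits below the expression threshold, so the affected
#' count is not bounded by the expressed count. Genes with zero expressed
#' tissues are excluded.
#'
#' @param gtm A \code{\link{GeneTissueMatrix}}.
#' @param expressed Named integer vector from
#'   \code{\link{expressedTissueCounts}}.
#' @return data.frame with columns \code{gene_id}, \code{n_expressed_tissues},
#'   \code{n_affected_tissues}, \code{affected_proportion}.
#' @export
affectedProportions <- function(gtm, expressed) {
    stopifnot(is(gtm, "GeneTissueMatrix"))
    genes <- intersect(rownames(gtm@affected), names(expressed))
    nExp <- unname(expressed[genes])
    nAff <- unname(rowSums(gtm@affected[genes, , drop = FALSE]))
    keep <- nExp > 0L
    data.frame(
        gene_id = genes[keep],
        n_expressed_tissues = nExp[keep],
        n_affected_tissues = as.integer(nAff[keep]),
        affected_proportion = pmin(1, nAff[keep] / nExp[keep]),
        stringsAsFactors = FALSE
    )
}

#' Broad-tissue-breadth threshold from the breadth distribution
#'
#' Returns the smallest integer t such that the fraction of eQTLs with
#' breadth >= t is at most \code{topFraction}: the "top 10\% of eQTLs affect
#' expression in t or more tissues" cutoff. If no eQTL qualifies (e.g. all breadths equal 1 and
#' topFraction < 1), the threshold exceeds the maximum observed breadth.
#'
#' @param breadths Integer vector of per-eQTL tissue breadths (non-empty).
#' @param topFraction Upper-tail fraction defining "broad" (default 0.10).
#' @return Integer threshold.
#' @export
breadthQuantileThreshold <- function(breadths, topFraction = 0.10) {
    if (length(breadths) == 0L) stop("empty breadth vector")
    if (topFraction <= 0 || topFraction > 1)
        stop("topFraction must lie in (0, 1]")
    for (t in seq_len(max(breadths) + 1L)) {
        if (mean(breadths >= t) <= topFraction) return(as.integer(t))
    }
    as.integer(max(breadths) + 1L)  # unreachable; defensive
}

#' Focal-set membership and broad-breadth status per gene
#'
#' A gene is in the focal set when it is eQTL-affected in at least
#' \code{minAffectedTissues} tissues (union over all its eQTLs) -- such a
#' gene could be affected by, say, 14 single-tissue eQTLs or by one
#' 14-tissue eQTL. It is \code{broad_affected} when at least one of its
#' eQTLs has breadth >= \code{threshold}.
#'
#' @param callset An \code{\link{EqtlCallSet}}.
#' @param gtm The matching \code{\link{GeneTissueMatrix}}.
#' @param threshold Broad-breadth cutoff from
#'   \code{\link{breadthQuantileThreshold}}.
#' @param minAffectedTissues Focal-set cutoff; defaults to \code{threshold}.
#' @return data.frame with columns \code{gene_id}, \code{in_focal_set},
#'   \code{broad_affected}.
#' @export
focalBroadClassification <- function(callset, gtm, threshold,
                                     minAffectedTissues = threshold) {
    stopifnot(is(callset, "EqtlCallSet"), is(gtm, "GeneTissueMatrix"))
    genes <- rownames(gtm@affected)
    inFocal <- rowSums(gtm@affected) >= minAffectedTissues
    broadGenes <- unique(callset@calls$gene_id[callset@calls$breadth >= threshold])
    data.frame(
        gene_id = genes,
        in_focal_set = unname(inFocal),
        broad_affected = genes %in% broadGenes,
        stringsAsFactors = FALSE
    )
}

#' Tissue-pair Jaccard matrix of eQTL-affected gene sets
#'
#' For each pair of tissues, the Jaccard index (size of the intersection
#' divided by the size of the union) of the sets of eQTL-affected genes in
#' the two tissues, restricted to a gene stratum (e.g. ohnologs). The index
#' of two empty sets is defined as 0; the diagonal is 1 wherever the
#' tissue's gene set is non-empty.
#'
#' @param gtm A \code{\link{GeneTissueMatrix}}.
#' @param stratum Character vector of gene ids to restrict to (non-empty).
#' @param stratumLabel Label stored with the result.
#' @return A \code{\link{JaccardIndexMatrix}}.
#' @export
jaccardMatrix <- function(gtm, stratum, stratumLabel = "all") {
    stopifnot(is(gtm, "GeneTissueMatrix"))
    if (length(stratum) == 0L) stop("stratum must be non-empty")
    x <- gtm@affected[rownames(gtm@affected) %in% stratum, , drop = FALSE]
    storage.mode(x) <- "double"
    inter <- crossprod(x)                         # |S_i intersect S_j|
    size <- colSums(x)
    uni <- outer(size, size, "+") - inter         # |S_i union S_j|
    j <- ifelse(uni > 0, inter / uni, 0)
    dimnames(j) <- list(colnames(gtm@affected), colnames(gtm@affected))
    new("JaccardIndexMatrix", values = j, stratum = stratumLabel)
}

#' Upper-triangle values of a Jaccard matrix
#'
#' @param jm A \code{\link{JaccardIndexMatrix}}.
#' @return Numeric vector of the C(n, 2) unordered tissue-pair values
#'   (diagonal excluded).
#' @export
upperTriValues <- function(jm) {
    stopifnot(is(jm, "JaccardIndexMatrix"))
    jm@values[upper.tri(jm@values)]
}

#' Paired tissue-pair Jaccard distributions for two strata
#'
#' Extracts the unordered tissue-pair Jaccard values of two strata computed
#' on the same tissue panel (C(n, 2) values each; 1,128 for a 48-tissue
#' panel), ready for a rank-sum comparison.
#'
#' @param jmA,jmB \code{\link{JaccardIndexMatrix}} objects on identical
#'   tissue panels.
#' @return List with elements \code{a} and \code{b} (numeric vectors) and
#'   \code{labels} (the two stratum labels).
#' @export
jaccardPairwiseDistributions <- function(jmA, jmB) {
    if (!identical(rownames(jmA@values), rownames(jmB@values)))
        stop("tissue panels of the two Jaccard matrices differ")
    list(a = upperTriValues(jmA), b = upperTriValues(jmB),
         labels = c(jmA@stratum, jmB@stratum))
}
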