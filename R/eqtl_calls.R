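#' @importFrom stats median
NULL

.callKey <- function(variant, gene) paste(variant, gene, sep = "\r")

.buildCallSet <- function(variant, gene, tissue, mode, tissuePanel) {
    key <- .callKey(variant, gene)
    o <- order(key, tissue, method = "radix")
    key <- key[o]; variant <- variant[o]; gene <- gene[o]; tissue <- tissue[o]
    first <- !duplicated(key)
    tissues <- IRanges::CharacterList(split(tissue, factor(key, levels = key[first])))
    tissues <- unique(tissues)
    calls <- S4Vectors::DataFrame(
        variant_id = variant[first],
        gene_id = gene[first],
        tissues = tissues,
        breadth = lengths(tissues)
    )
    rownames(calls) <- NULL
    new("EqtlCallSet", calls = calls, mode = mode, tissuePanel = tissuePanel)
}

#' Call eQTLs by Bonferroni correction across the tissue panel
#'
#' Each nominal per-tissue p-value is Bonferroni-corrected for the number of
#' tissues tested (adjusted p = min(1, p x nTissues)); a tissue is significant
#' for a (variant, gene) pair iff its adjusted p is strictly below
#' \code{alpha}. Pairs with no significant tissue are not emitted: an eQTL is
#' only considered further when it remains significant after correction in at
#' least one tissue.
#'
#' @param assoc data.frame of associations (columns \code{variant_id},
#'   \code{gene_id}, \code{tissue}, \code{nominal_p}).
#' @param nTissues Bonferroni factor; the size of the tissue panel
#'   (default 48).
#' @param alpha Significance level after correction (default 0.05).
#' @param tissuePanel Tissue labels of the panel; defaults to the tissues
#'   observed in \code{assoc}.
#' @return An \code{\link{EqtlCallSet}} with \code{mode = "bonferroni"}.
#' @export
bonferroniCalls <- function(assoc, nTissues = 48L, alpha = 0.05,
                            tissuePanel = sort(unique(assoc$tissue))) {
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
        stop("alpha must lie strictly in (0, 1)")
    if (nTissues < 1L) stop("nTissues must be >= 1")
    adj <- pmin(1, assoc$nominal_p * nTissues)
    sig <- adj < alpha
    .buildCallSet(assoc$variant_id[sig], assoc$gene_id[sig], assoc$tissue[sig],
                  "bonferroni", tissuePanel)
}

#' Call eQTLs by posterior probability threshold
#'
#' A tissue is significant for a (variant, gene) pair iff its posterior
#' probability (m-value) is strictly greater than \code{threshold}; an
#' m-value of exactly the threshold is excluded. Pairs with no passing tissue
#' are not emitted.
#'
#' @param mvalues data.frame with columns \code{variant_id}, \code{gene_id},
#'   \code{tissue}, \code{m_value}.
#' @param threshold Posterior probability cutoff (default 0.9, strict).
#' @param tissuePanel Tissue labels of the panel.
#' @return An \code{\link{EqtlCallSet}} with \code{mode = "posterior"}.
#' @export
posteriorCalls <- function(mvalues, threshold = 0.9,
                           tissuePanel = sort(unique(mvalues$tissue))) {
    if (any(mvalues$m_value < 0 | mvalues$m_value > 1))
        stop("m-values must lie in [0, 1]")
    sig <- mvalues$m_value > threshold
    .buildCallSet(mvalues$variant_id[sig], mvalues$gene_id[sig],
                  mvalues$tissue[sig], "posterior", tissuePanel)
}

#' Tissue breadth of each eQTL call
#'
#' The tissue breadth of an eQTL is simply the count of tissues in which the
#' (variant, gene) pair remained significant; always at least 1 for an
#' emitted call.
#'
#' @param callset An \code{\link{EqtlCallSet}}.
#' @return Integer vector, one breadth per call.
#' @export
eqtlTissueBreadth <- function(callset) {
    stopifnot(is(callset, "EqtlCallSet"))
    as.integer(callset@calls$breadth)
}

#' Build the gene-by-tissue eQTL-affected matrix
#'
#' \code{affected[g, t]} is the union over all calls for gene g of the
#' indicator that tissue t is significant; genes with no call get an all-false
#' row. Gene-level "eQTL-affected" status used in pooled comparisons is
#' \code{rowSums(affected) > 0}.
#'
#' @param callset An \code{\link{EqtlCallSet}} (single mode by construction).
#' @param genes Ordered gene ids for the rows; defaults to the genes with
#'   calls.
#' @param tissues Ordered tissue labels for the columns; defaults to the
#'   call set's panel.
#' @return A \code{\link{GeneTissueMatrix}}.
#' @export
geneTissueMatrix <- function(callset, genes = NULL, tissues = NULL) {
    stopifnot(is(callset, "EqtlCallSet"))
    if (is.null(tissues)) tissues <- callset@tissuePanel
    if (is.null(genes)) genes <- sort(unique(callset@calls$gene_id))
    m <- matrix(FALSE, nrow = length(genes), ncol = length(tissues),
                dimnames = list(genes, tissues))
    if (nrow(callset@calls)) {
        reps <- lengths(callset@calls$tissues)
        g <- rep(callset@calls$gene_id, reps)
        t <- unlist(callset@calls$tissues, use.names = FALSE)
        keep <- g %in% genes & t %in% tissues
        m[cbind(match(g[keep], genes), match(t[keep], tissues))] <- TRUE
    }
    new("GeneTissueMatrix", affected = m, mode = callset@mode)
}

#' Most significant calling association per gene and tissue
#'
#' Restricted to associations that are significant calls (the variant-gene
#' pair is in the call set and the tissue is among its significant tissues),
#' selects for every (gene, tissue) the record with the smallest nominal
#' p-value; exact ties are broken by the lexicographically smallest
#' variant id.
#'
#' @param assoc data.frame of associations (must include the calling records).
#' @param callset An \code{\link{EqtlCallSet}} derived from \code{assoc}.
#' @return data.frame with one row per (gene, tissue) holding the selected
#'   association.
#' @export
topEqtlPerGeneTissue <- function(assoc, callset) {
    stopifnot(is(callset, "EqtlCallSet"))
    calls <- callset@calls
    reps <- lengths(calls$tissues)
    sigKey <- paste(rep(calls$variant_id, reps), rep(calls$gene_id, reps),
                    unlist(calls$tissues, use.names = FALSE), sep = "\r")
    rowKey <- paste(assoc$variant_id, assoc$gene_id, assoc$tissue, sep = "\r")
    sub <- assoc[rowKey %in% sigKey, , drop = FALSE]
    if (nrow(sub) == 0L) return(sub)
    o <- order(sub$gene_id, sub$tissue, sub$nominal_p, sub$variant_id,
               method = "radix")
    sub <- sub[o, , drop = FALSE]
    first <- !duplicated(paste(sub$gene_id, sub$tissue, sep = "\r"))
    out <- sub[first, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write an eQTL call set as a TSV
#'
#' One row per call: variant, gene, mode, breadth and a semicolon-joined list
#' of significant tissues.
#'
#' @param callset An \code{\link{EqtlCallSet}}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeCalls <- function(callset, path) {
    df <- data.frame(
        variant_id = callset@calls$variant_id,
        gene_id = callset@calls$gene_id,
        mode = callset@mode,
        breadth = callset@calls$breadth,
        tissues = vapply(callset@calls$tissues, paste, "", collapse = ";"),
        stringsAsFactors = FALSE
    )
    writeTsv(df, path)
}
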