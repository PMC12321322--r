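#' @importFrom GenomicRanges countOverlaps
NULL

#' Classify genes by duplication status
#'
#' Genes named in the ohnolog list (duplicates retained from the vertebrate
#' whole-genome duplications) are labelled \code{ohnolog} even when they also
#' have other paralogs, since small-scale duplicates are defined as genes with
#' protein-coding paralogs not classed as ohnologs. Remaining genes with a
#' protein-coding paralog are \code{ssd}; genes with a paralogy entry and no
#' paralog are \code{singleton}; genes absent from the paralogy map are
#' \code{unknown}.
#'
#' @param genes Character vector of (normalized) gene ids.
#' @param ohnologIds Character vector of ohnolog gene ids; ids not present in
#'   \code{genes} are ignored with a warning.
#' @param paralogMap Named logical vector: does the gene have a protein-coding
#'   paralog?
#' @return Named character vector over \code{genes} with values in
#'   \code{ohnolog}, \code{ssd}, \code{singleton}, \code{unknown}.
#' @export
classifyDuplication <- function(genes, ohnologIds, paralogMap) {
    extra <- setdiff(ohnologIds, genes)
    if (length(extra))
        warning(length(extra), " ohnolog id(s) not in the gene universe ignored")
    status <- rep("unknown", length(genes))
    names(status) <- genes
    hasPar <- paralogMap[genes]
    known <- !is.na(hasPar)
    status[known & hasPar] <- "ssd"
    status[known & !hasPar] <- "singleton"
    status[genes %in% ohnologIds] <- "ohnolog"
    status
}

#' Classify genes by CNV-region membership
#'
#' A gene is \code{inside} iff its interval shares at least one base with at
#' least one CNV region on either strand (strand is ignored), matching a
#' bedtools-style intersection.
#'
#' @param annotations \code{GRanges} with metadata column \code{gene_id}.
#' @param cnvrs \code{GRanges} of CNV regions.
#' @return Named character vector (\code{inside}/\code{outside}) over gene ids.
#' @export
classifyCnvrMembership <- function(annotations, cnvrs) {
    if (length(annotations) == 0L) stop("empty gene annotation set")
    annPref <- grepl("^chr", as.character(unique(seqnames(annotations))))
    cnvPref <- grepl("^chr", as.character(unique(seqnames(cnvrs))))
    if (length(cnvrs) > 0L &&
        ((all(annPref) && !any(cnvPref)) || (!any(annPref) && all(cnvPref))))
        stop("chromosome naming mismatch: annotations and CNV regions use ",
             "different chromosome naming schemes for every gene")
    # disjoint seqlevel sets are legitimate here (a chromosome may simply
    # carry no CNVR), so the combine-Seqinfo warning is silenced
    n <- suppressWarnings(countOverlaps(annotations, cnvrs,
                                        ignore.strand = TRUE))
    out <- ifelse(n > 0L, "inside", "outside")
    names(out) <- annotations$gene_id
    out
}

#' Classify genes as haploinsufficient by pLI score
#'
#' pLI (probability of loss-of-function intolerance) strictly greater than 0.9
#' marks a gene haploinsufficient; strictly less than 0.9 haplosufficient.
#' A score of exactly 0.9, or a missing score, yields \code{unknown} and the
#' gene is excluded from haploinsufficiency comparisons.
#'
#' @param pliScores Named numeric vector of pLI scores in [0, 1] (NA allowed).
#' @param genes Character vector of gene ids to classify; defaults to the
#'   names of \code{pliScores}.
#' @return Named character vector with values \code{haploinsufficient},
#'   \code{haplosufficient}, \code{unknown}.
#' @export
classifyHaploinsufficiency <- function(pliScores, genes = names(pliScores)) {
    ok <- is.na(pliScores) | (pliScores >= 0 & pliScores <= 1)
    if (!all(ok))
        stop("pLI score(s) outside [0, 1]: ",
             paste(names(pliScores)[!ok], collapse = ", "))
    s <- pliScores[genes]
    out <- rep("unknown", length(genes))
    names(out) <- genes
    out[!is.na(s) & s > 0.9] <- "haploinsufficient"
    out[!is.na(s) & s < 0.9] <- "haplosufficient"
    out
}

#' Assemble the per-gene dosage-sensitivity class table
#'
#' Combines all five proxy axes into one table: duplication status
#' (ohnolog/SSD/singleton), CNV-region membership, exome-CNV call status, pLI
#' haploinsufficiency class and mammalian copy-number conservation. Genes
#' absent from the exome-CNV call universe are \code{unknown} on that axis
#' (absence from a call list is not evidence of being CNV-free unless the
#' gene was assayed).
#'
#' @param genes Character vector of gene ids (non-empty).
#' @param ohnologIds,paralogMap See \code{\link{classifyDuplication}}.
#' @param annotations,cnvrs See \code{\link{classifyCnvrMembership}}; pass
#'   \code{NULL} to leave the axis \code{unknown}.
#' @param cnvAffectedIds Gene ids with a confident exome CNV call.
#' @param cnvAssayedIds Gene ids in the exome-CNV call universe; genes here
#'   but not in \code{cnvAffectedIds} are \code{free}. Defaults to
#'   \code{genes} (all assayed).
#' @param pliScores Named numeric vector of pLI scores.
#' @param ccnIds Gene ids with conserved copy number across mammals.
#' @return data.frame with columns \code{gene_id}, \code{duplication_status},
#'   \code{cnvr_member}, \code{cnv_affected}, \code{pli}, \code{haplo_class},
#'   \code{ccn}.
#' @export
assembleClassTable <- function(genes, ohnologIds, paralogMap,
                               annotations = NULL, cnvrs = NULL,
                               cnvAffectedIds = character(),
                               cnvAssayedIds = genes,
                               pliScores = numeric(),
                               ccnIds = character()) {
    if (length(genes) == 0L) stop("empty gene list")
    dup <- classifyDuplication(genes, ohnologIds, paralogMap)
    cnvr <- rep(NA_character_, length(genes))
    if (!is.null(annotations) && !is.null(cnvrs)) {
        memb <- classifyCnvrMembership(annotations, cnvrs)
        cnvr <- unname(memb[genes])
    }
    cnvAff <- rep("unknown", length(genes))
    cnvAff[genes %in% cnvAssayedIds] <- "free"
    cnvAff[genes %in% cnvAffectedIds] <- "affected"
    haplo <- classifyHaploinsufficiency(pliScores, genes)
    pli <- unname(pliScores[genes])
    if (length(pli) == 0L) pli <- rep(NA_real_, length(genes))
    out <- data.frame(
        gene_id = genes,
        duplication_status = unname(dup),
        cnvr_member = cnvr,
        cnv_affected = cnvAff,
        pli = pli,
        haplo_class = unname(haplo),
        ccn = genes %in% ccnIds,
        stringsAsFactors = FALSE
    )
    message("gene classes: ",
            sum(out$duplication_status == "ohnolog"), " ohnolog / ",
            sum(out$duplication_status == "ssd"), " ssd / ",
            sum(out$duplication_status == "singleton"), " singleton; ",
            sum(out$cnvr_member == "inside", na.rm = TRUE), " in CNVR; ",
            sum(out$haplo_class == "haploinsufficient"), " haploinsufficient; ",
            sum(out$ccn), " CCN")
    out
}

#' Group labels for one dosage-sensitivity axis
#'
#' Returns the comparison grouping used throughout the analysis for a chosen
#' axis, with \code{NA} for genes excluded on that axis only. The
#' \code{duplication2} axis collapses SSDs and singletons into
#' \code{nonohnolog} for ohnolog-vs-nonohnolog contrasts.
#'
#' @param classTable data.frame from \code{\link{assembleClassTable}}.
#' @param axis One of \code{"duplication"}, \code{"duplication2"},
#'   \code{"cnvr"}, \code{"cnv"}, \code{"haplo"}, \code{"ccn"}.
#' @return Named character vector over \code{classTable$gene_id}.
#' @export
classAxisGroups <- function(classTable,
                            axis = c("duplication", "duplication2", "cnvr",
                                     "cnv", "haplo", "ccn")) {
    axis <- match.arg(axis)
    g <- switch(axis,
        duplication = ifelse(classTable$duplication_status %in%
                                 c("ohnolog", "ssd", "singleton"),
                             classTable$duplication_status, NA_character_),
        duplication2 = ifelse(classTable$duplication_status == "ohnolog",
                              "ohnolog",
                       ifelse(classTable$duplication_status %in%
                                  c("ssd", "singleton"),
                              "nonohnolog", NA_character_)),
        cnvr = classTable$cnvr_member,
        cnv = ifelse(classTable$cnv_affected %in% c("affected", "free"),
                     classTable$cnv_affected, NA_character_),
        haplo = ifelse(classTable$haplo_class %in%
                           c("haploinsufficient", "haplosufficient"),
                       classTable$haplo_class, NA_character_),
        ccn = ifelse(classTable$ccn, "conserved", "not_conserved")
    )
    names(g) <- classTable$gene_id
    g
}

#' Read a one-column gene-id list file
#'
#' @param path Path to a text file with one gene id per line (no header).
#' @return Character vector of normalized gene ids.
#' @export
readGeneList <- function(path) {
    if (!file.exists(path)) stop("gene list not found: ", path)
    ids <- readLines(path)
    ids <- ids[nzchar(ids)]
    stripGeneVersion(ids)
}

#' Read a two-column gene-id / pLI TSV
#'
#' @param path Path to a headered TSV with columns \code{gene_id}, \code{pli}.
#' @return Named numeric vector of pLI scores.
#' @export
readPliScores <- function(path) {
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "pli") %in% names(df)))
        stop("pLI table must have columns gene_id, pli")
    out <- df$pli
    names(out) <- stripGeneVersion(df$gene_id)
    out
}
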