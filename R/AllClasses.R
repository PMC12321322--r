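#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Set of eQTL calls under one calling mode
#'
#' An \code{EqtlCallSet} holds one row per (variant, gene) pair that is a
#' significant eQTL in at least one tissue of the panel, together with the set
#' of tissues in which it is significant. Calls are produced either by
#' Bonferroni correction of nominal per-tissue p-values across the tissue
#' panel (\code{mode = "bonferroni"}) or by thresholding per-tissue posterior
#' probabilities from a cross-tissue meta-analysis (\code{mode = "posterior"}).
#'
#' @slot calls A \code{\link[S4Vectors]{DataFrame}} with columns
#'   \code{variant_id}, \code{gene_id}, \code{tissues} (a
#'   \code{\link[IRanges]{CharacterList}} of significant tissues) and
#'   \code{breadth} (integer; the number of significant tissues).
#' @slot mode Character scalar, \code{"bonferroni"} or \code{"posterior"}.
#' @slot tissuePanel Character vector of all tissue labels in the panel.
#'
#' @seealso \code{\link{bonferroniCalls}}, \code{\link{posteriorCalls}}
#' @export
setClass("EqtlCallSet",
    representation(
        calls = "DataFrame",
        mode = "character",
        tissuePanel = "character"
    )
)

setValidity("EqtlCallSet", function(object) {
    msg <- character()
    need <- c("variant_id", "gene_id", "tissues", "breadth")
    if (!all(need %in% colnames(object@calls)))
        msg <- c(msg, paste("calls must have columns:", paste(need, collapse = ", ")))
    if (length(object@mode) != 1L || !object@mode %in% c("bonferroni", "posterior"))
        msg <- c(msg, "mode must be 'bonferroni' or 'posterior'")
    if (length(object@tissuePanel) < 1L)
        msg <- c(msg, "tissuePanel must be non-empty")
    if (nrow(object@calls) > 0L) {
        br <- object@calls$breadth
        if (any(br < 1L))
            msg <- c(msg, "every call must be significant in at least one tissue")
        tis <- unique(unlist(object@calls$tissues))
        if (length(tis) && !all(tis %in% object@tissuePanel))
            msg <- c(msg, "significant tissues must be drawn from the tissue panel")
    }
    if (length(msg)) msg else TRUE
})

#' Gene-by-tissue eQTL-affected indicator matrix
#'
#' Boolean matrix with one row per gene and one column per tissue;
#' \code{affected[g, t]} is \code{TRUE} iff at least one eQTL call for gene
#' \code{g} includes tissue \code{t} among its significant tissues.
#'
#' @slot affected Logical matrix with gene ids as rownames and tissue labels
#'   as colnames.
#' @slot mode Calling mode the matrix was derived from.
#'
#' @seealso \code{\link{geneTissueMatrix}}
#' @export
setClass("GeneTissueMatrix",
    representation(affected = "matrix", mode = "character")
)

setValidity("GeneTissueMatrix", function(object) {
    msg <- character()
    if (!is.logical(object@affected))
        msg <- c(msg, "affected must be a logical matrix")
    if (is.null(rownames(object@affected)) || is.null(colnames(object@affected)))
        msg <- c(msg, "affected must carry gene rownames and tissue colnames")
    if (length(object@mode) != 1L || !object@mode %in% c("bonferroni", "posterior"))
        msg <- c(msg, "mode must be 'bonferroni' or 'posterior'")
    if (length(msg)) msg else TRUE
})

#' Tissue-pair Jaccard similarity matrix
#'
#' Symmetric tissue-by-tissue matrix of Jaccard indices (intersection over
#' union) of the eQTL-affected gene sets of each tissue pair, computed on one
#' gene stratum (e.g. ohnologs). The Jaccard index of two empty sets is
#' defined as 0.
#'
#' @slot values Symmetric numeric matrix in [0, 1] with tissue labels as
#'   dimnames.
#' @slot stratum Label of the gene stratum the matrix was computed on.
#'
#' @seealso \code{\link{jaccardMatrix}}
#' @export
setClass("JaccardIndexMatrix",
    representation(values = "matrix", stratum = "character")
)

setValidity("JaccardIndexMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
    if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
        msg <- c(msg, "values must have matching tissue dimnames")
    if (any(v < 0 | v > 1)) msg <- c(msg, "Jaccard values must lie in [0, 1]")
    if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "values must be symmetric")
    if (length(msg)) msg else TRUE
})

#' A complete simulated multi-tissue eQTL dataset
#'
#' Container for the output of \code{\link{simulateDataset}}: per-gene
#' dosage-sensitivity class labels, gene annotations and CNV regions, a
#' multi-tissue expression experiment, nominal association and posterior
#' (m-value) tables, and the planted truth (which variant-gene pairs are real
#' eQTLs, in which tissues, with what slope).
#'
#' @slot classTable data.frame of per-gene class labels (see
#'   \code{\link{assembleClassTable}}).
#' @slot annotations \code{GRanges} of gene intervals with \code{gene_id}.
#' @slot cnvrs \code{GRanges} of copy-number-variable regions.
#' @slot expression \code{SummarizedExperiment}; assay \code{"tpm"}, columns
#'   are tissue/sample combinations with \code{colData} columns \code{tissue}
#'   and \code{sample_id}.
#' @slot associations data.frame of nominal per-tissue associations.
#' @slot mvalues data.frame of per-tissue posterior probabilities.
#' @slot truth data.frame of planted eQTLs (variant, gene, tissues, slope).
#' @slot config The resolved \code{\link{simulationConfig}} used.
#'
#' @export
setClass("SimulatedEqtlData",
    representation(
        classTable = "data.frame",
        annotations = "ANY",
        cnvrs = "ANY",
        expression = "ANY",
        associations = "data.frame",
        mvalues = "data.frame",
        truth = "data.frame",
        config = "list"
    )
)

#' Bundle of analysis report tables
#'
#' Named list of tidy data.frames produced by \code{\link{runFullAnalysis}},
#' mirroring the headline analyses: pooled enrichment by gene group, per-tissue
#' affected proportions, Jaccard overlap summaries, breadth tables, broad-
#' breadth depletion, effect sizes and the logistic model.
#'
#' @slot tables Named list of data.frames.
#' @slot mode Which call modes were run ("bonferroni", "posterior" or "both").
#'
#' @export
setClass("ReportBundle",
    representation(tables = "list", mode = "character")
)

#' @describeIn EqtlCallSet Number of calls in the set.
#' @param x,object An \code{EqtlCallSet}.
#' @export
setMethod("length", "EqtlCallSet", function(x) nrow(x@calls))

#' @export
setMethod("show", "EqtlCallSet", function(object) {
    cat("EqtlCallSet with", nrow(object@calls), "calls (mode:", object@mode, ")\n")
    cat("  tissue panel:", length(object@tissuePanel), "tissues\n")
    if (nrow(object@calls)) {
        br <- object@calls$breadth
        cat("  tissue breadth: median", stats::median(br),
            " range [", min(br), ",", max(br), "]\n")
    }
    invisible(NULL)
})

#' @export
setMethod("show", "GeneTissueMatrix", function(object) {
    cat("GeneTissueMatrix:", nrow(object@affected), "genes x",
        ncol(object@affected), "tissues (mode:", object@mode, ")\n")
    cat("  eQTL-affected genes:", sum(rowSums(object@affected) > 0L), "\n")
    invisible(NULL)
})

#' @export
setMethod("show", "JaccardIndexMatrix", function(object) {
    ut <- object@values[upper.tri(object@values)]
    cat("JaccardIndexMatrix:", nrow(object@values), "tissues, stratum:",
        object@stratum, "\n")
    if (length(ut))
        cat("  upper-triangle median:", signif(stats::median(ut), 3), "\n")
    invisible(NULL)
})

#' @export
setMethod("show", "SimulatedEqtlData", function(object) {
    cat("SimulatedEqtlData:", nrow(object@classTable), "genes,",
        object@config$nTissues, "tissues\n")
    cat("  planted eQTLs:", nrow(object@truth), "; association rows:",
        nrow(object@associations), "\n")
    invisible(NULL)
})

#' @export
setMethod("show", "ReportBundle", function(object) {
    cat("ReportBundle (mode:", object@mode, ") with tables:\n")
    for (nm in names(object@tables))
        cat("  -", nm, "(", nrow(object@tables[[nm]]), "rows )\n")
    invisible(NULL)
})

#' Accessors for package classes
#'
#' @param x An object of one of the package's S4 classes.
#' @return \code{callMode}: the calling mode; \code{tissuePanel}: the tissue
#'   label vector; \code{eqtlCalls}: the calls DataFrame; \code{affectedMatrix}:
#'   the logical gene x tissue matrix; \code{jaccardValues}: the numeric
#'   Jaccard matrix; \code{jaccardStratum}: the stratum label;
#'   \code{reportTables}: the named list of report data.frames.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("callMode", function(x) standardGeneric("callMode"))
#' @rdname accessors
#' @export
setMethod("callMode", "EqtlCallSet", function(x) x@mode)
#' @rdname accessors
#' @export
setMethod("callMode", "GeneTissueMatrix", function(x) x@mode)

#' @rdname accessors
#' @export
setGeneric("tissuePanel", function(x) standardGeneric("tissuePanel"))
#' @rdname accessors
#' @export
setMethod("tissuePanel", "EqtlCallSet", function(x) x@tissuePanel)

#' @rdname accessors
#' @export
setGeneric("eqtlCalls", function(x) standardGeneric("eqtlCalls"))
#' @rdname accessors
#' @export
setMethod("eqtlCalls", "EqtlCallSet", function(x) x@calls)

#' @rdname accessors
#' @export
setGeneric("affectedMatrix", function(x) standardGeneric("affectedMatrix"))
#' @rdname accessors
#' @export
setMethod("affectedMatrix", "GeneTissueMatrix", function(x) x@affected)

#' @rdname accessors
#' @export
setGeneric("jaccardValues", function(x) standardGeneric("jaccardValues"))
#' @rdname accessors
#' @export
setMethod("jaccardValues", "JaccardIndexMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("jaccardStratum", function(x) standardGeneric("jaccardStratum"))
#' @rdname accessors
#' @export
setMethod("jaccardStratum", "JaccardIndexMatrix", function(x) x@stratum)

#' @rdname accessors
#' @export
setGeneric("reportTables", function(x) standardGeneric("reportTables"))
#' @rdname accessors
#' @export
setMethod("reportTables", "ReportBundle", function(x) x@tables)

#' @describeIn SimulatedEqtlData Planted truth table.
#' @export
setGeneric("plantedTruth", function(x) standardGeneric("plantedTruth"))
#' @export
setMethod("plantedTruth", "SimulatedEqtlData", function(x) x@truth)

#' @describeIn SimulatedEqtlData Per-gene class table.
#' @export
setGeneric("geneClasses", function(x) standardGeneric("geneClasses"))
#' @export
setMethod("geneClasses", "SimulatedEqtlData", function(x) x@classTable)
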