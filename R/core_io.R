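#' @importFrom GenomicRanges GRanges findOverlaps seqnames strand
#' @importFrom IRanges IRanges CharacterList poverlaps
#' @importFrom S4Vectors mcols mcols<- queryHits
#' @importFrom utils read.delim write.table
NULL

#' Strip a trailing Ensembl-style version suffix from gene ids
#'
#' GTEx association tables and Ensembl annotation releases disagree on the
#' version suffix of stable gene ids (e.g. \code{ENSG00000000001.5} vs
#' \code{ENSG00000000001}); all ids are normalized by dropping a trailing
#' \code{.digits}. The operation is idempotent.
#'
#' @param ids Character vector of gene identifiers.
#' @return Character vector with version suffixes removed.
#' @examples
#' stripGeneVersion(c("ENSG00000000001.5", "ENSG00000000002"))
#' @export
stripGeneVersion <- function(ids) {
    sub("\\.[0-9]+$", "", as.character(ids))
}

#' Read gene annotation intervals
#'
#' Reads gene annotations from a BED file (0-based half-open coordinates,
#' columns chrom/start/end/name[/score/strand]) or a headered TSV with columns
#' \code{chrom}, \code{start} (0-based), \code{end}, \code{gene_id} and
#' optionally \code{strand} and \code{biotype}. Gene ids are normalized with
#' \code{\link{stripGeneVersion}}; duplicated ids after normalization are an
#' error.
#'
#' @param path Path to the annotation file.
#' @param format \code{"bed"} or \code{"tsv"}.
#' @return A \code{GRanges} with metadata columns \code{gene_id} and
#'   \code{biotype} (\code{NA} where not provided).
#' @export
readGeneAnnotations <- function(path, format = c("bed", "tsv")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("annotation file not found: ", path)
    if (format == "bed") {
        gr <- rtracklayer::import(path, format = "BED")
        if (length(gr) && is.null(gr$name))
            stop("BED annotation requires a name column carrying the gene id")
        ids <- stripGeneVersion(gr$name)
        mcols(gr) <- NULL
        gr$gene_id <- ids
        gr$biotype <- rep(NA_character_, length(gr))
    } else {
        df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
        need <- c("chrom", "start", "end", "gene_id")
        miss <- setdiff(need, names(df))
        if (length(miss))
            stop("TSV annotation missing columns: ", paste(miss, collapse = ", "))
        bad <- which(!is.finite(df$start) | !is.finite(df$end) | df$end <= df$start)
        if (length(bad))
            stop("malformed annotation row(s) at line(s): ",
                 paste(bad + 1L, collapse = ", "))
        gr <- GRanges(
            seqnames = df$chrom,
            # input is 0-based half-open; GRanges is 1-based closed
            ranges = IRanges(start = df$start + 1L, end = df$end),
            strand = if ("strand" %in% names(df)) df$strand else "*"
        )
        gr$gene_id <- stripGeneVersion(df$gene_id)
        gr$biotype <- if ("biotype" %in% names(df)) df$biotype else NA_character_
    }
    dup <- duplicated(gr$gene_id)
    if (any(dup))
        stop("duplicate gene id(s) after version stripping: ",
             paste(unique(gr$gene_id[dup]), collapse = ", "))
    gr
}

#' Read copy-number-variable regions from a BED file
#'
#' @param path Path to a BED file of CNV regions.
#' @return A \code{GRanges}.
#' @export
readCnvRegions <- function(path) {
    if (!file.exists(path)) stop("CNV region file not found: ", path)
    rtracklayer::import(path, format = "BED")
}

#' Default column mapping for GTEx-V7-style association tables
#'
#' @return Named character vector mapping the internal field names
#'   (\code{variant_id}, \code{gene_id}, \code{tissue}, \code{nominal_p},
#'   \code{slope}, \code{maf}) to the file's header names.
#' @export
gtexColumnMap <- function() {
    c(variant_id = "variant_id", gene_id = "gene_id", tissue = "tissue",
      nominal_p = "pval_nominal", slope = "slope", maf = "maf")
}

.remapColumns <- function(df, columnMap, required, path) {
    present <- columnMap[columnMap %in% names(df)]
    missreq <- setdiff(required, names(present))
    if (length(missreq))
        stop("association table ", path, " lacks required column(s): ",
             paste(columnMap[missreq], collapse = ", "))
    out <- df[, unname(present), drop = FALSE]
    names(out) <- names(present)
    out
}

#' Read a per-tissue SNP-gene association table
#'
#' Reads a tab-delimited table of nominal per-tissue associations (one row per
#' variant, gene, tissue). Rows whose tissue label is outside the declared
#' panel are skipped with a warning; the number skipped is attached as
#' attribute \code{"n_skipped"}. Nominal p-values must lie in [0, 1].
#'
#' @param path Path to the tab-delimited file (header required).
#' @param tissuePanel Character vector of admissible tissue labels.
#' @param columnMap Mapping from internal field names to header names; see
#'   \code{\link{gtexColumnMap}}.
#' @return data.frame with columns \code{variant_id}, \code{gene_id},
#'   \code{tissue}, \code{nominal_p}, \code{slope} and (if present in the
#'   file) \code{maf}.
#' @export
readAssociations <- function(path, tissuePanel, columnMap = gtexColumnMap()) {
    if (!file.exists(path)) stop("association file not found: ", path)
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    out <- .remapColumns(df, columnMap,
                         c("variant_id", "gene_id", "tissue", "nominal_p", "slope"),
                         path)
    out$gene_id <- stripGeneVersion(out$gene_id)
    if (any(!is.finite(out$nominal_p) | out$nominal_p < 0 | out$nominal_p > 1))
        stop("nominal p-values outside [0, 1] in ", path)
    keep <- out$tissue %in% tissuePanel
    nskip <- sum(!keep)
    if (nskip > 0L)
        warning(nskip, " row(s) with tissue outside the panel skipped")
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_skipped") <- nskip
    out
}

#' Read a per-tissue posterior-probability (m-value) table
#'
#' @param path Path to a tab-delimited file with header columns
#'   \code{variant_id}, \code{gene_id}, \code{tissue}, \code{m_value}.
#' @param tissuePanel Character vector of admissible tissue labels.
#' @return data.frame with those four columns; rows outside the panel are
#'   skipped with a warning.
#' @export
readMValues <- function(path, tissuePanel) {
    if (!file.exists(path)) stop("m-value file not found: ", path)
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("variant_id", "gene_id", "tissue", "m_value")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("m-value table missing column(s): ", paste(miss, collapse = ", "))
    df <- df[, need]
    df$gene_id <- stripGeneVersion(df$gene_id)
    if (any(!is.finite(df$m_value) | df$m_value < 0 | df$m_value > 1))
        stop("m-values outside [0, 1] in ", path)
    keep <- df$tissue %in% tissuePanel
    if (any(!keep))
        warning(sum(!keep), " row(s) with tissue outside the panel skipped")
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Read per-tissue expression matrices into one experiment
#'
#' Each file is a tab-delimited TPM matrix: first column \code{gene_id},
#' remaining columns one per sample. All tissues must share the same gene set;
#' columns are concatenated into a single \code{SummarizedExperiment} whose
#' \code{colData} records the tissue and sample of each column.
#'
#' @param paths Named character vector: names are tissue labels, values file
#'   paths.
#' @return A \code{SummarizedExperiment} with assay \code{"tpm"}.
#' @export
readExpressionTables <- function(paths) {
    if (is.null(names(paths)) || any(!nzchar(names(paths))))
        stop("paths must be named by tissue label")
    mats <- lapply(paths, function(p) {
        df <- read.delim(p, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE)
        m <- as.matrix(df[, -1, drop = FALSE])
        rownames(m) <- stripGeneVersion(df[[1]])
        if (any(m < 0)) stop("negative TPM values in ", p)
        m
    })
    genes <- rownames(mats[[1]])
    for (m in mats)
        if (!identical(rownames(m), genes))
            stop("expression tables do not share an identical gene set/order")
    tpm <- do.call(cbind, mats)
    tissue <- rep(names(paths), vapply(mats, ncol, 1L))
    sample_id <- unlist(lapply(mats, colnames), use.names = FALSE)
    colnames(tpm) <- paste(tissue, sample_id, sep = ".")
    SummarizedExperiment::SummarizedExperiment(
        assays = list(tpm = tpm),
        colData = S4Vectors::DataFrame(tissue = tissue, sample_id = sample_id)
    )
}

#' Do two genomic intervals overlap by at least one base?
#'
#' Two intervals overlap iff they are on the same chromosome and share at
#' least one base; strand is deliberately ignored, so intervals on opposite
#' strands can overlap. Vectorized over pairs.
#'
#' @param a,b \code{GRanges} of equal length; element i of \code{a} is
#'   compared with element i of \code{b}.
#' @return Logical vector.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 300))
#' intervalsOverlap(a, b)  # TRUE: one shared base
#' @export
intervalsOverlap <- function(a, b) {
    if (length(a) != length(b)) stop("a and b must have equal length")
    as.logical(poverlaps(a, b, ignore.strand = TRUE))
}

#' Write a data.frame as a TSV with header
#'
#' @param df data.frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write an association table (inverse of \code{readAssociations})
#'
#' Column names follow the GTEx-style default mapping so that a written table
#' round-trips through \code{\link{readAssociations}} unchanged.
#'
#' @param assoc data.frame of associations.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeAssociations <- function(assoc, path) {
    out <- assoc
    map <- gtexColumnMap()
    keep <- intersect(names(map), names(out))
    out <- out[, keep, drop = FALSE]
    names(out) <- unname(map[keep])
    writeTsv(out, path)
}
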