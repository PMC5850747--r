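#' DosageExperiment: counts and annotation for a dosage-compensation study
#'
#' A \linkS4class{SummarizedExperiment} specialised for sex-chromosome
#' dosage-compensation analyses. The `"counts"` assay holds integer read
#' counts (genes x libraries); normalized expression assays (`"rpkm"`,
#' `"nrpkm"`) are added by [computeRPKM()] and [quantileNormalize()] and are
#' deliberately distinct artifacts from the counts. Library metadata
#' (`sex`, `tissue`, `stage`, `replicate`) lives in `colData`; per-gene
#' annotation (`length` in bp, `chrom` with the reserved label `"Z"` for the
#' sex chromosome and `NA` for unassigned scaffolds) lives in `rowData`.
#'
#' @slot ... inherited from SummarizedExperiment.
#'
#' @seealso [DosageExperiment()] for construction, [dosagePanel()],
#'   [runDosageAnalysis()].
#' @export
setClass("DosageExperiment", contains = "SummarizedExperiment")

.validDosageExperiment <- function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(is.na(cts)))
            msg <- c(msg, "counts contain NA")
        else if (any(cts < 0) || any(cts != round(cts)))
            msg <- c(msg, "counts must be non-negative integers")
    }
    cd <- SummarizedExperiment::colData(object)
    need <- c("sex", "tissue", "stage", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if ("sex" %in% colnames(cd) && !all(cd$sex %in% c("male", "female")))
        msg <- c(msg, "sex must be 'male' or 'female'")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "library ids must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be unique")
    rd <- SummarizedExperiment::rowData(object)
    if ("length" %in% colnames(rd)) {
        len <- rd$length
        if (any(!is.na(len) & len <= 0))
            msg <- c(msg, "gene lengths must be positive")
    }
    if (length(msg)) msg else TRUE
}

setValidity("DosageExperiment", .validDosageExperiment)

#' Construct a DosageExperiment
#'
#' @param counts integer matrix of read counts, genes x libraries, with
#'   gene ids as rownames and library ids as colnames.
#' @param meta `data.frame` of library metadata with columns `library_id`,
#'   `sex` (`"male"`/`"female"`), `tissue`, `stage`, `replicate`; every
#'   column of `counts` must be described.
#' @param lengths optional named numeric vector of gene lengths in bp.
#' @param chrom optional named character vector of chromosome labels
#'   (`"Z"` reserved for the sex chromosome; genes absent from the vector
#'   are treated as unassigned).
#'
#' @return A [DosageExperiment-class] object.
#' @examples
#' cts <- matrix(rpois(8, 50), 2, 4,
#'               dimnames = list(c("g1", "g2"), paste0("L", 1:4)))
#' meta <- data.frame(library_id = paste0("L", 1:4),
#'                    sex = rep(c("male", "female"), each = 2),
#'                    tissue = "whole_body", stage = "adult",
#'                    replicate = c(1, 2, 1, 2))
#' de <- DosageExperiment(cts, meta, lengths = c(g1 = 1000, g2 = 1500),
#'                        chrom = c(g1 = "Z", g2 = "chr2"))
#' @export
DosageExperiment <- function(counts, meta, lengths = NULL, chrom = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) && nrow(counts) > 0)
        stop("counts must have gene ids as rownames")
    if (is.null(rownames(counts)))
        rownames(counts) <- character(0)
    if (is.null(colnames(counts)))
        stop("counts must have library ids as colnames")
    meta <- as.data.frame(meta)
    if (!"library_id" %in% colnames(meta))
        stop("meta must have a 'library_id' column")
    if (anyDuplicated(meta$library_id))
        stop("duplicate library_id in metadata")
    missing_meta <- setdiff(colnames(counts), meta$library_id)
    if (length(missing_meta))
        stop("missing metadata for library(ies): ",
             paste(missing_meta, collapse = ", "))
    meta <- meta[match(colnames(counts), meta$library_id), , drop = FALSE]
    rownames(meta) <- meta$library_id
    rd <- S4Vectors::DataFrame(row.names = rownames(counts))
    rd$length <- if (is.null(lengths)) rep(NA_real_, nrow(counts)) else
        unname(lengths[rownames(counts)])
    rd$chrom <- if (is.null(chrom)) rep(NA_character_, nrow(counts)) else
        unname(chrom[rownames(counts)])
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(meta),
        rowData = rd)
    methods::new("DosageExperiment", se)
}

#' SexBiasTable: per-gene sex-bias classification
#'
#' Holds, for each gene, the log2 fold-change of male over female expression,
#' an optional BH-adjusted p-value, and the label `MBG` (male-biased), `FBG`
#' (female-biased) or `UBG` (unbiased) at a given fold-change threshold.
#'
#' @slot table `DataFrame` with columns `log2_fc`, `adj_p`, `label`,
#'   gene ids as rownames.
#' @slot fcThreshold the fold-change threshold used (2 or 4).
#' @slot replicated whether the significance gate (adjusted p < 0.05)
#'   was applied.
#' @export
setClass("SexBiasTable",
         representation(table = "DataFrame",
                        fcThreshold = "numeric",
                        replicated = "logical"))

setValidity("SexBiasTable", function(object) {
    msg <- character()
    tb <- object@table
    if (!all(c("log2_fc", "adj_p", "label") %in% colnames(tb)))
        msg <- c(msg, "table needs columns log2_fc, adj_p, label")
    else if (!all(tb$label %in% c("MBG", "FBG", "UBG")))
        msg <- c(msg, "labels must be MBG, FBG or UBG")
    if (!object@fcThreshold %in% c(2, 4))
        msg <- c(msg, "fcThreshold must be 2 or 4")
    if (length(msg)) msg else TRUE
})

#' DosageReport: the Z:A / M:F expression-ratio panel
#'
#' One panel of the four dosage-compensation summary statistics for one
#' gene set: Z:A in males, Z:A in females, M:F on the autosomes and M:F on
#' the Z, each with a two-sided Wilcoxon rank-sum p-value, plus the
#' filtering/exclusion provenance.
#'
#' @slot ratios named numeric: `za_male`, `za_female`, `mf_autosomes`, `mf_z`.
#' @slot pvalues named numeric of matching Wilcoxon p-values.
#' @slot cutoff expression cut-off applied (`"none"`, `"0"`, `"1"`, `"5"`).
#' @slot sbgExcluded whether sex-biased genes were removed first.
#' @slot nZ,nA numbers of Z-linked and autosomal genes analysed.
#' @slot ratioType `"median"` (default) or `"mean"` aggregate ratios.
#' @export
setClass("DosageReport",
         representation(ratios = "numeric",
                        pvalues = "numeric",
                        cutoff = "character",
                        sbgExcluded = "logical",
                        nZ = "integer",
                        nA = "integer",
                        ratioType = "character"))

setValidity("DosageReport", function(object) {
    need <- c("za_male", "za_female", "mf_autosomes", "mf_z")
    msg <- character()
    if (!all(need %in% names(object@ratios)))
        msg <- c(msg, "ratios must be named za_male, za_female, mf_autosomes, mf_z")
    if (!all(need %in% names(object@pvalues)))
        msg <- c(msg, "pvalues must carry the same four names")
    pv <- object@pvalues
    if (any(!is.na(pv) & (pv < 0 | pv > 1)))
        msg <- c(msg, "p-values must be in [0, 1]")
    if (length(msg)) msg else TRUE
})
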