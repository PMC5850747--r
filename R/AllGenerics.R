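#' @rdname accessors
#' @export
setGeneric("libSex", function(x) standardGeneric("libSex"))

#' @rdname accessors
#' @export
setGeneric("libTissue", function(x) standardGeneric("libTissue"))

#' @rdname accessors
#' @export
setGeneric("libStage", function(x) standardGeneric("libStage"))

#' @rdname accessors
#' @export
setGeneric("geneChrom", function(x) standardGeneric("geneChrom"))

#' @rdname accessors
#' @export
setGeneric("geneChrom<-", function(x, value) standardGeneric("geneChrom<-"))

#' @rdname accessors
#' @export
setGeneric("geneLength", function(x) standardGeneric("geneLength"))

#' @rdname accessors
#' @export
setGeneric("geneLength<-", function(x, value) standardGeneric("geneLength<-"))

#' @rdname computeRPKM
#' @export
setGeneric("computeRPKM", function(x, ...) standardGeneric("computeRPKM"))

#' @rdname quantileNormalize
#' @export
setGeneric("quantileNormalize", function(x, ...)
    standardGeneric("quantileNormalize"))

#' @rdname biasAccessors
#' @export
setGeneric("biasLabels", function(x) standardGeneric("biasLabels"))

#' @rdname biasAccessors
#' @export
setGeneric("biasTable", function(x) standardGeneric("biasTable"))

#' @rdname reportAccessors
#' @export
setGeneric("panelRatios", function(x) standardGeneric("panelRatios"))

#' @rdname reportAccessors
#' @export
setGeneric("panelPvalues", function(x) standardGeneric("panelPvalues"))

#' Accessors for DosageExperiment annotation
#'
#' `libSex()`, `libTissue()`, `libStage()` return the per-library metadata;
#' `geneChrom()` and `geneLength()` return the per-gene chromosome label
#' (`NA` = unassigned) and length in bp, as named vectors. The replacement
#' forms accept named vectors and leave genes not mentioned untouched.
#'
#' @param x a [DosageExperiment-class].
#' @param value named vector of new annotation values.
#' @return Named vectors over libraries or genes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("libSex", "DosageExperiment", function(x)
    stats::setNames(SummarizedExperiment::colData(x)$sex, colnames(x)))

#' @rdname accessors
#' @export
setMethod("libTissue", "DosageExperiment", function(x)
    stats::setNames(SummarizedExperiment::colData(x)$tissue, colnames(x)))

#' @rdname accessors
#' @export
setMethod("libStage", "DosageExperiment", function(x)
    stats::setNames(SummarizedExperiment::colData(x)$stage, colnames(x)))

#' @rdname accessors
#' @export
setMethod("geneChrom", "DosageExperiment", function(x)
    stats::setNames(SummarizedExperiment::rowData(x)$chrom, rownames(x)))

#' @rdname accessors
#' @export
setMethod("geneChrom<-", "DosageExperiment", function(x, value) {
    chrom <- geneChrom(x)
    chrom[names(value)] <- unname(value)
    SummarizedExperiment::rowData(x)$chrom <- unname(chrom[rownames(x)])
    methods::validObject(x)
    x
})

#' @rdname accessors
#' @export
setMethod("geneLength", "DosageExperiment", function(x)
    stats::setNames(SummarizedExperiment::rowData(x)$length, rownames(x)))

#' @rdname accessors
#' @export
setMethod("geneLength<-", "DosageExperiment", function(x, value) {
    len <- geneLength(x)
    len[names(value)] <- unname(value)
    SummarizedExperiment::rowData(x)$length <- unname(len[rownames(x)])
    methods::validObject(x)
    x
})

#' Accessors for SexBiasTable
#'
#' `biasLabels()` returns the named MBG/FBG/UBG label vector; `biasTable()`
#' the full per-gene `DataFrame`.
#'
#' @param x a [SexBiasTable-class].
#' @return A named character vector, or a `DataFrame`.
#' @name biasAccessors
NULL

#' @rdname biasAccessors
#' @export
setMethod("biasLabels", "SexBiasTable", function(x)
    stats::setNames(x@table$label, rownames(x@table)))

#' @rdname biasAccessors
#' @export
setMethod("biasTable", "SexBiasTable", function(x) x@table)

#' Accessors for DosageReport
#'
#' @param x a [DosageReport-class].
#' @return Named numeric vectors of the four panel ratios or their
#'   Wilcoxon p-values.
#' @name reportAccessors
NULL

#' @rdname reportAccessors
#' @export
setMethod("panelRatios", "DosageReport", function(x) x@ratios)

#' @rdname reportAccessors
#' @export
setMethod("panelPvalues", "DosageReport", function(x) x@pvalues)

#' @export
setMethod("show", "DosageExperiment", function(object) {
    methods::callNextMethod()
    chrom <- SummarizedExperiment::rowData(object)$chrom
    nz <- sum(!is.na(chrom) & chrom == "Z")
    na_ <- sum(!is.na(chrom) & chrom != "Z")
    cat(sprintf("genes: %d Z-linked, %d autosomal, %d unassigned\n",
                nz, na_, sum(is.na(chrom))))
    cd <- SummarizedExperiment::colData(object)
    cat(sprintf("libraries: %d male, %d female; groups: %s\n",
                sum(cd$sex == "male"), sum(cd$sex == "female"),
                paste(unique(paste(cd$tissue, cd$stage, sep = "/")),
                      collapse = ", ")))
})

#' @export
setMethod("show", "SexBiasTable", function(object) {
    tab <- table(factor(object@table$label, c("MBG", "FBG", "UBG")))
    cat(sprintf(
        "SexBiasTable: %d genes at fold-change > %g (%s mode)\n",
        nrow(object@table), object@fcThreshold,
        if (object@replicated) "replicated, adj p < 0.05" else
            "fold-change only"))
    cat(sprintf("  MBG %d | FBG %d | UBG %d\n", tab[1], tab[2], tab[3]))
})

#' @export
setMethod("show", "DosageReport", function(object) {
    cat(sprintf(
        "DosageReport (cutoff %s, SBG %s, %s ratios; %d Z / %d A genes)\n",
        object@cutoff, if (object@sbgExcluded) "excluded" else "included",
        object@ratioType, object@nZ, object@nA))
    r <- object@ratios; p <- object@pvalues
    lab <- c(za_male = "Z:A males", za_female = "Z:A females",
             mf_autosomes = "M:F autosomes", mf_z = "M:F Z")
    for (k in names(lab))
        cat(sprintf("  %-14s %6.3f  (Wilcoxon p = %.4g)\n", lab[k], r[k], p[k]))
})
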