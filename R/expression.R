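#' Compute RPKM expression values
#'
#' RPKM = count / ((length / 1e3) * (library_size / 1e6)). Library sizes
#' default to the column sums of the count matrix (total mapped reads per
#' library).
#'
#' @param x a counts matrix (genes x libraries) or a
#'   [DosageExperiment-class] with a `"counts"` assay and gene lengths in
#'   `rowData`.
#' @param lengths named numeric vector of gene lengths in bp (matrix method).
#' @param librarySizes optional named numeric vector of mapped reads per
#'   library; defaults to `colSums(counts)`.
#' @param ... passed between methods.
#' @return For the matrix method, the RPKM matrix. For a
#'   `DosageExperiment`, the object with an added `"rpkm"` assay.
#' @examples
#' m <- matrix(c(10L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "L1"))
#' computeRPKM(m, lengths = c(g1 = 1000, g2 = 500),
#'             librarySizes = c(L1 = 1e6))
#' @rdname computeRPKM
#' @export
setMethod("computeRPKM", "matrix", function(x, lengths, librarySizes = NULL,
                                            ...) {
    lengths <- lengths[rownames(x)]
    if (any(is.na(lengths)))
        stop("missing gene length for: ",
             paste(rownames(x)[is.na(lengths)], collapse = ", "))
    if (any(lengths <= 0)) stop("gene lengths must be positive")
    if (is.null(librarySizes)) librarySizes <- colSums(x)
    else librarySizes <- librarySizes[colnames(x)]
    if (any(is.na(librarySizes) | librarySizes <= 0))
        stop("library sizes must be positive for every library")
    sweep(x / (unname(lengths) / 1e3), 2, unname(librarySizes) / 1e6, "/")
})

#' @rdname computeRPKM
#' @export
setMethod("computeRPKM", "DosageExperiment",
          function(x, librarySizes = NULL, ...) {
    rpkm <- computeRPKM(SummarizedExperiment::assay(x, "counts"),
                        lengths = geneLength(x),
                        librarySizes = librarySizes)
    SummarizedExperiment::assay(x, "rpkm") <- rpkm
    x
})

# Core single-group quantile normalization: replace rank r in each library
# by the mean of the r-th order statistics across libraries; ties within a
# library get the mean of the order-statistic means they span.
.quantile_normalize_matrix <- function(m) {
    if (ncol(m) < 2)
        stop("quantile normalization needs a group of at least 2 libraries")
    ref <- rowMeans(apply(m, 2, sort, method = "radix"))
    cs <- cumsum(ref)
    out <- m
    for (j in seq_len(ncol(m))) {
        lo <- rank(m[, j], ties.method = "min")
        hi <- rank(m[, j], ties.method = "max")
        out[, j] <- (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1)
    }
    out
}

#' Quantile-normalize expression between libraries
#'
#' Classic mean-of-order-statistics quantile normalization: each library's
#' rank-r value is replaced by the mean of the rank-r order statistics over
#' all libraries in the group, so every library ends up with the identical
#' empirical distribution while within-library ranks are preserved. Tied
#' values receive the mean of the order-statistic means their ranks span.
#'
#' For a [DosageExperiment-class], normalization is applied separately
#' within each tissue x stage group of libraries (the groups that are
#' biologically comparable), to the `"rpkm"` assay, producing an `"nrpkm"`
#' assay.
#'
#' @param x numeric matrix (genes x libraries, one group) or a
#'   [DosageExperiment-class] carrying an `"rpkm"` assay.
#' @param ... unused.
#' @return Normalized matrix, or the object with an `"nrpkm"` assay added.
#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "matrix", function(x, ...)
    .quantile_normalize_matrix(x))

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "DosageExperiment", function(x, ...) {
    if (!"rpkm" %in% SummarizedExperiment::assayNames(x))
        x <- computeRPKM(x)
    rpkm <- SummarizedExperiment::assay(x, "rpkm")
    grp <- paste(libTissue(x), libStage(x), sep = "\r")
    out <- rpkm
    for (g in unique(grp)) {
        idx <- which(grp == g)
        out[, idx] <- .quantile_normalize_matrix(rpkm[, idx, drop = FALSE])
    }
    SummarizedExperiment::assay(x, "nrpkm") <- out
    x
})

#' Expression cut-off filtering
#'
#' Selects the genes considered expressed at a given RPKM cut-off.
#' `mode = "both_sexes"` keeps genes with expression strictly above the
#' cut-off in at least one library of each sex (the convention for genes
#' "expressed in both sexes"); `mode = "all_libraries"` requires every
#' library to exceed the cut-off. `cutoff = "none"` keeps all genes.
#'
#' @param expr expression matrix (genes x libraries), typically the
#'   normalized RPKM assay.
#' @param sex named character vector over the libraries of `expr`.
#' @param cutoff `"none"` or a number among 0, 1, 5.
#' @param mode `"both_sexes"` or `"all_libraries"`.
#' @return Character vector of retained gene ids.
#' @export
filterExpressed <- function(expr, sex, cutoff = c("none", "0", "1", "5"),
                            mode = c("both_sexes", "all_libraries")) {
    mode <- match.arg(mode)
    if (is.numeric(cutoff)) cutoff <- as.character(cutoff)
    cutoff <- match.arg(cutoff)
    if (cutoff == "none") return(rownames(expr))
    co <- as.numeric(cutoff)
    sex <- sex[colnames(expr)]
    if (mode == "all_libraries") {
        keep <- rowSums(expr > co) == ncol(expr)
    } else {
        m <- expr[, sex == "male", drop = FALSE]
        f <- expr[, sex == "female", drop = FALSE]
        keep <- rowSums(m > co) >= 1 & rowSums(f > co) >= 1
    }
    rownames(expr)[keep]
}

#' Log2 fold-change of male over female expression
#'
#' log2((mean_male + pseudocount) / (mean_female + pseudocount)) per gene,
#' on normalized expression values. The pseudocount (default 1) shrinks
#' fold-changes of weakly expressed genes and guards zero denominators,
#' the standard fallback when no replicate-aware posterior fold-change is
#' available.
#'
#' @param expr normalized expression matrix (genes x libraries).
#' @param sex named character vector (`"male"`/`"female"`) over libraries.
#' @param pseudocount positive shrinkage constant, default 1.
#' @return Named numeric vector of per-gene log2 fold-changes.
#' @export
log2FoldChange <- function(expr, sex, pseudocount = 1) {
    stopifnot(pseudocount > 0)
    sex <- sex[colnames(expr)]
    mm <- rowMeans(expr[, sex == "male", drop = FALSE])
    mf <- rowMeans(expr[, sex == "female", drop = FALSE])
    stats::setNames(log2((mm + pseudocount) / (mf + pseudocount)),
                    rownames(expr))
}

#' Per-gene differential-expression test between sexes
#'
#' Welch two-sample t statistic on log2(normalized expression + 1), the
#' documented substitute for a full negative-binomial differential test in
#' replicated designs. Requires at least two replicates per sex; for
#' unreplicated designs use fold-change-only classification instead
#' ([classifySexBias()] without p-values).
#'
#' Degenerate genes (zero variance in both sexes) get p = 1 when the group
#' means are equal and p = 0 otherwise.
#'
#' @param expr normalized expression matrix (genes x libraries).
#' @param sex named character vector over libraries.
#' @return Named numeric vector of raw two-sided p-values; combine with
#'   [bhAdjust()].
#' @export
replicateTest <- function(expr, sex) {
    sex <- sex[colnames(expr)]
    nm <- sum(sex == "male"); nf <- sum(sex == "female")
    if (nm < 2 || nf < 2)
        stop("replicateTest needs >= 2 replicates per sex (got ", nm,
             " male, ", nf, " female); use fold-change-only classification")
    lx <- log2(expr + 1)
    m <- lx[, sex == "male", drop = FALSE]
    f <- lx[, sex == "female", drop = FALSE]
    mm <- rowMeans(m); mf <- rowMeans(f)
    vm <- rowSums((m - mm)^2) / (nm - 1)
    vf <- rowSums((f - mf)^2) / (nf - 1)
    se2 <- vm / nm + vf / nf
    tstat <- (mm - mf) / sqrt(se2)
    df <- se2^2 / ((vm / nm)^2 / (nm - 1) + (vf / nf)^2 / (nf - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    # degenerate genes: zero variance in both sexes
    degen <- se2 == 0
    p[degen] <- ifelse(abs(mm[degen] - mf[degen]) < 1e-12, 1, 0)
    stats::setNames(pmin(1, p), rownames(expr))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: with the p-values sorted
#' ascending, q_(i) = min over j >= i of p_(j) * m / j, capped at 1 and
#' returned in the input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bhAdjust <- function(pvals) {
    if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(pvals, method = "BH")
}

#' Classify genes as male-biased, female-biased or unbiased
#'
#' Fold-change-only mode: `MBG` iff log2_fc >= log2(threshold), `FBG` iff
#' log2_fc <= -log2(threshold), else `UBG`. Replicated mode (when adjusted
#' p-values are supplied) additionally requires `adj_p < alpha` for a gene
#' to be called biased.
#'
#' @param log2fc named numeric vector of male-over-female log2 fold-changes.
#' @param adjP optional named numeric vector of BH-adjusted p-values; its
#'   presence switches on the significance gate. Genes missing from `adjP`
#'   are an error in replicated mode.
#' @param fcThreshold fold-change threshold, 2 (default) or 4.
#' @param alpha significance level for the replicated gate, default 0.05.
#' @return A [SexBiasTable-class].
#' @export
classifySexBias <- function(log2fc, adjP = NULL, fcThreshold = 2,
                            alpha = 0.05) {
    if (!fcThreshold %in% c(2, 4))
        stop("fcThreshold must be 2 or 4")
    replicated <- !is.null(adjP)
    if (replicated) {
        adjP <- adjP[names(log2fc)]
        if (any(is.na(adjP)))
            stop("replicated mode requires an adjusted p-value per gene")
    }
    lt <- log2(fcThreshold)
    sig <- if (replicated) adjP < alpha else TRUE
    label <- ifelse(log2fc >= lt & sig, "MBG",
                    ifelse(log2fc <= -lt & sig, "FBG", "UBG"))
    tb <- S4Vectors::DataFrame(
        log2_fc = unname(log2fc),
        adj_p = if (replicated) unname(adjP) else NA_real_,
        label = unname(label),
        row.names = names(log2fc))
    methods::new("SexBiasTable", table = tb, fcThreshold = fcThreshold,
                 replicated = replicated)
}
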