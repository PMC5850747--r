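#' Two-sided Wilcoxon rank-sum test
#'
#' `mode = "exact"` computes the exact two-sided p-value by full enumeration
#' of the C(n+m, n) rank assignments (midranks under ties; two-sided p is
#' twice the smaller tail probability, capped at 1). `mode = "normal_approx"`
#' uses the tie-corrected normal approximation with continuity correction.
#' `mode = "auto"` (default) picks exact enumeration when
#' `max(n, m) <= 8` and the pooled sample is tie-free, otherwise the
#' approximation.
#'
#' @param x,y non-empty numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return List with `statistic` (the Mann-Whitney U of `x`) and `p.value`
#'   (two-sided, in (0, 1]).
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4), mode = "exact")$p.value  # 1/3
#' @export
wilcoxonRankSum <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
    mode <- match.arg(mode)
    if (!length(x) || !length(y)) stop("both samples must be non-empty")
    n <- length(x); m <- length(y)
    pooled <- c(x, y)
    ties <- anyDuplicated(pooled) > 0
    if (mode == "auto")
        mode <- if (max(n, m) <= 8 && !ties) "exact" else "normal_approx"
    r <- rank(pooled)
    U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    if (mode == "exact") {
        idx <- utils::combn(n + m, n)
        offset <- n * (n + 1) / 2
        ws <- colSums(matrix(r[idx], nrow = n)) - offset
        eps <- 1e-9
        p <- min(1, 2 * min(mean(ws <= U + eps), mean(ws >= U - eps)))
        return(list(statistic = U, p.value = p))
    }
    if (length(unique(pooled)) == 1L)
        return(list(statistic = U, p.value = 1))
    p <- suppressWarnings(
        stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    if (is.na(p)) p <- 1
    list(statistic = U, p.value = p)
}

#' Ratio of group aggregates
#'
#' Ratio of the medians (default) or means of two expression samples.
#' Medians are the default because a handful of very highly expressed genes
#' dominate means, which is at odds with the rank-based testing used
#' throughout.
#'
#' @param a,b numeric samples (numerator, denominator).
#' @param type `"median"` or `"mean"`.
#' @return `aggregate(a) / aggregate(b)`.
#' @export
medianRatio <- function(a, b, type = c("median", "mean")) {
    type <- match.arg(type)
    f <- if (type == "median") stats::median else mean
    den <- f(b)
    if (!is.finite(den) || den <= 0)
        stop("denominator aggregate must be positive")
    f(a) / den
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the minimum-likelihood rule: the sum of
#' hypergeometric probabilities of all margin-compatible tables no more
#' probable than the observed one (this is the convention of
#' `stats::fisher.test`, and differs from doubling the one-sided tail).
#'
#' @param tab 2x2 matrix (or length-4 vector, column-major) of non-negative
#'   integer counts.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
fisherExactTwoSided <- function(tab) {
    tab <- matrix(as.vector(tab), 2, 2)
    if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
        stop("table cells must be non-negative integers")
    if (sum(tab) == 0) return(1)
    min(1, stats::fisher.test(tab)$p.value)
}

# Per-gene expression summarized as the mean over same-sex libraries.
.sex_means <- function(expr, sex) {
    sex <- sex[colnames(expr)]
    list(male = rowMeans(expr[, sex == "male", drop = FALSE]),
         female = rowMeans(expr[, sex == "female", drop = FALSE]))
}

#' The Z:A / M:F dosage-compensation ratio panel
#'
#' Computes the four-way panel on a filtered gene set: Z:A within each sex
#' and M:F within the Z and the autosomes, each as a ratio of group medians
#' (or means) of per-gene expression (mean over same-sex libraries), with a
#' two-sided Wilcoxon rank-sum p-value per comparison. When a
#' [SexBiasTable-class] is supplied, its MBG and FBG are removed from both
#' the Z and the autosomes before any statistic — the exclusion protocol
#' that separates true dosage compensation from masculinization of the Z.
#' Genes without a fold-change classification are retained.
#'
#' @param expr normalized expression matrix (genes x libraries).
#' @param chrom named chromosome vector (`"Z"` = sex chromosome, other
#'   labels autosomal, `NA` = unassigned and dropped).
#' @param sex named character vector over libraries.
#' @param genes gene ids to analyse (after cut-off filtering); defaults to
#'   all rows of `expr`.
#' @param exclude optional [SexBiasTable-class]; its MBG/FBG are excluded.
#' @param cutoff provenance label stored in the report.
#' @param ratioType `"median"` (default) or `"mean"`.
#' @param heterogameticSex `"female"` for ZW systems (default). Setting
#'   `"male"` swaps the sex roles so the same panel serves XY data (the
#'   `mf_*` entries then report heterogametic:homogametic expression).
#' @return A [DosageReport-class].
#' @export
dosagePanel <- function(expr, chrom, sex, genes = rownames(expr),
                        exclude = NULL, cutoff = "none",
                        ratioType = c("median", "mean"),
                        heterogameticSex = c("female", "male")) {
    ratioType <- match.arg(ratioType)
    heterogameticSex <- match.arg(heterogameticSex)
    sex <- sex[colnames(expr)]
    if (heterogameticSex == "male")
        sex <- ifelse(sex == "male", "female", "male")
    genes <- intersect(genes, rownames(expr))
    chrom <- chrom[genes]
    genes <- genes[!is.na(chrom)]
    if (!is.null(exclude)) {
        lab <- biasLabels(exclude)[genes]
        biased <- !is.na(lab) & lab %in% c("MBG", "FBG")
        genes <- genes[!biased]
    }
    zgenes <- genes[chrom[genes] == "Z"]
    agenes <- genes[chrom[genes] != "Z"]
    if (!length(zgenes))
        stop("no Z-linked genes survive filtering", if (!is.null(exclude))
            " and sex-biased-gene exclusion" else "")
    if (!length(agenes))
        stop("no autosomal genes survive filtering")
    sm <- .sex_means(expr[genes, , drop = FALSE], sex)
    zm <- sm$male[zgenes]; zf <- sm$female[zgenes]
    am <- sm$male[agenes]; af <- sm$female[agenes]
    ratios <- c(za_male = medianRatio(zm, am, ratioType),
                za_female = medianRatio(zf, af, ratioType),
                mf_autosomes = medianRatio(am, af, ratioType),
                mf_z = medianRatio(zm, zf, ratioType))
    pvalues <- c(za_male = wilcoxonRankSum(zm, am)$p.value,
                 za_female = wilcoxonRankSum(zf, af)$p.value,
                 mf_autosomes = wilcoxonRankSum(am, af)$p.value,
                 mf_z = wilcoxonRankSum(zm, zf)$p.value)
    methods::new("DosageReport", ratios = ratios, pvalues = pvalues,
                 cutoff = as.character(cutoff),
                 sbgExcluded = !is.null(exclude),
                 nZ = length(zgenes), nA = length(agenes),
                 ratioType = ratioType)
}

#' Enrichment of sex-biased genes on the Z chromosome
#'
#' For each bias class (MBG, FBG) among the analysed genes: the observed
#' number on the Z, the expected number (proportion of Z-linked genes in
#' the analysed set times the class total), their ratio, and a two-sided
#' Fisher's exact test on the 2x2 table
#' `[[Z & class, Z & !class], [A & class, A & !class]]`.
#' An empty class yields ratio `NaN` and p = 1.
#'
#' @param sbt a [SexBiasTable-class].
#' @param chrom named chromosome vector (`NA` = unassigned, dropped).
#' @param analyzed gene ids forming the analysed (cut-off-filtered) set —
#'   the same set used for the ratio panel.
#' @return `data.frame` with one row per class: `class`, `observed`,
#'   `expected`, `ratio`, `p_fet`, `n_class`, `n_z`, `n_analyzed`.
#' @export
sbgEnrichment <- function(sbt, chrom, analyzed) {
    if (!length(analyzed)) stop("analysed gene set is empty")
    chrom <- chrom[analyzed]
    analyzed <- analyzed[!is.na(chrom)]
    onZ <- chrom[analyzed] == "Z"
    lab <- biasLabels(sbt)[analyzed]
    nz <- sum(onZ); ntot <- length(analyzed)
    out <- lapply(c("MBG", "FBG"), function(cl) {
        inCl <- !is.na(lab) & lab == cl
        ncl <- sum(inCl)
        obs <- sum(inCl & onZ)
        expd <- nz / ntot * ncl
        if (ncl == 0)
            return(data.frame(class = cl, observed = 0L, expected = 0,
                              ratio = NaN, p_fet = 1, n_class = 0L,
                              n_z = nz, n_analyzed = ntot))
        tab <- matrix(c(obs, nz - obs, ncl - obs,
                        (ntot - nz) - (ncl - obs)), 2, 2)
        data.frame(class = cl, observed = obs, expected = expd,
                   ratio = obs / expd, p_fet = fisherExactTwoSided(tab),
                   n_class = ncl, n_z = nz, n_analyzed = ntot)
    })
    do.call(rbind, out)
}
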