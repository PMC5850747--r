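#' Run the full dosage-compensation analysis
#'
#' End-to-end pipeline on a [DosageExperiment-class]: RPKM, quantile
#' normalization within each tissue x stage group, expression cut-off
#' filtering, sex-bias classification (replicate-aware when at least two
#' replicates per sex are present, otherwise fold-change only), the
#' Z:A / M:F ratio panel with and without sex-biased genes, and
#' enrichment of MBG/FBG on the Z.
#'
#' The consolidated report mirrors the classic dosage-compensation summary
#' table: one row per (tissue x stage, cutoff, SBG-inclusion mode) with the
#' four ratios (Z:A males, Z:A females, M:F autosomes, M:F Z) and their
#' Wilcoxon p-values; exclusion rows are repeated per fold-change
#' threshold.
#'
#' @param de a [DosageExperiment-class] with gene lengths and chromosome
#'   assignments.
#' @param cutoffs subset of `c("none", "0", "1", "5")`.
#' @param fcThresholds subset of `c(2, 4)`; thresholds used for exclusion
#'   and enrichment.
#' @param sbgModes subset of `c("with_sbg", "without_sbg")`.
#' @param filterMode passed to [filterExpressed()]; the default
#'   `"all_libraries"` requires expression above the cut-off in every
#'   library of the tissue/stage.
#' @param biasMode how genes are called sex-biased for exclusion and
#'   enrichment: `"auto"` applies the replicate-aware significance gate
#'   (Welch on log expression, BH-adjusted p < 0.05 on top of the
#'   fold-change threshold) whenever each sex has at least two replicates,
#'   `"fold_change"` classifies on fold-change alone (the exclusion rule
#'   itself, and the only option for unreplicated designs), `"replicated"`
#'   forces the gate and errors without replication.
#' @param ratioType `"median"` (default) or `"mean"`.
#' @param heterogameticSex `"female"` (ZW, default) or `"male"` (XY roles
#'   swapped).
#' @param pseudocount fold-change pseudocount, see [log2FoldChange()].
#' @param outDir optional directory; when given, writes
#'   `dosage_report.tsv`, `sbg_enrichment.tsv` and `run_summary.json`.
#' @param seed recorded in the JSON provenance summary (not used for
#'   computation, which is deterministic given `de`).
#' @return List with `report` (data.frame), `enrichment` (data.frame),
#'   `panels` (list of [DosageReport-class]), and `summary`.
#' @export
runDosageAnalysis <- function(de,
                              cutoffs = c("none", "0", "1", "5"),
                              fcThresholds = 2,
                              sbgModes = c("with_sbg", "without_sbg"),
                              filterMode = c("all_libraries", "both_sexes"),
                              biasMode = c("auto", "fold_change",
                                           "replicated"),
                              ratioType = c("median", "mean"),
                              heterogameticSex = c("female", "male"),
                              pseudocount = 1,
                              outDir = NULL, seed = NA_integer_) {
    filterMode <- match.arg(filterMode)
    biasMode <- match.arg(biasMode)
    ratioType <- match.arg(ratioType)
    heterogameticSex <- match.arg(heterogameticSex)
    cutoffs <- as.character(cutoffs)
    stopifnot(all(cutoffs %in% c("none", "0", "1", "5")),
              length(cutoffs) >= 1,
              all(fcThresholds %in% c(2, 4)),
              all(sbgModes %in% c("with_sbg", "without_sbg")),
              length(sbgModes) >= 1)
    zcLog("normalize", "RPKM + quantile normalization per tissue/stage")
    de <- quantileNormalize(computeRPKM(de))
    nrpkm <- SummarizedExperiment::assay(de, "nrpkm")
    sex <- libSex(de)
    grp <- paste(libTissue(de), libStage(de), sep = "\r")
    chrom <- geneChrom(de)
    report <- list(); enrich <- list(); panels <- list()
    for (g in unique(grp)) {
        libs <- colnames(de)[grp == g]
        gsex <- sex[libs]
        gexpr <- nrpkm[, libs, drop = FALSE]
        tissue <- libTissue(de)[libs][1]; stage <- libStage(de)[libs][1]
        can_rep <- sum(gsex == "male") >= 2 && sum(gsex == "female") >= 2
        if (biasMode == "replicated" && !can_rep)
            stop("biasMode 'replicated' needs >= 2 replicates per sex in ",
                 tissue, "/", stage)
        replicated <- can_rep && biasMode != "fold_change"
        lfc <- log2FoldChange(gexpr, gsex, pseudocount = pseudocount)
        adjP <- if (replicated)
            bhAdjust(replicateTest(gexpr, gsex)) else NULL
        sbts <- lapply(fcThresholds, function(th)
            classifySexBias(lfc, adjP = adjP, fcThreshold = th))
        names(sbts) <- as.character(fcThresholds)
        for (co in cutoffs) {
            zcLog("panel", tissue, "/", stage, " cutoff ", co)
            genes <- filterExpressed(gexpr, gsex, cutoff = co,
                                     mode = filterMode)
            for (mode in sbgModes) {
                ths <- if (mode == "with_sbg") NA else fcThresholds
                for (th in ths) {
                    excl <- if (is.na(th)) NULL else sbts[[as.character(th)]]
                    rep_ <- dosagePanel(gexpr, chrom, gsex, genes = genes,
                                        exclude = excl, cutoff = co,
                                        ratioType = ratioType,
                                        heterogameticSex = heterogameticSex)
                    key <- paste(tissue, stage, co, mode,
                                 ifelse(is.na(th), "", th), sep = "|")
                    panels[[key]] <- rep_
                    report[[key]] <- data.frame(
                        tissue = tissue, stage = stage, cutoff = co,
                        sbg_included = mode == "with_sbg",
                        fc_threshold = th,
                        za_male = unname(rep_@ratios["za_male"]),
                        za_female = unname(rep_@ratios["za_female"]),
                        mf_autosomes = unname(rep_@ratios["mf_autosomes"]),
                        mf_z = unname(rep_@ratios["mf_z"]),
                        p_za_male = unname(rep_@pvalues["za_male"]),
                        p_za_female = unname(rep_@pvalues["za_female"]),
                        p_mf_a = unname(rep_@pvalues["mf_autosomes"]),
                        p_mf_z = unname(rep_@pvalues["mf_z"]),
                        n_z = rep_@nZ, n_a = rep_@nA,
                        row.names = NULL)
                }
            }
            for (th in fcThresholds) {
                en <- sbgEnrichment(sbts[[as.character(th)]], chrom, genes)
                en <- data.frame(tissue = tissue, stage = stage,
                                 cutoff = co, fc_threshold = th, en,
                                 row.names = NULL)
                enrich[[paste(tissue, stage, co, th, sep = "|")]] <- en
            }
        }
    }
    report <- do.call(rbind, c(report, list(make.row.names = FALSE)))
    enrich <- do.call(rbind, c(enrich, list(make.row.names = FALSE)))
    summary <- list(
        seed = seed,
        package_version = as.character(utils::packageVersion("zcomp")),
        r_version = R.version.string,
        n_genes = nrow(de), n_libraries = ncol(de),
        cutoffs = cutoffs, fc_thresholds = fcThresholds,
        sbg_modes = sbgModes, filter_mode = filterMode,
        bias_mode = biasMode,
        ratio_type = ratioType, heterogametic_sex = heterogameticSex)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(report, file.path(outDir, "dosage_report.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(enrich, file.path(outDir, "sbg_enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(summary,
                             file.path(outDir, "run_summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        zcLog("output", "report written to ", outDir)
    }
    list(report = report, enrichment = enrich, panels = panels,
         summary = summary)
}

#' Faster-Z divergence analysis between two species
#'
#' For each 1:1 ortholog pair, computes the Euclidean distance between the
#' two species' expression profiles over matched conditions (sexes and
#' stages treated as "tissues"), optionally NG86 Ka/Ks from codon
#' alignments, and contrasts divergence between chromosome classes
#' (Z vs autosomes) and sex-bias classes via Wilcoxon rank-sum tests.
#'
#' @param profilesA,profilesB expression matrices (genes x conditions) for
#'   the two species; condition columns must match by name.
#' @param pairs ortholog pairs `data.frame` (`id_a` in species A, `id_b` in
#'   species B) from [reciprocalBestHits()].
#' @param chrom named chromosome vector over species-A genes (`NA` =
#'   unassigned, dropped from contrasts).
#' @param sbt optional [SexBiasTable-class] keyed by species-A gene ids
#'   (which species' classification to use is the caller's choice; pass a
#'   table built from either species' adults).
#' @param codonAlignments optional named list (by `id_a`) of
#'   `c(a=, b=)` codon alignment strings for Ka/Ks.
#' @param transform passed to [euclideanExpressionDistance()].
#' @return List with `records` (per-ortholog data.frame: `id_a`, `id_b`,
#'   `euclid`, `ka`, `ks`, `ka_ks`, `chrom_class`, `bias_class`),
#'   `euclid_contrasts` and (when alignments are given) `kaks_contrasts`,
#'   both as returned by [compareDivergenceGroups()].
#' @export
runFasterZ <- function(profilesA, profilesB, pairs, chrom, sbt = NULL,
                       codonAlignments = NULL,
                       transform = c("log2p1", "none")) {
    transform <- match.arg(transform)
    if (is.null(pairs) || !nrow(pairs))
        stop("ortholog pairs are required")
    keep <- pairs$id_a %in% rownames(profilesA) &
        pairs$id_b %in% rownames(profilesB)
    pairs <- pairs[keep, , drop = FALSE]
    zcLog("faster-z", nrow(pairs), " ortholog pairs with expression")
    euclid <- vapply(seq_len(nrow(pairs)), function(i)
        euclideanExpressionDistance(profilesA[pairs$id_a[i], ],
                                    profilesB[pairs$id_b[i], ],
                                    transform = transform),
        numeric(1))
    rec <- data.frame(id_a = pairs$id_a, id_b = pairs$id_b, euclid = euclid,
                      ka = NA_real_, ks = NA_real_, ka_ks = NA_real_,
                      stringsAsFactors = FALSE)
    if (!is.null(codonAlignments)) {
        for (i in seq_len(nrow(rec))) {
            aln <- codonAlignments[[rec$id_a[i]]]
            if (is.null(aln)) next
            kk <- kaKsNG86(aln[["a"]], aln[["b"]])
            rec$ka[i] <- kk$ka; rec$ks[i] <- kk$ks; rec$ka_ks[i] <- kk$ka_ks
        }
    }
    cc <- chrom[rec$id_a]
    rec$chrom_class <- ifelse(is.na(cc), NA,
                              ifelse(cc == "Z", "Z", "A"))
    lab <- if (!is.null(sbt)) biasLabels(sbt)[rec$id_a] else
        rep(NA_character_, nrow(rec))
    rec$bias_class <- unname(lab)
    cl_chrom <- stats::setNames(rec$chrom_class, rec$id_a)
    cl_bias <- stats::setNames(rec$bias_class, rec$id_a)
    out <- list(records = rec)
    out$euclid_contrasts <- compareDivergenceGroups(
        stats::setNames(rec$euclid, rec$id_a), cl_chrom, cl_bias)
    if (!is.null(codonAlignments))
        out$kaks_contrasts <- compareDivergenceGroups(
            stats::setNames(rec$ka_ks, rec$id_a), cl_chrom, cl_bias)
    out
}
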