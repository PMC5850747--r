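#' Best hit per query from tabular similarity hits
#'
#' Filters hits at `evalue <= evalueMax` (default 1e-5) and keeps, for each
#' query, the single best subject. Ranking is deterministic: higher bitscore,
#' then lower evalue, then lexicographically smaller subject id (the
#' `rankBy = "evalue"` ordering swaps the first two keys).
#'
#' @param hits `data.frame` from [readHitsTabular()].
#' @param evalueMax significance cut-off on the hit evalue (> 0).
#' @param rankBy `"bitscore"` (default) or `"evalue"`: which score leads
#'   the ordering.
#' @return Named character vector, query id -> best subject id.
#' @export
bestHits <- function(hits, evalueMax = 1e-5,
                     rankBy = c("bitscore", "evalue")) {
    rankBy <- match.arg(rankBy)
    stopifnot(is.numeric(evalueMax), evalueMax > 0)
    hits <- hits[hits$evalue <= evalueMax, , drop = FALSE]
    if (!nrow(hits)) return(stats::setNames(character(0), character(0)))
    ord <- if (rankBy == "bitscore")
        order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id)
    else
        order(hits$query_id, hits$evalue, -hits$bitscore, hits$subject_id)
    hits <- hits[ord, , drop = FALSE]
    best <- hits[!duplicated(hits$query_id), , drop = FALSE]
    stats::setNames(best$subject_id, best$query_id)
}

#' Reciprocal (bi-directional) best hits
#'
#' Extracts 1-to-1 ortholog pairs: `(a, b)` such that the best hit of `a`
#' in species B is `b` and the best hit of `b` in species A is `a`. The
#' result is a 1-to-1 mapping by construction.
#'
#' @param fwd named vector A -> B from [bestHits()].
#' @param rev named vector B -> A from [bestHits()].
#' @return `data.frame` with columns `id_a`, `id_b`, sorted by `id_a`.
#' @export
reciprocalBestHits <- function(fwd, rev) {
    a <- names(fwd)
    b <- unname(fwd)
    keep <- !is.na(rev[b]) & rev[b] == a
    keep[is.na(keep)] <- FALSE
    pairs <- data.frame(id_a = a[keep], id_b = b[keep],
                        stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$id_a), , drop = FALSE]
    rownames(pairs) <- NULL
    pairs
}

#' Transfer chromosome assignments through 1:1 orthologs
#'
#' A species-A gene inherits the chromosome class of its species-B ortholog;
#' genes without a 1:1 ortholog, or whose ortholog is itself unassigned,
#' stay unassigned (`NA`) and are excluded downstream.
#'
#' @param pairs `data.frame` with `id_a`, `id_b` from [reciprocalBestHits()].
#' @param refMap named character vector over species-B gene ids
#'   (from [readChromMap()]).
#' @param genes optional character vector of species-A gene ids to cover;
#'   defaults to `pairs$id_a`.
#' @return Named character vector over `genes` (`NA` = unassigned).
#' @export
transferChromosome <- function(pairs, refMap, genes = pairs$id_a) {
    out <- stats::setNames(rep(NA_character_, length(genes)), genes)
    hit <- match(genes, pairs$id_a)
    has <- !is.na(hit)
    out[has] <- unname(refMap[pairs$id_b[hit[has]]])
    out
}

#' Partition Z-linked genes into old and new strata
#'
#' Z-linked genes of the focal species are split by the location of their
#' ortholog in an outgroup species whose Z is ancestral: ortholog on the
#' outgroup Z -> `"old"` (conserved Z), on an outgroup autosome -> `"new"`
#' (recently Z-linked), no 1:1 ortholog or unassigned ortholog -> `"unknown"`.
#'
#' @param queryZGenes character vector of focal-species Z-linked gene ids.
#' @param pairs ortholog pairs (`id_a` = focal, `id_b` = outgroup).
#' @param outgroupMap named chromosome vector over outgroup gene ids.
#' @return Named character vector over `queryZGenes` with values
#'   `"old"`, `"new"` or `"unknown"`.
#' @export
partitionZAge <- function(queryZGenes, pairs, outgroupMap) {
    chrom <- transferChromosome(pairs, outgroupMap, genes = queryZGenes)
    out <- ifelse(is.na(chrom), "unknown",
                  ifelse(chrom == "Z", "old", "new"))
    stats::setNames(out, queryZGenes)
}

#' Collapse scaffold-level counts to gene models
#'
#' For fragmented de novo assemblies where several scaffolds map to one
#' reference gene model, sums the scaffold counts per gene model before any
#' analysis. Scaffolds absent from the map are dropped.
#'
#' @param counts integer matrix, scaffolds x libraries.
#' @param scaffoldToGene named character vector, scaffold id -> gene model id.
#' @return Integer matrix, gene models x libraries.
#' @export
collapseToGeneModels <- function(counts, scaffoldToGene) {
    keep <- rownames(counts) %in% names(scaffoldToGene)
    counts <- counts[keep, , drop = FALSE]
    gene <- scaffoldToGene[rownames(counts)]
    out <- rowsum(counts, group = unname(gene))
    storage.mode(out) <- "integer"
    out
}
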