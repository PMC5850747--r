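# Independent oracles used to cross-check the package implementations.
# These deliberately avoid the code paths they verify.

# Two-sided Fisher exact p by direct hypergeometric enumeration over all
# tables compatible with the margins (minimum-likelihood rule, with the
# same relative slack fisher.test uses for "no more probable").
oracle_fisher_two_sided <- function(tab) {
    tab <- matrix(as.vector(tab), 2, 2)
    m <- sum(tab[1, ])          # row-1 total
    n <- sum(tab[2, ])          # row-2 total
    k <- sum(tab[, 1])          # col-1 total
    if (m + n == 0) return(1)
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    pobs <- dhyper(tab[1, 1], m, n, k)
    sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Brute-force BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
oracle_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- numeric(m)
    for (i in seq_len(m))
        q[i] <- min(1, min(ps[i:m] * m / (i:m)))
    out <- numeric(m)
    out[o] <- q
    out
}

# Per-cell RPKM recomputation.
oracle_rpkm <- function(counts, lengths, lib_sizes) {
    out <- counts * 0
    for (i in seq_len(nrow(counts)))
        for (j in seq_len(ncol(counts)))
            out[i, j] <- counts[i, j] /
                ((lengths[rownames(counts)[i]] / 1e3) *
                 (lib_sizes[colnames(counts)[j]] / 1e6))
    out
}

# NG86 site counts by exhaustive single-mutation enumeration, using
# seqinr's translation table as an independent genetic-code source.
oracle_ng86_sites <- function(codon) {
    bases <- c("a", "c", "g", "t")
    cd <- tolower(strsplit(codon, "")[[1]])
    aa <- seqinr::translate(cd)
    syn <- 0
    nonsyn <- 0
    for (pos in 1:3) {
        for (nb in bases[bases != cd[pos]]) {
            mut <- cd
            mut[pos] <- nb
            maa <- seqinr::translate(mut)
            if (maa == "*") next
            if (maa == aa) syn <- syn + 1 / 3 else nonsyn <- nonsyn + 1 / 3
        }
    }
    c(syn = syn, nonsyn = nonsyn)
}

all_sense_codons <- function() {
    b <- c("A", "C", "G", "T")
    cods <- as.vector(outer(outer(b, b, paste0), b, paste0))
    cods[!cods %in% c("TAA", "TAG", "TGA")]
}

# Small DosageExperiment fixture: nGenes x (2 male + 2 female), first
# nZ genes Z-linked.
make_toy_experiment <- function(nGenes = 20, nZ = 4, seed = 42,
                                counts = NULL) {
    set.seed(seed)
    if (is.null(counts))
        counts <- matrix(rpois(nGenes * 4, 100), nGenes, 4)
    ids <- sprintf("g%03d", seq_len(nGenes))
    dimnames(counts) <- list(ids, c("m1", "m2", "f1", "f2"))
    meta <- data.frame(
        library_id = colnames(counts),
        sex = c("male", "male", "female", "female"),
        tissue = "whole_body", stage = "adult", replicate = c(1, 2, 1, 2))
    chrom <- setNames(c(rep("Z", nZ), rep("chr1", nGenes - nZ)), ids)
    lengths <- setNames(rep(1000, nGenes), ids)
    DosageExperiment(counts, meta, lengths = lengths, chrom = chrom)
}
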