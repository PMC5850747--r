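#' Euclidean distance between orthologous expression profiles
#'
#' Distance between two genes' expression profiles over matched conditions
#' (e.g. male/female x adult/pupa treated as four "tissues"). By default
#' profiles are log2(x + 1)-transformed first, since raw-scale distances are
#' dominated by the few most highly expressed genes.
#'
#' @param a,b named numeric vectors over identical condition keys.
#' @param transform `"log2p1"` (default) or `"none"`.
#' @return Non-negative distance.
#' @export
euclideanExpressionDistance <- function(a, b,
                                        transform = c("log2p1", "none")) {
    transform <- match.arg(transform)
    if (is.null(names(a)) || is.null(names(b)) ||
        !setequal(names(a), names(b)) || length(a) != length(b))
        stop("profiles must share an identical set of condition names")
    b <- b[names(a)]
    if (transform == "log2p1") {
        a <- log2(a + 1); b <- log2(b + 1)
    }
    sqrt(sum((a - b)^2))
}

.CODONS <- {
    b <- c("A", "C", "G", "T")
    as.vector(outer(outer(b, b, paste0), b, paste0))
}

.translate_codon <- function(codon) {
    unname(Biostrings::GENETIC_CODE[codon])
}

#' Back-translate a protein alignment into a codon-aware CDS alignment
#'
#' Maps each aligned amino-acid column onto its source codon (gap columns
#' become `"---"`), after verifying that each CDS translates exactly to the
#' ungapped protein under the standard genetic code. A terminal stop codon
#' on the CDS is trimmed automatically.
#'
#' @param protAlnA,protAlnB aligned amino-acid strings (same length, `-`
#'   for gaps).
#' @param cdsA,cdsB unaligned coding sequences (A/C/G/T).
#' @return Character vector `c(a = , b = )` of equal-length codon
#'   alignments (length divisible by 3).
#' @export
codonAlignFromProtein <- function(protAlnA, protAlnB, cdsA, cdsB) {
    if (nchar(protAlnA) != nchar(protAlnB))
        stop("aligned protein strings must have equal length")
    back <- function(prot_aln, cds, who) {
        cds <- toupper(cds)
        if (nchar(cds) %% 3 != 0)
            stop("CDS length of ", who, " is not divisible by 3")
        codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
        if (length(codons) &&
            .translate_codon(codons[length(codons)]) %in% "*")
            codons <- codons[-length(codons)]
        aa <- strsplit(prot_aln, "")[[1]]
        res <- sum(aa != "-")
        if (res != length(codons))
            stop("ungapped protein length (", res, ") does not match codon ",
                 "count (", length(codons), ") for ", who)
        out <- character(length(aa))
        k <- 0L
        for (i in seq_along(aa)) {
            if (aa[i] == "-") { out[i] <- "---"; next }
            k <- k + 1L
            trans <- .translate_codon(codons[k])
            if (is.na(trans) || trans != toupper(aa[i]))
                stop("codon ", codons[k], " of ", who, " translates to '",
                     trans, "', not '", aa[i], "', at alignment column ", i)
            out[i] <- codons[k]
        }
        paste(out, collapse = "")
    }
    c(a = back(protAlnA, cdsA, "sequence a"),
      b = back(protAlnB, cdsB, "sequence b"))
}

#' Synonymous and nonsynonymous site counts of a codon (NG86)
#'
#' For each of the three codon positions, counts the fraction of the three
#' possible point mutations that are synonymous; mutations creating stop
#' codons contribute to neither class, so `syn + nonsyn` equals 3 minus the
#' stop-mutation mass.
#'
#' @param codon a 3-mer over A/C/G/T that is not a stop codon.
#' @return Named numeric vector `c(syn = , nonsyn = )`.
#' @examples
#' ng86Sites("TTT")  # syn = 1/3: only the third-position T->C is silent
#' @export
ng86Sites <- function(codon) {
    codon <- toupper(codon)
    if (!codon %in% .CODONS)
        stop("codon must be an unambiguous A/C/G/T triplet, got '", codon, "'")
    aa <- .translate_codon(codon)
    if (aa == "*") stop("stop codon has no defined site counts")
    bases <- c("A", "C", "G", "T")
    syn <- 0; nonsyn <- 0
    sp <- strsplit(codon, "")[[1]]
    for (pos in 1:3) {
        for (nb in setdiff(bases, sp[pos])) {
            mut <- sp; mut[pos] <- nb
            maa <- .translate_codon(paste(mut, collapse = ""))
            if (maa == "*") next
            if (maa == aa) syn <- syn + 1 / 3 else nonsyn <- nonsyn + 1 / 3
        }
    }
    c(syn = syn, nonsyn = nonsyn)
}

# Average syn/nonsyn difference counts between two codons over all
# mutational pathways (equal weight), excluding pathways through stops.
# Returns c(sd, nd) or NULL when every pathway traverses a stop codon.
.ng86_diffs <- function(ca, cb) {
    if (ca == cb) return(c(sd = 0, nd = 0))
    sa <- strsplit(ca, "")[[1]]; sb <- strsplit(cb, "")[[1]]
    pos <- which(sa != sb)
    paths <- if (length(pos) == 1) list(pos) else
        lapply(seq_len(ncol(perms <- .permutations(pos))), function(j)
            perms[, j])
    acc <- c(sd = 0, nd = 0); nok <- 0L
    for (path in paths) {
        cur <- sa; steps <- c(sd = 0, nd = 0); ok <- TRUE
        for (p in path) {
            prev_aa <- .translate_codon(paste(cur, collapse = ""))
            cur[p] <- sb[p]
            new_codon <- paste(cur, collapse = "")
            new_aa <- .translate_codon(new_codon)
            if (new_aa == "*") { ok <- FALSE; break }
            if (new_aa == prev_aa) steps["sd"] <- steps["sd"] + 1
            else steps["nd"] <- steps["nd"] + 1
        }
        if (ok) { acc <- acc + steps; nok <- nok + 1L }
    }
    if (nok == 0L) return(NULL)
    acc / nok
}

# All permutations of a small vector, one per column.
.permutations <- function(v) {
    n <- length(v)
    if (n == 1) return(matrix(v, 1, 1))
    out <- NULL
    for (i in seq_len(n)) {
        sub <- .permutations(v[-i])
        out <- cbind(out, rbind(v[i], sub))
    }
    out
}

#' NG86 Ka and Ks from an aligned codon pair
#'
#' The approximate site-counting method: synonymous (S) and nonsynonymous
#' (N) sites are averaged over the two sequences via [ng86Sites()];
#' differences within a codon pair are decomposed over all mutational
#' pathways with equal weight, dropping pathways that traverse stop codons
#' (codon pairs whose every pathway hits a stop are skipped and counted in
#' `skipped`). Proportions ps = Sd/S and pn = Nd/N are Jukes-Cantor
#' corrected, d = -(3/4) ln(1 - (4/3) p); a proportion >= 3/4 saturates the
#' correction and is flagged rather than returned as a number.
#'
#' Only gap-free codon columns are counted.
#'
#' @param alnA,alnB equal-length codon alignment strings (length divisible
#'   by 3), e.g. from [codonAlignFromProtein()].
#' @return List with `ka`, `ks`, `ka_ks` (`NA` when `ks` is 0 or either
#'   rate is saturated), site counts `S`, `N`, difference counts `Sd`, `Nd`,
#'   `saturated` flag and `skipped` codon-pair count.
#' @export
kaKsNG86 <- function(alnA, alnB) {
    alnA <- toupper(alnA); alnB <- toupper(alnB)
    if (nchar(alnA) != nchar(alnB))
        stop("alignment strings must have equal length")
    if (nchar(alnA) %% 3 != 0)
        stop("alignment length must be divisible by 3")
    starts <- seq(1, nchar(alnA), 3)
    ca <- substring(alnA, starts, starts + 2)
    cb <- substring(alnB, starts, starts + 2)
    keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
    ca <- ca[keep]; cb <- cb[keep]
    S <- 0; N <- 0; Sd <- 0; Nd <- 0; skipped <- 0L
    for (i in seq_along(ca)) {
        if (.translate_codon(ca[i]) == "*" || .translate_codon(cb[i]) == "*")
            stop("stop codon inside the alignment at codon ", i)
        d <- .ng86_diffs(ca[i], cb[i])
        if (is.null(d)) { skipped <- skipped + 1L; next }
        sa <- ng86Sites(ca[i]); sb <- ng86Sites(cb[i])
        S <- S + (sa["syn"] + sb["syn"]) / 2
        N <- N + (sa["nonsyn"] + sb["nonsyn"]) / 2
        Sd <- Sd + d["sd"]; Nd <- Nd + d["nd"]
    }
    jc <- function(p) {
        if (p >= 3 / 4) return(NA_real_)
        -3 / 4 * log(1 - 4 / 3 * p)
    }
    ps <- if (S > 0) Sd / S else 0
    pn <- if (N > 0) Nd / N else 0
    ks <- jc(ps); ka <- jc(pn)
    saturated <- is.na(ks) || is.na(ka)
    ratio <- if (saturated || ks == 0) NA_real_ else ka / ks
    list(ka = unname(ka), ks = unname(ks), ka_ks = unname(ratio),
         S = unname(S), N = unname(N), Sd = unname(Sd), Nd = unname(Nd),
         saturated = saturated, skipped = skipped)
}

#' Compare divergence between gene groups
#'
#' Group medians and pairwise two-sided Wilcoxon rank-sum tests for a
#' per-gene divergence measure (Euclidean expression distance or Ka/Ks)
#' across chromosome classes and sex-bias classes: Z vs autosomes overall,
#' each bias class vs unbiased genes, and Z vs autosomes within each bias
#' class. Saturated/undefined records (`NA`) are dropped; empty contrasts
#' are skipped with a warning.
#'
#' @param values named numeric vector of per-gene divergence values.
#' @param chromClass named vector with values `"Z"`/`"A"` over genes.
#' @param biasClass named vector with values `"MBG"`/`"FBG"`/`"UBG"`.
#' @return List with `medians` (data.frame of group medians and sizes) and
#'   `contrasts` (data.frame: contrast, group sizes, Wilcoxon p).
#' @export
compareDivergenceGroups <- function(values, chromClass, biasClass) {
    genes <- names(values)[!is.na(values)]
    values <- values[genes]
    chromClass <- chromClass[genes]
    biasClass <- biasClass[genes]
    grp <- function(sel) values[!is.na(sel) & sel]
    groups <- list(
        Z = grp(chromClass == "Z"), A = grp(chromClass == "A"),
        MBG = grp(biasClass == "MBG"), FBG = grp(biasClass == "FBG"),
        UBG = grp(biasClass == "UBG"))
    for (cc in c("Z", "A")) for (bb in c("MBG", "FBG", "UBG"))
        groups[[paste(cc, bb, sep = ".")]] <-
            grp(chromClass == cc & biasClass == bb)
    medians <- data.frame(
        group = names(groups),
        n = vapply(groups, length, integer(1)),
        median = vapply(groups, function(g)
            if (length(g)) stats::median(g) else NA_real_, numeric(1)),
        row.names = NULL)
    contrast_defs <- list(
        c("Z", "A"), c("MBG", "UBG"), c("FBG", "UBG"),
        c("Z.MBG", "A.MBG"), c("Z.FBG", "A.FBG"), c("Z.UBG", "A.UBG"))
    rows <- lapply(contrast_defs, function(cd) {
        g1 <- groups[[cd[1]]]; g2 <- groups[[cd[2]]]
        if (!length(g1) || !length(g2)) {
            warning("empty group in contrast ", cd[1], " vs ", cd[2],
                    "; skipped", call. = FALSE)
            return(NULL)
        }
        w <- wilcoxonRankSum(g1, g2)
        data.frame(contrast = paste(cd[1], "vs", cd[2]),
                   n1 = length(g1), n2 = length(g2),
                   median1 = stats::median(g1), median2 = stats::median(g2),
                   p = w$p.value)
    })
    list(medians = medians, contrasts = do.call(rbind, rows))
}
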