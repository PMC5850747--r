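#' Simulation configuration
#'
#' Parameters of the synthetic RNA-seq experiment generator. Defaults mirror
#' a typical two-replicate, whole-body design in a ZW clade: ~5% of genes
#' Z-linked, negative-binomially dispersed counts, and one of three planted
#' dosage regimes:
#' \describe{
#'   \item{`uncompensated`}{female Z expression halved (single Z dose, no
#'     compensation); male Z unchanged.}
#'   \item{`compensated_female_up`}{female Z up-regulated back to the
#'     two-dose level: both sexes at factor 1.}
#'   \item{`compensated_male_down`}{both sexes' Z expression at factor
#'     `male_down_k` (default 0.7): compensated between the sexes but with
#'     Z:A below 1 in both.}
#' }
#' Sex-biased genes are planted multiplicatively (symmetric in log space):
#' a fraction `sbg_fraction_z` of Z-linked genes is made male-biased (the
#' masculinization scenario) and a fraction `sbg_fraction_a` of autosomal
#' genes is split evenly between male- and female-biased, each at fold
#' `sbg_fold`.
#'
#' @param n_autosomal,n_z numbers of autosomal and Z-linked genes.
#' @param regime one of `"uncompensated"`, `"compensated_female_up"`,
#'   `"compensated_male_down"`.
#' @param sbg_fraction_z,sbg_fraction_a planted sex-biased fractions in
#'   `[0, 1]`.
#' @param sbg_fold planted fold-change (> 1).
#' @param n_replicates libraries per sex (1 mirrors an unreplicated design).
#' @param depth expected mapped reads per library.
#' @param dispersion negative-binomial dispersion alpha
#'   (variance = mu + alpha mu^2); 0 gives Poisson counts.
#' @param male_down_k shared Z factor of the male-down regime.
#' @param tissue,stage metadata labels for the simulated libraries.
#' @param seed integer seed; all generators are pure functions of
#'   (config, seed).
#' @return A `SimConfig` (validated named list).
#' @export
simConfig <- function(n_autosomal = 6000, n_z = 300,
                      regime = c("compensated_female_up", "uncompensated",
                                 "compensated_male_down"),
                      sbg_fraction_z = 0, sbg_fraction_a = 0,
                      sbg_fold = 4, n_replicates = 2, depth = 5e6,
                      dispersion = 0.1, male_down_k = 0.7,
                      tissue = "whole_body", stage = "adult", seed = 1L) {
    regime <- match.arg(regime)
    stopifnot(n_autosomal >= 1, n_z >= 0,
              sbg_fraction_z >= 0, sbg_fraction_z <= 1,
              sbg_fraction_a >= 0, sbg_fraction_a <= 1,
              sbg_fold > 1, n_replicates >= 1, depth > 0, dispersion >= 0,
              male_down_k > 0)
    structure(list(n_autosomal = as.integer(n_autosomal),
                   n_z = as.integer(n_z), regime = regime,
                   sbg_fraction_z = sbg_fraction_z,
                   sbg_fraction_a = sbg_fraction_a, sbg_fold = sbg_fold,
                   n_replicates = as.integer(n_replicates), depth = depth,
                   dispersion = dispersion, male_down_k = male_down_k,
                   tissue = tissue, stage = stage, seed = as.integer(seed)),
              class = "SimConfig")
}

#' Simulate a gene catalog with planted ground truth
#'
#' Gene lengths are log-normal with median ~1.5 kb (sdlog 0.45); baseline
#' expression levels are log-normal (meanlog 0, sdlog 1, ~1.4 log2-units of
#' spread, typical of expressed genes in bulk RNA-seq). The first `n_z`
#' genes are Z-linked; autosomal genes are spread over labels
#' `chr1`..`chr28`. Sex-bias labels and folds are planted per the config.
#'
#' @param config a [simConfig()].
#' @return `data.frame` (one row per gene): `gene_id`, `chrom`, `length`,
#'   `baseline`, `bias` (`MBG`/`FBG`/`UBG`), `fold`.
#' @export
simulateCatalog <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    n <- config$n_z + config$n_autosomal
    gene_id <- sprintf("g%05d", seq_len(n))
    chrom <- c(rep("Z", config$n_z),
               paste0("chr", rep_len(1:28, config$n_autosomal)))
    len <- pmax(150, round(stats::rlnorm(n, meanlog = log(1500),
                                         sdlog = 0.45)))
    baseline <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
    bias <- rep("UBG", n)
    fold <- rep(1, n)
    if (config$n_z > 0 && config$sbg_fraction_z > 0) {
        nz_sbg <- round(config$sbg_fraction_z * config$n_z)
        zi <- sample(seq_len(config$n_z), nz_sbg)
        bias[zi] <- "MBG"
        fold[zi] <- config$sbg_fold
    }
    if (config$sbg_fraction_a > 0) {
        na_sbg <- round(config$sbg_fraction_a * config$n_autosomal)
        ai <- config$n_z + sample(seq_len(config$n_autosomal), na_sbg)
        bias[ai] <- rep_len(c("MBG", "FBG"), na_sbg)
        fold[ai] <- config$sbg_fold
    }
    data.frame(gene_id = gene_id, chrom = chrom, length = len,
               baseline = baseline, bias = bias, fold = fold,
               stringsAsFactors = FALSE)
}

# Expected expression factor of each gene in each sex under the planted
# regime and bias labels.
.sim_factors <- function(catalog, config) {
    onZ <- catalog$chrom == "Z"
    fm <- rep(1, nrow(catalog)); ff <- rep(1, nrow(catalog))
    if (config$regime == "uncompensated") {
        ff[onZ] <- 0.5
    } else if (config$regime == "compensated_male_down") {
        fm[onZ] <- config$male_down_k
        ff[onZ] <- config$male_down_k
    }
    mbg <- catalog$bias == "MBG"; fbg <- catalog$bias == "FBG"
    fm[mbg] <- fm[mbg] * catalog$fold[mbg]
    ff[fbg] <- ff[fbg] * catalog$fold[fbg]
    list(male = fm, female = ff)
}

#' Simulate a count matrix under a planted dosage regime
#'
#' Expected counts are proportional to baseline x regime/bias factor x gene
#' length within each library, scaled so each library's expected total is
#' `depth`; counts are drawn from a negative binomial with the configured
#' dispersion (Poisson when `dispersion = 0`). The RNG is seeded from
#' `config$seed + 1` so the catalog and counts are independently
#' reproducible.
#'
#' @param catalog output of [simulateCatalog()].
#' @param config the same [simConfig()].
#' @return A [DosageExperiment-class] with the truth columns of `catalog`
#'   carried in `rowData` (`true_bias`, `true_fold`, `baseline`).
#' @export
simulateCounts <- function(catalog, config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + 1L)
    fac <- .sim_factors(catalog, config)
    libs <- expand.grid(replicate = seq_len(config$n_replicates),
                        sex = c("male", "female"),
                        stringsAsFactors = FALSE)
    libs$library_id <- paste0(substr(libs$sex, 1, 1), "_rep", libs$replicate)
    n <- nrow(catalog)
    counts <- matrix(0L, n, nrow(libs),
                     dimnames = list(catalog$gene_id, libs$library_id))
    for (j in seq_len(nrow(libs))) {
        f <- if (libs$sex[j] == "male") fac$male else fac$female
        w <- catalog$baseline * f * catalog$length
        mu <- config$depth * w / sum(w)
        counts[, j] <- as.integer(if (config$dispersion == 0)
            stats::rpois(n, mu)
        else
            stats::rnbinom(n, mu = mu, size = 1 / config$dispersion))
    }
    meta <- data.frame(library_id = libs$library_id, sex = libs$sex,
                       tissue = config$tissue, stage = config$stage,
                       replicate = libs$replicate)
    de <- DosageExperiment(counts, meta,
                           lengths = stats::setNames(catalog$length,
                                                     catalog$gene_id),
                           chrom = stats::setNames(catalog$chrom,
                                                   catalog$gene_id))
    SummarizedExperiment::rowData(de)$baseline <- catalog$baseline
    SummarizedExperiment::rowData(de)$true_bias <- catalog$bias
    SummarizedExperiment::rowData(de)$true_fold <- catalog$fold
    de
}

#' Simulate a complete experiment
#'
#' @param config a [simConfig()].
#' @return List with `de` (a [DosageExperiment-class]) and `truth`
#'   (the catalog data.frame).
#' @export
simulateExperiment <- function(config) {
    truth <- simulateCatalog(config)
    list(de = simulateCounts(truth, config), truth = truth)
}

.mk_hits <- function(q, s, bitscore, evalue = 1e-50) {
    n <- length(q)
    data.frame(query_id = q, subject_id = s,
               percent_identity = rep(90, n), aln_length = rep(300, n),
               mismatches = rep(30, n), gap_opens = rep(0, n),
               qstart = rep(1, n), qend = rep(300, n),
               sstart = rep(1, n), send = rep(300, n),
               evalue = rep_len(evalue, n), bitscore = bitscore,
               stringsAsFactors = FALSE)
}

#' Simulate tabular hit files with planted 1:1 orthologs
#'
#' Produces forward (A vs B) and reverse (B vs A) hit tables containing
#' `nTrue` reciprocal top-scoring pairs plus `nDecoys` one-directional
#' lower-bitscore decoy hits, and optionally `nAdversarial` one-way decoys
#' that outscore a true forward hit (those pairs are intentionally lost and
#' flagged in the truth table).
#'
#' @param nTrue number of planted ortholog pairs.
#' @param nDecoys number of low-score one-way decoy hits.
#' @param nAdversarial number of true pairs sabotaged by a higher-scoring
#'   one-way decoy.
#' @param seed integer seed.
#' @return List with `fwd`, `rev` (hit `data.frame`s in the 12-column
#'   dialect) and `truth` (`id_a`, `id_b`, `recoverable`).
#' @export
simulateOrthologHits <- function(nTrue = 50, nDecoys = 20,
                                 nAdversarial = 0, seed = 1L) {
    stopifnot(nTrue >= 0, nDecoys >= 0, nAdversarial >= 0,
              nAdversarial <= nTrue)
    set.seed(seed)
    ida <- sprintf("a%04d", seq_len(nTrue))
    idb <- sprintf("b%04d", sample(seq_len(nTrue)))
    true_bits <- stats::runif(nTrue, 300, 500)
    fwd <- .mk_hits(ida, idb, true_bits)
    rev <- .mk_hits(idb, ida, true_bits)
    recoverable <- rep(TRUE, nTrue)
    if (nDecoys > 0 && nTrue > 0) {
        dq <- sample(ida, nDecoys, replace = TRUE)
        ds <- sprintf("bdecoy%03d", seq_len(nDecoys))
        fwd <- rbind(fwd, .mk_hits(dq, ds,
                                   stats::runif(nDecoys, 50, 250),
                                   evalue = 1e-10))
    }
    if (nAdversarial > 0) {
        hit_i <- seq_len(nAdversarial)
        recoverable[hit_i] <- FALSE
        fwd <- rbind(fwd, .mk_hits(ida[hit_i],
                                   sprintf("badv%03d", hit_i),
                                   true_bits[hit_i] + 100))
    }
    list(fwd = fwd, rev = rev,
         truth = data.frame(id_a = ida, id_b = idb,
                            recoverable = recoverable,
                            stringsAsFactors = FALSE))
}

.SENSE_CODONS <- {
    b <- c("A", "C", "G", "T")
    all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
    all3[Biostrings::GENETIC_CODE[all3] != "*"]
}

#' Simulate a diverged codon-aligned sequence pair
#'
#' Evolves a derived sequence from a random ancestral coding sequence by
#' proposing single-base substitutions: proposals creating stop codons are
#' rejected, synonymous proposals are always accepted, nonsynonymous
#' proposals are accepted with probability `omega` (the planted Ka/Ks).
#' Proposals continue until the accepted synonymous substitutions reach
#' `expectedKs` per synonymous site of the ancestral sequence.
#'
#' @param nCodons length of the coding sequence in codons.
#' @param omega planted nonsynonymous acceptance probability.
#' @param expectedKs target synonymous divergence (substitutions per
#'   synonymous site, before multiple-hit correction).
#' @param seed integer seed.
#' @return List with `a` (ancestral), `b` (derived) aligned codon strings,
#'   `syn_subs`, `nonsyn_subs` (accepted counts), `nonsyn_proposed`, and
#'   `true_omega` (realized acceptance ratio).
#' @export
simulateCodonPair <- function(nCodons = 300, omega = 1, expectedKs = 0.3,
                              seed = 1L) {
    stopifnot(nCodons >= 1, omega >= 0, omega <= 1, expectedKs >= 0)
    set.seed(seed)
    anc <- sample(.SENSE_CODONS, nCodons, replace = TRUE)
    sites <- vapply(anc, ng86Sites, numeric(2))
    S0 <- sum(sites["syn", ])
    target_syn <- round(expectedKs * S0)
    cur <- strsplit(paste(anc, collapse = ""), "")[[1]]
    bases <- c("A", "C", "G", "T")
    syn_subs <- 0L; nonsyn_subs <- 0L; nonsyn_prop <- 0L
    it <- 0L; max_it <- 1000L * (target_syn + 10L)
    while (syn_subs < target_syn && it < max_it) {
        it <- it + 1L
        p <- sample.int(length(cur), 1L)
        nb <- sample(setdiff(bases, cur[p]), 1L)
        ci <- (p - 1L) %/% 3L
        idx <- ci * 3L + 1:3
        old_codon <- paste(cur[idx], collapse = "")
        new <- cur[idx]; new[(p - 1L) %% 3L + 1L] <- nb
        new_codon <- paste(new, collapse = "")
        new_aa <- unname(Biostrings::GENETIC_CODE[new_codon])
        if (new_aa == "*") next
        old_aa <- unname(Biostrings::GENETIC_CODE[old_codon])
        if (new_aa == old_aa) {
            cur[p] <- nb
            syn_subs <- syn_subs + 1L
        } else {
            nonsyn_prop <- nonsyn_prop + 1L
            if (stats::runif(1) < omega) {
                cur[p] <- nb
                nonsyn_subs <- nonsyn_subs + 1L
            }
        }
    }
    list(a = paste(anc, collapse = ""), b = paste(cur, collapse = ""),
         syn_subs = syn_subs, nonsyn_subs = nonsyn_subs,
         nonsyn_proposed = nonsyn_prop,
         true_omega = if (nonsyn_prop) nonsyn_subs / nonsyn_prop else NA)
}

#' Classify the dosage regime implied by a ratio panel
#'
#' Matches the observed (log) deviations of `mf_z`, `za_female` and
#' `za_male` from 1 against the three regime signatures — uncompensated:
#' M:F on Z up, Z:A in females down; compensated by female up-regulation:
#' all near 1; compensated by male down-regulation: M:F near 1 with Z:A
#' depressed in both sexes — and returns the nearest signature in log-ratio
#' space (the robust form of sign-pattern matching).
#'
#' @param report a [DosageReport-class].
#' @param male_down_k assumed shared Z factor of the male-down signature.
#' @return One of `"uncompensated"`, `"compensated_female_up"`,
#'   `"compensated_male_down"`.
#' @export
classifyRegime <- function(report, male_down_k = 0.7) {
    r <- panelRatios(report)
    obs <- log(c(r["mf_z"], r["za_female"], r["za_male"]))
    sig <- rbind(uncompensated = c(log(2), log(0.5), 0),
                 compensated_female_up = c(0, 0, 0),
                 compensated_male_down = c(0, log(male_down_k),
                                           log(male_down_k)))
    d <- apply(sig, 1, function(s) sum((obs - s)^2))
    names(which.min(d))
}
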