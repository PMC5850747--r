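---
title: "Assessing Z-chromosome dosage compensation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing Z-chromosome dosage compensation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zcomp)
options(zcomp.quiet = TRUE)
```

## The problem

In female-heterogametic (ZW) species, females carry a single Z chromosome.
Without a compensating mechanism, Z-linked genes are expressed at half the
male level in females, which shows up in two summary statistics computed
from RNA-seq: the male-to-female ratio on the Z (M:F on Z ≈ 2) and the
Z-to-autosome ratio in females (Z:A females ≈ 0.5).

The central methodological point this package implements is that these
summaries are confounded by the *gene content* of the Z. Sex chromosomes
often accumulate male-biased genes (MBG) and lose female-biased genes
(FBG). A Z enriched for MBG shows M:F > 1 even when every individual gene
is perfectly dose-compensated — masculinization masquerading as missing
compensation. The remedy is to compute the ratio panel twice: once on all
expressed genes and once after removing all genes with a sex-bias
fold-change above a threshold (2, or 4 for a stricter definition) from
both the Z and the autosomes, and to test directly whether MBG/FBG are
over- or under-represented on the Z (observed/expected ratio with a
two-sided Fisher's exact test).

## Pipeline and its assumptions

`runDosageAnalysis()` fixes the order of operations as:

1. **RPKM** per gene and library: `count / ((length/10^3) ×
   (library_size/10^6))`, with library sizes defaulting to column sums.
2. **Quantile normalization** between the libraries of each tissue ×
   stage group: every library's rank-r value is replaced by the mean of
   the rank-r order statistics across libraries. Tied values receive the
   mean of the order-statistic means their ranks span. Normalizing within
   tissue × stage groups assumes only those libraries share an expression
   distribution; normalizing across tissues would erase genuine
   tissue differences.
3. **Cut-off filtering** at RPKM `none`, `> 0`, `> 1`, or `> 5`, either in
   every library (`all_libraries`, the default) or in at least one library
   of each sex (`both_sexes`). Filtering after normalization keeps a
   single normalization per group valid across all cut-offs; results
   should be (and in the simulations are) robust across cut-offs.
4. **Sex-bias classification.** The degree of sex bias is
   `log2((mean_male + 1) / (mean_female + 1))` on normalized RPKM; the
   pseudocount of 1 shrinks fold-changes of weakly expressed genes and
   guards zeros. A gene is MBG if the log2 fold-change is at least
   `log2(threshold)`, FBG if at most `-log2(threshold)`, otherwise UBG.
   With at least two replicates per sex, a significance gate can be added:
   a Welch two-sample t statistic on `log2(normalized expression + 1)`
   per gene, Benjamini–Hochberg adjusted, requiring adjusted p < 0.05.
   This plain Welch-on-logs test is a deliberately simple stand-in for a
   full negative-binomial differential-expression model; it does not
   shrink dispersions across genes and has little power at n = 2 per
   group, which is why the exclusion step itself (`biasMode =
   "fold_change"`) uses the fold-change rule alone — exclusion is meant to
   remove *strongly* sex-biased genes, not statistically certified ones.
5. **The ratio panel** (`dosagePanel()`): per-gene expression is the mean
   over same-sex libraries; the four comparisons (Z vs A within each sex,
   M vs F within Z and within A) use two-sided Wilcoxon rank-sum tests and
   ratios of group medians.
6. **Enrichment** (`sbgEnrichment()`): expected MBG (or FBG) on the Z is
   the proportion of Z-linked genes among analysed genes times the class
   total; significance by two-sided Fisher's exact test.

Genes not present in the chromosome map are "unassigned" and are excluded
from all panel and enrichment statistics. Genes without a fold-change
classification are retained during exclusion runs.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `cutoff` | `none`, `0`, `1`, `5` | RPKM expression floor (RPKM units) |
| `fcThreshold` | 2 (4 optional) | fold-change defining MBG/FBG |
| `pseudocount` | 1 (RPKM units) | fold-change shrinkage for weak genes |
| `ratioType` | `"median"` | aggregate used in the four ratios |
| `filterMode` | `"all_libraries"` | where the cut-off must hold |
| `heterogameticSex` | `"female"` | ZW convention; `"male"` swaps roles for XY data |

**Ratio of medians, not means.** Ratio panels of this kind are
conventionally labelled "average expression ratios", but a mean over
genes is dominated by a handful of very highly expressed genes, which is
at odds with the rank-based Wilcoxon tests used for significance
throughout. The package therefore reports ratios of group
medians by default and offers `ratioType = "mean"` for comparison.
Likewise, M:F is the ratio of the two group aggregates, not the average of
per-gene ratios (which is unstable for genes with near-zero female
expression).

## Orthology transfer

For species without linkage information, chromosome classes are inherited
from a well-assembled relative through 1:1 orthologs: best hits per query
from 12-column tabular similarity searches (evalue ≤ 1e-5), ranked by
bitscore, then evalue, then lexicographically smaller subject id — the
similarity tools themselves do not define a tie-break, and determinism is
required for reproducible pair sets; `rankBy = "evalue"` swaps the first
two keys. Reciprocal best hits define the 1:1 pairs; a gene whose
ortholog is unassigned stays unassigned. `partitionZAge()` further splits
Z-linked genes into an "old" stratum (ortholog on the outgroup Z, i.e. the
conserved Z) and a "new" stratum (ortholog on an outgroup autosome),
which matters because recently Z-linked genes may differ in compensation
status. Fragmented de novo assemblies are handled upstream by
`collapseToGeneModels()`, which sums scaffold counts per reference gene
model before any analysis.

## Faster-Z divergence

Expression divergence between two species is the Euclidean distance
between the orthologs' expression profiles, with sexes and stages treated
as separate conditions. Distances are computed on `log2(x + 1)` by
default: on the raw scale the distance of a gene pair is essentially the
difference of their two largest expression values. Sequence divergence is
the NG86 approximate method: synonymous/nonsynonymous site counts per
codon (mutations to stop codons contribute to neither class, so sites sum
to 3 minus the stop-mutation mass), equal-weight averaging over all
mutational pathways between differing codons with stop-traversing
pathways dropped (codon pairs where every pathway hits a stop are skipped
and counted), and a Jukes–Cantor correction `d = -(3/4) ln(1 - (4/3) p)`.
A proportion p ≥ 3/4 saturates the correction; such records are flagged
and excluded from group statistics rather than silently clamped. NG86 was
chosen over model-averaged or maximum-likelihood estimators because it is
fully specified, fast, and testable against exhaustive per-codon
enumeration; for the moderate divergences it is applied to here
(Ks ≈ 0.3) its known downward bias at high divergence is immaterial.

## Statistical primitives

* **Wilcoxon rank-sum**: exact enumeration over all C(n+m, n) rank
  assignments (two-sided p = twice the smaller tail, capped at 1;
  midranks under ties) when `max(n, m) ≤ 8` and the pooled sample is
  tie-free; otherwise the tie-corrected normal approximation with
  continuity correction. An all-tied comparison returns p = 1.
* **Fisher's exact test**: two-sided by the minimum-likelihood rule
  (sum of hypergeometric probabilities of tables no more probable than
  the observed one). This is documented because the alternative
  convention — doubling the one-sided tail — gives different p-values.
* **Benjamini–Hochberg**: the classic step-up, q(i) = min over j ≥ i of
  p(j)·m/j, capped at 1.

## The synthetic-data generator

`simConfig()`/`simulateExperiment()` generate every input the pipeline
consumes, with known ground truth. Defaults describe the study design the
package targets: 300 Z-linked and 6,000 autosomal genes (~5% Z), two
replicates per sex, 5 million reads per library, negative-binomial counts
with dispersion α = 0.1 (variance = μ + αμ²), a typical bulk RNA-seq
overdispersion. Gene lengths are log-normal with median 1.5 kb (sdlog
0.45). Baseline expression is log-normal with sdlog 1 (≈1.4 log2-units of
spread), the spread of *expressed* genes rather than of the full
transcriptome — panel statistics are computed on cut-off-filtered sets, so
this is the relevant population. Expected counts are proportional to
baseline × regime factor × length within each library and scaled to the
library depth, making simulated RPKM proportional to the planted
expression level.

Three dosage regimes are planted: `uncompensated` (female Z × 0.5),
`compensated_female_up` (both sexes × 1), and `compensated_male_down`
(both sexes × 0.7 — equalized between sexes but Z:A < 1 in both, the
signature of compensation achieved partly by down-regulating males).
Sex-biased genes are planted multiplicatively: a chosen fraction of Z
genes becomes male-biased (the masculinization scenario under study),
and autosomal planted genes split evenly between MBG and FBG so the
autosomal M:F stays near 1.

`classifyRegime()` recovers the planted regime from a ratio panel by
matching the observed log-deviations of (M:F on Z, Z:A females, Z:A males)
to the three regime signatures and choosing the nearest in log-ratio
space. This is the robust form of sign-pattern matching: a hard band
around 1 would misclassify a fully compensated simulation whenever the
Z:A ratio — whose sampling noise with 300 Z genes is about 7% — strays
past the band edge.

What the generator does **not** emulate: GC and length biases in read
sampling, between-replicate library-preparation effects beyond NB noise,
correlated expression between genes, tissue mixtures within a library
(whole-body samples are treated as one tissue named `whole_body` — gonad
signal is not deconvolved), and isoform-level variation. Passing the
recovery tests therefore shows the statistics behave correctly under a
clean generative model, not that any particular real data set is
compensated.

`simulateCodonPair()` evolves a derived coding sequence from a random
ancestral one: proposals creating stops are rejected, synonymous
proposals always accepted, nonsynonymous ones accepted with probability
ω; proposals continue until the accepted synonymous substitutions reach
the target Ks per ancestral synonymous site. The realized acceptance
ratio is recorded, so estimator recovery can be checked against the
planted ω. `simulateOrthologHits()` plants reciprocal top-scoring hit
pairs plus one-way lower-score decoys, and optionally "adversarial"
decoys that outscore a true hit, whose pairs are deliberately lost and
marked as unrecoverable in the truth table.

## Problem sizes used in validation

The shipped validation (test suite and `scripts/acceptance.R`) runs the
masking-recovery study at 50 seeds × (300 Z + 6,000 A genes), regime
discrimination at 3 × 50 seeds, Ka/Ks recovery at 200 pairs × 300 codons
per selection regime, exhaustive Fisher-vs-enumeration sweeps over all
2×2 tables with margins ≤ 12, and exact-Wilcoxon enumeration for all
sample sizes up to 7 per group. These sizes give stable medians and
recovery rates (re-running with a different master seed moves the
reported medians by well under 2%) while keeping a full run in the
low minutes on one CPU.

## Worked example

```{r example}
cfg <- simConfig(regime = "compensated_female_up",
                 sbg_fraction_z = 0.2, sbg_fold = 4, seed = 7)
sim <- simulateExperiment(cfg)
res <- runDosageAnalysis(sim$de, cutoffs = "0", fcThresholds = 2,
                         biasMode = "fold_change")
res$report[, c("cutoff", "sbg_included", "za_male", "za_female",
               "mf_autosomes", "mf_z", "p_mf_z")]
res$enrichment[, c("class", "observed", "expected", "ratio", "p_fet")]
```

A fully compensated Z that carries planted male-biased genes shows
M:F on Z well above 1 with sex-biased genes included, and returns to ≈1
once fold-change > 2 genes are excluded, while the enrichment table
flags the MBG excess on the Z — distinguishing masculinization from
missing compensation.

## Known limitations

* The Welch-on-logs replicate test is underpowered at two replicates per
  sex; with such designs, classification is fold-change-based and the
  gate should be reserved for n ≥ 3.
* Quantile normalization forces identical library distributions; genuine
  global expression differences between sexes within a tissue are removed
  by construction.
* NG86 underestimates divergence when substitution rates vary strongly
  among sites, and the Jukes–Cantor correction saturates at p ≥ 3/4.
* The ratio panel treats genes as exchangeable; it does not model
  gene-level dosage sensitivity or meiotic sex-chromosome inactivation.
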