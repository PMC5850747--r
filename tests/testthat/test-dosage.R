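test_that("exact Wilcoxon matches enumeration and handles degenerate ties", {
    expect_equal(wilcoxonRankSum(c(1, 2), c(3, 4), mode = "exact")$p.value,
                 1 / 3)
    x <- c(2, 2, 2)
    expect_equal(wilcoxonRankSum(x, x)$p.value, 1)
    expect_error(wilcoxonRankSum(numeric(0), 1:3), "non-empty")
})

test_that("exact mode equals the reference exact distribution for n,m <= 7", {
    set.seed(33)
    for (n in 2:7) for (m in 2:7) {
        pooled <- sample(seq_len(40), n + m)   # tie-free
        x <- pooled[seq_len(n)]; y <- pooled[-seq_len(n)]
        mine <- wilcoxonRankSum(x, y, mode = "exact")$p.value
        ref <- wilcox.test(x, y, exact = TRUE)$p.value
        expect_equal(mine, ref, tolerance = 1e-12,
                     label = sprintf("n=%d m=%d", n, m))
    }
})

test_that("normal approximation is close to exact at moderate sizes", {
    set.seed(44)
    for (i in 1:10) {
        x <- rnorm(20); y <- rnorm(20, 0.3)
        approx <- wilcoxonRankSum(x, y, mode = "normal_approx")$p.value
        exact <- wilcox.test(x, y, exact = TRUE)$p.value
        expect_lt(abs(approx - exact), 0.01)
    }
})

test_that("median ratios are scale-equivariant", {
    expect_equal(medianRatio(c(1, 5, 9), c(1, 5, 9)), 1)
    b <- c(2, 3, 8)
    expect_equal(medianRatio(2 * b, b), 2)
    expect_equal(medianRatio(c(1, 2, 9), c(2, 4, 4)), 0.5)
    expect_equal(medianRatio(c(1, 2, 9), c(2, 4, 6), type = "mean"), 1)
    expect_error(medianRatio(1:3, c(0, 0, 0)), "positive")
})

test_that("Fisher exact matches hypergeometric enumeration on examples", {
    expect_equal(fisherExactTwoSided(matrix(c(5, 5, 5, 5), 2)), 1)
    expect_equal(fisherExactTwoSided(matrix(c(3, 1, 1, 3), 2)), 34 / 70)
    expect_equal(fisherExactTwoSided(matrix(c(0, 10, 10, 0), 2)),
                 2 / choose(20, 10))
    expect_error(fisherExactTwoSided(matrix(c(-1, 1, 1, 1), 2)),
                 "non-negative")
})

test_that("Fisher exact equals the enumeration oracle on a margin sweep", {
    # subset here; the exhaustive margins <= 12 sweep runs in the
    # acceptance suite
    set.seed(55)
    for (i in 1:200) {
        tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
        expect_equal(fisherExactTwoSided(tab), oracle_fisher_two_sided(tab),
                     tolerance = 1e-9)
    }
})

test_that("dosage panel is exact on constant expression", {
    expr <- matrix(5, 20, 4,
                   dimnames = list(sprintf("g%02d", 1:20),
                                   c("m1", "m2", "f1", "f2")))
    sex <- setNames(c("male", "male", "female", "female"), colnames(expr))
    chrom <- setNames(c(rep("Z", 5), rep("chr1", 15)), rownames(expr))
    rep_ <- dosagePanel(expr, chrom, sex)
    expect_equal(unname(panelRatios(rep_)), rep(1, 4))
    expect_equal(unname(panelPvalues(rep_)), rep(1, 4))
})

test_that("dosage panel recovers the uncompensated regime", {
    rs <- sapply(1:5, function(s) {
        sim <- simulateExperiment(simConfig(regime = "uncompensated",
                                            n_z = 300, n_autosomal = 6000,
                                            seed = 70 + s))
        de <- quantileNormalize(computeRPKM(sim$de))
        expr <- SummarizedExperiment::assay(de, "nrpkm")
        panelRatios(dosagePanel(expr, geneChrom(de), libSex(de)))
    })
    expect_gt(median(rs["mf_z", ]), 1.8)
    expect_lt(median(rs["mf_z", ]), 2.2)
    expect_gt(median(rs["mf_autosomes", ]), 0.95)
    expect_lt(median(rs["mf_autosomes", ]), 1.05)
})

test_that("masculinization masks compensation until SBG are excluded", {
    mfz <- sapply(1:5, function(s) {
        cfg <- simConfig(regime = "compensated_female_up",
                         sbg_fraction_z = 0.2, sbg_fold = 4, seed = 12 + s)
        sim <- simulateExperiment(cfg)
        de <- quantileNormalize(computeRPKM(sim$de))
        expr <- SummarizedExperiment::assay(de, "nrpkm")
        sex <- libSex(de); chrom <- geneChrom(de)
        raw <- dosagePanel(expr, chrom, sex)
        sbt <- classifySexBias(log2FoldChange(expr, sex), fcThreshold = 2)
        excl <- dosagePanel(expr, chrom, sex, exclude = sbt)
        c(raw = panelRatios(raw)[["mf_z"]],
          excl = panelRatios(excl)[["mf_z"]])
    })
    expect_gt(median(mfz["raw", ]), 1.2)
    expect_gt(median(mfz["excl", ]), 0.9)
    expect_lt(median(mfz["excl", ]), 1.1)
})

test_that("dosage panel is invariant to library order and common scaling", {
    de <- make_toy_experiment(nGenes = 40, nZ = 8, seed = 9)
    de <- quantileNormalize(computeRPKM(de))
    expr <- SummarizedExperiment::assay(de, "nrpkm")
    sex <- libSex(de); chrom <- geneChrom(de)
    r1 <- dosagePanel(expr, chrom, sex)
    perm <- c(3, 1, 4, 2)
    r2 <- dosagePanel(expr[, perm], chrom, sex[perm])
    expect_equal(panelRatios(r1), panelRatios(r2))
    expect_equal(panelPvalues(r1), panelPvalues(r2))
    r3 <- dosagePanel(expr * 7, chrom, sex)
    expect_equal(panelRatios(r1), panelRatios(r3))
    expect_equal(panelPvalues(r1), panelPvalues(r3))
})

test_that("a filtered set without Z genes is a clear error", {
    de <- make_toy_experiment(nGenes = 20, nZ = 4)
    de <- quantileNormalize(computeRPKM(de))
    expr <- SummarizedExperiment::assay(de, "nrpkm")
    agenes <- names(geneChrom(de))[geneChrom(de) != "Z"]
    expect_error(dosagePanel(expr, geneChrom(de), libSex(de),
                             genes = agenes), "no Z-linked genes")
})

test_that("SBG enrichment reproduces the observed/expected arithmetic", {
    genes <- sprintf("g%05d", 1:13000)
    chrom <- setNames(c(rep("Z", 300), rep("chr1", 12700)), genes)
    # 100 MBG, 10 of them on Z
    fc <- setNames(rep(0, 13000), genes)
    fc[c(1:10, 311:400)] <- 3          # >= log2(4) -> MBG
    sbt <- classifySexBias(fc, fcThreshold = 2)
    en <- sbgEnrichment(sbt, chrom, genes)
    mbg <- en[en$class == "MBG", ]
    expect_identical(mbg$observed, 10L)
    expect_equal(mbg$expected, 100 * 300 / 13000, tolerance = 1e-12)
    expect_equal(mbg$ratio, 10 / (100 * 300 / 13000), tolerance = 1e-12)
    fbg <- en[en$class == "FBG", ]
    expect_identical(fbg$n_class, 0L)
    expect_true(is.nan(fbg$ratio))
    expect_equal(fbg$p_fet, 1)
})

test_that("uniformly planted MBG show no Z enrichment on average", {
    set.seed(66)
    ratios <- replicate(100, {
        genes <- sprintf("g%04d", 1:2000)
        chrom <- setNames(c(rep("Z", 150), rep("chr1", 1850)), genes)
        fc <- setNames(rep(0, 2000), genes)
        fc[sample(2000, 100)] <- 3
        en <- sbgEnrichment(classifySexBias(fc), chrom, genes)
        en$ratio[en$class == "MBG"]
    })
    expect_gt(mean(ratios), 0.8)
    expect_lt(mean(ratios), 1.2)
})

test_that("strong FBG depletion on Z yields a small two-sided FET p", {
    genes <- sprintf("g%04d", 1:2000)
    chrom <- setNames(c(rep("Z", 400), rep("chr1", 1600)), genes)
    fc <- setNames(rep(0, 2000), genes)
    fc[500:799] <- -3                   # 300 FBG, all autosomal
    en <- sbgEnrichment(classifySexBias(fc), chrom, genes)
    fbg <- en[en$class == "FBG", ]
    expect_identical(fbg$observed, 0L)
    expect_equal(fbg$ratio, 0)
    expect_lt(fbg$p_fet, 1e-6)
})
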