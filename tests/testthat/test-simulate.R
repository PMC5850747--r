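test_that("catalog honours sizes, labels and determinism", {
    cfg <- simConfig(n_autosomal = 100, n_z = 10, seed = 4)
    cat1 <- simulateCatalog(cfg)
    expect_identical(nrow(cat1), 110L)
    expect_identical(sum(cat1$chrom == "Z"), 10L)
    expect_identical(cat1, simulateCatalog(cfg))
    # lengths log-normal around 1.5 kb
    expect_gt(median(cat1$length), 1000)
    expect_lt(median(cat1$length), 2200)

    cfg0 <- simConfig(n_autosomal = 50, n_z = 0, seed = 4)
    cat0 <- simulateCatalog(cfg0)
    expect_identical(sum(cat0$chrom == "Z"), 0L)
    de0 <- simulateCounts(cat0, cfg0)
    de0 <- quantileNormalize(computeRPKM(de0))
    expect_error(dosagePanel(SummarizedExperiment::assay(de0, "nrpkm"),
                             geneChrom(de0), libSex(de0)),
                 "no Z-linked genes")
})

test_that("planted sex-bias fractions and folds appear in the catalog", {
    cfg <- simConfig(n_autosomal = 1000, n_z = 200, sbg_fraction_z = 0.2,
                     sbg_fraction_a = 0.1, sbg_fold = 4, seed = 8)
    ct <- simulateCatalog(cfg)
    z <- ct[ct$chrom == "Z", ]; a <- ct[ct$chrom != "Z", ]
    expect_identical(sum(z$bias == "MBG"), 40L)
    expect_identical(sum(z$bias == "FBG"), 0L)
    expect_identical(sum(a$bias != "UBG"), 100L)
    expect_identical(sum(a$bias == "MBG"), 50L)
    expect_true(all(ct$fold[ct$bias != "UBG"] == 4))
})

test_that("count simulation realises the planted regime factors", {
    # uncompensated: female Z halved -> raw count M:F on Z near 2
    sim <- simulateExperiment(simConfig(regime = "uncompensated",
                                        seed = 21))
    cts <- SummarizedExperiment::assay(sim$de, "counts")
    sex <- libSex(sim$de)
    onZ <- geneChrom(sim$de) == "Z"
    mfz <- median(rowMeans(cts[onZ, sex == "male"]) /
                  pmax(rowMeans(cts[onZ, sex == "female"]), 0.5))
    expect_gt(mfz, 1.8); expect_lt(mfz, 2.2)

    # male-down: Z:A near 0.7 in both sexes, M:F on Z near 1
    simd <- simulateExperiment(simConfig(regime = "compensated_male_down",
                                         seed = 22))
    ded <- quantileNormalize(computeRPKM(simd$de))
    r <- panelRatios(dosagePanel(SummarizedExperiment::assay(ded, "nrpkm"),
                                 geneChrom(ded), libSex(ded)))
    expect_gt(r[["za_male"]], 0.6); expect_lt(r[["za_male"]], 0.8)
    expect_gt(r[["za_female"]], 0.6); expect_lt(r[["za_female"]], 0.8)
    expect_gt(r[["mf_z"]], 0.9); expect_lt(r[["mf_z"]], 1.1)
})

test_that("zero dispersion approaches Poisson noise", {
    cfg <- simConfig(n_autosomal = 2000, n_z = 100, dispersion = 0,
                     depth = 1e6, seed = 31)
    sim <- simulateExperiment(cfg)
    cts <- SummarizedExperiment::assay(sim$de, "counts")
    m <- rowMeans(cts[, libSex(sim$de) == "male"])
    v <- apply(cts[, libSex(sim$de) == "male"], 1, var)
    keep <- m > 50
    # Poisson: variance ~ mean; NB with alpha 0.1 would give v/m ~ 1 + 0.1 m
    expect_lt(median(v[keep] / m[keep]), 2)
})

test_that("simulated fixtures round-trip through the readers", {
    sim <- simulateExperiment(simConfig(n_autosomal = 40, n_z = 6,
                                        seed = 19))
    dir <- withr::local_tempdir()
    writeCountTable(sim$de, file.path(dir, "counts.tsv"))
    writeLibraryMeta(sim$de, file.path(dir, "meta.tsv"))
    writeChromMap(geneChrom(sim$de), file.path(dir, "chrom.tsv"))
    len <- geneLength(sim$de)
    utils::write.table(data.frame(names(len), unname(len)),
                       file.path(dir, "lengths.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    de2 <- readCountTable(file.path(dir, "counts.tsv"),
                          file.path(dir, "meta.tsv"),
                          lengths = file.path(dir, "lengths.tsv"),
                          chrom = file.path(dir, "chrom.tsv"))
    expect_identical(SummarizedExperiment::assay(de2, "counts"),
                     SummarizedExperiment::assay(sim$de, "counts"))
    expect_identical(geneChrom(de2), geneChrom(sim$de))
    expect_identical(geneLength(de2), geneLength(sim$de))
    expect_identical(libSex(de2), libSex(sim$de))
})

test_that("ortholog hit simulation plants recoverable and sabotaged pairs", {
    sim <- simulateOrthologHits(nTrue = 40, nDecoys = 15, nAdversarial = 5,
                                seed = 3)
    pairs <- reciprocalBestHits(bestHits(sim$fwd), bestHits(sim$rev))
    rec <- sim$truth[sim$truth$recoverable, ]
    expect_identical(sort(pairs$id_a), sort(rec$id_a))
    expect_identical(nrow(pairs), 35L)
    # no decoy subject ever appears in the recovered pairs
    expect_false(any(grepl("decoy|adv", pairs$id_b)))

    empty <- simulateOrthologHits(nTrue = 0, nDecoys = 0, seed = 1)
    expect_identical(nrow(reciprocalBestHits(bestHits(empty$fwd),
                                             bestHits(empty$rev))), 0L)
})

test_that("codon-pair evolution respects omega and the zero limit", {
    p0 <- simulateCodonPair(nCodons = 50, omega = 1, expectedKs = 0,
                            seed = 2)
    expect_identical(p0$a, p0$b)
    kk <- kaKsNG86(p0$a, p0$b)
    expect_equal(kk$ka, 0); expect_equal(kk$ks, 0)

    p <- simulateCodonPair(nCodons = 300, omega = 0.2, expectedKs = 0.3,
                           seed = 5)
    expect_gt(p$true_omega, 0.1); expect_lt(p$true_omega, 0.3)
    expect_identical(nchar(p$a), nchar(p$b))
    expect_identical(nchar(p$a) %% 3L, 0L)
})

test_that("generators are pure functions of config and seed", {
    cfg <- simConfig(n_autosomal = 30, n_z = 5, sbg_fraction_z = 0.2,
                     seed = 99)
    s1 <- simulateExperiment(cfg)
    s2 <- simulateExperiment(cfg)
    expect_identical(SummarizedExperiment::assay(s1$de, "counts"),
                     SummarizedExperiment::assay(s2$de, "counts"))
    h1 <- simulateOrthologHits(seed = 7); h2 <- simulateOrthologHits(seed = 7)
    expect_identical(h1$fwd, h2$fwd)
    c1 <- simulateCodonPair(seed = 12); c2 <- simulateCodonPair(seed = 12)
    expect_identical(c1$b, c2$b)
})
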