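test_that("RPKM formula identities hold", {
    m <- matrix(c(10L, 0L, 25L), 3, 1,
                dimnames = list(c("g1", "g2", "g3"), "L1"))
    lens <- c(g1 = 1000, g2 = 800, g3 = 500)
    r1 <- computeRPKM(m, lens, librarySizes = c(L1 = 1e6))
    expect_equal(unname(r1["g1", 1]), 10)
    expect_equal(unname(r1["g2", 1]), 0)
    r2 <- computeRPKM(m, lens, librarySizes = c(L1 = 2e6))
    expect_equal(unname(r2["g3", 1]), 25)
    expect_error(computeRPKM(m, c(g1 = 0, g2 = 800, g3 = 500),
                             librarySizes = c(L1 = 1e6)), "positive")
})

test_that("RPKM matches brute-force per-cell recomputation", {
    set.seed(101)
    for (i in 1:10) {
        n <- sample(5:30, 1); k <- sample(2:6, 1)
        cts <- matrix(rpois(n * k, 200), n, k,
                      dimnames = list(paste0("g", 1:n), paste0("L", 1:k)))
        lens <- setNames(sample(200:5000, n), rownames(cts))
        libs <- colSums(cts)
        expect_equal(computeRPKM(cts, lens),
                     oracle_rpkm(cts, lens, libs))
    }
})

test_that("quantile normalization follows the order-statistic definition", {
    # identical libraries are a fixed point
    m <- cbind(a = c(5, 1, 3), b = c(5, 1, 3))
    expect_equal(quantileNormalize(m), m)
    # hand-computed two-library case
    m2 <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
    expect_equal(unname(quantileNormalize(m2)),
                 cbind(c(1.5, 3, 4.5), c(1.5, 3, 4.5)))
    expect_error(quantileNormalize(m2[, 1, drop = FALSE]), "at least 2")
})

test_that("normalized libraries share one distribution and keep their ranks", {
    set.seed(7)
    m <- matrix(rlnorm(400), 100, 4)
    q <- quantileNormalize(m)
    s <- apply(q, 2, sort)
    for (j in 2:4) expect_equal(s[, j], s[, 1], tolerance = 1e-12)
    for (j in 1:4) expect_identical(rank(q[, j]), rank(m[, j]))
    # idempotent
    expect_equal(quantileNormalize(q), q, tolerance = 1e-12)
})

test_that("ties receive the mean of the order-statistic means they span", {
    m <- cbind(a = c(1, 1, 5), b = c(2, 4, 6))
    # sorted means: (1.5, 2.5, 5.5); ties in a span ranks 1-2 -> 2.0
    q <- quantileNormalize(m)
    expect_equal(unname(q[, "a"]), c(2, 2, 5.5))
    expect_equal(unname(q[, "b"]), c(1.5, 2.5, 5.5))
})

test_that("quantile normalization agrees with limma on tie-free matrices", {
    set.seed(21)
    m <- matrix(rlnorm(600, 2, 1), 150, 4)
    expect_equal(unname(quantileNormalize(m)),
                 unname(limma::normalizeQuantiles(m)),
                 tolerance = 1e-10)
})

test_that("expression filtering honours cut-off and mode", {
    expr <- rbind(g1 = c(0, 5, 3, 3), g2 = c(2, 2, 2, 2),
                  g3 = c(0, 0, 3, 3))
    colnames(expr) <- c("m1", "m2", "f1", "f2")
    sex <- c(m1 = "male", m2 = "male", f1 = "female", f2 = "female")
    expect_true("g1" %in% filterExpressed(expr, sex, 0, "both_sexes"))
    expect_false("g1" %in% filterExpressed(expr, sex, 0, "all_libraries"))
    expect_false("g3" %in% filterExpressed(expr, sex, 0, "both_sexes"))
    expect_identical(filterExpressed(expr, sex, "none"), rownames(expr))
})

test_that("filtering is monotone in the cut-off", {
    set.seed(3)
    de <- make_toy_experiment(nGenes = 60, nZ = 10,
                              counts = matrix(rpois(240, 8), 60, 4))
    de <- quantileNormalize(computeRPKM(de))
    expr <- SummarizedExperiment::assay(de, "nrpkm")
    sex <- libSex(de)
    sets <- lapply(c("0", "1", "5"), function(co)
        filterExpressed(expr, sex, co, "all_libraries"))
    expect_true(all(sets[[3]] %in% sets[[2]]))
    expect_true(all(sets[[2]] %in% sets[[1]]))
    expect_true(all(sets[[1]] %in% filterExpressed(expr, sex, "none")))
})

test_that("log2 fold-changes use the pseudocount-shrunken mean ratio", {
    expr <- rbind(g1 = c(7, 7, 1, 1), g2 = c(3, 3, 3, 3),
                  g3 = c(3, 3, 0, 0))
    colnames(expr) <- c("m1", "m2", "f1", "f2")
    sex <- c(m1 = "male", m2 = "male", f1 = "female", f2 = "female")
    fc <- log2FoldChange(expr, sex, pseudocount = 1)
    expect_equal(unname(fc["g1"]), 2)
    expect_equal(unname(fc["g2"]), 0)
    expect_equal(unname(fc["g3"]), 2)   # zero female mean guarded
})

test_that("replicate-aware test behaves like per-gene Welch on logs", {
    expr <- rbind(g1 = c(10, 12, 50, 60), g2 = c(5, 5, 5, 5))
    colnames(expr) <- c("m1", "m2", "f1", "f2")
    sex <- c(m1 = "male", m2 = "male", f1 = "female", f2 = "female")
    p <- replicateTest(expr, sex)
    ref <- t.test(log2(c(10, 12) + 1), log2(c(50, 60) + 1))$p.value
    expect_equal(unname(p["g1"]), ref)
    expect_equal(unname(p["g2"]), 1)    # identical groups: no signal
    expect_error(replicateTest(expr[, c(1, 3)],
                               sex[c(1, 3)]), "replicates")
})

test_that("an 8-fold planted shift is detected at n = 3 vs 3", {
    set.seed(909)
    hits <- 0
    for (i in 1:200) {
        mu <- 100
        x <- rnbinom(3, mu = mu * 8, size = 10)  # dispersion 0.1
        y <- rnbinom(3, mu = mu, size = 10)
        expr <- matrix(c(x, y), 1,
                       dimnames = list("g", paste0("L", 1:6)))
        sex <- setNames(rep(c("male", "female"), each = 3), colnames(expr))
        if (replicateTest(expr, sex)["g"] < 0.05) hits <- hits + 1
    }
    expect_gte(hits / 200, 0.95)
})

test_that("BH adjustment reproduces the step-up rule", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
    set.seed(77)
    for (i in 1:20) {
        p <- runif(sample(1:50, 1))
        expect_equal(bhAdjust(p), oracle_bh(p))
    }
})

test_that("sex-bias labels follow threshold and significance gates", {
    fc <- c(gA = 2.0, gB = 0.58, gC = -2.5, gD = 0.9)
    sbt <- classifySexBias(fc, fcThreshold = 2)
    expect_identical(unname(biasLabels(sbt)[c("gA", "gB", "gC", "gD")]),
                     c("MBG", "UBG", "FBG", "UBG"))
    # significance gate turns a large fold-change into UBG
    sbt2 <- classifySexBias(fc, adjP = c(gA = 0.2, gB = 0.01, gC = 0.01,
                                         gD = 0.01), fcThreshold = 2)
    expect_identical(unname(biasLabels(sbt2)[["gA"]]), "UBG")
    expect_identical(unname(biasLabels(sbt2)[["gC"]]), "FBG")
    expect_error(classifySexBias(fc, adjP = c(gA = 0.2), fcThreshold = 2),
                 "per gene")
    expect_error(classifySexBias(fc, fcThreshold = 3), "2 or 4")
})

test_that("threshold-4 labels nest within threshold-2 labels", {
    set.seed(5)
    fc <- setNames(rnorm(500, 0, 1.5), paste0("g", 1:500))
    l2 <- biasLabels(classifySexBias(fc, fcThreshold = 2))
    l4 <- biasLabels(classifySexBias(fc, fcThreshold = 4))
    expect_true(all(names(l4)[l4 == "MBG"] %in% names(l2)[l2 == "MBG"]))
    expect_true(all(names(l4)[l4 == "FBG"] %in% names(l2)[l2 == "FBG"]))
})
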