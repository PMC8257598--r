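makeSig <- function(up, down) {
    new("SignaturePair", upInHigh = up, upInLow = down,
        stats = data.frame(gene = c(up, down), t = 0, fc = 0, pPerm = 1),
        pMax = 1, fcMin = 0)
}

test_that("templates are signed indicators with template B = -A", {
    m <- randMatrix(20, 6, seed = 30)
    sig <- makeSig(rownames(m)[1:4], rownames(m)[5:10])
    tmpl <- buildTemplates(sig, m)
    expect_length(tmpl$genes, 10L)
    expect_identical(tmpl$templateB, -tmpl$templateA)
    expect_true(all(tmpl$templateA[rownames(m)[1:4]] == 1))
    expect_true(all(tmpl$templateA[rownames(m)[5:10]] == -1))

    # 40% overlap at the default 50% threshold is an error
    sig2 <- makeSig(c(rownames(m)[1:2], "X1", "X2", "X3"),
                    c(rownames(m)[3:4], "X4", "X5", "X6"))
    expect_error(buildTemplates(sig2, m), "40% of signature genes present")
    sigLost <- makeSig(c("X1", "X2", "X3"), c(rownames(m)[1:2]))
    expect_error(buildTemplates(sigLost, m), "present")
})

test_that("a sample matching a template is called with distance ~ 0", {
    set.seed(31)
    nG <- 40
    genes <- sprintf("G%03d", 1:nG)
    a <- c(rep(1, 20), rep(-1, 20))
    # build samples as noisy copies of +a / -a so z-scores align with a
    m <- cbind(vapply(1:10, function(i) a * 2 + rnorm(nG, 0, 0.01),
                      numeric(nG)),
               vapply(1:10, function(i) -a * 2 + rnorm(nG, 0, 0.01),
                      numeric(nG)))
    dimnames(m) <- list(genes, sprintf("s%02d", 1:20))
    sig <- makeSig(genes[1:20], genes[21:40])
    tmpl <- buildTemplates(sig, m)
    calls <- ntpCalls(ntpClassify(m, tmpl, nNull = 200, seed = 1))
    expect_true(all(calls$label[1:10] == "A"))
    expect_true(all(calls$label[11:20] == "B"))
    expect_lt(max(calls$distance), 0.05)
    expect_true(all(calls$p >= 1 / 201))
})

test_that("negating the expression matrix swaps calls and keeps distances", {
    cfg <- smallConfig(seed = 37L)
    co <- simulateCohort(cfg)
    st <- makeStrat(co$truth$subtypeOf)
    stats <- permutationTStats(co$expr, st, nPerm = 100, seed = 2)
    sig <- buildSignature(stats, 0.01, 0.5)
    m <- SummarizedExperiment::assay(co$expr)
    tmpl <- buildTemplates(sig, m)
    c1 <- ntpCalls(ntpClassify(m, tmpl, nNull = 200, seed = 3))
    c2 <- ntpCalls(ntpClassify(-m, tmpl, nNull = 200, seed = 3))
    expect_equal(c1$distance, c2$distance, tolerance = 1e-12)
    expect_identical(c1$p, c2$p)
    swap <- c(A = "B", B = "A", ND = "ND")
    expect_identical(unname(swap[as.character(c1$label)]),
                     as.character(c2$label))
})

test_that("FDR labeling is monotone in the threshold", {
    cfg <- smallConfig(seed = 41L, delta = 0.6)
    co <- simulateCohort(cfg)
    st <- makeStrat(co$truth$subtypeOf)
    stats <- permutationTStats(co$expr, st, nPerm = 100, seed = 5)
    sig <- buildSignature(stats, 0.05, 0.3)
    tmpl <- buildTemplates(sig, co$expr)
    loose <- ntpCalls(ntpClassify(co$expr, tmpl, nNull = 200,
                                  fdrThreshold = 0.2, seed = 7))
    tight <- ntpCalls(ntpClassify(co$expr, tmpl, nNull = 200,
                                  fdrThreshold = 0.05, seed = 7))
    # lowering the threshold never converts ND into a determinate call
    ndLoose <- loose$sample[loose$label == "ND"]
    ndTight <- tight$sample[tight$label == "ND"]
    expect_true(all(ndLoose %in% ndTight))
    expect_true(all(loose$distance >= 0 & loose$distance <= 2))
})

test_that("NTP recovers planted classes and stays calibrated on noise", {
    # two-class recovery at delta = 1.5, sigma = 0.5, 100 + 100 samples
    cfg <- simConfig(nSamples = 200L, nGenes = 1000L, fracDeg = 0.1,
                     delta = 1.5, sigma = 0.5, seed = 55L)
    co <- simulateCohort(cfg)
    st <- makeStrat(co$truth$subtypeOf)
    stats <- permutationTStats(co$expr, st, nPerm = 200, seed = 8)
    sig <- buildSignature(stats, 1e-3, 0.5)
    tmpl <- buildTemplates(sig, co$expr)
    res <- ntpCalls(ntpClassify(co$expr, tmpl, nNull = 1000, seed = 9))
    truthLab <- ifelse(co$truth$subtypeOf[res$sample] == "HIGH", "A", "B")
    expect_gte(mean(res$label == truthLab), 0.95)
    expect_lte(mean(res$label == "ND"), 0.05)

    # label-free noise: non-ND call rate bounded near the nominal FDR
    mNull <- randMatrix(length(tmpl$genes), 150, seed = 61)
    rownames(mNull) <- tmpl$genes
    resNull <- ntpCalls(ntpClassify(mNull, tmpl, nNull = 1000, seed = 10))
    nonNd <- mean(resNull$label != "ND")
    # 0.05 plus a generous binomial allowance at n = 150
    expect_lte(nonNd, 0.05 + 2 * sqrt(0.05 * 0.95 / 150))
})
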