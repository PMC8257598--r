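test_that("running-sum score equals the step-by-step oracle on random instances", {
    set.seed(20)
    for (i in 1:60) {
        N <- sample(5:50, 1)
        genes <- sprintf("G%03d", seq_len(N))
        metric <- sort(rnorm(N), decreasing = TRUE)
        ranked <- setNames(metric, sample(genes))
        nSet <- sample(seq_len(N - 1), 1)
        gs <- sample(names(ranked), nSet)
        for (w in c(0, 1)) {
            mine <- enrichmentScore(ranked, gs, weightExp = w)
            ref <- esOracle(names(ranked), unname(ranked), gs, w)
            expect_equal(mine$es, ref$es, tolerance = 1e-12)
            expect_equal(mine$runningSum, ref$runningSum, tolerance = 1e-12)
        }
    }
})

test_that("running-sum boundary cases behave as forced extremes", {
    genes <- sprintf("G%02d", 1:10)
    ranked <- setNames(seq(10, 1), genes)
    # single member at rank 1: the running sum peaks at +1 immediately
    expect_equal(enrichmentScore(ranked, genes[1], weightExp = 0)$es, 1)
    # single member at the last rank, unweighted: minimum equals the oracle
    mine <- enrichmentScore(ranked, genes[10], weightExp = 0)
    ref <- esOracle(genes, unname(ranked), genes[10], 0)
    expect_equal(mine$es, ref$es, tolerance = 1e-12)
    expect_equal(mine$es, -1)   # nine misses of -1/9 before the only hit

    expect_error(enrichmentScore(ranked, "ABSENT"), "empty overlap")
    expect_error(enrichmentScore(ranked, genes), "universe")
})

test_that("group ranking matches brute force and is antisymmetric", {
    m <- randMatrix(100, 20, seed = 14)
    lab <- setNames(rep(c("HIGH", "LOW"), each = 10), colnames(m))
    st <- makeStrat(lab)
    r <- rankByGroupMetric(m, st, "snr")
    # brute-force recomputation with the documented floor
    mH <- rowMeans(m[, 1:10]); mL <- rowMeans(m[, 11:20])
    sH <- pmax(apply(m[, 1:10], 1, sd), pmax(0.2 * abs(mH), 0.2))
    sL <- pmax(apply(m[, 11:20], 1, sd), pmax(0.2 * abs(mL), 0.2))
    snr <- (mH - mL) / (sH + sL)
    expect_identical(names(r), names(snr[order(-snr, names(snr))]))
    expect_equal(unname(r), unname(sort(snr, decreasing = TRUE)),
                 tolerance = 1e-12)

    flipped <- makeStrat(setNames(ifelse(lab == "HIGH", "LOW", "HIGH"),
                                  names(lab)))
    r2 <- rankByGroupMetric(m, flipped, "snr")
    expect_equal(unname(r2), -rev(unname(r)), tolerance = 1e-12)

    # a gene up only in HIGH ranks first
    m["G0001", 1:10] <- m["G0001", 1:10] + 50
    expect_equal(names(rankByGroupMetric(m, st, "snr"))[1], "G0001")
})

test_that("per-sample scores depend only on within-sample ranking", {
    m <- randMatrix(60, 6, seed = 15)
    gs <- rownames(m)[c(3, 10, 25, 40)]
    es <- sampleEnrichment(m, gs, weightExp = 0.25)
    # adding a constant to one sample leaves its score unchanged
    m2 <- m; m2[, 2] <- m2[, 2] + 100
    expect_equal(sampleEnrichment(m2, gs, weightExp = 0.25)[2], es[2])
    # permuting gene rows leaves every score unchanged
    m3 <- m[sample(nrow(m)), ]
    expect_equal(sampleEnrichment(m3, gs, weightExp = 0.25), es)
    # monotone within-sample transform leaves scores unchanged at weight 0
    es0 <- sampleEnrichment(m, gs, weightExp = 0)
    expect_equal(sampleEnrichment(2^m, gs, weightExp = 0), es0)

    # sample with the set genes in the top ranks scores the maximal value
    m4 <- m
    m4[gs, 1] <- max(m4[, 1]) + seq_along(gs)
    esTop <- sampleEnrichment(m4, gs, weightExp = 0)[1]
    genes <- rownames(m4)
    ord <- order(-m4[, 1], genes)
    ref <- esOracle(genes[ord], as.numeric(nrow(m4):1), gs, 0)
    expect_equal(unname(esTop), ref$es, tolerance = 1e-12)
    expect_equal(unname(esTop), 1)      # all hits before any miss
})

test_that("oncoactivity identities hold exactly", {
    m <- randMatrix(80, 10, seed = 16)
    gsA <- rownames(m)[1:10]
    gsB <- rownames(m)[31:45]
    same <- oncoactivityScores(m, gsA, gsA)
    expect_equal(unname(oncoactivity(same)), rep(0, 10))
    ab <- oncoactivityScores(m, gsA, gsB)
    ba <- oncoactivityScores(m, gsB, gsA)
    expect_identical(oncoactivity(ab), -oncoactivity(ba))
    expect_true(all(abs(ab@esOnco) <= 1 & abs(ab@esTsg) <= 1))
})

test_that("group comparison of scores uses exact small-sample enumeration", {
    lab <- setNames(c(rep("HIGH", 3), rep("LOW", 3)), paste0("s", 1:6))
    st <- makeStrat(lab)
    sc <- setNames(c(1, 2, 3, 4, 5, 6), names(lab))
    res <- compareGroupScores(sc, st)
    expect_equal(res$p, 0.1)            # 2/20 splits as extreme, two-sided
    expect_warning(resT <- compareGroupScores(setNames(rep(1, 6),
                                                       names(lab)), st),
                   "tied")
    expect_equal(resT$p, 1)
})

test_that("two-group GSEA finds planted enrichment and stays calibrated", {
    cfg <- smallConfig(seed = 19L)
    co <- simulateCohort(cfg)
    st <- makeStrat(co$truth$subtypeOf)
    gs <- co$truth$degUpInHigh[1:10]
    res <- gseaTwoGroup(co$expr, st, gs, nPerm = 200, seed = 6)
    expect_gt(res@es, 0)
    expect_lte(res@pNominal, 0.05)
    expect_equal(sign(res@nes), sign(res@es))

    # null calibration: random sets on a null cohort give roughly uniform p
    cfg0 <- smallConfig(nSamples = 30L, nGenes = 80L, delta = 0,
                        markerDelta = 0, seed = 23L)
    co0 <- simulateCohort(cfg0)
    st0 <- makeStrat(co0$truth$subtypeOf)
    set.seed(31)
    ps <- replicate(60, {
        gs0 <- sample(rownames(co0$expr), 8)
        gseaTwoGroup(co0$expr, st0, gs0, nPerm = 60,
                     seed = sample.int(1e6, 1))@pNominal
    })
    expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)

    mConst <- matrix(1, 4, 6, dimnames = list(paste0("G", 1:4),
                                              paste0("s", 1:6)))
    stC <- makeStrat(setNames(rep(c("HIGH", "LOW"), each = 3),
                              colnames(mConst)))
    expect_error(gseaTwoGroup(mConst, stC, "G1", nPerm = 10), "degenerate")
})
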