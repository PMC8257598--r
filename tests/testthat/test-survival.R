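test_that("Kaplan-Meier estimate equals the hand product-limit", {
    # no events: survival stays at 1
    km <- kmCurve(c(5, 10, 15), c(0, 0, 0))
    expect_true(all(km$surv == 1))

    # three subjects, all events at 1, 2, 3 -> S = 2/3, 1/3, 0
    km <- kmCurve(c(1, 2, 3), c(1, 1, 1))
    expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

    # random data with censoring equals the closed-form oracle
    set.seed(44)
    for (i in 1:5) {
        tt <- round(rexp(30, 0.1), 1) + 0.1
        ev <- rbinom(30, 1, 0.7)
        km <- kmCurve(tt, ev)
        ref <- kmOracle(tt, ev)
        expect_equal(km$surv[km$nEvent > 0], ref, tolerance = 1e-12)
    }
})

test_that("log-rank test matches the manual O-E computation", {
    # identical groups: no signal
    tt <- c(1, 2, 3, 4, 1, 2, 3, 4)
    ev <- rep(1, 8)
    g <- rep(c("a", "b"), each = 4)
    res <- logrankTest(tt, ev, g)
    expect_equal(res$chi2, 0, tolerance = 1e-12)
    expect_equal(res$p, 1)

    # hand-computable example
    tt <- c(1, 3, 2, 4)
    ev <- c(1, 1, 1, 0)
    g <- c("a", "a", "b", "b")
    res <- logrankTest(tt, ev, g)
    expect_equal(res$chi2, logrankOracle(tt, ev, g), tolerance = 1e-9)

    expect_warning(res0 <- logrankTest(c(1, 2), c(0, 0), c("a", "b")),
                   "no events")
    expect_equal(res0$p, 1)
})

test_that("log-rank has power at hr = 3 with n = 200 per arm", {
    set.seed(50)
    hits <- replicate(20, {
        tt <- c(rexp(200, 0.03), rexp(200, 0.09))
        g <- rep(c("h", "l"), each = 200)
        logrankTest(tt, rep(1, 400), g)$p < 0.001
    })
    expect_gte(mean(hits), 0.95)
})

test_that("Cox regression recovers truth and matches the grid oracle", {
    # identical survival in both groups (duplicated records): HR = 1
    tt <- rep(c(1, 2, 3, 4, 5), 2)
    x <- rep(c(0, 1), each = 5)
    fit <- coxFit(tt, rep(1, 10), data.frame(x = x))
    expect_lt(abs(fit["x", "hr"] - 1), 1e-6)

    # tiny tie-free dataset against 1-d partial-likelihood maximization
    set.seed(52)
    tt <- c(2.3, 4.1, 1.7, 5.2, 3.3, 6.4)
    ev <- c(1, 1, 1, 0, 1, 1)
    x <- c(1, 0, 1, 0, 0, 1)
    fit <- coxFit(tt, ev, data.frame(x = x))
    expect_equal(fit["x", "coef"], coxOracle(tt, ev, x), tolerance = 1e-3)

    expect_error(coxFit(tt, ev, data.frame(k = rep(1, 6))), "constant")
    expect_error(coxFit(tt, rep(0, 6), data.frame(x = x)), "event")
})

test_that("Cox score test at beta = 0 equals the log-rank chi-square", {
    set.seed(53)
    tt <- rexp(60, 0.05) + runif(60, 0, 1e-4)   # tie-free
    ev <- rbinom(60, 1, 0.8)
    x <- rep(c(0, 1), 30)
    fit <- coxFit(tt, ev, data.frame(x = x))
    lr <- logrankTest(tt, ev, x)
    expect_equal(attr(fit, "scoreTest"), lr$chi2, tolerance = 1e-6)
})

test_that("Fisher's exact test handles conventions, identities and oracles", {
    # no association possible
    expect_equal(fisherExact(matrix(c(0, 10, 0, 10), 2))$p, 1)

    # printed 2x2 from the motivating cohort: both conventions near 0.03
    tab <- matrix(c(12, 20, 182, 125), 2, 2, byrow = TRUE)
    expect_equal(fisherExact(tab)$p, fisher.test(tab)$p.value,
                 tolerance = 1e-12)
    expect_lt(abs(fisherExact(tab, convention = "doubled")$p - 0.029),
              0.005)
    expect_equal(fisherExact(tab)$oddsRatio, 12 * 125 / (20 * 182),
                 tolerance = 1e-12)

    # enumeration oracle on a strongly associated table
    expect_equal(fisherExact(matrix(c(1, 9, 9, 1), 2, byrow = TRUE))$p,
                 fisherEnumOracle(1, 9, 9, 1), tolerance = 1e-9)

    # invariance under transposition and joint row/column swap
    t1 <- matrix(c(3, 7, 9, 2), 2)
    expect_equal(fisherExact(t1)$p, fisherExact(t(t1))$p, tolerance = 1e-12)
    expect_equal(fisherExact(t1)$p,
                 fisherExact(t1[2:1, 2:1])$p, tolerance = 1e-12)
})

test_that("chi-square test matches the 2x2 closed form and is calibrated", {
    tab <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
    res <- chiSquareTest(tab, yates = FALSE)
    a <- 10; b <- 20; c <- 20; d <- 10; N <- 60
    closed <- N * (a * d - b * c)^2 /
        ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(res$chi2, closed, tolerance = 1e-9)

    # independence: table proportional to the margin outer product
    tabInd <- outer(c(2, 3), c(5, 10))
    resInd <- chiSquareTest(tabInd)
    expect_equal(resInd$chi2, 0, tolerance = 1e-12)
    expect_equal(resInd$p, 1)
    expect_error(chiSquareTest(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "zero margin")

    # null calibration
    set.seed(54)
    ps <- replicate(300, {
        x <- rbinom(80, 1, 0.5); y <- rbinom(80, 1, 0.5)
        tab <- table(factor(x, 0:1), factor(y, 0:1)) + 0
        chiSquareTest(tab)$p
    })
    expect_gt(mean(ps < 0.05), 0.01)
    expect_lt(mean(ps < 0.05), 0.10)
})

test_that("t test variants behave and p is monotone in the shift", {
    x <- c(1, 2, 3)
    expect_equal(groupTTest(x, x)$p, 1, tolerance = 1e-12)
    ps <- vapply(c(0, 1, 5, 50),
                 function(d) groupTTest(x, x + d)$p, numeric(1))
    expect_true(all(diff(ps) <= 0))
    expect_error(groupTTest(c(1, 1), c(2, 2)), "zero variance")
    # Welch equals Student under equal group sizes and variances
    set.seed(55)
    a <- rnorm(10); b <- rnorm(10)
    expect_equal(groupTTest(a, b, welch = TRUE)$t,
                 groupTTest(a, b, welch = FALSE)$t, tolerance = 1e-9)
})

test_that("contingency rates reproduce Table-1-style percentages", {
    # marker-positive vs -negative cohort split
    expect_equal(contingencyRates(matrix(c(32, 307), 1, 2))[1, 1],
                 9.4, tolerance = 0.05)
    # outcome rates within strata
    tab <- matrix(c(12, 20, 182, 125), 2, byrow = TRUE)
    r <- contingencyRates(tab)
    expect_equal(round(r[1, 1], 1), 37.5)
    expect_equal(round(r[2, 1]), 59)
})
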