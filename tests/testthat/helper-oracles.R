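# Independent, deliberately naive reference implementations used as oracles.
# These share no code with the package internals.

# Step-by-step running-sum enrichment score: walk the ranked list once,
# incrementing on hits by |metric|^w / (total hit weight) and decrementing on
# misses by 1 / (N - nHits).
esOracle <- function(rankedNames, metricValues, geneSet, weightExp) {
    N <- length(rankedNames)
    isHit <- rankedNames %in% geneSet
    nh <- sum(isHit)
    tot <- sum(abs(metricValues[isHit])^weightExp)
    run <- numeric(N)
    cur <- 0
    for (i in seq_len(N)) {
        if (isHit[i]) {
            cur <- cur + abs(metricValues[i])^weightExp / tot
        } else {
            cur <- cur - 1 / (N - nh)
        }
        run[i] <- cur
    }
    hi <- max(run); lo <- min(run)
    es <- if (hi - (-lo) >= -1e-9) hi else lo   # magnitude ties -> positive
    list(es = es, runningSum = run)
}

# Exact permutation p for a single gene: enumerate every way to choose the
# HIGH group, compute the Welch t via t.test, and count |t| >= |t_obs|.
exactPermPOracle <- function(values, isHigh) {
    n <- length(values)
    nH <- sum(isHigh)
    tOf <- function(idxH) {
        unname(t.test(values[idxH], values[-idxH])$statistic)
    }
    tObs <- tOf(which(isHigh))
    combs <- combn(n, nH)
    tAll <- apply(combs, 2L, tOf)
    mean(abs(tAll) >= abs(tObs) - 1e-12)
}

# Hand product-limit estimator.
kmOracle <- function(time, event) {
    ut <- sort(unique(time[event == 1]))
    s <- 1
    vapply(ut, function(tt) {
        n <- sum(time >= tt)
        d <- sum(time == tt & event == 1)
        s <<- s * (1 - d / n)
        s
    }, numeric(1))
}

# Manual two-group log-rank chi-square via observed-minus-expected sums.
logrankOracle <- function(time, event, group) {
    g <- as.factor(group)
    ut <- sort(unique(time[event == 1]))
    O <- 0; E <- 0; V <- 0
    for (tt in ut) {
        atRisk <- time >= tt
        n <- sum(atRisk)
        n1 <- sum(atRisk & g == levels(g)[1])
        d <- sum(time == tt & event == 1)
        d1 <- sum(time == tt & event == 1 & g == levels(g)[1])
        O <- O + d1
        E <- E + d * n1 / n
        if (n > 1)
            V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
}

# Grid/1-d optimization of the Cox partial log-likelihood for one covariate,
# Breslow form (fixtures are tie-free, so Breslow = Efron).
coxOracle <- function(time, event, x) {
    pll <- function(beta) {
        eta <- beta * x
        ll <- 0
        for (i in which(event == 1)) {
            risk <- time >= time[i]
            ll <- ll + eta[i] - log(sum(exp(eta[risk])))
        }
        ll
    }
    stats::optimize(pll, c(-10, 10), maximum = TRUE)$maximum
}

# Minimum-likelihood two-sided Fisher p by explicit enumeration.
fisherEnumOracle <- function(a, b, c, d) {
    m <- a + c; nn <- b + d; k <- a + b
    as <- max(0, k - nn):min(k, m)
    probs <- dhyper(as, m, nn, k)
    pObs <- dhyper(a, m, nn, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Small default cohort for quick tests.
smallConfig <- function(...) {
    args <- list(nSamples = 60L, nGenes = 300L, fracDeg = 0.1, delta = 1.2,
                 sigma = 0.5, markerDelta = 2, nOnco = 20L, nTsg = 30L,
                 seed = 42L)
    do.call(simConfig, utils::modifyList(args, list(...)))
}

# StratificationResult from an explicit label vector (test scaffolding).
makeStrat <- function(labels, marker = "ESR1", cutoff = 0) {
    f <- factor(labels, levels = c("HIGH", "LOW"))
    names(f) <- names(labels)
    new("StratificationResult", labels = f, cutoff = cutoff, marker = marker)
}

randMatrix <- function(nGenes, nSamples, seed) {
    set.seed(seed)
    m <- matrix(rnorm(nGenes * nSamples), nGenes, nSamples,
                dimnames = list(sprintf("G%04d", seq_len(nGenes)),
                                sprintf("S%03d", seq_len(nSamples))))
    m
}
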