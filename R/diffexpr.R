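## Vectorized Welch statistics for a genes x samples matrix, given column
## index sets for the two groups. Genes with zero variance in both groups
## get t = 0.
.welchRows <- function(m, m2, idxH, idxL) {
    nH <- length(idxH); nL <- length(idxL)
    sH <- rowSums(m[, idxH, drop = FALSE])
    sL <- rowSums(m[, idxL, drop = FALSE])
    qH <- rowSums(m2[, idxH, drop = FALSE])
    qL <- rowSums(m2[, idxL, drop = FALSE])
    mH <- sH / nH; mL <- sL / nL
    vH <- pmax((qH - nH * mH^2) / (nH - 1), 0)
    vL <- pmax((qL - nL * mL^2) / (nL - 1), 0)
    se <- sqrt(vH / nH + vL / nL)
    t <- (mH - mL) / se
    t[se == 0] <- 0
    list(t = t, fc = mH - mL)
}

#' Permutation t-test between strata
#'
#' Per gene: the Welch t statistic on log2 values and the log2 fold change
#' (mean HIGH minus mean LOW). The null is built by relabeling samples with
#' the group sizes fixed. With \code{pooledNull = TRUE} (default) the null
#' statistics are pooled across genes, giving a p-value resolution of
#' \code{1 / (nPerm * nGenes + 1)} -- fine enough for thresholds like
#' p < 1e-6 with moderate \code{nPerm}. With \code{exhaustive = TRUE} all
#' distinct relabelings are enumerated (small cohorts only) and the exact
#' permutation p (which includes the observed labeling) is returned.
#'
#' @param expr expression matrix or \code{SummarizedExperiment}.
#' @param strat a \linkS4class{StratificationResult}.
#' @param nPerm number of random relabelings (>= 10).
#' @param pooledNull pool null statistics across genes?
#' @param exhaustive enumerate all relabelings instead of sampling (requires
#'   choose(n, nHigh) <= 1e5; implies gene-wise null).
#' @param seed integer seed for the relabelings.
#' @return data.frame with columns \code{gene}, \code{t}, \code{fc},
#'   \code{pPerm}.
#' @export
permutationTStats <- function(expr, strat, nPerm = 1000L, pooledNull = TRUE,
                              exhaustive = FALSE, seed = 1L) {
    m <- .exprMat(expr)
    lab <- strataLabels(strat)[colnames(m)]
    idxH <- which(lab == "HIGH"); idxL <- which(lab == "LOW")
    if (length(idxH) < 2L || length(idxL) < 2L)
        stop("both strata must have at least 2 samples")
    if (!exhaustive && nPerm < 10L) stop("nPerm must be >= 10")
    n <- ncol(m); nH <- length(idxH)
    m2 <- m * m
    obs <- .welchRows(m, m2, idxH, idxL)
    if (any(obs$t == 0 & obs$fc == 0))
        warning("gene(s) with zero within-group variance in both groups: ",
                "t set to 0")
    absObs <- abs(obs$t)

    if (exhaustive) {
        if (choose(n, nH) > 1e5)
            stop("too many relabelings for exhaustive enumeration")
        combs <- combn(n, nH)
        tNull <- vapply(seq_len(ncol(combs)), function(j) {
            iH <- combs[, j]
            .welchRows(m, m2, iH, setdiff(seq_len(n), iH))$t
        }, numeric(nrow(m)))
        tNull <- matrix(tNull, nrow = nrow(m))
        ## exact p: the observed labeling is one of the enumerated ones
        p <- rowMeans(abs(tNull) >= absObs - 1e-12 * pmax(absObs, 1))
    } else {
        tNull <- withSeed(seed, {
            vapply(seq_len(nPerm), function(j) {
                iH <- sample.int(n, nH)
                .welchRows(m, m2, iH, setdiff(seq_len(n), iH))$t
            }, numeric(nrow(m)))
        })
        tNull <- matrix(tNull, nrow = nrow(m))
        if (pooledNull) {
            nullSorted <- sort(abs(as.numeric(tNull)))
            nNull <- length(nullSorted)
            ## #{null >= t} via binary search; tiny relative tolerance so
            ## exact ties (t = 0 genes) are counted as >=
            nGe <- nNull - findInterval(absObs - 1e-10 * pmax(absObs, 1),
                                        nullSorted)
            p <- (1 + nGe) / (1 + nNull)
        } else {
            nGe <- rowSums(abs(tNull) >= absObs - 1e-12 * pmax(absObs, 1))
            p <- (1 + nGe) / (1 + nPerm)
        }
    }
    data.frame(gene = rownames(m), t = obs$t, fc = obs$fc, pPerm = p,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a directional signature pair from per-gene statistics
#'
#' Genes with \code{pPerm < pMax} and log2 fold change above \code{fcMin}
#' (in absolute value) enter the signature on the side of their direction:
#' \code{fc > fcMin} up in HIGH, \code{fc < -fcMin} up in LOW.
#'
#' @param stats data.frame from [permutationTStats()].
#' @param pMax p-value threshold, in (0, 1].
#' @param fcMin non-negative log2 fold-change threshold.
#' @return a \linkS4class{SignaturePair}.
#' @export
buildSignature <- function(stats, pMax, fcMin) {
    if (!is.numeric(pMax) || pMax <= 0 || pMax > 1)
        stop("pMax must lie in (0, 1]")
    if (!is.numeric(fcMin) || fcMin < 0) stop("fcMin must be >= 0")
    stopifnot(nrow(stats) > 0L)
    sig <- stats$pPerm < pMax
    new("SignaturePair",
        upInHigh = stats$gene[sig & stats$fc > fcMin],
        upInLow = stats$gene[sig & stats$fc < -fcMin],
        stats = stats, pMax = pMax, fcMin = fcMin)
}

#' Write a signature pair as a two-line GMT file
#'
#' @param sig a \linkS4class{SignaturePair}.
#' @param path output path.
#' @param prefix set-name prefix (sets are named \code{<prefix>_HIGH} and
#'   \code{<prefix>_LOW}).
#' @export
writeSignatureGmt <- function(sig, path, prefix = "SIG") {
    writeGmt(setNames(list(upInHigh(sig), upInLow(sig)),
                      paste0(prefix, c("_HIGH", "_LOW"))),
             path,
             descriptions = c("up in HIGH stratum", "up in LOW stratum"))
}
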