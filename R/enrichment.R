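#' Rank genes by a two-group association metric
#'
#' Ranks all genes by a HIGH-vs-LOW metric in descending order. The
#' signal-to-noise ratio follows the classic GSEA convention:
#' (muH - muL) / (sH + sL) with each group SD floored at
#' max(0.2 * |group mean|, 0.2). Ties are broken by gene symbol order so the
#' ranking is deterministic.
#'
#' @param expr expression matrix or \code{SummarizedExperiment}.
#' @param strat a \linkS4class{StratificationResult}.
#' @param metric \code{"snr"} (default) or \code{"tstat"} (Welch t).
#' @return a named numeric vector (names = genes) sorted descending: the
#'   ranked list.
#' @export
rankByGroupMetric <- function(expr, strat, metric = c("snr", "tstat")) {
    metric <- match.arg(metric)
    m <- .exprMat(expr)
    lab <- strataLabels(strat)[colnames(m)]
    idxH <- which(lab == "HIGH"); idxL <- which(lab == "LOW")
    if (length(idxH) < 2L || length(idxL) < 2L)
        stop("degenerate strata: both groups need >= 2 samples")
    if (metric == "snr") {
        mH <- rowMeans(m[, idxH, drop = FALSE])
        mL <- rowMeans(m[, idxL, drop = FALSE])
        sH <- apply(m[, idxH, drop = FALSE], 1L, sd)
        sL <- apply(m[, idxL, drop = FALSE], 1L, sd)
        sH <- pmax(sH, pmax(0.2 * abs(mH), 0.2))
        sL <- pmax(sL, pmax(0.2 * abs(mL), 0.2))
        v <- (mH - mL) / (sH + sL)
    } else {
        v <- .welchRows(m, m * m, idxH, idxL)$t
    }
    names(v) <- rownames(m)
    v[order(-v, names(v))]
}

#' Weighted Kolmogorov-Smirnov running-sum enrichment score
#'
#' Walks the ranked list from top to bottom: a gene-set hit increments the
#' running sum by |metric|^weightExp normalized by the total hit weight, a
#' miss decrements it by 1/(N - nHits). The enrichment score is the value of
#' the running sum at its maximum absolute deviation from zero (signed).
#' If all hit weights are zero (possible when weightExp > 0 and every hit
#' has metric 0), hits fall back to equal weights.
#'
#' @param ranked named numeric vector from [rankByGroupMetric()] (or any
#'   descending-ordered metric named by unique genes).
#' @param geneSet character vector of gene symbols.
#' @param weightExp weighting exponent (0 = classic unweighted KS, 1 =
#'   classic two-group GSEA, 0.25 = single-sample convention).
#' @return list with \code{es} and \code{runningSum}.
#' @export
enrichmentScore <- function(ranked, geneSet, weightExp = 1) {
    stopifnot(is.numeric(ranked), !is.null(names(ranked)),
              !anyDuplicated(names(ranked)), weightExp >= 0)
    N <- length(ranked)
    hit <- names(ranked) %in% toupper(geneSet)
    nHit <- sum(hit)
    if (nHit == 0L) stop("empty overlap between gene set and ranked list")
    if (nHit == N) stop("set equals universe: no misses to score against")
    w <- abs(ranked)^weightExp
    w[!hit] <- 0
    tot <- sum(w)
    if (tot == 0) {            # degenerate: all hit metrics are zero
        w[hit] <- 1
        tot <- nHit
    }
    run <- cumsum(w / tot - (!hit) / (N - nHit))
    hi <- max(run); lo <- min(run)
    ## signed maximum deviation; an exact magnitude tie goes to the positive
    ## extreme (tolerance guards against accumulation-order noise)
    es <- if (hi - (-lo) >= -1e-9) hi else lo
    list(es = es, runningSum = unname(run))
}

#' Two-group GSEA with phenotype-permutation NES and nominal p
#'
#' The observed enrichment score is computed on the ranked list of the true
#' labels; the null distribution comes from \code{nPerm} relabelings with
#' fixed group sizes. NES is the observed ES divided by the mean |null ES|
#' of matching sign; the nominal p is the plus-one-corrected one-sided tail
#' among null ES of matching sign.
#'
#' @inheritParams rankByGroupMetric
#' @param geneSet character vector of gene symbols.
#' @param nPerm number of phenotype permutations (>= 10).
#' @param weightExp running-sum weighting exponent.
#' @param seed integer seed.
#' @return a \linkS4class{GseaResult}.
#' @export
gseaTwoGroup <- function(expr, strat, geneSet, nPerm = 1000L,
                         metric = c("snr", "tstat"), weightExp = 1,
                         seed = 1L) {
    metric <- match.arg(metric)
    stopifnot(nPerm >= 10L)
    m <- .exprMat(expr)
    if (max(m) == min(m)) stop("degenerate input: all values identical")
    lab <- strataLabels(strat)[colnames(m)]
    obs <- enrichmentScore(rankByGroupMetric(m, strat, metric), geneSet,
                           weightExp)
    n <- ncol(m); nH <- sum(lab == "HIGH")
    nullEs <- withSeed(seed, vapply(seq_len(nPerm), function(j) {
        iH <- sample.int(n, nH)
        permLab <- factor(ifelse(seq_len(n) %in% iH, "HIGH", "LOW"),
                          levels = c("HIGH", "LOW"))
        names(permLab) <- colnames(m)
        permStrat <- new("StratificationResult", labels = permLab,
                         cutoff = 0, marker = markerGene(strat))
        enrichmentScore(rankByGroupMetric(m, permStrat, metric), geneSet,
                        weightExp)$es
    }, numeric(1)))
    if (obs$es == 0) {
        nes <- 0; p <- 1
    } else {
        same <- nullEs[sign(nullEs) == sign(obs$es)]
        if (!length(same) || mean(abs(same)) == 0)
            stop("NES undefined: no null enrichment scores of matching sign")
        nes <- obs$es / mean(abs(same))
        p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    }
    new("GseaResult", es = obs$es, nes = nes, pNominal = p,
        nPerm = as.integer(nPerm), runningSum = obs$runningSum)
}

#' Per-sample running-sum enrichment scores
#'
#' For each sample independently, genes are ranked by descending expression
#' within that sample and the running-sum score is computed with a
#' rank-based metric (the gene's rank from the bottom, so the top gene has
#' metric N). Scores therefore depend only on the within-sample ordering:
#' adding a constant to a sample, or permuting the gene rows, leaves them
#' unchanged. Ties are broken by gene symbol order.
#'
#' @param expr expression matrix or \code{SummarizedExperiment}.
#' @param geneSet character vector of gene symbols.
#' @param weightExp weighting exponent (default 0.25, the single-sample
#'   convention).
#' @return named numeric vector of per-sample enrichment scores.
#' @export
sampleEnrichment <- function(expr, geneSet, weightExp = 0.25) {
    m <- .exprMat(expr)
    N <- nrow(m)
    genes <- rownames(m)
    es <- vapply(seq_len(ncol(m)), function(j) {
        ord <- order(-m[, j], genes)
        ranked <- setNames(as.numeric(N:1), genes[ord])
        enrichmentScore(ranked, geneSet, weightExp)$es
    }, numeric(1))
    setNames(es, colnames(m))
}

#' Per-sample oncoactivity scores
#'
#' Oncoactivity = ES over the oncogene set minus ES over the
#' tumor-suppressor set, both computed per sample with
#' [sampleEnrichment()]. Identically zero when the two sets coincide, and
#' exactly negated when they are swapped.
#'
#' @param expr expression matrix or \code{SummarizedExperiment}.
#' @param onco,tsg character vectors of gene symbols.
#' @param weightExp running-sum weighting exponent.
#' @return an \linkS4class{OncoactivityScores}.
#' @export
oncoactivityScores <- function(expr, onco, tsg, weightExp = 0.25) {
    esO <- sampleEnrichment(expr, onco, weightExp)
    esT <- sampleEnrichment(expr, tsg, weightExp)
    new("OncoactivityScores", esOnco = esO, esTsg = esT,
        score = esO - esT)
}

#' Compare per-sample scores between strata
#'
#' Two-sided Wilcoxon rank-sum test of the scores between the HIGH and LOW
#' strata; exact enumeration when both groups have at most 10 samples (and
#' no ties), normal approximation otherwise.
#'
#' @param scores named numeric vector (names = sample ids).
#' @param strat a \linkS4class{StratificationResult}.
#' @return list with \code{statistic} (rank-sum W) and \code{p}.
#' @export
compareGroupScores <- function(scores, strat) {
    lab <- strataLabels(strat)[names(scores)]
    x <- scores[lab == "HIGH"]; y <- scores[lab == "LOW"]
    if (!length(x) || !length(y)) stop("both strata must be non-empty")
    if (max(scores) == min(scores)) {
        warning("all scores tied; p set to 1")
        return(list(statistic = length(x) * length(y) / 2, p = 1))
    }
    exact <- length(x) <= 10L && length(y) <= 10L
    wt <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided", exact = exact))
    list(statistic = unname(wt$statistic), p = wt$p.value)
}
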