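#' Stratification of a cohort by marker expression
#'
#' Holds the HIGH/LOW labels produced by [medianSplit()], together with the
#' marker gene and the cutoff (log2 units) that defined them.
#'
#' @slot labels named factor with levels \code{HIGH}, \code{LOW}; names are
#'   sample identifiers.
#' @slot cutoff numeric(1), the median marker expression used as cutoff.
#' @slot marker character(1), the marker gene symbol.
#' @export
setClass("StratificationResult",
    representation(labels = "factor", cutoff = "numeric",
                   marker = "character"))

setValidity("StratificationResult", function(object) {
    msg <- character()
    if (!identical(levels(object@labels), c("HIGH", "LOW")))
        msg <- c(msg, "labels must be a factor with levels HIGH, LOW")
    if (anyNA(object@labels))
        msg <- c(msg, "every sample must be labeled")
    if (is.null(names(object@labels)))
        msg <- c(msg, "labels must be named by sample id")
    if (length(object@cutoff) != 1L || !is.finite(object@cutoff))
        msg <- c(msg, "cutoff must be a single finite number")
    if (length(msg)) msg else TRUE
})

#' Directional differential-expression signature pair
#'
#' The result of [buildSignature()]: genes significantly up in the HIGH
#' stratum and genes significantly up in the LOW stratum, with the per-gene
#' statistics and the thresholds that defined membership.
#'
#' @slot upInHigh character vector of gene symbols up-regulated in HIGH.
#' @slot upInLow character vector of gene symbols up-regulated in LOW.
#' @slot stats data.frame with columns \code{gene}, \code{t}, \code{fc},
#'   \code{pPerm} (one row per tested gene).
#' @slot pMax,fcMin numeric(1) thresholds used.
#' @export
setClass("SignaturePair",
    representation(upInHigh = "character", upInLow = "character",
                   stats = "data.frame", pMax = "numeric", fcMin = "numeric"))

setValidity("SignaturePair", function(object) {
    msg <- character()
    if (length(intersect(object@upInHigh, object@upInLow)))
        msg <- c(msg, "signature sets must be disjoint")
    if (anyDuplicated(object@upInHigh) || anyDuplicated(object@upInLow))
        msg <- c(msg, "signature sets must not contain duplicates")
    need <- c("gene", "t", "fc", "pPerm")
    if (!all(need %in% colnames(object@stats)))
        msg <- c(msg, "stats must have columns gene, t, fc, pPerm")
    if (length(msg)) msg else TRUE
})

#' Per-sample oncoactivity scores
#'
#' Per-sample running-sum enrichment scores over an oncogene set and a
#' tumor-suppressor set, and their difference (the oncoactivity).
#'
#' @slot esOnco,esTsg,score named numeric vectors (one value per sample);
#'   \code{score = esOnco - esTsg}.
#' @export
setClass("OncoactivityScores",
    representation(esOnco = "numeric", esTsg = "numeric", score = "numeric"))

setValidity("OncoactivityScores", function(object) {
    msg <- character()
    if (length(object@esOnco) != length(object@esTsg) ||
        length(object@score) != length(object@esOnco))
        msg <- c(msg, "score vectors must have equal length")
    if (max(abs(object@score - (object@esOnco - object@esTsg))) > 1e-12)
        msg <- c(msg, "score must equal esOnco - esTsg")
    if (any(abs(object@esOnco) > 1 + 1e-12) ||
        any(abs(object@esTsg) > 1 + 1e-12))
        msg <- c(msg, "enrichment scores must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})

#' Two-group GSEA result
#'
#' @slot es observed enrichment score in [-1, 1].
#' @slot nes normalized enrichment score (sign-matched null normalization).
#' @slot pNominal plus-one-corrected one-sided nominal p of matching sign.
#' @slot nPerm number of phenotype permutations used.
#' @slot runningSum the observed running-sum vector (for plotting).
#' @export
setClass("GseaResult",
    representation(es = "numeric", nes = "numeric", pNominal = "numeric",
                   nPerm = "integer", runningSum = "numeric"))

setValidity("GseaResult", function(object) {
    msg <- character()
    if (object@es != 0 && sign(object@nes) != sign(object@es))
        msg <- c(msg, "sign(nes) must equal sign(es) when es != 0")
    if (object@pNominal <= 0 || object@pNominal > 1)
        msg <- c(msg, "pNominal must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Nearest-template prediction calls
#'
#' @slot calls data.frame with one row per sample and columns \code{sample},
#'   \code{label} (factor A/B/ND), \code{distance} (1 - cosine similarity to
#'   the nearest template, in [0, 2]), \code{p}, \code{fdr}.
#' @slot fdrThreshold numeric(1), the significance criterion; samples at
#'   \code{fdr >= fdrThreshold} are labeled ND (not determined).
#' @export
setClass("NTPCalls",
    representation(calls = "data.frame", fdrThreshold = "numeric"))

setValidity("NTPCalls", function(object) {
    msg <- character()
    need <- c("sample", "label", "distance", "p", "fdr")
    if (!all(need %in% colnames(object@calls)))
        return("calls must have columns sample, label, distance, p, fdr")
    cl <- object@calls
    if (!identical(levels(cl$label), c("A", "B", "ND")))
        msg <- c(msg, "label levels must be A, B, ND")
    if (any(cl$distance < -1e-12 | cl$distance > 2 + 1e-12))
        msg <- c(msg, "distances must lie in [0, 2]")
    if (any(cl$p <= 0 | cl$p > 1))
        msg <- c(msg, "p must lie in (0, 1]")
    nd <- cl$fdr >= object@fdrThreshold
    if (!identical(nd, cl$label == "ND"))
        msg <- c(msg, "label must be ND exactly when fdr >= fdrThreshold")
    if (length(msg)) msg else TRUE
})
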