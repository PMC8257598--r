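#' @rdname StratificationResult-class
#' @param x a \code{StratificationResult}.
#' @export
setGeneric("strataLabels", function(x) standardGeneric("strataLabels"))

#' @rdname StratificationResult-class
#' @export
setGeneric("cutoffValue", function(x) standardGeneric("cutoffValue"))

#' @rdname StratificationResult-class
#' @export
setGeneric("markerGene", function(x) standardGeneric("markerGene"))

#' @rdname SignaturePair-class
#' @param x a \code{SignaturePair}.
#' @export
setGeneric("upInHigh", function(x) standardGeneric("upInHigh"))

#' @rdname SignaturePair-class
#' @export
setGeneric("upInLow", function(x) standardGeneric("upInLow"))

#' @rdname SignaturePair-class
#' @export
setGeneric("geneStats", function(x) standardGeneric("geneStats"))

#' @rdname OncoactivityScores-class
#' @param x an \code{OncoactivityScores}.
#' @export
setGeneric("oncoactivity", function(x) standardGeneric("oncoactivity"))

#' @rdname NTPCalls-class
#' @param x an \code{NTPCalls}.
#' @export
setGeneric("ntpCalls", function(x) standardGeneric("ntpCalls"))

setMethod("strataLabels", "StratificationResult", function(x) x@labels)
setMethod("cutoffValue", "StratificationResult", function(x) x@cutoff)
setMethod("markerGene", "StratificationResult", function(x) x@marker)
setMethod("upInHigh", "SignaturePair", function(x) x@upInHigh)
setMethod("upInLow", "SignaturePair", function(x) x@upInLow)
setMethod("geneStats", "SignaturePair", function(x) x@stats)
setMethod("oncoactivity", "OncoactivityScores",
          function(x) x@score)
setMethod("ntpCalls", "NTPCalls", function(x) x@calls)

setMethod("show", "StratificationResult", function(object) {
    tab <- table(object@labels)
    cat("StratificationResult on marker", object@marker, "\n")
    cat(sprintf("  cutoff (log2): %.4g\n", object@cutoff))
    cat(sprintf("  HIGH: %d  LOW: %d\n", tab[["HIGH"]], tab[["LOW"]]))
})

setMethod("show", "SignaturePair", function(object) {
    cat("SignaturePair\n")
    cat(sprintf("  up in HIGH: %d genes; up in LOW: %d genes\n",
                length(object@upInHigh), length(object@upInLow)))
    cat(sprintf("  thresholds: p < %g, |log2 FC| > %g\n",
                object@pMax, object@fcMin))
})

setMethod("show", "OncoactivityScores", function(object) {
    cat(sprintf("OncoactivityScores for %d samples\n", length(object@score)))
    cat(sprintf("  oncoactivity range: [%.3f, %.3f]\n",
                min(object@score), max(object@score)))
})

setMethod("show", "GseaResult", function(object) {
    cat(sprintf("GseaResult: ES = %.3f, NES = %.3f, p = %.4g (%d perms)\n",
                object@es, object@nes, object@pNominal, object@nPerm))
})

setMethod("show", "NTPCalls", function(object) {
    tab <- table(object@calls$label)
    cat(sprintf("NTPCalls for %d samples (FDR < %g)\n",
                nrow(object@calls), object@fdrThreshold))
    cat(sprintf("  A: %d  B: %d  ND: %d\n",
                tab[["A"]], tab[["B"]], tab[["ND"]]))
})
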