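#' Build signed templates from a signature pair
#'
#' Template A is +1 on the genes up in HIGH and -1 on the genes up in LOW
#' (restricted to the genes present in the expression matrix); template B is
#' its negation. Errors if less than \code{minOverlap} of the signature is
#' present (pooled multi-platform cohorts lose genes; a silent heavy loss
#' would bias the calls).
#'
#' @param sig a \linkS4class{SignaturePair}.
#' @param expr expression matrix or \code{SummarizedExperiment} of the
#'   cohort to classify.
#' @param minOverlap minimum fraction of signature genes that must be
#'   present (default 0.5).
#' @return list with \code{genes}, \code{templateA}, \code{templateB}.
#' @export
buildTemplates <- function(sig, expr, minOverlap = 0.5) {
    m <- .exprMat(expr)
    sigGenes <- c(upInHigh(sig), upInLow(sig))
    if (!length(sigGenes)) stop("empty signature")
    present <- sigGenes[sigGenes %in% rownames(m)]
    frac <- length(present) / length(sigGenes)
    if (frac < minOverlap)
        stop(sprintf(
            "only %.0f%% of signature genes present (minimum %.0f%%)",
            100 * frac, 100 * minOverlap))
    a <- ifelse(present %in% upInHigh(sig), 1, -1)
    names(a) <- present
    list(genes = present, templateA = a, templateB = -a)
}

#' Nearest-template prediction with a resampling FDR
#'
#' Expression over the template genes is z-scored across samples
#' (zero-variance genes are dropped with a warning). Each sample is assigned
#' to the template (A or B = -A) with the smaller cosine distance
#' (1 - cosine similarity). Significance: \code{nNull} random sign templates
#' with the same +/- composition as template A are drawn; the null distance
#' of a sample to a random template is the distance to the nearer of the
#' template and its negation (mirroring the observed nearest-template
#' distance, and making calls exactly symmetric under negation of the
#' expression matrix). The per-sample p is the plus-one-corrected fraction
#' of null distances at or below the observed one; FDR is Benjamini-Hochberg
#' across samples, and samples at \code{fdr >= fdrThreshold} are labeled ND.
#'
#' @param expr expression matrix or \code{SummarizedExperiment}.
#' @param templates output of [buildTemplates()].
#' @param nNull number of resampled templates (>= 100).
#' @param fdrThreshold FDR criterion for a determinate call (default 0.05).
#' @param seed integer seed for the resampled templates.
#' @return an \linkS4class{NTPCalls}.
#' @export
ntpClassify <- function(expr, templates, nNull = 1000L, fdrThreshold = 0.05,
                        seed = 1L) {
    stopifnot(nNull >= 100L, fdrThreshold > 0, fdrThreshold <= 1)
    m <- .exprMat(expr)
    genes <- templates$genes[templates$genes %in% rownames(m)]
    if (!length(genes)) stop("no template genes present in the matrix")
    x <- m[genes, , drop = FALSE]
    sds <- apply(x, 1L, sd)
    if (any(sds == 0)) {
        warning(sum(sds == 0), " zero-variance template gene(s) dropped")
        genes <- genes[sds > 0]
        if (!length(genes)) stop("all template genes have zero variance")
        x <- x[genes, , drop = FALSE]
        sds <- sds[sds > 0]
    }
    z <- (x - rowMeans(x)) / sds
    a <- templates$templateA[genes]
    nG <- length(genes)

    colNorm <- sqrt(colSums(z^2))
    cosA <- as.numeric(crossprod(z, a)) / (colNorm * sqrt(nG))
    dObs <- 1 - abs(cosA)                 # distance to the nearest template
    label <- ifelse(cosA >= 0, "A", "B")

    nPlus <- sum(a > 0)
    nullT <- withSeed(seed, {
        vapply(seq_len(nNull), function(j) {
            t <- rep(-1, nG)
            t[sample.int(nG, nPlus)] <- 1
            t
        }, numeric(nG))
    })
    ## samples x nNull cosines; null distance uses the nearer of +/- template
    cosNull <- crossprod(z, nullT) / (colNorm * sqrt(nG))
    dNull <- 1 - abs(cosNull)
    p <- (1 + rowSums(dNull <= dObs + 1e-12)) / (1 + nNull)
    fdr <- p.adjust(p, method = "BH")
    label[fdr >= fdrThreshold] <- "ND"

    calls <- data.frame(sample = colnames(m),
                        label = factor(label, levels = c("A", "B", "ND")),
                        distance = dObs, p = p, fdr = fdr,
                        stringsAsFactors = FALSE, row.names = NULL)
    new("NTPCalls", calls = calls, fdrThreshold = fdrThreshold)
}
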