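#' Stratify samples by marker-gene expression at the median
#'
#' The cutoff is the sample median of the marker's expression; a sample is
#' labeled HIGH if its value is strictly above the cutoff and LOW otherwise
#' (ties at the median go to LOW, so with an odd number of distinct values
#' the LOW stratum has one more member than HIGH, e.g. 186/185 at n = 371).
#'
#' @param expr expression matrix or \code{SummarizedExperiment}.
#' @param marker marker gene symbol.
#' @return a \linkS4class{StratificationResult}.
#' @export
medianSplit <- function(expr, marker) {
    m <- .exprMat(expr)
    marker <- toupper(marker)
    if (!marker %in% rownames(m))
        stop("marker gene '", marker, "' not present in the matrix")
    v <- m[marker, ]
    if (max(v) == min(v))
        stop("degenerate split: all marker values identical")
    cutoff <- median(v)
    lab <- factor(ifelse(v > cutoff, "HIGH", "LOW"),
                  levels = c("HIGH", "LOW"))
    names(lab) <- colnames(m)
    new("StratificationResult", labels = lab, cutoff = cutoff,
        marker = marker)
}

#' Select variably expressed genes by median absolute deviation
#'
#' Computes, per gene, the raw MAD median(|x - median(x)|) -- without the
#' 1.4826 normal-consistency constant by default -- and returns the genes
#' whose MAD strictly exceeds the threshold, in input order.
#'
#' @param expr expression matrix or \code{SummarizedExperiment}.
#' @param threshold non-negative MAD cutoff (genes with MAD > threshold are
#'   kept).
#' @param constant multiplier applied to the raw MAD (set to 1.4826 for the
#'   normal-consistent convention).
#' @return character vector of gene symbols.
#' @export
madFilter <- function(expr, threshold, constant = 1) {
    stopifnot(threshold >= 0)
    m <- .exprMat(expr)
    mads <- constant * apply(m, 1L, function(x) median(abs(x - median(x))))
    rownames(m)[mads > threshold]
}

#' Concordance between unsupervised clusters and marker strata
#'
#' Clusters samples into k = 2 groups by hierarchical agglomeration with
#' average linkage on a (1 - Pearson correlation) distance computed over the
#' given genes, matches clusters to strata by the assignment that maximizes
#' agreement, and reports the per-stratum fraction of samples falling in the
#' matched cluster.
#'
#' @param expr expression matrix or \code{SummarizedExperiment}.
#' @param genes gene symbols to cluster on (>= 2).
#' @param strat a \linkS4class{StratificationResult}.
#' @return list with \code{concordance} (named numeric, HIGH and LOW),
#'   \code{clusterSizes}, and \code{nGenes}.
#' @export
clusterConcordance <- function(expr, genes, strat) {
    m <- .exprMat(expr)
    genes <- intersect(toupper(genes), rownames(m))
    if (length(genes) < 2L) stop("need at least 2 genes after filtering")
    if (ncol(m) < 4L) stop("need at least 4 samples")
    lab <- strataLabels(strat)[colnames(m)]
    if (any(table(lab) == 0L)) stop("a stratum has no members")
    d <- as.dist(1 - cor(m[genes, , drop = FALSE]))
    cl <- cutree(hclust(d, method = "average"), k = 2L)
    tab <- table(cluster = cl, stratum = lab)
    ## match clusters to strata by the diagonal-maximizing assignment
    straight <- tab[1L, "HIGH"] + tab[2L, "LOW"]
    crossed <- tab[1L, "LOW"] + tab[2L, "HIGH"]
    if (straight >= crossed) {
        conc <- c(HIGH = tab[1L, "HIGH"] / sum(tab[, "HIGH"]),
                  LOW = tab[2L, "LOW"] / sum(tab[, "LOW"]))
    } else {
        conc <- c(HIGH = tab[2L, "HIGH"] / sum(tab[, "HIGH"]),
                  LOW = tab[1L, "LOW"] / sum(tab[, "LOW"]))
    }
    list(concordance = conc,
         clusterSizes = as.integer(table(cl)),
         nGenes = length(genes))
}
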