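#' @import methods
#' @importFrom stats median p.adjust pchisq phyper pt rexp rnorm runif
#'   sd var cor hclust cutree as.dist quantile rbinom setNames
#' @importFrom utils read.table write.table combn packageVersion
NULL

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) {
            assign(".Random.seed", old, envir = globalenv())
        } else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
        }
    })
    set.seed(seed)
    expr
}

## Accept either a plain numeric matrix (rownames = gene symbols) or a
## SummarizedExperiment holding one; return the matrix.
.exprMat <- function(x) {
    if (is(x, "SummarizedExperiment")) {
        m <- SummarizedExperiment::assay(x, 1L)
    } else if (is.matrix(x) && is.numeric(x)) {
        m <- x
    } else {
        stop("expression input must be a numeric matrix or a ",
             "SummarizedExperiment")
    }
    if (is.null(rownames(m)) || is.null(colnames(m)))
        stop("expression matrix must have gene rownames and sample colnames")
    m
}

.datasetOf <- function(x) {
    if (is(x, "SummarizedExperiment")) {
        cd <- SummarizedExperiment::colData(x)
        if ("dataset" %in% colnames(cd))
            return(setNames(as.character(cd$dataset), colnames(x)))
    }
    NULL
}

.upgenes <- function(g) {
    up <- toupper(g)
    if (!identical(up, g))
        warning("gene symbols contained lower-case characters; uppercased")
    up
}
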