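#' Build an expression container
#'
#' Wraps a log2-scale gene x sample matrix in a
#' \linkS4class{SummarizedExperiment}, enforcing the package's invariants:
#' unique uppercased gene symbols, no missing values, at least 2 genes and
#' 2 samples. An optional per-sample dataset tag (for multi-cohort merges)
#' is stored in \code{colData(x)$dataset}.
#'
#' @param values numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns (colnames = sample ids), log2 expression units.
#' @param dataset optional character vector (length = ncol) of dataset tags.
#' @return a \code{SummarizedExperiment} with assay \code{exprs}.
#' @export
exprCohort <- function(values, dataset = NULL) {
    m <- .exprMat(values)
    rownames(m) <- .upgenes(rownames(m))
    if (anyDuplicated(rownames(m)))
        stop("gene symbols must be unique after uppercasing")
    if (anyNA(m))
        stop("expression matrix must not contain missing values")
    if (nrow(m) < 2L || ncol(m) < 2L)
        stop("need at least 2 genes and 2 samples")
    if (anyDuplicated(colnames(m)))
        stop("sample ids must be unique")
    cd <- S4Vectors::DataFrame(row.names = colnames(m))
    if (!is.null(dataset)) {
        stopifnot(length(dataset) == ncol(m))
        cd$dataset <- as.character(dataset)
    }
    SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = m), colData = cd)
}

#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample ids and a first column of gene symbols.
#' Symbols are uppercased; duplicate symbols are resolved by keeping the row
#' with the highest mean expression (the number of dropped duplicates is
#' reported via \code{message}); rows containing any missing value are
#' dropped and counted.
#'
#' @param path file path.
#' @param transform \code{"none"} (values already log2) or \code{"log2p1"}
#'   (apply \code{log2(x + 1)}).
#' @return a \code{SummarizedExperiment} (see [exprCohort()]).
#' @export
readExprMatrix <- function(path, transform = c("none", "log2p1")) {
    transform <- match.arg(transform)
    df <- tryCatch(
        read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   quote = "", comment.char = "", fill = FALSE,
                   colClasses = NA, stringsAsFactors = FALSE),
        error = function(e) stop("malformed expression file: ",
                                 conditionMessage(e)))
    if (ncol(df) < 3L)
        stop("malformed header: need a gene column and at least 2 samples")
    genes <- .upgenes(as.character(df[[1L]]))
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m))
        stop("malformed expression file: non-numeric values")
    rownames(m) <- genes

    nMiss <- sum(rowSums(is.na(m)) > 0L)
    if (nMiss > 0L) {
        allMiss <- rowSums(!is.na(m)) == 0L
        if (any(allMiss))
            warning(sum(allMiss), " all-missing gene row(s) dropped")
        m <- m[rowSums(is.na(m)) == 0L, , drop = FALSE]
        message(nMiss, " gene row(s) with missing values dropped")
    }
    if (anyDuplicated(rownames(m))) {
        nDup <- sum(duplicated(rownames(m)))
        message(nDup, " duplicate gene symbol row(s) resolved by max mean")
        keep <- order(-rowMeans(m))
        m <- m[keep, , drop = FALSE]
        m <- m[!duplicated(rownames(m)), , drop = FALSE]
        m <- m[order(match(rownames(m), genes)), , drop = FALSE]
    }
    if (transform == "log2p1") m <- log2(m + 1)
    exprCohort(m)
}

#' Write an expression matrix as tab-separated text
#'
#' @param x expression matrix or \code{SummarizedExperiment}.
#' @param path output file path.
#' @export
writeExprMatrix <- function(x, path) {
    m <- .exprMat(x)
    df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line is \code{name TAB description TAB gene1 TAB gene2 ...}. Symbols
#' are uppercased and deduplicated.
#'
#' @param path file path.
#' @return a named list of character vectors (one element per set).
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(structure(list(), names = character()))
    sets <- vector("list", length(lines))
    nm <- character(length(lines))
    for (i in seq_along(lines)) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop("GMT format error at line ", i, ": fewer than 3 fields")
        nm[i] <- f[1L]
        g <- unique(toupper(f[-(1:2)]))
        g <- g[nzchar(g)]
        if (!length(g))
            stop("GMT format error at line ", i, ": empty gene set")
        sets[[i]] <- g
    }
    names(sets) <- nm
    sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param descriptions optional character vector of set descriptions.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
    lines <- vapply(seq_along(sets), function(i) {
        paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a clinical covariate table
#'
#' CSV with a header and a \code{sample_id} column. An optional schema maps
#' column names to types (\code{continuous}, \code{binary},
#' \code{categorical}); typed columns are validated (binary must be 0/1,
#' continuous must be numeric). Per-column missingness is reported via
#' \code{message}; rows are never dropped here (samples missing survival
#' time are excluded later, by the survival utilities, but retained for
#' association tests).
#'
#' @param path file path.
#' @param schema optional named character vector, column -> type.
#' @return a data.frame with character \code{sample_id}.
#' @export
readClinical <- function(path, schema = NULL) {
    df <- read.table(path, header = TRUE, sep = ",", check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (!"sample_id" %in% colnames(df))
        stop("clinical table must contain a sample_id column")
    df$sample_id <- as.character(df$sample_id)
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id in clinical table")
    for (col in names(schema)) {
        if (!col %in% colnames(df)) next
        type <- schema[[col]]
        v <- df[[col]]
        if (type == "continuous") {
            num <- suppressWarnings(as.numeric(v))
            bad <- which(!is.na(v) & is.na(num) & v != "")
            if (length(bad))
                stop("non-numeric value in continuous column '", col,
                     "' at row ", bad[1L])
            num[!is.na(v) & v == ""] <- NA
            df[[col]] <- num
        } else if (type == "binary") {
            num <- suppressWarnings(as.numeric(v))
            if (any(!is.na(num) & !num %in% c(0, 1)))
                stop("binary column '", col, "' must contain only 0/1")
            df[[col]] <- num
        } else if (type == "categorical") {
            df[[col]] <- as.character(v)
        } else stop("unknown schema type '", type, "' for column '", col, "'")
    }
    nMiss <- vapply(df, function(v) sum(is.na(v) | (is.character(v) & v == "")),
                    integer(1))
    if (any(nMiss > 0L))
        message("missing values per column: ",
                paste(sprintf("%s=%d", names(nMiss)[nMiss > 0],
                              nMiss[nMiss > 0]), collapse = ", "))
    df
}

#' Merge expression datasets onto their common gene universe
#'
#' Genes are matched by uppercased symbol; the merged matrix covers exactly
#' the intersection, in sorted order. With \code{adjust = "center"} each gene
#' is median-centered within each source dataset, a simple location batch
#' adjustment (idempotent).
#'
#' @param matrices named list (length >= 2) of expression matrices or
#'   \code{SummarizedExperiment}s with pairwise-disjoint sample ids; list
#'   names become the dataset tags.
#' @param adjust \code{"none"} or \code{"center"}.
#' @return a \code{SummarizedExperiment} with \code{colData(x)$dataset}.
#' @export
mergeDatasets <- function(matrices, adjust = c("none", "center")) {
    adjust <- match.arg(adjust)
    if (length(matrices) < 2L) stop("need at least 2 datasets to merge")
    if (is.null(names(matrices)) || any(!nzchar(names(matrices))))
        names(matrices) <- paste0("dataset", seq_along(matrices))
    mats <- lapply(matrices, function(x) {
        m <- .exprMat(x)
        rownames(m) <- toupper(rownames(m))
        m
    })
    genes <- Reduce(intersect, lapply(mats, rownames))
    if (!length(genes)) stop("empty gene intersection across datasets")
    genes <- sort(genes)
    samples <- unlist(lapply(mats, colnames), use.names = FALSE)
    if (anyDuplicated(samples))
        stop("duplicate sample id across datasets")
    merged <- do.call(cbind, lapply(mats, function(m)
        m[genes, , drop = FALSE]))
    dataset <- rep(names(mats), vapply(mats, ncol, integer(1)))
    if (adjust == "center") {
        for (d in unique(dataset)) {
            idx <- which(dataset == d)
            med <- apply(merged[, idx, drop = FALSE], 1L, median)
            merged[, idx] <- merged[, idx, drop = FALSE] - med
        }
    }
    exprCohort(merged, dataset = dataset)
}
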