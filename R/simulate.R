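#' Configuration for the synthetic-cohort generator
#'
#' Defaults describe a desk-scale two-subtype tumor cohort: 200 samples,
#' 2000 genes on the log2 scale, 10\% of genes differentially expressed at a
#' one-unit log2 shift, within-group SD 0.5, a strongly shifted stratifying
#' marker gene, oncogene/TSG set sizes scaled down from genome-wide lists,
#' exponential survival with a hazard ratio of 2 for the aggressive (LOW)
#' subtype and administrative censoring at 120 months.
#'
#' @param nSamples number of samples (>= 4).
#' @param nGenes number of genes (including the marker).
#' @param fracDeg fraction of genes differentially expressed between
#'   subtypes (split evenly between the two directions).
#' @param delta log2 mean shift of each DEG between subtypes.
#' @param sigma within-group SD, log2 units.
#' @param markerDelta log2 shift of the stratifying marker (HIGH minus LOW).
#' @param marker marker gene symbol.
#' @param nOnco,nTsg oncogene / tumor-suppressor set sizes.
#' @param oncoFracUpInLow fraction of oncogene-set members drawn from the
#'   genes up-regulated in the LOW subtype (the TSG set symmetrically draws
#'   the same fraction from genes up-regulated in HIGH).
#' @param batchShifts named numeric vector of per-dataset additive offsets;
#'   samples are split evenly across its names.
#' @param hr true hazard ratio, LOW vs HIGH.
#' @param baselineHazard events per month in the HIGH subtype.
#' @param censorTime administrative censoring horizon, months.
#' @param seed integer seed; one global seed drives a fixed sub-stream per
#'   component (expression, survival, gene sets).
#' @return a validated list of class \code{SimulationConfig}.
#' @export
simConfig <- function(nSamples = 200L, nGenes = 2000L, fracDeg = 0.1,
                      delta = 1.0, sigma = 0.5, markerDelta = 2.0,
                      marker = "ESR1", nOnco = 100L, nTsg = 150L,
                      oncoFracUpInLow = 0.5, batchShifts = c(ds1 = 0),
                      hr = 2.0, baselineHazard = 0.02, censorTime = 120,
                      seed = 1L) {
    cfg <- list(nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
                fracDeg = fracDeg, delta = delta, sigma = sigma,
                markerDelta = markerDelta, marker = toupper(marker),
                nOnco = as.integer(nOnco), nTsg = as.integer(nTsg),
                oncoFracUpInLow = oncoFracUpInLow,
                batchShifts = batchShifts, hr = hr,
                baselineHazard = baselineHazard, censorTime = censorTime,
                seed = as.integer(seed))
    stopifnot(cfg$nSamples >= 4L, cfg$nGenes >= 4L,
              cfg$fracDeg >= 0, cfg$fracDeg <= 1,
              cfg$oncoFracUpInLow >= 0, cfg$oncoFracUpInLow <= 1,
              cfg$sigma > 0, cfg$hr > 0, cfg$baselineHazard > 0,
              cfg$censorTime > 0, length(cfg$batchShifts) >= 1L)
    if (is.null(names(cfg$batchShifts)))
        names(cfg$batchShifts) <- paste0("ds", seq_along(cfg$batchShifts))
    if (round(cfg$fracDeg * (cfg$nGenes - 1L)) < 2)
        stop("fracDeg x nGenes < 2: cannot form both signatures")
    class(cfg) <- "SimulationConfig"
    cfg
}

## Fixed offsets give each stochastic component its own reproducible stream.
.subSeed <- function(seed, component) {
    seed + c(expression = 11L, survival = 223L, sets = 3637L)[[component]]
}

#' Simulate a two-subtype tumor cohort with known ground truth
#'
#' Generates a log2 expression matrix, a clinical table and the ground truth
#' behind them. Per gene, expression is Normal(mu_g + effects, sigma) with
#' baseline means mu_g ~ Uniform(2, 12); DEGs get a +delta shift in their
#' subtype, the marker gene a +markerDelta shift in HIGH, and each dataset
#' an additive batch offset. Survival is exponential with rate
#' baselineHazard (HIGH) or baselineHazard * hr (LOW), administratively
#' censored at censorTime. Identical seeds give identical output.
#'
#' @param config a \code{SimulationConfig} from [simConfig()].
#' @return a list with elements \code{expr} (SummarizedExperiment),
#'   \code{clinical} (data.frame: sample_id, time, event, age, mvi, dataset),
#'   \code{truth} (list: subtypeOf, degUpInLow, degUpInHigh, markerGene,
#'   trueHr).
#' @export
simulateCohort <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    n <- config$nSamples
    g <- config$nGenes
    genes <- c(config$marker,
               sprintf("G%05d", seq_len(g - 1L)))
    samples <- sprintf("S%04d", seq_len(n))

    nLow <- ceiling(n / 2)
    nDeg <- round(config$fracDeg * (g - 1L))
    nUpLow <- floor(nDeg / 2)
    nUpHigh <- nDeg - nUpLow

    expr <- withSeed(.subSeed(config$seed, "expression"), {
        subtype <- sample(rep(c("LOW", "HIGH"), c(nLow, n - nLow)))
        deg <- sample(genes[-1L], nDeg)
        degUpInLow <- deg[seq_len(nUpLow)]
        degUpInHigh <- deg[nUpLow + seq_len(nUpHigh)]
        mu <- runif(g, 2, 12)
        m <- matrix(rnorm(g * n, mean = mu, sd = config$sigma), g, n,
                    dimnames = list(genes, samples))
        isHigh <- subtype == "HIGH"
        m[config$marker, isHigh] <- m[config$marker, isHigh] +
            config$markerDelta
        m[degUpInHigh, isHigh] <- m[degUpInHigh, isHigh] + config$delta
        m[degUpInLow, !isHigh] <- m[degUpInLow, !isHigh] + config$delta
        ## even split across datasets, in sample order
        dataset <- names(config$batchShifts)[
            ceiling(seq_len(n) / (n / length(config$batchShifts)))]
        m <- m + matrix(config$batchShifts[dataset], g, n, byrow = TRUE)
        list(m = m, subtype = subtype, dataset = dataset,
             degUpInLow = degUpInLow, degUpInHigh = degUpInHigh)
    })

    surv <- withSeed(.subSeed(config$seed, "survival"), {
        rate <- ifelse(expr$subtype == "LOW",
                       config$baselineHazard * config$hr,
                       config$baselineHazard)
        tt <- rexp(n, rate)
        event <- as.integer(tt <= config$censorTime)
        time <- pmin(tt, config$censorTime)
        age <- round(rnorm(n, mean = ifelse(expr$subtype == "HIGH", 62, 58),
                           sd = 8), 1)
        mvi <- rbinom(n, 1L, ifelse(expr$subtype == "LOW", 0.6, 0.35))
        data.frame(sample_id = samples, time = time, event = event,
                   age = age, mvi = mvi, dataset = expr$dataset,
                   stringsAsFactors = FALSE)
    })

    list(expr = exprCohort(expr$m, dataset = expr$dataset),
         clinical = surv,
         truth = list(subtypeOf = setNames(expr$subtype, samples),
                      degUpInLow = expr$degUpInLow,
                      degUpInHigh = expr$degUpInHigh,
                      markerGene = config$marker,
                      trueHr = config$hr))
}

#' Simulate oncogene and tumor-suppressor gene sets
#'
#' Draws an oncogene set containing \code{oncoFracUpInLow * nOnco} members
#' from the genes truly up-regulated in the aggressive LOW subtype (the rest
#' from non-DEG genes), and a TSG set symmetrically enriched for genes
#' up-regulated in HIGH, so that oncoactivity (ES_onco - ES_TSG) is higher
#' in LOW by construction.
#'
#' @param truth the \code{truth} element of [simulateCohort()] output.
#' @param config the same \code{SimulationConfig}.
#' @return list with character vectors \code{onco} and \code{tsg}.
#' @export
simulateGeneSets <- function(truth, config) {
    stopifnot(inherits(config, "SimulationConfig"))
    allGenes <- c(truth$markerGene,
                  sprintf("G%05d", seq_len(config$nGenes - 1L)))
    nonDeg <- setdiff(allGenes,
                      c(truth$markerGene, truth$degUpInLow,
                        truth$degUpInHigh))
    nOncoDeg <- round(config$oncoFracUpInLow * config$nOnco)
    nTsgDeg <- round(config$oncoFracUpInLow * config$nTsg)
    if (nOncoDeg > length(truth$degUpInLow) ||
        nTsgDeg > length(truth$degUpInHigh))
        stop("requested overlap exceeds available DEGs")
    if ((config$nOnco - nOncoDeg) + (config$nTsg - nTsgDeg) > length(nonDeg))
        stop("not enough non-DEG genes for the requested set sizes")
    withSeed(.subSeed(config$seed, "sets"), {
        onco <- c(sample(truth$degUpInLow, nOncoDeg),
                  sample(nonDeg, config$nOnco - nOncoDeg))
        rest <- setdiff(nonDeg, onco)
        tsg <- c(sample(truth$degUpInHigh, nTsgDeg),
                 sample(rest, config$nTsg - nTsgDeg))
        list(onco = sort(onco), tsg = sort(tsg))
    })
}

#' Write a simulated cohort as the pipeline's standard input files
#'
#' Writes the expression matrix (TSV), the clinical table (CSV) and the
#' oncogene/TSG gene sets (GMT) into a directory, so that the end-to-end
#' pipeline can be exercised from files alone.
#'
#' @param cohort output of [simulateCohort()].
#' @param sets output of [simulateGeneSets()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
writeCohortFiles <- function(cohort, sets, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(expression = file.path(dir, "expression.tsv"),
               clinical = file.path(dir, "clinical.csv"),
               gene_sets = file.path(dir, "gene_sets.gmt"))
    writeExprMatrix(cohort$expr, paths[["expression"]])
    write.table(cohort$clinical, paths[["clinical"]], sep = ",",
                quote = FALSE, row.names = FALSE)
    writeGmt(list(onco = sets$onco, tsg = sets$tsg), paths[["gene_sets"]])
    invisible(paths)
}
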