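.pipelineDefaults <- function() {
    list(marker = "ESR1", mad_threshold = 0.5, p_max = 1e-3, fc_min = 0.5,
         n_perm = 1000L, pooled_null = TRUE, fdr_threshold = 0.05,
         n_null = 1000L, weight_gsea = 1, weight_sample = 0.25,
         seed = 1L, outdir = NULL, simulation = NULL, inputs = NULL)
}

#' Read and validate a pipeline configuration
#'
#' Configurations are YAML mappings mirroring the arguments of the stage
#' functions. Exactly one of \code{simulation} (a mapping of [simConfig()]
#' arguments) or \code{inputs} (paths: \code{expression}, \code{gene_sets},
#' \code{clinical}, set names \code{onco_set}/\code{tsg_set}, optional
#' \code{ntp_expression}) must be present.
#'
#' @param x path to a YAML file, or a named list.
#' @return the validated, default-filled config list.
#' @export
readPipelineConfig <- function(x) {
    cfg <- if (is.character(x) && length(x) == 1L) yaml::read_yaml(x) else x
    stopifnot(is.list(cfg))
    full <- utils::modifyList(.pipelineDefaults(), cfg)
    hasSim <- !is.null(full$simulation)
    hasInp <- !is.null(full$inputs)
    if (hasSim == hasInp)
        stop("config must contain exactly one of 'simulation' or 'inputs'")
    if (hasInp && !all(c("expression", "gene_sets", "clinical") %in%
                       names(full$inputs)))
        stop("inputs must name expression, gene_sets and clinical paths")
    with(full, stopifnot(
        mad_threshold >= 0, p_max > 0, p_max <= 1, fc_min >= 0,
        n_perm >= 10, fdr_threshold > 0, fdr_threshold <= 1, n_null >= 100,
        weight_gsea >= 0, weight_sample >= 0))
    full$seed <- as.integer(full$seed)
    full
}

.writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Run the full stratification analysis end-to-end
#'
#' Executes the stage sequence stratify -> differential expression ->
#' oncoactivity -> nearest-template prediction -> survival and association
#' statistics, on either a simulated cohort or user-supplied files, writing
#' every result plus a reproducibility manifest into \code{outdir}. All
#' stochastic stages are seeded deterministically from \code{config$seed},
#' so a config re-run reproduces the output files byte for byte.
#'
#' @param config a config list or YAML path (see [readPipelineConfig()]).
#' @return invisibly, a list bundle with the in-memory results
#'   (stratification, concordance, stats, signature, oncoactivity,
#'   comparison, ntp, survival, associations, manifest).
#' @export
runPipeline <- function(config) {
    cfg <- readPipelineConfig(config)
    out <- cfg$outdir
    if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)
    emit <- function(df, name) {
        if (!is.null(out)) .writeTsv(df, file.path(out, name))
    }
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e) {
            if (!is.null(out))
                writeLines(paste("FAILED at stage:", name, "--",
                                 conditionMessage(e)),
                           file.path(out, "FAILED"))
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE)
        })
    }

    dat <- stage("data", {
        if (!is.null(cfg$simulation)) {
            simArgs <- cfg$simulation
            simArgs$seed <- cfg$seed
            scfg <- do.call(simConfig, simArgs)
            cohort <- simulateCohort(scfg)
            sets <- simulateGeneSets(cohort$truth, scfg)
            list(expr = cohort$expr, clinical = cohort$clinical,
                 onco = sets$onco, tsg = sets$tsg, truth = cohort$truth,
                 ntpExpr = cohort$expr)
        } else {
            gmt <- readGmt(cfg$inputs$gene_sets)
            oncoName <- cfg$inputs$onco_set %||% "onco"
            tsgName <- cfg$inputs$tsg_set %||% "tsg"
            if (!all(c(oncoName, tsgName) %in% names(gmt)))
                stop("gene_sets file must contain sets '", oncoName,
                     "' and '", tsgName, "'")
            expr <- readExprMatrix(cfg$inputs$expression)
            ntpExpr <- if (!is.null(cfg$inputs$ntp_expression))
                readExprMatrix(cfg$inputs$ntp_expression) else expr
            list(expr = expr,
                 clinical = readClinical(cfg$inputs$clinical),
                 onco = gmt[[oncoName]], tsg = gmt[[tsgName]],
                 truth = NULL, ntpExpr = ntpExpr)
        }
    })

    strat <- stage("stratify", medianSplit(dat$expr, cfg$marker))
    varGenes <- stage("stratify", madFilter(dat$expr, cfg$mad_threshold))
    conc <- stage("stratify", {
        if (length(varGenes) >= 2L)
            clusterConcordance(dat$expr, varGenes, strat)
        else NULL
    })
    emit(data.frame(sample = names(strataLabels(strat)),
                    label = as.character(strataLabels(strat))),
         "stratification.tsv")

    stats <- stage("diffexpr",
                   permutationTStats(dat$expr, strat, nPerm = cfg$n_perm,
                                     pooledNull = cfg$pooled_null,
                                     seed = cfg$seed + 101L))
    sig <- stage("diffexpr", buildSignature(stats, cfg$p_max, cfg$fc_min))
    emit(stats, "gene_stats.tsv")
    if (!is.null(out))
        writeSignatureGmt(sig, file.path(out, "signature.gmt"))

    onc <- stage("enrichment",
                 oncoactivityScores(dat$expr, dat$onco, dat$tsg,
                                    weightExp = cfg$weight_sample))
    cmp <- stage("enrichment", compareGroupScores(oncoactivity(onc), strat))
    emit(data.frame(sample = names(oncoactivity(onc)),
                    es_onco = onc@esOnco, es_tsg = onc@esTsg,
                    oncoactivity = oncoactivity(onc)),
         "oncoactivity.tsv")

    ntp <- stage("ntp", {
        if (length(upInHigh(sig)) && length(upInLow(sig))) {
            tmpl <- buildTemplates(sig, dat$ntpExpr)
            ntpClassify(dat$ntpExpr, tmpl, nNull = cfg$n_null,
                        fdrThreshold = cfg$fdr_threshold,
                        seed = cfg$seed + 202L)
        } else NULL
    })
    if (!is.null(ntp)) emit(ntpCalls(ntp), "ntp_calls.tsv")

    surv <- stage("survival", {
        cl <- dat$clinical
        if (all(c("time", "event") %in% colnames(cl))) {
            keep <- !is.na(cl$time) & !is.na(cl$event)
            cl <- cl[keep, ]
            lab <- strataLabels(strat)[cl$sample_id]
            lr <- logrankTest(cl$time, cl$event, lab)
            covs <- data.frame(low = as.integer(lab == "LOW"))
            if ("age" %in% colnames(cl)) covs$age <- cl$age
            cox <- coxFit(cl$time, cl$event, covs)
            km <- do.call(rbind, lapply(levels(lab), function(lv) {
                k <- kmCurve(cl$time[lab == lv], cl$event[lab == lv])
                cbind(group = lv, k)
            }))
            list(logrank = lr, cox = cox, km = km)
        } else NULL
    })
    if (!is.null(surv)) {
        emit(cbind(covariate = rownames(surv$cox), surv$cox),
             "survival_cox.tsv")
        emit(surv$km, "km_curves.tsv")
    }

    assoc <- stage("associations", {
        cl <- dat$clinical
        lab <- strataLabels(strat)[cl$sample_id]
        rows <- list()
        if ("mvi" %in% colnames(cl)) {
            tab <- table(lab, factor(cl$mvi, levels = c(1, 0)))
            fe <- fisherExact(unclass(tab))
            rates <- contingencyRates(unclass(tab))
            rows$mvi <- data.frame(
                variable = "mvi", test = "fisher_exact",
                statistic = fe$oddsRatio, p = fe$p,
                rate_high = rates["HIGH", 1], rate_low = rates["LOW", 1])
        }
        if ("age" %in% colnames(cl)) {
            tt <- groupTTest(cl$age[lab == "HIGH"], cl$age[lab == "LOW"])
            rows$age <- data.frame(
                variable = "age", test = "t_test", statistic = tt$t,
                p = tt$p, rate_high = NA, rate_low = NA)
        }
        if (length(rows)) do.call(rbind, rows) else NULL
    })
    if (!is.null(assoc)) emit(assoc, "associations.tsv")

    manifest <- stage("manifest", {
        mf <- list(seed = cfg$seed,
                   package_version = as.character(packageVersion("OncoStrat")),
                   config = cfg[setdiff(names(cfg), "outdir")])
        if (!is.null(out)) {
            cfgPath <- file.path(out, "config.yaml")
            yaml::write_yaml(mf$config, cfgPath)
            mf$config_md5 <- unname(tools::md5sum(cfgPath))
            jsonlite::write_json(mf, file.path(out, "manifest.json"),
                                  auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE)
        }
        mf
    })

    invisible(list(stratification = strat, concordance = conc,
                   stats = stats, signature = sig, oncoactivity = onc,
                   comparison = cmp, ntp = ntp, survival = surv,
                   associations = assoc, truth = dat$truth,
                   manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
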