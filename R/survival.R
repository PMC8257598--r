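#' @importFrom survival Surv survfit survdiff coxph coxph.control
NULL

## Survival times must be positive; zero times are bumped to half the
## smallest positive time (short-follow-up records exist in real registries).
.fixTimes <- function(time) {
    stopifnot(all(is.finite(time)), all(time >= 0))
    if (any(time == 0)) {
        warning(sum(time == 0), " zero survival time(s) bumped to half the ",
                "smallest positive time")
        time[time == 0] <- min(time[time > 0]) / 2
    }
    time
}

#' Kaplan-Meier product-limit curve
#'
#' @param time follow-up times (months).
#' @param event event indicator (1 = event, 0 = censored). Subjects censored
#'   at an event time count as at risk for that time.
#' @return data.frame with columns \code{time}, \code{nRisk}, \code{nEvent},
#'   \code{surv} (one row per distinct observed time); \code{S(0) = 1} is
#'   implicit.
#' @export
kmCurve <- function(time, event) {
    stopifnot(length(time) >= 1L, length(time) == length(event))
    time <- .fixTimes(time)
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    data.frame(time = fit$time, nRisk = fit$n.risk, nEvent = fit$n.event,
               surv = fit$surv)
}

#' Two-group log-rank test
#'
#' @param time,event as in [kmCurve()].
#' @param group two-level grouping vector.
#' @return list with \code{chi2} (1 df) and \code{p}.
#' @export
logrankTest <- function(time, event, group) {
    group <- as.factor(group)
    stopifnot(nlevels(group) == 2L)
    time <- .fixTimes(time)
    if (sum(event) == 0) {
        warning("no events in either group; p set to 1")
        return(list(chi2 = 0, p = 1))
    }
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    chi2 <- sd$chisq
    list(chi2 = chi2, p = pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Cox proportional-hazards regression
#'
#' Fits the partial likelihood by Newton-Raphson (via
#' \code{survival::coxph}) with the chosen tie correction, and reports per
#' covariate the coefficient, hazard ratio, Wald 95\% CI and p-value.
#'
#' @param time,event as in [kmCurve()].
#' @param covariates data.frame of covariates (non-constant columns).
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return data.frame (one row per coefficient: \code{coef}, \code{hr},
#'   \code{lo95}, \code{hi95}, \code{p}) with attributes \code{logLik},
#'   \code{converged} and \code{scoreTest} (the global score chi-square at
#'   beta = 0, which for a single binary covariate without ties equals the
#'   log-rank chi-square).
#' @export
coxFit <- function(time, event, covariates, ties = c("efron", "breslow")) {
    ties <- match.arg(ties)
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(time), ncol(covariates) >= 1L)
    if (sum(event) < 1L) stop("need at least one event")
    isConst <- vapply(covariates,
                      function(v) length(unique(v)) < 2L, logical(1))
    if (any(isConst))
        stop("constant covariate(s): ",
             paste(colnames(covariates)[isConst], collapse = ", "))
    time <- .fixTimes(time)
    dat <- cbind(data.frame(.time = time, .event = event), covariates)
    converged <- TRUE
    fit <- withCallingHandlers(
        survival::coxph(
            survival::Surv(.time, .event) ~ ., data = dat, ties = ties,
            control = survival::coxph.control(eps = 1e-9, iter.max = 50L)),
        warning = function(w) {
            if (grepl("coefficient may be infinite|did not converge",
                      conditionMessage(w))) {
                converged <<- FALSE
                warning("possible monotone likelihood: a coefficient is ",
                        "diverging", call. = FALSE)
            }
            invokeRestart("muffleWarning")
        })
    s <- summary(fit)
    co <- s$coefficients
    res <- data.frame(coef = co[, "coef"],
                      hr = exp(co[, "coef"]),
                      lo95 = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                      hi95 = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                      p = co[, "Pr(>|z|)"])
    rownames(res) <- rownames(co)
    attr(res, "logLik") <- fit$loglik[2L]
    attr(res, "converged") <- converged
    attr(res, "scoreTest") <- unname(s$sctest["test"])
    res
}

#' Fisher's exact test on a 2x2 table
#'
#' The odds ratio is the sample cross-product ad/bc (infinite when bc = 0
#' and ad > 0, undefined when both products are 0). Two conventions for the
#' two-sided p are offered: \code{"minlik"} (default; sum of hypergeometric
#' probabilities of all tables no more probable than the observed one, the
#' standard-software convention) and \code{"doubled"} (twice the smaller
#' one-sided tail, capped at 1).
#'
#' @param tab 2x2 integer matrix, rows = group, columns = outcome.
#' @param convention \code{"minlik"} or \code{"doubled"}.
#' @return list with \code{oddsRatio} and \code{p}.
#' @export
fisherExact <- function(tab, convention = c("minlik", "doubled")) {
    convention <- match.arg(convention)
    tab <- as.matrix(tab)
    stopifnot(identical(dim(tab), c(2L, 2L)) || all(dim(tab) == 2),
              all(tab >= 0), sum(tab) >= 1)
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    or <- if (b * c == 0) {
        if (a * d == 0) NaN else Inf
    } else a * d / (b * c)
    if (convention == "minlik") {
        p <- stats::fisher.test(tab)$p.value
    } else {
        m <- a + c; nn <- b + d; k <- a + b
        pLower <- phyper(a, m, nn, k)
        pUpper <- phyper(a - 1, m, nn, k, lower.tail = FALSE)
        p <- min(1, 2 * min(pLower, pUpper))
    }
    list(oddsRatio = unname(or), p = unname(p))
}

#' Pearson chi-square test on an r x c contingency table
#'
#' @param tab matrix of counts with positive margins.
#' @param yates apply the Yates continuity correction (2x2 tables only).
#' @return list with \code{chi2}, \code{df}, \code{p}.
#' @export
chiSquareTest <- function(tab, yates = FALSE) {
    tab <- as.matrix(tab)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("zero margin in contingency table")
    ct <- suppressWarnings(
        stats::chisq.test(tab, correct = yates && all(dim(tab) == 2)))
    list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
         p = unname(ct$p.value))
}

#' Two-sample t-test
#'
#' @param x,y numeric vectors (each of length >= 2; at least one group with
#'   positive variance).
#' @param welch use the Welch unequal-variance statistic (default pooled
#'   Student).
#' @return list with \code{t}, \code{df}, \code{p} (two-sided).
#' @export
groupTTest <- function(x, y, welch = FALSE) {
    stopifnot(length(x) >= 2L, length(y) >= 2L)
    if (var(x) == 0 && var(y) == 0) stop("both groups have zero variance")
    tt <- stats::t.test(x, y, var.equal = !welch)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
}

#' Per-group outcome rates from a contingency table
#'
#' Utility behind Table-1-style summaries: given counts with groups in rows,
#' returns each cell as a percentage of its row total.
#'
#' @param tab matrix of counts, groups in rows.
#' @return matrix of row percentages (0-100).
#' @export
contingencyRates <- function(tab) {
    tab <- as.matrix(tab)
    stopifnot(all(tab >= 0), all(rowSums(tab) > 0))
    100 * tab / rowSums(tab)
}
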