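# Survival association: Kaplan-Meier estimation, log-rank comparison and
# Cox proportional-hazards fits (Efron tie handling), built on the survival
# package with the contracts the subtype analyses need.

#' Kaplan-Meier product-limit estimate
#'
#' @param times positive follow-up times (months).
#' @param events event indicators (1 = progression/relapse, 0 = censored).
#' @return list: `time` (event times), `surv` (S(t) steps), `n_risk`,
#'   `n_event`, `median` (earliest time with S(t) <= 0.5, `NA` = not
#'   reached).
#' @export
km_estimate <- function(times, events) {
  if (length(times) < 1) stop("need >= 1 subject", call. = FALSE)
  if (any(times <= 0) || any(!is.finite(times)))
    stop("times must be positive and finite", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- unname(summary(fit)$table["median"])
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       n_event = fit$n.event,
       median = if (is.na(med)) NA_real_ else med)
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected statistic over the pooled event times,
#' chi-square with (groups - 1) degrees of freedom.
#'
#' @param times,events as in [km_estimate()].
#' @param groups group labels.
#' @return list: `statistic`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop("need >= 2 groups", call. = FALSE)
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Cox proportional-hazards association
#'
#' Partial-likelihood Cox regression with Efron tie handling. In
#' `"univariate"` mode each covariate is fitted alone; `"multivariate"`
#' fits them jointly. Hazard ratios with Wald 95\% confidence intervals and
#' p-values are reported per covariate level.
#'
#' @param data data.frame containing `time`, `event` and the covariates.
#' @param covariates character vector of covariate column names.
#' @param mode `"univariate"` or `"multivariate"`.
#' @return data.frame: `covariate`, `term`, `hr`, `ci_lower`, `ci_upper`,
#'   `p`, `mode`, `converged`.
#' @export
cox_fit <- function(data, covariates, mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  stopifnot(all(c("time", "event") %in% names(data)))
  miss <- setdiff(covariates, names(data))
  if (length(miss)) stop("unknown covariates: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (sum(data$event) < length(covariates) + 1)
    warning("fewer events than covariates + 1; estimates unstable",
            call. = FALSE)
  fit_one <- function(covs) {
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                   paste(covs, collapse = " + ")))
    fit <- survival::coxph(fml, data = data, ties = "efron",
                           control = survival::coxph.control(eps = 1e-9,
                                                             iter.max = 50))
    s <- summary(fit)
    co <- s$coefficients
    ci <- s$conf.int
    infinite <- !is.finite(co[, "se(coef)"]) | co[, "se(coef)"] > 1e3
    if (any(infinite))
      warning("possible monotone likelihood (separation) in Cox fit",
              call. = FALSE)
    data.frame(covariate = rep(paste(covs, collapse = "+"), nrow(co)),
               term = rownames(co),
               hr = co[, "exp(coef)"],
               ci_lower = ci[, "lower .95"],
               ci_upper = ci[, "upper .95"],
               p = co[, "Pr(>|z|)"],
               mode = mode,
               converged = rep(fit$iter < 50, nrow(co)),
               row.names = NULL)
  }
  if (mode == "univariate") {
    do.call(rbind, lapply(covariates, fit_one))
  } else {
    fit_one(covariates)
  }
}

#' Median-split survival comparison for a single gene
#'
#' Splits samples at the median expression of one gene ("high" vs "low")
#' and compares survival between the halves by log-rank test and univariate
#' Cox fit. The median cutoff is a package choice (the source analyses do
#' not state one) and is recorded in the output.
#'
#' @param expr [expression_matrix] (log scale).
#' @param gene gene ID to split on.
#' @param survival_data data.frame with `sample_id`, `time`, `event`.
#' @return list: `cutoff`, `group` (named factor high/low), `logrank`,
#'   `cox`.
#' @export
median_split_survival <- function(expr, gene, survival_data) {
  m <- unclass(expr)
  if (!gene %in% rownames(m)) stop("gene not in matrix", call. = FALSE)
  x <- m[gene, survival_data$sample_id]
  cutoff <- stats::median(x)
  grp <- factor(ifelse(x > cutoff, "high", "low"), levels = c("low", "high"))
  d <- data.frame(time = survival_data$time, event = survival_data$event,
                  group = grp)
  list(cutoff = cutoff, group = stats::setNames(grp, survival_data$sample_id),
       logrank = logrank_test(d$time, d$event, d$group),
       cox = cox_fit(d, "group", mode = "univariate"))
}
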