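#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function with Greenwood
#' confidence bands, plus the median survival time (earliest time at which
#' the estimate drops to 0.5 or below; `NA` when never reached).
#'
#' @param records `data.frame` with columns `time` (months) and `event`
#'   (1 = event, 0 = censored).
#' @param group Optional factor splitting the records into strata.
#' @return List with `curve` (data.frame: time, n.risk, n.event, surv,
#'   lower, upper and, if stratified, `group`) and `median` (named numeric).
#' @export
km_estimate <- function(records, group = NULL) {
  stopifnot(all(c("time", "event") %in% colnames(records)))
  if (any(records$time <= 0)) stop("survival times must be positive")
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
    curve <- data.frame(time = fit$time, n.risk = fit$n.risk,
                        n.event = fit$n.event, surv = fit$surv,
                        lower = fit$lower, upper = fit$upper)
    med <- km_median(curve$time, curve$surv)
    return(list(curve = curve, median = c(all = med)))
  }
  records$.g <- factor(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ .g, data = records)
  strata <- rep(sub("^\\.g=", "", names(fit$strata)), fit$strata)
  curve <- data.frame(group = strata, time = fit$time, n.risk = fit$n.risk,
                      n.event = fit$n.event, surv = fit$surv,
                      lower = fit$lower, upper = fit$upper)
  med <- vapply(split(curve, curve$group),
                function(cv) km_median(cv$time, cv$surv), numeric(1))
  list(curve = curve, median = med)
}

km_median <- function(time, surv) {
  hit <- surv <= 0.5 + 1e-12
  if (!any(hit)) return(NA_real_)
  min(time[hit])
}

#' Multivariable Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron handling of tied event times.
#' Reports per-covariate hazard ratios with Wald confidence intervals and
#' p-values; the fitted `coxph` object is attached for residual checks.
#'
#' @param records `data.frame` with `time`, `event` and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param conf Confidence level (default 0.95).
#' @return `data.frame` (term, coef, hr, lo, hi, p) with the `coxph` fit in
#'   attribute `"fit"`.
#' @export
cox_fit <- function(records, covariates, conf = 0.95) {
  stopifnot(all(c("time", "event") %in% colnames(records)))
  if (sum(records$event) < 1) stop("no events; cannot fit a Cox model")
  for (cv in covariates) {
    if (!cv %in% colnames(records)) stop("missing covariate column: ", cv)
    if (length(unique(records[[cv]])) < 2L) {
      stop("constant covariate: ", cv)
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = records, ties = "efron", x = TRUE)
  if (!is.null(fit$coefficients) && any(!is.finite(fit$coefficients))) {
    stop("Cox fit did not converge (possible separation)")
  }
  s <- summary(fit, conf.int = conf)
  out <- data.frame(term = rownames(s$coefficients),
                    coef = s$coefficients[, "coef"],
                    hr = s$coefficients[, "exp(coef)"],
                    lo = s$conf.int[, 3], hi = s$conf.int[, 4],
                    p = s$coefficients[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}

#' Schoenfeld-residual trend test of proportional hazards
#'
#' Tests, per covariate, the correlation of the scaled Schoenfeld residuals
#' with (transformed) event time via [survival::cox.zph()]. A small p-value
#' flags a time-varying effect, i.e. a proportional-hazards violation.
#'
#' @param fit A [cox_fit()] result (or a `coxph` object).
#' @param transform Time transform for the trend test (default `"km"`, the
#'   `cox.zph` default).
#' @param alpha Flagging threshold (default 0.05).
#' @return `data.frame` (term, chisq, df, p, violation).
#' @export
schoenfeld_trend <- function(fit, transform = "km", alpha = 0.05) {
  cph <- if (inherits(fit, "coxph")) fit else attr(fit, "fit")
  if (is.null(cph)) stop("no coxph fit found; pass a cox_fit() result")
  if (sum(cph$nevent) < 2) stop("too few events for a residual trend test")
  z <- survival::cox.zph(cph, transform = transform)
  tb <- as.data.frame(z$table)
  data.frame(term = rownames(tb), chisq = tb$chisq, df = tb$df, p = tb$p,
             violation = tb$p < alpha, stringsAsFactors = FALSE)
}
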