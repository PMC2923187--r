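#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] with Greenwood variance and log-log 95%
#' confidence limits, returning the step function on the event-time grid.
#'
#' @param time follow-up times (>= 0).
#' @param event event indicators (1 = death observed).
#' @param conf_level confidence level (default 0.95).
#' @return object of class `km_estimate`: data.frame `table` (`time`,
#'   `n_risk`, `n_event`, `surv`, `lower`, `upper`) and the underlying
#'   `survfit` object.
#' @export
km_fit <- function(time, event, conf_level = 0.95) {
  if (length(time) == 0L) stop("empty survival data")
  if (any(time < 0)) stop("negative survival time")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  structure(list(
    table = data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv,
                       lower = fit$lower, upper = fit$upper),
    fit = fit
  ), class = "km_estimate")
}

#' Evaluate a Kaplan-Meier estimate at given times
#'
#' @param km a [km_fit()] result.
#' @param t times at which to evaluate the survival step function
#'   (S(0) = 1; right-continuous).
#' @return numeric vector of survival probabilities.
#' @export
km_surv <- function(km, t) {
  stopifnot(inherits(km, "km_estimate"))
  ev <- km$table[km$table$n_event > 0, , drop = FALSE]
  if (nrow(ev) == 0L) return(rep(1, length(t)))
  sf <- stats::stepfun(ev$time, c(1, ev$surv), right = FALSE)
  sf(t)
}

#' Log-rank test between survival groups
#'
#' Standard (unweighted) log-rank chi-square statistic with
#' `n_groups - 1` degrees of freedom, via [survival::survdiff()].
#'
#' @param time follow-up times.
#' @param event event indicators.
#' @param group group membership (factor or coercible).
#' @return list: `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2L) stop("log-rank test needs at least two groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(chisq = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards evaluation
#'
#' Fits a Cox model with Efron tie handling. Character/factor covariates
#' are expanded against declared reference levels; numeric covariates
#' (e.g. a continuous risk score) enter as-is. Reports per-term hazard
#' ratios with Wald confidence intervals and p-values, plus the per-sample
#' linear predictor used by [cpe()].
#'
#' @param covariates data.frame of covariates, one row per sample.
#' @param time follow-up times.
#' @param event event indicators.
#' @param reference named list mapping covariate names to their reference
#'   level (defaults to each factor's first level).
#' @param conf_level confidence level for the hazard-ratio intervals.
#' @return object of class `cox_fit_result`: data.frame `coefficients`
#'   (`term`, `coef`, `hr`, `lower`, `upper`, `p`), `lp` linear predictors,
#'   and the `coxph` fit.
#' @export
cox_fit <- function(covariates, time, event, reference = list(),
                    conf_level = 0.95) {
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  if (sum(event) == 0L) stop("no events observed; Cox model cannot be fit")
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      if (!is.null(reference[[nm]])) v <- stats::relevel(v, ref = reference[[nm]])
      covariates[[nm]] <- v
      if (nlevels(v) < 2L) stop("constant covariate: ", nm)
    } else if (length(unique(v)) < 2L) stop("constant covariate: ", nm)
  }
  if (sum(event) < ncol(covariates))
    stop("fewer events than covariates")
  dat <- cbind(covariates, .time = time, .event = event)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", names(covariates)),
                                       collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  if (anyNA(stats::coef(fit)))
    stop("Cox fit did not converge to finite coefficients")
  sm <- summary(fit, conf.int = conf_level)
  structure(list(
    coefficients = data.frame(
      term = rownames(sm$coefficients),
      coef = sm$coefficients[, "coef"],
      hr = sm$conf.int[, 1L],
      lower = sm$conf.int[, 3L],
      upper = sm$conf.int[, 4L],
      p = sm$coefficients[, "Pr(>|z|)"],
      row.names = NULL, stringsAsFactors = FALSE),
    lp = unname(stats::predict(fit, type = "lp")),
    fit = fit
  ), class = "cox_fit_result")
}

#' @export
print.cox_fit_result <- function(x, ...) {
  print(x$coefficients)
  invisible(x)
}

#' Gonen-Heller concordance probability estimate
#'
#' The censoring-independent concordance probability of a fitted Cox model:
#' over all sample pairs, the model-implied probability that the sample
#' with the higher linear predictor fails first,
#' `mean over pairs of 1 / (1 + exp(-|eta_i - eta_j|))`. Equals exactly 0.5
#' when all linear predictors coincide (null model) and approaches 1 for
#' well-separated predictors.
#'
#' @param x a [cox_fit_result] or a numeric vector of linear predictors.
#' @return concordance probability in \[0.5, 1\].
#' @export
cpe <- function(x) {
  lp <- if (inherits(x, "cox_fit_result")) x$lp else as.numeric(x)
  n <- length(lp)
  if (n < 2L) stop("need at least two samples")
  d <- abs(outer(lp, lp, "-"))
  mean(stats::plogis(d[upper.tri(d)]))
}

#' Sensitivity and specificity of predicted risk groups at a horizon
#'
#' Ground truth comes from [dichotomize()] at the horizon: deaths by the
#' horizon are true high-risk, survivors past it true low-risk, and
#' samples censored before the horizon are excluded from both denominators.
#' Sensitivity is the fraction of true high-risk samples predicted
#' high-risk; specificity the fraction of true low-risk samples predicted
#' low-risk.
#'
#' @param predicted named factor/character of predicted labels
#'   (low_risk/high_risk), e.g. from [classify_risk()].
#' @param clinical clinical table.
#' @param horizon_months truth horizon (default 60).
#' @return list: `sensitivity`, `specificity`, `counts` (tp, fn, tn, fp,
#'   excluded).
#' @export
horizon_sens_spec <- function(predicted, clinical, horizon_months = 60) {
  truth <- dichotomize(clinical, horizon_months)
  ids <- intersect(truth$sample_id, names(predicted))
  if (length(ids) == 0L) stop("no overlap between predictions and labelled samples")
  tl <- stats::setNames(as.character(truth$label), truth$sample_id)[ids]
  pl <- as.character(predicted[ids])
  tp <- sum(tl == "high_risk" & pl == "high_risk")
  fn <- sum(tl == "high_risk" & pl == "low_risk")
  tn <- sum(tl == "low_risk" & pl == "low_risk")
  fp <- sum(tl == "low_risk" & pl == "high_risk")
  if ((tp + fn) == 0L || (tn + fp) == 0L)
    stop("a truth class is empty at this horizon; sensitivity/specificity undefined")
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       counts = c(tp = tp, fn = fn, tn = tn, fp = fp,
                  excluded = length(truth$excluded_ids)))
}
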