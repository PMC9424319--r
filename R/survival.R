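check_time_event <- function(time, event) {
  if (length(time) == 0) stop("empty survival input", call. = FALSE)
  if (length(time) != length(event))
    stop("`time` and `event` must have equal length", call. = FALSE)
  if (!is.numeric(time) || anyNA(time) || any(time < 0))
    stop("`time` must be non-negative and complete", call. = FALSE)
  if (anyNA(event) || !all(event %in% c(0, 1)))
    stop("`event` must be 0 or 1", call. = FALSE)
  invisible(NULL)
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit survival curve
#' S(t) = prod over event times t_j <= t of (1 - d_j / n_j). The median is
#' the smallest event time at which S(t) <= 0.5 (first crossing), `NA` if
#' the curve never reaches 0.5.
#'
#' @param time Non-negative follow-up times (months).
#' @param event 0/1 event indicator (1 = event observed).
#' @return Object of class `SurvivalCurve`: `event_times`, `survival`,
#'   `at_risk`, `events`, `median_survival`, `n`.
#' @export
km_fit <- function(time, event) {
  check_time_event(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  surv <- fit$surv[keep]
  times <- fit$time[keep]
  med <- if (any(surv <= 0.5)) times[which(surv <= 0.5)[1]] else NA_real_
  structure(list(event_times = times, survival = surv,
                 at_risk = fit$n.risk[keep], events = fit$n.event[keep],
                 median_survival = med, n = length(time)),
            class = "SurvivalCurve")
}

#' @export
print.SurvivalCurve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d events at %d distinct times; median = %s\n",
              x$n, sum(x$events), length(x$event_times),
              if (is.na(x$median_survival)) "not reached"
              else format(x$median_survival)))
  invisible(x)
}

#' K-sample log-rank test
#'
#' Standard log-rank comparison of k >= 2 survival curves: at each distinct
#' event time the observed events per group are compared with the
#' expectation under the hypergeometric model on the risk set; the
#' chi-square statistic has k - 1 degrees of freedom.
#'
#' @param time Non-negative follow-up times.
#' @param event 0/1 event indicator.
#' @param group Group labels (factor or coercible); every group non-empty.
#' @return Object of class `LogRankResult`: `statistic`, `df`, `p`, plus
#'   per-group observed/expected event counts.
#' @export
logrank_test <- function(time, event, group) {
  check_time_event(time, event)
  group <- droplevels(factor(group))
  if (length(group) != length(time))
    stop("`group` must have the same length as `time`", call. = FALSE)
  if (anyNA(group)) stop("`group` contains missing labels", call. = FALSE)
  if (nlevels(group) < 2)
    stop("log-rank test needs at least 2 non-empty groups", call. = FALSE)
  if (sum(event) == 0)
    stop("no events: log-rank statistic undefined", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  stat <- as.numeric(sd$chisq)
  structure(list(statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE),
                 observed = as.numeric(sd$obs), expected = as.numeric(sd$exp),
                 groups = levels(group), n = as.numeric(sd$n)),
            class = "LogRankResult")
}

#' @export
print.LogRankResult <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.4g on %d df, p = %.3g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood with the Efron correction for tied
#' event times and returns per-covariate log-hazard coefficients, hazard
#' ratios with Wald 95% confidence intervals, and Wald p-values.
#'
#' @param covariates Numeric vector or matrix (samples in rows); each
#'   covariate must vary across subjects.
#' @param time Non-negative follow-up times.
#' @param event 0/1 event indicator.
#' @return Object of class `CoxResult`: `beta`, `hr`, `ci_low`, `ci_high`,
#'   `se`, `wald_p`, `converged`, `n`, `n_event`. `converged` is `FALSE`
#'   when the partial likelihood is monotone (e.g. perfect separation) or
#'   iteration limits were hit.
#' @export
cox_fit <- function(covariates, time, event) {
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  check_time_event(time, event)
  if (nrow(x) != length(time))
    stop("covariate rows must match the number of subjects", call. = FALSE)
  if (length(time) <= ncol(x))
    stop("need more subjects than covariates", call. = FALSE)
  if (is.null(colnames(x)))
    colnames(x) <- if (ncol(x) == 1) "x" else paste0("x", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant covariate: ", paste(colnames(x)[sds == 0], collapse = ", "),
         call. = FALSE)
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(diag(as.matrix(fit$var)))
  zcrit <- stats::qnorm(0.975)
  names(beta) <- names(se) <- colnames(x)
  structure(list(beta = beta, hr = exp(beta),
                 ci_low = exp(beta - zcrit * se),
                 ci_high = exp(beta + zcrit * se),
                 se = se,
                 wald_p = 2 * stats::pnorm(-abs(beta / se)),
                 converged = !warned && all(is.finite(beta)),
                 n = length(time), n_event = sum(event)),
            class = "CoxResult")
}

#' @export
print.CoxResult <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (n = %d, %d events)%s\n", x$n,
              x$n_event, if (x$converged) "" else "  [NOT CONVERGED]"))
  for (i in seq_along(x$beta))
    cat(sprintf("  %s: HR = %.3g (95%% CI %.3g-%.3g), beta = %.3g, p = %.3g\n",
                names(x$beta)[i], x$hr[i], x$ci_low[i], x$ci_high[i],
                x$beta[i], x$wald_p[i]))
  invisible(x)
}
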