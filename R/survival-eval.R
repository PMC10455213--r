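#' Kaplan-Meier overall-survival estimate
#'
#' Product-limit estimate of the survivor function, with the median defined
#' as the first event time at which the estimate drops to 0.5 or below
#' (`NA`, "not reached", when it never does) and survival probabilities read
#' off at the requested horizons (defaults 180/365/1095 days: 6-month,
#' 1-year and 3-year survival).
#'
#' @param times follow-up in days (>= 0).
#' @param events event flags: 1 = death, 0 = censored.
#' @param horizons days at which to report survival.
#' @return object of class `km_curve`: list with `time`, `surv`, `n_risk`,
#'   `n_event`, `median`, `horizon_surv`, `n`, `n_events`.
#' @examples
#' km_estimate(c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 0, 1, 1))
#' @export
km_estimate <- function(times, events, horizons = c(180, 365, 1095)) {
  if (length(times) == 0L) stop("empty survival input", call. = FALSE)
  if (length(times) != length(events)) {
    stop("times and events must have equal length", call. = FALSE)
  }
  if (any(times < 0)) stop_field("times", "must be >= 0")
  if (!all(events %in% c(0, 1))) stop_field("events", "must be 0/1")
  fit <- survfit(Surv(times, events) ~ 1, conf.type = "none")
  s <- summary(fit, censored = TRUE)
  est_at <- function(h) {
    idx <- which(fit$time <= h)
    if (!length(idx)) return(1)
    fit$surv[max(idx)]
  }
  drop_idx <- which(fit$n.event > 0 & fit$surv <= 0.5 + 1e-12)
  med <- if (length(drop_idx)) fit$time[min(drop_idx)] else NA_real_
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event,
                 median = med,
                 horizon_surv = setNames(vapply(horizons, est_at,
                                                numeric(1L)),
                                         paste0("d", horizons)),
                 n = length(times), n_events = sum(events)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, events = %d\n", x$n,
              x$n_events))
  cat("  median survival:",
      if (is.na(x$median)) "not reached" else paste(x$median, "days"), "\n")
  hs <- paste(sprintf("%s %.0f%%", names(x$horizon_surv),
                      100 * x$horizon_surv), collapse = ", ")
  cat("  survival at horizons:", hs, "\n")
  invisible(x)
}

#' Log-rank comparison of survival between groups
#'
#' Standard (unweighted) log-rank chi-square test with `k - 1` degrees of
#' freedom for `k` groups.
#'
#' @param times,events as in [km_estimate()].
#' @param group group membership (factor or vector coercible to one); every
#'   group must contain at least one subject.
#' @return object of class `log_rank_result`: list with `chisq`, `df`, `p`,
#'   `n`, per-group observed and expected event counts.
#' @export
log_rank <- function(times, events, group) {
  if (length(times) != length(events) || length(times) != length(group)) {
    stop("times, events and group must have equal length", call. = FALSE)
  }
  group <- factor(group)
  if (nlevels(group) < 2L) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  if (any(table(group) == 0L)) {
    stop("every group must contain at least one subject", call. = FALSE)
  }
  sd_fit <- survdiff(Surv(times, events) ~ group)
  df <- length(sd_fit$n) - 1L
  structure(list(chisq = sd_fit$chisq, df = df,
                 p = pchisq(sd_fit$chisq, df, lower.tail = FALSE),
                 n = sum(sd_fit$n), observed = sd_fit$obs,
                 expected = sd_fit$exp, groups = levels(group)),
            class = "log_rank_result")
}

#' @export
print.log_rank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.3f, df = %d, p = %.4g (n = %d)\n",
              x$chisq, x$df, x$p, x$n))
  invisible(x)
}

extract_cox <- function(fit, variables) {
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  flagged <- !is.null(fit$info) ||
    any(!is.finite(co[, "coef"])) || any(co[, "se(coef)"] > 50)
  per <- data.frame(
    variable = rownames(co),
    beta = co[, "coef"],
    hr = co[, "exp(coef)"],
    ci_low = ci[, "lower .95"],
    ci_high = ci[, "upper .95"],
    p = co[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = per,
                 model_p = s$logtest[["pvalue"]],
                 n = s$n, n_events = s$nevent,
                 flagged = flagged,
                 diagnostics = if (flagged)
                   "possible non-convergence or monotone likelihood"
                 else NA_character_),
            class = "cox_fit")
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit (Efron tie handling) of overall survival on a
#' single coded covariate, reporting the hazard ratio with Wald 95%
#' confidence interval and p-value plus the model likelihood-ratio p.
#' Fits with signs of non-convergence or monotone likelihood (complete
#' separation) are flagged rather than silently reported.
#'
#' @param table data frame with the covariate plus time and event columns.
#' @param variable covariate column name (coded numerically, or categorical
#'   with a coding available in `coding`).
#' @param time,event column names of follow-up days and death flag.
#' @param coding a [variable_coding()] applied to categorical covariates.
#' @return object of class `cox_fit`.
#' @export
cox_univariate <- function(table, variable, time = "os_days",
                           event = "death_event",
                           coding = variable_coding()) {
  if (!variable %in% names(table)) {
    stop(sprintf("unknown variable '%s'", variable), call. = FALSE)
  }
  x <- table[[variable]]
  if (identical(variable, "risk_group")) x <- as.character(x)
  if (!is.numeric(x)) x <- code_variable(x, variable, coding)
  d <- data.frame(.t = table[[time]], .e = table[[event]], x = x)
  d <- d[complete.cases(d), , drop = FALSE]
  if (sum(d$.e) < 1L) stop("no events in the data", call. = FALSE)
  fit <- withCallingHandlers(
    coxph(Surv(.t, .e) ~ x, data = d, ties = "efron"),
    warning = function(w) invokeRestart("muffleWarning"))
  out <- extract_cox(fit, variable)
  out$coefficients$variable <- variable
  out
}

#' Multivariate Cox proportional-hazards regression
#'
#' Joint partial-likelihood fit on a candidate covariate list. Two covariate
#' selection policies are provided: `"enter_all"` (default) keeps every
#' candidate in the model, and `"backward_elimination"` iteratively removes
#' the least significant covariate until all Wald p-values are below
#' `alpha`. The policy used is recorded in the result.
#'
#' @param table data frame with the covariates plus time and event columns.
#' @param candidates character vector of covariate column names.
#' @param policy `"enter_all"` or `"backward_elimination"`.
#' @param alpha retention threshold for backward elimination.
#' @inheritParams cox_univariate
#' @return object of class `cox_fit` with `policy` and `retained` fields.
#' @export
cox_multivariate <- function(table, candidates,
                             policy = c("enter_all", "backward_elimination"),
                             alpha = 0.05, time = "os_days",
                             event = "death_event",
                             coding = variable_coding()) {
  policy <- match.arg(policy)
  miss <- setdiff(candidates, names(table))
  if (length(miss)) {
    stop("unknown covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- data.frame(.t = table[[time]], .e = table[[event]])
  for (v in candidates) {
    x <- table[[v]]
    if (identical(v, "risk_group")) x <- as.character(x)
    if (!is.numeric(x)) x <- code_variable(x, v, coding)
    d[[v]] <- x
  }
  d <- d[complete.cases(d), , drop = FALSE]
  if (sum(d$.e) < 1L) stop("no events in the data", call. = FALSE)
  fit_with <- function(vars) {
    f <- as.formula(paste("Surv(.t, .e) ~",
                          paste(sprintf("`%s`", vars), collapse = " + ")))
    withCallingHandlers(
      coxph(f, data = d, ties = "efron"),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  vars <- candidates
  fit <- fit_with(vars)
  if (policy == "backward_elimination") {
    repeat {
      ps <- summary(fit)$coefficients[, "Pr(>|z|)"]
      if (all(ps <= alpha) || length(vars) == 1L) break
      drop_var <- vars[which.max(ps)]
      vars <- setdiff(vars, drop_var)
      fit <- fit_with(vars)
    }
  }
  out <- extract_cox(fit, vars)
  out$coefficients$variable <- vars
  out$policy <- policy
  out$retained <- vars
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit: n = %d, events = %d%s\n",
              x$n, x$n_events,
              if (!is.null(x$policy)) paste0(" (", x$policy, ")") else ""))
  co <- x$coefficients
  for (i in seq_len(nrow(co))) {
    cat(sprintf("  %-28s HR %.3g (95%% CI %.3g-%.3g), p = %.3g\n",
                co$variable[i], co$hr[i], co$ci_low[i], co$ci_high[i],
                co$p[i]))
  }
  cat(sprintf("  model likelihood-ratio p = %.3g\n", x$model_p))
  if (x$flagged) cat("  !", x$diagnostics, "\n")
  invisible(x)
}
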