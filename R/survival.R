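#' Kaplan-Meier estimate with Greenwood standard errors
#'
#' Product-limit estimator of the survival function, with Greenwood variance
#' at each event time. Wraps [survival::survfit()].
#'
#' @param times positive event/censoring times.
#' @param events event indicator (1 = event, 0 = censored).
#' @return An object of class `jip_km`: list with `time`, `surv` (step
#'   values), `se` (Greenwood), `n_risk`, `n_event` and an `estimate(t)`
#'   function returning S(t).
#' @export
km_estimate <- function(times, events) {
  if (length(times) < 1L) stop("need at least one observation")
  if (any(times <= 0)) stop("non-positive times")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = "plain")
  est <- stats::stepfun(sf$time, c(1, sf$surv), right = FALSE)
  out <- list(time = sf$time, surv = sf$surv, se = sf$std.err * sf$surv,
              n_risk = sf$n.risk, n_event = sf$n.event, estimate = est)
  class(out) <- "jip_km"
  out
}

#' @export
print.jip_km <- function(x, ...) {
  cat("Kaplan-Meier estimate over", length(x$time), "time points; final S =",
      round(utils::tail(x$surv, 1), 4), "\n")
  invisible(x)
}

#' Log-rank test for survival differences between groups
#'
#' Standard observed-minus-expected statistic over pooled event times,
#' `df = groups - 1`. Wraps [survival::survdiff()].
#'
#' @param times,events as in [km_estimate()].
#' @param group group label per observation (>= 2 groups).
#' @return list with `statistic`, `df`, `p`.
#' @export
logrank_test <- function(times, events, group) {
  if (length(unique(group)) < 2L) stop("need at least 2 groups")
  if (sum(events) < 1L) stop("no events")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- length(sd$n) - 1L
  list(statistic = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood maximisation (Newton-Raphson, Efron tie handling by
#' default) via [survival::coxph()], returning hazard ratios with Wald 95%
#' confidence intervals.
#'
#' @param data data.frame with columns `time`, `event` and covariates (e.g.
#'   from [mtx_survival()]).
#' @param formula right-hand side or full formula; e.g. `~ group` or
#'   `Surv(time, event) ~ group + age`.
#' @param ties `"efron"` or `"breslow"`.
#' @return An object of class `jip_cox`: list with `coef`, `se`, `hr`,
#'   `ci_lower`, `ci_upper`, `p`, `loglik` (null, fitted), `n`, `n_event`,
#'   `ties`, and the underlying `coxph` fit.
#' @export
cox_fit <- function(data, formula = ~ group, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(data$event) < 1L) stop("no events in the data")
  if (length(formula) == 2L) {
    formula <- stats::as.formula(paste("survival::Surv(time, event)",
                                       paste(deparse(formula), collapse = "")))
  }
  fit <- withCallingHandlers(
    survival::coxph(formula, data = data, ties = ties,
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations",
                conditionMessage(w))) {
        stop("divergence error (monotone likelihood / separation): ",
             conditionMessage(w), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  out <- list(coef = stats::coef(fit),
              se = s$coefficients[, "se(coef)"],
              hr = exp(stats::coef(fit)),
              ci_lower = s$conf.int[, "lower .95"],
              ci_upper = s$conf.int[, "upper .95"],
              p = s$coefficients[, "Pr(>|z|)"],
              loglik = fit$loglik, n = fit$n, n_event = fit$nevent,
              ties = ties, coxph = fit)
  class(out) <- "jip_cox"
  out
}

#' @export
print.jip_cox <- function(x, ...) {
  cat("Cox proportional hazards fit (", x$ties, " ties): ",
      x$n, " subjects, ", x$n_event, " events\n", sep = "")
  df <- data.frame(coef = round(x$coef, 4), HR = round(x$hr, 3),
                   lower95 = round(x$ci_lower, 3),
                   upper95 = round(x$ci_upper, 3),
                   p = signif(x$p, 3))
  print(df)
  invisible(x)
}

#' Likelihood-ratio comparison of nested Cox models
#'
#' The "ANOVA" for Cox models: twice the difference in maximised partial
#' log-likelihood, chi-square with df equal to the difference in parameter
#' count. Used to quantify the informative value of cluster labels beyond
#' known covariates.
#'
#' @param nested,full `jip_cox` fits on the same data, `nested` a submodel
#'   of `full`.
#' @return list with `statistic`, `df`, `p`.
#' @export
cox_lrt <- function(nested, full) {
  stopifnot(inherits(nested, "jip_cox"), inherits(full, "jip_cox"))
  if (nested$n != full$n || nested$n_event != full$n_event) {
    stop("models were not fitted on the same data")
  }
  tn <- attr(stats::terms(nested$coxph), "term.labels")
  tf <- attr(stats::terms(full$coxph), "term.labels")
  if (!all(tn %in% tf)) stop("models are not nested")
  df <- length(full$coef) - length(nested$coef)
  if (df < 0L) stop("models are not nested")
  stat <- max(0, 2 * (full$loglik[2] - nested$loglik[2]))
  list(statistic = stat, df = df,
       p = if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Schoenfeld-residual test of proportional hazards
#'
#' Grambsch-Therneau style test: correlation of the scaled Schoenfeld
#' residuals with event rank time, per covariate. Wraps
#' [survival::cox.zph()] with the rank time transform.
#'
#' @param fit a `jip_cox`.
#' @return data.frame with one row per covariate (plus GLOBAL): `chisq`,
#'   `df`, `p`.
#' @export
schoenfeld_ph_test <- function(fit) {
  stopifnot(inherits(fit, "jip_cox"))
  if (fit$n_event < 3L) stop("need at least 3 events")
  z <- survival::cox.zph(fit$coxph, transform = "rank")
  data.frame(covariate = rownames(z$table), chisq = z$table[, "chisq"],
             df = z$table[, "df"], p = z$table[, "p"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-year remission status by last observation carried forward
#'
#' Carries the last DAS44 value observed on or before the horizon forward to
#' the horizon: remission is that value below 1.6. The first day a value
#' below 1.6 was observed is also reported (time-to-event reading); both are
#' returned because a patient can dip below 1.6 and relapse before the
#' horizon.
#'
#' @param days visit days, sorted increasing.
#' @param values DAS44 values at those days.
#' @param horizon horizon in days (default 365).
#' @return list with `remission` (logical; `NA` if no observation before the
#'   horizon), `time` (first day with DAS44 < 1.6, `NA` if never) and
#'   `das_locf` (the carried-forward value).
#' @export
locf_remission <- function(days, values, horizon = 365) {
  keep <- !is.na(days) & !is.na(values)
  days <- days[keep]; values <- values[keep]
  if (length(days) == 0L) {
    return(list(remission = NA, time = NA_real_, das_locf = NA_real_))
  }
  if (is.unsorted(days)) stop("das series must be sorted by day")
  before <- which(days <= horizon)
  if (length(before) == 0L) {
    return(list(remission = NA, time = NA_real_, das_locf = NA_real_))
  }
  locf <- values[max(before)]
  below <- which(values < 1.6 & days <= horizon)
  list(remission = locf < 1.6,
       time = if (length(below) > 0L) days[min(below)] else NA_real_,
       das_locf = locf)
}

#' Cohort-level one-year remission fractions
#'
#' Applies [locf_remission()] to every patient's stored DAS series.
#'
#' @param cohort a `jip_cohort` with `das_day_*`/`das_val_*` columns.
#' @param horizon horizon in days.
#' @return data.frame with `patient_id`, `remission`, `time`, `das_locf`.
#' @export
cohort_remission <- function(cohort, horizon = 365) {
  d <- cohort$data
  day_cols <- sort(grep("^das_day_", names(d), value = TRUE))
  val_cols <- sub("day", "val", day_cols)
  if (length(day_cols) == 0L) stop("cohort has no DAS series columns")
  days_m <- as.matrix(d[, day_cols, drop = FALSE])
  vals_m <- as.matrix(d[, val_cols, drop = FALSE])
  ok <- !is.na(days_m) & !is.na(vals_m) & days_m <= horizon
  last_col <- apply(ok, 1L, function(r) if (any(r)) max(which(r)) else NA_integer_)
  locf <- vals_m[cbind(seq_len(nrow(d)), last_col)]
  below <- ok & vals_m < 1.6
  first_col <- apply(below, 1L, function(r) if (any(r)) min(which(r)) else NA_integer_)
  t_first <- days_m[cbind(seq_len(nrow(d)), first_col)]
  data.frame(patient_id = d$patient_id,
             remission = locf < 1.6,
             time = t_first,
             das_locf = locf,
             stringsAsFactors = FALSE)
}

#' Pearson chi-square test for a cross-tabulation
#'
#' Without continuity correction; `df = (r-1)(c-1)`.
#'
#' @param table r x c matrix of counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi2_crosstab <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate margins")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}
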