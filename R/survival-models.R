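#' Kaplan-Meier curve
#'
#' Product-limit estimate of disease-free survival. The median is the
#' earliest time at which the survival curve drops to 0.5 or below;
#' undefined (NA) when the curve never reaches 0.5 (e.g. all-censored
#' input).
#'
#' @param time Non-negative follow-up times (months).
#' @param event 0/1 event indicators (1 = recurrence).
#' @return Object of class `km_curve`: list with `time` (all distinct
#'   follow-up times), `surv`, `n_risk`, `n_event`, `n_censor`,
#'   `event_times` (times with at least one event) and `median`.
#' @export
km_fit <- function(time, event) {
  if (!length(time)) stop("need at least one sample", call. = FALSE)
  if (any(time < 0)) stop("times must be non-negative", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- if (any(sf$surv <= 0.5)) min(sf$time[sf$surv <= 0.5]) else NA_real_
  structure(list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                 n_event = sf$n.event, n_censor = sf$n.censor,
                 event_times = sf$time[sf$n.event > 0], median = med,
                 n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d, median = %s months\n",
              x$n, sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Log-rank test across two or more groups
#'
#' Standard observed-minus-expected log-rank statistic with hypergeometric
#' variance and `k - 1` degrees of freedom.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param group Group labels (>= 2 non-empty groups required).
#' @return List with `chi_square`, `df`, `p_value`, `n` and the per-group
#'   observed/expected event table.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2) {
    stop("log-rank test needs at least 2 non-empty groups", call. = FALSE)
  }
  if (length(unique(c(length(time), length(event), length(group)))) != 1) {
    stop("time, event and group lengths differ", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  df <- nlevels(group) - 1L
  list(chi_square = unname(sd$chisq), df = df,
       p_value = pchisq(sd$chisq, df, lower.tail = FALSE),
       n = length(time),
       table = data.frame(group = levels(group), n = as.vector(sd$n),
                          observed = sd$obs, expected = sd$exp))
}

# Table-1-style dichotomised design matrix from a clinical table
.clinical_design <- function(clinical) {
  data.frame(
    age_gt50     = as.integer(clinical$age_years > 50),
    male         = as.integer(clinical$gender == "male"),
    stage_iii_iv = as.integer(clinical$stage %in% c("III", "IV")),
    t3_t4        = as.integer(clinical$t_stage %in% c("T3", "T4")),
    n1           = as.integer(clinical$n_stage == "N1"),
    row.names = NULL
  )
}

#' Cox proportional-hazards fit
#'
#' Maximum partial likelihood via [survival::coxph()] with the Efron
#' approximation for tied event times and Wald 95% confidence intervals
#' (log HR +/- 1.96 SE), matching the usual "HR (95% CI)" presentation.
#' Rows with missing covariates are dropped and the number of patients used
#' is reported.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param covariates Data frame of numeric covariates (binary covariates
#'   coded 0/1); one column per model term.
#' @return Object of class `cox_result`: data frame `coefficients` with
#'   `term`, `log_hr`, `hr`, `se`, `ci95_low`, `ci95_high`, `p_value`, plus
#'   `model` ("univariate"/"multivariate"), `n_used`, `n_events`,
#'   `score_test` (chi-square of the score test at beta = 0) and
#'   `flagged` (possible monotone-likelihood/separation warning).
#' @export
cox_fit <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  if (!ncol(covariates)) stop("no covariates supplied", call. = FALSE)
  if (!all(vapply(covariates, is.numeric, logical(1)))) {
    stop("covariates must be numeric (code binary covariates 0/1)",
         call. = FALSE)
  }
  dat <- data.frame(.time = time, .event = event, covariates,
                    check.names = FALSE)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n_used <- nrow(dat)
  if (sum(dat$.event) < 1) stop("no events in data", call. = FALSE)
  const <- vapply(dat[, -(1:2), drop = FALSE],
                  function(x) length(unique(x)) == 1L, logical(1))
  if (any(const)) {
    stop("constant covariate(s): ",
         paste(names(const)[const], collapse = ", "), call. = FALSE)
  }
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ .,
                    data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  s <- summary(fit)
  beta <- fit$coefficients
  se <- sqrt(diag(fit$var))
  coefs <- data.frame(
    term = names(beta),
    log_hr = unname(beta),
    hr = exp(unname(beta)),
    se = unname(se),
    ci95_low = exp(unname(beta) - 1.96 * unname(se)),
    ci95_high = exp(unname(beta) + 1.96 * unname(se)),
    p_value = 2 * pnorm(-abs(unname(beta) / unname(se))),
    stringsAsFactors = FALSE
  )
  if (flagged) {
    # monotone likelihood: Wald intervals are unreliable -> report unbounded
    huge <- abs(coefs$log_hr) > 15 | coefs$se > 1e3
    coefs$ci95_low[huge] <- 0
    coefs$ci95_high[huge] <- Inf
  }
  structure(list(
    coefficients = coefs,
    model = if (ncol(covariates) == 1) "univariate" else "multivariate",
    n_used = n_used, n_events = sum(dat$.event),
    score_test = unname(s$sctest["test"]),
    loglik = fit$loglik, flagged = flagged
  ), class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> %s model, n = %d (%d events)%s\n", x$model,
              x$n_used, x$n_events,
              if (x$flagged) " [flagged: possible separation]" else ""))
  df <- x$coefficients
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-14s HR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
                df$term[i], df$hr[i], df$ci95_low[i], df$ci95_high[i],
                df$p_value[i]))
  }
  invisible(x)
}
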