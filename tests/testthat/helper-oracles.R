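# Independent oracles used to check the package's primitives. These are
# deliberately naive (brute force / enumeration) and share no code with the
# implementation.

# AUC by exhaustive case-control pair counting, ties scored one half
oracle_auc <- function(marker, outcome) {
  cases <- marker[outcome == 1]
  ctrls <- marker[outcome == 0]
  total <- 0
  for (a in cases) {
    for (b in ctrls) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(cases) * length(ctrls))
}

# maximum Youden J over every threshold (midpoints of adjacent distinct
# values plus infinite sentinels), after orienting the marker so its AUC is
# at least 0.5 (the cutpoint definition fixes the orientation by AUC first)
oracle_max_j <- function(marker, outcome) {
  m <- if (oracle_auc(marker, outcome) >= 0.5) marker else -marker
  u <- sort(unique(m))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- -Inf
  for (cc in cand) {
    sens <- mean(m[outcome == 1] > cc)
    spec <- mean(m[outcome == 0] <= cc)
    best <- max(best, sens + spec - 1)
  }
  best
}

# two-sided exact Mann-Whitney p by complete enumeration of group
# assignments, extremeness as |U - E[U]|
oracle_mw_exact <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * length(y) / 2
  sets <- combn(n, nx)
  u_all <- apply(sets, 2, function(s) sum(r[s]) - nx * (nx + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# hand product-limit estimator at the event times
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

# Cox partial log-likelihood for one covariate, no ties
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

# small expression matrix with one tumour sample per patient
make_expr <- function(values, gene_ids = NULL, patient_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) {
    gene_ids <- rownames(values)
    if (is.null(gene_ids)) gene_ids <- sprintf("g%d", seq_len(nrow(values)))
  }
  if (is.null(patient_ids)) patient_ids <- sprintf("p%d", seq_len(ncol(values)))
  dimnames(values) <- list(gene_ids, paste0(patient_ids, "-T"))
  expr_matrix(values, data.frame(sample_id = colnames(values),
                                 patient_id = patient_ids,
                                 sample_type = "tumour"))
}

# minimal valid clinical table
make_clinical <- function(n, dfs = NULL, event = NULL,
                          rai = TRUE, braf = TRUE) {
  data.frame(
    patient_id = sprintf("p%d", seq_len(n)),
    dfs_months = if (is.null(dfs)) seq_len(n) else dfs,
    recurrence_event = if (is.null(event)) rep_len(c(0, 1), n) else event,
    age_years = rep_len(c(40, 60), n),
    gender = rep_len(c("female", "male"), n),
    stage = rep_len(c("I", "III"), n),
    t_stage = rep_len(c("T1", "T3"), n),
    n_stage = rep_len(c("N0", "N1"), n),
    rai_treated = rep_len(rai, n),
    braf_like = rep_len(braf, n),
    braf_mutation = rep_len(c(TRUE, FALSE), n),
    stringsAsFactors = FALSE
  )
}
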