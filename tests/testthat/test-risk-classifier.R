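# build a minimal delta table / cutoff table / calls / clinical quadruple
make_panel_inputs <- function(calls, event, deltas = NULL) {
  genes <- colnames(calls)
  if (is.null(deltas)) deltas <- seq(0.9, 0.4, length.out = length(genes))
  delta <- data.frame(gene_id = genes, delta_vs_ref1 = deltas,
                      delta_vs_ref2 = deltas, mean_delta = deltas,
                      selected = deltas >= 0.3, stringsAsFactors = FALSE)
  cutoffs <- data.frame(gene_id = genes, cutoff = 0,
                        risk_direction = "high_is_risk", auc = 0.7,
                        youden_j = 0.3, stringsAsFactors = FALSE)
  clinical <- make_clinical(nrow(calls), event = event)
  clinical$patient_id <- rownames(calls)
  list(delta = delta, cutoffs = cutoffs, clinical = clinical)
}

test_that("a single candidate size forces the full selected panel", {
  set.seed(15)
  calls <- matrix(rbinom(40 * 6, 1, 0.4), nrow = 40,
                  dimnames = list(sprintf("p%02d", 1:40), sprintf("g%d", 1:6)))
  inp <- make_panel_inputs(calls, event = rbinom(40, 1, 0.4))
  clf <- build_classifier(inp$delta, inp$cutoffs, calls, inp$clinical,
                          panel_sizes = 6)
  expect_setequal(clf$panel$gene_id, colnames(calls))
  expect_true(clf$high_risk_threshold >= 0 &&
                clf$high_risk_threshold <= nrow(clf$panel) + 1)
})

test_that("a perfect single-gene marker yields a perfect one-gene classifier", {
  set.seed(16)
  event <- rbinom(50, 1, 0.5)
  calls <- cbind(g1 = event, g2 = rbinom(50, 1, 0.5))
  rownames(calls) <- sprintf("p%02d", 1:50)
  inp <- make_panel_inputs(calls, event, deltas = c(0.9, 0.5))
  clf <- build_classifier(inp$delta, inp$cutoffs, calls, inp$clinical,
                          panel_sizes = 1)
  expect_identical(clf$panel$gene_id, "g1")
  scored <- score_patients(clf, calls)
  expect_equal(roc_auc(scored$score, event), 1)
})

test_that("no selected genes is an error", {
  calls <- cbind(g1 = rep(0L, 10))
  rownames(calls) <- sprintf("p%d", 1:10)
  inp <- make_panel_inputs(calls, event = rep_len(c(0, 1), 10),
                           deltas = 0.1)
  expect_error(build_classifier(inp$delta, inp$cutoffs, calls, inp$clinical),
               "no genes selected")
})

test_that("risk scores count dysregulated panel genes and saturate correctly", {
  calls <- matrix(c(1, 1, 0,
                    0, 1, 0,
                    0, 0, 0), nrow = 3, byrow = TRUE,
                  dimnames = list(c("pa", "pb", "pc"), c("g1", "g2", "g3")))
  clf <- structure(list(panel = data.frame(gene_id = c("g1", "g2", "g3")),
                        high_risk_threshold = 2L), class = "risk_classifier")
  sc <- score_patients(clf, calls)
  expect_identical(sc$score, c(2L, 1L, 0L))
  expect_identical(as.character(sc$risk_group), c("high", "low", "low"))
  all_ones <- matrix(1L, 2, 3, dimnames = list(c("x", "y"),
                                               c("g1", "g2", "g3")))
  expect_true(all(score_patients(clf, all_ones)$risk_group == "high"))
  zero <- matrix(0L, 2, 3, dimnames = dimnames(all_ones))
  expect_true(all(score_patients(clf, zero)$risk_group == "low"))
  expect_error(score_patients(clf, calls[, 1:2]), "g3")
})

test_that("adding a dysregulated call never lowers a score or demotes a patient", {
  set.seed(17)
  calls <- matrix(rbinom(30 * 5, 1, 0.3), nrow = 30,
                  dimnames = list(sprintf("p%02d", 1:30), sprintf("g%d", 1:5)))
  clf <- structure(list(panel = data.frame(gene_id = colnames(calls)),
                        high_risk_threshold = 2L), class = "risk_classifier")
  before <- score_patients(clf, calls)
  zero_cells <- which(calls == 0L)
  flip <- zero_cells[sample(length(zero_cells), 10)]
  calls2 <- calls
  calls2[flip] <- 1L
  after <- score_patients(clf, calls2)
  expect_true(all(after$score >= before$score))
  expect_false(any(before$risk_group == "high" & after$risk_group == "low"))
})

test_that("evaluation reports perfect metrics for an oracle score and skips degenerate groupings", {
  set.seed(18)
  n <- 80
  event <- rbinom(n, 1, 0.4)
  calls <- cbind(g1 = as.integer(event))
  rownames(calls) <- sprintf("p%02d", 1:n)
  clin <- make_clinical(n, event = event,
                        dfs = ifelse(event == 1, runif(n, 1, 12),
                                     runif(n, 24, 60)))
  clin$patient_id <- rownames(calls)
  clf <- structure(list(panel = data.frame(gene_id = "g1"),
                        high_risk_threshold = 1L), class = "risk_classifier")
  ev <- evaluate_classifier(clf, calls, clin)
  expect_equal(ev$auc_score, 1)
  expect_lt(ev$logrank$p_value, 1e-6)
  expect_false(ev$skipped)

  clin$recurrence_event <- rep(c(1, 0), length.out = n)
  zero <- calls; zero[, 1] <- 0L
  ev2 <- evaluate_classifier(clf, zero, clin)
  expect_true(ev2$skipped)
  expect_match(ev2$diagnostic, "degenerate")
})

test_that("a null-effect evaluation gives chance AUC and a CI covering 1", {
  co <- generate_cohort(simulation_config(n_patients = 600,
                                          per_gene_hazard_log_hr = 0,
                                          covariate_effects = NULL,
                                          seed = 19))
  calls <- call_dysregulation(
    co$expression,
    data.frame(gene_id = co$truth$risk_gene_ids, cutoff = 8,
               risk_direction = "high_is_risk", auc = 0.5, youden_j = 0,
               stringsAsFactors = FALSE))
  clf <- structure(list(panel = data.frame(gene_id = co$truth$risk_gene_ids),
                        high_risk_threshold = 5L), class = "risk_classifier")
  ev <- evaluate_classifier(clf, calls, co$clinical)
  expect_lt(abs(ev$auc_score - 0.5), 0.07)
  hr <- ev$cox_multivariate$coefficients
  hr <- hr[hr$term == "risk_high", ]
  expect_true(hr$ci95_low <= 1 && 1 <= hr$ci95_high)
})

test_that("single-gene baselines are oriented (all AUC >= 0.5) and sorted", {
  co <- generate_cohort(simulation_config(n_patients = 300, seed = 20))
  cuts <- gene_cutoffs(co$expression, co$clinical,
                       genes = co$truth$risk_gene_ids)
  sg <- single_gene_baselines(co$expression, cuts, co$clinical)
  expect_true(all(sg$auc >= 0.5))
  expect_true(!is.unsorted(rev(sg$auc)))
})

test_that("dual-gene stratification reduces to single-gene when one gene is silent", {
  set.seed(21)
  n <- 60
  vals <- rbind(ga = rnorm(n), gb = rnorm(n))
  ex <- make_expr(vals, patient_ids = sprintf("p%02d", 1:n))
  cuts <- data.frame(gene_id = c("ga", "gb"), cutoff = c(0, 1e9),
                     risk_direction = "high_is_risk", auc = 0.6,
                     youden_j = 0.2, stringsAsFactors = FALSE)
  clin <- make_clinical(n, dfs = runif(n, 1, 40), event = rbinom(n, 1, 0.5))
  clin$patient_id <- sprintf("p%02d", 1:n)
  ds <- dual_gene_stratification(ex, "ga", "gb", cuts, clin)
  expect_match(ds$diagnostic, "empty group")
  single <- logrank_test(clin$dfs_months, clin$recurrence_event,
                         ifelse(vals["ga", ] > 0, "high", "low"))
  expect_equal(ds$logrank_overall$chi_square, single$chi_square,
               tolerance = 1e-10)
})

test_that("doubly dysregulated planted risk genes mark the highest-recurrence group", {
  co <- generate_cohort(simulation_config(n_patients = 500, seed = 22))
  rg <- co$truth$risk_gene_ids[1:2]
  cuts <- gene_cutoffs(co$expression, co$clinical, genes = rg)
  ds <- dual_gene_stratification(co$expression, rg[1], rg[2], cuts,
                                 co$clinical)
  rates <- vapply(names(ds$km), function(g) {
    sel <- ds$groups == g
    mean(co$clinical$recurrence_event[match(names(ds$groups)[sel],
                                            co$clinical$patient_id)])
  }, numeric(1))
  expect_identical(names(which.max(rates)), "high/high")
})

test_that("overall dual-gene log-rank p-values are uniform under the null", {
  set.seed(23)
  ps <- replicate(200, {
    n <- 120
    vals <- rbind(ga = rnorm(n), gb = rnorm(n))
    ex <- make_expr(vals, patient_ids = sprintf("q%03d", 1:n))
    cuts <- data.frame(gene_id = c("ga", "gb"), cutoff = 0,
                       risk_direction = "high_is_risk", auc = 0.5,
                       youden_j = 0, stringsAsFactors = FALSE)
    clin <- make_clinical(n, dfs = rexp(n, 0.05), event = rbinom(n, 1, 0.6))
    clin$patient_id <- sprintf("q%03d", 1:n)
    dual_gene_stratification(ex, "ga", "gb", cuts, clin)$logrank_overall$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("training AUC does not trail validation AUC by more than the optimism margin", {
  co <- generate_cohort(simulation_config(seed = 24))
  pipe <- run_pipeline(co$expression, co$clinical, seed = 24)
  ev_train <- evaluate_classifier(pipe$classifier, pipe$calls, pipe$clinical)
  co_val <- generate_cohort(simulation_config(seed = 1024))
  calls_val <- call_dysregulation(co_val$expression, pipe$cutoffs)
  ev_val <- evaluate_classifier(pipe$classifier, calls_val, co_val$clinical)
  expect_gte(ev_train$auc_score, ev_val$auc_score - 0.05)
})
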