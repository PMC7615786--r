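# Youden-optimal integer threshold on a count score: label high when
# score >= t; ties in J broken toward fewer high-risk patients (larger t).
.integer_threshold <- function(score, outcome) {
  cand <- 0:(max(score) + 1L)
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  j <- vapply(cand, function(t) {
    sum(score >= t & outcome == 1) / n1 + sum(score < t & outcome == 0) / n0 - 1
  }, numeric(1))
  cand[max(which(j >= max(j) - 1e-12))]
}

# event-stratified fold assignment; returns integer vector of folds
.stratified_folds <- function(outcome, n_folds, seed) {
  set.seed(seed)
  folds <- integer(length(outcome))
  for (cls in unique(outcome)) {
    idx <- sample(which(outcome == cls))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Build a multigene risk-score classifier
#'
#' Ranks delta-EG-selected genes by decreasing mean delta (ties by gene
#' identifier), then picks the panel size from `panel_sizes` that maximises
#' the cross-validated AUC of the count score (number of dysregulated panel
#' genes) for recurrence, using event-stratified folds. The high/low risk
#' threshold is the Youden-optimal integer cutoff on the training scores,
#' with ties broken toward fewer high-risk patients.
#'
#' @param delta_results Data frame from [delta_eg()].
#' @param cutoffs Cutoff table from [gene_cutoffs()] (frozen training
#'   cutpoints; carried into the classifier).
#' @param calls Binary call matrix of the training cohort.
#' @param clinical Training clinical table.
#' @param panel_sizes Candidate panel sizes (default `c(10, 20, 30, 40)`;
#'   sizes exceeding the number of selected genes are clamped to it, so the
#'   full selected set is always a valid candidate).
#' @param n_folds Number of cross-validation folds (default 5).
#' @param seed Seed for fold assignment.
#' @return Object of class `risk_classifier`: list with `panel` (data frame
#'   of panel genes with cutpoints, directions and mean deltas),
#'   `high_risk_threshold`, `cv` (per-size mean CV AUC) and
#'   `training_cohort_id`.
#' @export
build_classifier <- function(delta_results, cutoffs, calls, clinical,
                             panel_sizes = c(10, 20, 30, 40), n_folds = 5,
                             seed = 1L) {
  clinical <- validate_clinical(clinical)
  sel <- delta_results[delta_results$selected, , drop = FALSE]
  if (!nrow(sel)) stop("no genes selected by delta-EG", call. = FALSE)
  sel <- sel[order(-sel$mean_delta, sel$gene_id), , drop = FALSE]
  missing_g <- setdiff(sel$gene_id, colnames(calls))
  if (length(missing_g)) {
    stop("selected gene(s) absent from calls: ",
         paste(head(missing_g, 5), collapse = ", "), call. = FALSE)
  }
  panel_sizes <- sort(unique(pmin(panel_sizes, nrow(sel))))
  patients <- rownames(calls)
  outcome <- clinical$recurrence_event[match(patients, clinical$patient_id)]
  if (anyNA(outcome)) {
    stop("calls contain patients missing from the clinical table",
         call. = FALSE)
  }

  cv_auc <- rep(NA_real_, length(panel_sizes))
  if (length(panel_sizes) > 1) {
    folds <- NULL
    for (attempt in seq_len(3)) {
      cand <- .stratified_folds(outcome, n_folds, seed + attempt - 1L)
      ok <- all(vapply(seq_len(n_folds), function(f) {
        length(unique(outcome[cand == f])) == 2
      }, logical(1)))
      if (ok) { folds <- cand; break }
    }
    if (is.null(folds)) {
      stop("could not build folds with both outcome classes after 3 attempts",
           call. = FALSE)
    }
    for (i in seq_along(panel_sizes)) {
      genes_m <- sel$gene_id[seq_len(panel_sizes[i])]
      score <- rowSums(calls[, genes_m, drop = FALSE])
      aucs <- vapply(seq_len(n_folds), function(f) {
        roc_auc(score[folds == f], outcome[folds == f])
      }, numeric(1))
      cv_auc[i] <- mean(aucs)
    }
    best_m <- panel_sizes[which.max(cv_auc)]
  } else {
    best_m <- panel_sizes[1]
  }

  panel_genes <- sel$gene_id[seq_len(best_m)]
  panel <- merge(data.frame(gene_id = panel_genes, stringsAsFactors = FALSE),
                 cutoffs, by = "gene_id", sort = FALSE)
  panel$mean_delta <- sel$mean_delta[match(panel$gene_id, sel$gene_id)]
  panel <- panel[order(-panel$mean_delta, panel$gene_id), , drop = FALSE]
  rownames(panel) <- NULL
  if (nrow(panel) != best_m) {
    stop("panel gene(s) missing from the cutoff table", call. = FALSE)
  }
  score <- rowSums(calls[, panel$gene_id, drop = FALSE])
  threshold <- .integer_threshold(score, outcome)
  structure(list(
    panel = panel, high_risk_threshold = threshold,
    cv = data.frame(panel_size = panel_sizes, cv_auc = cv_auc),
    training_cohort_id = sprintf("n%d-e%d", length(patients), sum(outcome))
  ), class = "risk_classifier")
}

#' @export
print.risk_classifier <- function(x, ...) {
  cat(sprintf("<risk_classifier> %d-gene panel, high risk at score >= %d (training cohort %s)\n",
              nrow(x$panel), x$high_risk_threshold, x$training_cohort_id))
  invisible(x)
}

#' Score patients with a risk classifier
#'
#' The risk score is the number of panel genes called dysregulated; patients
#' with score at or above the classifier threshold are labelled high risk.
#'
#' @param classifier A [build_classifier()] result.
#' @param calls Binary call matrix containing every panel gene.
#' @return Data frame with `patient_id`, `score` and `risk_group`
#'   (`"high"`/`"low"`).
#' @export
score_patients <- function(classifier, calls) {
  missing_g <- setdiff(classifier$panel$gene_id, colnames(calls))
  if (length(missing_g)) {
    stop("panel gene(s) absent from calls: ",
         paste(head(missing_g, 5), collapse = ", "), call. = FALSE)
  }
  score <- rowSums(calls[, classifier$panel$gene_id, drop = FALSE])
  data.frame(patient_id = rownames(calls), score = as.integer(score),
             risk_group = factor(ifelse(score >= classifier$high_risk_threshold,
                                        "high", "low"),
                                 levels = c("low", "high")),
             stringsAsFactors = FALSE)
}

#' Evaluate a risk classifier on a cohort
#'
#' Computes the AUC of the risk score (continuous count and binary label)
#' for recurrence, Kaplan-Meier curves and a log-rank test for high versus
#' low risk, a univariate Cox model on the risk group and a multivariate
#' Cox model adding the dichotomised clinical covariates (age > 50, male,
#' stage III+IV, T3+T4, N1). Covariates constant within the evaluated
#' cohort are dropped from the multivariate model with a note.
#'
#' @param classifier A [build_classifier()] result.
#' @param calls Binary call matrix for the cohort to evaluate.
#' @param clinical Clinical table for the same cohort.
#' @param cohort_filter Optional character vector of [filter_cohort()]
#'   names applied to `clinical` before evaluation.
#' @return Object of class `classifier_evaluation`, or a degenerate result
#'   with `skipped = TRUE` and a diagnostic when all patients fall in one
#'   risk group.
#' @export
evaluate_classifier <- function(classifier, calls, clinical,
                                cohort_filter = NULL) {
  clinical <- validate_clinical(clinical)
  if (!is.null(cohort_filter)) clinical <- filter_cohort(clinical, cohort_filter)
  patients <- intersect(rownames(calls), clinical$patient_id)
  if (!length(patients)) stop("no patients left after filtering", call. = FALSE)
  calls <- calls[patients, , drop = FALSE]
  clinical <- clinical[match(patients, clinical$patient_id), , drop = FALSE]
  scored <- score_patients(classifier, calls)
  high <- scored$risk_group == "high"
  out <- list(n = length(patients), n_events = sum(clinical$recurrence_event),
              n_high = sum(high), cohort_filter = cohort_filter,
              scores = scored, skipped = FALSE, diagnostic = NULL)
  if (length(unique(scored$risk_group)) < 2 ||
      length(unique(clinical$recurrence_event)) < 2) {
    out$skipped <- TRUE
    out$diagnostic <- "degenerate risk grouping or single-class outcome; evaluation skipped"
    return(structure(out, class = "classifier_evaluation"))
  }
  out$auc_score <- roc_auc(scored$score, clinical$recurrence_event)
  out$auc_label <- roc_auc(as.integer(high), clinical$recurrence_event)
  out$km_high <- km_fit(clinical$dfs_months[high],
                        clinical$recurrence_event[high])
  out$km_low <- km_fit(clinical$dfs_months[!high],
                       clinical$recurrence_event[!high])
  out$median_dfs_high_risk <- out$km_high$median
  out$logrank <- logrank_test(clinical$dfs_months, clinical$recurrence_event,
                              ifelse(high, "high", "low"))
  risk_high <- data.frame(risk_high = as.integer(high))
  out$cox_univariate <- cox_fit(clinical$dfs_months,
                                clinical$recurrence_event, risk_high)
  design <- cbind(risk_high, .clinical_design(clinical))
  const <- vapply(design, function(x) length(unique(x)) == 1L, logical(1))
  if (any(const)) {
    out$diagnostic <- paste("dropped constant covariate(s):",
                            paste(names(design)[const], collapse = ", "))
    design <- design[, !const, drop = FALSE]
  }
  out$cox_multivariate <- cox_fit(clinical$dfs_months,
                                  clinical$recurrence_event, design)
  structure(out, class = "classifier_evaluation")
}

#' @export
print.classifier_evaluation <- function(x, ...) {
  cat(sprintf("<classifier_evaluation> n = %d (%d events), %d high risk%s\n",
              x$n, x$n_events, x$n_high,
              if (!is.null(x$cohort_filter))
                paste0(" [", paste(x$cohort_filter, collapse = " & "), "]")
              else ""))
  if (x$skipped) {
    cat("  skipped:", x$diagnostic, "\n")
    return(invisible(x))
  }
  cat(sprintf("  AUC (score) %.3f | AUC (label) %.3f | log-rank p %.3g\n",
              x$auc_score, x$auc_label, x$logrank$p_value))
  cat(sprintf("  median DFS high risk: %s months\n",
              if (is.na(x$median_dfs_high_risk)) "not reached"
              else format(x$median_dfs_high_risk)))
  hr <- x$cox_multivariate$coefficients
  hr <- hr[hr$term == "risk_high", ]
  cat(sprintf("  multivariate HR (high vs low) %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              hr$hr, hr$ci95_low, hr$ci95_high, hr$p_value))
  invisible(x)
}

#' Single-gene classifier baselines
#'
#' AUC of each gene's oriented tumour expression (flipped so that the risk
#' direction scores high) for recurrence, as a baseline against the
#' multigene score.
#'
#' @param expr An [expr_matrix()].
#' @param cutoffs Cutoff table from [gene_cutoffs()] (supplies the risk
#'   directions).
#' @param clinical Clinical table.
#' @return Data frame with `gene_id` and `auc`, sorted by decreasing AUC.
#' @export
single_gene_baselines <- function(expr, cutoffs, clinical) {
  clinical <- validate_clinical(clinical)
  tv <- tumour_values(expr)
  patients <- intersect(rownames(tv), clinical$patient_id)
  tv <- tv[patients, , drop = FALSE]
  outcome <- clinical$recurrence_event[match(patients, clinical$patient_id)]
  if (length(unique(outcome)) < 2) {
    stop("outcome has a single class", call. = FALSE)
  }
  auc <- vapply(seq_len(nrow(cutoffs)), function(i) {
    m <- tv[, cutoffs$gene_id[i]]
    if (cutoffs$risk_direction[i] == "low_is_risk") m <- -m
    roc_auc(m, outcome)
  }, numeric(1))
  out <- data.frame(gene_id = cutoffs$gene_id, auc = auc,
                    stringsAsFactors = FALSE)
  out[order(-out$auc), , drop = FALSE]
}

#' Dual-gene stratification
#'
#' Partitions patients into four groups by the dysregulation calls of two
#' genes (high/high, high/low, low/high, low/low), fits Kaplan-Meier curves
#' per non-empty group, and runs an overall log-rank test plus a pairwise
#' test of the doubly dysregulated group against all others.
#'
#' @param expr An [expr_matrix()].
#' @param gene_a,gene_b Gene identifiers with rows in `cutoffs`.
#' @param cutoffs Cutoff table from [gene_cutoffs()].
#' @param clinical Clinical table.
#' @return List with `groups` (per-patient labels), `km` (list of
#'   `km_curve` per non-empty group), `logrank_overall`,
#'   `logrank_highhigh_vs_rest`; tests degenerate to `NULL` with a
#'   `diagnostic` when groups are empty.
#' @export
dual_gene_stratification <- function(expr, gene_a, gene_b, cutoffs, clinical) {
  clinical <- validate_clinical(clinical)
  idx <- match(c(gene_a, gene_b), cutoffs$gene_id)
  if (anyNA(idx)) {
    stop("no cutoff for gene(s): ",
         paste(c(gene_a, gene_b)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  calls <- call_dysregulation(expr, cutoffs[idx, , drop = FALSE])
  patients <- intersect(rownames(calls), clinical$patient_id)
  calls <- calls[patients, , drop = FALSE]
  clinical <- clinical[match(patients, clinical$patient_id), , drop = FALSE]
  lab <- paste(ifelse(calls[, gene_a] == 1, "high", "low"),
               ifelse(calls[, gene_b] == 1, "high", "low"), sep = "/")
  lab <- factor(lab, levels = c("high/high", "high/low", "low/high", "low/low"))
  present <- levels(lab)[table(lab) > 0]
  diagnostic <- if (length(present) < 4) {
    paste("empty group(s):", paste(setdiff(levels(lab), present), collapse = ", "))
  }
  km <- lapply(setNames(present, present), function(g) {
    sel <- lab == g
    km_fit(clinical$dfs_months[sel], clinical$recurrence_event[sel])
  })
  overall <- if (length(present) >= 2) {
    logrank_test(clinical$dfs_months, clinical$recurrence_event,
                 droplevels(lab))
  }
  hh <- if ("high/high" %in% present && length(present) >= 2) {
    logrank_test(clinical$dfs_months, clinical$recurrence_event,
                 ifelse(lab == "high/high", "high/high", "rest"))
  }
  list(groups = setNames(as.character(lab), patients), km = km,
       logrank_overall = overall, logrank_highhigh_vs_rest = hh,
       diagnostic = diagnostic)
}
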