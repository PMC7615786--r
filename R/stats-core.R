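#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false discovery rate adjustment (via
#' [stats::p.adjust()]) with input validation.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("p-values must be numeric", call. = FALSE)
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

# two-sided Mann-Whitney p-value: exact enumeration of group assignments for
# small samples (handles ties), tie-corrected normal approximation otherwise.
# Extremeness is measured as |U - n1*n2/2|.
.mann_whitney_p <- function(x, y, exact_max_n = 12) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (n <= exact_max_n) {
    sets <- combn(n, nx)
    u_all <- colSums(matrix(r[sets], nrow = nx)) - nx * (nx + 1) / 2
    return(mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
  }
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u_obs - mu) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Differential expression between two sample groups
#'
#' Per-gene mean log2 difference (group A minus group B) with a two-sided
#' Mann-Whitney U test (exact enumeration when the combined group size is at
#' most 12, tie-corrected normal approximation otherwise) and
#' Benjamini-Hochberg adjustment across genes.
#'
#' @param expr An [expr_matrix()].
#' @param group_a,group_b Disjoint character vectors of sample identifiers,
#'   each of size >= 2.
#' @return Data frame with `gene_id`, `log2_fc`, `p_value`, `q_value` and
#'   `constant` (flag: gene constant across both groups, p set to 1).
#' @export
differential_expression <- function(expr, group_a, group_b) {
  if (length(intersect(group_a, group_b))) {
    stop("groups must be disjoint", call. = FALSE)
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  missing_s <- setdiff(c(group_a, group_b), colnames(expr$values))
  if (length(missing_s)) {
    stop("unknown sample(s): ", paste(head(missing_s, 5), collapse = ", "),
         call. = FALSE)
  }
  A <- expr$values[, group_a, drop = FALSE]
  B <- expr$values[, group_b, drop = FALSE]
  genes <- rownames(expr$values)
  lfc <- rowMeans(A) - rowMeans(B)
  p <- numeric(length(genes))
  constant <- logical(length(genes))
  for (i in seq_along(genes)) {
    xs <- A[i, ]; ys <- B[i, ]
    if (length(unique(c(xs, ys))) == 1L) {
      p[i] <- 1
      constant[i] <- TRUE
    } else {
      p[i] <- .mann_whitney_p(xs, ys)
    }
  }
  data.frame(gene_id = genes, log2_fc = unname(lfc), p_value = p,
             q_value = bh_adjust(p), constant = constant,
             stringsAsFactors = FALSE)
}

#' Quartile stratification of one gene's expression
#'
#' Splits patients into low (Q1Q2) and high (Q3Q4) expression groups at the
#' median: values at or below the median are `low`, values above are `high`.
#' Ties at the median therefore fall into the low group.
#'
#' @param values Numeric vector of per-patient expression (length >= 4).
#' @return Factor with levels `low`, `high`, same length as `values`.
#' @export
quartile_stratify <- function(values) {
  if (length(values) < 4) {
    stop("quartile stratification needs at least 4 values", call. = FALSE)
  }
  med <- median(values)
  labels <- ifelse(values > med, "high", "low")
  if (all(labels == "low")) {
    warning("all values at or below the median; every patient labelled low")
  }
  factor(labels, levels = c("low", "high"))
}

#' Area under the ROC curve
#'
#' AUC of a continuous marker for a binary outcome, computed as the
#' normalised Mann-Whitney U statistic with ties counted one half.
#'
#' @param marker Numeric vector.
#' @param outcome Binary 0/1 vector (cases = 1); both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(marker, outcome) {
  if (length(marker) != length(outcome)) {
    stop("marker and outcome lengths differ", call. = FALSE)
  }
  if (!all(outcome %in% c(0, 1))) stop("outcome must be 0/1", call. = FALSE)
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: outcome has a single class", call. = FALSE)
  }
  r <- rank(marker)
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC-optimal (Youden) cutpoint for one marker
#'
#' Orients the marker so its AUC for the outcome is at least 0.5 (recording
#' whether high or low values carry risk), then maximises Youden's J
#' (sensitivity + specificity - 1) over all cutpoints placed at midpoints
#' between adjacent distinct marker values, plus infinite sentinels. A
#' patient is on the risk side when expression is strictly beyond the
#' cutpoint in the risk direction. Ties in J are broken toward the cutpoint
#' classifying fewer patients as high risk.
#'
#' @param marker Numeric vector (e.g. log2 expression of one gene).
#' @param outcome Binary 0/1 vector (recurrence = 1); both classes required.
#' @param gene_id Optional gene identifier carried into the result.
#' @return A one-row data frame (`gene_cutoff`): `gene_id`, `cutoff`,
#'   `risk_direction` (`"high_is_risk"`/`"low_is_risk"`), `auc` (oriented,
#'   >= 0.5) and `youden_j`.
#' @export
youden_cutoff <- function(marker, outcome, gene_id = NA_character_) {
  auc <- roc_auc(marker, outcome)
  if (auc >= 0.5) {
    dir <- "high_is_risk"; m <- marker
  } else {
    dir <- "low_is_risk"; m <- -marker; auc <- 1 - auc
  }
  u <- sort(unique(m))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  case <- m[outcome == 1]; ctrl <- m[outcome == 0]
  # counts strictly above each candidate, via cumulative counts at the
  # distinct values (candidates interleave the distinct values)
  n_case_le <- cumsum(tabulate(match(case, u), nbins = length(u)))
  n_ctrl_le <- cumsum(tabulate(match(ctrl, u), nbins = length(u)))
  sens <- c(1, 1 - n_case_le / length(case))           # aligned with cand
  spec <- c(0, n_ctrl_le / length(ctrl))
  j <- sens + spec - 1
  best <- max(j)
  pick <- max(which(j >= best - 1e-12))  # ties -> larger cutoff, fewer high-risk
  cutoff <- cand[pick]
  if (dir == "low_is_risk") cutoff <- -cutoff
  data.frame(gene_id = gene_id, cutoff = cutoff, risk_direction = dir,
             auc = auc, youden_j = best, stringsAsFactors = FALSE)
}

#' Per-gene ROC-optimal cutpoints against recurrence
#'
#' Applies [youden_cutoff()] to every gene's tumour expression with the
#' patients' recurrence events as outcome.
#'
#' @param expr An [expr_matrix()].
#' @param clinical Clinical table; only patients present in both inputs are
#'   used.
#' @param genes Optional subset of gene identifiers (default: all genes).
#' @return Data frame with one `gene_cutoff` row per gene.
#' @export
gene_cutoffs <- function(expr, clinical, genes = NULL) {
  clinical <- validate_clinical(clinical)
  tv <- tumour_values(expr)
  patients <- intersect(rownames(tv), clinical$patient_id)
  if (length(patients) < 4) {
    stop("need at least 4 patients with tumour samples and clinical data",
         call. = FALSE)
  }
  tv <- tv[patients, , drop = FALSE]
  outcome <- clinical$recurrence_event[match(patients, clinical$patient_id)]
  if (is.null(genes)) genes <- colnames(tv)
  missing_g <- setdiff(genes, colnames(tv))
  if (length(missing_g)) {
    stop("gene(s) absent from expression matrix: ",
         paste(head(missing_g, 5), collapse = ", "), call. = FALSE)
  }
  res <- lapply(genes, function(g) youden_cutoff(tv[, g], outcome, g))
  do.call(rbind, res)
}

#' Per-gene association of tumour expression with recurrence
#'
#' Two-sided Mann-Whitney U test of each gene's tumour expression between
#' recurrent and non-recurrent patients, with Benjamini-Hochberg adjustment
#' across genes. Used to restrict clustering and panel selection to
#' clinically relevant genes (those whose expression carries recurrence
#' signal).
#'
#' @param expr An [expr_matrix()].
#' @param clinical Clinical table; patients present in both inputs are used.
#' @return Data frame with `gene_id`, `auc` (oriented to >= 0.5), `p_value`
#'   and `q_value`.
#' @export
recurrence_relevance <- function(expr, clinical) {
  clinical <- validate_clinical(clinical)
  tv <- tumour_values(expr)
  patients <- intersect(rownames(tv), clinical$patient_id)
  tv <- tv[patients, , drop = FALSE]
  outcome <- clinical$recurrence_event[match(patients, clinical$patient_id)]
  if (length(unique(outcome)) < 2) {
    stop("outcome has a single class", call. = FALSE)
  }
  p <- vapply(seq_len(ncol(tv)), function(j) {
    .mann_whitney_p(tv[outcome == 1, j], tv[outcome == 0, j])
  }, numeric(1))
  auc <- vapply(seq_len(ncol(tv)), function(j) {
    a <- roc_auc(tv[, j], outcome)
    max(a, 1 - a)
  }, numeric(1))
  data.frame(gene_id = colnames(tv), auc = auc, p_value = p,
             q_value = bh_adjust(p), stringsAsFactors = FALSE)
}

#' Binary dysregulation calls
#'
#' A patient is called dysregulated for a gene when tumour expression lies
#' strictly beyond that gene's cutpoint on the risk side (above the cutoff
#' for `high_is_risk` genes, below it for `low_is_risk` genes). Expression
#' exactly at the cutoff is not called.
#'
#' @param expr An [expr_matrix()].
#' @param cutoffs Cutoff table from [gene_cutoffs()] (or rows of
#'   [youden_cutoff()] output).
#' @param patients Optional character vector of patients to call (default:
#'   all patients with a tumour sample).
#' @return Integer 0/1 matrix, patients x genes. Per-patient dysregulation
#'   counts are its row sums.
#' @export
call_dysregulation <- function(expr, cutoffs, patients = NULL) {
  tv <- tumour_values(expr, patients)
  missing_g <- setdiff(cutoffs$gene_id, colnames(tv))
  if (length(missing_g)) {
    stop("cutoff gene(s) absent from expression matrix: ",
         paste(head(missing_g, 5), collapse = ", "), call. = FALSE)
  }
  calls <- matrix(0L, nrow = nrow(tv), ncol = nrow(cutoffs),
                  dimnames = list(rownames(tv), cutoffs$gene_id))
  for (i in seq_len(nrow(cutoffs))) {
    g <- cutoffs$gene_id[i]
    x <- tv[, g]
    calls[, i] <- if (cutoffs$risk_direction[i] == "high_is_risk") {
      as.integer(x > cutoffs$cutoff[i])
    } else {
      as.integer(x < cutoffs$cutoff[i])
    }
  }
  calls
}
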