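#' Run the full dysregulation-to-risk-score pipeline on a cohort
#'
#' Convenience wrapper chaining the pipeline stages on one training cohort:
#' restriction to clinically relevant genes ([recurrence_relevance()]),
#' per-gene ROC cutpoints against recurrence ([gene_cutoffs()]), binary
#' dysregulation calls ([call_dysregulation()]), hierarchical clustering
#' ([cluster_patients()]), cluster frequencies ([cluster_frequencies()]),
#' automatic choice of the high-recurrence target subcluster and
#' low-recurrence references ([select_contrast()]), delta-EG gene selection
#' ([delta_eg()]) and classifier construction ([build_classifier()]).
#'
#' The relevance filter mirrors the usual staging of signature
#' discovery (all pathway genes -> clinically relevant genes -> clustering
#' input): genes whose tumour
#' expression carries no recurrence signal would contribute arbitrary
#' data-driven cutpoints, and their noise calls would swamp the distances
#' the clustering is based on. The screen uses the raw Mann-Whitney p-value
#' at `relevance_p` (the Benjamini-Hochberg q-values are reported
#' alongside). Supplying `gene_subset` (e.g. a curated clinically relevant
#' gene list) bypasses the filter; when the filter rejects (almost)
#' everything, as in an effect-free cohort, all genes are kept.
#'
#' @param expression An [expr_matrix()].
#' @param clinical Clinical table for the same patients.
#' @param cohort_filter Optional [filter_cohort()] names applied before
#'   training (e.g. `c("braf_like", "rai_treated")`).
#' @param gene_subset Optional character vector of gene identifiers to
#'   analyse (overrides the relevance filter).
#' @param relevance_p Raw p-value threshold of the relevance screen
#'   (default 0.05).
#' @param k_major,k_sub Cluster counts (defaults 4 and 14).
#' @param delta_threshold Delta-EG selection threshold (default 0.3).
#' @param panel_sizes Candidate panel sizes for [build_classifier()].
#' @param seed Seed for cross-validation fold assignment.
#' @return List with `relevance` (per-gene association table or NULL),
#'   `genes_used`, `cutoffs`, `calls`, `assignment`, `freqs`, `contrast`,
#'   `delta`, `classifier`, `clinical` (the training subset used).
#' @export
run_pipeline <- function(expression, clinical, cohort_filter = NULL,
                         gene_subset = NULL, relevance_p = 0.05,
                         k_major = 4, k_sub = 14, delta_threshold = 0.3,
                         panel_sizes = c(10, 20, 30, 40), seed = 1L) {
  clinical <- validate_clinical(clinical)
  if (!is.null(cohort_filter)) clinical <- filter_cohort(clinical, cohort_filter)
  relevance <- NULL
  genes_used <- gene_subset
  if (is.null(genes_used)) {
    relevance <- recurrence_relevance(expression, clinical)
    genes_used <- relevance$gene_id[relevance$p_value < relevance_p]
    if (length(genes_used) < 2) genes_used <- relevance$gene_id
  }
  cutoffs <- gene_cutoffs(expression, clinical, genes = genes_used)
  calls <- call_dysregulation(expression, cutoffs,
                              patients = intersect(
                                rownames(tumour_values(expression)),
                                clinical$patient_id))
  assignment <- cluster_patients(calls, k_major = k_major, k_sub = k_sub)
  freqs <- cluster_frequencies(calls, assignment, clinical)
  contrast <- select_contrast(freqs)
  delta <- delta_eg(freqs, contrast$target, contrast$refs,
                    threshold = delta_threshold)
  classifier <- build_classifier(delta, cutoffs, calls, clinical,
                                 panel_sizes = panel_sizes, seed = seed)
  list(relevance = relevance, genes_used = genes_used, cutoffs = cutoffs,
       calls = calls, assignment = assignment, freqs = freqs,
       contrast = contrast, delta = delta, classifier = classifier,
       clinical = clinical)
}
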