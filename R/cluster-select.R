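#' Hierarchical clustering of patients on dysregulation profiles
#'
#' Agglomerative clustering of the binary patients x genes call matrix.
#' Major clusters and subclusters are obtained by cutting the same tree at
#' `k_major` and `k_sub` groups, so subclusters nest within major clusters.
#'
#' The default distance, `"hamming"` (count of genes on which two patients
#' disagree), treats shared absence of dysregulation as similarity, which
#' is essential when one end of the dysregulation spectrum is a largely
#' call-free "quiet" patient group: under Jaccard, two quiet patients with
#' one stray background call each are maximally distant and the quiet
#' group shatters. For binary profiles the Hamming count is the squared
#' Euclidean distance, so Ward linkage (`"ward.D2"` on the Euclidean
#' embedding) is well defined and is the default: it recovers compact
#' clusters far more reliably than average linkage on noisy binary calls,
#' which tends to chain and split off outlier singletons. `"jaccard"`
#' (ignores co-absence; 0/0 pairs scored 0) with `"average"` linkage is
#' retained for cohorts where every patient carries substantial
#' dysregulation.
#'
#' @param calls Binary matrix from [call_dysregulation()] (row names =
#'   patients).
#' @param k_major Number of major clusters (default 4).
#' @param k_sub Number of subclusters (default 14);
#'   `k_major <= k_sub <=` number of patients.
#' @param distance `"hamming"` (default) or `"jaccard"`.
#' @param linkage `"ward"` (default; requires `distance = "hamming"`) or
#'   `"average"`.
#' @return Object of class `cluster_assignment`: list with `major` and `sub`
#'   (named integer vectors), `sub_to_major` (map), and the `hclust` tree
#'   (merge heights) for reproducibility.
#' @export
cluster_patients <- function(calls, k_major = 4, k_sub = 14,
                             distance = c("hamming", "jaccard"),
                             linkage = c("ward", "average")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (!nrow(calls)) stop("empty call matrix", call. = FALSE)
  n <- nrow(calls)
  if (!(k_major >= 1 && k_major <= k_sub && k_sub <= n)) {
    stop("need 1 <= k_major <= k_sub <= number of patients (",
         n, ")", call. = FALSE)
  }
  if (linkage == "ward" && distance != "hamming") {
    stop("Ward linkage requires the hamming (Euclidean-embeddable) distance",
         call. = FALSE)
  }
  # canonical patient order: merge ties are then broken identically however
  # the input rows were ordered, making the partition permutation-invariant
  input_order <- rownames(calls)
  calls <- calls[order(rownames(calls)), , drop = FALSE]
  d <- if (distance == "hamming") {
    if (linkage == "ward") sqrt(dist(calls, method = "manhattan"))
    else dist(calls, method = "manhattan") / ncol(calls)
  } else {
    dist(calls, method = "binary")
  }
  d[is.na(d)] <- 0
  hc <- hclust(d, method = if (linkage == "ward") "ward.D2" else "average")
  major <- cutree(hc, k = k_major)[input_order]
  sub <- cutree(hc, k = k_sub)[input_order]
  sub_to_major <- vapply(split(major, sub), function(m) m[1], integer(1))
  structure(list(major = major, sub = sub, sub_to_major = sub_to_major,
                 hclust = hc, k_major = k_major, k_sub = k_sub),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d patients, %d major clusters, %d subclusters\n",
              length(x$major), x$k_major, x$k_sub))
  print(table(major = x$major))
  invisible(x)
}

#' Per-cluster dysregulation frequencies and recurrence rates
#'
#' For each major cluster and each subcluster: the fraction of patients with
#' a dysregulation call per gene, the mean per-patient dysregulation count,
#' the recurrence rate and the cluster size.
#'
#' @param calls Binary matrix from [call_dysregulation()].
#' @param assignment A [cluster_patients()] result covering the same
#'   patients.
#' @param clinical Clinical table containing every patient in `calls`.
#' @return Object of class `cluster_gene_frequency`: list with elements
#'   `major` and `sub`, each holding `gene_freq` (clusters x genes matrix),
#'   `recurrence_rate`, `mean_dysregulated`, `size`; plus `sub_to_major`.
#' @export
cluster_frequencies <- function(calls, assignment, clinical) {
  clinical <- validate_clinical(clinical)
  patients <- rownames(calls)
  if (!setequal(patients, names(assignment$major))) {
    stop("assignment does not cover the patients in `calls`", call. = FALSE)
  }
  missing_p <- setdiff(patients, clinical$patient_id)
  if (length(missing_p)) {
    stop("patient(s) missing from clinical table: ",
         paste(head(missing_p, 5), collapse = ", "), call. = FALSE)
  }
  event <- clinical$recurrence_event[match(patients, clinical$patient_id)]
  level_stats <- function(cl) {
    cl <- cl[patients]
    sizes <- table(cl)
    freq <- rowsum(calls, cl) / as.vector(sizes)
    rr <- tapply(event, cl, mean)
    md <- tapply(rowSums(calls), cl, mean)
    list(gene_freq = freq,
         recurrence_rate = setNames(as.vector(rr), names(rr)),
         mean_dysregulated = setNames(as.vector(md), names(md)),
         size = as.vector(sizes))
  }
  structure(list(major = level_stats(assignment$major),
                 sub = level_stats(assignment$sub),
                 sub_to_major = assignment$sub_to_major),
            class = "cluster_gene_frequency")
}

#' Identify the high-recurrence target subcluster and reference clusters
#'
#' Operational labelling rule for the delta-EG contrast: the target is the
#' subcluster with the highest recurrence rate inside the major cluster with
#' the highest recurrence rate, and the references are the two major
#' clusters with the lowest recurrence rates.
#'
#' @param freqs A [cluster_frequencies()] result.
#' @param min_size Smallest subcluster considered as target (default 3
#'   patients; tiny subclusters give unstable frequencies).
#' @return List with `target` (subcluster label) and `refs` (two major
#'   cluster labels).
#' @export
select_contrast <- function(freqs, min_size = 3) {
  rr_major <- freqs$major$recurrence_rate
  top_major <- names(rr_major)[which.max(rr_major)]
  subs <- names(freqs$sub_to_major)[freqs$sub_to_major == as.integer(top_major)]
  sizes <- setNames(freqs$sub$size, rownames(freqs$sub$gene_freq))
  big <- subs[sizes[subs] >= min_size]
  if (!length(big)) big <- subs
  rr_sub <- freqs$sub$recurrence_rate[big]
  target <- big[which.max(rr_sub)]
  refs <- names(sort(rr_major))[1:2]
  list(target = target, refs = refs)
}

#' Delta-EG: differential dysregulation frequency gene selection
#'
#' For each gene, the difference between its dysregulation frequency in a
#' high-recurrence target subcluster and in each of two low-recurrence
#' reference major clusters; genes whose mean delta reaches the threshold
#' (default 0.3) are selected as risk-panel candidates.
#'
#' @param freqs A [cluster_frequencies()] result.
#' @param target Subcluster label (character) used as the high-recurrence
#'   group.
#' @param refs Two major-cluster labels used as low-recurrence references.
#' @param threshold Selection threshold on the mean delta (default 0.3).
#' @return Data frame with `gene_id`, `delta_vs_ref1`, `delta_vs_ref2`,
#'   `mean_delta` and `selected`.
#' @export
delta_eg <- function(freqs, target, refs, threshold = 0.3) {
  if (!(is.numeric(threshold) && threshold >= 0 && threshold <= 1)) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  if (length(refs) != 2) stop("exactly two reference clusters required",
                              call. = FALSE)
  target <- as.character(target); refs <- as.character(refs)
  if (!target %in% rownames(freqs$sub$gene_freq)) {
    stop("unknown target subcluster: ", target, call. = FALSE)
  }
  missing_r <- setdiff(refs, rownames(freqs$major$gene_freq))
  if (length(missing_r)) {
    stop("unknown reference cluster(s): ", paste(missing_r, collapse = ", "),
         call. = FALSE)
  }
  ft <- freqs$sub$gene_freq[target, ]
  d1 <- ft - freqs$major$gene_freq[refs[1], ]
  d2 <- ft - freqs$major$gene_freq[refs[2], ]
  mean_delta <- (d1 + d2) / 2
  data.frame(gene_id = colnames(freqs$sub$gene_freq),
             delta_vs_ref1 = unname(d1), delta_vs_ref2 = unname(d2),
             mean_delta = unname(mean_delta),
             selected = unname(mean_delta >= threshold),
             stringsAsFactors = FALSE)
}

# Spearman rho with a permutation p-value (exact for small n)
.spearman_test <- function(x, y, exact_max_n = 8) {
  n <- length(x)
  rho <- suppressWarnings(cor(x, y, method = "spearman"))
  if (is.na(rho)) {
    warning("Spearman correlation undefined (constant input)")
    return(list(rho = NA_real_, p_value = NA_real_, method = "undefined"))
  }
  if (n <= exact_max_n) {
    perms <- .permutations(n)
    rhos <- apply(perms, 1, function(idx) {
      suppressWarnings(cor(x, y[idx], method = "spearman"))
    })
    p <- mean(abs(rhos) >= abs(rho) - 1e-12, na.rm = TRUE)
    method <- "exact permutation"
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, method = method)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1))
  smaller <- .permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(smaller), ncol = n)
  row <- 1
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    for (j in seq_len(nrow(smaller))) {
      out[row, ] <- c(i, rest[smaller[j, ]])
      row <- row + 1
    }
  }
  out
}

#' Correlation between subcluster dysregulation frequency and recurrence
#'
#' Spearman rank correlation between the per-subcluster mean dysregulation
#' count and the per-subcluster recurrence rate, with an exact permutation
#' p-value for up to 8 subclusters and a t approximation otherwise.
#'
#' @param freqs A [cluster_frequencies()] result (>= 3 subclusters).
#' @param level `"sub"` (default) or `"major"`.
#' @return List with `rho`, `p_value`, `method`, `n_clusters`.
#' @export
frequency_recurrence_correlation <- function(freqs, level = c("sub", "major")) {
  level <- match.arg(level)
  f <- freqs[[level]]
  x <- as.vector(f$mean_dysregulated)
  y <- as.vector(f$recurrence_rate)
  if (length(x) < 3) {
    stop("need at least 3 clusters for a correlation", call. = FALSE)
  }
  res <- .spearman_test(x, y)
  c(res, list(n_clusters = length(x)))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items,
#' used to score recovery of planted clusters.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Adjusted Rand index (1 = identical partitions up to relabelling).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length", call. = FALSE)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
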