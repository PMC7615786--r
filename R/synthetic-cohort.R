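#' Configuration for a synthetic cohort
#'
#' Defines the statistical structure of a simulated papillary thyroid cancer
#' cohort: cluster-structured co-dysregulation of endocytic genes, a planted
#' subset of risk genes whose dysregulation multiplies the recurrence hazard,
#' exponential event times under proportional hazards, and administrative
#' uniform censoring calibrated to a target censored fraction.
#'
#' Patients belong to one of `n_clusters` latent clusters ordered by
#' dysregulation breadth. Marker-gene co-dysregulation is nested: cluster
#' `k` dysregulates the hazard-neutral marker blocks introduced at levels
#' `2 .. k` (`markers_per_cluster` genes per block), so cluster 1 is a
#' quiet, largely call-free group. Risk genes concentrate in two
#' recurrence-prone clusters, as seen in real papillary thyroid cancer
#' dysregulation profiles: the top cluster dysregulates
#' the full risk set, and (for `n_clusters >= 4`) cluster 2 additionally
#' dysregulates the first half of the risk genes, so that recurrence risk
#' is not monotone in dysregulation breadth. Marker genes carry no hazard
#' of their own but, like real co-dysregulated endocytic genes, are
#' recurrence-associated through their correlation with the risk-carrying
#' clusters. Dysregulated entries of tumour expression are shifted by
#' `dysregulation_shift` log2 units relative to the gene baseline
#' (over-expressed by default, see `direction`).
#'
#' @param n_patients Number of patients.
#' @param n_genes Number of endocytic genes in the expression matrix.
#' @param n_risk_genes Number of planted risk genes (hazard-carrying).
#' @param n_clusters Number of latent patient clusters (>= 2).
#' @param dysregulation_shift Shift of dysregulated entries, log2 units.
#' @param noise_sd Standard deviation of per-entry expression noise
#'   (log2 units); the shift in noise-SD units is
#'   `dysregulation_shift / noise_sd`.
#' @param per_gene_hazard_log_hr Log hazard ratio added per dysregulated
#'   risk gene.
#' @param baseline_hazard Baseline recurrence hazard, events per month.
#' @param censoring_rate Target fraction of censored patients in `[0, 1)`;
#'   the administrative censoring horizon is solved so the expected censored
#'   fraction equals this value.
#' @param covariate_effects Named numeric vector of clinical log hazard
#'   ratios; allowed names: `age_gt50`, `male`, `stage_iii_iv`, `t3_t4`,
#'   `n1`. Use `NULL` or zeros for a covariate-free hazard.
#' @param direction `"over"` (risk genes over-expressed, the default) or
#'   `"under"`.
#' @param markers_per_cluster Hazard-neutral marker genes per severity
#'   block; blocks are introduced at clusters `2 .. n_clusters` (shrunk
#'   automatically if `n_genes` is too small).
#' @param p_active Dysregulation probability of an active risk gene.
#' @param p_marker Dysregulation probability of a cluster-marker gene.
#' @param p_background Background dysregulation probability of any other
#'   (gene, patient) pair.
#' @param normal_fraction Fraction of patients with a matched normal sample.
#' @param seed Integer RNG seed for the patient-level draws; identical
#'   configurations produce bit-identical cohorts.
#' @param population_seed Integer RNG seed for the gene-level population
#'   structure (which genes are risk genes, the marker blocks, per-gene
#'   baseline expression). Cohorts generated with different `seed` but the
#'   same `population_seed` share a gene universe, so cutpoints and
#'   classifiers trained on one transfer meaningfully to the other
#'   (training/validation pairs).
#' @return A `simulation_config` object (validated list).
#' @export
simulation_config <- function(n_patients = 500,
                              n_genes = 137,
                              n_risk_genes = 10,
                              n_clusters = 4,
                              dysregulation_shift = 2,
                              noise_sd = 1,
                              per_gene_hazard_log_hr = 0.4,
                              baseline_hazard = 0.001,
                              censoring_rate = 0.85,
                              covariate_effects = c(age_gt50 = 0.6,
                                                    male = 0.2,
                                                    stage_iii_iv = 0.9,
                                                    t3_t4 = 0.8,
                                                    n1 = 0.5),
                              direction = c("over", "under"),
                              markers_per_cluster = 16,
                              p_active = 0.95,
                              p_marker = 0.75,
                              p_background = 0.02,
                              normal_fraction = 0.12,
                              seed = 1L,
                              population_seed = 101L) {
  direction <- match.arg(direction)
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid `", field, "`: ", msg, call. = FALSE)
  }
  chk(is.numeric(n_patients) && length(n_patients) == 1 && n_patients >= 0 &&
        n_patients == floor(n_patients), "n_patients", "must be a count >= 0")
  chk(is.numeric(n_genes) && n_genes >= 1 && n_genes == floor(n_genes),
      "n_genes", "must be a count >= 1")
  chk(is.numeric(n_risk_genes) && n_risk_genes >= 0 &&
        n_risk_genes == floor(n_risk_genes) && n_risk_genes <= n_genes,
      "n_risk_genes", "must be a count <= n_genes")
  chk(is.numeric(n_clusters) && n_clusters >= 2 &&
        n_clusters == floor(n_clusters), "n_clusters", "must be a count >= 2")
  chk(is.numeric(dysregulation_shift) && dysregulation_shift >= 0,
      "dysregulation_shift", "must be >= 0")
  chk(is.numeric(noise_sd) && noise_sd > 0, "noise_sd", "must be > 0")
  chk(is.numeric(per_gene_hazard_log_hr) && is.finite(per_gene_hazard_log_hr),
      "per_gene_hazard_log_hr", "must be finite")
  chk(is.numeric(baseline_hazard) && baseline_hazard > 0,
      "baseline_hazard", "must be > 0 (events per month)")
  chk(is.numeric(censoring_rate) && censoring_rate >= 0 && censoring_rate < 1,
      "censoring_rate", "must be a probability in [0, 1)")
  if (is.null(covariate_effects)) covariate_effects <- numeric(0)
  allowed <- c("age_gt50", "male", "stage_iii_iv", "t3_t4", "n1")
  chk(all(names(covariate_effects) %in% allowed), "covariate_effects",
      paste("names must be among:", paste(allowed, collapse = ", ")))
  for (p in c(p_active, p_marker, p_background, normal_fraction)) {
    chk(is.numeric(p) && p >= 0 && p <= 1,
        "p_active/p_marker/p_background/normal_fraction",
        "must be probabilities")
  }
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
      "seed", "must be a single integer")
  chk(is.numeric(population_seed) && length(population_seed) == 1 &&
        is.finite(population_seed), "population_seed",
      "must be a single integer")
  markers_per_cluster <- min(markers_per_cluster,
                             (n_genes - n_risk_genes) %/% (n_clusters - 1))
  structure(list(
    n_patients = as.integer(n_patients), n_genes = as.integer(n_genes),
    n_risk_genes = as.integer(n_risk_genes), n_clusters = as.integer(n_clusters),
    dysregulation_shift = dysregulation_shift, noise_sd = noise_sd,
    per_gene_hazard_log_hr = per_gene_hazard_log_hr,
    baseline_hazard = baseline_hazard, censoring_rate = censoring_rate,
    covariate_effects = covariate_effects, direction = direction,
    markers_per_cluster = as.integer(markers_per_cluster),
    p_active = p_active, p_marker = p_marker, p_background = p_background,
    normal_fraction = normal_fraction, seed = as.integer(seed),
    population_seed = as.integer(population_seed)
  ), class = "simulation_config")
}

# censoring horizon tau such that, for uniform C ~ U(0, tau) independent of
# exponential event times with rates r, the mean censored fraction equals the
# target: P(C < T | r) = (1 - exp(-r * tau)) / (r * tau).
.censoring_horizon <- function(rates, target) {
  f <- function(tau) mean((1 - exp(-rates * tau)) / (rates * tau)) - target
  uniroot(f, lower = 1e-9, upper = 1e12, tol = 1e-10)$root
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws a full synthetic cohort under a [simulation_config()]: a log2
#' expression matrix with tumour and matched-normal samples, a clinical table
#' with disease-free survival and Table-1-style covariates, and a ground
#' truth record (risk genes, latent clusters, per-patient true risk score,
#' planted log hazard ratios) for recovery tests.
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(per_gene_hazard_log_hr * true_score + covariate
#' effects)`; censoring is administrative uniform with horizon solved so the
#' expected censored fraction equals `censoring_rate`.
#'
#' @param config A [simulation_config()].
#' @return List of class `endorisk_cohort` with elements `expression`
#'   ([expr_matrix()]), `clinical` (data frame) and `truth` (list with
#'   `risk_gene_ids`, `patient_cluster_ids`, `per_patient_true_score`,
#'   `true_log_hrs`, `marker_genes`, `dysregulated` 0/1 matrix, `seed`).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("`config` must be created with simulation_config()", call. = FALSE)
  }
  n <- config$n_patients
  G <- config$n_genes
  K <- config$n_clusters
  gene_ids <- sprintf("EG%03d", seq_len(G))
  patient_ids <- sprintf("PT%04d", seq_len(n))

  # gene-level population structure: shared by all cohorts with the same
  # population_seed, so cutpoints/classifiers transfer across cohorts
  set.seed(config$population_seed)
  risk_genes <- sort(sample(gene_ids, config$n_risk_genes))
  pool <- setdiff(gene_ids, risk_genes)
  # marker blocks introduced at severities 2..K (cluster 1 = quiet baseline)
  marker_genes <- rep(list(character(0)), K)
  names(marker_genes) <- paste0("cluster", seq_len(K))
  if (config$markers_per_cluster > 0 && K > 1) {
    picked <- sample(pool, (K - 1) * config$markers_per_cluster)
    marker_genes[2:K] <- split(picked,
                               rep(seq_len(K - 1),
                                   each = config$markers_per_cluster))
  }
  mu <- rnorm(G, mean = 8, sd = 1.5)  # per-gene baseline, population level

  # patient-level draws
  set.seed(config$seed)

  # risk genes concentrate in two recurrence-prone clusters: the top
  # cluster carries the full risk set; for K >= 4 cluster 2 carries the
  # first half, so recurrence is high in clusters 2 and K but low in the
  # broadly-dysregulated middle clusters
  risk_active <- rep(list(character(0)), K)
  names(risk_active) <- paste0("cluster", seq_len(K))
  risk_active[[K]] <- risk_genes
  if (K >= 4 && config$n_risk_genes > 0) {
    risk_active[[2]] <- risk_genes[seq_len(ceiling(config$n_risk_genes / 2))]
  }
  cluster_probs <- 1.2^(rev(seq_len(K)))
  cluster_probs <- cluster_probs / sum(cluster_probs)
  cluster <- sample.int(K, n, replace = TRUE, prob = cluster_probs)

  # dysregulation indicators
  D <- matrix(rbinom(n * G, 1, config$p_background), nrow = n, ncol = G,
              dimnames = list(patient_ids, gene_ids))
  if (n > 0) {
    for (k in seq_len(K)) {
      in_k <- which(cluster == k)
      if (!length(in_k)) next
      if (length(risk_active[[k]])) {
        D[in_k, risk_active[[k]]] <- rbinom(length(in_k) * length(risk_active[[k]]),
                                            1, config$p_active)
      }
      act_markers <- unlist(marker_genes[seq_len(k)], use.names = FALSE)
      if (length(act_markers)) {
        D[in_k, act_markers] <- rbinom(length(in_k) * length(act_markers),
                                       1, config$p_marker)
      }
    }
  }
  true_score <- if (length(risk_genes)) {
    as.integer(rowSums(D[, risk_genes, drop = FALSE]))
  } else {
    integer(n)
  }

  # expression: gene baseline + shift * D + noise, rounded for exact TSV
  # round trips
  sgn <- if (config$direction == "over") 1 else -1
  tum <- matrix(rnorm(n * G, sd = config$noise_sd), nrow = G, ncol = n)
  if (n > 0) tum <- tum + mu + sgn * config$dysregulation_shift * t(D)
  tum <- round(tum, 4)
  dimnames(tum) <- list(gene_ids,
                        if (n > 0) paste0(patient_ids, "-T"))

  n_norm <- floor(config$normal_fraction * n)
  norm_patients <- if (n_norm > 0) sort(sample(patient_ids, n_norm)) else character(0)
  nor <- matrix(rnorm(n_norm * G, sd = config$noise_sd), nrow = G,
                ncol = n_norm)
  if (n_norm > 0) nor <- nor + mu
  nor <- round(nor, 4)
  dimnames(nor) <- list(gene_ids,
                        if (n_norm > 0) paste0(norm_patients, "-N"))

  values <- cbind(tum, nor)
  samples <- data.frame(
    sample_id = if (is.null(colnames(values))) character(0)
                else colnames(values),
    patient_id = c(patient_ids, norm_patients),
    sample_type = rep(c("tumour", "normal"), c(n, n_norm)),
    stringsAsFactors = FALSE
  )

  # clinical covariates (marginals loosely matching TCGA THCA)
  age <- pmin(pmax(round(rnorm(n, 47, 14)), 18), 90)
  gender <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.27, 0.73))
  stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                  prob = c(0.56, 0.10, 0.20, 0.14))
  t_stage <- sample(paste0("T", 1:4), n, replace = TRUE,
                    prob = c(0.25, 0.35, 0.30, 0.10))
  n_stage <- sample(c("N0", "N1"), n, replace = TRUE, prob = c(0.45, 0.55))
  rai_treated <- rbinom(n, 1, 0.55) == 1
  braf_like <- rbinom(n, 1, 0.70) == 1
  braf_mutation <- rbinom(n, 1, ifelse(braf_like, 0.75, 0.10)) == 1

  ce <- config$covariate_effects
  eff <- function(name) if (name %in% names(ce)) ce[[name]] else 0
  eta <- config$per_gene_hazard_log_hr * true_score +
    eff("age_gt50") * (age > 50) +
    eff("male") * (gender == "male") +
    eff("stage_iii_iv") * (stage %in% c("III", "IV")) +
    eff("t3_t4") * (t_stage %in% c("T3", "T4")) +
    eff("n1") * (n_stage == "N1")
  rates <- config$baseline_hazard * exp(eta)
  event_time <- rexp(n, rate = rates)
  if (config$censoring_rate > 0 && n > 0) {
    tau <- .censoring_horizon(rates, config$censoring_rate)
    cens_time <- runif(n, 0, tau)
  } else {
    tau <- Inf
    cens_time <- rep(Inf, n)
  }
  dfs <- round(pmin(event_time, cens_time), 2)
  event <- as.integer(event_time <= cens_time)

  clinical <- data.frame(
    patient_id = patient_ids, dfs_months = dfs, recurrence_event = event,
    age_years = age, gender = gender, stage = stage, t_stage = t_stage,
    n_stage = n_stage, rai_treated = rai_treated, braf_like = braf_like,
    braf_mutation = braf_mutation, stringsAsFactors = FALSE
  )
  clinical <- validate_clinical(clinical)

  truth <- list(
    risk_gene_ids = risk_genes,
    patient_cluster_ids = setNames(cluster, patient_ids),
    per_patient_true_score = setNames(true_score, patient_ids),
    true_log_hrs = c(score = config$per_gene_hazard_log_hr, ce),
    marker_genes = marker_genes,
    risk_active = risk_active,
    dysregulated = D,
    censoring_horizon = tau,
    seed = config$seed
  )
  structure(list(expression = expr_matrix(values, samples),
                 clinical = clinical, truth = truth, config = config),
            class = "endorisk_cohort")
}

#' @export
print.endorisk_cohort <- function(x, ...) {
  cat(sprintf("<endorisk_cohort> %d patients, %d genes, %d risk genes, %d clusters; %d events (%.0f%% censored)\n",
              x$config$n_patients, x$config$n_genes, x$config$n_risk_genes,
              x$config$n_clusters, sum(x$clinical$recurrence_event),
              100 * mean(1 - x$clinical$recurrence_event)))
  invisible(x)
}

#' Write a cohort and its ground truth to disk
#'
#' Writes `expression.tsv` (gene_id + one column per sample), `samples.tsv`,
#' `clinical.tsv` and `truth.json` into a directory. Files are plain text
#' and byte-identical across repeated writes of the same cohort.
#'
#' @param cohort An `endorisk_cohort` from [generate_cohort()].
#' @param directory Output directory (created if needed).
#' @return Invisibly, the named character vector of file paths written.
#' @export
write_cohort_fixture <- function(cohort, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  }
  paths <- c(expression = file.path(directory, "expression.tsv"),
             samples = file.path(directory, "samples.tsv"),
             clinical = file.path(directory, "clinical.tsv"),
             truth = file.path(directory, "truth.json"))
  expr_tab <- data.frame(gene_id = rownames(cohort$expression$values),
                         cohort$expression$values, check.names = FALSE,
                         stringsAsFactors = FALSE)
  write.table(expr_tab, paths[["expression"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$expression$samples, paths[["samples"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$clinical, paths[["clinical"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- cohort$truth
  truth$dysregulated <- NULL  # recoverable from seed; keep the JSON light
  # named atomic vectors serialise as bare arrays; reshape so names survive
  truth$true_log_hrs <- as.list(truth$true_log_hrs)
  truth$patient_ids <- names(truth$patient_cluster_ids)
  truth$patient_cluster_ids <- unname(truth$patient_cluster_ids)
  truth$per_patient_true_score <- unname(truth$per_patient_true_score)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Read back a cohort fixture written by [write_cohort_fixture()]
#'
#' @param directory Directory containing `expression.tsv`, `samples.tsv`,
#'   `clinical.tsv` and `truth.json`.
#' @return List with `expression`, `clinical` and `truth`.
#' @export
read_cohort_fixture <- function(directory) {
  expr <- read_expression(file.path(directory, "expression.tsv"),
                          file.path(directory, "samples.tsv"))
  clinical <- if (file.size(file.path(directory, "clinical.tsv")) > 0) {
    tab <- read.delim(file.path(directory, "clinical.tsv"),
                      stringsAsFactors = FALSE)
    validate_clinical(tab)
  }
  truth <- jsonlite::read_json(file.path(directory, "truth.json"),
                               simplifyVector = TRUE)
  list(expression = expr, clinical = clinical, truth = truth)
}
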