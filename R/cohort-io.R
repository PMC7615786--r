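#' Construct an expression matrix object
#'
#' Container for a genes x samples matrix of log2 expression values together
#' with the sample sheet mapping each sample to a patient and a sample type
#' (tumour or matched normal).
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   `rownames` = gene identifiers and `colnames` = sample identifiers.
#' @param samples Data frame with columns `sample_id`, `patient_id`,
#'   `sample_type` (values `"tumour"` or `"normal"`), one row per column of
#'   `values`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `samples`.
#' @export
expr_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || (ncol(values) > 0 && is.null(colnames(values)))) {
    stop("`values` must carry gene row names and sample column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene identifiers in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample identifiers in expression matrix", call. = FALSE)
  }
  req <- c("sample_id", "patient_id", "sample_type")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols)) {
    stop("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  samples <- as.data.frame(samples)[req]
  if (!setequal(samples$sample_id, colnames(values)) ||
      nrow(samples) != ncol(values)) {
    stop("sample sheet does not match expression matrix columns", call. = FALSE)
  }
  bad_type <- setdiff(unique(samples$sample_type), c("tumour", "normal"))
  if (length(bad_type)) {
    stop("unknown sample_type value(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples (%d tumour, %d normal, %d patients)\n",
              nrow(x$values), ncol(x$values),
              sum(x$samples$sample_type == "tumour"),
              sum(x$samples$sample_type == "normal"),
              length(unique(x$samples$patient_id))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# required clinical schema; column names fixed by the on-disk interface
.clinical_columns <- c("patient_id", "dfs_months", "recurrence_event",
                       "age_years", "gender", "stage", "t_stage", "n_stage",
                       "rai_treated", "braf_like", "braf_mutation")

#' Validate a clinical table
#'
#' Checks the per-patient clinical schema: unique patient identifiers,
#' non-negative disease-free survival times, 0/1 recurrence events and the
#' categorical/flag columns used by cohort filters and Cox models.
#'
#' @param clinical Data frame with columns `patient_id`, `dfs_months`,
#'   `recurrence_event`, `age_years`, `gender`, `stage`, `t_stage`,
#'   `n_stage`, `rai_treated`, `braf_like`, `braf_mutation`.
#' @return The validated data frame (invisibly unchanged), with flag columns
#'   coerced to logical.
#' @export
validate_clinical <- function(clinical) {
  clinical <- as.data.frame(clinical)
  missing_cols <- setdiff(.clinical_columns, names(clinical))
  if (length(missing_cols)) {
    stop("clinical table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(clinical$patient_id)) {
    stop("duplicate patient_id in clinical table", call. = FALSE)
  }
  if (nrow(clinical)) {
    bad <- which(!is.finite(clinical$dfs_months) | clinical$dfs_months < 0)
    if (length(bad)) {
      stop("negative or missing dfs_months for patient(s): ",
           paste(clinical$patient_id[bad], collapse = ", "), call. = FALSE)
    }
    if (!all(clinical$recurrence_event %in% c(0, 1))) {
      bad <- clinical$patient_id[!clinical$recurrence_event %in% c(0, 1)]
      stop("recurrence_event must be 0/1; offending patient(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    bad_stage <- setdiff(unique(clinical$stage), c("I", "II", "III", "IV"))
    if (length(bad_stage)) {
      stop("unknown stage value(s): ", paste(bad_stage, collapse = ", "),
           call. = FALSE)
    }
    bad_t <- setdiff(unique(clinical$t_stage), paste0("T", 1:4))
    if (length(bad_t)) {
      stop("unknown t_stage value(s): ", paste(bad_t, collapse = ", "),
           call. = FALSE)
    }
    bad_n <- setdiff(unique(clinical$n_stage), c("N0", "N1"))
    if (length(bad_n)) {
      stop("unknown n_stage value(s): ", paste(bad_n, collapse = ", "),
           call. = FALSE)
    }
  }
  for (fl in c("rai_treated", "braf_like", "braf_mutation")) {
    v <- clinical[[fl]]
    if (is.numeric(v)) v <- v != 0
    if (!is.logical(v)) v <- as.logical(v)
    if (anyNA(v)) stop("column ", fl, " must be logical (or 0/1)", call. = FALSE)
    clinical[[fl]] <- v
  }
  clinical
}

#' Read a log2 expression matrix and its sample sheet
#'
#' The expression file is tab-separated with gene identifiers in the first
#' column (header `gene_id`) and one column per sample; the companion sample
#' sheet maps `sample_id` to `patient_id` and `sample_type`
#' (`tumour`/`normal`).
#'
#' @param path Path to the expression TSV.
#' @param samples_path Path to the sample sheet TSV.
#' @return An [expr_matrix()] object.
#' @export
read_expression <- function(path, samples_path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!ncol(tab) || names(tab)[1] != "gene_id") {
    stop("expression file must have `gene_id` as its first column: ", path,
         call. = FALSE)
  }
  genes <- as.character(tab$gene_id)
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "NA")
      if (length(bad)) {
        stop(sprintf("non-numeric expression value '%s' at gene %s, sample %s",
                     col[bad[1]], genes[bad[1]], names(vals)[j]), call. = FALSE)
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  samples <- read.delim(samples_path, stringsAsFactors = FALSE)
  expr_matrix(m, samples)
}

#' Read a per-patient clinical table
#'
#' @param path Path to a tab-separated clinical table with the schema
#'   documented in [validate_clinical()].
#' @return Validated clinical data frame.
#' @export
read_clinical <- function(path) {
  validate_clinical(read.delim(path, stringsAsFactors = FALSE))
}

#' Read gene sets in GMT format
#'
#' Standard tab-separated GMT: one set per line, `name<TAB>description<TAB>`
#' followed by gene symbols. Gene symbols are upper-cased so membership tests
#' are case-insensitive.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors of gene identifiers.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop(sprintf("malformed GMT line %d (need name, description, >=1 gene)", i),
           call. = FALSE)
    }
    name <- parts[1]
    if (name %in% names(sets)) {
      stop("duplicate gene-set name in GMT: ", name, call. = FALSE)
    }
    genes <- unique(toupper(parts[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("empty gene set in GMT: ", name, call. = FALSE)
    sets[[name]] <- genes
  }
  sets
}

#' Impute missing expression values
#'
#' Genes missing in more than `max_missing` of samples are dropped; remaining
#' missing entries are imputed with the gene median.
#'
#' @param expr An [expr_matrix()].
#' @param max_missing Maximum tolerated fraction of missing values per gene.
#' @return An [expr_matrix()] without missing values.
#' @export
impute_expression <- function(expr, max_missing = 0.2) {
  v <- expr$values
  frac_na <- rowMeans(!is.finite(v))
  keep <- frac_na <= max_missing
  if (!all(keep)) {
    message("dropping ", sum(!keep), " gene(s) with >",
            round(100 * max_missing), "% missing values")
  }
  v <- v[keep, , drop = FALSE]
  for (i in which(rowSums(!is.finite(v)) > 0)) {
    miss <- !is.finite(v[i, ])
    v[i, miss] <- median(v[i, !miss])
  }
  expr_matrix(v, expr$samples)
}

#' Subset a clinical table by named cohort filters
#'
#' Named filters correspond to the standard subcohorts of RAI-treated
#' thyroid cancer analyses: `braf_like`,
#' `ras_like`, `rai_treated`, `non_rai_treated`, `braf_mutant` and `all`.
#' Several names combine by conjunction (set intersection), so
#' `c("braf_like", "rai_treated")` selects the BRAF-like, RAI-treated
#' subcohort.
#'
#' @param clinical Clinical data frame (see [validate_clinical()]).
#' @param filters Character vector of filter names.
#' @return The subset of `clinical` rows matching all filters.
#' @export
filter_cohort <- function(clinical, filters = "all") {
  clinical <- validate_clinical(clinical)
  known <- c("all", "braf_like", "ras_like", "rai_treated",
             "non_rai_treated", "braf_mutant")
  bad <- setdiff(filters, known)
  if (length(bad)) {
    stop("unknown cohort filter(s): ", paste(bad, collapse = ", "),
         "; known filters: ", paste(known, collapse = ", "), call. = FALSE)
  }
  keep <- rep(TRUE, nrow(clinical))
  for (f in filters) {
    keep <- keep & switch(f,
      all             = TRUE,
      braf_like       = clinical$braf_like,
      ras_like        = !clinical$braf_like,
      rai_treated     = clinical$rai_treated,
      non_rai_treated = !clinical$rai_treated,
      braf_mutant     = clinical$braf_mutation
    )
  }
  out <- clinical[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect candidate interactor lists with endocytosis gene sets
#'
#' Takes one or more pre-thresholded interactor lists (e.g. hits from
#' independent mass-spectrometry screens) and one or more endocytosis
#' pathway gene sets, and returns the genes appearing in at least one
#' interactor list and in the union of endocytosis sets, together with a
#' per-source membership table suitable for a Venn-style summary.
#'
#' @param interactor_lists Named list of character vectors (as from
#'   [read_gmt()]).
#' @param endocytosis_sets Named list of character vectors.
#' @return List with `candidates` (character vector) and `membership`
#'   (data frame with one row per gene in the union of interactor lists and
#'   one logical column per source plus `in_endocytosis` and `candidate`).
#' @export
intersect_interactors <- function(interactor_lists, endocytosis_sets) {
  if (!length(interactor_lists) || !length(endocytosis_sets)) {
    warning("empty interactor lists or endocytosis sets; no candidates")
    return(list(candidates = character(0),
                membership = data.frame(gene_id = character(0))))
  }
  interactor_lists <- lapply(interactor_lists, toupper)
  endo <- unique(toupper(unlist(endocytosis_sets)))
  universe <- sort(unique(unlist(interactor_lists)))
  membership <- data.frame(gene_id = universe, stringsAsFactors = FALSE)
  for (nm in names(interactor_lists)) {
    membership[[nm]] <- universe %in% interactor_lists[[nm]]
  }
  membership$in_endocytosis <- universe %in% endo
  membership$candidate <- membership$in_endocytosis
  list(candidates = universe[membership$candidate], membership = membership)
}

#' Per-patient tumour expression values
#'
#' Extracts a patients x genes matrix of tumour-sample expression. Patients
#' with several tumour samples contribute their first sample in sample-sheet
#' order.
#'
#' @param expr An [expr_matrix()].
#' @param patients Optional character vector restricting (and ordering) the
#'   patients returned; defaults to all patients with a tumour sample.
#' @return Numeric matrix, patients in rows, genes in columns.
#' @export
tumour_values <- function(expr, patients = NULL) {
  sh <- expr$samples[expr$samples$sample_type == "tumour", , drop = FALSE]
  sh <- sh[!duplicated(sh$patient_id), , drop = FALSE]
  if (is.null(patients)) {
    patients <- sh$patient_id
  } else {
    missing_p <- setdiff(patients, sh$patient_id)
    if (length(missing_p)) {
      stop("no tumour sample for patient(s): ",
           paste(head(missing_p, 5), collapse = ", "), call. = FALSE)
    }
  }
  idx <- match(sh$sample_id[match(patients, sh$patient_id)], colnames(expr$values))
  out <- t(expr$values[, idx, drop = FALSE])
  rownames(out) <- patients
  out
}
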