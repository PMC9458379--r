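#' Assemble a two-class expression dataset
#'
#' Builds the tidy samples-by-genes table that every selection and
#' evaluation function in opcaselect consumes: one row per sample, a
#' `sample_id` column, a two-class `label` column, and one numeric column
#' per gene.
#'
#' @param matrix Numeric matrix, samples in rows and genes in columns.
#'   Row names (if any) become sample ids, column names gene ids.
#' @param labels Character or factor vector of class symbols, one per
#'   sample; exactly two distinct values must be present.
#' @param gene_ids,sample_ids Optional identifier vectors overriding the
#'   matrix dimnames. Defaults are generated (`g001`..., `s001`...).
#' @return A tibble of class `expr_dataset` with columns `sample_id`,
#'   `label`, then one column per gene.
#' @examples
#' m <- matrix(rnorm(12), nrow = 3)
#' expression_data(m, labels = c("tumor", "normal", "tumor"))
#' @export
expression_data <- function(matrix, labels, gene_ids = NULL, sample_ids = NULL) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  n <- nrow(matrix)
  m <- ncol(matrix)
  if (is.null(gene_ids)) gene_ids <- colnames(matrix)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(m))
  if (is.null(sample_ids)) sample_ids <- rownames(matrix)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) {
    rlang::abort(sprintf("`labels` has length %d but the matrix has %d samples.",
                         length(labels), n))
  }
  if (length(sample_ids) != n || anyDuplicated(sample_ids)) {
    rlang::abort("`sample_ids` must be unique and match the number of samples.")
  }
  if (length(gene_ids) != m || anyDuplicated(gene_ids)) {
    rlang::abort("`gene_ids` must be unique and match the number of genes.")
  }
  classes <- sort(unique(labels))
  if (length(classes) != 2) {
    rlang::abort(sprintf("expected exactly 2 classes, found %d (%s)",
                         length(classes), paste(classes, collapse = ", ")))
  }
  if (!all(is.finite(matrix))) {
    bad <- which(!is.finite(matrix), arr.ind = TRUE)[1, ]
    rlang::abort(sprintf("non-finite expression value at row %d, column %d",
                         bad[1], bad[2]))
  }
  out <- tibble::as_tibble(as.data.frame(matrix, optional = TRUE),
                           .name_repair = "minimal")
  names(out) <- gene_ids
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = sample_ids, label = labels), out
  )
  class(out) <- c("expr_dataset", class(out))
  out
}

#' Gene identifiers of an expression dataset
#'
#' @param data An `expr_dataset` tibble (or any data frame with
#'   `sample_id` and `label` columns followed by gene columns).
#' @return Character vector of gene column names.
#' @export
gene_ids <- function(data) {
  setdiff(names(data), c("sample_id", "label"))
}

#' Extract the samples-by-genes numeric matrix
#'
#' @inheritParams gene_ids
#' @param genes Optional character vector (gene ids) or integer indices
#'   into the gene columns; default all genes.
#' @return Numeric matrix with sample ids as row names.
#' @export
expr_matrix <- function(data, genes = NULL) {
  ids <- gene_ids(data)
  if (is.null(genes)) genes <- ids
  if (is.numeric(genes)) {
    if (any(genes < 1 | genes > length(ids))) {
      rlang::abort("gene index out of range")
    }
    genes <- ids[genes]
  }
  missing <- setdiff(genes, ids)
  if (length(missing)) {
    rlang::abort(paste0("unknown gene id(s): ", paste(missing, collapse = ", ")))
  }
  x <- as.matrix(data[, genes, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- data$sample_id
  x
}

#' @export
print.expr_dataset <- function(x, ...) {
  ids <- gene_ids(x)
  tab <- table(x$label)
  cat(sprintf("<expr_dataset> %d samples x %d genes (%s)\n",
              nrow(x), length(ids),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  NextMethod()
}

guess_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read an expression matrix and its labels from delimited files
#'
#' Loads a delimited (CSV or TSV, sniffed from the header line) numeric
#' matrix with one header row and one leading id column, plus a labels
#' file mapping sample id to class symbol, and returns the standard
#' samples-by-genes [expression_data()] tibble.
#'
#' Microarray matrices conventionally ship genes-as-rows, so that is the
#' default on-disk orientation; set `orientation = "samples-rows"` if the
#' file already has one row per sample.
#'
#' @param matrix_path Path to the delimited matrix file.
#' @param labels_path Path to a delimited two-column file whose first two
#'   columns are sample id and class label (header row required).
#' @param orientation `"genes-rows"` (default) or `"samples-rows"`:
#'   orientation of the file on disk.
#' @param missing `"error"` (default) rejects any missing or non-numeric
#'   cell, reporting its row and column; `"impute-mean"` replaces missing
#'   values with the gene's mean across samples.
#' @return An `expr_dataset` tibble.
#' @export
read_expression <- function(matrix_path, labels_path,
                            orientation = c("genes-rows", "samples-rows"),
                            missing = c("error", "impute-mean")) {
  orientation <- match.arg(orientation)
  missing <- match.arg(missing)
  delim <- guess_delim(matrix_path)
  raw <- readr::read_delim(matrix_path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE, na = character())
  if (ncol(raw) < 2) rlang::abort("matrix file needs an id column plus data columns")
  row_ids <- as.character(raw[[1]])
  cells <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  dimnames(vals) <- list(row_ids, colnames(cells))
  if (anyNA(vals) || any(!is.finite(vals))) {
    if (missing == "error") {
      bad <- which(!is.finite(vals) | is.na(vals), arr.ind = TRUE)[1, ]
      rlang::abort(sprintf(
        "non-numeric or missing cell at row %d, column %d of %s",
        bad[1], bad[2], matrix_path))
    }
  }
  if (orientation == "genes-rows") vals <- t(vals)
  # samples are now rows
  if (missing == "impute-mean" && anyNA(vals)) {
    for (j in seq_len(ncol(vals))) {
      nas <- is.na(vals[, j])
      if (any(nas)) vals[nas, j] <- mean(vals[!nas, j])
    }
    if (anyNA(vals)) rlang::abort("a gene had no observed values to impute from")
  }
  lab_tbl <- readr::read_delim(labels_path, delim = guess_delim(labels_path),
                               col_types = readr::cols(.default = readr::col_character()),
                               progress = FALSE, show_col_types = FALSE)
  if (ncol(lab_tbl) < 2) rlang::abort("labels file needs sample id and label columns")
  lab_map <- stats::setNames(as.character(lab_tbl[[2]]), as.character(lab_tbl[[1]]))
  absent <- setdiff(rownames(vals), names(lab_map))
  if (length(absent)) {
    rlang::abort(paste0("sample id(s) missing from labels file: ",
                        paste(absent, collapse = ", ")))
  }
  expression_data(vals, labels = unname(lab_map[rownames(vals)]),
                  gene_ids = colnames(vals), sample_ids = rownames(vals))
}

#' Run configuration for the OPCA pipeline
#'
#' Collects the tunable parameters of the selection pipeline with the
#' defaults used throughout: a 1% contribution-rate threshold for the
#' PCA screen, a neighborhood-radius grid covering \[0, 2\] in steps of
#' 0.01, a significance (dependency-gain) floor of 0.01, a linear SVM
#' evaluated by stratified 10-fold cross-validation.
#'
#' @param contribution_threshold Fraction in (0, 1); PCA components and
#'   gene scores above this share of variance survive the screen.
#' @param delta_grid Numeric vector of neighborhood radii, all in \[0, 2\].
#' @param significance_floor Minimum dependency gain for a gene to enter
#'   the reduct (>= 0).
#' @param classifier `"linear-svm"` or `"knn1"`.
#' @param cv_folds Number of stratified cross-validation folds (>= 2).
#' @param seed Integer seed controlling fold assignment and any other
#'   randomness.
#' @param positive_class Class symbol treated as positive for precision;
#'   default `NULL` means the lexicographically larger label.
#' @return A list of class `opca_config`.
#' @export
opca_config <- function(contribution_threshold = 0.01,
                        delta_grid = seq(0, 2, by = 0.01),
                        significance_floor = 0.01,
                        classifier = c("linear-svm", "knn1"),
                        cv_folds = 10,
                        seed = 1,
                        positive_class = NULL) {
  classifier <- match.arg(classifier)
  if (!is.numeric(contribution_threshold) || length(contribution_threshold) != 1 ||
      contribution_threshold <= 0 || contribution_threshold >= 1) {
    rlang::abort("`contribution_threshold` must be a fraction in (0, 1)")
  }
  if (length(delta_grid) < 1 || any(delta_grid < 0 | delta_grid > 2)) {
    rlang::abort("`delta_grid` must be non-empty with all radii in [0, 2]")
  }
  if (significance_floor < 0) rlang::abort("`significance_floor` must be >= 0")
  if (cv_folds < 2) rlang::abort("`cv_folds` must be >= 2")
  structure(list(
    contribution_threshold = contribution_threshold,
    delta_grid = as.numeric(delta_grid),
    significance_floor = significance_floor,
    classifier = classifier,
    cv_folds = as.integer(cv_folds),
    seed = as.integer(seed),
    positive_class = positive_class
  ), class = "opca_config")
}

#' Write a selected gene panel and its run report
#'
#' Writes the reduct as a tab-separated table (rank, gene id, significance
#' at acceptance, cumulative dependency) and, optionally, a JSON run
#' report carrying the configuration, the radius, the search traces and
#' any evaluation metrics.
#'
#' @param result An `opca_reduct` (from [greedy_reduct()] or
#'   [radius_search()]) or an `opca_fit` (from [run_opca()]).
#' @param data The `expr_dataset` the reduct indices refer to.
#' @param path Output path for the TSV selection table.
#' @param report_path Optional path for the JSON run report.
#' @param config Optional `opca_config` echoed into the report.
#' @param metrics Optional `opca_eval` echoed into the report.
#' @return `path`, invisibly.
#' @export
write_selection <- function(result, data, path, report_path = NULL,
                            config = NULL, metrics = NULL) {
  if (inherits(result, "opca_fit")) {
    if (is.null(config)) config <- result$config
    if (is.null(metrics)) metrics <- result$evaluation
    result <- result$reduct
  }
  stopifnot(inherits(result, "opca_reduct"))
  ids <- gene_ids(data)
  if (length(result$selected) && any(result$selected < 1 | result$selected > length(ids))) {
    rlang::abort("reduct contains a gene index outside the dataset")
  }
  tab <- tibble::tibble(
    rank = seq_along(result$selected),
    gene_id = ids[result$selected],
    significance = result$significance_trace,
    cumulative_dependency = result$dependency_trace
  )
  readr::write_tsv(tab, path, progress = FALSE)
  if (!is.null(report_path)) {
    report <- list(
      selection = tab,
      delta = result$delta_used,
      final_dependency = result$final_dependency,
      config = if (!is.null(config)) unclass(config),
      metrics = if (!is.null(metrics)) {
        list(precision = metrics$precision, accuracy = metrics$accuracy,
             classifier = metrics$classifier, folds = metrics$folds,
             seed = metrics$seed, per_fold = metrics$per_fold)
      }
    )
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read back a selection table written by [write_selection()]
#'
#' @param path Path to the TSV selection file.
#' @return Tibble with columns `rank`, `gene_id`, `significance`,
#'   `cumulative_dependency`.
#' @export
read_selection <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    rank = readr::col_integer(),
    gene_id = readr::col_character(),
    significance = readr::col_double(),
    cumulative_dependency = readr::col_double()
  ), progress = FALSE)
}
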