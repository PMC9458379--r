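#' Simulate a two-class expression matrix with planted structure
#'
#' Generates a microarray-like dataset on a standardized intensity scale
#' with three gene roles: informative genes shift their class means by
#' `effect_size` standard deviations (Normal(0, 1) in the negative
#' class, Normal(effect_size, 1) in the positive class); redundant genes
#' are noisy copies of informative genes (cyclically assigned parents
#' plus Normal(0, `redundancy_noise_sd`) noise); noise genes are
#' Normal(0, 1) in both classes. Gene order is shuffled deterministically
#' under the seed, and the returned truth table stays aligned with the
#' shuffled gene ids.
#'
#' The defaults emulate the planted-panel study condition used
#' throughout the package's tests: 60 samples (30 per class), 200 genes
#' of which 6 are informative at a 2 SD effect, 20 redundant and 174
#' pure noise.
#'
#' @param n_pos,n_neg Samples in the positive ("tumor") and negative
#'   ("normal") class.
#' @param n_informative,n_redundant,n_noise Gene counts per role;
#'   `n_informative >= 1` whenever `n_redundant > 0`.
#' @param effect_size Class-mean separation of informative genes, in SD
#'   units.
#' @param redundancy_noise_sd SD of the noise added to a redundant
#'   gene's parent.
#' @param seed Integer seed; same seed, same dataset.
#' @return List with `data` (an `expr_dataset` tibble, positive class
#'   labelled `"tumor"`, negative `"normal"`) and `truth` (tibble with
#'   `gene_id`, `role` in informative/redundant/noise, and `parent`
#'   gene id for redundant genes).
#' @examples
#' sim <- simulate_expression(n_pos = 5, n_neg = 5, n_informative = 2,
#'                            n_redundant = 1, n_noise = 7, seed = 42)
#' table(sim$truth$role)
#' @export
simulate_expression <- function(n_pos = 30, n_neg = 30,
                                n_informative = 6, n_redundant = 20,
                                n_noise = 174, effect_size = 2,
                                redundancy_noise_sd = 0.3, seed = 1) {
  counts <- c(n_pos, n_neg, n_informative, n_redundant, n_noise)
  if (any(counts < 0) || any(counts != floor(counts))) {
    rlang::abort("all counts must be non-negative integers")
  }
  if (n_redundant > 0 && n_informative < 1) {
    rlang::abort("redundant genes need at least one informative parent")
  }
  m <- n_informative + n_redundant + n_noise
  n <- n_pos + n_neg
  if (m < 1) rlang::abort("at least one gene is required")
  if (n < 2) rlang::abort("at least two samples are required")
  restore <- local_seed(seed)
  on.exit(restore())
  labels <- c(rep("tumor", n_pos), rep("normal", n_neg))
  x <- matrix(0, n, m)
  role <- character(m)
  parent <- rep(NA_integer_, m)
  for (j in seq_len(n_informative)) {
    x[, j] <- stats::rnorm(n) + ifelse(labels == "tumor", effect_size, 0)
    role[j] <- "informative"
  }
  for (r in seq_len(n_redundant)) {
    j <- n_informative + r
    p <- (r - 1L) %% n_informative + 1L
    x[, j] <- x[, p] + stats::rnorm(n, sd = redundancy_noise_sd)
    role[j] <- "redundant"
    parent[j] <- p
  }
  for (j in seq_len(n_noise) + n_informative + n_redundant) {
    x[, j] <- stats::rnorm(n)
    role[j] <- "noise"
  }
  perm <- sample.int(m)
  x <- x[, perm, drop = FALSE]
  role <- role[perm]
  parent <- parent[perm]
  ids <- sprintf("g%04d", seq_len(m))
  # parent indices refer to pre-shuffle positions; map to shuffled ids
  parent_id <- ids[match(parent, perm)]
  data <- expression_data(x, labels = labels, gene_ids = ids,
                          sample_ids = sprintf("s%03d", seq_len(n)))
  truth <- tibble::tibble(gene_id = ids, role = role, parent = parent_id)
  list(data = data, truth = truth)
}

#' Write a simulated dataset as plain-text fixtures
#'
#' Writes the matrix (genes-as-rows CSV, the on-disk convention
#' [read_expression()] expects by default), the labels CSV, and the
#' truth table TSV, so a simulation round-trips through the loader.
#'
#' @param sim A list with `data` and `truth`, as returned by
#'   [simulate_expression()].
#' @param matrix_path,labels_path Output CSV paths.
#' @param truth_path Optional output TSV path for the gene-role truth.
#' @return Invisibly, a named list of the written paths.
#' @export
write_fixture <- function(sim, matrix_path, labels_path, truth_path = NULL) {
  data <- sim$data
  x <- t(expr_matrix(data))           # genes as rows on disk
  tab <- tibble::as_tibble(as.data.frame(x), .name_repair = "minimal")
  names(tab) <- data$sample_id
  tab <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(x)), tab)
  readr::write_csv(tab, matrix_path, progress = FALSE)
  readr::write_csv(tibble::tibble(sample_id = data$sample_id,
                                  label = data$label),
                   labels_path, progress = FALSE)
  if (!is.null(truth_path)) {
    readr::write_tsv(sim$truth, truth_path, progress = FALSE)
  }
  invisible(list(matrix = matrix_path, labels = labels_path,
                 truth = truth_path))
}
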