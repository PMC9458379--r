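#' Covariance matrix of an expression dataset
#'
#' Computes the genes-by-genes covariance of the sample vectors,
#' H = (1/M) sum_k (x_k - mean)(x_k - mean)^T with M the sample count.
#' The population divisor 1/M is the default; `divisor = "M-1"` gives the
#' usual unbiased estimate.
#'
#' @param data An `expr_dataset` tibble (see [expression_data()]).
#' @param divisor `"M"` (population, default) or `"M-1"` (unbiased).
#' @return Symmetric genes-by-genes numeric matrix.
#' @export
expr_covariance <- function(data, divisor = c("M", "M-1")) {
  divisor <- match.arg(divisor)
  x <- expr_matrix(data)
  M <- nrow(x)
  if (M < 2) rlang::abort("covariance needs at least 2 samples")
  xc <- sweep(x, 2, colMeans(x))
  denom <- if (divisor == "M") M else M - 1
  H <- crossprod(xc) / denom
  (H + t(H)) / 2
}

#' Eigendecomposition with a fixed sign convention
#'
#' Decomposes a symmetric matrix into eigenvalues sorted non-increasing
#' and orthonormal loading vectors. Eigenvalues in (-1e-10, 0) are
#' clipped to zero. Each loading's sign is fixed by making its
#' largest-magnitude entry non-negative (ties broken by lower index), so
#' repeated runs are bit-identical.
#'
#' @param H Symmetric numeric matrix (tolerance 1e-8 relative).
#' @return List with `values` (numeric vector) and `vectors` (matrix,
#'   one column per eigenvalue).
#' @export
eigen_sorted <- function(H) {
  H <- as.matrix(H)
  tol <- 1e-8 * max(1, max(abs(H)))
  if (nrow(H) != ncol(H) || max(abs(H - t(H))) > tol) {
    rlang::abort("`H` must be symmetric")
  }
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  vals <- e$values
  vals[vals < 0 & vals > -1e-10] <- 0
  vecs <- e$vectors
  for (k in seq_len(ncol(vecs))) {
    i0 <- which.max(abs(vecs[, k]))
    if (vecs[i0, k] < 0) vecs[, k] <- -vecs[, k]
  }
  list(values = vals, vectors = vecs)
}

#' Contribution rates of a PCA spectrum
#'
#' The contribution rate of component k is its eigenvalue's share of the
#' total variance, c_k = beta_k / sum(beta).
#'
#' @param eigenvalues Non-negative numeric vector, at least one positive.
#' @return Numeric vector of fractions summing to 1.
#' @export
contribution_rates <- function(eigenvalues) {
  if (any(eigenvalues < -1e-10)) rlang::abort("eigenvalues must be non-negative")
  eigenvalues <- pmax(eigenvalues, 0)
  total <- sum(eigenvalues)
  if (total <= 0) rlang::abort("degenerate data: all eigenvalues are zero")
  eigenvalues / total
}

#' PCA screen of an expression dataset
#'
#' Runs the principal-component screen of the OPCA pipeline: covariance
#' eigenstructure, per-component contribution rates, per-gene scores, and
#' the candidate gene set passed on to rough-set reduction.
#'
#' Components whose contribution rate exceeds `contribution_threshold`
#' are retained; each gene j is then scored by its contribution-weighted
#' squared loading across the retained components,
#' s_j = sum_k c_k l_kj^2, renormalized to sum to 1, and the same
#' threshold is applied to the gene scores. If no gene clears it, the top
#' ceiling(sqrt(m)) genes by score are kept so the pipeline never stalls
#' (ties broken by lower gene index).
#'
#' @inheritParams expr_covariance
#' @param contribution_threshold Fraction in (0, 1); default 0.01 (the
#'   1% rule).
#' @return Object of class `opca_pca`: eigenvalues, loadings,
#'   contribution rates, a per-gene score tibble and the candidate index
#'   set.
#' @examples
#' sim <- simulate_expression(seed = 1)
#' pca <- gene_pca(sim$data)
#' head(tidy(pca))
#' @export
gene_pca <- function(data, contribution_threshold = 0.01,
                     divisor = c("M", "M-1")) {
  H <- expr_covariance(data, divisor = divisor)
  e <- eigen_sorted(H)
  rates <- contribution_rates(e$values)
  ids <- gene_ids(data)
  scores <- gene_scores_(e$vectors, rates, contribution_threshold)
  res <- structure(list(
    eigenvalues = e$values,
    loadings = e$vectors,
    contribution_rates = rates,
    gene_scores = scores,
    gene_ids = ids,
    contribution_threshold = contribution_threshold,
    candidates = integer()
  ), class = "opca_pca")
  res$candidates <- candidate_genes(res, contribution_threshold)
  res
}

gene_scores_ <- function(loadings, rates, threshold) {
  keep <- which(rates > threshold)
  if (length(keep) == 0) return(rep(0, nrow(loadings)))
  s <- drop(loadings[, keep, drop = FALSE]^2 %*% rates[keep])
  tot <- sum(s)
  if (tot > 0) s <- s / tot
  s
}

#' Candidate gene set from PCA gene scores
#'
#' @param pca An `opca_pca` object from [gene_pca()].
#' @param threshold Fraction in (0, 1): genes with score above it become
#'   candidates. If none qualify, the top ceiling(sqrt(m)) genes by score
#'   are returned (deterministic, ties by lower index).
#' @return Integer vector of candidate gene indices, ascending.
#' @export
candidate_genes <- function(pca, threshold = pca$contribution_threshold) {
  if (threshold <= 0 || threshold >= 1) {
    rlang::abort("`threshold` must be in (0, 1)")
  }
  s <- if (isTRUE(all.equal(threshold, pca$contribution_threshold))) {
    pca$gene_scores
  } else {
    gene_scores_(pca$loadings, pca$contribution_rates, threshold)
  }
  cand <- which(s > threshold)
  if (length(cand) == 0) {
    k <- ceiling(sqrt(length(s)))
    cand <- sort(order(-s, seq_along(s))[seq_len(k)])
  }
  as.integer(cand)
}

#' @export
print.opca_pca <- function(x, ...) {
  cat(sprintf("<opca_pca> %d genes, %d components; %d candidates above %.3g\n",
              length(x$gene_ids), length(x$eigenvalues),
              length(x$candidates), x$contribution_threshold))
  cat(sprintf("  top contribution rates: %s\n",
              paste(sprintf("%.3f", utils::head(x$contribution_rates, 5)),
                    collapse = " ")))
  invisible(x)
}

#' @rdname tidy.opca_pca
#' @export
glance.opca_pca <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$gene_ids),
    n_components_retained = sum(x$contribution_rates > x$contribution_threshold),
    n_candidates = length(x$candidates),
    top_contribution = x$contribution_rates[1],
    contribution_threshold = x$contribution_threshold
  )
}

#' Tidy per-gene scores of a PCA screen
#'
#' @param x An `opca_pca` object.
#' @param ... Unused.
#' @return `tidy()`: one row per gene with its score and candidate flag,
#'   ordered by descending score. `glance()`: a one-row summary.
#' @export
tidy.opca_pca <- function(x, ...) {
  tibble::tibble(
    gene_id = x$gene_ids,
    gene_score = x$gene_scores,
    candidate = seq_along(x$gene_ids) %in% x$candidates
  ) |>
    dplyr::arrange(dplyr::desc(.data$gene_score))
}
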