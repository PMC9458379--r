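#' Min-max normalize a matrix column-wise
#'
#' Maps each column onto \[0, 1\] via (x - min) / (max - min); a constant
#' column maps to all zeros. Normalization is idempotent. Attributes are
#' normalized before any neighborhood computation so a radius in \[0, 2\]
#' is commensurate across genes.
#'
#' @param x Numeric matrix (samples in rows).
#' @return Numeric matrix of the same shape with values in \[0, 1\].
#' @export
normalize_minmax <- function(x) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) rlang::abort("non-finite value in attribute matrix")
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  rng <- hi - lo
  out <- sweep(x, 2, lo)
  pos <- rng > 0
  out[, pos] <- sweep(out[, pos, drop = FALSE], 2, rng[pos], "/")
  out[, !pos] <- 0
  out
}

#' Build a decision table for rough-set computation
#'
#' Restricts an expression dataset to a gene subset, min-max normalizes
#' each gene to \[0, 1\], and attaches the class labels as the decision
#' attribute and a neighborhood radius `delta`. This is the universe on
#' which neighborhoods, approximations, positive region and dependency
#' are computed.
#'
#' @inheritParams expr_matrix
#' @param delta Neighborhood radius in \[0, 2\].
#' @return Object of class `decision_table` with fields `attributes`
#'   (normalized matrix), `decision` (character vector), `delta`,
#'   `gene_ids`.
#' @export
decision_table <- function(data, genes = NULL, delta) {
  if (length(delta) != 1 || !is.finite(delta) || delta < 0 || delta > 2) {
    rlang::abort("`delta` must be a single radius in [0, 2]")
  }
  x <- expr_matrix(data, genes)
  if (nrow(x) < 2) rlang::abort("decision table needs at least 2 samples")
  dec <- as.character(data$label)
  if (length(unique(dec)) != 2) rlang::abort("decision must have exactly two classes")
  structure(list(
    attributes = normalize_minmax(x),
    decision = dec,
    delta = as.numeric(delta),
    gene_ids = colnames(x)
  ), class = "decision_table")
}

#' @export
print.decision_table <- function(x, ...) {
  cat(sprintf("<decision_table> %d samples x %d attributes, delta = %g\n",
              nrow(x$attributes), ncol(x$attributes), x$delta))
  invisible(x)
}

resolve_cols <- function(table, genes) {
  if (is.null(genes)) return(seq_along(table$gene_ids))
  if (is.character(genes)) {
    idx <- match(genes, table$gene_ids)
    if (anyNA(idx)) {
      rlang::abort(paste0("unknown attribute(s): ",
                          paste(genes[is.na(idx)], collapse = ", ")))
    }
    return(idx)
  }
  genes <- as.integer(genes)
  if (length(genes) && any(genes < 1 | genes > length(table$gene_ids))) {
    rlang::abort("attribute index out of range")
  }
  genes
}

# squared pairwise distances over an attribute subset (n x n, column order
# accumulation so results are reproducible to the last bit)
dist2_subset <- function(table, cols) {
  n <- nrow(table$attributes)
  D2 <- matrix(0, n, n)
  for (j in cols) {
    d <- outer(table$attributes[, j], table$attributes[, j], "-")
    D2 <- D2 + d * d
  }
  D2
}

#' Neighborhood of a sample
#'
#' The delta-neighborhood of sample `i` over attribute subset `B`:
#' all samples within Euclidean distance `delta` of `i` measured on the
#' columns in `B` (closed ball, so `i` itself always belongs). With an
#' empty `B` the distance is defined as 0 and the neighborhood is the
#' whole universe.
#'
#' @param table A `decision_table`.
#' @param i Sample index.
#' @param genes Attribute subset `B`: column indices or gene ids;
#'   `NULL` means all attributes, `integer(0)` the empty set.
#' @return Integer vector of sample indices, ascending.
#' @export
neighborhood <- function(table, i, genes = NULL) {
  n <- nrow(table$attributes)
  if (length(i) != 1 || i < 1 || i > n) rlang::abort("invalid sample index")
  cols <- resolve_cols(table, genes)
  if (length(cols) == 0) return(seq_len(n))
  d2 <- numeric(n)
  for (j in cols) {
    d <- table$attributes[, j] - table$attributes[i, j]
    d2 <- d2 + d * d
  }
  as.integer(which(unname(d2) <= table$delta^2))
}

#' Lower approximation of a decision class
#'
#' Samples whose entire neighborhood lies inside class `class`.
#'
#' @inheritParams neighborhood
#' @param class A decision class symbol present in the table.
#' @return Integer vector of sample indices.
#' @export
lower_approximation <- function(table, class, genes = NULL) {
  if (!class %in% table$decision) {
    rlang::abort(sprintf("unknown decision class '%s'", class))
  }
  cols <- resolve_cols(table, genes)
  D2 <- dist2_subset(table, cols)
  inside <- D2 <= table$delta^2
  in_class <- table$decision == class
  impure <- as.vector(inside %*% (!in_class))   # neighbors outside the class
  as.integer(which(in_class & impure == 0))
}

#' Positive region of a decision table
#'
#' Union of the lower approximations of every decision class: the
#' samples whose neighborhood is class-pure, i.e. that attribute subset
#' `B` classifies consistently at radius delta.
#'
#' @inheritParams neighborhood
#' @return Integer vector of sample indices.
#' @export
positive_region <- function(table, genes = NULL) {
  cols <- resolve_cols(table, genes)
  D2 <- dist2_subset(table, cols)
  inside <- D2 <= table$delta^2
  mism <- outer(table$decision, table$decision, "!=")
  as.integer(which(unname(rowSums(inside & mism)) == 0))
}

#' Dependency degree of an attribute subset
#'
#' gamma_B(D) = |POS_B(D)| / |U|: the fraction of samples whose
#' neighborhood under `B` is class-pure. For the empty subset every
#' neighborhood is the whole universe, so gamma is 0 whenever both
#' classes are present.
#'
#' @inheritParams neighborhood
#' @return A number in \[0, 1\].
#' @export
nrs_dependency <- function(table, genes = NULL) {
  length(positive_region(table, genes)) / nrow(table$attributes)
}

#' Significance (dependency gain) of an attribute
#'
#' SIG(a, B) = gamma(B + a) - gamma(B), also called the importance
#' degree of gene `a` relative to the current subset `B`. Non-negative, because
#' adding a coordinate never enlarges a Euclidean neighborhood. Returns
#' 0 when `a` is already in `B`.
#'
#' @inheritParams neighborhood
#' @param gene Attribute index or id to evaluate.
#' @param genes Current subset `B` (default empty).
#' @return Dependency gain, >= 0.
#' @export
attribute_significance <- function(table, gene, genes = integer()) {
  a <- resolve_cols(table, gene)
  B <- resolve_cols(table, genes)
  if (a %in% B) return(0)
  nrs_dependency(table, c(B, a)) - nrs_dependency(table, B)
}

# flattened n^2 engine used by the greedy search: per-gene squared
# difference matrices as columns, decision-mismatch mask as a vector
dt_engine <- function(table) {
  n <- nrow(table$attributes)
  m <- ncol(table$attributes)
  A2 <- matrix(0, n * n, m)
  for (j in seq_len(m)) {
    d <- outer(table$attributes[, j], table$attributes[, j], "-")
    A2[, j] <- as.vector(d * d)
  }
  list(A2 = A2, mism = as.vector(outer(table$decision, table$decision, "!=")),
       n = n, m = m)
}

dep_flat <- function(D2v, eng, d2) {
  bad <- (D2v <= d2) & eng$mism
  sum(.colSums(bad, eng$n, eng$n) == 0) / eng$n
}

#' Greedy significance-gated reduct search
#'
#' Forward selection over the decision table's attributes: starting from
#' the empty subset, repeatedly add the attribute with the largest
#' significance (dependency gain), as long as that gain exceeds
#' `significance_floor`. Ties go to the lowest attribute index, so the
#' search is fully deterministic. The result records the significance of
#' each accepted gene and the dependency after each acceptance.
#'
#' @param table A `decision_table`.
#' @param significance_floor Minimum gain to keep adding (>= 0);
#'   default 0.01.
#' @return Object of class `opca_reduct` with fields `selected` (ordered
#'   column indices), `gene_ids`, `significance_trace`,
#'   `dependency_trace`, `delta_used`, `final_dependency`.
#' @export
greedy_reduct <- function(table, significance_floor = 0.01) {
  if (significance_floor < 0) rlang::abort("`significance_floor` must be >= 0")
  eng <- dt_engine(table)
  d2 <- table$delta^2
  B <- integer()
  D2v <- numeric(eng$n * eng$n)
  depB <- dep_flat(D2v, eng, d2)
  sig_trace <- numeric()
  dep_trace <- numeric()
  while (length(B) < eng$m) {
    rem <- setdiff(seq_len(eng$m), B)
    deps <- vapply(rem, function(a) dep_flat(D2v + eng$A2[, a], eng, d2),
                   numeric(1))
    k <- which.max(deps)            # first max -> lowest index (rem ascending)
    if (deps[k] - depB <= significance_floor) break
    a <- rem[k]
    sig_trace <- c(sig_trace, deps[k] - depB)
    B <- c(B, a)
    D2v <- D2v + eng$A2[, a]
    depB <- deps[k]
    dep_trace <- c(dep_trace, depB)
  }
  new_reduct(B, table$gene_ids[B], sig_trace, dep_trace, table$delta)
}

new_reduct <- function(selected, ids, sig_trace, dep_trace, delta) {
  structure(list(
    selected = as.integer(selected),
    gene_ids = ids,
    significance_trace = sig_trace,
    dependency_trace = dep_trace,
    delta_used = delta,
    final_dependency = if (length(dep_trace)) dep_trace[length(dep_trace)] else 0
  ), class = "opca_reduct")
}

#' @export
print.opca_reduct <- function(x, ...) {
  cat(sprintf("<opca_reduct> %d genes at delta = %g, dependency = %.3f\n",
              length(x$selected), x$delta_used, x$final_dependency))
  if (length(x$selected)) {
    cat("  ", paste(x$gene_ids, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname tidy.opca_reduct
#' @export
glance.opca_reduct <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected),
    delta = x$delta_used,
    final_dependency = x$final_dependency
  )
}

#' Tidy the selection trace of a reduct
#'
#' @param x An `opca_reduct`.
#' @param ... Unused.
#' @return `tidy()`: one row per accepted gene (rank, gene id,
#'   significance at acceptance, cumulative dependency). `glance()`: a
#'   one-row summary.
#' @export
tidy.opca_reduct <- function(x, ...) {
  tibble::tibble(
    rank = seq_along(x$selected),
    gene_id = if (is.null(x$gene_ids)) as.character(x$selected) else x$gene_ids,
    significance = x$significance_trace,
    cumulative_dependency = x$dependency_trace
  )
}

#' Sweep the neighborhood radius over a grid
#'
#' Runs [greedy_reduct()] at every radius in `delta_grid` (deduplicated,
#' ascending) and scores each reduct, either with a caller-supplied
#' evaluator (e.g. cross-validated accuracy of the selected panel) or,
#' by default, by its final dependency. Returns the best radius and its
#' reduct; ties are resolved toward fewer selected genes, then the
#' smaller radius.
#'
#' @inheritParams expr_matrix
#' @param delta_grid Numeric vector of radii in \[0, 2\].
#' @param significance_floor Gain floor passed to [greedy_reduct()].
#' @param evaluator Optional `function(gene_ids) -> score` where
#'   `gene_ids` are dataset gene ids (possibly empty). `NULL` scores by
#'   final dependency.
#' @return Object of class `opca_radius_search`: `best_delta`, `reduct`
#'   (an `opca_reduct` whose `selected` indices refer to the full
#'   dataset), and `grid`, a tibble with one row per radius.
#' @export
radius_search <- function(data, genes = NULL, delta_grid = seq(0, 2, by = 0.01),
                          significance_floor = 0.01, evaluator = NULL) {
  grid <- sort(unique(as.numeric(delta_grid)))
  if (length(grid) == 0) rlang::abort("`delta_grid` must be non-empty")
  if (any(grid < 0 | grid > 2)) rlang::abort("all radii must lie in [0, 2]")
  ids <- gene_ids(data)
  if (is.null(genes)) genes <- seq_along(ids)
  if (is.character(genes)) genes <- match(genes, ids)
  genes <- as.integer(genes)
  base <- decision_table(data, genes, delta = grid[1])
  cache <- new.env(parent = emptyenv())
  score_of <- function(sel_ids) {
    if (is.null(evaluator)) return(NA_real_)
    key <- paste0("k:", paste(sel_ids, collapse = "\r"))
    if (is.null(cache[[key]])) cache[[key]] <- evaluator(sel_ids)
    cache[[key]]
  }
  rows <- vector("list", length(grid))
  best <- NULL
  best_score <- -Inf
  for (g in seq_along(grid)) {
    tab <- base
    tab$delta <- grid[g]
    red <- greedy_reduct(tab, significance_floor)
    score <- if (is.null(evaluator)) red$final_dependency else score_of(red$gene_ids)
    rows[[g]] <- tibble::tibble(delta = grid[g], n_genes = length(red$selected),
                                score = score,
                                final_dependency = red$final_dependency)
    better <- score > best_score ||
      (score == best_score && length(red$selected) < length(best$selected))
    if (is.null(best) || better) {
      best <- red
      best_score <- score
    }
  }
  # re-express the winning reduct in full-dataset gene indices
  best$selected <- genes[best$selected]
  structure(list(
    best_delta = best$delta_used,
    reduct = best,
    grid = dplyr::bind_rows(rows)
  ), class = "opca_radius_search")
}

#' @export
print.opca_radius_search <- function(x, ...) {
  cat(sprintf("<opca_radius_search> best delta = %g (%d radii searched)\n",
              x$best_delta, nrow(x$grid)))
  print(x$reduct)
  invisible(x)
}
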