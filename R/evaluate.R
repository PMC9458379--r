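#' Precision and accuracy from confusion counts
#'
#' Standard pooled definitions: precision = TP / (TP + FP) for the
#' designated positive class (0 when that denominator is 0), accuracy =
#' (TP + TN) / total.
#'
#' @param tp,fp,fn,tn Non-negative confusion counts; total must be > 0.
#' @return One-row tibble with `precision` and `accuracy`.
#' @export
compute_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) rlang::abort("confusion counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) rlang::abort("total count must be positive")
  tibble::tibble(
    precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    accuracy = (tp + tn) / total
  )
}

# deterministic stratified fold ids; samples of each class are shuffled
# under the seed then dealt round-robin into folds
stratified_folds <- function(labels, k, seed) {
  counts <- table(labels)
  if (any(counts < k)) {
    rlang::abort(sprintf(
      "class '%s' has %d samples, fewer than %d folds; use fewer folds",
      names(counts)[which.min(counts)], min(counts), k))
  }
  fold <- integer(length(labels))
  rng <- local_seed(seed)
  on.exit(rng())
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# set.seed scoped to the caller: returns a restore function
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

fit_predict <- function(train_x, train_y, test_x, classifier) {
  if (classifier == "knn1") {
    as.character(class::knn(train_x, test_x, cl = factor(train_y), k = 1))
  } else {
    sds <- apply(train_x, 2, stats::sd)
    fit <- e1071::svm(train_x, factor(train_y), kernel = "linear",
                      scale = sds > 0)
    as.character(stats::predict(fit, test_x))
  }
}

#' Cross-validated evaluation of a gene panel
#'
#' Stratified k-fold cross-validation of a classifier restricted to the
#' given genes: the classifier is refit on the training folds only, the
#' held-out confusion counts are pooled over folds, and precision /
#' accuracy are computed from the pooled counts. Fold assignment is a
#' deterministic function of the seed, so repeated calls are identical.
#'
#' @inheritParams expr_matrix
#' @param genes Gene ids or indices of the panel to evaluate (>= 1 gene).
#' @param classifier `"linear-svm"` (default) or `"knn1"`.
#' @param folds Number of stratified folds; every class needs at least
#'   `folds` samples.
#' @param seed Integer seed for the fold assignment.
#' @param positive_class Label treated as positive for precision;
#'   default the lexicographically larger of the two.
#' @return Object of class `opca_eval` with pooled `precision` and
#'   `accuracy`, the `per_fold` confusion tibble, and the protocol
#'   fields.
#' @examples
#' sim <- simulate_expression(seed = 1)
#' ev <- cross_validate(sim$data, genes = head(gene_ids(sim$data), 5))
#' glance(ev)
#' @export
cross_validate <- function(data, genes, classifier = c("linear-svm", "knn1"),
                           folds = 10, seed = 1, positive_class = NULL) {
  classifier <- match.arg(classifier)
  x <- expr_matrix(data, genes)
  if (ncol(x) < 1) rlang::abort("at least one gene is required")
  y <- as.character(data$label)
  classes <- sort(unique(y))
  if (is.null(positive_class)) positive_class <- classes[length(classes)]
  if (!positive_class %in% classes) {
    rlang::abort(sprintf("positive class '%s' not present in labels", positive_class))
  }
  fold <- stratified_folds(y, folds, seed)
  per_fold <- purrr::map_dfr(seq_len(folds), function(f) {
    test <- fold == f
    pred <- fit_predict(x[!test, , drop = FALSE], y[!test],
                        x[test, , drop = FALSE], classifier)
    truth <- y[test]
    tibble::tibble(
      fold = f,
      tp = sum(pred == positive_class & truth == positive_class),
      fp = sum(pred == positive_class & truth != positive_class),
      fn = sum(pred != positive_class & truth == positive_class),
      tn = sum(pred != positive_class & truth != positive_class)
    )
  })
  pooled <- compute_metrics(sum(per_fold$tp), sum(per_fold$fp),
                            sum(per_fold$fn), sum(per_fold$tn))
  structure(list(
    precision = pooled$precision,
    accuracy = pooled$accuracy,
    per_fold = per_fold,
    n_features_used = ncol(x),
    classifier = classifier,
    folds = as.integer(folds),
    seed = as.integer(seed),
    positive_class = positive_class
  ), class = "opca_eval")
}

#' @export
print.opca_eval <- function(x, ...) {
  cat(sprintf(
    "<opca_eval> %s, %d-fold CV, %d features: precision %.3f, accuracy %.3f\n",
    x$classifier, x$folds, x$n_features_used, x$precision, x$accuracy))
  invisible(x)
}

#' @rdname tidy.opca_eval
#' @export
glance.opca_eval <- function(x, ...) {
  tibble::tibble(
    precision = x$precision,
    accuracy = x$accuracy,
    n_features_used = x$n_features_used,
    classifier = x$classifier,
    folds = x$folds,
    seed = x$seed,
    positive_class = x$positive_class
  )
}

#' Tidy per-fold confusion counts
#'
#' @param x An `opca_eval` object.
#' @param ... Unused.
#' @return `tidy()`: one row per fold with TP/FP/FN/TN. `glance()`: the
#'   pooled one-row summary.
#' @export
tidy.opca_eval <- function(x, ...) x$per_fold

#' Run the full OPCA selection pipeline
#'
#' The complete method: (1) PCA screen — covariance eigenstructure,
#' contribution rates, candidate genes above the 1% threshold; (2)
#' min-max normalization of the candidates into a decision table; (3)
#' radius sweep — at each delta in the grid a greedy significance-gated
#' reduct is grown and scored by cross-validated accuracy of the panel;
#' (4) the best radius's reduct is evaluated with the full CV protocol.
#' If the winning reduct is empty, the report falls back to the single
#' best-scoring candidate gene and is flagged.
#'
#' @inheritParams expr_matrix
#' @param config An [opca_config()].
#' @return Object of class `opca_fit` with components `pca`
#'   (`opca_pca`), `reduct` (`opca_reduct`), `evaluation` (`opca_eval`),
#'   `search` (the radius-sweep grid tibble), `config`, and
#'   `fallback_used`.
#' @examples
#' \donttest{
#' sim <- simulate_expression(seed = 1)
#' fit <- run_opca(sim$data, opca_config(delta_grid = seq(0, 2, by = 0.1)))
#' glance(fit)
#' }
#' @export
run_opca <- function(data, config = opca_config()) {
  stopifnot(inherits(config, "opca_config"))
  pca <- gene_pca(data, config$contribution_threshold)
  ids <- gene_ids(data)
  evaluator <- function(sel_ids) {
    if (length(sel_ids) == 0) return(0)
    glance(cross_validate(data, sel_ids, classifier = config$classifier,
                          folds = config$cv_folds, seed = config$seed,
                          positive_class = config$positive_class))$accuracy
  }
  search <- radius_search(data, genes = pca$candidates,
                          delta_grid = config$delta_grid,
                          significance_floor = config$significance_floor,
                          evaluator = evaluator)
  reduct <- search$reduct
  fallback <- length(reduct$selected) == 0
  eval_genes <- if (fallback) {
    # single best-scoring candidate gene, deterministic tie-break
    best <- pca$candidates[order(-pca$gene_scores[pca$candidates],
                                 pca$candidates)][1]
    ids[best]
  } else {
    reduct$gene_ids
  }
  evaluation <- cross_validate(data, eval_genes, classifier = config$classifier,
                               folds = config$cv_folds, seed = config$seed,
                               positive_class = config$positive_class)
  structure(list(
    pca = pca,
    reduct = reduct,
    evaluation = evaluation,
    search = search$grid,
    config = config,
    fallback_used = fallback,
    evaluated_genes = eval_genes
  ), class = "opca_fit")
}

#' @export
print.opca_fit <- function(x, ...) {
  cat("<opca_fit>\n")
  cat(sprintf("  candidates after PCA screen: %d\n", length(x$pca$candidates)))
  print(x$reduct)
  if (x$fallback_used) {
    cat("  empty reduct: metrics computed on best single candidate gene\n")
  }
  print(x$evaluation)
  invisible(x)
}

#' @rdname tidy.opca_fit
#' @export
glance.opca_fit <- function(x, ...) {
  tibble::tibble(
    n_candidates = length(x$pca$candidates),
    n_selected = length(x$reduct$selected),
    delta = x$reduct$delta_used,
    final_dependency = x$reduct$final_dependency,
    precision = x$evaluation$precision,
    accuracy = x$evaluation$accuracy,
    classifier = x$evaluation$classifier,
    fallback_used = x$fallback_used
  )
}

#' Tidy the selected panel of a fitted pipeline
#'
#' @param x An `opca_fit` object.
#' @param ... Unused.
#' @return `tidy()`: one row per selected gene with its acceptance
#'   significance and cumulative dependency. `glance()`: a one-row
#'   summary of the whole run.
#' @export
tidy.opca_fit <- function(x, ...) tidy(x$reduct)

#' Nested cross-validation of the whole selection pipeline
#'
#' The honest performance estimate: the entire OPCA pipeline (PCA
#' screen, radius sweep, greedy reduct) is re-run from scratch inside
#' each training fold, the fold's panel is fit on the training samples
#' only, and the held-out confusion counts are pooled. Unlike
#' [run_opca()]'s report -- which evaluates a panel selected on the full
#' data and is therefore optimistic when no true signal exists -- this
#' estimator is unbiased at chance level under a null dataset.
#'
#' @inheritParams run_opca
#' @return An `opca_eval` whose `n_features_used` is the mean panel size
#'   across folds, with a `panel_sizes` field recording each fold's
#'   panel.
#' @export
nested_opca_cv <- function(data, config = opca_config()) {
  y <- as.character(data$label)
  classes <- sort(unique(y))
  positive <- config$positive_class %||% classes[length(classes)]
  fold <- stratified_folds(y, config$cv_folds, config$seed)
  x_all <- expr_matrix(data)
  per_fold <- purrr::map_dfr(seq_len(config$cv_folds), function(f) {
    test <- fold == f
    fit <- run_opca(data[!test, , drop = FALSE], config)
    genes <- fit$evaluated_genes
    pred <- fit_predict(x_all[!test, genes, drop = FALSE], y[!test],
                        x_all[test, genes, drop = FALSE], config$classifier)
    truth <- y[test]
    tibble::tibble(
      fold = f,
      tp = sum(pred == positive & truth == positive),
      fp = sum(pred == positive & truth != positive),
      fn = sum(pred != positive & truth == positive),
      tn = sum(pred != positive & truth != positive),
      n_panel = length(genes)
    )
  })
  pooled <- compute_metrics(sum(per_fold$tp), sum(per_fold$fp),
                            sum(per_fold$fn), sum(per_fold$tn))
  structure(list(
    precision = pooled$precision,
    accuracy = pooled$accuracy,
    per_fold = per_fold[, c("fold", "tp", "fp", "fn", "tn")],
    n_features_used = mean(per_fold$n_panel),
    panel_sizes = per_fold$n_panel,
    classifier = config$classifier,
    folds = config$cv_folds,
    seed = config$seed,
    positive_class = positive
  ), class = "opca_eval")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare OPCA against PCA-only and rough-set-only selection
#'
#' Runs up to three selectors under the identical cross-validation
#' protocol and reports one row per method: `"opca"` is the full
#' pipeline; `"pca"` takes the top candidate genes by PCA gene score
#' alone, capped at OPCA's panel size (minimum 1) for comparability;
#' `"nrs"` runs the greedy rough-set reduction over all genes with no
#' PCA screen.
#'
#' @inheritParams run_opca
#' @param methods Non-empty subset of `c("opca", "pca", "nrs")`.
#' @return Tibble with columns `method`, `n_genes`, `precision`,
#'   `accuracy`, `delta`.
#' @export
compare_selectors <- function(data, config = opca_config(),
                              methods = c("opca", "pca", "nrs")) {
  valid <- c("opca", "pca", "nrs")
  if (length(methods) == 0 || !all(methods %in% valid)) {
    rlang::abort(paste0("`methods` must be a non-empty subset of: ",
                        paste(valid, collapse = ", ")))
  }
  ids <- gene_ids(data)
  evaluate <- function(genes) {
    glance(cross_validate(data, genes, classifier = config$classifier,
                          folds = config$cv_folds, seed = config$seed,
                          positive_class = config$positive_class))
  }
  fit <- NULL
  need_fit <- any(c("opca", "pca") %in% methods)
  if (need_fit) fit <- run_opca(data, config)
  rows <- purrr::map(methods, function(mth) {
    if (mth == "opca") {
      g <- glance(fit)
      tibble::tibble(method = "opca", n_genes = g$n_selected,
                     precision = g$precision, accuracy = g$accuracy,
                     delta = g$delta)
    } else if (mth == "pca") {
      k <- max(1L, length(fit$reduct$selected))
      top <- order(-fit$pca$gene_scores, seq_along(ids))[seq_len(k)]
      ev <- evaluate(ids[sort(top)])
      tibble::tibble(method = "pca", n_genes = k,
                     precision = ev$precision, accuracy = ev$accuracy,
                     delta = NA_real_)
    } else {
      evaluator <- function(sel_ids) {
        if (length(sel_ids) == 0) return(0)
        evaluate(sel_ids)$accuracy
      }
      search <- radius_search(data, genes = NULL,
                              delta_grid = config$delta_grid,
                              significance_floor = config$significance_floor,
                              evaluator = evaluator)
      red <- search$reduct
      genes <- red$gene_ids
      if (length(genes) == 0) {
        # fall back to the single most significant gene at the chosen radius
        tab <- decision_table(data, NULL, delta = search$best_delta)
        deps <- vapply(seq_along(ids), function(j) nrs_dependency(tab, j),
                       numeric(1))
        genes <- ids[order(-deps, seq_along(ids))[1]]
      }
      ev <- evaluate(genes)
      tibble::tibble(method = "nrs", n_genes = length(red$selected),
                     precision = ev$precision, accuracy = ev$accuracy,
                     delta = search$best_delta)
    }
  })
  dplyr::bind_rows(rows)
}
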