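test_that("confusion metrics follow the pooled definitions with guards", {
  m <- compute_metrics(3, 1, 2, 4)
  expect_equal(m$precision, 0.75)
  expect_equal(m$accuracy, 0.7)
  expect_equal(compute_metrics(0, 0, 5, 5),
               tibble::tibble(precision = 0, accuracy = 0.5))
  expect_equal(compute_metrics(7, 0, 0, 3),
               tibble::tibble(precision = 1, accuracy = 1))
  expect_error(compute_metrics(-1, 0, 0, 2), "non-negative")
  expect_error(compute_metrics(0, 0, 0, 0), "positive")
})

test_that("cross-validation separates a label-encoding gene perfectly", {
  set.seed(8)
  labels <- rep(c("tumor", "normal"), each = 15)
  x <- cbind(ifelse(labels == "tumor", 1, 0) + rnorm(30, sd = 0.01),
             rnorm(30))
  d <- expression_data(x, labels = labels)
  for (clf in c("linear-svm", "knn1")) {
    ev <- cross_validate(d, "g001", classifier = clf, folds = 5, seed = 1)
    expect_equal(ev$accuracy, 1)
    expect_equal(ev$precision, 1)
  }
})

test_that("cross-validation is deterministic, pooled, and stratified", {
  sim <- simulate_expression(seed = 4)
  genes <- head(gene_ids(sim$data), 4)
  ev1 <- cross_validate(sim$data, genes, folds = 10, seed = 7)
  ev2 <- cross_validate(sim$data, genes, folds = 10, seed = 7)
  expect_identical(ev1, ev2)

  # pooled metrics equal metrics recomputed from summed per-fold counts
  pf <- tidy(ev1)
  expect_equal(nrow(pf), 10)
  re <- compute_metrics(sum(pf$tp), sum(pf$fp), sum(pf$fn), sum(pf$tn))
  expect_equal(ev1$precision, re$precision)
  expect_equal(ev1$accuracy, re$accuracy)
  # every sample appears exactly once across folds
  expect_equal(sum(pf$tp + pf$fp + pf$fn + pf$tn), nrow(sim$data))

  # positive class defaults to the lexicographically larger label
  expect_identical(ev1$positive_class, "tumor")

  # a class smaller than the fold count is refused with advice
  small <- simulate_expression(n_pos = 4, n_neg = 20, n_noise = 10,
                               n_redundant = 0, n_informative = 2, seed = 1)
  expect_error(cross_validate(small$data, "g0001", folds = 10),
               "fewer folds")
})

test_that("a fixed panel on label-independent data scores at chance", {
  # genes chosen without looking at the labels: CV accuracy is unbiased
  acc <- vapply(1:20, function(s) {
    sim <- simulate_expression(effect_size = 0, n_informative = 2,
                               n_redundant = 0, n_noise = 18, seed = s)
    cross_validate(sim$data, head(gene_ids(sim$data), 3), seed = s)$accuracy
  }, numeric(1))
  se <- stats::sd(acc) / sqrt(length(acc))
  expect_lt(abs(mean(acc) - 0.5), 3 * se + 1e-12)
})

test_that("nested cross-validation re-selects per fold and stays honest", {
  sim <- simulate_expression(n_noise = 40, n_redundant = 4, seed = 5)
  cfg <- opca_config(delta_grid = seq(0, 2, by = 0.1), seed = 5)
  ev <- nested_opca_cv(sim$data, cfg)
  expect_s3_class(ev, "opca_eval")
  expect_equal(nrow(ev$per_fold), cfg$cv_folds)
  expect_length(ev$panel_sizes, cfg$cv_folds)
  expect_gt(ev$accuracy, 0.5)   # real signal survives honest evaluation
  expect_identical(ev$per_fold, nested_opca_cv(sim$data, cfg)$per_fold)
})

test_that("the full pipeline recovers planted structure and is deterministic", {
  sim <- simulate_expression(seed = 1)
  cfg <- opca_config(delta_grid = seq(0, 2, by = 0.05), seed = 1)
  fit <- run_opca(sim$data, cfg)
  expect_s3_class(fit, "opca_fit")
  expect_gt(length(fit$reduct$selected), 0)
  expect_lte(length(fit$reduct$selected), 20)
  expect_gt(fit$evaluation$accuracy, 0.5)
  expect_false(fit$fallback_used)

  fit2 <- run_opca(sim$data, cfg)
  expect_identical(fit$reduct$gene_ids, fit2$reduct$gene_ids)
  expect_identical(glance(fit), glance(fit2))

  # singleton grid skips the search
  fit3 <- run_opca(sim$data, opca_config(delta_grid = 0.3, seed = 1))
  expect_equal(nrow(fit3$search), 1)
  expect_identical(fit3$reduct$delta_used, 0.3)

  # tidy/glance surface the panel and the summary
  expect_equal(tidy(fit)$gene_id, fit$reduct$gene_ids)
  g <- glance(fit)
  expect_true(all(c("n_candidates", "n_selected", "delta", "precision",
                    "accuracy") %in% names(g)))
})

test_that("selector comparison has one row per method and shared metrics", {
  sim <- simulate_expression(n_noise = 40, n_redundant = 6, seed = 2)
  cfg <- opca_config(delta_grid = seq(0.1, 1, by = 0.1), seed = 2)
  tab <- compare_selectors(sim$data, cfg, methods = c("opca", "pca", "nrs"))
  expect_equal(tab$method, c("opca", "pca", "nrs"))
  expect_true(all(is.finite(tab$precision)))
  expect_true(all(is.finite(tab$accuracy)))
  expect_true(all(tab$n_genes >= 0))

  one <- compare_selectors(sim$data, cfg, methods = "opca")
  expect_equal(nrow(one), 1)

  expect_error(compare_selectors(sim$data, cfg, methods = "magic"),
               "opca, pca, nrs")
  expect_error(compare_selectors(sim$data, cfg, methods = character()),
               "non-empty")
})
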