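test_that("min-max normalization maps endpoints, guards constants, idempotent", {
  x <- cbind(c(0, 5, 10), c(7, 7, 7))
  nx <- normalize_minmax(x)
  expect_equal(unname(nx[, 1]), c(0, 0.5, 1))
  expect_equal(unname(nx[, 2]), c(0, 0, 0))
  expect_identical(normalize_minmax(nx), nx)
  expect_error(normalize_minmax(cbind(c(1, NA))), "non-finite")
})

test_that("neighborhoods on the toy table enumerate exactly", {
  t1 <- toy_t1(0.2)
  expect_equal(neighborhood(t1, 1, "a1"), c(1L, 2L))
  expect_equal(neighborhood(t1, 3, "a1"), c(3L, 4L))
  expect_error(neighborhood(t1, 9, "a1"), "sample index")

  t1w <- with_delta(t1, 1.0)
  expect_equal(neighborhood(t1w, 1, "a1"), 1:4)

  # empty attribute set: zero distance, neighborhood is the universe
  expect_equal(neighborhood(t1, 2, integer()), 1:4)

  # reflexivity and symmetry across random tables
  for (seed in 1:10) {
    tab <- random_table(12, 3, delta = runif(1, 0.1, 1), seed = seed)
    for (i in seq_len(12)) {
      nb <- neighborhood(tab, i)
      expect_true(i %in% nb)
      for (j in nb) expect_true(i %in% neighborhood(tab, j))
    }
  }
})

test_that("approximations, positive region and dependency are exact on T1", {
  t1 <- toy_t1(0.2)
  expect_equal(lower_approximation(t1, "+", "a1"), c(1L, 2L))
  expect_equal(positive_region(t1, "a1"), 1:4)
  expect_identical(nrs_dependency(t1, "a1"), 1)

  t1w <- with_delta(t1, 1.0)
  expect_length(lower_approximation(t1w, "+", "a1"), 0)
  expect_length(positive_region(t1w, "a1"), 0)
  expect_identical(nrs_dependency(t1w, "a1"), 0)

  expect_error(lower_approximation(t1, "bogus", "a1"), "unknown decision class")

  # delta at least the data diameter: every neighborhood is the whole
  # impure universe, so the positive region empties
  t_all <- with_delta(t1, 2.0)
  expect_length(positive_region(t_all), 0)
  expect_identical(nrs_dependency(t_all, integer()), 0)
})

test_that("significance is the dependency gain, zero for members, never negative", {
  t1 <- toy_t1(0.2)
  expect_identical(attribute_significance(t1, "a1", integer()), 1)
  expect_identical(attribute_significance(t1, "a1", "a1"), 0)

  # duplicated column: gains stay non-negative at any radius
  x <- matrix(runif(16), 4, 4)
  x[, 4] <- x[, 1]
  d <- expression_data(x, labels = c("a", "a", "b", "b"))
  for (delta in c(0.1, 0.4, 0.9)) {
    tab <- decision_table(d, delta = delta)
    expect_gte(attribute_significance(tab, 4, 1), 0)
    expect_gte(attribute_significance(tab, 1, c(2, 4)), 0)
  }
})

test_that("rough-set primitives agree exactly with brute-force enumeration", {
  for (seed in 1:30) {
    set.seed(seed + 500)
    n <- sample(4:20, 1)
    m <- sample(1:5, 1)
    tab <- random_table(n, m, delta = runif(1, 0, 1.2), seed = seed)
    cols <- sort(sample(seq_len(m), sample(seq_len(m), 1)))
    i <- sample(n, 1)
    expect_identical(neighborhood(tab, i, cols), oracle_neighborhood(tab, i, cols))
    for (cl in unique(tab$decision)) {
      expect_identical(lower_approximation(tab, cl, cols),
                       oracle_lower_approximation(tab, cl, cols))
    }
    expect_identical(positive_region(tab, cols), oracle_positive_region(tab, cols))
    expect_identical(nrs_dependency(tab, cols), oracle_dependency(tab, cols))
  }
})

test_that("dependency is monotone in attributes and anti-monotone in radius", {
  for (trial in 1:60) {
    set.seed(trial + 900)
    tab <- random_table(sample(6:14, 1), 5, delta = runif(1, 0.05, 1),
                        seed = trial + 31)
    B2 <- sort(resample(1:5, sample(2:5, 1)))
    B1 <- sort(resample(B2, sample(length(B2), 1)))
    expect_lte(nrs_dependency(tab, B1), nrs_dependency(tab, B2))

    d1 <- runif(1, 0, 1)
    d2 <- d1 + runif(1, 0, 1)
    expect_gte(nrs_dependency(with_delta(tab, d1), B2),
               nrs_dependency(with_delta(tab, d2), B2))

    rest <- setdiff(1:5, B1)
    if (length(rest)) {
      a <- resample(rest, 1)
      expect_gte(attribute_significance(tab, a, B1), 0)
    }
  }
})

test_that("greedy reduct solves T1, respects the floor and is deterministic", {
  t1 <- toy_t1(0.2)
  red <- greedy_reduct(t1, 0.01)
  expect_identical(red$selected, 1L)          # a1 wins the tie with a2
  expect_identical(red$gene_ids, "a1")
  expect_identical(red$final_dependency, 1)
  expect_identical(red$significance_trace, 1)

  # floor >= 1 gates everything out
  red0 <- greedy_reduct(t1, significance_floor = 1)
  expect_length(red0$selected, 0)
  expect_identical(red0$final_dependency, 0)

  # traces are consistent and dependency non-decreasing
  for (seed in 1:10) {
    tab <- random_table(14, 6, delta = 0.35, seed = seed + 70)
    r <- greedy_reduct(tab, 0.01)
    expect_lte(length(r$selected), 6)
    expect_identical(anyDuplicated(r$selected), 0L)
    expect_true(all(r$significance_trace > 0.01))
    expect_true(all(diff(c(0, r$dependency_trace)) > 0))
    r2 <- greedy_reduct(tab, 0.01)
    expect_identical(r, r2)
  }
})

test_that("greedy attains full dependency whenever some subset does", {
  for (seed in 1:8) {
    set.seed(seed)
    tab <- random_table(12, 6, delta = runif(1, 0.02, 0.15), seed = seed + 40)
    subsets <- lapply(1:63, function(k) which(bitwAnd(k, 2^(0:5)) > 0))
    best <- max(vapply(subsets, function(s) nrs_dependency(tab, s), numeric(1)))
    red <- greedy_reduct(tab, 0.01)
    if (best == 1) expect_identical(red$final_dependency, 1)
  }
})

test_that("radius search scores reducts and breaks ties deterministically", {
  t1 <- toy_t1(0.2)
  d <- expression_data(t1$attributes, labels = t1$decision)

  # dependency scoring picks the radius that separates the classes
  rs <- radius_search(d, delta_grid = c(0.2, 1.0), significance_floor = 0.01)
  expect_identical(rs$best_delta, 0.2)
  expect_identical(rs$reduct$final_dependency, 1)

  # singleton grid returns that radius; duplicates are deduplicated
  rs1 <- radius_search(d, delta_grid = 0.2)
  expect_identical(rs1$best_delta, 0.2)
  rs2 <- radius_search(d, delta_grid = c(0.2, 1.0, 0.2, 1.0))
  expect_identical(rs2$grid, rs$grid)
  expect_identical(rs2$best_delta, rs$best_delta)

  expect_error(radius_search(d, delta_grid = numeric()), "non-empty")
  expect_error(radius_search(d, delta_grid = c(0.5, 3)), "\\[0, 2\\]")

  # a custom evaluator drives the choice
  rs3 <- radius_search(d, delta_grid = c(0.2, 1.0),
                       evaluator = function(ids) length(ids))
  expect_identical(rs3$best_delta, 0.2)
})
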