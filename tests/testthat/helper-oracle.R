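# Brute-force double-loop reference implementations of the rough-set
# primitives, kept deliberately independent of the package's vectorized
# engine, plus small random-table builders shared across tests.

oracle_neighborhood <- function(tab, i, cols) {
  X <- tab$attributes
  n <- nrow(X)
  out <- integer()
  for (j in seq_len(n)) {
    d2 <- 0
    for (cc in cols) d2 <- d2 + (X[i, cc] - X[j, cc])^2
    if (d2 <= tab$delta^2) out <- c(out, j)
  }
  out
}

oracle_lower_approximation <- function(tab, class, cols) {
  n <- nrow(tab$attributes)
  out <- integer()
  for (i in seq_len(n)) {
    nb <- oracle_neighborhood(tab, i, cols)
    if (all(tab$decision[nb] == class)) out <- c(out, i)
  }
  out
}

oracle_positive_region <- function(tab, cols) {
  sort(unique(unlist(lapply(unique(tab$decision), function(cl) {
    oracle_lower_approximation(tab, cl, cols)
  }))))
}

oracle_dependency <- function(tab, cols) {
  length(oracle_positive_region(tab, cols)) / nrow(tab$attributes)
}

# random two-class decision table on [0,1] attributes
random_table <- function(n, m, delta, seed) {
  set.seed(seed)
  x <- matrix(stats::runif(n * m), n, m)
  labels <- sample(c("a", "b"), n, replace = TRUE)
  labels[1:2] <- c("a", "b")    # both classes always present
  tab <- decision_table(expression_data(x, labels), delta = delta)
  tab
}

# the toy table printed in the docs/tests: two attributes, two classes
toy_t1 <- function(delta = 0.2) {
  x <- matrix(c(0.0, 0.1, 0.9, 1.0,
                0.0, 0.0, 1.0, 0.9), ncol = 2)
  colnames(x) <- c("a1", "a2")
  decision_table(expression_data(x, labels = c("+", "+", "-", "-")),
                 delta = delta)
}

# sample() without the scalar-x surprise
resample <- function(x, k) x[sample.int(length(x), k)]

with_delta <- function(tab, delta) {
  tab$delta <- delta
  tab
}
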