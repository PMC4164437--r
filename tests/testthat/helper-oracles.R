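# Shared fixtures and independent oracles for the test suite.

# Worked example used throughout: balanced genotypes, binary trait.
worked_example <- function() {
  list(g = c(0, 0, 1, 1, 2, 2), y = c(0, 0, 0, 1, 1, 1))
}

# Central-difference gradient of f at x (independent numeric oracle).
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# Random complete-case instance with all three genotype classes present.
random_instance <- function(n = 40, q = 2) {
  repeat {
    g <- sample(0:2, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    if (length(unique(g)) == 3L) break
  }
  y <- matrix(stats::rnorm(n * q), n, q)
  list(g = g, y = y)
}

# Expand a 2x3 case-control table (rows control/case) into (g, y) vectors.
expand_cc_table <- function(control, case) {
  list(g = c(rep(0:2, control), rep(0:2, case)),
       y = rep(c(0, 1), c(sum(control), sum(case))))
}

# Binary logistic-regression score test of a 0/1 response z on
# covariates y: U = sum (z - zbar) y, V = zbar(1-zbar) * sum (y-ybar)^2
# cross-products.  Used as the two-genotype-category reduction oracle.
binary_logistic_score <- function(z, y) {
  y <- as.matrix(y)
  zb <- mean(z)
  yc <- sweep(y, 2, colMeans(y))
  U <- drop(crossprod(z - zb, yc))
  V <- zb * (1 - zb) * crossprod(yc)
  stat <- drop(crossprod(U, solve(V, U)))
  list(statistic = stat, df = ncol(y),
       p.value = stats::pchisq(stat, ncol(y), lower.tail = FALSE))
}
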