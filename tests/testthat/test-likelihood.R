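# A fixed 12-observation dataset with all three genotype classes and a
# moderate, non-separating phenotype effect.
mle_fixture <- function() {
  list(g = c(0, 0, 0, 1, 1, 2, 2, 1, 0, 2, 1, 0),
       y = c(0.5, -1, 0, 1, 0.2, 1.5, 0.3, -0.4, 0.8, 1.1, -0.2, -1.3))
}

test_that("log-likelihood closed forms at the null", {
  g <- c(0, 0, 1, 1, 2, 2)
  ll <- po_loglik(g, rnorm(6), alpha = qlogis(c(1 / 3, 2 / 3)), beta = 0)
  expect_equal(ll, 6 * log(1 / 3))

  # at beta = 0 with alpha = logits of the null fit, the likelihood is the
  # saturated trinomial value sum n_j log p_j
  fx <- mle_fixture()
  fit <- po_null_fit(fx$g)
  ll <- po_loglik(fx$g, fx$y, qlogis(c(fit$gamma1, fit$gamma2)), 0)
  expect_equal(ll, sum(fit$counts * log(fit$proportions)))

  # out-of-order intercepts hit the -Inf contract, not an error
  expect_identical(po_loglik(g, rnorm(6), alpha = c(1, 0), beta = 0), -Inf)
})

test_that("score vector equals the numeric gradient of the log-likelihood", {
  set.seed(101)
  for (i in 1:20) {
    inst <- random_instance(n = sample(20:80, 1), q = sample(1:3, 1))
    fit <- po_null_fit(inst$g)
    a_hat <- qlogis(c(fit$gamma1, fit$gamma2))
    U <- po_score_vector(inst$g, inst$y, fit)
    gnum <- num_grad(function(b) po_loglik(inst$g, inst$y, a_hat, b),
                     rep(0, ncol(inst$y)))
    expect_equal(U, gnum, tolerance = 1e-6)
  }
})

test_that("the analytic gradient matches numeric differentiation away from the null", {
  set.seed(202)
  inst <- random_instance(n = 50, q = 2)
  theta <- c(-0.4, 0.9, 0.3, -0.2)
  d <- podscore:::po_derivs(inst$g, inst$y, theta[1:2], theta[3:4])
  gnum <- num_grad(function(th) po_loglik(inst$g, inst$y, th[1:2], th[3:4]),
                   theta)
  expect_equal(d$grad, gnum, tolerance = 1e-6)
  # Hessian columns = numeric gradient of the analytic gradient
  hnum <- sapply(seq_along(theta), function(j) {
    e <- numeric(4); e[j] <- 1e-5
    (podscore:::po_derivs(inst$g, inst$y, (theta + e)[1:2], (theta + e)[3:4])$grad -
       podscore:::po_derivs(inst$g, inst$y, (theta - e)[1:2], (theta - e)[3:4])$grad) / 2e-5
  })
  expect_equal(d$hessian, hnum, tolerance = 1e-5)
})

test_that("Newton MLE agrees with a brute-force profile search and with polr", {
  fx <- mle_fixture()
  fit <- po_mle(fx$g, fx$y)
  expect_true(fit$converged)

  # coarse-to-fine grid search over (alpha1, alpha2, beta), independent of
  # the Newton path
  best <- c(0, 1, 0)
  width <- c(4, 4, 4)
  for (round in 1:12) {
    gr <- expand.grid(a1 = best[1] + seq(-width[1], width[1], length.out = 9),
                      a2 = best[2] + seq(-width[2], width[2], length.out = 9),
                      b = best[3] + seq(-width[3], width[3], length.out = 9))
    ll <- mapply(function(a1, a2, b) po_loglik(fx$g, fx$y, c(a1, a2), b),
                 gr$a1, gr$a2, gr$b)
    best <- as.numeric(gr[which.max(ll), ])
    width <- width / 3
  }
  expect_equal(unname(fit$beta), best[3], tolerance = 1e-4)
  expect_equal(unname(fit$alpha), best[1:2], tolerance = 1e-4)

  # MASS::polr parameterizes logit P(G <= j) = zeta_j - beta'y, so its
  # coefficients are the negation of ours and its zeta our alpha
  pf <- MASS::polr(factor(fx$g, ordered = TRUE) ~ fx$y, method = "logistic")
  expect_equal(unname(fit$beta), -unname(coef(pf)), tolerance = 1e-4)
  expect_equal(unname(fit$alpha), unname(pf$zeta), tolerance = 1e-4)
  expect_equal(fit$loglik, -pf$deviance / 2, tolerance = 1e-8)
})

test_that("null-constrained intercept estimates have closed form", {
  fx <- mle_fixture()
  fit0 <- po_null_fit(fx$g)
  # beta = 0 likelihood is maximized at alpha = logit of cumulative props:
  # perturbing either intercept can only lower it
  ll_star <- po_loglik(fx$g, fx$y, qlogis(c(fit0$gamma1, fit0$gamma2)), 0)
  for (d in c(-0.05, 0.05)) {
    expect_lt(po_loglik(fx$g, fx$y, qlogis(c(fit0$gamma1, fit0$gamma2)) + c(d, 0), 0), ll_star)
    expect_lt(po_loglik(fx$g, fx$y, qlogis(c(fit0$gamma1, fit0$gamma2)) + c(0, d), 0), ll_star)
  }
})

test_that("MLE recovers the generating slope at large n", {
  set.seed(77)
  n <- 20000
  y <- rnorm(n)
  alpha <- c(-0.3, 1.1); beta <- 0.4
  F1 <- plogis(alpha[1] + beta * y)
  F2 <- plogis(alpha[2] + beta * y)
  u <- runif(n)
  g <- ifelse(u < F1, 0L, ifelse(u < F2, 1L, 2L))
  fit <- po_mle(g, y)
  expect_true(fit$converged)
  pf <- MASS::polr(factor(g, ordered = TRUE) ~ y, method = "logistic", Hess = TRUE)
  se <- sqrt(diag(vcov(pf)))[1]
  expect_lt(abs(unname(fit$beta) - beta), 3 * se)
  expect_equal(unname(fit$beta), -unname(coef(pf)), tolerance = 1e-4)
})
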