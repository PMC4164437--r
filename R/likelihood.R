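#' Proportional-odds log-likelihood
#'
#' Log-likelihood of the cumulative logit model of genotype on phenotypes,
#' \deqn{P(G \le 0 \mid y) = \mathrm{expit}(\alpha_1 + \beta^\top y), \quad
#'       P(G \le 1 \mid y) = \mathrm{expit}(\alpha_2 + \beta^\top y),}
#' with a common slope vector \eqn{\beta} (the proportional-odds
#' assumption) and ordered intercepts \eqn{\alpha_1 < \alpha_2}.  Parameter
#' values that put zero or negative mass on an observed category return
#' `-Inf` rather than raising an error, so optimizers can step-halve.
#'
#' @param g genotype vector (0/1/2, complete cases).
#' @param y phenotype matrix (rows = individuals).
#' @param alpha length-2 vector of intercepts, `alpha[1] < alpha[2]`.
#' @param beta slope vector, length `ncol(y)`.
#' @param weights optional nonnegative case weights (frequency weights).
#' @return The log-likelihood (scalar, possibly `-Inf`).
#' @examples
#' g <- c(0, 0, 1, 1, 2, 2)
#' po_loglik(g, rep(0, 6), alpha = stats::qlogis(c(1/3, 2/3)), beta = 0)
#' # 6 * log(1/3)
#' @export
po_loglik <- function(g, y, alpha, beta, weights = NULL) {
  g <- check_genotypes(g)
  y <- as.matrix(y)
  if (alpha[1L] >= alpha[2L]) return(-Inf)
  eta <- drop(y %*% beta)
  F1 <- stats::plogis(alpha[1L] + eta)
  F2 <- stats::plogis(alpha[2L] + eta)
  pr <- numeric(length(g))
  pr[g == 0L] <- F1[g == 0L]
  pr[g == 1L] <- (F2 - F1)[g == 1L]
  pr[g == 2L] <- (1 - F2)[g == 2L]
  if (any(pr <= 0)) return(-Inf)
  if (is.null(weights)) sum(log(pr)) else sum(weights * log(pr))
}

# Gradient and Hessian of po_loglik in theta = (alpha1, alpha2, beta).
# Per-observation derivatives are taken w.r.t. the two linear predictors
# eta_j = alpha_j + beta'y and then mapped to theta by the chain rule.
po_derivs <- function(g, y, alpha, beta, weights = NULL) {
  n <- length(g)
  q <- ncol(y)
  if (is.null(weights)) weights <- rep(1, n)
  eta <- drop(y %*% beta)
  F1 <- stats::plogis(alpha[1L] + eta)
  F2 <- stats::plogis(alpha[2L] + eta)
  d1 <- F1 * (1 - F1)          # dF1/deta1
  d2 <- F2 * (1 - F2)          # dF2/deta2
  u1 <- u2 <- numeric(n)       # dlogLi/deta1, dlogLi/deta2
  h11 <- h12 <- h22 <- numeric(n)

  i0 <- g == 0L
  u1[i0] <- 1 - F1[i0]
  h11[i0] <- -d1[i0]

  i2 <- g == 2L
  u2[i2] <- -F2[i2]
  h22[i2] <- -d2[i2]

  i1 <- g == 1L
  if (any(i1)) {
    D <- (F2 - F1)[i1]
    a1 <- d1[i1]; a2 <- d2[i1]
    dp1 <- a1 * (1 - 2 * F1[i1])   # d d1/deta1
    dp2 <- a2 * (1 - 2 * F2[i1])
    u1[i1] <- -a1 / D
    u2[i1] <- a2 / D
    h11[i1] <- -(dp1 * D + a1^2) / D^2
    h12[i1] <- a1 * a2 / D^2
    h22[i1] <- (dp2 * D - a2^2) / D^2
  }

  u1 <- u1 * weights; u2 <- u2 * weights
  h11 <- h11 * weights; h12 <- h12 * weights; h22 <- h22 * weights

  grad <- c(sum(u1), sum(u2), drop(crossprod(y, u1 + u2)))
  H <- matrix(0, 2L + q, 2L + q)
  H[1L, 1L] <- sum(h11)
  H[2L, 2L] <- sum(h22)
  H[1L, 2L] <- H[2L, 1L] <- sum(h12)
  Hb1 <- drop(crossprod(y, h11 + h12))
  Hb2 <- drop(crossprod(y, h12 + h22))
  H[1L, 3:(2L + q)] <- Hb1; H[3:(2L + q), 1L] <- Hb1
  H[2L, 3:(2L + q)] <- Hb2; H[3:(2L + q), 2L] <- Hb2
  H[3:(2L + q), 3:(2L + q)] <- crossprod(y, y * (h11 + 2 * h12 + h22))
  list(grad = grad, hessian = H)
}

# Collapse duplicated (g, y) rows into frequency weights when the data are
# discrete (binary traits, case-control studies): the likelihood is
# unchanged and Newton iterations become O(#unique rows).
collapse_rows <- function(g, y, max_unique = 64L) {
  key <- do.call(paste, c(list(g), lapply(seq_len(ncol(y)), function(j) y[, j]),
                          sep = "\r"))
  ug <- !duplicated(key)
  if (sum(ug) > max_unique) return(NULL)
  w <- as.vector(table(factor(key, levels = key[ug])))
  list(g = g[ug], y = y[ug, , drop = FALSE], w = w)
}

#' Maximum-likelihood fit of the proportional odds model
#'
#' Newton-Raphson maximization with analytic gradient and Hessian,
#' step-halving whenever a step fails to increase the likelihood, starting
#' from the closed-form null fit (`alpha = logit` of the cumulative
#' genotype proportions, `beta = 0`).  Convergence is declared when the
#' gradient max-norm falls below `tol`.  Quasi-separated data (diverging
#' slope estimates) are flagged via a parameter-norm guard; the achieved
#' log-likelihood is still returned so a likelihood-ratio statistic can be
#' formed.
#'
#' @inheritParams po_loglik
#' @param tol convergence tolerance on the gradient max-norm.
#' @param max_iter maximum number of Newton iterations.
#' @return List with `alpha`, `beta`, `loglik`, `converged`, `iterations`,
#'   and `separation` (logical quasi-separation flag).
#' @export
po_mle <- function(g, y, tol = 1e-8, max_iter = 50L) {
  g <- check_genotypes(g)
  y <- as.matrix(y)
  if (nrow(y) != length(g)) stop("genotype/phenotype dimension mismatch")
  if (anyNA(g) || anyNA(y)) stop("missing values: apply complete-case filtering first")
  q <- ncol(y)
  if (length(g) <= q + 2L) stop("too few observations to fit ", q, " slopes")
  fit0 <- po_null_fit(g)

  cl <- collapse_rows(g, y)
  if (!is.null(cl)) { g <- cl$g; y <- cl$y; w <- cl$w } else w <- NULL

  # ensure both cumulative cut-points are interior so logits are finite
  eps <- 0.5 / fit0$n
  gam <- pmin(pmax(c(fit0$gamma1, fit0$gamma2), eps), 1 - eps)
  theta <- c(stats::qlogis(gam), rep(0, q))
  ll <- po_loglik(g, y, theta[1:2], theta[-(1:2)], w)
  separation <- FALSE
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    d <- po_derivs(g, y, theta[1:2], theta[-(1:2)], w)
    if (max(abs(d$grad)) < tol) { converged <- TRUE; iter <- iter - 1L; break }
    step <- tryCatch(solve(d$hessian, d$grad),
                     error = function(e) d$grad / max(1, sqrt(sum(d$grad^2))))
    step <- -step            # Newton ascent: H is negative definite at the MLE
    lambda <- 1
    repeat {
      cand <- theta + lambda * step
      ll_new <- po_loglik(g, y, cand[1:2], cand[-(1:2)], w)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { cand <- theta; ll_new <- ll; break }
    }
    theta <- cand
    if (lambda < 1e-10) break   # stalled: no ascent direction improves
    ll <- ll_new
    if (sqrt(sum(theta[-(1:2)]^2)) > 1e3) { separation <- TRUE; break }
  }
  if (!converged && !separation) {
    d <- po_derivs(g, y, theta[1:2], theta[-(1:2)], w)
    converged <- max(abs(d$grad)) < tol
  }
  list(alpha = theta[1:2], beta = theta[-(1:2)], loglik = ll,
       converged = converged && !separation, iterations = iter,
       separation = separation)
}

#' Likelihood-ratio test of the proportional odds model
#'
#' Tests the null hypothesis that no phenotype is associated with the
#' genotype (`beta = 0`) against the full proportional odds model.  The
#' null fit has closed form (sample genotype proportions); the alternative
#' is fitted with [po_mle()].  The statistic
#' `2 * (loglik_alt - loglik_null)` is referred to a chi-square
#' distribution with `q = ncol(y)` degrees of freedom.  Asymptotically
#' equivalent to [po_score_test()] but requires iterative fitting.
#'
#' @inheritParams po_score_test
#' @return An object of class `"po_lrt"`: list with `statistic`, `df`,
#'   `p.value`, `loglik_null`, `loglik_alt`, `converged`, `iterations`.
#' @export
po_lrt <- function(g, y) {
  g <- check_genotypes(g)
  y <- as.matrix(y)
  if (nrow(y) != length(g)) stop("genotype/phenotype dimension mismatch")
  keep <- !is.na(g) & stats::complete.cases(y)
  g <- g[keep]
  y <- y[keep, , drop = FALSE]
  fit0 <- po_null_fit(g)
  ll0 <- sum(fit0$counts[fit0$counts > 0] * log(fit0$proportions[fit0$counts > 0]))
  fit1 <- po_mle(g, y)
  stat <- max(0, 2 * (fit1$loglik - ll0))
  df <- ncol(y)
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 loglik_null = ll0, loglik_alt = fit1$loglik,
                 converged = fit1$converged, iterations = fit1$iterations,
                 beta = fit1$beta, alpha = fit1$alpha),
            class = "po_lrt")
}

#' @export
print.po_lrt <- function(x, ...) {
  cat("Proportional-odds likelihood-ratio test\n")
  cat(sprintf("  LR = %.4f, df = %d, p = %.4g%s\n", x$statistic, x$df,
              x$p.value, if (x$converged) "" else "  (fit did not converge)"))
  invisible(x)
}
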