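#' Null trinomial fit of a genotype vector
#'
#' Fits the genotype distribution under the null hypothesis of no
#' phenotype effect.  In the reverse-regression (genotype-on-phenotype)
#' proportional odds model the null maximum-likelihood estimates of the
#' genotype category probabilities are simply the sample proportions
#' \eqn{\hat p_0, \hat p_1, \hat p_2}, with cumulative probabilities
#' \eqn{\hat\gamma_1 = \hat p_0} and \eqn{\hat\gamma_2 = \hat p_0 + \hat p_1}.
#' The per-category score weights
#' \deqn{c = (1-\hat\gamma_1,\; 1-\hat\gamma_1-\hat\gamma_2,\; -\hat\gamma_2)}
#' are the derivative of each category's log-probability with respect to the
#' linear predictor evaluated at the null, and satisfy
#' \eqn{\sum_j \hat p_j c_j = 0} exactly.  The variance scalar is
#' \eqn{\bar w = \sum_j \hat p_j c_j^2}.
#'
#' @param g integer vector of genotypes coded 0, 1, 2 (copies of one
#'   allele); `NA` marks missing calls and is dropped.
#' @return An object of class `"po_null_fit"`: a list with elements
#'   `counts`, `proportions`, `gamma1`, `gamma2`, `weights`, `wbar`,
#'   and `n` (number of non-missing genotypes used).
#' @examples
#' fit <- po_null_fit(c(0, 0, 1, 2))
#' fit$proportions   # 0.50 0.25 0.25
#' fit$weights       # 0.50 -0.25 -0.75
#' @export
po_null_fit <- function(g) {
  g <- check_genotypes(g)
  g <- g[!is.na(g)]
  if (length(g) == 0L) stop("no non-missing genotypes")
  counts <- tabulate(g + 1L, nbins = 3L)
  if (sum(counts > 0L) < 2L) {
    stop("degenerate marker: fewer than two genotype categories observed")
  }
  n <- length(g)
  p <- counts / n
  gamma1 <- p[1L]
  gamma2 <- p[1L] + p[2L]
  w <- c(1 - gamma1, 1 - gamma1 - gamma2, -gamma2)
  structure(list(
    counts = counts,
    proportions = p,
    gamma1 = gamma1,
    gamma2 = gamma2,
    weights = w,
    wbar = sum(p * w^2),
    n = n
  ), class = "po_null_fit")
}

check_genotypes <- function(g) {
  if (length(g) < 1L) stop("empty genotype vector")
  if (!is.numeric(g)) stop("genotypes must be numeric codes 0/1/2")
  ok <- is.na(g) | g %in% c(0, 1, 2)
  if (!all(ok)) {
    stop("genotype codes must be 0, 1, 2 or NA (dosages are not supported); ",
         "offending value: ", g[!ok][1L])
  }
  as.integer(g)
}

#' Score vector of the proportional odds model at the null
#'
#' Computes \eqn{U = \sum_i c(G_i)\,(y_i - \bar y)}, the gradient of the
#' proportional-odds log-likelihood with respect to the slope vector
#' evaluated at the null MLE.  Because the weights sum to zero over the
#' sample, centring the phenotypes does not change the value; it is done
#' for numerical stability.
#'
#' @param g genotype vector (0/1/2, no missing values; align first).
#' @param y numeric phenotype matrix with one row per individual (a vector
#'   is treated as a single column).
#' @param fit the [po_null_fit()] of `g`.
#' @return Numeric vector of length `ncol(y)`.
#' @export
po_score_vector <- function(g, y, fit = po_null_fit(g)) {
  g <- check_genotypes(g)
  y <- as.matrix(y)
  if (nrow(y) != length(g)) stop("genotype/phenotype dimension mismatch")
  if (anyNA(g) || anyNA(y)) stop("missing values: apply complete-case filtering first")
  yc <- sweep(y, 2L, colMeans(y))
  drop(crossprod(fit$weights[g + 1L], yc))
}

#' Score variance matrix
#'
#' The variance of the score vector under the null:
#' \eqn{V = \bar w \sum_i (y_i-\bar y)(y_i-\bar y)^\top}, i.e. the
#' (uncorrected) sum-of-squares phenotype scatter scaled by the genotype
#' variance factor \eqn{\bar w} from the null fit.
#'
#' @inheritParams po_score_vector
#' @return A `q x q` symmetric positive semi-definite matrix.
#' @export
po_score_variance <- function(y, fit) {
  y <- as.matrix(y)
  if (nrow(y) < 2L) stop("need at least two observations")
  yc <- sweep(y, 2L, colMeans(y))
  fit$wbar * crossprod(yc)
}

#' Proportional-odds score test of genotype on phenotypes
#'
#' The closed-form score test for association between a biallelic marker
#' and a (possibly multivariate) phenotype vector under the
#' genotype-on-phenotype proportional odds model.  The statistic
#' \eqn{T = U^\top V^{-1} U} needs only the sample genotype proportions and
#' the phenotype scatter matrix, so no iterative model fit is required;
#' under the null it is asymptotically chi-square with `q = ncol(y)`
#' degrees of freedom.
#'
#' Individuals missing the genotype or any phenotype are dropped
#' (complete-case analysis).  A monomorphic marker yields a result with
#' `status = "monomorphic"` and `NA` statistic rather than an error, so
#' genome scans can proceed.  Collinear phenotype columns make `V`
#' singular: by default this is an error; with `pseudo_inverse = TRUE` the
#' Moore-Penrose inverse is used and the degrees of freedom are reduced to
#' the rank of `V`.
#'
#' @param g genotype vector coded 0/1/2 with `NA` for missing calls.
#' @param y numeric phenotype vector or matrix, one row per individual;
#'   binary traits enter as 0/1 codes.
#' @param pseudo_inverse use a Moore-Penrose inverse when the phenotype
#'   scatter matrix is singular (degrees of freedom become `rank(V)`).
#' @return An object of class `"po_score_test"`: list with `statistic`,
#'   `df`, `p.value`, `U`, `V`, `n_used`, `n_dropped`, `status`
#'   (`"ok"`, `"monomorphic"` or `"collinear"`), and the null `fit`.
#' @examples
#' g <- c(0, 0, 1, 1, 2, 2)
#' y <- c(0, 0, 0, 1, 1, 1)
#' po_score_test(g, y)   # T = 4, df = 1, p = 0.0455
#' @export
po_score_test <- function(g, y, pseudo_inverse = FALSE) {
  g <- check_genotypes(g)
  y <- as.matrix(y)
  if (nrow(y) != length(g)) stop("genotype/phenotype dimension mismatch")
  keep <- !is.na(g) & stats::complete.cases(y)
  n_dropped <- sum(!keep)
  g <- g[keep]
  y <- y[keep, , drop = FALSE]
  q <- ncol(y)

  na_result <- function(status) {
    structure(list(statistic = NA_real_, df = NA_integer_, p.value = NA_real_,
                   U = rep(NA_real_, q), V = NULL, n_used = length(g),
                   n_dropped = n_dropped, status = status, fit = NULL),
              class = "po_score_test")
  }
  if (length(g) < 2L || length(unique(g)) < 2L) return(na_result("monomorphic"))

  fit <- po_null_fit(g)
  U <- po_score_vector(g, y, fit)
  V <- po_score_variance(y, fit)

  qrV <- qr(V)
  if (qrV$rank < q && !pseudo_inverse) {
    stop("collinear phenotypes: score variance matrix is singular ",
         "(set pseudo_inverse = TRUE to test on its column space)")
  }
  if (qrV$rank == q) {
    stat <- drop(crossprod(U, solve(V, U)))
    df <- q
  } else {
    sv <- svd(V)
    pos <- sv$d > max(sv$d) * 1e-10
    Vinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    stat <- drop(crossprod(U, Vinv %*% U))
    df <- sum(pos)
  }
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 U = U, V = V, n_used = length(g), n_dropped = n_dropped,
                 status = "ok", fit = fit),
            class = "po_score_test")
}

#' @export
print.po_score_test <- function(x, ...) {
  cat("Proportional-odds score test (genotype on phenotypes)\n")
  if (x$status != "ok") {
    cat("  status:", x$status, "- no test performed\n")
    return(invisible(x))
  }
  cat(sprintf("  T = %.4f, df = %d, p = %.4g (n = %d used, %d dropped)\n",
              x$statistic, x$df, x$p.value, x$n_used, x$n_dropped))
  invisible(x)
}
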