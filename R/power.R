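#' Hardy-Weinberg genotype frequencies
#'
#' @param p frequency of the counted allele, in (0, 1).
#' @return Length-3 probability vector `((1-p)^2, 2p(1-p), p^2)` for
#'   genotypes 0, 1, 2.
#' @export
hwe_genotype_freqs <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("allele frequency must be a single number in (0, 1)")
  }
  c((1 - p)^2, 2 * p * (1 - p), p^2)
}

#' Specify a single-locus disease model
#'
#' A biallelic disease model is fully determined by the risk-allele
#' frequency `p` (Hardy-Weinberg equilibrium is assumed in the
#' population), the disease prevalence `K`, and the genotype relative
#' risks `(R1, R2)` of carrying one or two copies of the allele relative
#' to none.  Presets: `recessive` is `(1, 1, 1.5)`, `additive` is
#' `(1, 1.25, 1.5)`, and `dominant` is `(1, 1.5, 1.5)`.
#'
#' @param p risk-allele frequency in (0, 1).
#' @param K disease prevalence in (0, 1).
#' @param mode one of `"recessive"`, `"additive"`, `"dominant"`,
#'   `"null"` (all risks 1) or `"custom"` (supply `risks`).
#' @param risks for `mode = "custom"`: length-2 numeric `(R1, R2)`.
#' @return An object of class `"genetic_model"`.
#' @examples
#' genetic_model(p = 0.3, K = 0.01, mode = "recessive")
#' @export
genetic_model <- function(p, K,
                          mode = c("additive", "recessive", "dominant",
                                   "null", "custom"),
                          risks = NULL) {
  mode <- match.arg(mode)
  if (p <= 0 || p >= 1) stop("allele frequency must be in (0, 1)")
  if (K <= 0 || K >= 1) stop("prevalence must be in (0, 1)")
  risks <- switch(mode,
    recessive = c(1, 1.5),
    additive  = c(1.25, 1.5),
    dominant  = c(1.5, 1.5),
    null      = c(1, 1),
    custom    = {
      if (is.null(risks) || length(risks) != 2L) {
        stop("mode = 'custom' requires risks = c(R1, R2)")
      }
      risks
    })
  if (any(risks <= 0)) stop("relative risks must be positive")
  m <- structure(list(p = p, K = K, risks = risks, mode = mode),
                 class = "genetic_model")
  penetrances(m)   # validate f2 <= 1 at construction
  m
}

#' @export
print.genetic_model <- function(x, ...) {
  cat(sprintf("Single-locus disease model (%s): p = %g, K = %g, risks = (1, %g, %g)\n",
              x$mode, x$p, x$K, x$risks[1L], x$risks[2L]))
  invisible(x)
}

#' Genotype penetrances implied by a disease model
#'
#' With population genotype frequencies \eqn{q_j} (HWE) and relative risks
#' \eqn{R_j} (with \eqn{R_0 = 1}), the penetrances \eqn{f_j = R_j f_0}
#' must reproduce the prevalence \eqn{K = \sum_j q_j f_j}, giving
#' \eqn{f_0 = K / (q_0 + q_1 R_1 + q_2 R_2)}.
#'
#' @param model a [genetic_model()].
#' @return Length-3 vector of penetrances `(f0, f1, f2)`.
#' @export
penetrances <- function(model) {
  q <- hwe_genotype_freqs(model$p)
  R <- c(1, model$risks)
  f <- model$K / sum(q * R) * R
  if (f[3L] > 1) {
    stop("inconsistent model: implied penetrance f2 = ", signif(f[3L], 4),
         " exceeds 1")
  }
  f
}

#' Genotype distributions in cases and controls
#'
#' Bayes inversion of the penetrance model: cases carry genotype `j` with
#' probability \eqn{q_j f_j / K} and controls with probability
#' \eqn{q_j (1 - f_j) / (1 - K)}.
#'
#' @param model a [genetic_model()].
#' @return List with simplex-3 vectors `case` and `control`.
#' @export
case_control_geno_dists <- function(model) {
  q <- hwe_genotype_freqs(model$p)
  f <- penetrances(model)
  list(case = q * f / model$K,
       control = q * (1 - f) / (1 - model$K))
}

#' Non-centrality parameter of the score test for a case-control design
#'
#' Analytic non-centrality parameter of the proportional-odds score test
#' when the single phenotype is the case indicator.  Writing `p_j` for the
#' pooled genotype distribution (`phi` cases, `1 - phi` controls), the
#' score weights `c_j` are built from the pooled cumulative proportions
#' exactly as in [po_null_fit()], and
#' \deqn{\lambda = n\,\phi(1-\phi)\,
#'   \frac{\left[\sum_j (g^{case}_j - g^{ctrl}_j)\,c_j\right]^2}{\bar w}.}
#'
#' @param model a [genetic_model()].
#' @param n total sample size.
#' @param phi proportion of cases, in (0, 1).
#' @return The non-centrality parameter (nonnegative scalar).
#' @examples
#' m <- genetic_model(p = 0.3, K = 0.01, mode = "recessive")
#' ncp_case_control(m, n = 2000, phi = 0.5)   # 2.8697
#' @export
ncp_case_control <- function(model, n = 2000, phi = 0.5) {
  if (phi <= 0 || phi >= 1) stop("phi must be in (0, 1)")
  if (n <= 0) stop("n must be positive")
  d <- case_control_geno_dists(model)
  pj <- phi * d$case + (1 - phi) * d$control
  if (any(pj <= 0)) stop("degenerate pooled genotype distribution")
  gamma1 <- pj[1L]
  gamma2 <- pj[1L] + pj[2L]
  cw <- c(1 - gamma1, 1 - gamma1 - gamma2, -gamma2)
  wbar <- sum(pj * cw^2)
  delta <- sum((d$case - d$control) * cw)
  n * phi * (1 - phi) * delta^2 / wbar
}

#' Power of a chi-square test from its non-centrality parameter
#'
#' Upper-tail probability of a noncentral chi-square beyond the central
#' `1 - alpha` critical value.
#'
#' @param ncp non-centrality parameter, `>= 0`.
#' @param alpha significance level in (0, 1).
#' @param df degrees of freedom.
#' @return Power in `[alpha, 1]`.
#' @examples
#' power_from_ncp(4.6780, alpha = 0.005, df = 1)   # 0.2597
#' @export
power_from_ncp <- function(ncp, alpha = 0.005, df = 1) {
  if (any(ncp < 0)) stop("ncp must be nonnegative")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (df < 1) stop("df must be >= 1")
  crit <- stats::qchisq(1 - alpha, df)
  stats::pchisq(crit, df, ncp = ncp, lower.tail = FALSE)
}

#' Analytic NCP/power table over a set of disease models
#'
#' @param models list of [genetic_model()] objects.
#' @param n total case-control sample size.
#' @param phi proportion of cases.
#' @param alpha significance level (required, no silent default at the
#'   single-model level; the score test has 1 df here).
#' @return A data.frame with one row per model: `p`, `K`, `mode`, `R1`,
#'   `R2`, `ncp`, `power`.
#' @export
power_table <- function(models, n = 2000, phi = 0.5, alpha = 0.005) {
  rows <- lapply(models, function(m) {
    ncp <- ncp_case_control(m, n = n, phi = phi)
    data.frame(p = m$p, K = m$K, mode = m$mode,
               R1 = m$risks[1L], R2 = m$risks[2L],
               ncp = ncp, power = power_from_ncp(ncp, alpha = alpha, df = 1L))
  })
  if (length(rows) == 0L) {
    return(data.frame(p = numeric(), K = numeric(), mode = character(),
                      R1 = numeric(), R2 = numeric(), ncp = numeric(),
                      power = numeric()))
  }
  do.call(rbind, rows)
}
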