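#' Simulate a case-control dataset under a disease model
#'
#' Draws `round(n * phi)` case genotypes from the case genotype
#' distribution and the remaining controls from the control distribution
#' (see [case_control_geno_dists()]), and returns the genotype vector
#' together with the case indicator as a one-column phenotype matrix.
#' Fully reproducible given `seed`.
#'
#' @param model a [genetic_model()].
#' @param n total sample size.
#' @param phi proportion of cases.
#' @param seed optional integer seed.
#' @return List with `g` (genotypes 0/1/2), `y` (n x 1 matrix, 1 = case),
#'   `model`, `n`, `phi`.
#' @export
simulate_case_control <- function(model, n = 2000, phi = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_case <- round(n * phi)
  n_ctrl <- n - n_case
  d <- case_control_geno_dists(model)
  cnt_case <- stats::rmultinom(1L, n_case, d$case)[, 1L]
  cnt_ctrl <- stats::rmultinom(1L, n_ctrl, d$control)[, 1L]
  list(g = c(rep.int(0:2, cnt_case), rep.int(0:2, cnt_ctrl)),
       y = matrix(rep(c(1, 0), c(n_case, n_ctrl)), ncol = 1L,
                  dimnames = list(NULL, "case")),
       case_counts = cnt_case, control_counts = cnt_ctrl,
       model = model, n = n, phi = phi)
}

#' Specify a multivariate-phenotype QTL scenario
#'
#' Describes a cohort in which a biallelic QTL with allele frequency `maf`
#' (genotypes drawn as Binomial(2, maf) under HWE) affects a subset of
#' three phenotypes.  Associated phenotypes `k` follow
#' \deqn{y_k = b_k \beta (G - 2\,\mathrm{maf}) + e_k,}
#' with effect directions `b1 = b2 = +1` and `b3` switchable, residuals
#' `e` trivariate normal with unit variances and a common pairwise
#' (equicorrelated) residual correlation `rE`, and the slope `beta` set so
#' the QTL explains a fraction `effect_var` of each associated phenotype's
#' variance: `beta^2 = effect_var / ((1 - effect_var) * 2 maf (1 - maf))`.
#' Non-associated phenotypes are pure residual noise.
#'
#' Scenario presets: scenario I associates phenotype 1 only, II phenotypes
#' 1 and 2, III all three.
#'
#' @param scenario `"I"`, `"II"` or `"III"`, or `NULL` to give
#'   `associated` explicitly.
#' @param associated integer subset of 1:3 (ignored when `scenario` given).
#' @param rE common pairwise residual correlation.
#' @param b3 direction (+1 or -1) of the phenotype-3 effect.
#' @param maf QTL allele frequency in (0, 1).
#' @param effect_var fraction of variance explained per associated
#'   phenotype, in `[0, 1)`.
#' @param n sample size.
#' @return An object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(scenario = NULL, associated = 1L, rE = 0,
                         b3 = 1, maf = 0.4, effect_var = 0.005, n = 1000) {
  if (!is.null(scenario)) {
    associated <- switch(match.arg(scenario, c("I", "II", "III")),
                         I = 1L, II = 1:2, III = 1:3)
  }
  if (!all(associated %in% 1:3)) stop("associated must be a subset of 1:3")
  if (!b3 %in% c(-1, 1)) stop("b3 must be +1 or -1")
  if (maf <= 0 || maf >= 1) stop("maf must be in (0, 1)")
  if (effect_var < 0 || effect_var >= 1) stop("effect_var must be in [0, 1)")
  if (abs(rE) > 1) stop("rE must be in [-1, 1]")
  R <- matrix(rE, 3L, 3L); diag(R) <- 1
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 1e-12) {
    stop("residual correlation matrix is not positive definite")
  }
  structure(list(associated = sort(unique(as.integer(associated))), rE = rE,
                 b3 = b3, maf = maf, effect_var = effect_var, n = n,
                 resid_cor = R),
            class = "sim_scenario")
}

#' Simulate a cohort with three correlated phenotypes and one QTL
#'
#' @param scenario a [sim_scenario()].
#' @param seed optional integer seed.
#' @return List with `g` (genotypes), `y` (n x 3 phenotype matrix),
#'   `beta` (the per-phenotype slope actually applied, signed), and the
#'   scenario.
#' @export
simulate_multiphen <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n
  maf <- scenario$maf
  g <- stats::rbinom(n, 2L, maf)
  e <- MASS::mvrnorm(n, mu = rep(0, 3L), Sigma = scenario$resid_cor)
  b <- rep(0, 3L)
  if (scenario$effect_var > 0 && length(scenario$associated) > 0L) {
    beta <- sqrt(scenario$effect_var /
                   ((1 - scenario$effect_var) * 2 * maf * (1 - maf)))
    dir <- c(1, 1, scenario$b3)
    b[scenario$associated] <- beta * dir[scenario$associated]
  }
  y <- e + outer(g - 2 * maf, b)
  colnames(y) <- paste0("y", 1:3)
  list(g = g, y = y, beta = b, scenario = scenario)
}
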