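#' Disease-model grid of the analytic power study
#'
#' The 12 populated cells of the analytic NCP/power surface: prevalences
#' 0.01 and 0.1 crossed with (p = 0.1: additive, dominant), (p = 0.3:
#' recessive, additive, dominant), (p = 0.4: recessive).
#'
#' @return List of [genetic_model()] objects.
#' @export
analytic_study_models <- function() {
  out <- list()
  for (K in c(0.01, 0.1)) {
    out <- c(out, list(
      genetic_model(0.1, K, "additive"),  genetic_model(0.1, K, "dominant"),
      genetic_model(0.3, K, "recessive"), genetic_model(0.3, K, "additive"),
      genetic_model(0.3, K, "dominant"),  genetic_model(0.4, K, "recessive")))
  }
  out
}

#' Regenerate the analytic NCP/power table
#'
#' @param alpha significance level used for the analytic power column.
#' @param n total case-control sample size.
#' @param phi proportion of cases.
#' @param path optional TSV output path.
#' @return data.frame as from [power_table()] over [analytic_study_models()].
#' @export
reproduce_ncp_table <- function(alpha = 0.005, n = 2000, phi = 0.5,
                                path = NULL) {
  tab <- power_table(analytic_study_models(), n = n, phi = phi, alpha = alpha)
  if (!is.null(path)) write_study_tsv(tab, path)
  tab
}

run_cc_study <- function(models, reps, n, phi, alpha_levels, tests, seed) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (m in models) {
    pvals <- matrix(NA_real_, reps, length(tests),
                    dimnames = list(NULL, tests))
    for (r in seq_len(reps)) {
      d <- simulate_case_control(m, n = n, phi = phi)
      tab <- rbind(control = d$control_counts, case = d$case_counts)
      if ("score" %in% tests) {
        pvals[r, "score"] <- po_score_test(d$g, d$y)$p.value
      }
      if ("lrt" %in% tests) pvals[r, "lrt"] <- po_lrt(d$g, d$y)$p.value
      if ("trend" %in% tests) {
        pvals[r, "trend"] <- tryCatch(trend_test(tab)$p.value,
                                      error = function(e) NA_real_)
      }
      if ("chisq" %in% tests) {
        pvals[r, "chisq"] <- tryCatch(pearson_chisq_test(tab)$p.value,
                                      error = function(e) NA_real_)
      }
    }
    for (a in alpha_levels) {
      for (te in tests) {
        ok <- !is.na(pvals[, te])
        rows[[length(rows) + 1L]] <- data.frame(
          K = m$K, p = m$p, mode = m$mode, level = a, test = te,
          rate = mean(pvals[ok, te] < a), replicates = sum(ok),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Empirical type-I-error study for case-control data
#'
#' Simulates case-control datasets under null disease models (all
#' relative risks 1, so the genotype distribution is identical in cases
#' and controls) and reports empirical rejection rates of the score,
#' likelihood-ratio, Cochran-Armitage trend and Pearson chi-square tests
#' at the requested nominal levels.  Deterministic given `seed`.
#'
#' @param K_grid,p_grid prevalences and allele frequencies to cross.
#' @param reps simulation replicates per model.
#' @param n,phi case-control design.
#' @param alpha_levels nominal significance levels.
#' @param tests subset of `c("score", "lrt", "trend", "chisq")`.
#' @param seed integer seed.
#' @param path optional TSV output path.
#' @return data.frame with columns `K`, `p`, `mode`, `level`, `test`,
#'   `rate`, `replicates`.
#' @export
type1_study <- function(K_grid = c(0.01, 0.1), p_grid = c(0.1, 0.3),
                        reps = 2000, n = 2000, phi = 0.5,
                        alpha_levels = c(0.1, 0.01, 0.005),
                        tests = c("score", "lrt", "trend", "chisq"),
                        seed = 1, path = NULL) {
  tests <- match.arg(tests, several.ok = TRUE)
  models <- list()
  for (K in K_grid) for (p in p_grid) {
    models[[length(models) + 1L]] <- genetic_model(p, K, "null")
  }
  out <- run_cc_study(models, reps, n, phi, alpha_levels, tests, seed)
  if (!is.null(path)) write_study_tsv(out, path, seed = seed)
  out
}

#' Empirical power study for case-control data
#'
#' Simulates under the alternative disease models of the analytic study
#' and reports empirical power per test, alongside the analytic score-test
#' power from the non-centrality parameter.
#'
#' @param models list of [genetic_model()] objects
#'   (default [analytic_study_models()]).
#' @param reps simulation replicates per model.
#' @param n,phi case-control design.
#' @param alpha significance level.
#' @param tests subset of `c("score", "lrt", "trend", "chisq")`.
#' @param seed integer seed.
#' @param path optional TSV output path.
#' @return data.frame with one row per (model, test): empirical `rate`
#'   plus `ncp` and `analytic_power` (score test) columns.
#' @export
power_study <- function(models = analytic_study_models(), reps = 2000,
                        n = 2000, phi = 0.5, alpha = 0.005,
                        tests = c("score", "trend", "chisq"),
                        seed = 1, path = NULL) {
  tests <- match.arg(tests, c("score", "lrt", "trend", "chisq"),
                     several.ok = TRUE)
  out <- run_cc_study(models, reps, n, phi, alpha_levels = alpha, tests, seed)
  ana <- do.call(rbind, lapply(models, function(m) {
    ncp <- ncp_case_control(m, n = n, phi = phi)
    data.frame(K = m$K, p = m$p, mode = m$mode, ncp = ncp,
               analytic_power = power_from_ncp(ncp, alpha = alpha, df = 1L),
               stringsAsFactors = FALSE)
  }))
  out <- merge(out, unique(ana), by = c("K", "p", "mode"), sort = FALSE)
  if (!is.null(path)) write_study_tsv(out, path, seed = seed)
  out
}

#' Score-vs-LRT power study for correlated multivariate phenotypes
#'
#' For each scenario cell, simulates cohorts with three equicorrelated
#' phenotypes and a QTL ([simulate_multiphen()]) and reports the
#' empirical power of the score and likelihood-ratio tests side by side.
#' The two tests are asymptotically equivalent; their empirical powers
#' track each other closely on every cell.
#'
#' @param grid data.frame with columns `scenario` ("I"/"II"/"III"), `b3`,
#'   `rE`, `maf`; default is the full study grid
#'   (`rE` in 0/0.3/0.7, `maf` in 0.01/0.40, scenarios I-III with
#'   `b3 = +1` and scenarios II-III also with `b3 = -1`).
#' @param reps replicates per cell.
#' @param n cohort size per replicate.
#' @param effect_var variance explained by the QTL per associated
#'   phenotype.
#' @param alpha significance level.
#' @param seed integer seed.
#' @param path optional TSV output path.
#' @return data.frame with the grid columns plus `power_lrt`,
#'   `power_score`, `replicates`.
#' @export
multiphen_power_study <- function(grid = multiphen_study_grid(), reps = 1000,
                                  n = 1000, effect_var = 0.005,
                                  alpha = 0.005, seed = 1, path = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- sim_scenario(scenario = as.character(grid$scenario[i]),
                       rE = grid$rE[i], b3 = grid$b3[i], maf = grid$maf[i],
                       effect_var = effect_var, n = n)
    # per-cell stream derived from the master seed and the parameters that
    # enter the generator (b3 excluded: it only flips a fixed coefficient,
    # so e.g. scenario I is exactly symmetric in b3); results do not
    # depend on grid order
    cell_seed <- (seed +
                    101L * match(as.character(grid$scenario[i]),
                                 c("I", "II", "III")) +
                    13L * as.integer(round(1e4 * grid$rE[i])) +
                    7L * as.integer(round(1e4 * grid$maf[i]))) %%
      .Machine$integer.max
    set.seed(cell_seed)
    rej_s <- rej_l <- 0L
    for (r in seq_len(reps)) {
      d <- simulate_multiphen(sc)
      st <- po_score_test(d$g, d$y)
      if (st$status == "ok" && st$p.value < alpha) rej_s <- rej_s + 1L
      lr <- if (st$status == "ok") po_lrt(d$g, d$y) else NULL
      if (!is.null(lr) && lr$p.value < alpha) rej_l <- rej_l + 1L
    }
    data.frame(scenario = grid$scenario[i], b3 = grid$b3[i], rE = grid$rE[i],
               maf = grid$maf[i], power_lrt = rej_l / reps,
               power_score = rej_s / reps, replicates = reps,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) write_study_tsv(out, path, seed = seed)
  out
}

#' @rdname multiphen_power_study
#' @export
multiphen_study_grid <- function() {
  g1 <- expand.grid(scenario = c("I", "II", "III"), b3 = 1,
                    rE = c(0, 0.3, 0.7), maf = c(0.01, 0.40),
                    stringsAsFactors = FALSE)
  g2 <- expand.grid(scenario = c("II", "III"), b3 = -1,
                    rE = c(0, 0.3, 0.7), maf = c(0.01, 0.40),
                    stringsAsFactors = FALSE)
  rbind(g1, g2)
}

write_study_tsv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# podscore study output%s",
                     if (is.null(seed)) "" else sprintf(" (seed=%d)", seed)),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
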