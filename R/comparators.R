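#' Cochran-Armitage trend test on a 2x3 case-control genotype table
#'
#' One-degree-of-freedom chi-square test for a linear trend in case
#' proportion across ordered genotype columns, computed through
#' [stats::prop.trend.test()] with no continuity correction.
#'
#' @param tab 2x3 matrix of counts; rows are control/case (row order does
#'   not matter), columns are genotypes 0/1/2.
#' @param scores numeric genotype scores, strictly monotone.
#' @return List with `statistic`, `df` (= 1), `p.value`.
#' @examples
#' tab <- rbind(control = c(20, 10, 10), case = c(10, 10, 20))
#' trend_test(tab)   # statistic 6.667, p = 0.0098
#' @export
trend_test <- function(tab, scores = c(0, 1, 2)) {
  tab <- check_table_2x3(tab)
  if (any(rowSums(tab) == 0)) stop("both rows of the table must be non-empty")
  if (any(diff(scores) <= 0)) stop("scores must be strictly increasing")
  ht <- suppressWarnings(
    stats::prop.trend.test(tab[2L, ], colSums(tab), score = scores))
  list(statistic = unname(ht$statistic), df = 1L,
       p.value = unname(ht$p.value))
}

#' Pearson chi-square test on a 2x3 case-control genotype table
#'
#' Genotype columns with zero margin are dropped and the degrees of
#' freedom reduced accordingly (a marker with an absent genotype class is
#' tested on the 2x2 subtable).  No continuity correction.
#'
#' @inheritParams trend_test
#' @return List with `statistic`, `df`, `p.value`.
#' @export
pearson_chisq_test <- function(tab) {
  tab <- check_table_2x3(tab)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L || any(rowSums(tab) == 0)) {
    stop("table degenerate after dropping empty margins")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = unname(ht$p.value))
}

check_table_2x3 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 3L))) stop("expected a 2x3 count table")
  if (any(tab < 0) || sum(tab) == 0) stop("counts must be nonnegative, total > 0")
  tab
}

# 2x3 table (rows control/case) from a genotype vector and binary phenotype
cc_table <- function(g, y) {
  y <- as.numeric(y)
  rbind(control = tabulate(g[y == 0] + 1L, 3L),
        case    = tabulate(g[y == 1] + 1L, 3L))
}
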