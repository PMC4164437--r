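test_that("HWE genotype frequencies", {
  expect_equal(hwe_genotype_freqs(0.1), c(0.81, 0.18, 0.01))
  expect_equal(hwe_genotype_freqs(0.5), c(0.25, 0.5, 0.25))
  for (p in c(0.01, 0.37, 0.93)) expect_equal(sum(hwe_genotype_freqs(p)), 1)
  expect_error(hwe_genotype_freqs(0), "in \\(0, 1\\)")
  expect_error(hwe_genotype_freqs(1.2), "in \\(0, 1\\)")
})

test_that("penetrances reproduce the prevalence", {
  m <- genetic_model(0.2, 0.05, "null")
  expect_equal(penetrances(m), rep(0.05, 3))

  m <- genetic_model(0.3, 0.01, "recessive")
  f <- penetrances(m)
  expect_equal(f[1], 0.01 / 1.045, tolerance = 1e-10)
  expect_equal(sum(hwe_genotype_freqs(0.3) * f), 0.01, tolerance = 1e-12)

  m <- genetic_model(0.1, 0.01, "additive")
  expect_equal(penetrances(m)[1], 0.01 / 1.05, tolerance = 1e-10)

  expect_error(genetic_model(0.05, 0.6, "custom", risks = c(10, 40)),
               "inconsistent model")
})

test_that("case/control genotype distributions are proper and correct", {
  m <- genetic_model(0.3, 0.01, "recessive")
  d <- case_control_geno_dists(m)
  expect_equal(sum(d$case), 1, tolerance = 1e-12)
  expect_equal(sum(d$control), 1, tolerance = 1e-12)
  expect_equal(d$case, c(0.46890, 0.40191, 0.12919), tolerance = 1e-4)
  expect_equal(d$control, c(0.49021, 0.42018, 0.08960), tolerance = 1e-4)

  m0 <- genetic_model(0.3, 0.01, "null")
  d0 <- case_control_geno_dists(m0)
  expect_equal(d0$case, hwe_genotype_freqs(0.3))
  expect_equal(d0$control, hwe_genotype_freqs(0.3))
})

test_that("case-control NCP matches hand-checked values and null gives zero", {
  expect_equal(ncp_case_control(genetic_model(0.3, 0.01, "recessive")),
               2.8697, tolerance = 5e-5)
  expect_equal(ncp_case_control(genetic_model(0.1, 0.01, "additive")),
               4.6780, tolerance = 5e-5)
  expect_equal(ncp_case_control(genetic_model(0.2, 0.05, "null")), 0)
})

test_that("NCP scales linearly in n and is maximized at phi = 0.5", {
  m <- genetic_model(0.3, 0.1, "additive")
  l1 <- ncp_case_control(m, n = 2000)
  expect_equal(ncp_case_control(m, n = 4000), 2 * l1, tolerance = 1e-12)
  phis <- seq(0.1, 0.9, by = 0.05)
  ncps <- sapply(phis, function(f) ncp_case_control(m, n = 2000, phi = f))
  expect_equal(phis[which.max(ncps)], 0.5)
})

test_that("NCP is invariant to allele relabeling", {
  m <- genetic_model(0.3, 0.01, "additive")
  f <- penetrances(m)
  # relabel: count the other allele; genotype 2 becomes the baseline
  m_rev <- genetic_model(1 - m$p, m$K, "custom",
                         risks = c(f[2] / f[3], f[1] / f[3]))
  expect_equal(ncp_case_control(m_rev), ncp_case_control(m), tolerance = 1e-10)
})

test_that("noncentral chi-square power behaves and hits known values", {
  expect_equal(power_from_ncp(0, alpha = 0.05, df = 1), 0.05)
  expect_equal(power_from_ncp(4.6780, alpha = 0.005, df = 1), 0.2597,
               tolerance = 5e-4)
  expect_equal(power_from_ncp(18.5977, alpha = 0.005, df = 1), 0.9339,
               tolerance = 5e-4)
  # monotone in ncp and in alpha
  lams <- seq(0, 20, by = 0.5)
  expect_true(all(diff(power_from_ncp(lams, 0.005, 1)) > 0))
  alphas <- c(0.001, 0.005, 0.01, 0.05, 0.1)
  pw <- sapply(alphas, function(a) power_from_ncp(5, a, 1))
  expect_true(all(diff(pw) > 0))
})

test_that("power_table assembles models and degenerate inputs", {
  tab <- power_table(list(genetic_model(0.3, 0.01, "recessive"),
                          genetic_model(0.3, 0.01, "null")))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$ncp[2], 0)
  expect_equal(tab$power[2], 0.005)
  expect_equal(nrow(power_table(list())), 0L)
})

test_that("mean simulated score statistic matches df + NCP", {
  m <- genetic_model(0.3, 0.01, "dominant")
  lam <- ncp_case_control(m, n = 2000)
  set.seed(909)
  reps <- 600
  stats <- replicate(reps, {
    d <- simulate_case_control(m, n = 2000, phi = 0.5)
    po_score_test(d$g, d$y)$statistic
  })
  # noncentral chi2 variance = 2(df + 2*lambda)
  mc_se <- sqrt(2 * (1 + 2 * lam) / reps)
  expect_lt(abs(mean(stats) - (1 + lam)), 3 * mc_se)
})
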