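# Population genotype-frequency estimator and polymorphism LRT.

quartet_matrix <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("A", "C", "G", "T")
  m
}

test_that("major/minor identification uses pooled counts with alphabetical tie-breaks", {
  x <- quartet_matrix(c(60, 30, 3, 2), c(40, 10, 0, 0))  # pooled 100,40,3,2
  expect_equal(identify_major_minor(x)[c("M", "m")], list(M = "A", m = "C"))
  # single observed nucleotide: minor falls back to first unobserved
  x <- quartet_matrix(c(100, 0, 0, 0))
  expect_equal(identify_major_minor(x)[c("M", "m")], list(M = "A", m = "C"))
  x <- quartet_matrix(c(0, 0, 100, 0))
  expect_equal(identify_major_minor(x)[c("M", "m")], list(M = "G", m = "A"))
  # 40/40 tie between C and T for the minor slot goes to C
  x <- quartet_matrix(c(100, 40, 0, 40))
  expect_equal(identify_major_minor(x)$m, "C")
  # zero-coverage site is skipped
  expect_null(identify_major_minor(quartet_matrix(c(0, 0, 0, 0))))
})

test_that("a pure monomorphic sample gives gamma1 = 1, eps = 0 and LRT 0", {
  x <- quartet_matrix(matrix(rep(c(20, 0, 0, 0), 50), ncol = 4, byrow = TRUE))
  pr <- estimate_site_priors(x)
  expect_equal(unname(pr$gamma), c(1, 0, 0), tolerance = 1e-8)
  expect_equal(pr$eps, 0, tolerance = 1e-8)
  expect_equal(pr$lrt_poly, 0, tolerance = 1e-6)
  expect_false(test_polymorphism(pr))
})

test_that("with error-free reads the fit recovers the empirical genotype proportions", {
  sim <- sim_biallelic(6, 200, gamma1 = 0.5, gamma3 = 0.2, mean_cov = 8,
                       error_rate = 0, seed = 5)
  for (i in seq_len(6)) {
    cnt <- site_counts(sim$sites, i)
    covered <- rowSums(cnt) > 0
    # individuals with reads from both alleles identify the genotype exactly
    pr <- estimate_site_priors(cnt)
    emp <- table(factor(sim$truth[i, covered], levels = c("AA", "AC", "CC")))
    both_seen <- cnt[, 1] > 0 & cnt[, 2] > 0
    # heterozygotes whose two alleles were both sequenced must be fully
    # attributed to gamma2 at eps = 0
    expect_gte(pr$gamma[2] * sum(covered), sum(both_seen) - 1e-6)
    # the finite-sample ML error rate is not exactly zero (a tiny eps can
    # trade unbalanced heterozygotes against homozygotes) but is negligible
    expect_lt(pr$eps, 1e-3)
    expect_equal(sum(pr$gamma), 1, tolerance = 1e-12)
  }
})

test_that("the fit recovers simulation parameters within Monte-Carlo error", {
  # replicate sites at high coverage; truth (0.25, 0.50, 0.25, 0.01)
  n_rep <- 200
  sim <- sim_biallelic(n_rep, 1000, gamma1 = 0.25, gamma3 = 0.25,
                       mean_cov = 20, error_rate = 0.01, seed = 99)
  pr <- estimate_priors(sim$sites)
  # at q = 0.5 the major/minor identity flips between replicate sites;
  # map the estimates back onto the fixed simulated labels (major = A)
  flip <- pr$M == "C"
  g_AA <- ifelse(flip, pr$gamma3, pr$gamma1)
  g_CC <- ifelse(flip, pr$gamma1, pr$gamma3)
  for (col in list(list(g_AA, 0.25), list(pr$gamma2, 0.50),
                   list(g_CC, 0.25), list(pr$eps, 0.01))) {
    est <- col[[1]]
    se <- stats::sd(est) / sqrt(n_rep)
    expect_lt(abs(mean(est) - col[[2]]), 3 * se + 1e-4)
  }
})

test_that("the full model never falls below the monomorphic null", {
  sim <- sim_biallelic(40, 50, gamma1 = 0.9, gamma3 = 0.05, mean_cov = 2,
                       error_rate = 0.02, seed = 13)
  pr <- estimate_priors(sim$sites)
  expect_true(all(pr$ll_full >= pr$ll_null - 1e-8, na.rm = TRUE))
  expect_true(all(pr$lrt_poly >= 0, na.rm = TRUE))
  expect_true(all(abs(pr$gamma1 + pr$gamma2 + pr$gamma3 - 1) < 1e-9,
                  na.rm = TRUE))
})

test_that("the polymorphism LRT holds its size under monomorphism and has power", {
  # type-I error: monomorphic truth; chi-squared(2) reference is
  # conservative on the simplex boundary
  sim0 <- sim_biallelic(800, 100, gamma1 = 1, gamma3 = 0, mean_cov = 3,
                        error_rate = 0.01, seed = 17)
  pr0 <- estimate_priors(sim0$sites)
  expect_lte(mean(test_polymorphism(pr0, alpha = 0.05)), 0.05 + 0.015)
  # power at a common polymorphism with moderate coverage
  sim1 <- sim_biallelic(150, 100, gamma1 = 0.49, gamma3 = 0.09,
                        mean_cov = 10, error_rate = 0.01, seed = 18)
  pr1 <- estimate_priors(sim1$sites)
  expect_gte(mean(test_polymorphism(pr1, alpha = 0.05)), 0.99)
})

test_that("the call-free allele-frequency estimate is unbiased at low coverage", {
  sim <- sim_biallelic(400, 100, gamma1 = 0.81, gamma3 = 0.01, mean_cov = 3,
                       error_rate = 0.01, seed = 23)
  pr <- estimate_priors(sim$sites)
  afb <- allele_freq_bias(pr)
  expect_lt(abs(afb$mean_q_hat - 0.1), 3 * afb$sem2 / 2 + 0.003)
})
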