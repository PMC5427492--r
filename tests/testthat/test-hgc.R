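# High-coverage diploid caller: closed-form error rates, ML calls,
# polymorphism LRT, heterozygote refinement and allele counting.

test_that("closed-form error rates match their stated forms and the grid oracle", {
  expect_equal(ml_error_rate(c(9, 1, 0, 0), "AA"), 0.1)
  expect_equal(ml_error_rate(c(5, 5, 0, 0), "AC"), 0)
  expect_equal(ml_error_rate(c(4, 4, 1, 1), "AC"), 0.3)
  expect_equal(ml_error_rate(c(1, 0, 3, 9), "AA"), 0.75)  # clamped
  set.seed(61)
  for (rep in 1:40) {
    q <- random_quartet()
    g <- sample(c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT"), 1)
    e_hat <- ml_error_rate(q, g)
    grid <- oracle_grid_eps(q, g)
    # the closed form must be at least as good as the best grid point
    expect_gte(oracle_ll(q, g, e_hat), grid$ll - 1e-8)
    expect_true(e_hat >= 0 && e_hat <= 0.75)
  }
})

test_that("maximum-likelihood calls follow the worked examples", {
  res <- hgc_call(c(10, 0, 0, 0))
  expect_equal(res$call, "AA")
  expect_equal(res$eps_call, 0)
  res <- hgc_call(c(5, 0, 0, 0))          # below the default min_cov of 6
  expect_true(is.na(res$call))
  expect_equal(res$reason, "low_coverage")
  res <- hgc_call(c(3, 3, 0, 0))
  expect_equal(res$call, "AC")
  # candidates are restricted to observed nucleotides
  res <- hgc_call(c(4, 3, 0, 0), min_cov = 1)
  expect_true(res$call %in% c("AA", "AC", "CC"))
})

test_that("the homozygote/heterozygote decision flips at coverages 6 and 11", {
  # one discordant read: an allele at coverage <= 5, an error at >= 6
  expect_equal(hgc_call(c(4, 1, 0, 0), min_cov = 1)$call, "AC")
  expect_equal(hgc_call(c(5, 1, 0, 0), min_cov = 1)$call, "AA")
  # two discordant reads: alleles at coverage <= 10, errors at >= 11
  expect_equal(hgc_call(c(8, 2, 0, 0), min_cov = 1)$call, "AC")
  expect_equal(hgc_call(c(9, 2, 0, 0), min_cov = 1)$call, "AA")
  # the same boundaries fall out of the independent grid-likelihood oracle
  for (q in list(c(4, 1, 0, 0), c(5, 1, 0, 0), c(8, 2, 0, 0), c(9, 2, 0, 0))) {
    expect_equal(hgc_call(q, min_cov = 1)$call,
                 oracle_best_genotype(q, ploidy = 2)$genotype)
  }
})

test_that("the polymorphism LRT reproduces the 10 ln 3 worked example", {
  res <- hgc_call(c(5, 5, 0, 0), min_cov = 6, M = "A")
  expect_equal(res$lrt_vs_MM, 10 * log(3), tolerance = 1e-10)
  expect_true(res$significant)
  # all-MM sites are never declared polymorphic
  calls <- hgc_call(matrix(rep(c(10, 0, 0, 0), 5), ncol = 4, byrow = TRUE),
                    M = "A")
  expect_false(hgc_test_polymorphism(calls))
})

test_that("LRT statistics are non-negative whenever the call maximises the profile", {
  set.seed(67)
  Q <- t(vapply(1:60, function(i) random_quartet(max_cov = 25, min_cov = 6),
                numeric(4)))
  res <- hgc_call(Q, min_cov = 6, M = "A", alpha = 0.05)
  expect_true(all(res$lrt_vs_MM >= -1e-9, na.rm = TRUE))
})

test_that("unconfirmed heterozygotes are counted as homozygotes for allele number", {
  # balanced reads: refinement confirms the heterozygote overwhelmingly
  res <- hgc_call(c(50, 50, 0, 0), M = "A")
  expect_true(res$het_confirmed)
  # significant vs a different population-major allele, but indistinguishable
  # from the individual's own homozygote: refinement fails
  res <- hgc_call(c(4, 1, 0, 0), min_cov = 1, M = "G")
  expect_equal(res$call, "AC")
  expect_true(res$significant)
  expect_false(res$het_confirmed)
  expect_equal(hgc_count_alleles(res, c(4, 1, 0, 0), M = "G"), 2L)  # G + A only
  # homozygous significant calls contribute their allele directly
  res <- hgc_call(c(0, 20, 0, 0), M = "A")
  expect_true(res$significant)
  expect_true(is.na(res$het_confirmed))
  expect_equal(hgc_count_alleles(res, c(0, 20, 0, 0), M = "A"), 2L)
})

test_that("correct-call rate shows the documented valleys at fixed coverage", {
  eps <- 0.01
  hom5 <- hgc_exact_rate("AA", 5, eps)
  hom6 <- hgc_exact_rate("AA", 6, eps)
  hom10 <- hgc_exact_rate("AA", 10, eps)
  expect_gt(hom6, hom5)            # sudden increase entering coverage 6
  expect_gt(hom10, hom5)
  het5 <- hgc_exact_rate("AC", 5, eps)
  het6 <- hgc_exact_rate("AC", 6, eps)
  het10 <- hgc_exact_rate("AC", 10, eps)
  het11 <- hgc_exact_rate("AC", 11, eps)
  expect_lt(het6, het5)            # valley at coverage 6
  expect_lt(het11, het10)          # second valley at coverage 11
  expect_gt(het10, het6)
})

test_that("error-free data with both alleles well covered are called perfectly", {
  set.seed(71)
  Q <- sim_individual("AC", coverage = 8, error_rate = 0, n_reps = 400)
  # a lone discordant read is attributed to error above coverage 5 even
  # when the data are error-free, so require two reads per allele
  both <- Q[, 1] >= 2 & Q[, 2] >= 2
  res <- hgc_call(Q[both, ], min_cov = 6)
  expect_true(all(res$call == "AC"))
  Q <- sim_individual("GG", coverage = 8, error_rate = 0, n_reps = 100)
  res <- hgc_call(Q, min_cov = 6)
  expect_true(all(res$call == "GG"))
})

test_that("site-level driver ties calls, polymorphism and allele counts together", {
  sim <- sim_triallelic(30, 50, p = 0.6, q = 0.3, r = 0.1, mean_cov = 20,
                        error_rate = 0.005, seed = 73)
  res <- hgc_call_sites(sim$sites, min_cov = 6)
  expect_equal(dim(res$calls), c(30L, 50L))
  expect_true(all(res$site$polymorphic))     # q = 0.3 at coverage 20
  expect_true(all(res$site$n_alleles >= 2))
  sc <- score_calls(res$calls, sim$truth)
  expect_gt(sc$correct_among_called, 0.9)
})
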