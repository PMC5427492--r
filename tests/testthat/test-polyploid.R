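# Triploid and tetraploid callers.

test_that("polyploid error-rate estimates match the printed closed forms", {
  expect_equal(poly_ml_error_rate(c(9, 1, 0, 0), "AAA"), 0.1)
  expect_equal(poly_ml_error_rate(c(3, 6, 1, 0), "ACC"),
               (129 - sqrt(13041)) / 100, tolerance = 1e-12)
  expect_equal(poly_ml_error_rate(c(5, 3, 1, 1), "ACG"), 3 * 1 / 10)
  expect_equal(poly_ml_error_rate(c(9, 1, 0, 0), "AAAA"), 0.1)
  expect_equal(poly_ml_error_rate(c(2, 6, 1, 1), "ACCC"), (9 / 8) * 2 / 8)
  expect_equal(poly_ml_error_rate(c(4, 4, 1, 1), "AACC"), 1.5 * 2 / 10)
  expect_equal(poly_ml_error_rate(c(6, 2, 2, 1), "AACG"), 1.5 * 1 / 7)
})

test_that("every genotype class beats the grid oracle at its closed-form estimate", {
  set.seed(79)
  classes <- c("AAA", "AAC", "ACC", "ACG",                  # triploid
               "AAAA", "AAAC", "ACCC", "AACC", "AACG", "ACGT")  # tetraploid
  for (g in classes) {
    for (rep in 1:25) {
      q <- random_quartet(max_cov = 40)
      e_hat <- poly_ml_error_rate(q, g)
      grid <- oracle_grid_eps(q, g)
      expect_gte(oracle_ll(q, g, e_hat), grid$ll - 1e-8)
    }
  }
})

test_that("triploid calls follow direct likelihood comparison", {
  expect_equal(poly_call(c(30, 0, 0, 0), ploidy = 3)$call, "AAA")
  # 2:1 read ratio favours the matching allele dosage
  res <- poly_call(c(20, 10, 0, 0), ploidy = 3)
  expect_equal(res$call, "AAC")
  expect_equal(res$call, oracle_best_genotype(c(20, 10, 0, 0), 3)$genotype)
  set.seed(83)
  for (rep in 1:15) {
    q <- random_quartet(max_cov = 30, min_cov = 6)
    res <- poly_call(q, ploidy = 3, min_cov = 6)
    if (!is.na(res$call)) {
      expect_equal(res$call, oracle_best_genotype(q, 3)$genotype)
    }
  }
})

test_that("at ploidy 2 the generic engine reproduces the diploid caller", {
  set.seed(89)
  Q <- t(vapply(1:80, function(i) random_quartet(max_cov = 25),
                numeric(4)))
  a <- hgc_call(Q, min_cov = 4, M = "A")
  b <- poly_call(Q, ploidy = 2, min_cov = 4, M = "A")
  expect_identical(a$call, b$call)
  expect_equal(a$eps_call, b$eps_call)
  expect_equal(a$ll_call, b$ll_call)
  expect_equal(a$lrt_vs_MM, b$lrt_vs_hom)
  expect_identical(a$significant, b$significant)
})

test_that("a single discordant read is absorbed up to triploid coverage 8 and not beyond", {
  expect_equal(poly_call(c(7, 1, 0, 0), ploidy = 3, min_cov = 1)$call, "AAC")
  expect_equal(poly_call(c(8, 1, 0, 0), ploidy = 3, min_cov = 1)$call, "AAA")
  expect_equal(oracle_best_genotype(c(7, 1, 0, 0), 3)$genotype, "AAC")
  expect_equal(oracle_best_genotype(c(8, 1, 0, 0), 3)$genotype, "AAA")
})

test_that("a singleton third nucleotide stops being an allele above triploid coverage 6", {
  expect_equal(poly_call(c(3, 2, 1, 0), ploidy = 3, min_cov = 1)$call, "ACG")
  res7 <- poly_call(c(4, 2, 1, 0), ploidy = 3, min_cov = 1)
  expect_equal(length(unique(strsplit(res7$call, "")[[1]])), 2L)
  expect_equal(res7$call, oracle_best_genotype(c(4, 2, 1, 0), 3)$genotype)
})

test_that("all three triploid genotype classes are called reliably at high coverage", {
  set.seed(97)
  for (truth in c("AAA", "AAC", "ACG")) {
    Q <- sim_individual(truth, coverage = 100, error_rate = 0.01,
                        n_reps = 200)
    res <- poly_call(Q, ploidy = 3, min_cov = 6)
    expect_gte(mean(res$call == truth, na.rm = TRUE), 0.97)
    expect_lte(mean(is.na(res$call)), 0.02)
  }
})

test_that("tetraploid calls recover balanced and unbalanced dosages at high coverage", {
  set.seed(101)
  for (truth in c("AAAA", "AACC", "AAAC", "AACG")) {
    Q <- sim_individual(truth, coverage = 150, error_rate = 0.005,
                        n_reps = 120)
    res <- poly_call(Q, ploidy = 4, min_cov = 6)
    expect_gte(mean(res$call == truth, na.rm = TRUE), 0.9)
  }
  # the fully heterozygous genotype has no free error parameter (every
  # read probability is exactly 1/4), so dosage-flexible candidates fit
  # sampling noise better and dominate it under maximum likelihood
  Q <- sim_individual("ACGT", coverage = 150, error_rate = 0.005,
                      n_reps = 50)
  res <- poly_call(Q, ploidy = 4, min_cov = 6)
  expect_lt(mean(res$call == "ACGT", na.rm = TRUE), 0.5)
})

test_that("polyploid site driver reports polymorphism and allele counts", {
  counts <- array(0L, dim = c(1, 4, 4))
  counts[1, , 1] <- c(30L, 20L, 28L, 0L)   # A reads
  counts[1, , 2] <- c(0L, 10L, 2L, 29L)    # C reads
  x <- quartet_sites(counts)
  res <- poly_call_sites(x, ploidy = 3, min_cov = 6)
  expect_equal(res$site$M, "A")
  expect_true(res$site$polymorphic)
  expect_equal(res$site$n_alleles, 2L)
  expect_equal(res$calls[1, 1], "AAA")
  expect_equal(res$calls[1, 2], "AAC")
  expect_equal(res$calls[1, 4], "CCC")
})
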