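# Independent oracles used across the suite.  These deliberately avoid
# the package's closed forms: probabilities are computed by summing over
# chromosomes, likelihood maximisation is done by grid search, and
# posteriors by direct evaluation of the three numerators.

# P(read x | genotype, eps) by explicit averaging over the chromosomes
# of the genotype (not the k/m shortcut used by the package).
oracle_read_prob <- function(x, genotype, eps) {
  chroms <- strsplit(genotype, "", fixed = TRUE)[[1]]
  mean(ifelse(chroms == x, 1 - eps, eps / 3))
}

oracle_ll <- function(q, genotype, eps) {
  p <- vapply(c("A", "C", "G", "T"), oracle_read_prob, 0,
              genotype = genotype, eps = eps)
  terms <- ifelse(q == 0, 0, q * log(p))
  sum(terms)
}

# grid maximisation of the quartet log-likelihood over eps in [0, 3/4];
# probabilities still built by summing over chromosomes, vectorised over
# the grid
oracle_grid_eps <- function(q, genotype, step = 1e-5) {
  eps <- seq(0, 0.75, by = step)
  chroms <- strsplit(genotype, "", fixed = TRUE)[[1]]
  ll <- 0
  for (j in 1:4) {
    x <- c("A", "C", "G", "T")[j]
    p <- 0
    for (ch in chroms) p <- p + (if (ch == x) 1 - eps else eps / 3)
    p <- p / length(chroms)
    ll <- ll + (if (q[j] == 0) 0 else q[j] * log(p))
  }
  i <- which.max(ll)
  list(eps = eps[i], ll = ll[i])
}

# best genotype by grid-maximised likelihood over all candidate multisets
# built from the observed nucleotides
oracle_best_genotype <- function(q, ploidy, step = 1e-4) {
  nucs <- c("A", "C", "G", "T")[q > 0]
  cands <- unique(apply(
    expand.grid(rep(list(nucs), ploidy), stringsAsFactors = FALSE), 1L,
    function(v) paste(sort(v), collapse = "")
  ))
  lls <- vapply(cands, function(g) oracle_grid_eps(q, g, step)$ll, 0)
  list(genotype = cands[which.max(lls)], ll = max(lls),
       lls = stats::setNames(lls, cands))
}

# Eq.-3-style posterior by direct evaluation of the three numerators
oracle_bgc_posterior <- function(q, M, m, gamma, eps) {
  genos <- c(paste0(M, M), paste0(M, m), paste0(m, m))
  num <- vapply(seq_along(genos), function(g) {
    gamma[g] * exp(oracle_ll(q, genos[g], eps))
  }, 0)
  num / sum(num)
}

random_quartet <- function(max_cov = 30, min_cov = 1) {
  n <- sample(min_cov:max_cov, 1L)
  as.vector(stats::rmultinom(1L, n, prob = stats::runif(4, 0.05, 1)))
}

# expected correct-call rate of the diploid high-coverage caller at fixed
# coverage by exact enumeration of all read quartets
hgc_exact_rate <- function(truth, coverage, eps, min_cov = 1) {
  p <- vapply(c("A", "C", "G", "T"), oracle_read_prob, 0,
              genotype = truth, eps = eps)
  truth <- paste(sort(strsplit(truth, "", fixed = TRUE)[[1]]), collapse = "")
  rate <- 0
  for (nA in 0:coverage) for (nC in 0:(coverage - nA)) {
    for (nG in 0:(coverage - nA - nC)) {
      nT <- coverage - nA - nC - nG
      q <- c(nA, nC, nG, nT)
      pq <- stats::dmultinom(q, prob = p)
      if (pq < 1e-14) next
      call <- hgc_call(q, min_cov = min_cov)$call
      if (!is.na(call) && call == truth) rate <- rate + pq
    }
  }
  rate
}
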