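# Read-quartet simulator with recorded truth.
#
# Generative model: each individual's genotype is drawn from its
# population frequency; coverage is Poisson with mean `mean_cov` (or
# fixed); each read picks a chromosome of the genotype uniformly and is
# mis-read as one of the three other nucleotides with probability
# `error_rate` (uniform among the three).  Read-by-read this is exactly
# a categorical draw from the genotype's read-probability row, so reads
# are sampled directly from `read_prob()` probabilities.  Zero-coverage
# individuals occur (no truncation) and are the callers' missing-data
# case.  One seeded generator drives a whole run with sites in outer
# order and individuals in inner order, so identical seeds give
# identical quartets and truth.

# draw quartets for a vector of individuals given genotype strings and
# per-individual coverages
sim_quartets <- function(genotypes, coverage, error_rate) {
  k <- length(genotypes)
  counts <- matrix(0L, k, 4L, dimnames = list(NULL, NUCS))
  total <- sum(coverage)
  if (total == 0L) return(counts)
  gt <- unique(genotypes)
  for (g in gt) {
    sel <- which(genotypes == g & coverage > 0L)
    if (length(sel) == 0L) next
    p <- vapply(NUCS, read_prob, 0, genotype = g, eps = error_rate)
    cov <- coverage[sel]
    reads <- sample.int(4L, sum(cov), replace = TRUE, prob = p)
    owner <- rep(seq_along(sel), cov)
    tab <- tabulate((owner - 1L) * 4L + reads, nbins = 4L * length(sel))
    counts[sel, ] <- matrix(tab, ncol = 4L, byrow = TRUE)
  }
  counts
}

sim_population <- function(n_sites, n_ind, geno_strings, geno_freqs,
                           mean_cov, error_rate, fixed_cov, seed) {
  if (!is.null(seed)) set.seed(seed)
  counts <- array(0L, dim = c(n_sites, n_ind, 4L))
  truth <- matrix(NA_character_, n_sites, n_ind)
  for (s in seq_len(n_sites)) {
    g <- sample(geno_strings, n_ind, replace = TRUE, prob = geno_freqs)
    cov <- if (is.null(fixed_cov)) stats::rpois(n_ind, mean_cov)
           else rep(as.integer(fixed_cov), n_ind)
    counts[s, , ] <- sim_quartets(g, cov, error_rate)
    truth[s, ] <- g
  }
  list(sites = quartet_sites(counts), truth = truth)
}

#' Simulate biallelic diploid sites
#'
#' Population of `n_ind` diploid individuals at `n_sites` independent
#' replicate sites.  Genotypes MM, Mm, mm are drawn with frequencies
#' `(gamma1, 1 - gamma1 - gamma3, gamma3)`; the major and minor alleles
#' are fixed to A and C (callers must not care which nucleotides play
#' those roles).
#'
#' @param n_sites Number of replicate sites.
#' @param n_ind Individuals per site.
#' @param gamma1,gamma3 Major- and minor-homozygote frequencies
#'   (`gamma1 + gamma3 <= 1`).
#' @param mean_cov Mean of the Poisson coverage distribution.
#' @param error_rate Error rate per read per site.
#' @param fixed_cov When non-`NULL`, every individual gets exactly this
#'   coverage instead of a Poisson draw.
#' @param seed Optional seed for reproducibility.
#' @return List with `sites` (a [quartet_sites()] object), `truth`
#'   (`n_sites x n_ind` matrix of true genotype strings) and `params`.
#' @examples
#' sim <- sim_biallelic(5, 20, gamma1 = 0.81, gamma3 = 0.01, mean_cov = 3,
#'                      error_rate = 0.01, seed = 1)
#' table(sim$truth)
#' @export
sim_biallelic <- function(n_sites, n_ind, gamma1, gamma3, mean_cov = 3,
                          error_rate = 0.01, fixed_cov = NULL, seed = NULL) {
  gamma2 <- 1 - gamma1 - gamma3
  if (gamma1 < 0 || gamma3 < 0 || gamma2 < -1e-12) {
    stop("genotype frequencies must lie on the simplex (gamma1 + gamma3 <= 1)")
  }
  gamma2 <- max(gamma2, 0)
  out <- sim_population(n_sites, n_ind,
                        geno_strings = c("AA", "AC", "CC"),
                        geno_freqs = c(gamma1, gamma2, gamma3),
                        mean_cov, error_rate, fixed_cov, seed)
  out$params <- list(gamma = c(gamma1, gamma2, gamma3),
                     q = gamma3 + gamma2 / 2, mean_cov = mean_cov,
                     error_rate = error_rate, M = "A", m = "C")
  out
}

#' Simulate triallelic diploid sites under Hardy-Weinberg equilibrium
#'
#' Three alleles A, C, G with frequencies `p >= q >= r` (most abundant
#' first); the six genotype frequencies are the HWE products
#' `p^2, 2pq, 2pr, q^2, 2qr, r^2`.
#'
#' @inheritParams sim_biallelic
#' @param p,q,r Allele frequencies (must sum to 1).
#' @return As [sim_biallelic()].
#' @export
sim_triallelic <- function(n_sites, n_ind, p = 0.7, q = 0.2, r = 0.1,
                           mean_cov = 10, error_rate = 0.01,
                           fixed_cov = NULL, seed = NULL) {
  if (abs(p + q + r - 1) > 1e-9 || p < 0 || q < 0 || r < 0) {
    stop("allele frequencies p, q, r must be non-negative and sum to 1")
  }
  out <- sim_population(
    n_sites, n_ind,
    geno_strings = c("AA", "AC", "AG", "CC", "CG", "GG"),
    geno_freqs = c(p^2, 2 * p * q, 2 * p * r, q^2, 2 * q * r, r^2),
    mean_cov, error_rate, fixed_cov, seed
  )
  out$params <- list(p = p, q = q, r = r, mean_cov = mean_cov,
                     error_rate = error_rate,
                     alleles = c("A", "C", "G"))
  out
}

#' Simulate read quartets for a single individual at fixed coverage
#'
#' @param genotype True genotype string (any ploidy 2-4).
#' @param coverage Exact number of reads per replicate.
#' @param error_rate Error rate per read per site.
#' @param n_reps Number of independent replicates.
#' @param seed Optional seed.
#' @return `n_reps x 4` integer matrix of quartets (columns A, C, G, T).
#' @examples
#' sim_individual("AC", coverage = 10, error_rate = 0, n_reps = 3, seed = 1)
#' @export
sim_individual <- function(genotype, coverage, error_rate, n_reps = 1L,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(coverage >= 0)
  genotype <- normalize_genotype(genotype)
  sim_quartets(rep(genotype, n_reps), rep(as.integer(coverage), n_reps),
               error_rate)
}
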