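# Core nucleotide-read probability model shared by every caller.
#
# A genotype is a multiset of 2, 3 or 4 nucleotides written as a sorted
# string ("AC", "ACC", "AACG", ...).  A read from an individual with m
# chromosomes, k of which carry nucleotide x, is x with probability
#   P(x | G, eps) = (k/m) (1 - eps) + ((m - k)/m) (eps/3),
# i.e. either the sequenced chromosome carries x and is read correctly, or
# it carries another nucleotide and is mis-read as x (errors are uniform
# over the three wrong nucleotides).  The diploid specialisation is the
# classic 3x4 table of read probabilities for MM/Mm/mm, and the triploid/
# tetraploid instances follow the same rule.

NUCS <- c("A", "C", "G", "T")

#' Multiplicity vector of a genotype
#'
#' @param genotype Genotype string, e.g. `"AC"`, `"ACC"`, `"AACG"`.
#' @return Named integer vector of length 4 (A, C, G, T copy numbers).
#' @keywords internal
genotype_mult <- function(genotype) {
  alleles <- strsplit(genotype, "", fixed = TRUE)[[1]]
  if (!all(alleles %in% NUCS)) {
    stop("invalid genotype '", genotype, "': alleles must be A, C, G or T")
  }
  if (!(length(alleles) %in% 2:4)) {
    stop("invalid genotype '", genotype, "': ploidy must be 2, 3 or 4")
  }
  k <- tabulate(match(alleles, NUCS), nbins = 4L)
  names(k) <- NUCS
  k
}

#' Canonical (sorted) genotype string
#' @keywords internal
normalize_genotype <- function(genotype) {
  paste(sort(strsplit(genotype, "", fixed = TRUE)[[1]]), collapse = "")
}

check_error_rate <- function(eps) {
  if (any(eps < 0 | eps > 0.75)) {
    stop("error rate must lie in [0, 3/4]")
  }
  invisible(eps)
}

#' Probability of an observed nucleotide read given a genotype
#'
#' Computes `P(x | G, eps)` under the uniform-error model: a read is drawn
#' from a uniformly chosen chromosome of the genotype and mis-read as each
#' of the three other nucleotides with probability `eps/3`.  With `k`
#' copies of `x` among the `m` chromosomes,
#' `P = (k/m)(1 - eps) + ((m - k)/m)(eps/3)`.
#'
#' @param x Nucleotide read, one of `"A","C","G","T"` (vectorised).
#' @param genotype Genotype string of ploidy 2, 3 or 4 (e.g. `"AC"`,
#'   `"ACC"`, `"AACG"`); allele order is irrelevant.
#' @param eps Sequencing error rate per read per site, in `[0, 3/4]`.
#' @return Probability (vectorised over `x`); the four nucleotide
#'   probabilities always sum to 1.
#' @examples
#' read_prob("A", "AC", 0.01)            # (1/2)(1-eps) + (1/2)(eps/3)
#' sum(sapply(c("A","C","G","T"), read_prob, genotype = "ACC", eps = 0.3))
#' @export
read_prob <- function(x, genotype, eps) {
  check_error_rate(eps)
  k <- genotype_mult(genotype)
  m <- sum(k)
  idx <- match(x, NUCS)
  if (anyNA(idx)) stop("invalid nucleotide in 'x'")
  kx <- k[idx]
  unname((kx / m) * (1 - eps) + ((m - kx) / m) * (eps / 3))
}

#' x * log(y) with the convention 0 * log(0) = 0
#' @keywords internal
xlogy <- function(x, y) {
  out <- x * log(y)
  out[x == 0] <- 0
  out
}

#' Log-likelihood of a read quartet given a genotype
#'
#' Multinomial log-likelihood of the observed counts of A, C, G and T reads
#' for one individual at one site, with the constant multinomial
#' coefficient dropped (it cancels from every likelihood ratio and
#' posterior used downstream, so this is exact, not an approximation):
#' `sum_x n_x * ln P(x | G, eps)`.
#'
#' A zero-coverage quartet has log-likelihood 0 for every genotype; a
#' positive count on a zero-probability read gives `-Inf`.
#'
#' @param q Read quartet: numeric vector of length 4 (counts of A, C, G, T),
#'   or a matrix with 4 columns (one quartet per row).
#' @param genotype Genotype string (ploidy 2, 3 or 4).
#' @param eps Error rate in `[0, 3/4]`.
#' @return Log-likelihood (one value per quartet row).
#' @examples
#' quartet_loglik(c(5, 0, 0, 0), "AA", 0)      # 0
#' quartet_loglik(c(3, 3, 0, 0), "AC", 0.01)   # 6 * log(0.4966667)
#' @export
quartet_loglik <- function(q, genotype, eps) {
  check_error_rate(eps)
  if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
  if (ncol(q) != 4L) stop("a read quartet has exactly 4 counts (A, C, G, T)")
  if (any(q < 0) || any(q != round(q))) stop("read counts must be non-negative integers")
  k <- genotype_mult(genotype)
  m <- sum(k)
  p <- (k / m) * (1 - eps) + ((m - k) / m) * (eps / 3)
  ll <- numeric(nrow(q))
  for (j in 1:4) ll <- ll + xlogy(q[, j], unname(p[j]))
  ll
}

#' Enumerate candidate genotypes (multisets of nucleotides)
#'
#' @param nucs Nucleotides to draw alleles from.
#' @param ploidy Multiset size (2, 3 or 4).
#' @return Character vector of sorted genotype strings.
#' @keywords internal
enumerate_genotypes <- function(nucs = NUCS, ploidy = 2L) {
  idx <- utils::combn(seq_len(length(nucs) + ploidy - 1L), ploidy)
  # stars-and-bars: multisets of size `ploidy` over `nucs`
  apply(idx, 2L, function(co) {
    paste(nucs[co - seq_len(ploidy) + 1L], collapse = "")
  })
}
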