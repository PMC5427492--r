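# Triploid (TRI) and tetraploid (TET) genotype callers, plus a generic
# engine that also reproduces the diploid HGC at ploidy 2.
#
# Candidates are all multisets of size `ploidy` over the nucleotides
# observed in the individual's quartet.  Each candidate G is scored at
# its own ML error rate; with k copies of nucleotide x among m
# chromosomes the read probability is p_k = k/m + eps (m - 4k)/(3m), so
# the log-likelihood is a sum of terms grouped by copy number, and the
# ML error rate has a closed form for every genotype class:
#
#   class (by positive copy numbers)      eps-hat
#   homozygote (m)                        (n - n_hi)/n
#   diploid het (1,1)                     (3/2) nE / n
#   triploid (2,1)                        root of 5n e^2 - (6 nS + 15 nD + 21 nE) e + 18 nE = 0
#   triploid (1,1,1)                      3 nE / n
#   tetraploid (3,1)                      (9/8) nE / (n3 + nE)
#   tetraploid (2,2)                      (3/2) nE / n
#   tetraploid (2,1,1)                    (3/2) nE / (n2 + nE)
#   tetraploid (1,1,1,1)                  likelihood free of eps (set 0)
#
# where nS/nD/n3/n2 are the read counts of the single-, double- and
# triple-copy alleles and nE the reads matching no allele.  All estimates
# are clamped to [0, 3/4]; the log-likelihood is concave in eps, so the
# clamped stationary point is the constrained maximiser.  Each closed
# form was re-derived by differentiating the grouped log-likelihood and
# is cross-checked against grid maximisation in the test suite.

# eps-hat for one candidate (multiplicity vector k over A,C,G,T),
# vectorised over the rows of Q.
poly_eps_hat <- function(Q, k) {
  m <- sum(k)
  n <- rowSums(Q)
  pos <- sort(k[k > 0], decreasing = TRUE)
  pat <- paste(pos, collapse = ",")
  alleles <- which(k > 0)
  nE <- n - rowSums(Q[, alleles, drop = FALSE])
  e <- switch(
    pat,
    "2" = , "3" = , "4" = {
      n_hi <- Q[, alleles]
      (n - n_hi) / n
    },
    "1,1" = 1.5 * nE / n,
    "2,1" = {
      nD <- Q[, which(k == 2L)]
      nS <- Q[, which(k == 1L)]
      A1 <- 6 * nS + 15 * nD + 21 * nE
      disc <- pmax(A1^2 - 360 * n * nE, 0)
      ifelse(n > 0, (A1 - sqrt(disc)) / (10 * n), 0)
    },
    "1,1,1" = 3 * nE / n,
    "3,1" = {
      n3 <- Q[, which(k == 3L)]
      ifelse(n3 + nE > 0, (9 / 8) * nE / (n3 + nE), 0)
    },
    "2,2" = 1.5 * nE / n,
    "2,1,1" = {
      n2 <- Q[, which(k == 2L)]
      ifelse(n2 + nE > 0, 1.5 * nE / (n2 + nE), 0)
    },
    "1,1,1,1" = rep(0, nrow(Q)),
    stop("unsupported genotype class: ", pat)
  )
  e[n == 0] <- 0
  pmin(pmax(e, 0), 0.75)
}

#' Maximum-likelihood error rate for any-ploidy genotypes
#'
#' Closed-form maximiser of the quartet log-likelihood over
#' `eps in [0, 3/4]` for a genotype of ploidy 2, 3 or 4 (see the genotype
#' class table in the package source; e.g. the triploid two-allele
#' genotype uses the root of a quadratic, the tetraploid `AACG`-type
#' gives `(3/2) nT / (nA + nT)`).
#'
#' @param q Read quartet (length-4 counts of A, C, G, T) or a matrix of
#'   quartets.
#' @param genotype Genotype string of ploidy 2, 3 or 4.
#' @return Error-rate estimate(s) in `[0, 3/4]`.
#' @examples
#' poly_ml_error_rate(c(9, 1, 0, 0), "AAA")      # 0.1
#' poly_ml_error_rate(c(3, 6, 1, 0), "ACC")      # (129 - sqrt(13041))/100
#' poly_ml_error_rate(c(6, 2, 2, 1), "AACG")     # (3/2) * 1/7
#' @export
poly_ml_error_rate <- function(q, genotype) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
  k <- genotype_mult(genotype)
  e <- poly_eps_hat(q, k)
  if (nrow(q) == 1L) e[[1]] else e
}

# Full log-likelihood profile over candidate multisets of size `ploidy`,
# vectorised over quartets.
poly_ll_profile <- function(Q, ploidy) {
  genotypes <- enumerate_genotypes(ploidy = ploidy)
  n <- rowSums(Q)
  nc <- length(genotypes)
  ll <- matrix(-Inf, nrow(Q), nc, dimnames = list(NULL, genotypes))
  ep <- matrix(NA_real_, nrow(Q), nc, dimnames = list(NULL, genotypes))
  allowed <- matrix(FALSE, nrow(Q), nc, dimnames = list(NULL, genotypes))
  m <- ploidy
  for (j in seq_len(nc)) {
    k <- genotype_mult(genotypes[j])
    e <- poly_eps_hat(Q, k)
    lj <- 0
    for (x in 1:4) {
      p <- k[x] / m + e * (m - 4 * k[x]) / (3 * m)
      lj <- lj + xlogy(Q[, x], p)
    }
    ll[, j] <- lj
    ep[, j] <- e
    allowed[, j] <- rowSums(Q[, k > 0, drop = FALSE] > 0) == sum(k > 0)
  }
  ll[n == 0, ] <- NA
  list(ll = ll, eps = ep, allowed = allowed, n = n, genotypes = genotypes)
}

#' Call genotypes of arbitrary ploidy per individual
#'
#' Maximum-likelihood call over all multisets of size `ploidy` built from
#' the nucleotides observed in each quartet, each candidate at its own ML
#' error rate.  The LRT machinery mirrors the diploid high-coverage
#' caller: the null is the homozygote for the population-major nucleotide
#' `M`, and significant heterozygotes are re-tested against the
#' homozygote for the individual's most abundant allele (one df each).
#' At `ploidy = 2` the results coincide with [hgc_call()].
#'
#' Accurate polyploid calls need substantially more coverage than diploid
#' ones -- all three chromosomes of a triploid must be sampled, and
#' allele-dosage look-alikes (e.g. AAC vs ACC) are separated only by read
#' proportions -- so in practice a much higher minimum coverage than the
#' default is advisable; no hard floor is imposed.
#'
#' @param counts Read quartet(s): length-4 vector or `n_ind x 4` matrix.
#' @param ploidy 2, 3 or 4.
#' @param min_cov Minimum coverage to call (default 6).
#' @param M Population-major nucleotide; enables `lrt_vs_hom`,
#'   `significant` and `het_confirmed` columns.
#' @param alpha Significance level for the tests.
#' @param tie_tol Log-likelihood tie tolerance.
#' @return Data frame per individual: `call`, `eps_call`, `ll_call`,
#'   `geno_class` (number of distinct nucleotides in the call), `reason`,
#'   and the LRT columns when `M` is given.
#' @examples
#' poly_call(c(20, 10, 0, 0), ploidy = 3)
#' @export
poly_call <- function(counts, ploidy, min_cov = 6L, M = NULL, alpha = 0.05,
                      tie_tol = 1e-9) {
  stopifnot(ploidy %in% 2:4)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  prof <- poly_ll_profile(counts, ploidy)
  pick <- hgc_pick_call(prof$ll, prof$allowed, prof$n, min_cov, tie_tol,
                        prof$genotypes)
  n_distinct <- vapply(
    pick$call,
    function(g) if (is.na(g)) NA_integer_
                else length(unique(strsplit(g, "", fixed = TRUE)[[1]])),
    0L, USE.NAMES = FALSE
  )
  out <- data.frame(
    call = pick$call,
    eps_call = ifelse(is.na(pick$idx), NA_real_,
                      prof$eps[cbind(seq_along(pick$idx), pick$idx)]),
    ll_call = pick$ll_call,
    geno_class = n_distinct,
    reason = pick$reason,
    stringsAsFactors = FALSE
  )
  if (!is.null(M)) {
    homM <- strrep(M, ploidy)
    mm_col <- match(homM, prof$genotypes)
    lrt <- 2 * (pick$ll_call - prof$ll[, mm_col])
    crit <- stats::qchisq(1 - alpha, df = 1)
    significant <- !is.na(pick$call) & pick$call != homM &
      !is.na(lrt) & lrt > crit
    out$lrt_vs_hom <- lrt
    out$significant <- significant
    out$het_confirmed <- poly_refine_heterozygotes(counts, pick, prof,
                                                   alpha, ploidy,
                                                   which(significant))
  }
  out
}

poly_refine_heterozygotes <- function(counts, pick, prof, alpha, ploidy,
                                      idx) {
  crit <- stats::qchisq(1 - alpha, df = 1)
  conf <- rep(NA, length(pick$call))
  for (i in idx) {
    g <- pick$call[i]
    if (is.na(g)) next
    al <- unique(strsplit(g, "", fixed = TRUE)[[1]])
    if (length(al) == 1L) next
    cnt <- counts[i, match(al, NUCS)]
    major_al <- al[which.max(cnt)]
    hom_col <- match(strrep(major_al, ploidy), prof$genotypes)
    lrt_het <- 2 * (pick$ll_call[i] - prof$ll[i, hom_col])
    conf[i] <- lrt_het > crit
  }
  conf
}

#' Run the polyploid caller over every site of a population sample
#'
#' @param x A [quartet_sites()] object.
#' @inheritParams poly_call
#' @return As [hgc_call_sites()], with `geno_class` per individual.
#' @export
poly_call_sites <- function(x, ploidy, min_cov = 6L, alpha = 0.05,
                            tie_tol = 1e-9) {
  stopifnot(inherits(x, "quartet_sites"))
  ns <- n_sites(x)
  N <- n_ind(x)
  calls <- matrix(NA_character_, ns, N)
  eps_hat <- matrix(NA_real_, ns, N)
  Mv <- rep(NA_character_, ns)
  poly <- rep(FALSE, ns)
  n_alleles <- rep(NA_integer_, ns)
  for (i in seq_len(ns)) {
    cnt <- site_counts(x, i)
    mm <- identify_major_minor(cnt)
    if (is.null(mm)) next
    res <- poly_call(cnt, ploidy, min_cov = min_cov, M = mm$M,
                     alpha = alpha, tie_tol = tie_tol)
    calls[i, ] <- res$call
    eps_hat[i, ] <- res$eps_call
    Mv[i] <- mm$M
    poly[i] <- any(res$significant, na.rm = TRUE)
    n_alleles[i] <- if (poly[i]) {
      poly_count_alleles(res, cnt, mm$M)
    } else 1L
  }
  list(calls = calls, eps_hat = eps_hat,
       site = data.frame(seq_id = x$seq_id, pos = x$pos, M = Mv,
                         polymorphic = poly, n_alleles = n_alleles,
                         stringsAsFactors = FALSE))
}

#' Allele counting for polyploid sites
#'
#' Same significant-genotype union rule as [hgc_count_alleles()]:
#' unconfirmed significant heterozygotes contribute as the homozygote
#' for their most abundant allele.
#'
#' @param calls Data frame from [poly_call()] with `M` supplied.
#' @param counts The corresponding quartets.
#' @param M Population-major nucleotide.
#' @return Integer in 1..4.
#' @export
poly_count_alleles <- function(calls, counts, M) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  nucs <- M
  for (i in which(calls$significant)) {
    al <- unique(strsplit(calls$call[i], "", fixed = TRUE)[[1]])
    if (length(al) > 1L && isFALSE(calls$het_confirmed[i])) {
      cnt <- counts[i, match(al, NUCS)]
      al <- al[which.max(cnt)]
    }
    nucs <- union(nucs, al)
  }
  length(nucs)
}
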