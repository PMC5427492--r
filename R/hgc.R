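# High-coverage genotype caller (HGC) for diploid data.
#
# Prior-free, per-individual: every multiset of size 2 over the
# nucleotides observed in the individual's quartet is a candidate
# genotype; each candidate is scored at its own maximum-likelihood error
# rate (closed form: (n - n_match)/n for homozygotes,
# (3/2) n_nonallele / n for heterozygotes, clamped to [0, 3/4]) and the
# call is the likelihood arg-max.  Polymorphism is detected by per-
# individual likelihood-ratio tests of the called genotype against the
# homozygote for the population-major nucleotide M, each hypothesis at
# its own ML error rate, on a chi-squared reference with 1 df.

DIPLOID_GENOTYPES <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")

#' Maximum-likelihood error rate for a diploid genotype
#'
#' Closed-form maximiser of the quartet log-likelihood over
#' `eps in [0, 3/4]`: homozygote XX gives `(n - nX)/n`; heterozygote XY
#' gives `(3/2)(n - nX - nY)/n`.  The homozygote form can exceed 3/4 when
#' under a quarter of the reads match; it is clamped to 3/4, the
#' uniform-read limit of the model.
#'
#' @param q Read quartet (length-4 counts of A, C, G, T; coverage >= 1).
#' @param genotype Diploid genotype string, e.g. `"AA"` or `"AC"`.
#' @return Error-rate estimate in `[0, 3/4]`.
#' @examples
#' ml_error_rate(c(9, 1, 0, 0), "AA")  # 0.1
#' ml_error_rate(c(4, 4, 1, 1), "AC")  # 0.3
#' @export
ml_error_rate <- function(q, genotype) {
  poly_ml_error_rate(q, genotype)
}

# Log-likelihood profile over the 10 diploid genotypes, vectorised over
# quartets.  Returns ll and eps matrices (k x 10) plus the candidate mask
# (a genotype is a candidate only when all its alleles have nonzero
# counts).
hgc_ll_profile <- function(Q) {
  n <- rowSums(Q)
  ll <- matrix(-Inf, nrow(Q), 10L, dimnames = list(NULL, DIPLOID_GENOTYPES))
  ep <- matrix(NA_real_, nrow(Q), 10L, dimnames = list(NULL, DIPLOID_GENOTYPES))
  allowed <- matrix(FALSE, nrow(Q), 10L, dimnames = list(NULL, DIPLOID_GENOTYPES))
  col <- 0L
  for (a in 1:4) {
    for (b in a:4) {
      col <- col + 1L
      if (a == b) {
        nX <- Q[, a]
        e <- pmin((n - nX) / n, 0.75)
        ll[, col] <- xlogy(nX, 1 - e) + xlogy(n - nX, e / 3)
        allowed[, col] <- nX > 0
      } else {
        s <- Q[, a] + Q[, b]
        e <- pmin(1.5 * (n - s) / n, 0.75)
        ll[, col] <- xlogy(s, 0.5 - e / 3) + xlogy(n - s, e / 3)
        allowed[, col] <- Q[, a] > 0 & Q[, b] > 0
      }
      ep[, col] <- e
    }
  }
  ll[n == 0, ] <- NA
  list(ll = ll, eps = ep, allowed = allowed, n = n)
}

hgc_pick_call <- function(ll, allowed, n, min_cov, tie_tol, genotypes) {
  k <- length(n)
  masked <- ll
  masked[!allowed | is.na(masked)] <- -Inf
  j <- max.col(masked, ties.method = "first")
  first <- cbind(seq_len(k), j)
  m1 <- masked[first]
  masked2 <- masked
  masked2[first] <- -Inf
  m2 <- do.call(pmax, as.data.frame(masked2))
  gap <- m1 - m2                       # NaN when no finite candidate
  ok <- n >= min_cov & is.finite(m1) & !is.nan(gap) & gap > tie_tol
  reason <- rep("", k)
  reason[!ok & is.finite(m1)] <- "tie"
  reason[!is.finite(m1)] <- "no_reads"
  reason[n < min_cov] <- "low_coverage"
  reason[ok] <- ""
  call <- ifelse(ok, genotypes[j], NA_character_)
  list(call = call,
       ll_call = ifelse(ok, m1, NA_real_),
       idx = ifelse(ok, j, NA_integer_),
       reason = reason)
}

#' Call diploid genotypes per individual with the HGC
#'
#' @param counts Read quartet(s): length-4 vector or `n_ind x 4` matrix.
#' @param min_cov Minimum coverage to call a genotype (default 6, the
#'   threshold at which homozygotes are reliably distinguished from
#'   single-error heterozygote look-alikes; set lower for
#'   simulation-style evaluation of raw ML calls).
#' @param M Population-major nucleotide for the polymorphism LRT; when
#'   `NULL` no LRT columns are computed.
#' @param alpha Significance level for the per-individual LRT and the
#'   heterozygote refinement test.
#' @param tie_tol Log-likelihood tie tolerance for a no-call.
#' @return Data frame per individual: `call` (`NA` = no-call), `eps_call`
#'   (ML error rate of the called genotype), `ll_call`, `reason`, and --
#'   when `M` is supplied -- `lrt_vs_MM` (statistic of Eq.-style test of
#'   the call against the M homozygote, each at its own ML error rate),
#'   `significant`, and `het_confirmed` (heterozygote refinement against
#'   the homozygote for the individual's more abundant allele; `NA` for
#'   homozygous or non-significant calls).
#' @examples
#' hgc_call(c(5, 5, 0, 0), min_cov = 6, M = "A")
#' @export
hgc_call <- function(counts, min_cov = 6L, M = NULL, alpha = 0.05,
                     tie_tol = 1e-9) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  prof <- hgc_ll_profile(counts)
  pick <- hgc_pick_call(prof$ll, prof$allowed, prof$n, min_cov, tie_tol,
                        DIPLOID_GENOTYPES)
  out <- data.frame(
    call = pick$call,
    eps_call = ifelse(is.na(pick$idx), NA_real_,
                      prof$eps[cbind(seq_along(pick$idx), pick$idx)]),
    ll_call = pick$ll_call,
    reason = pick$reason,
    stringsAsFactors = FALSE
  )
  if (!is.null(M)) {
    mm_col <- match(paste0(M, M), DIPLOID_GENOTYPES)
    ll0 <- prof$ll[, mm_col]
    lrt <- 2 * (pick$ll_call - ll0)
    crit <- stats::qchisq(1 - alpha, df = 1)
    significant <- !is.na(pick$call) & pick$call != paste0(M, M) &
      !is.na(lrt) & lrt > crit
    out$lrt_vs_MM <- lrt
    out$significant <- significant
    out$het_confirmed <- refine_heterozygotes(counts, pick, prof, alpha,
                                              which(significant))
  }
  out
}

# Heterozygote refinement: for significant heterozygous calls, LRT of the
# called heterozygote against the homozygote for the individual's more
# abundant allele (count ties broken alphabetically).  NA when not
# applicable.
refine_heterozygotes <- function(counts, pick, prof, alpha,
                                 idx = seq_along(pick$call)) {
  crit <- stats::qchisq(1 - alpha, df = 1)
  conf <- rep(NA, length(pick$call))
  for (i in idx) {
    g <- pick$call[i]
    if (is.na(g)) next
    al <- strsplit(g, "", fixed = TRUE)[[1]]
    if (al[1] == al[2]) next
    cnt <- counts[i, match(al, NUCS)]
    major_al <- al[which.max(cnt)]
    hom_col <- match(paste0(major_al, major_al), colnames(prof$ll))
    lrt_het <- 2 * (pick$ll_call[i] - prof$ll[i, hom_col])
    conf[i] <- lrt_het > crit
  }
  conf
}

#' Likelihood-ratio test of site polymorphism from HGC calls
#'
#' The monomorphic null (every individual is MM) is rejected when at
#' least one non-MM called genotype has `LRT = 2(LL1 - LL0)` above the
#' chi-squared(1) critical value at `alpha`.
#'
#' @param calls Data frame from [hgc_call()] run with `M` supplied.
#' @param alpha Ignored when `calls` already carries `significant` at the
#'   same level; retained for clarity.
#' @return Logical: is the site significantly polymorphic?
#' @export
hgc_test_polymorphism <- function(calls, alpha = 0.05) {
  any(calls$significant, na.rm = TRUE)
}

#' Estimate the number of alleles at a site from HGC calls
#'
#' Distinct nucleotides in the union of the population-major nucleotide M
#' and all significant genotypes, where a significant heterozygote that
#' fails the refinement test contributes as the homozygote for its more
#' abundant allele (the reported individual call is unchanged).
#'
#' @param calls Data frame from [hgc_call()] run with `M`.
#' @param counts The quartets the calls were made from (needed to resolve
#'   unconfirmed heterozygotes).
#' @param M Population-major nucleotide.
#' @return Integer in 1..4.
#' @export
hgc_count_alleles <- function(calls, counts, M) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  nucs <- M
  for (i in which(calls$significant)) {
    g <- calls$call[i]
    al <- strsplit(g, "", fixed = TRUE)[[1]]
    if (al[1] != al[2] && isFALSE(calls$het_confirmed[i])) {
      cnt <- counts[i, match(al, NUCS)]
      al <- rep(al[which.max(cnt)], 2L)
    }
    nucs <- union(nucs, al)
  }
  length(nucs)
}

#' Run the HGC over every site of a population sample
#'
#' Per site: identify the population-major nucleotide, call every
#' individual, test polymorphism and count alleles.
#'
#' @param x A [quartet_sites()] object.
#' @inheritParams hgc_call
#' @return List with `calls` (`n_sites x n_ind` character matrix),
#'   `eps_hat` (matching matrix of error-rate estimates) and `site` (data
#'   frame: `seq_id`, `pos`, `M`, `polymorphic`, `n_alleles`).
#' @export
hgc_call_sites <- function(x, min_cov = 6L, alpha = 0.05, tie_tol = 1e-9) {
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
    res <- hgc_call(cnt, min_cov = min_cov, M = mm$M, alpha = alpha,
                    tie_tol = tie_tol)
    calls[i, ] <- res$call
    eps_hat[i, ] <- res$eps_call
    Mv[i] <- mm$M
    poly[i] <- hgc_test_polymorphism(res)
    n_alleles[i] <- if (poly[i]) hgc_count_alleles(res, cnt, mm$M) else 1L
  }
  list(calls = calls, eps_hat = eps_hat,
       site = data.frame(seq_id = x$seq_id, pos = x$pos, M = Mv,
                         polymorphic = poly, n_alleles = n_alleles,
                         stringsAsFactors = FALSE))
}
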