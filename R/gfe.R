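# Population-level genotype-frequency estimator (GFE).
#
# At each site the two most abundant nucleotides pooled over the
# population sample are the candidate major (M) and minor (m) alleles.
# The per-site parameters (gamma1, gamma2, gamma3, eps) -- frequencies of
# the MM, Mm and mm genotypes and the error rate -- are estimated by
# maximising
#   sum_i ln[ sum_g gamma_g * L(quartet_i | g, eps) ]
# over the genotype-frequency simplex and eps in [0, 3/4].  This is a
# three-component finite mixture; the fit uses EM with closed-form
# M-steps (implemented in C++), deterministic multiple restarts and a
# monomorphic-null comparison yielding the polymorphism LRT.  The
# minor-allele frequency estimate is q-hat = gamma3 + gamma2/2, obtained
# without calling any genotype.

#' Identify the candidate major and minor alleles at a site
#'
#' The two most abundant nucleotide reads pooled over the population
#' sample; count ties are broken alphabetically (A < C < G < T), and when
#' fewer than two nucleotides are observed the minor allele is the
#' alphabetically first unobserved nucleotide (its frequency is then
#' estimated as ~0).
#'
#' @param counts `n_ind x 4` matrix of read quartets (columns A, C, G, T),
#'   or a pooled length-4 count vector.
#' @return Named list with `M`, `m` (nucleotide characters) and `pooled`
#'   (the pooled counts); `NULL` if the site has zero total coverage.
#' @export
identify_major_minor <- function(counts) {
  pooled <- if (is.null(dim(counts))) as.numeric(counts) else colSums(counts)
  names(pooled) <- NUCS
  if (sum(pooled) == 0) return(NULL)
  ord <- order(-pooled, NUCS)
  list(M = NUCS[ord[1]], m = NUCS[ord[2]], pooled = pooled)
}

gfe_null_fit <- function(nM, nm, nE) {
  n_tot <- sum(nM) + sum(nm) + sum(nE)
  eps0 <- if (n_tot == 0) 0 else min(0.75, (sum(nm) + sum(nE)) / n_tot)
  ll0 <- sum(xlogy(nM, 1 - eps0)) + sum(xlogy(nm + nE, eps0 / 3))
  list(eps = eps0, loglik = ll0)
}

# Deterministic EM initialisations: (1) naive genotype proportions from
# per-individual majority reads, (2) HWE at the naive read-frequency
# estimate of q, (3) uniform.
gfe_inits <- function(nM, nm) {
  tot <- nM + nm
  inits <- list()
  with_reads <- tot > 0
  if (any(with_reads)) {
    pM <- nM[with_reads] / tot[with_reads]
    naive <- c(mean(pM > 0.75), mean(pM >= 0.25 & pM <= 0.75), mean(pM < 0.25))
    naive <- (naive + 1e-3) / sum(naive + 3e-3)
    inits[[1]] <- list(gamma = naive, eps = 0.005)
    q0 <- min(max(sum(nm) / sum(tot), 1e-3), 0.999)
    inits[[2]] <- list(gamma = c((1 - q0)^2, 2 * q0 * (1 - q0), q0^2),
                       eps = 0.005)
  } else {
    inits[[1]] <- list(gamma = c(1 / 3, 1 / 3, 1 / 3), eps = 0.005)
    inits[[2]] <- list(gamma = c(0.8, 0.15, 0.05), eps = 0.01)
  }
  inits[[3]] <- list(gamma = c(1 / 3, 1 / 3, 1 / 3), eps = 0.05)
  inits
}

#' Estimate site genotype-frequency priors and error rate
#'
#' Maximum-likelihood fit of the three-genotype mixture at one site:
#' genotype frequencies `(gamma1, gamma2, gamma3)` for (MM, Mm, mm) on the
#' simplex and error rate `eps` in `[0, 3/4]`.  Reads that are neither M
#' nor m stay in the likelihood as error categories.  The polymorphism
#' likelihood-ratio statistic compares the full fit against the
#' monomorphic null (site fixed for M, `gamma1 = 1`, `eps` free) and is
#' referred to a chi-squared distribution with 2 df.
#'
#' @param counts `n_ind x 4` matrix of read quartets (columns A, C, G, T).
#' @param tol EM convergence tolerance on successive log-likelihoods.
#' @param max_iter Maximum EM iterations per restart.
#' @param n_restarts Number of deterministic restarts (up to 3).
#' @return An object of class `site_priors`: list with `M`, `m`, `gamma`
#'   (named length-3 vector), `eps`, `q_hat`, `ll_full`, `ll_null`,
#'   `lrt_poly`, `p_poly`, `converged`, `iterations`; or `NULL` for a
#'   zero-coverage site.
#' @examples
#' counts <- matrix(0L, 4, 4); counts[, 1] <- c(9, 10, 4, 5); counts[, 2] <- c(1, 0, 6, 5)
#' estimate_site_priors(counts)
#' @export
estimate_site_priors <- function(counts, tol = 1e-12, max_iter = 5000L,
                                 n_restarts = 3L) {
  mm <- identify_major_minor(counts)
  if (is.null(mm)) return(NULL)
  iM <- match(mm$M, NUCS)
  im <- match(mm$m, NUCS)
  nM <- counts[, iM]
  nm <- counts[, im]
  nE <- rowSums(counts) - nM - nm

  inits <- gfe_inits(nM, nm)[seq_len(min(n_restarts, 3L))]
  best <- NULL
  for (ini in inits) {
    fit <- gfe_em_fit(nM, nm, nE, ini$gamma, ini$eps,
                      tol = tol, max_iter = max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  null <- gfe_null_fit(nM, nm, nE)
  # the null (gamma1 = 1, eps free) is nested in the full model: never
  # report a full-model likelihood below it
  if (best$loglik < null$loglik) {
    best$gamma <- c(1, 0, 0)
    best$eps <- null$eps
    best$loglik <- null$loglik
    best$converged <- TRUE
  }
  gamma <- best$gamma / sum(best$gamma)
  names(gamma) <- c("MM", "Mm", "mm")
  lrt <- max(0, 2 * (best$loglik - null$loglik))
  structure(list(
    M = mm$M, m = mm$m, gamma = gamma, eps = best$eps,
    q_hat = unname(gamma[3] + gamma[2] / 2),
    ll_full = best$loglik, ll_null = null$loglik,
    lrt_poly = lrt,
    p_poly = stats::pchisq(lrt, df = 2, lower.tail = FALSE),
    converged = best$converged, iterations = best$iterations
  ), class = "site_priors")
}

#' @export
print.site_priors <- function(x, ...) {
  cat(sprintf(
    "<site_priors> M=%s m=%s  gamma=(%.4f, %.4f, %.4f)  eps=%.5f\n  q_hat=%.4f  LRT=%.3f (p=%.3g)%s\n",
    x$M, x$m, x$gamma[1], x$gamma[2], x$gamma[3], x$eps, x$q_hat,
    x$lrt_poly, x$p_poly, if (x$converged) "" else "  [not converged]"
  ))
  invisible(x)
}

#' Estimate priors for every site of a population sample
#'
#' Runs [estimate_site_priors()] at each site and collects the results in
#' a priors table consumable by [bgc_call_population()].
#'
#' @param x A [quartet_sites()] object.
#' @inheritParams estimate_site_priors
#' @return Data frame with one row per site: `seq_id`, `pos`, `M`, `m`,
#'   `gamma1`, `gamma2`, `gamma3`, `eps`, `q_hat`, `ll_full`, `ll_null`,
#'   `lrt_poly`, `p_poly`, `converged`.  Zero-coverage sites get `NA`
#'   estimates.
#' @export
estimate_priors <- function(x, tol = 1e-12, max_iter = 5000L,
                            n_restarts = 3L) {
  stopifnot(inherits(x, "quartet_sites"))
  ns <- n_sites(x)
  out <- data.frame(
    seq_id = x$seq_id, pos = x$pos,
    M = NA_character_, m = NA_character_,
    gamma1 = NA_real_, gamma2 = NA_real_, gamma3 = NA_real_,
    eps = NA_real_, q_hat = NA_real_,
    ll_full = NA_real_, ll_null = NA_real_,
    lrt_poly = NA_real_, p_poly = NA_real_, converged = NA,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(ns)) {
    pr <- estimate_site_priors(site_counts(x, i), tol = tol,
                               max_iter = max_iter, n_restarts = n_restarts)
    if (is.null(pr)) next
    out$M[i] <- pr$M; out$m[i] <- pr$m
    out$gamma1[i] <- pr$gamma[1]; out$gamma2[i] <- pr$gamma[2]
    out$gamma3[i] <- pr$gamma[3]
    out$eps[i] <- pr$eps; out$q_hat[i] <- pr$q_hat
    out$ll_full[i] <- pr$ll_full; out$ll_null[i] <- pr$ll_null
    out$lrt_poly[i] <- pr$lrt_poly; out$p_poly[i] <- pr$p_poly
    out$converged[i] <- pr$converged
  }
  out
}

#' Likelihood-ratio test of site polymorphism
#'
#' A site is significantly polymorphic when the mixture fit beats the
#' monomorphic null (fixed for M) at level `alpha` on a chi-squared
#' reference with 2 df.
#'
#' @param priors A `site_priors` object or a priors table from
#'   [estimate_priors()].
#' @param alpha Significance level (default 0.05).
#' @return Logical (vector for a priors table; `NA` rows give `FALSE`).
#' @export
test_polymorphism <- function(priors, alpha = 0.05) {
  p <- if (inherits(priors, "site_priors")) priors$p_poly else priors$p_poly
  !is.na(p) & p < alpha
}
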