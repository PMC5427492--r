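# Bayesian genotype caller (BGC) for low-coverage diploid data.
#
# Per individual, the posterior over {MM, Mm, mm} combines the quartet
# likelihood with the site-level genotype-frequency priors estimated by
# the GFE:
#   post_g  propto  gamma_g * P_g(M)^nM P_g(m)^nm P_g(e1)^ne1 P_g(e2)^ne2
# with eps fixed at the site estimate.  The call is the posterior arg-max;
# genotypes are only called at sites that pass the polymorphism LRT.

bgc_geno_strings <- function(M, m) {
  c(MM = paste0(M, M),
    Mm = normalize_genotype(paste0(M, m)),
    mm = paste0(m, m))
}

#' Posterior genotype call for individuals at one site
#'
#' @param counts Read quartet(s): length-4 vector or `n_ind x 4` matrix
#'   (columns A, C, G, T).
#' @param priors A `site_priors` object from [estimate_site_priors()], or
#'   any list carrying `M`, `m`, `gamma` (length 3, on the simplex) and
#'   `eps`.
#' @param min_cov Minimum individual coverage to call (default 1; a
#'   zero-coverage quartet is never called since all genotypes are
#'   equally likely).
#' @param tie_tol Log-posterior tolerance below which the top two
#'   genotypes are considered tied, giving a no-call.
#' @return Data frame, one row per individual: `call` (genotype string
#'   such as `"AC"`, `NA` for no-call), `post_MM`, `post_Mm`, `post_mm`
#'   (posterior masses, summing to 1 for every covered individual) and
#'   `reason` (`""`, `"low_coverage"` or `"tie"`).
#' @examples
#' pr <- list(M = "A", m = "C", gamma = c(0.25, 0.5, 0.25), eps = 0.01)
#' bgc_call(c(2, 1, 0, 0), pr)
#' @export
bgc_call <- function(counts, priors, min_cov = 1L, tie_tol = 1e-9) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  gamma <- as.numeric(priors$gamma)
  if (abs(sum(gamma) - 1) > 1e-6 || any(gamma < 0)) {
    stop("prior genotype frequencies must lie on the simplex")
  }
  eps <- priors$eps
  iM <- match(priors$M, NUCS)
  im <- match(priors$m, NUCS)
  nM <- counts[, iM]
  nm <- counts[, im]
  n <- rowSums(counts)
  nE <- n - nM - nm

  lg <- cbind(
    xlogy(nM, 1 - eps) + xlogy(nm + nE, eps / 3),
    xlogy(nM + nm, 0.5 - eps / 3) + xlogy(nE, eps / 3),
    xlogy(nm, 1 - eps) + xlogy(nM + nE, eps / 3)
  )
  lpost <- sweep(lg, 2L, log(gamma), "+")  # log gamma_g + log L_g
  k <- nrow(counts)
  call_idx <- max.col(lpost, ties.method = "first")
  first <- cbind(seq_len(k), call_idx)
  lmax <- lpost[first]
  w <- exp(lpost - lmax)
  w[is.nan(w)] <- 0  # -Inf - -Inf (zero coverage with a zero prior)
  post <- w / rowSums(w)
  rest <- lpost
  rest[first] <- -Inf
  gap <- lmax - do.call(pmax, as.data.frame(rest))  # NaN if both -Inf

  strings <- bgc_geno_strings(priors$M, priors$m)
  call <- strings[call_idx]
  reason <- rep("", nrow(counts))
  tie <- is.na(gap) | gap <= tie_tol
  call[tie] <- NA
  reason[tie] <- "tie"
  low <- n < max(min_cov, 1L)
  call[low] <- NA
  reason[low] <- "low_coverage"
  data.frame(call = unname(call), post_MM = post[, 1], post_Mm = post[, 2],
             post_mm = post[, 3], reason = reason, stringsAsFactors = FALSE)
}

#' Call genotypes for a whole population sample with the BGC
#'
#' Applies the site polymorphism test at level `alpha`; sites that fail
#' yield all-no-call rows (reason `"not_polymorphic"`), the rest get
#' per-individual posterior calls via [bgc_call()].
#'
#' @param x A [quartet_sites()] object.
#' @param priors Priors table from [estimate_priors()] with one row per
#'   site of `x`.
#' @param alpha Significance level of the polymorphism LRT.
#' @param min_cov,tie_tol Passed to [bgc_call()].
#' @return List with `calls` (`n_sites x n_ind` character matrix, `NA` =
#'   no-call), `reason` (same shape) and `polymorphic` (logical per
#'   site).
#' @export
bgc_call_population <- function(x, priors, alpha = 0.05, min_cov = 1L,
                                tie_tol = 1e-9) {
  stopifnot(inherits(x, "quartet_sites"))
  if (nrow(priors) != n_sites(x)) {
    stop("priors table has ", nrow(priors), " rows but the sample has ",
         n_sites(x), " sites")
  }
  ns <- n_sites(x)
  N <- n_ind(x)
  calls <- matrix(NA_character_, ns, N)
  reason <- matrix("not_polymorphic", ns, N)
  poly <- test_polymorphism(priors, alpha)
  for (i in which(poly)) {
    pr <- list(M = priors$M[i], m = priors$m[i],
               gamma = c(priors$gamma1[i], priors$gamma2[i], priors$gamma3[i]),
               eps = priors$eps[i])
    res <- bgc_call(site_counts(x, i), pr, min_cov = min_cov,
                    tie_tol = tie_tol)
    calls[i, ] <- res$call
    reason[i, ] <- res$reason
  }
  list(calls = calls, reason = reason, polymorphic = poly)
}
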