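# Scoring of genotype calls against recorded truth.
#
# Two accuracy definitions are used throughout: the correct-call rate
# among individuals treats a missing call as incorrect, while the rate
# among called genotypes is computed only over individuals that received
# a call.  Both are computed per site and summarised as mean +/- 2 SEM
# over the replicate sites.

#' Score genotype calls against truth
#'
#' @param calls `n_sites x n_ind` character matrix of genotype strings
#'   (`NA` = no-call), alleles in any order.
#' @param truth Matching matrix of true genotype strings.
#' @return List of class `call_score`: `correct_among_individuals` and
#'   `correct_among_called` (means over sites, with `*_2sem` companions;
#'   the among-called mean is over sites with at least one call),
#'   `no_call_fraction`, `n_sites`, `n_ind` and `per_site` (data frame of
#'   per-site rates).
#' @examples
#' truth <- matrix("AC", 2, 10)
#' calls <- truth; calls[, 1] <- NA; calls[1, 2] <- "AA"
#' score_calls(calls, truth)
#' @export
score_calls <- function(calls, truth) {
  if (!all(dim(calls) == dim(truth))) {
    stop("'calls' and 'truth' must have identical dimensions")
  }
  canon <- function(m) {
    out <- m
    needs <- !is.na(m)
    out[needs] <- vapply(m[needs], normalize_genotype, "", USE.NAMES = FALSE)
    out
  }
  calls <- canon(calls)
  truth <- canon(truth)
  called <- !is.na(calls)
  correct <- called & calls == truth
  correct[is.na(correct)] <- FALSE
  among_ind <- rowMeans(correct)
  n_called <- rowSums(called)
  among_called <- ifelse(n_called > 0, rowSums(correct) / n_called, NA)
  sem2 <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_real_)
    2 * stats::sd(v) / sqrt(length(v))
  }
  structure(list(
    correct_among_individuals = mean(among_ind),
    correct_among_individuals_2sem = sem2(among_ind),
    correct_among_called = mean(among_called, na.rm = TRUE),
    correct_among_called_2sem = sem2(among_called),
    no_call_fraction = 1 - mean(called),
    n_sites = nrow(calls), n_ind = ncol(calls),
    per_site = data.frame(correct_among_individuals = among_ind,
                          correct_among_called = among_called,
                          n_called = n_called)
  ), class = "call_score")
}

#' @export
print.call_score <- function(x, ...) {
  cat(sprintf(
    paste0("<call_score> %d sites x %d individuals\n",
           "  correct among individuals: %.4f +/- %.5f (2 SEM)\n",
           "  correct among called:      %.4f +/- %.5f (2 SEM)\n",
           "  no-call fraction:          %.4f\n"),
    x$n_sites, x$n_ind,
    x$correct_among_individuals, x$correct_among_individuals_2sem,
    x$correct_among_called, x$correct_among_called_2sem,
    x$no_call_fraction
  ))
  invisible(x)
}

#' False-positive and -negative rates of polymorphism detection
#'
#' @param declared Logical vector: was each site declared polymorphic
#'   (or, for allele-count power, declared to have >= 3 alleles)?
#' @param truly Logical vector: is each site truly so?
#' @return List with `fp_rate` (fraction of truly negative sites
#'   declared), `fn_rate` (fraction of truly positive sites missed) and
#'   the counts they are based on.
#' @export
polymorphism_power <- function(declared, truly) {
  stopifnot(length(declared) == length(truly))
  n_neg <- sum(!truly)
  n_pos <- sum(truly)
  list(
    fp_rate = if (n_neg > 0) mean(declared[!truly]) else NA_real_,
    fn_rate = if (n_pos > 0) mean(!declared[truly]) else NA_real_,
    n_negative = n_neg, n_positive = n_pos
  )
}

#' Theoretical floor of the polymorphism false-negative rate
#'
#' The probability that a finite sample of `N` diploid individuals
#' carries only one of the two alleles, `q^(2N) + (1 - q)^(2N)`: no
#' method can detect a polymorphism absent from the sample, so the
#' false-negative rate cannot fall below this at any coverage.
#'
#' @param q Minor-allele frequency.
#' @param N Number of diploid individuals.
#' @return Lower bound on the false-negative rate.
#' @examples
#' fn_rate_floor(0.5, 1)    # 0.5
#' fn_rate_floor(0.1, 100)  # ~7.1e-10
#' @export
fn_rate_floor <- function(q, N) {
  q^(2 * N) + (1 - q)^(2 * N)
}

#' Mean and 2 SEM of the minor-allele-frequency estimates
#'
#' Summarises `q_hat = gamma3_hat + gamma2_hat/2` over the replicate
#' sites of a priors table, the direct (call-free) allele-frequency
#' estimate whose unbiasedness at low coverage is the point of
#' estimating frequencies before calling genotypes.
#'
#' @param priors Priors table from [estimate_priors()] (uses its `q_hat`
#'   column), or a numeric vector of per-site estimates.
#' @return List with `mean_q_hat`, `sem2` and `n_sites`.
#' @export
allele_freq_bias <- function(priors) {
  q <- if (is.numeric(priors)) priors else priors$q_hat
  q <- q[!is.na(q)]
  list(mean_q_hat = mean(q),
       sem2 = if (length(q) > 1) 2 * stats::sd(q) / sqrt(length(q)) else 0,
       n_sites = length(q))
}
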