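---
title: "Maximum-likelihood genotype calling from read quartets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-likelihood genotype calling from read quartets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlgenocall)
```

## The problem

Population-genomic studies need individual genotypes, but
high-throughput sequencing delivers them only indirectly: at every
genomic site each individual contributes a *read quartet* — the counts
of A, C, G and T reads — shaped by three confounded random processes:
which of the individual's chromosomes happened to be sequenced, how many
reads landed on the site at all (coverage), and sequencing errors, which
occur at rates (typically 0.001–0.01 per read per site) comparable to
real polymorphism. `mlgenocall` implements a family of
maximum-likelihood genotype callers that disentangle these processes
from the read counts themselves, without using base-quality strings —
the error rate is a free parameter estimated from the data, which also
captures errors introduced upstream of the sequencer.

## The read model

Everything rests on one observation model. For an individual with $m$
chromosomes ($m$ = ploidy), $k$ of which carry nucleotide $x$, a read is
$x$ with probability

$$P(x \mid G, \epsilon) \;=\; \frac{k}{m}(1-\epsilon) \;+\;
  \frac{m-k}{m}\,\frac{\epsilon}{3},$$

i.e. either a chromosome carrying $x$ was sequenced correctly, or
another chromosome was sequenced and mis-read as $x$; errors are uniform
over the three wrong nucleotides, so $\epsilon \in [0, 3/4]$ (at $3/4$
all four reads are equiprobable). For a diploid this is the familiar
three-row table for MM, Mm and mm; reads are independent, so a quartet
$(n_A, n_C, n_G, n_T)$ has multinomial log-likelihood
$\sum_x n_x \ln P(x \mid G, \epsilon)$. The multinomial coefficient is
dropped throughout: it cancels from every likelihood ratio and every
posterior, so nothing downstream is approximate. `read_prob()` and
`quartet_loglik()` expose the model; log-domain arithmetic with the
convention $0 \ln 0 = 0$ is used everywhere, and $-\infty$ is a valid
log-likelihood (a positive count on an impossible read).

## Population priors: the genotype-frequency estimator

At low coverage (a few reads per individual) a single quartet cannot
separate a heterozygote from a homozygote whose second allele was simply
not sequenced. A population sample can: at each site the two most
abundant pooled nucleotides are taken as the candidate major/minor
alleles M and m (count ties broken alphabetically; if fewer than two
nucleotides are observed, m is the alphabetically first unobserved one
and its frequency is estimated as ~0), and the genotype frequencies
$(\gamma_1, \gamma_2, \gamma_3)$ of MM, Mm, mm together with the error
rate are estimated by maximising the mixture likelihood

$$\ell(\gamma, \epsilon) = \sum_{i=1}^{N}
  \ln \sum_{g=1}^{3} \gamma_g\, L(q_i \mid g, \epsilon).$$

No mating-system assumption is made: $\gamma$ ranges over the whole
simplex, so heterozygote excess (negative inbreeding coefficients,
common in asexual and clonally propagating organisms) is representable,
unlike HWE-based callers. The minor-allele frequency estimate
$\hat q = \hat\gamma_3 + \hat\gamma_2/2$ comes straight from the
frequencies, *without calling any genotype* — this is what keeps it
unbiased at coverages where per-individual calls are unreliable.

The maximisation is an EM over genotype memberships, implemented in
C++. Both M-steps are closed forms: $\gamma$ is the mean responsibility,
and $\epsilon$ solves
$(2B + 2a + 2c)\,\epsilon^2 - (5B + 3a + 2c)\,\epsilon + 3B = 0$, where
$a$, $c$ and $B$ are the responsibility-weighted read counts hitting the
$1-\epsilon$, $1/2 - \epsilon/3$ and $\epsilon/3$ probability classes
(smaller root; the expected log-likelihood is concave in $\epsilon$, so
the root clamped to $[0, 3/4]$ is the constrained maximiser). Three
deterministic restarts guard against local optima: naive genotype
proportions from per-individual majority reads, HWE at the pooled read
frequency, and a uniform start. Convergence is declared when successive
log-likelihoods differ by less than $10^{-12}$ (up to 5000 iterations).
With closed-form M-steps the EM reaches this tolerance directly, so no
separate quasi-Newton polish is applied on top — a finite-difference
polish is fragile exactly where the optimum commonly sits, on the
simplex boundary ($\hat\gamma_3 = 0$ at minimised inbreeding).

Polymorphism is tested per site by a likelihood-ratio statistic against
the monomorphic null (fixed for M, $\gamma_1 = 1$, $\epsilon$ free),
referred to $\chi^2_2$ (two freed frequencies). Because the null lies on
the simplex boundary the test is conservative, which the type-I-error
test confirms. If a restart ends below the null, the null solution is
returned — the null is nested, so the full-model likelihood can never
legitimately be smaller.

```{r gfe-example}
sim <- sim_biallelic(n_sites = 200, n_ind = 100, gamma1 = 0.81,
                     gamma3 = 0.01, mean_cov = 3, error_rate = 0.01,
                     seed = 1)
priors <- estimate_priors(sim$sites)
allele_freq_bias(priors)$mean_q_hat   # ~0.10: unbiased at mean coverage 3
```

## The Bayesian genotype caller (BGC)

At significantly polymorphic sites, each individual's posterior over
{MM, Mm, mm} multiplies its quartet likelihood (at the site
$\hat\epsilon$) by the site priors $\hat\gamma$; the call is the
posterior arg-max. Individuals are not called when they have no reads
(all genotypes are then equally likely) or when the top two posteriors
tie within $10^{-9}$ in log space (an exact-equality rule needs a
floating-point tolerance). Reads that are neither M nor m stay in the
likelihood as error categories — they are evidence about $\epsilon$, not
discarded. The default minimum coverage is 1: the prior does real work
precisely for sparsely covered individuals.

## The high-coverage caller (HGC) and its polyploid extensions

With enough reads per individual, both chromosomes are almost surely
sampled and population priors become unnecessary — and with them goes
the biallelic restriction. The HGC scores, per individual, every
genotype (multiset of size = ploidy) built from the nucleotides observed
in the quartet, each at its own ML error rate, and calls the arg-max.
The per-genotype $\hat\epsilon$ are closed forms: $(n - n_X)/n$ for
homozygotes, $\tfrac32 n_E/n$ for diploid heterozygotes (and the
analogous expressions per polyploid dosage class, including the
quadratic root for triploid 2:1 genotypes), clamped to $[0, 3/4]$; the
test suite checks each against grid maximisation.

Polymorphism detection is per individual: the called genotype is
compared against the homozygote for the population-major nucleotide M by
$LRT = 2(LL_1 - LL_0)$ on $\chi^2_1$, each hypothesis at its own ML
error rate (a standard profile-likelihood LRT; whether the original
implementation profiled $\epsilon$ under the null the same way is not
documented, so this choice is stated here explicitly). A site is
polymorphic if at least one non-MM call is significant — deliberately no
multiple-testing correction across individuals, matching the "at least
one" rejection rule; the level `alpha` is exposed. For allele counting,
significant *heterozygous* calls must additionally beat the homozygote
for the individual's own more abundant allele at $\chi^2_1$; a
heterozygote that fails this refinement contributes that homozygote to
the allele count instead (the reported individual call is not re-made —
refinement guards the allele count, not the call). The number of alleles
is the number of distinct nucleotides in M plus all significant,
refinement-adjusted genotypes.

Characteristic (and intended) decision boundaries fall out of the ML
comparison, all asserted in the tests by direct likelihood arithmetic:
a lone discordant read is part of a heterozygote up to coverage 5 and an
error from coverage 6; two discordant reads flip at coverage 11; the
triploid single-read boundary sits at coverage 8, and a singleton third
nucleotide stops being a triploid allele above coverage 6. These
boundaries produce the correct-call-rate valleys at fixed coverage 6 and
11 (diploid heterozygotes) and motivate the default `min_cov = 6` for
the HGC — below that, homozygotes masquerade as heterozygotes too
easily. For the simulation-style accuracy evaluations reported by
`scripts/acceptance.R` the threshold is set to 1, since those measure
raw ML-call accuracy over all individuals.

Polyploid calling needs much more coverage than diploid calling: all
$m$ chromosomes must be sampled, and dosage pairs (AAC vs ACC) differ
only through read proportions. The same `min_cov` flag applies with no
hard floor, but realistic use needs substantially deeper data.

## The simulator

`sim_biallelic()`, `sim_triallelic()` and `sim_individual()` implement
the exact generative model the callers assume: genotypes drawn from
their population frequencies (biallelic: arbitrary $(\gamma_1, \gamma_2,
\gamma_3)$; triallelic: HWE products of $p, q, r$ over three fixed
nucleotides), coverage Poisson (untruncated — zero-coverage individuals
are the missing-data case) or fixed, and reads drawn per chromosome with
uniform error — which collapses to a categorical draw from the
genotype's read-probability row, so the simulator and the likelihood are
two faces of one model. Allele identities are fixed (major = A); a test
permutes the nucleotide labels to confirm no caller cares. One seed
drives a run, sites outer, individuals inner, so runs are bit
reproducible.

What passing simulation tests do *not* show: the simulator has no
mapping artifacts, no reference bias, no indels, no base-quality
structure and no correlated errors. Performance numbers from it are
properties of the statistical model under its own assumptions; on real
data the error categories absorb mismapping only to the extent it looks
like uniform error, which is why the site filters (population-coverage
window, post-call mean-error filter) exist.

## Evaluation conventions

`score_calls()` computes both published accuracy definitions: the
correct-call rate *among individuals* (missing calls count as incorrect
— zero-coverage individuals included) and *among called genotypes*
(restricted to individuals with a call; sites with no calls at all drop
out of this average). Rates are computed per replicate site and
summarised as mean ± 2 SEM across sites, matching the "mean ± 2 SEM over
10,000 replicate sites" convention of the reference tables.
`polymorphism_power()` reports false-positive/-negative detection rates,
and `fn_rate_floor(q, N)` $= q^{2N} + (1-q)^{2N}$ is the finite-sample
lower bound on the false-negative rate — the probability the sample
contains only one allele, which no caller can beat at any coverage.

## Problem sizes and numerical choices

The packaged evaluation (`scripts/acceptance.R`) reruns each simulation
regime at its published scale, 10,000 replicate sites × 100 individuals,
in a few minutes thanks to the C++ EM; the test suite uses 1,500 sites
per regime with tolerances widened by $\sqrt{10000/1500}$, fixed before
any measurement. Other numerics worth stating: log-posterior/likelihood
tie tolerance $10^{-9}$ (no-call); EM tolerance $10^{-12}$, 5,000
iterations, 3 deterministic restarts; the homozygote error-rate formula
is clamped at $3/4$ (the uniform-read limit) when fewer than a quarter
of reads match; degenerate inputs — zero-coverage quartets, sites with a
single observed nucleotide, empty files — are exercised in the tests.

## Known limitations

* The BGC is biallelic by construction. At truly triallelic sites it
  cannot call genotypes carrying the third allele; on the standard
  triallelic benchmark (p, q, r = 0.7/0.2/0.1) its accuracy plateaus
  near 0.81 at any coverage, which is reproduced (not fixed) here — the
  intended workflow is HGC first to find >2-allele sites, then BGC at
  the biallelic ones.
* The fully heterozygous tetraploid genotype ACGT has no free error
  parameter (every read probability is exactly 1/4), so under
  per-genotype profile likelihood it is dominated by dosage-flexible
  candidates that fit multinomial sampling noise, and is essentially
  never called even from its own data. This is a property of the ML
  rule itself at the extreme of heterozygosity.
* The ML $\hat\epsilon$ of a population sample simulated with
  $\epsilon = 0$ is slightly positive in finite samples (trading
  unbalanced heterozygotes against homozygotes); it converges to zero
  with sample size.
* Ploidies above 4, allele-dosage uncertainty beyond the ML call, and
  population priors for polyploids (combinatorially expensive) are out
  of scope, as are read mapping and BAM/mpileup processing — input is
  the tab-separated pro dialect documented in `read_pro()`.
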