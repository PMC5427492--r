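# Population read-quartet container, pro-dialect file I/O and site filters.
#
# Dialect: a header line "#seq<TAB>pos<TAB>ref<TAB>q_1<TAB>...<TAB>q_N",
# then one tab-separated data line per site with the sequence name, the
# 1-based position, the reference nucleotide (or N) and one quartet
# "nA,nC,nG,nT" per individual in fixed A,C,G,T order.

#' Population read-quartet set
#'
#' Container for per-site, per-individual nucleotide read quartets: a
#' `n_sites x n_ind x 4` integer array of counts (third dimension A, C, G,
#' T) plus site coordinates.  Individual order is fixed across sites.
#'
#' @param counts Integer array `n_sites x n_ind x 4`, or for a single site
#'   an `n_ind x 4` matrix.
#' @param seq_id Character vector of sequence names (recycled).
#' @param pos 1-based integer positions.
#' @param ref Reference nucleotides (`"N"` when unknown).
#' @return An object of class `quartet_sites`.
#' @export
quartet_sites <- function(counts, seq_id = "sim", pos = NULL, ref = "N") {
  if (length(dim(counts)) == 2L) {
    counts <- array(counts, dim = c(1L, dim(counts)))
  }
  if (length(dim(counts)) != 3L || dim(counts)[3] != 4L) {
    stop("'counts' must be an n_sites x n_ind x 4 array")
  }
  if (any(counts < 0)) stop("read counts must be non-negative")
  n_sites <- dim(counts)[1]
  if (is.null(pos)) pos <- seq_len(n_sites)
  structure(
    list(
      counts = counts,
      seq_id = rep_len(as.character(seq_id), n_sites),
      pos = as.integer(rep_len(pos, n_sites)),
      ref = rep_len(as.character(ref), n_sites)
    ),
    class = "quartet_sites"
  )
}

#' @export
print.quartet_sites <- function(x, ...) {
  cat(sprintf(
    "<quartet_sites> %d site(s) x %d individual(s), total coverage %.0f\n",
    n_sites(x), n_ind(x), sum(x$counts)
  ))
  invisible(x)
}

#' @rdname quartet_sites
#' @param x A `quartet_sites` object.
#' @export
n_sites <- function(x) dim(x$counts)[1]

#' @rdname quartet_sites
#' @export
n_ind <- function(x) dim(x$counts)[2]

#' Read quartets of one site
#'
#' @param x A `quartet_sites` object.
#' @param i Site index.
#' @return `n_ind x 4` integer matrix with columns A, C, G, T.
#' @export
site_counts <- function(x, i) {
  m <- x$counts[i, , , drop = FALSE]
  dim(m) <- dim(x$counts)[2:3]
  colnames(m) <- NUCS
  m
}

#' Subset sites
#' @param x A `quartet_sites` object.
#' @param i Site indices (integer or logical).
#' @param ... Unused.
#' @export
`[.quartet_sites` <- function(x, i, ...) {
  quartet_sites(x$counts[i, , , drop = FALSE],
                seq_id = x$seq_id[i], pos = x$pos[i], ref = x$ref[i])
}

#' Write a population pro file
#'
#' @param x A `quartet_sites` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_pro()]
#' @export
write_pro <- function(x, path) {
  stopifnot(inherits(x, "quartet_sites"))
  N <- n_ind(x)
  header <- paste(c("#seq", "pos", "ref", paste0("q_", seq_len(N))),
                  collapse = "\t")
  # one "nA,nC,nG,nT" token per individual
  flat <- matrix(
    apply(x$counts, c(1, 2), function(v) paste(v, collapse = ",")),
    nrow = n_sites(x)
  )
  lines <- paste(x$seq_id, x$pos, x$ref,
                 apply(flat, 1L, paste, collapse = "\t"), sep = "\t")
  if (n_sites(x) == 0L) lines <- character(0)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a population pro file
#'
#' Parses the tab-separated pro dialect written by [write_pro()]: a header
#' line starting with `#`, then per site the sequence name, 1-based
#' position, reference nucleotide and `n_ind` comma-separated read
#' quartets in A,C,G,T order.  Malformed lines are reported with their
#' line number.
#'
#' @param path File path.
#' @param n_ind Declared number of individuals; every data line must carry
#'   exactly this many quartets.
#' @return A [quartet_sites()] object (zero sites for an empty file).
#' @export
read_pro <- function(path, n_ind) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L) {
    return(quartet_sites(array(0L, dim = c(0L, n_ind, 4L)),
                         seq_id = character(0), pos = integer(0),
                         ref = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 3L + n_ind)
  if (length(bad) > 0L) {
    stop(sprintf("line %d: expected %d tab-separated fields (seq, pos, ref, %d quartets), found %d",
                 lineno[bad[1]], 3L + n_ind, n_ind, nf[bad[1]]))
  }
  fm <- matrix(unlist(fields), ncol = 3L + n_ind, byrow = TRUE)
  counts <- array(0L, dim = c(length(lines), n_ind, 4L))
  for (j in seq_len(n_ind)) {
    qparts <- strsplit(fm[, 3L + j], ",", fixed = TRUE)
    nq <- lengths(qparts)
    if (any(nq != 4L)) {
      b <- which(nq != 4L)[1]
      stop(sprintf("line %d: quartet %d has %d comma-separated counts, expected 4",
                   lineno[b], j, nq[b]))
    }
    vals <- suppressWarnings(as.integer(unlist(qparts)))
    if (anyNA(vals) || any(vals < 0)) {
      b <- which(is.na(vals) | vals < 0)[1]
      stop(sprintf("line %d: quartet %d contains a negative or non-integer count",
                   lineno[ceiling(b / 4)], j))
    }
    counts[, j, ] <- matrix(vals, ncol = 4L, byrow = TRUE)
  }
  quartet_sites(counts, seq_id = fm[, 1], pos = as.integer(fm[, 2]),
                ref = fm[, 3])
}

#' Site filter configuration
#'
#' Defaults follow the filtering used for high-coverage population data:
#' an individual needs coverage of at least 6 to be callable by the
#' high-coverage caller, a site's population coverage (summed over
#' individuals) must lie within `[0.5, 1.5]` times the mean population
#' coverage (both bounds inclusive), and sites whose mean per-individual
#' error-rate estimate exceeds 0.01 are flagged by the post-filter
#' [filter_by_mean_error()].
#'
#' @param min_ind_cov Minimum individual coverage to be callable.
#' @param pop_cov_lo_frac,pop_cov_hi_frac Population-coverage bounds as
#'   fractions of the mean.
#' @param max_mean_error Maximum mean error-rate estimate for the
#'   post-caller filter.
#' @return A `site_filter_config` list.
#' @export
site_filter_config <- function(min_ind_cov = 6L, pop_cov_lo_frac = 0.5,
                               pop_cov_hi_frac = 1.5, max_mean_error = 0.01) {
  stopifnot(min_ind_cov >= 1, pop_cov_lo_frac >= 0,
            pop_cov_lo_frac < pop_cov_hi_frac)
  structure(list(min_ind_cov = as.integer(min_ind_cov),
                 pop_cov_lo_frac = pop_cov_lo_frac,
                 pop_cov_hi_frac = pop_cov_hi_frac,
                 max_mean_error = max_mean_error),
            class = "site_filter_config")
}

#' Apply population-coverage site filters
#'
#' Keeps a site iff its population coverage lies within
#' `[lo_frac * mean, hi_frac * mean]` (inclusive).  Individual quartets
#' with coverage below `cfg$min_ind_cov` are flagged uncallable but
#' retained.  Filtering is idempotent when `mean_pop_cov` is supplied.
#'
#' @param x A [quartet_sites()] object.
#' @param cfg A [site_filter_config()].
#' @param mean_pop_cov Mean population coverage; computed from `x` in a
#'   first pass when `NULL`.
#' @return List with `sites` (kept sites), `mask` (per-site data frame:
#'   `pop_cov`, `kept`, `reason`) and `uncallable` (logical
#'   `n_sites x n_ind` matrix for the kept sites).
#' @export
apply_site_filters <- function(x, cfg = site_filter_config(),
                               mean_pop_cov = NULL) {
  stopifnot(inherits(x, "quartet_sites"))
  pop_cov <- apply(x$counts, 1L, sum)
  if (is.null(mean_pop_cov)) mean_pop_cov <- mean(pop_cov)
  if (n_sites(x) > 0L && !(mean_pop_cov > 0)) {
    stop("mean population coverage must be positive")
  }
  lo <- cfg$pop_cov_lo_frac * mean_pop_cov
  hi <- cfg$pop_cov_hi_frac * mean_pop_cov
  kept <- pop_cov >= lo & pop_cov <= hi
  reason <- rep("", n_sites(x))
  reason[pop_cov < lo] <- "pop_cov_low"
  reason[pop_cov > hi] <- "pop_cov_high"
  ind_cov <- apply(x$counts, c(1, 2), sum)
  dim(ind_cov) <- dim(x$counts)[1:2]
  list(
    sites = x[kept],
    mask = data.frame(seq_id = x$seq_id, pos = x$pos, pop_cov = pop_cov,
                      kept = kept, reason = reason,
                      stringsAsFactors = FALSE),
    uncallable = (ind_cov < cfg$min_ind_cov)[kept, , drop = FALSE]
  )
}

#' Post-caller mean-error-rate site filter
#'
#' Flags sites whose mean per-individual error-rate estimate (for the
#' called genotypes, e.g. from [hgc_call_sites()]) exceeds
#' `max_mean_error`; intended to drop sites enriched for mismapped reads.
#'
#' @param eps_hat `n_sites x n_ind` matrix of per-individual error-rate
#'   estimates (`NA` for uncalled individuals), or a list of per-site
#'   vectors.
#' @param max_mean_error Threshold on the per-site mean (default 0.01).
#' @return Logical vector, `TRUE` for sites that pass.
#' @export
filter_by_mean_error <- function(eps_hat, max_mean_error = 0.01) {
  if (is.list(eps_hat)) {
    mean_eps <- vapply(eps_hat, function(v) mean(v, na.rm = TRUE), 0)
  } else {
    mean_eps <- rowMeans(eps_hat, na.rm = TRUE)
  }
  is.na(mean_eps) | mean_eps <= max_mean_error
}

#' Write a genotype-call table
#'
#' Tab-separated output with site columns (`seq`, `pos`, `ref`, and any
#' extra per-site columns supplied in `site_info`) followed by one
#' genotype string per individual (`"A/C"`, `"A/C/C"`, ...; `"./."`,
#' `"././."` etc. for no-calls).
#'
#' @param calls Character matrix `n_sites x n_ind` of genotype strings
#'   (e.g. `"AC"`) with `NA` for no-calls.
#' @param path Output path.
#' @param seq_id,pos,ref Site coordinates (recycled).
#' @param site_info Optional data frame of extra per-site columns
#'   (e.g. M, m, LRT, p-value, n_alleles).
#' @param ploidy Ploidy used to format no-calls.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, seq_id = "sim",
                        pos = seq_len(nrow(calls)), ref = "N",
                        site_info = NULL, ploidy = 2L) {
  fmt <- function(g) {
    ifelse(is.na(g),
           paste(rep(".", ploidy), collapse = "/"),
           vapply(strsplit(g, "", fixed = TRUE),
                  paste, "", collapse = "/"))
  }
  gm <- apply(calls, c(1, 2), fmt)
  df <- data.frame(seq = rep_len(seq_id, nrow(calls)),
                   pos = rep_len(pos, nrow(calls)),
                   ref = rep_len(ref, nrow(calls)),
                   stringsAsFactors = FALSE)
  if (!is.null(site_info)) df <- cbind(df, site_info)
  df <- cbind(df, as.data.frame(gm, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
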