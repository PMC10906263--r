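# Coverage-based richness: the genus-rule taxon filter, Good-Turing sample
# coverage, rarefaction/extrapolation of coverage and richness, and the
# quorum (SQS) richness estimate, plus bin summaries and crown proportions.

#' Filter taxa within a bioregion and count occurrences
#'
#' Applies the indeterminate-occurrence rule used when tallying taxa in a
#' bioregion: species-rank occurrences are always retained; an occurrence
#' identified only to genus (or higher) level counts as its own taxon *only*
#' when no retained subordinate taxon of it occurs in the same bioregion.
#' E.g. a "Thomasia" genus-level occurrence alongside *Thomasia hahni* is
#' discarded (it may or may not be another species), but with no named
#' *Thomasia* species in the region, "Thomasia" is kept as a taxon.
#'
#' @param occurrences Occurrence data frame of one (bioregion, group):
#'   columns `taxon_name`, `taxon_rank`, `lineage`.
#' @return Named integer vector: retained taxon -> occurrence count.
#'   Discarded occurrences increment no count.
#' @export
filter_taxa <- function(occurrences) {
  if (nrow(occurrences) == 0L)
    return(stats::setNames(integer(0), character(0)))
  occ <- occurrences
  # lineage strictly above the occurrence's own taxon, most specific first
  above <- function(i) {
    lin <- strsplit(occ$lineage[i], ";", fixed = TRUE)[[1]]
    lin <- lin[lin != "" & lin != occ$taxon_name[i]]
    if (occ$taxon_rank[i] == "species")
      lin <- c(strsplit(occ$taxon_name[i], "\\s+")[[1]][1], lin)
    lin
  }

  counts <- integer(0)
  covered <- character(0)  # clades subordinate to some retained taxon

  sp <- which(occ$taxon_rank == "species")
  for (i in sp) covered <- union(covered, above(i))
  if (length(sp)) counts <- c(counts, table(occ$taxon_name[sp]))

  gen <- which(occ$taxon_rank == "genus")
  keep_gen <- gen[!(occ$taxon_name[gen] %in% covered)]
  for (i in keep_gen) covered <- union(covered, above(i))
  if (length(keep_gen)) counts <- c(counts, table(occ$taxon_name[keep_gen]))

  hi <- which(occ$taxon_rank == "above_genus")
  if (length(hi)) {
    # most specific (longest lineage) first so nested indeterminates are
    # themselves treated as subordinates of broader ones
    depth <- vapply(hi, function(i) length(above(i)), integer(1))
    kept_hi <- integer(0)
    for (i in hi[order(-depth)]) {
      if (occ$taxon_name[i] %in% covered) next
      kept_hi <- c(kept_hi, i)
      covered <- union(covered, above(i))
    }
    if (length(kept_hi)) counts <- c(counts, table(occ$taxon_name[kept_hi]))
  }
  out <- vapply(split(as.integer(counts), names(counts)), sum, integer(1))
  out[order(names(out))]
}

#' Good-Turing sample coverage of an abundance vector
#'
#' Estimated probability that one more sampled occurrence belongs to an
#' already-observed taxon, using the improved Good-Turing estimator
#' \deqn{\hat C = 1 - \frac{f_1}{n}\,
#'   \frac{(n-1) f_1}{(n-1) f_1 + 2 f_2}}
#' with `n` occurrences and `f1`, `f2` the numbers of taxa observed once and
#' twice. Equals 1 when there are no singletons.
#'
#' @param counts Positive integer abundance vector (taxon occurrence counts).
#' @return Coverage in \[0, 1\].
#' @export
sample_coverage <- function(counts) {
  counts <- check_counts(counts)
  n <- sum(counts)
  f1 <- sum(counts == 1L); f2 <- sum(counts == 2L)
  if (f1 == 0L) return(1)
  denom <- (n - 1) * f1 + 2 * f2
  if (denom == 0) return(1 - f1 / n)  # n = f1 = 1 edge case
  1 - (f1 / n) * ((n - 1) * f1 / denom)
}

check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (!length(counts)) stop("empty abundance vector")
  if (any(!is.finite(counts)) || any(counts < 1) ||
      any(counts != floor(counts)))
    stop("abundance counts must be positive integers")
  counts
}

#' Expected coverage of a sample of given size
#'
#' Rarefied (`m < n`) and extrapolated (`m > n`) sample coverage. For
#' `m < n` the unbiased rarefaction estimator
#' \eqn{\hat C(m) = 1 - \sum_i (x_i/n)\binom{n-x_i}{m}/\binom{n-1}{m}} is
#' used; at `m = n` it is [sample_coverage()]; beyond `n`,
#' \eqn{\hat C(n+m^*) = 1 - (f_1/n) [ (n-1)f_1 / ((n-1)f_1 + 2 f_2) ]^{m^*+1}}.
#'
#' @param counts Positive integer abundance vector.
#' @param m Sample sizes (positive integers, vectorised).
#' @return Coverage values in \[0, 1\], non-decreasing in `m`.
#' @export
coverage_at_size <- function(counts, m) {
  counts <- check_counts(counts)
  n <- sum(counts)
  f1 <- sum(counts == 1L); f2 <- sum(counts == 2L)
  A <- if (f1 == 0L) 0 else if ((n - 1) * f1 + 2 * f2 == 0) 1 else
    (n - 1) * f1 / ((n - 1) * f1 + 2 * f2)
  vapply(m, function(mi) {
    if (mi < 1 || mi != floor(mi)) stop("m must be a positive integer")
    if (mi < n) {
      1 - sum((counts / n) *
                exp(lchoose(n - counts, mi) - lchoose(n - 1, mi)))
    } else if (mi == n) {
      sample_coverage(counts)
    } else {
      1 - (f1 / n) * A^(mi - n + 1)
    }
  }, numeric(1))
}

#' Expected richness of a sample of given size
#'
#' Hill-order-0 rarefaction and extrapolation. For `m <= n` this is the exact
#' hypergeometric expectation of the number of distinct taxa in a size-`m`
#' subsample, \eqn{S(m) = S_{obs} - \sum_i \binom{n-x_i}{m}/\binom{n}{m}}.
#' For `m > n` the Chao1-type extrapolation
#' \eqn{S(n+m^*) = S_{obs} + \hat f_0 [1 - (1 - f_1/(n \hat f_0 + f_1))^{m^*}]}
#' with \eqn{\hat f_0 = \frac{n-1}{n} f_1^2/(2 f_2)} (or
#' \eqn{\frac{n-1}{n} f_1 (f_1 - 1)/2} when `f2 = 0`).
#'
#' @inheritParams coverage_at_size
#' @return Expected distinct-taxon counts, non-decreasing in `m`.
#' @export
richness_at_size <- function(counts, m) {
  counts <- check_counts(counts)
  n <- sum(counts)
  s_obs <- length(counts)
  f1 <- sum(counts == 1L); f2 <- sum(counts == 2L)
  f0 <- if (f1 == 0L) 0 else if (f2 > 0L) (n - 1) / n * f1^2 / (2 * f2) else
    (n - 1) / n * f1 * (f1 - 1) / 2
  vapply(m, function(mi) {
    if (mi < 1 || mi != floor(mi)) stop("m must be a positive integer")
    if (mi <= n) {
      s_obs - sum(exp(lchoose(n - counts, mi) - lchoose(n, mi)))
    } else if (f0 == 0) {
      s_obs
    } else {
      s_obs + f0 * (1 - (1 - f1 / (n * f0 + f1))^(mi - n))
    }
  }, numeric(1))
}

#' Richness at a fixed coverage quorum (shareholder quorum subsampling)
#'
#' Finds the (real-valued) sample size `m` at which estimated coverage equals
#' the quorum — rarefying below the observed sample size and extrapolating
#' above it, up to `max_extrapolation_factor * n` — and returns the Hill
#' order-0 richness at that size. Coverage and richness are evaluated at
#' integer sizes ([coverage_at_size()], [richness_at_size()]) and linearly
#' interpolated between the bracketing sizes. The estimate is
#' `"insufficient"` when the quorum is unreachable within the extrapolation
#' bound (including the all-singletons case, whose estimated coverage is 0).
#'
#' @param counts Positive integer abundance vector.
#' @param quorum Target coverage in (0, 1); default 0.9, below which coverage
#'   quorums give imprecise richness comparisons.
#' @param max_extrapolation_factor Largest multiple of `n` to extrapolate to
#'   (default 2).
#' @return List of class `"richness_estimate"`: `value` (estimated richness,
#'   `NA` if insufficient), `achieved_coverage`, `m` (sample size used), `n`,
#'   `mode` (`"interpolated"`, `"observed"`, `"extrapolated"`) and `status`
#'   (`"ok"`/`"insufficient"`).
#' @export
richness_at_coverage <- function(counts, quorum = 0.9,
                                 max_extrapolation_factor = 2) {
  counts <- check_counts(counts)
  if (!is.finite(quorum) || quorum <= 0 || quorum >= 1)
    stop("quorum must be in (0, 1)")
  n <- sum(counts)
  m_max <- max(1, floor(max_extrapolation_factor * n))
  mm <- seq_len(m_max)
  cv <- coverage_at_size(counts, mm)
  est <- function(value, cov, m, mode, status = "ok")
    structure(list(value = value, achieved_coverage = cov, m = m, n = n,
                   mode = mode, status = status),
              class = "richness_estimate")
  if (cv[m_max] < quorum)
    return(est(NA_real_, cv[m_max], NA_real_, "insufficient", "insufficient"))
  if (cv[1] >= quorum) {
    # quorum met before a single draw resolves; richness at m = 1 is 1
    mode <- if (n == 1L) "observed" else "interpolated"
    return(est(richness_at_size(counts, 1L), cv[1], 1, mode))
  }
  m1 <- which(cv >= quorum)[1]
  m0 <- m1 - 1L
  frac <- (quorum - cv[m0]) / (cv[m1] - cv[m0])
  m_star <- m0 + frac
  s <- richness_at_size(counts, c(m0, m1))
  value <- s[1] + frac * (s[2] - s[1])
  mode <- if (abs(m_star - n) < 1e-9) "observed"
          else if (m_star < n) "interpolated" else "extrapolated"
  est(value, quorum, m_star, mode)
}

#' @export
print.richness_estimate <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("richness %.3f at coverage %.3f (m = %.2f of n = %d, %s)\n",
                x$value, x$achieved_coverage, x$m, x$n, x$mode))
  else
    cat(sprintf("insufficient: quorum unreachable (n = %d, max coverage %.3f)\n",
                x$n, x$achieved_coverage))
  invisible(x)
}

#' Per-bin mean richness by group
#'
#' Averages quorum-subsampled richness over the bioregions of each time bin,
#' per group, keeping only estimates with status `"ok"`. A group with no ok
#' estimate in a bin is absent from that bin's summary.
#'
#' @param estimates Data frame with columns `bin`, `bioregion`, `group`,
#'   `richness`, `status` (the per-bioregion points, Fig-1-style).
#' @return Data frame `bin`, `group`, `n_bioregions`, `mean_richness`.
#' @export
bin_summaries <- function(estimates) {
  ok <- estimates[estimates$status == "ok", , drop = FALSE]
  if (!nrow(ok))
    return(data.frame(bin = character(), group = character(),
                      n_bioregions = integer(), mean_richness = numeric()))
  agg <- stats::aggregate(richness ~ bin + group, data = ok, FUN = mean)
  cnt <- stats::aggregate(richness ~ bin + group, data = ok, FUN = length)
  out <- data.frame(bin = agg$bin, group = agg$group,
                    n_bioregions = cnt$richness, mean_richness = agg$richness,
                    stringsAsFactors = FALSE)
  out[order(out$bin, out$group), , drop = FALSE]
}

#' Crown proportion within a shared bioregion
#'
#' For a bioregion containing at least one crown and one stem occurrence,
#' the fraction of retained taxa (after [filter_taxa()], applied per group)
#' that are crown mammals — raw taxon counts, no subsampling. `NA` for
#' bioregions lacking either group.
#'
#' @param occurrences Occurrences of one bioregion with a `group` column
#'   (`"crown"`/`"stem"`).
#' @return Proportion in \[0, 1\], or `NA_real_` when not applicable.
#' @export
crown_proportion <- function(occurrences) {
  cr <- occurrences[occurrences$group == "crown", , drop = FALSE]
  st <- occurrences[occurrences$group == "stem", , drop = FALSE]
  if (!nrow(cr) || !nrow(st)) return(NA_real_)
  n_cr <- length(filter_taxa(cr))
  n_st <- length(filter_taxa(st))
  if (n_cr + n_st == 0L) return(NA_real_)
  n_cr / (n_cr + n_st)
}
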