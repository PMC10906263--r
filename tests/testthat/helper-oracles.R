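# Independent oracles used by the unit and acceptance tests. These
# deliberately avoid the package's own code paths: exhaustive enumeration,
# brute force over labelled spanning trees, naive UPGMA, and sequential
# hypergeometric Monte-Carlo subsampling.

# exact subsampling expectations by enumeration of all size-m subsets of the
# occurrence slots: expected distinct taxa and expected singleton count
enum_subsample_stats <- function(counts, m) {
  slots <- rep(seq_along(counts), counts)
  n <- length(slots)
  stopifnot(m >= 1, m <= n)
  combs <- utils::combn(n, m)
  distinct <- singles <- numeric(ncol(combs))
  for (j in seq_len(ncol(combs))) {
    tab <- tabulate(slots[combs[, j]], nbins = length(counts))
    distinct[j] <- sum(tab > 0)
    singles[j] <- sum(tab == 1)
  }
  list(e_distinct = mean(distinct), e_singletons = mean(singles))
}

# all integer partitions of n (as abundance vectors), largest part first
integer_partitions <- function(n, max_part = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (k in seq_len(min(n, max_part))) {
    for (rest in integer_partitions(n - k, k))
      out[[length(out) + 1L]] <- c(k, rest)
  }
  out
}

# Monte-Carlo expected distinct taxa in a size-m subsample drawn without
# replacement, via sequential multivariate-hypergeometric draws
mc_expected_distinct <- function(counts, m, draws = 1e5) {
  n_rem <- sum(counts)
  m_rem <- rep(m, draws)
  distinct <- numeric(draws)
  for (x in counts) {
    k <- stats::rhyper(draws, x, n_rem - x, m_rem)
    distinct <- distinct + (k > 0)
    m_rem <- m_rem - k
    n_rem <- n_rem - x
  }
  mean(distinct)
}

# naive average-linkage agglomeration: cluster distance is the mean of all
# cross-pair dissimilarities in the *original* matrix; returns merge heights
upgma_merge_heights <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1L)) for (j in (i + 1L):length(clusters)) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best - 1e-12) { best <- d; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# all labelled spanning trees on n vertices via Pruefer sequences, as an
# (n^(n-2)) x (n-1) matrix of linear edge indices into an n x n weight matrix
pruefer_edge_index <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    stopifnot(n >= 2, n <= 7)
    if (n == 2) {
      m <- matrix((2L - 1L) * n + 1L, 1, 1)  # edge (1,2): W[1,2]
      cache[[key]] <<- m
      return(m)
    }
    seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
    idx <- matrix(0L, nrow(seqs), n - 1L)
    for (r in seq_len(nrow(seqs))) {
      s <- seqs[r, ]
      deg <- tabulate(s, n) + 1L
      edges <- integer(0)
      for (si in s) {
        leaf <- which(deg == 1L)[1]
        edges <- c(edges, leaf + (si - 1L) * n)
        deg[leaf] <- 0L
        deg[si] <- deg[si] - 1L
      }
      last <- which(deg == 1L)
      edges <- c(edges, last[1] + (last[2] - 1L) * n)
      idx[r, ] <- edges
    }
    cache[[key]] <<- idx
    idx
  }
})

# brute-force MST length: minimum total weight over every labelled tree
brute_mst <- function(W) {
  n <- nrow(W)
  if (n < 2) return(0)
  idx <- pruefer_edge_index(n)
  min(rowSums(matrix(W[as.vector(idx)], nrow(idx))))
}

# random abundance vector: counts from a geometric rank-abundance pool
random_abundance <- function(n_target, s_pool = 10, theta = 0.6) {
  p <- theta^seq_len(s_pool)
  counts <- tabulate(sample.int(s_pool, n_target, replace = TRUE,
                                prob = p / sum(p)), s_pool)
  counts[counts > 0]
}

# random point cloud (degrees), away from the poles
random_points <- function(k, lat_range = c(-60, 60)) {
  data.frame(lat = runif(k, lat_range[1], lat_range[2]),
             lon = runif(k, -179, 180))
}

# small occurrence data frame builder for filter/proportion tests
occ_df <- function(names, ranks, lineages = "", groups = NULL,
                   collection_id = "c1") {
  d <- data.frame(occurrence_id = paste0("o", seq_along(names)),
                  collection_id = collection_id, taxon_name = names,
                  taxon_rank = ranks, lineage = lineages,
                  stringsAsFactors = FALSE)
  if (!is.null(groups)) d$group <- groups
  d
}

# minimal PBDB-dialect CSV written to a temp file
write_pbdb_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- paste("occurrence_no", "collection_no", "accepted_name",
                  "accepted_rank", "family", "order", "class", "paleolat",
                  "paleolng", "max_ma", "min_ma", "flags", sep = ",")
  writeLines(c(header, rows), path)
  path
}
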