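# Minimum-spanning-tree spatial sampling proxy and the normalised
# geographic-range fraction per group and time bin.

#' Minimum spanning tree length over localities
#'
#' Total edge length, in km, of a minimum spanning tree connecting the given
#' points under great-circle (haversine) distance — a proxy for the spatial
#' extent of sampling that is robust to the spatial arrangement of
#' localities. Computed with Prim's algorithm; ties are resolved toward the
#' lowest point index (points are taken in lexicographic order of their
#' labels when named), though the total length is invariant to tie order.
#'
#' @param lat,lon Coordinates in decimal degrees. Fewer than two points give
#'   length 0. Duplicate coordinates are kept and contribute zero-length
#'   edges.
#' @return Total MST length in kilometres.
#' @export
mst_length <- function(lat, lon) {
  if (length(lat) != length(lon)) stop("lat and lon lengths differ")
  p <- length(lat)
  if (p < 2L) return(0)
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("invalid coordinates")
  in_tree <- logical(p)
  in_tree[1L] <- TRUE
  # best known distance from each outside vertex to the tree
  best <- haversine_km(lat[1L], lon[1L], lat, lon)
  best[1L] <- Inf
  total <- 0
  for (k in seq_len(p - 1L)) {
    v <- which.min(replace(best, in_tree, Inf))
    total <- total + best[v]
    in_tree[v] <- TRUE
    cand <- haversine_km(lat[v], lon[v], lat, lon)
    best <- pmin(best, cand)
  }
  total
}

#' Normalised geographic-range fraction of a group in a time bin
#'
#' The MST length over the collections where a group occurs, divided by the
#' MST length over all collections with any occurrence in the bin — the
#' proportion of the bin's spatially sampled area in which the group is
#' found. Normalising by the total sampling MST makes range estimates
#' comparable between bins with very different spatial sampling.
#'
#' @param collections Collections of one bin (`collection_id`, `paleo_lat`,
#'   `paleo_lon`).
#' @param group_collections Character vector of collection ids holding at
#'   least one occurrence of the group (subset of
#'   `collections$collection_id`).
#' @return List: `n_collections` (of the group), `mst_km`, `total_mst_km`,
#'   `fraction` (in \[0,1\]; 0 when the group occurs at fewer than two
#'   collections; `NA` when the bin itself has fewer than two collections,
#'   where the normalisation is undefined).
#' @export
range_fraction <- function(collections, group_collections) {
  ids <- collections$collection_id
  unknown <- setdiff(group_collections, ids)
  if (length(unknown))
    stop("group collection(s) not in bin: ", paste(unknown, collapse = ", "))
  total <- mst_length(collections$paleo_lat, collections$paleo_lon)
  sub <- collections[ids %in% group_collections, , drop = FALSE]
  mst_g <- mst_length(sub$paleo_lat, sub$paleo_lon)
  frac <- if (nrow(collections) < 2L || total == 0) NA_real_ else mst_g / total
  list(n_collections = nrow(sub), mst_km = mst_g, total_mst_km = total,
       fraction = frac)
}
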