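# Bioregion delineation: paired hierarchical clustering of collections on
# geographic (great-circle) and taxonomic (modified Forbes) distances, each
# dendrogram cut at a fixed node height, bioregions = meet of the two cuts.

EARTH_RADIUS_KM <- 6371.0

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371 km. Paleocoordinates are
#' treated as spherical; no ellipsoid correction.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorised).
#' @return Distance(s) in kilometres.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(!is.finite(c(lat1, lon1, lat2, lon2))))
    stop("non-finite coordinate")
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("coordinate out of range")
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Modified Forbes taxonomic distance between two assemblages
#'
#' One minus Alroy's corrected Forbes similarity for binary (presence)
#' assemblage data: with `a` shared taxa, `b` and `c` unique to each side and
#' `n = a + b + c`,
#' \deqn{F' = \frac{a(n+\sqrt n)}{a(n+\sqrt n) + \frac{3}{2} b c}}
#' and the distance is \eqn{1 - F'}. The correction keeps the index from
#' inflating similarity when many taxa are unsampled.
#'
#' @param assemblage_a,assemblage_b Character vectors of taxon names
#'   (duplicates ignored). Both must be non-empty.
#' @return Distance in \[0, 1\]: 0 for identical sets, 1 for disjoint sets.
#' @export
forbes_distance <- function(assemblage_a, assemblage_b) {
  sa <- unique(assemblage_a); sb <- unique(assemblage_b)
  if (!length(sa) || !length(sb))
    stop("Forbes distance is undefined for an empty assemblage")
  a <- length(intersect(sa, sb))
  b <- length(sa) - a
  c <- length(sb) - a
  n <- a + b + c
  num <- a * (n + sqrt(n))
  1 - num / (num + 1.5 * b * c)
}

#' Pairwise distance matrix over collections
#'
#' @param collections Collection data frame (`collection_id`, `paleo_lat`,
#'   `paleo_lon`).
#' @param assemblages Named list: `collection_id` -> character vector of taxa
#'   present. Required for `kind = "taxonomic"`; collections with an empty or
#'   missing assemblage are dropped with a warning.
#' @param kind `"geographic_km"` (haversine, km) or `"taxonomic"` (modified
#'   Forbes, dimensionless in \[0,1\]).
#' @return Symmetric matrix with zero diagonal; dimnames are collection ids
#'   (sorted); attribute `kind` records the distance type.
#' @export
distance_matrix <- function(collections, assemblages = NULL,
                            kind = c("geographic_km", "taxonomic")) {
  kind <- match.arg(kind)
  ids <- sort(collections$collection_id)
  collections <- collections[match(ids, collections$collection_id), ,
                             drop = FALSE]
  if (kind == "taxonomic") {
    sizes <- vapply(ids, function(id) length(unique(assemblages[[id]])),
                    integer(1))
    if (any(sizes == 0L)) {
      warning("dropping collection(s) with empty assemblage: ",
              paste(ids[sizes == 0L], collapse = ", "))
      keep <- sizes > 0L
      ids <- ids[keep]
      collections <- collections[keep, , drop = FALSE]
    }
  }
  p <- length(ids)
  if (p < 2L) stop("need at least 2 collections for a distance matrix")
  m <- matrix(0, p, p, dimnames = list(ids, ids))
  if (kind == "geographic_km") {
    for (i in seq_len(p - 1L)) {
      j <- (i + 1L):p
      m[i, j] <- m[j, i] <- haversine_km(
        collections$paleo_lat[i], collections$paleo_lon[i],
        collections$paleo_lat[j], collections$paleo_lon[j])
    }
  } else {
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p)
      m[i, j] <- m[j, i] <- forbes_distance(assemblages[[ids[i]]],
                                            assemblages[[ids[j]]])
  }
  attr(m, "kind") <- kind
  m
}

#' Agglomerative clustering of a distance matrix
#'
#' Hierarchical clustering via [stats::hclust()]. Labels are sorted before
#' clustering so that, among tied merges, the pair first in lexicographic
#' label order is taken first — merge heights are then bit-reproducible.
#'
#' @param dm Symmetric distance matrix with labelled dimnames
#'   ([distance_matrix()]).
#' @param linkage `"average"` (UPGMA, default), `"complete"` or `"single"`.
#' @return An `hclust` object.
#' @export
cluster_collections <- function(dm, linkage = c("average", "complete",
                                                "single")) {
  linkage <- match.arg(linkage)
  if (is.null(dim(dm)) || nrow(dm) < 2L)
    stop("need at least 2 leaves to cluster")
  ord <- order(rownames(dm))
  dm <- dm[ord, ord, drop = FALSE]
  stats::hclust(stats::as.dist(dm), method = linkage)
}

#' Cut a dendrogram at a fixed node height
#'
#' Clusters are the maximal subtrees whose internal merge heights are all at
#' or below `height`.
#'
#' @param dend An `hclust` object.
#' @param height Cut height (same units as the clustered distances), >= 0.
#' @return Named integer vector: leaf label -> cluster id, ids dense from 1
#'   in order of first appearance of the sorted labels.
#' @export
cut_dendrogram <- function(dend, height) {
  if (!is.finite(height) || height < 0) stop("height must be >= 0")
  cl <- stats::cutree(dend, h = height)
  relabel_partition(cl)
}

relabel_partition <- function(cl) {
  cl <- cl[order(names(cl))]
  ids <- match(cl, unique(cl))
  names(ids) <- names(cl)
  ids
}

#' Delineate bioregions within one time bin
#'
#' Collections are clustered twice — on great-circle distance and on modified
#' Forbes taxonomic distance — and each dendrogram is cut at its height
#' threshold. Bioregions are the meet (common refinement) of the two cut
#' partitions: collections belong to the same bioregion iff they fall in the
#' same cluster in *both* analyses, making a bioregion a geographically
#' continuous area holding a distinct assemblage.
#'
#' @param collections Collections of one time bin.
#' @param assemblages Named list `collection_id` -> taxa present (all
#'   occurrences, any rank).
#' @param geo_height_km Geographic cut height in km (default 100).
#' @param tax_height Taxonomic cut height, Forbes distance (default 0.5).
#' @param linkage Linkage method passed to [cluster_collections()].
#' @return Named integer vector `collection_id` -> bioregion id (dense from
#'   1). A single collection forms a singleton bioregion without clustering.
#' @export
delineate_bioregions <- function(collections, assemblages,
                                 geo_height_km = 100, tax_height = 0.5,
                                 linkage = "average") {
  ids <- sort(collections$collection_id)
  if (length(ids) == 0L) return(stats::setNames(integer(0), character(0)))
  if (length(ids) == 1L) return(stats::setNames(1L, ids))
  geo <- cut_dendrogram(
    cluster_collections(distance_matrix(collections, kind = "geographic_km"),
                        linkage), geo_height_km)
  tax <- cut_dendrogram(
    cluster_collections(distance_matrix(collections, assemblages,
                                        kind = "taxonomic"), linkage),
    tax_height)
  common <- intersect(names(geo), names(tax))
  meet <- paste(geo[common], tax[common], sep = "/")
  relabel_partition(stats::setNames(match(meet, unique(meet)), common))
}
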