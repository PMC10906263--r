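# Synthetic occurrence worlds with known bioregions, abundance structure and
# group range restrictions, emitted in the same table dialect the reader
# ingests, plus the chance-adjusted partition agreement used to score
# bioregion recovery.

#' Specify a synthetic occurrence world
#'
#' Describes a world of `n_bins` time bins, each holding `K` bioregions:
#' clusters of collections scattered within `region_radius_km` of
#' well-separated centroids, sampling species from regional pools with a
#' configurable endemic fraction and abundance model. Two higher groups
#' (crown and stem) partition the species; an optional whitelist restricts
#' stem species to a subset of regions, planting a known geographic-range
#' contrast.
#'
#' @param n_bins Number of time bins.
#' @param K Bioregions per bin.
#' @param centroid_spacing_km Minimum great-circle distance between region
#'   centroids (km).
#' @param region_radius_km Scatter radius of collections around their
#'   centroid (km).
#' @param collections_per_region Collections per bioregion.
#' @param pool_size Species per regional pool.
#' @param endemicity Fraction of each pool unique to its region, in \[0,1\];
#'   the remainder is a bin-wide shared pool.
#' @param group_split Fraction of species assigned to the crown group.
#' @param stem_region_whitelist Optional integer vector of region indices
#'   (1..K) where stem species may occur; `NULL` means everywhere.
#' @param abundance_model `"geometric"` (rank abundance `p_k ∝ θ^k`) or
#'   `"log_series"` (`p_k ∝ θ^k / k`).
#' @param abundance_param Model parameter θ in (0,1); default 0.5.
#' @param occurrences_per_collection Mean occurrences per collection
#'   (Poisson, floored at 1).
#' @param genus_indeterminate_rate Probability an occurrence is recorded at
#'   genus rather than species rank.
#' @param seed Integer seed; the same spec yields an identical world.
#' @return Object of class `"world_spec"`.
#' @export
world_spec <- function(n_bins = 2, K = 4, centroid_spacing_km = 500,
                       region_radius_km = 25, collections_per_region = 10,
                       pool_size = 15, endemicity = 0.8, group_split = 0.5,
                       stem_region_whitelist = NULL,
                       abundance_model = c("geometric", "log_series"),
                       abundance_param = 0.5,
                       occurrences_per_collection = 10,
                       genus_indeterminate_rate = 0.1, seed = 1L) {
  abundance_model <- match.arg(abundance_model)
  stopifnot(n_bins >= 1, K >= 1, centroid_spacing_km > 0,
            region_radius_km > 0, collections_per_region >= 1,
            pool_size >= 1, endemicity >= 0, endemicity <= 1,
            group_split >= 0, group_split <= 1,
            abundance_param > 0, abundance_param < 1,
            occurrences_per_collection > 0,
            genus_indeterminate_rate >= 0, genus_indeterminate_rate <= 1)
  if (!is.null(stem_region_whitelist))
    stopifnot(all(stem_region_whitelist %in% seq_len(K)))
  structure(as.list(environment()), class = "world_spec")
}

# destination point on the sphere: start, bearing (rad), distance (km)
move_point <- function(lat, lon, bearing, dist_km) {
  to_rad <- pi / 180
  d <- dist_km / EARTH_RADIUS_KM
  la1 <- lat * to_rad
  la2 <- asin(sin(la1) * cos(d) + cos(la1) * sin(d) * cos(bearing))
  lo2 <- lon * to_rad +
    atan2(sin(bearing) * sin(d) * cos(la1), cos(d) - sin(la1) * sin(la2))
  lo2 <- ((lo2 / to_rad + 180) %% 360) - 180
  c(la2 / to_rad, ifelse(lo2 == -180, 180, lo2))
}

place_centroids <- function(K, spacing_km, max_attempts = 10000L) {
  lat <- numeric(0); lon <- numeric(0)
  attempts <- 0L
  while (length(lat) < K) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", K, " centroids at spacing ", spacing_km,
           " km after ", max_attempts, " attempts")
    la <- asin(stats::runif(1, sin(-70 * pi / 180), sin(70 * pi / 180))) *
      180 / pi
    lo <- stats::runif(1, -180, 180)
    if (!length(lat) ||
        all(haversine_km(la, lo, lat, lon) >= spacing_km)) {
      lat <- c(lat, la); lon <- c(lon, lo)
    }
  }
  data.frame(lat = lat, lon = lon)
}

rank_abundance <- function(model, theta, s) {
  p <- if (model == "geometric") theta^seq_len(s) else theta^seq_len(s) /
    seq_len(s)
  p / sum(p)
}

#' Generate a synthetic occurrence world
#'
#' Realises a [world_spec()] into occurrence and collection tables in the
#' dialect read by [read_occurrences()], together with the ground truth
#' needed to score every downstream stage: the planted bioregion partition
#' per bin, the species pools with group labels, and the true group range
#' fractions computed from the planted collection memberships.
#'
#' Crown species carry a lineage resolving to Mammalia, stem species one
#' resolving to a non-mammalian cynodont clade, so scenario-based group
#' assignment reproduces the planted groups.
#'
#' @param spec A `"world_spec"`.
#' @return List: `occurrences`, `collections` (data frames as from
#'   [read_occurrences()]), `bins` (bin table) and `truth` (list with
#'   `partitions` — per-bin named vectors collection_id -> region —,
#'   `species` — data frame `bin`, `region`, `taxon`, `genus`, `group` —,
#'   and `range_fractions` — data frame `bin`, `group`, `fraction`).
#' @export
generate_world <- function(spec) {
  stopifnot(inherits(spec, "world_spec"))
  set.seed(spec$seed)
  bins <- data.frame(
    name = paste0("bin", seq_len(spec$n_bins)),
    older_ma = 250 - 10 * (seq_len(spec$n_bins) - 1),
    younger_ma = 240 - 10 * (seq_len(spec$n_bins) - 1))

  occ_rows <- list(); coll_rows <- list()
  partitions <- list(); species_rows <- list(); range_rows <- list()
  oid <- 0L

  n_shared <- round((1 - spec$endemicity) * spec$pool_size)
  n_endemic <- spec$pool_size - n_shared

  for (b in seq_len(spec$n_bins)) {
    cent <- place_centroids(spec$K, spec$centroid_spacing_km)

    # bin-wide shared pool + per-region endemics; genera hold ~2 species
    mk_species <- function(prefix, k)
      if (k == 0L) character(0) else
        paste0(prefix, "g", (seq_len(k) + 1L) %/% 2L, " sp", seq_len(k))
    shared <- mk_species(paste0("Sha", b), n_shared)
    pools <- lapply(seq_len(spec$K), function(r)
      c(shared, mk_species(paste0("End", b, "r", r), n_endemic)))

    all_sp <- unique(unlist(pools))
    n_crown <- round(spec$group_split * length(all_sp))
    crown_sp <- sample(all_sp, n_crown)
    group_of <- stats::setNames(ifelse(all_sp %in% crown_sp, "crown", "stem"),
                                all_sp)
    lineage_of <- ifelse(group_of == "crown",
                         "Synthafam;Theriiformes;Mammalia",
                         "Synthbfam;Cynodontia;Osteichthyes")
    names(lineage_of) <- all_sp

    stem_ok <- if (is.null(spec$stem_region_whitelist)) seq_len(spec$K) else
      spec$stem_region_whitelist

    part <- character(0)
    for (r in seq_len(spec$K)) {
      pool <- pools[[r]]
      if (!(r %in% stem_ok)) pool <- pool[group_of[pool] == "crown"]
      if (!length(pool)) next
      probs <- rank_abundance(spec$abundance_model, spec$abundance_param,
                              length(pool))
      pool <- sample(pool)  # random abundance ranks within the pool
      for (ci in seq_len(spec$collections_per_region)) {
        cid <- sprintf("b%02dr%02dc%02d", b, r, ci)
        theta <- stats::runif(1, 0, 2 * pi)
        d <- spec$region_radius_km * sqrt(stats::runif(1))
        pt <- move_point(cent$lat[r], cent$lon[r], theta, d)
        mid <- stats::runif(1, bins$younger_ma[b] + 1, bins$older_ma[b] - 1)
        coll_rows[[cid]] <- data.frame(
          collection_id = cid, paleo_lat = round(pt[1], 4),
          paleo_lon = round(pt[2], 4),
          max_ma = round(mid + 0.5, 2), min_ma = round(mid - 0.5, 2),
          stringsAsFactors = FALSE)
        part[cid] <- r
        n_occ <- max(1L, stats::rpois(1, spec$occurrences_per_collection))
        sp_drawn <- sample(pool, n_occ, replace = TRUE, prob = probs)
        as_genus <- stats::runif(n_occ) < spec$genus_indeterminate_rate
        for (k in seq_len(n_occ)) {
          oid <- oid + 1L
          sp <- sp_drawn[k]
          occ_rows[[oid]] <- data.frame(
            occurrence_id = sprintf("o%06d", oid), collection_id = cid,
            taxon_name = if (as_genus[k]) strsplit(sp, " ")[[1]][1] else sp,
            taxon_rank = if (as_genus[k]) "genus" else "species",
            lineage = lineage_of[[sp]], stringsAsFactors = FALSE)
        }
      }
      species_rows[[paste(b, r)]] <- data.frame(
        bin = bins$name[b], region = r, taxon = pools[[r]],
        genus = vapply(strsplit(pools[[r]], " "), `[`, character(1), 1L),
        group = unname(group_of[pools[[r]]]), stringsAsFactors = FALSE)
    }
    part_num <- stats::setNames(as.integer(part), names(part))
    partitions[[bins$name[b]]] <- part_num[order(names(part_num))]

    # planted range fractions from region membership, not from sampling
    bc <- do.call(rbind, coll_rows[names(part)])
    crown_regions <- seq_len(spec$K)[vapply(seq_len(spec$K), function(r)
      any(group_of[pools[[r]]] == "crown"), logical(1))]
    for (g in c("crown", "stem")) {
      regs <- if (g == "crown") crown_regions else
        stem_ok[vapply(stem_ok, function(r)
          any(group_of[pools[[r]]] == "stem"), logical(1))]
      ids <- names(part)[as.integer(part) %in% regs]
      rf <- range_fraction(bc, ids)
      range_rows[[paste(b, g)]] <- data.frame(
        bin = bins$name[b], group = g, fraction = rf$fraction,
        stringsAsFactors = FALSE)
    }
  }

  occurrences <- do.call(rbind, occ_rows)
  collections <- do.call(rbind, coll_rows)
  collections <- collections[order(collections$collection_id), , drop = FALSE]
  rownames(occurrences) <- rownames(collections) <- NULL
  list(occurrences = occurrences, collections = collections, bins = bins,
       truth = list(partitions = partitions,
                    species = do.call(rbind, species_rows),
                    range_fractions = do.call(rbind, range_rows)))
}

#' Chance-adjusted partition agreement (adjusted Rand index)
#'
#' Agreement between an estimated and a true partition of the same items,
#' corrected for chance: 1 for identical partitions (up to relabelling),
#' about 0 for independent ones, possibly negative for worse-than-chance.
#'
#' @param estimated,truth Named vectors mapping item -> cluster label; the
#'   name sets must coincide.
#' @return Adjusted Rand index in \[-1, 1\].
#' @export
score_partition <- function(estimated, truth) {
  if (!setequal(names(estimated), names(truth)))
    stop("partitions are over different item sets")
  truth <- truth[names(estimated)]
  tab <- table(estimated, truth)
  n <- sum(tab)
  if (n < 2) return(1)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  max_index <- (a + b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
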