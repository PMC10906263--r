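# Reading and validating PBDB-style occurrence tables, crown/stem group
# assignment under alternative haramiyidan scenarios, and time-bin assignment.

#' Default column mapping for PBDB flat-file downloads
#'
#' Maps the internal field names used throughout the package to the column
#' names of a standard Paleobiology Database flat CSV download. Pass a
#' modified copy to [read_occurrences()] for tables with different headers.
#'
#' @return Named list. Fields `occurrence_id`, `collection_id`, `taxon_name`,
#'   `taxon_rank`, `paleo_lat`, `paleo_lon`, `max_ma`, `min_ma` map to single
#'   columns; `lineage` maps to a character vector of higher-taxonomy columns
#'   ordered most specific first; `flags` (optional, may be `NA`) names a
#'   column whose non-empty values mark trace-fossil records to drop.
#' @export
pbdb_column_map <- function() {
  list(
    occurrence_id = "occurrence_no",
    collection_id = "collection_no",
    taxon_name    = "accepted_name",
    taxon_rank    = "accepted_rank",
    paleo_lat     = "paleolat",
    paleo_lon     = "paleolng",
    max_ma        = "max_ma",
    min_ma        = "min_ma",
    lineage       = c("family", "order", "class"),
    flags         = "flags"
  )
}

#' Read a PBDB-style occurrence table
#'
#' Parses a flat occurrence CSV into an occurrence table and a collection
#' table, validating coordinates, ages and identifiers. Taxonomic ranks other
#' than `"species"` and `"genus"` are recorded as `"above_genus"`. Higher
#' taxonomy is kept as a single `lineage` string of clade names joined by
#' `";"`, ordered most specific first; it drives crown/stem assignment via
#' [assign_groups()].
#'
#' @param path Path to a UTF-8 comma-separated file.
#' @param column_map Named list as returned by [pbdb_column_map()]. The
#'   `flags` entry is optional: when it names a present column, rows whose
#'   flag value is non-empty (e.g. PBDB trace-fossil flags) are dropped.
#' @return List with elements `occurrences` (data frame: `occurrence_id`,
#'   `collection_id`, `taxon_name`, `taxon_rank`, `lineage`) and
#'   `collections` (data frame: `collection_id`, `paleo_lat`, `paleo_lon`,
#'   `max_ma`, `min_ma`), one row per distinct collection.
#' @export
read_occurrences <- function(path, column_map = pbdb_column_map()) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  required <- c("occurrence_id", "collection_id", "taxon_name", "taxon_rank",
                "paleo_lat", "paleo_lon", "max_ma", "min_ma")
  for (f in required) {
    col <- column_map[[f]]
    if (is.null(col) || length(col) != 1L)
      stop("column_map is missing a single-column mapping for '", f, "'")
    if (nrow(raw) >= 0L && !(col %in% names(raw)))
      stop("mapped column '", col, "' (", f, ") absent from ", path)
  }
  lineage_cols <- intersect(column_map$lineage, names(raw))

  # optional trace-fossil flag column: non-empty value => dropped row
  flag_col <- column_map$flags
  if (!is.null(flag_col) && !is.na(flag_col) && flag_col %in% names(raw)) {
    keep <- is.na(raw[[flag_col]]) | trimws(raw[[flag_col]]) == ""
    raw <- raw[keep, , drop = FALSE]
  }

  if (nrow(raw) == 0L) {
    occ <- data.frame(occurrence_id = character(), collection_id = character(),
                      taxon_name = character(), taxon_rank = character(),
                      lineage = character(), stringsAsFactors = FALSE)
    coll <- data.frame(collection_id = character(), paleo_lat = numeric(),
                       paleo_lon = numeric(), max_ma = numeric(),
                       min_ma = numeric(), stringsAsFactors = FALSE)
    return(list(occurrences = occ, collections = coll))
  }

  get <- function(f) raw[[column_map[[f]]]]
  num <- function(f) suppressWarnings(as.numeric(get(f)))

  occurrence_id <- trimws(get("occurrence_id"))
  collection_id <- trimws(get("collection_id"))
  taxon_name    <- trimws(get("taxon_name"))
  rank_raw      <- tolower(trimws(get("taxon_rank")))
  taxon_rank    <- ifelse(rank_raw == "species", "species",
                   ifelse(rank_raw == "genus", "genus", "above_genus"))
  paleo_lat <- num("paleo_lat"); paleo_lon <- num("paleo_lon")
  max_ma    <- num("max_ma");    min_ma    <- num("min_ma")

  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      stop("invalid ", what, " in row(s): ", paste(rows, collapse = ", "))
  }
  bad(occurrence_id == "", "occurrence_id (empty)")
  if (anyDuplicated(occurrence_id))
    stop("duplicate occurrence_id: ",
         paste(unique(occurrence_id[duplicated(occurrence_id)]), collapse = ", "))
  bad(collection_id == "", "collection_id (empty)")
  bad(taxon_name == "", "taxon_name (empty)")
  n_parts <- lengths(strsplit(taxon_name, "\\s+"))
  bad(taxon_rank == "species" & n_parts < 2L,
      "species-rank name (not a binomial)")
  bad(!is.finite(paleo_lat) | paleo_lat < -90 | paleo_lat > 90, "paleo_lat")
  bad(!is.finite(paleo_lon) | paleo_lon <= -180 | paleo_lon > 180, "paleo_lon")
  bad(!is.finite(max_ma) | !is.finite(min_ma) | min_ma <= 0 | max_ma < min_ma,
      "age range (need max_ma >= min_ma > 0)")

  lineage <- if (length(lineage_cols)) {
    parts <- lapply(lineage_cols, function(cn) trimws(raw[[cn]]))
    apply(do.call(cbind, parts), 1L, function(v)
      paste(v[!is.na(v) & v != ""], collapse = ";"))
  } else rep("", nrow(raw))

  occ <- data.frame(occurrence_id = occurrence_id,
                    collection_id = collection_id,
                    taxon_name = taxon_name, taxon_rank = taxon_rank,
                    lineage = lineage, stringsAsFactors = FALSE)

  first <- !duplicated(collection_id)
  coll <- data.frame(collection_id = collection_id[first],
                     paleo_lat = paleo_lat[first], paleo_lon = paleo_lon[first],
                     max_ma = max_ma[first], min_ma = min_ma[first],
                     stringsAsFactors = FALSE)
  # a collection must be internally consistent across its rows
  key_all <- paste(collection_id, paleo_lat, paleo_lon, max_ma, min_ma)
  key_first <- key_all[first][match(collection_id, coll$collection_id)]
  if (any(key_all != key_first))
    stop("collection(s) with conflicting coordinates or ages: ",
         paste(unique(collection_id[key_all != key_first]), collapse = ", "))
  coll <- coll[order(coll$collection_id), , drop = FALSE]
  rownames(coll) <- NULL
  list(occurrences = occ, collections = coll)
}

#' Write an occurrence table in the PBDB dialect
#'
#' Inverse of [read_occurrences()]: joins the occurrence and collection tables
#' and writes a flat CSV using the given column mapping, so that reading the
#' file back reproduces all mapped fields.
#'
#' @param occurrences,collections Data frames as returned by
#'   [read_occurrences()] (or [generate_world()]).
#' @param path Output file path.
#' @param column_map Named list as for [read_occurrences()].
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occurrences, collections, path,
                              column_map = pbdb_column_map()) {
  idx <- match(occurrences$collection_id, collections$collection_id)
  if (anyNA(idx)) stop("occurrence references an unknown collection")
  lineage_cols <- column_map$lineage
  lin <- strsplit(occurrences$lineage, ";", fixed = TRUE)
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    a = occurrences$occurrence_id, b = occurrences$collection_id,
    c = occurrences$taxon_name,    d = occurrences$taxon_rank)
  names(out) <- unlist(column_map[c("occurrence_id", "collection_id",
                                    "taxon_name", "taxon_rank")])
  for (i in seq_along(lineage_cols))
    out[[lineage_cols[i]]] <- vapply(lin, function(v)
      if (length(v) >= i) v[i] else "", character(1))
  out[[column_map$paleo_lat]] <- collections$paleo_lat[idx]
  out[[column_map$paleo_lon]] <- collections$paleo_lon[idx]
  out[[column_map$max_ma]]    <- collections$max_ma[idx]
  out[[column_map$min_ma]]    <- collections$min_ma[idx]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Default clade-to-group table
#'
#' The base mapping of higher taxa to crown or stem used by [scenario()].
#' The crown is seeded by the clade Mammalia (with Eutriconodonta kept in the
#' crown); the stem collects the non-mammalian synapsid and mammaliaform
#' clades, including the PBDB's legacy "Osteichthyes" bucket for stem
#' synapsids. Haramiyida-related clades are deliberately absent here: their
#' placement is what the three scenarios vary. Ships as
#' `inst/extdata/clade_groups.csv` so users can edit the mapping.
#'
#' @return Data frame with columns `clade` and `group` (`"crown"`/`"stem"`).
#' @export
default_clade_groups <- function() {
  path <- system.file("extdata", "clade_groups.csv", package = "paleoregions")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Haramiyidan placement scenarios
#'
#' Builds the clade-to-group assignment for one of the three analysis
#' scenarios reflecting competing phylogenetic hypotheses for Haramiyida:
#' \describe{
#'   \item{`haramiyida_crown`}{all Haramiyida (including Gondwanatheria) are
#'     crown mammals;}
#'   \item{`haramiyida_stem`}{all Haramiyida are stem mammals;}
#'   \item{`haramiyida_polyphyletic`}{Haramiyidae and Haramiyaviidae are stem
#'     mammals, the remaining Haramiyida (incl. Gondwanatheria) crown.}
#' }
#'
#' @param name One of `"haramiyida_crown"`, `"haramiyida_stem"`,
#'   `"haramiyida_polyphyletic"`.
#' @param clade_groups Base clade table (columns `clade`, `group`); defaults
#'   to [default_clade_groups()].
#' @return Object of class `"scenario"`: list with `name`, `crown_clades`,
#'   `stem_clades` (character vectors, disjoint).
#' @export
scenario <- function(name = c("haramiyida_crown", "haramiyida_stem",
                              "haramiyida_polyphyletic"),
                     clade_groups = default_clade_groups()) {
  name <- match.arg(name)
  crown <- clade_groups$clade[clade_groups$group == "crown"]
  stem  <- clade_groups$clade[clade_groups$group == "stem"]
  haram_families <- c("Haramiyidae", "Haramiyaviidae")
  haram_rest     <- c("Haramiyida", "Gondwanatheria", "Eleutherodontidae",
                      "Arboroharamiyidae")
  if (name == "haramiyida_crown") {
    crown <- c(crown, haram_families, haram_rest)
  } else if (name == "haramiyida_stem") {
    stem <- c(stem, haram_families, haram_rest)
  } else {
    stem  <- c(stem, haram_families)
    crown <- c(crown, haram_rest)
  }
  crown <- unique(crown); stem <- unique(stem)
  overlap <- intersect(crown, stem)
  if (length(overlap))
    stop("clade(s) assigned to both crown and stem: ",
         paste(overlap, collapse = ", "))
  structure(list(name = name, crown_clades = crown, stem_clades = stem),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("scenario:", x$name, "\n",
      " crown clades:", length(x$crown_clades), "\n",
      " stem clades: ", length(x$stem_clades), "\n")
  invisible(x)
}

#' Assign occurrences to crown or stem under a scenario
#'
#' Resolves each occurrence by the most specific matching entry of its
#' lineage: the taxon name itself is checked first, then the `";"`-separated
#' lineage string from most specific to least specific. Occurrences whose
#' lineage matches neither clade set are `"excluded"` and must not reach
#' downstream analyses.
#'
#' @param occurrences Occurrence data frame ([read_occurrences()]).
#' @param scen A `"scenario"` object from [scenario()].
#' @return Character vector (`"crown"`, `"stem"`, `"excluded"`), one element
#'   per occurrence row.
#' @export
assign_groups <- function(occurrences, scen) {
  stopifnot(inherits(scen, "scenario"))
  lineages <- strsplit(paste(occurrences$taxon_name, occurrences$lineage,
                             sep = ";"), ";", fixed = TRUE)
  vapply(lineages, function(lin) {
    lin <- lin[lin != ""]
    for (cl in lin) {
      in_crown <- cl %in% scen$crown_clades
      in_stem  <- cl %in% scen$stem_clades
      if (in_crown && in_stem)
        stop("clade '", cl, "' is in both crown and stem sets")
      if (in_crown) return("crown")
      if (in_stem)  return("stem")
    }
    "excluded"
  }, character(1))
}

#' Read a time-bin (stage) table
#'
#' @param path CSV with columns `name`, `older_ma`, `younger_ma`.
#' @return Data frame ordered old to young; bins validated to be
#'   non-overlapping with `older_ma > younger_ma`.
#' @export
read_bins <- function(path) {
  bins <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "older_ma", "younger_ma")
  if (!all(need %in% names(bins)))
    stop("bin table must have columns: ", paste(need, collapse = ", "))
  validate_bins(bins)
}

validate_bins <- function(bins) {
  if (any(!is.finite(bins$older_ma)) || any(!is.finite(bins$younger_ma)))
    stop("non-finite bin ages")
  if (any(bins$older_ma <= bins$younger_ma))
    stop("each bin needs older_ma > younger_ma")
  bins <- bins[order(-bins$older_ma), , drop = FALSE]
  if (nrow(bins) > 1L &&
      any(bins$older_ma[-1L] > bins$younger_ma[-nrow(bins)] + 1e-9))
    stop("bins overlap")
  rownames(bins) <- NULL
  bins
}

#' Bundled Mesozoic stage bins
#'
#' Stage-level time bins for the Triassic through Cretaceous with boundary
#' ages following the current International Commission on Stratigraphy
#' chronostratigraphic chart.
#'
#' @return Data frame with columns `name`, `older_ma`, `younger_ma`, old to
#'   young.
#' @export
mesozoic_stages <- function() {
  path <- system.file("extdata", "mesozoic_stages.csv",
                      package = "paleoregions")
  validate_bins(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Assign collections to time bins
#'
#' @param collections Collection data frame (`max_ma`, `min_ma` in Ma).
#' @param bins Bin table ([read_bins()] / [mesozoic_stages()]).
#' @param rule `"midpoint"` places a collection in the bin containing the
#'   midpoint of its age range (bin interval taken as `(younger_ma,
#'   older_ma]`); `"majority_overlap"` picks the bin with the largest
#'   age-range intersection, ties broken toward the older bin.
#' @return Character vector of bin names, `NA` where the collection's range
#'   falls outside all bins (a valid outcome, not an error).
#' @export
assign_bins <- function(collections, bins,
                        rule = c("midpoint", "majority_overlap")) {
  rule <- match.arg(rule)
  bins <- validate_bins(bins)
  n <- nrow(collections)
  out <- rep(NA_character_, n)
  if (rule == "midpoint") {
    mid <- (collections$max_ma + collections$min_ma) / 2
    for (j in seq_len(nrow(bins))) {
      hit <- is.na(out) & mid <= bins$older_ma[j] & mid > bins$younger_ma[j]
      out[hit] <- bins$name[j]
    }
  } else {
    for (i in seq_len(n)) {
      ov <- pmin(collections$max_ma[i], bins$older_ma) -
            pmax(collections$min_ma[i], bins$younger_ma)
      ov[ov < 0] <- 0
      if (any(ov > 0)) out[i] <- bins$name[which.max(ov)]  # bins old->young
    }
  }
  out
}
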