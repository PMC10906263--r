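# End-to-end orchestration: occurrences -> bins -> bioregions -> quorum
# richness, crown proportions and MST range fractions, with a run log that
# accounts for every input occurrence.

#' Pipeline run configuration
#'
#' Bundles inputs and tuning parameters for [run_pipeline()]. Defaults
#' reproduce the reference settings: coverage quorum 0.9 and a geographic
#' cluster node height of 100 km.
#'
#' @param occurrences Path to an occurrence CSV, or a list with elements
#'   `occurrences` and `collections` (as from [read_occurrences()] or
#'   [generate_world()]).
#' @param bins Path to a bin CSV ([read_bins()]) or a bin data frame.
#' @param scenario_name Haramiyidan scenario ([scenario()]), or `NULL` if the
#'   occurrence table already carries a `group` column.
#' @param quorum Coverage quorum for richness estimation (default 0.9).
#' @param geo_height_km Geographic dendrogram cut height, km (default 100).
#' @param tax_height Taxonomic (Forbes) cut height (default 0.5).
#' @param linkage Clustering linkage (default `"average"`).
#' @param binning_rule `"midpoint"` or `"majority_overlap"`
#'   ([assign_bins()]).
#' @param min_n Minimum occurrence count for a (bioregion, group) to be
#'   estimable (default 5).
#' @param max_extrapolation_factor Extrapolation bound as a multiple of the
#'   sample size (default 2).
#' @param stages Optional character vector restricting the analysis to the
#'   named bins.
#' @param column_map Column mapping for reading occurrence files.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(occurrences, bins,
                       scenario_name = c("haramiyida_crown",
                                         "haramiyida_stem",
                                         "haramiyida_polyphyletic"),
                       quorum = 0.9, geo_height_km = 100, tax_height = 0.5,
                       linkage = "average",
                       binning_rule = c("midpoint", "majority_overlap"),
                       min_n = 5, max_extrapolation_factor = 2,
                       stages = NULL, column_map = pbdb_column_map()) {
  scenario_name <- if (is.null(scenario_name)) NULL else
    match.arg(scenario_name)
  binning_rule <- match.arg(binning_rule)
  stopifnot(quorum > 0, quorum < 1, geo_height_km >= 0, tax_height >= 0,
            min_n >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full diversity and range analysis
#'
#' For each time bin: delineates bioregions ([delineate_bioregions()]),
#' builds per-(bioregion, group) abundance vectors under the genus rule
#' ([filter_taxa()]), estimates richness at the coverage quorum
#' ([richness_at_coverage()]), averages over bioregions, computes crown
#' proportions in bioregions holding both groups ([crown_proportion()]) and
#' MST-normalised range fractions ([range_fraction()]). Deterministic:
#' identical inputs and configuration give identical outputs.
#'
#' @param config A [run_config()].
#' @return List of class `"paleoregions_result"` with data frames
#'   `bioregions` (`bin`, `collection_id`, `bioregion`), `richness`
#'   (per-bioregion points: `bin`, `bioregion`, `group`, `n`, `coverage`,
#'   `richness`, `mode`, `status`), `bin_means`, `proportions` (`bin`,
#'   `bioregion`, `crown_proportion`), `ranges` (`bin`, `group`,
#'   `n_collections`, `mst_km`, `total_mst_km`, `fraction`, `absent`) and
#'   `log` (`occurrence_id`, `status`, `reason`: every input occurrence
#'   appears exactly once).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dat <- if (is.character(config$occurrences))
    read_occurrences(config$occurrences, config$column_map) else
    config$occurrences
  occ <- dat$occurrences; coll <- dat$collections
  bins <- if (is.character(config$bins)) read_bins(config$bins) else
    validate_bins(config$bins)
  if (!is.null(config$stages))
    bins <- bins[bins$name %in% config$stages, , drop = FALSE]

  if (!is.null(config$scenario_name)) {
    occ$group <- assign_groups(occ, scenario(config$scenario_name))
  } else if (is.null(occ$group)) {
    stop("scenario_name is NULL but occurrences carry no 'group' column")
  }

  log <- data.frame(occurrence_id = occ$occurrence_id,
                    status = "used", reason = "", stringsAsFactors = FALSE)
  log$status[occ$group == "excluded"] <- "excluded"
  log$reason[occ$group == "excluded"] <- "unmatched_lineage"

  coll$bin <- assign_bins(coll, bins, config$binning_rule)
  occ$bin <- coll$bin[match(occ$collection_id, coll$collection_id)]
  unb <- is.na(occ$bin) & log$status == "used"
  log$status[unb] <- "excluded"; log$reason[unb] <- "unassigned_bin"

  used <- occ[log$status == "used", , drop = FALSE]

  breg_rows <- list(); rich_rows <- list(); prop_rows <- list()
  range_rows <- list()

  for (bn in bins$name) {
    obin <- used[used$bin == bn, , drop = FALSE]
    if (!nrow(obin)) next
    cbin <- coll[coll$collection_id %in% obin$collection_id, , drop = FALSE]
    assemblages <- lapply(split(obin$taxon_name, obin$collection_id), unique)
    part <- delineate_bioregions(cbin, assemblages,
                                 geo_height_km = config$geo_height_km,
                                 tax_height = config$tax_height,
                                 linkage = config$linkage)
    breg_rows[[bn]] <- data.frame(bin = bn, collection_id = names(part),
                                  bioregion = unname(part),
                                  stringsAsFactors = FALSE)
    obin$bioregion <- part[obin$collection_id]

    for (rg in sort(unique(part))) {
      oreg <- obin[obin$bioregion == rg, , drop = FALSE]
      for (g in c("crown", "stem")) {
        og <- oreg[oreg$group == g, , drop = FALSE]
        if (!nrow(og)) next
        counts <- filter_taxa(og)
        n <- sum(counts)
        if (n < config$min_n) {
          rich_rows[[length(rich_rows) + 1L]] <- data.frame(
            bin = bn, bioregion = rg, group = g, n = n, coverage = NA_real_,
            richness = NA_real_, mode = "insufficient",
            status = "insufficient", stringsAsFactors = FALSE)
          next
        }
        est <- richness_at_coverage(counts, config$quorum,
                                    config$max_extrapolation_factor)
        rich_rows[[length(rich_rows) + 1L]] <- data.frame(
          bin = bn, bioregion = rg, group = g, n = n,
          coverage = est$achieved_coverage, richness = est$value,
          mode = est$mode, status = est$status, stringsAsFactors = FALSE)
      }
      pr <- crown_proportion(oreg)
      if (!is.na(pr))
        prop_rows[[length(prop_rows) + 1L]] <- data.frame(
          bin = bn, bioregion = rg, crown_proportion = pr,
          stringsAsFactors = FALSE)
    }

    for (g in c("crown", "stem")) {
      gids <- unique(obin$collection_id[obin$group == g])
      rf <- range_fraction(cbin, gids)
      absent <- length(gids) == 0L
      range_rows[[paste(bn, g)]] <- data.frame(
        bin = bn, group = g, n_collections = rf$n_collections,
        mst_km = rf$mst_km, total_mst_km = rf$total_mst_km,
        fraction = if (absent) 0 else rf$fraction, absent = absent,
        stringsAsFactors = FALSE)
    }
  }

  bind <- function(rows, template) {
    if (length(rows)) { out <- do.call(rbind, rows); rownames(out) <- NULL
      out } else template
  }
  richness <- bind(rich_rows, data.frame(
    bin = character(), bioregion = integer(), group = character(),
    n = integer(), coverage = numeric(), richness = numeric(),
    mode = character(), status = character()))
  structure(list(
    bioregions = bind(breg_rows, data.frame(
      bin = character(), collection_id = character(), bioregion = integer())),
    richness = richness,
    bin_means = bin_summaries(richness),
    proportions = bind(prop_rows, data.frame(
      bin = character(), bioregion = integer(),
      crown_proportion = numeric())),
    ranges = bind(range_rows, data.frame(
      bin = character(), group = character(), n_collections = integer(),
      mst_km = numeric(), total_mst_km = numeric(), fraction = numeric(),
      absent = logical())),
    log = log), class = "paleoregions_result")
}

#' @export
print.paleoregions_result <- function(x, ...) {
  cat("paleoregions result:",
      length(unique(x$bioregions$bin)), "bin(s),",
      nrow(unique(x$bioregions[c("bin", "bioregion")])), "bioregion(s),",
      sum(x$log$status == "used"), "of", nrow(x$log), "occurrences used\n")
  invisible(x)
}

#' Write pipeline results as tidy CSVs
#'
#' @param result A `"paleoregions_result"` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "paleoregions_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("bioregions", "richness", "bin_means", "proportions",
               "ranges", "log"))
    utils::write.csv(result[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}

#' Command-line entry point
#'
#' Two subcommands:
#' \preformatted{
#' run      --occurrences PATH --bins PATH --scenario crown|stem|polyphyletic
#'          [--quorum 0.9] [--height-km 100] [--tax-height 0.5]
#'          [--linkage average] [--rule midpoint] [--min-n 5]
#'          [--stages A,B,...] --out DIR
#' generate [--seed 1] [--k 4] [--n-bins 2] [--spacing-km 500]
#'          [--radius-km 25] [--collections 10] [--endemicity 0.8]
#'          [--stem-whitelist 1,2] --out DIR
#' }
#' Invoke as `Rscript -e 'paleoregions::cli_main()' run ...`.
#'
#' @param args Character vector of arguments (defaults to the command line).
#' @return Invisibly, the result object or generated world.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: paleoregions run|generate ...")
  cmd <- args[1]
  opts <- parse_flags(args[-1])
  get <- function(key, default = NULL) {
    if (!is.null(opts[[key]])) opts[[key]] else default
  }
  if (cmd == "run") {
    scen <- switch(get("scenario", "crown"),
                   crown = "haramiyida_crown", stem = "haramiyida_stem",
                   polyphyletic = "haramiyida_polyphyletic",
                   stop("unknown scenario: ", get("scenario")))
    cfg <- run_config(
      occurrences = get("occurrences") %||% stop("--occurrences required"),
      bins = get("bins") %||% stop("--bins required"),
      scenario_name = scen,
      quorum = as.numeric(get("quorum", 0.9)),
      geo_height_km = as.numeric(get("height-km", 100)),
      tax_height = as.numeric(get("tax-height", 0.5)),
      linkage = get("linkage", "average"),
      binning_rule = get("rule", "midpoint"),
      min_n = as.numeric(get("min-n", 5)),
      stages = if (is.null(get("stages"))) NULL else
        strsplit(get("stages"), ",", fixed = TRUE)[[1]])
    res <- run_pipeline(cfg)
    out <- get("out") %||% stop("--out required")
    write_results(res, out)
    message("wrote results to ", out)
    invisible(res)
  } else if (cmd == "generate") {
    wl <- get("stem-whitelist")
    spec <- world_spec(
      n_bins = as.integer(get("n-bins", 2)), K = as.integer(get("k", 4)),
      centroid_spacing_km = as.numeric(get("spacing-km", 500)),
      region_radius_km = as.numeric(get("radius-km", 25)),
      collections_per_region = as.integer(get("collections", 10)),
      endemicity = as.numeric(get("endemicity", 0.8)),
      stem_region_whitelist = if (is.null(wl)) NULL else
        as.integer(strsplit(wl, ",", fixed = TRUE)[[1]]),
      seed = as.integer(get("seed", 1)))
    world <- generate_world(spec)
    out <- get("out") %||% stop("--out required")
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    write_occurrences(world$occurrences, world$collections,
                      file.path(out, "occurrences.csv"))
    utils::write.csv(world$bins, file.path(out, "bins.csv"),
                     row.names = FALSE)
    truth_part <- do.call(rbind, lapply(names(world$truth$partitions),
      function(bn) data.frame(bin = bn,
                              collection_id = names(world$truth$partitions[[bn]]),
                              region = unname(world$truth$partitions[[bn]]))))
    utils::write.csv(truth_part, file.path(out, "truth_partition.csv"),
                     row.names = FALSE)
    utils::write.csv(world$truth$range_fractions,
                     file.path(out, "truth_range_fractions.csv"),
                     row.names = FALSE)
    message("wrote synthetic world to ", out)
    invisible(world)
  } else {
    stop("unknown subcommand: ", cmd)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("expected --flag, got: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE; i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  opts
}
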