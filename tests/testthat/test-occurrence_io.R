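test_that("read_occurrences parses, counts and validates", {
  # header-only file
  empty <- read_occurrences(write_pbdb_csv(character(0)))
  expect_identical(nrow(empty$occurrences), 0L)
  expect_identical(nrow(empty$collections), 0L)

  # 3 valid rows in 2 collections
  p <- write_pbdb_csv(c(
    "1,10,Thomasia hahni,species,Haramiyidae,Haramiyida,Mammalia,45.0,10.0,205,202,",
    "2,10,Thomasia,genus,Haramiyidae,Haramiyida,Mammalia,45.0,10.0,205,202,",
    "3,11,Morganucodon watsoni,species,Morganucodontidae,Morganucodonta,Osteichthyes,46.0,11.0,204,203,"))
  d <- read_occurrences(p)
  expect_equal(nrow(d$occurrences), 3L)
  expect_equal(nrow(d$collections), 2L)
  expect_setequal(d$occurrences$collection_id, c("10", "11"))
  expect_equal(d$occurrences$lineage[1], "Haramiyidae;Haramiyida;Mammalia")
  expect_equal(d$occurrences$taxon_rank, c("species", "genus", "species"))
  expect_true(all(d$occurrences$collection_id %in% d$collections$collection_id))

  # out-of-range coordinate is a row-level error naming the row
  bad <- write_pbdb_csv(
    "1,10,Thomasia hahni,species,Haramiyidae,Haramiyida,Mammalia,95.0,10.0,205,202,")
  expect_error(read_occurrences(bad), "paleo_lat.*row")

  # duplicate occurrence id
  dup <- write_pbdb_csv(c(
    "1,10,Thomasia hahni,species,Haramiyidae,,Mammalia,45,10,205,202,",
    "1,10,Thomasia hahni,species,Haramiyidae,,Mammalia,45,10,205,202,"))
  expect_error(read_occurrences(dup), "duplicate occurrence_id")

  # species rank requires a binomial; bad ages rejected
  expect_error(read_occurrences(write_pbdb_csv(
    "1,10,Thomasia,species,Haramiyidae,,Mammalia,45,10,205,202,")),
    "binomial")
  expect_error(read_occurrences(write_pbdb_csv(
    "1,10,Thomasia hahni,species,Haramiyidae,,Mammalia,45,10,202,205,")),
    "age range")

  # trace-flagged rows are dropped when the flag column is mapped
  tr <- write_pbdb_csv(c(
    "1,10,Thomasia hahni,species,Haramiyidae,,Mammalia,45,10,205,202,",
    "2,10,Brontopodus isp.,above_genus,,,,45,10,205,202,trace"))
  expect_equal(nrow(read_occurrences(tr)$occurrences), 1L)

  # unmapped required column is a schema error
  cm <- pbdb_column_map(); cm$paleo_lat <- "nope"
  expect_error(read_occurrences(p, cm), "nope")
})

test_that("occurrence tables round-trip through write_occurrences", {
  w <- generate_world(world_spec(n_bins = 1, K = 2,
                                 collections_per_region = 3, seed = 11))
  path <- tempfile(fileext = ".csv")
  write_occurrences(w$occurrences, w$collections, path)
  back <- read_occurrences(path)
  ord <- function(d) d[order(d$occurrence_id), , drop = FALSE]
  expect_equal(ord(back$occurrences), ord(w$occurrences),
               ignore_attr = "row.names")
  expect_equal(back$collections, w$collections, ignore_attr = "row.names")
})

test_that("scenarios assign haramiyidans per hypothesis and partition sums", {
  occ <- occ_df(
    names = c("Thomasia hahni", "Gondwanatherium patagonicum",
              "Haramiyavia clemmenseni", "Morganucodon watsoni",
              "Kuehneodon dietrichi", "Weirdobeast ignotum"),
    ranks = "species",
    lineages = c("Haramiyidae;Haramiyida;Mammalia",
                 "Gondwanatheria;Haramiyida;Mammalia",
                 "Haramiyaviidae;Haramiyida;Mammalia",
                 "Morganucodontidae;Morganucodonta;Osteichthyes",
                 "Paulchoffatiidae;Multituberculata;Mammalia",
                 "Unknownidae;Unknownida;Unknownia"))
  g_crown <- assign_groups(occ, scenario("haramiyida_crown"))
  g_stem  <- assign_groups(occ, scenario("haramiyida_stem"))
  g_poly  <- assign_groups(occ, scenario("haramiyida_polyphyletic"))

  expect_equal(g_crown, c("crown", "crown", "crown", "stem", "crown",
                          "excluded"))
  expect_equal(g_stem[1:3], c("stem", "stem", "stem"))
  # polyphyletic: the Triassic families are stem, other haramiyidans crown
  expect_equal(g_poly[1:3], c("stem", "crown", "stem"))

  # each occurrence lands in exactly one partition, counts sum to input
  for (g in list(g_crown, g_stem, g_poly)) {
    expect_true(all(g %in% c("crown", "stem", "excluded")))
    expect_equal(sum(g == "crown") + sum(g == "stem") +
                   sum(g == "excluded"), nrow(occ))
  }
  # scenario swap only moves haramiyidan-lineage occurrences
  haram <- grepl("Haramiyida|Gondwanatheria", occ$lineage)
  expect_equal(g_crown[!haram], g_stem[!haram])
  expect_equal(g_crown[!haram], g_poly[!haram])
  # a clade present in both sets is a configuration error when matched
  bad <- scenario("haramiyida_crown")
  bad$crown_clades <- c(bad$crown_clades, "Morganucodontidae")
  expect_error(assign_groups(occ, bad), "both")
})

test_that("bin assignment follows midpoint and majority-overlap rules", {
  bins <- data.frame(name = c("Rhaetian", "Hettangian"),
                     older_ma = c(208.5, 201.4), younger_ma = c(201.4, 199.3))
  colls <- data.frame(collection_id = c("a", "b", "c", "d"),
                      paleo_lat = 0, paleo_lon = 0,
                      max_ma = c(201, 205, 210, 150),
                      min_ma = c(199, 204, 195, 140))
  # midpoint 200.0 lies in the Hettangian
  expect_equal(assign_bins(colls, bins, "midpoint"),
               c("Hettangian", "Rhaetian", "Rhaetian", NA))
  # 210-195 overlaps Rhaetian by 7.1 Myr, more than any other bin
  expect_equal(assign_bins(colls, bins, "majority_overlap")[3], "Rhaetian")
  # wholly-contained range gets its bin under both rules
  expect_equal(assign_bins(colls[2, ], bins, "majority_overlap"), "Rhaetian")
  expect_true(is.na(assign_bins(colls, bins, "majority_overlap")[4]))

  bad_bins <- tempfile(fileext = ".csv")
  writeLines("name,older_ma", bad_bins)  # missing younger_ma
  expect_error(read_bins(bad_bins), "columns")
  overlapping <- data.frame(name = c("A", "B"), older_ma = c(10, 6),
                            younger_ma = c(5, 2))
  expect_error(assign_bins(colls, overlapping), "overlap")
})

test_that("bundled stage table is valid and ordered old to young", {
  st <- mesozoic_stages()
  expect_equal(st$name[1], "Induan")
  expect_equal(st$name[nrow(st)], "Maastrichtian")
  expect_true(all(diff(st$older_ma) < 0))
  expect_true(all(st$older_ma > st$younger_ma))
  # stages tile the Mesozoic without gaps
  expect_equal(st$older_ma[-1], st$younger_ma[-nrow(st)])
})
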