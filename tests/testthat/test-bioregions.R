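test_that("haversine distance matches closed forms", {
  expect_equal(haversine_km(10, 20, 10, 20), 0)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-12)
  expect_equal(haversine_km(0, 0, 0, 1), pi / 180 * 6371, tolerance = 1e-12)
  expect_equal(haversine_km(-30, 50, 40, -110),
               haversine_km(40, -110, -30, 50))
  expect_error(haversine_km(NA, 0, 0, 0), "non-finite")
  expect_error(haversine_km(91, 0, 0, 0), "out of range")
})

test_that("Forbes distance follows the corrected index", {
  expect_equal(forbes_distance(letters[1:3], letters[1:3]), 0)
  expect_equal(forbes_distance(letters[1:3], letters[4:6]), 1)
  # a=2, b=1, c=1: F' = 2(4+2)/(2(4+2) + 1.5) = 12/13.5
  expect_equal(forbes_distance(c("a", "b", "c"), c("a", "b", "d")),
               1 - 12 / 13.5, tolerance = 1e-12)
  expect_error(forbes_distance(character(0), "a"), "empty")
  # bounded in [0,1] over random set pairs
  set.seed(42)
  for (i in 1:50) {
    A <- sample(letters, sample(1:10, 1))
    B <- sample(letters, sample(1:10, 1))
    d <- forbes_distance(A, B)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, forbes_distance(B, A))
  }
})

test_that("distance matrices are symmetric and match single-pair calls", {
  colls <- data.frame(collection_id = c("c1", "c2", "c3"),
                      paleo_lat = c(0, 0, 10), paleo_lon = c(0, 1, 1))
  asm <- list(c1 = c("a", "b"), c2 = c("a", "b"), c3 = c("x", "y"))
  g <- distance_matrix(colls, kind = "geographic_km")
  t <- distance_matrix(colls, asm, kind = "taxonomic")
  for (m in list(g, t)) {
    expect_equal(m, t(m))
    expect_equal(diag(m), setNames(rep(0, 3), colls$collection_id))
  }
  expect_equal(g["c1", "c2"], haversine_km(0, 0, 0, 1))
  expect_equal(t["c1", "c2"], 0)
  expect_equal(t["c1", "c3"], forbes_distance(asm$c1, asm$c3))
  # empty assemblage dropped with warning under taxonomic kind
  asm2 <- asm; asm2$c3 <- character(0)
  expect_warning(t2 <- distance_matrix(colls, asm2, kind = "taxonomic"),
                 "empty assemblage")
  expect_equal(dim(t2), c(2L, 2L))
  expect_error(distance_matrix(colls[1, ], kind = "geographic_km"),
               "at least 2")
})

test_that("average-linkage clustering matches a brute-force reference", {
  # two leaves merge at their distance; three equidistant leaves tie
  d2 <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  h2 <- cluster_collections(d2)
  expect_equal(h2$height, 5)
  d3 <- matrix(3, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  expect_equal(cluster_collections(d3)$height, c(3, 3))

  set.seed(7)
  for (rep in 1:5) {
    p <- 6
    D <- matrix(0, p, p, dimnames = list(letters[1:p], letters[1:p]))
    D[upper.tri(D)] <- runif(p * (p - 1) / 2, 1, 100)
    D <- D + t(D)
    h <- cluster_collections(D, "average")
    expect_equal(sort(h$height), sort(upgma_merge_heights(D)),
                 tolerance = 1e-9)
  }
  expect_error(cluster_collections(d2[1, 1, drop = FALSE]), "at least 2")
})

test_that("cut_dendrogram yields maximal subtrees at or below the height", {
  # two tight pairs 1 km wide, 300 km apart
  colls <- data.frame(collection_id = c("a1", "a2", "b1", "b2"),
                      paleo_lat = c(0, 0.009, 2.7, 2.709), paleo_lon = 0)
  dend <- cluster_collections(distance_matrix(colls, kind = "geographic_km"))
  part <- cut_dendrogram(dend, 100)
  expect_equal(unname(part[c("a1", "a2")]), c(1L, 1L))
  expect_equal(unname(part[c("b1", "b2")]), c(2L, 2L))
  # height 0: all singletons; height >= root: one cluster
  expect_equal(max(cut_dendrogram(dend, 0)), 4L)
  expect_equal(max(cut_dendrogram(dend, 1e6)), 1L)
  expect_error(cut_dendrogram(dend, -1), ">= 0")
})

test_that("bioregions are the meet of geographic and taxonomic partitions", {
  # co-located pairs with contrasting faunas and a distant pair
  colls <- data.frame(collection_id = sprintf("c%d", 1:6),
                      paleo_lat = c(0, 0, 0.01, 0.01, 10, 10.01),
                      paleo_lon = c(0, 0.01, 0, 0.01, 0, 0))
  asm <- list(c1 = c("a", "b"), c2 = c("a", "b"),
              c3 = c("x", "y"), c4 = c("x", "y"),
              c5 = c("a", "b"), c6 = c("a", "b"))
  part <- delineate_bioregions(colls, asm)
  # c1+c2 together; c3+c4 co-located but faunally disjoint from them;
  # c5+c6 faunally like c1 but 1100 km away
  expect_equal(part[["c1"]], part[["c2"]])
  expect_equal(part[["c3"]], part[["c4"]])
  expect_false(part[["c1"]] == part[["c3"]])
  expect_false(part[["c1"]] == part[["c5"]])
  expect_equal(length(unique(part)), 3L)

  # meet property: each bioregion sits inside one cluster of each partition
  geo <- cut_dendrogram(cluster_collections(
    distance_matrix(colls, kind = "geographic_km")), 100)
  tax <- cut_dendrogram(cluster_collections(
    distance_matrix(colls, asm, kind = "taxonomic")), 0.5)
  for (rg in unique(part)) {
    members <- names(part)[part == rg]
    expect_equal(length(unique(geo[members])), 1L)
    expect_equal(length(unique(tax[members])), 1L)
  }

  # identical faunas within 50 km: a single bioregion
  near <- data.frame(collection_id = c("x", "y"),
                     paleo_lat = c(0, 0.2), paleo_lon = 0)
  expect_equal(max(delineate_bioregions(
    near, list(x = "a", y = "a"))), 1L)
  # single collection: singleton without clustering
  expect_equal(delineate_bioregions(near[1, ], list(x = "a")),
               c(x = 1L))
})

test_that("doubling the geographic cut height never splits bioregions", {
  set.seed(31)
  for (rep in 1:10) {
    pts <- random_points(12)
    colls <- data.frame(collection_id = sprintf("c%02d", 1:12),
                        paleo_lat = pts$lat / 20, paleo_lon = pts$lon / 20)
    asm <- setNames(lapply(1:12, function(i) letters[1:3]),
                    colls$collection_id)
    for (h in c(50, 100, 200, 400, 800)) {
      k1 <- length(unique(delineate_bioregions(colls, asm,
                                               geo_height_km = h)))
      k2 <- length(unique(delineate_bioregions(colls, asm,
                                               geo_height_km = 2 * h)))
      expect_lte(k2, k1)
    }
  }
})
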