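test_that("polyline length matches per-segment Euclidean sums", {
  expect_equal(polyline_length(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(polyline_length(rbind(c(0, 0), c(1, 0), c(1, 1))), 2)
  set.seed(101)
  for (i in 1:10) {
    g <- matrix(runif(20, -500, 500), ncol = 2)
    expect_equal(polyline_length(g), oracle_polyline_length(g))
  }
  expect_error(polyline_length(matrix(c(1, 2), ncol = 2)), "degenerate")
})

test_that("road-district split honours symmetry and containment", {
  dd <- make_grid_districts(2, 1, cell = 1000)
  # 10 m segment crossing the shared edge at its midpoint
  rd <- road_segment("r1", rbind(c(995, 500), c(1005, 500)), geoid_length = 10)
  p <- split_road_by_districts(rd, dd)
  expect_equal(nrow(p), 2L)
  expect_equal(sort(p$actual_length_dA), c(5, 5))
  expect_equal(sum(p$ratio_R), 1)
  # fully inside one district
  rd2 <- road_segment("r2", rbind(c(100, 100), c(400, 500)), geoid_length = 600)
  p2 <- split_road_by_districts(rd2, dd)
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$district, "G01")
  expect_equal(p2$actual_length_dA, 500)
  expect_equal(p2$ratio_R, 500 / 600)
  # entirely outside every district -> empty, not an error
  rd3 <- road_segment("r3", rbind(c(5000, 5000), c(6000, 5000)), geoid_length = 1000)
  expect_equal(nrow(split_road_by_districts(rd3, dd)), 0L)
})

test_that("split lengths agree with a dense point-sampling oracle", {
  dd <- make_grid_districts(3, 1, cell = 1000)
  rects <- rects_of(dd)
  set.seed(202)
  for (i in 1:5) {
    p1 <- c(runif(1, 0, 400), runif(1, 0, 1000))
    p2 <- c(runif(1, 2600, 3000), runif(1, 0, 1000))
    rd <- road_segment("x", rbind(p1, p2), geoid_length = 1)
    got <- split_road_by_districts(rd, dd)
    ora <- oracle_split_lengths(p1, p2, rects, n = 1e5)
    for (k in seq_along(dd)) {
      g <- got$actual_length_dA[got$district == dd[[k]]$name]
      g <- if (length(g)) g else 0
      expect_equal(g, ora[k], tolerance = 1e-3)
    }
  }
})

test_that("length is conserved across a split", {
  dd <- make_grid_districts(2, 2, cell = 1000)
  set.seed(303)
  for (i in 1:20) {
    g <- matrix(runif(8, 0, 2000), ncol = 2)  # 4-vertex polyline inside tiling
    rd <- road_segment("c", g, geoid_length = polyline_length(g))
    p <- split_road_by_districts(rd, dd)
    expect_equal(sum(p$actual_length_dA), polyline_length(g), tolerance = 1e-6)
  }
})

test_that("dissolve merges duplicate records and sets single-district R to 1", {
  dd <- make_grid_districts(1, 1, cell = 1000)
  r1 <- road_segment("915276", rbind(c(0, 10), c(40, 10)), geoid_length = 100,
                     record_id = "a")
  r2 <- road_segment("915276", rbind(c(40, 10), c(100, 10)), geoid_length = 100,
                     record_id = "b")
  p <- dissolve_records(split_roads(list(r1, r2), dd))
  expect_equal(nrow(p), 1L)
  expect_equal(p$actual_length_dA, 100)
  expect_equal(p$ratio_R, 1)
  # identity on a single record
  single <- split_roads(list(r1), dd)
  d1 <- dissolve_records(single)
  expect_equal(d1$actual_length_dA, single$actual_length_dA)
  # k duplicates sum their lengths (multi-district road keeps summed ratio)
  dd2 <- make_grid_districts(2, 1, cell = 1000)
  parts <- lapply(1:4, function(k) {
    road_segment("m", rbind(c(800 + 100 * (k - 1), 5), c(900 + 100 * (k - 1), 5)),
                 geoid_length = 400, record_id = paste0("m", k))
  })
  pm <- dissolve_records(split_roads(parts, dd2))
  expect_equal(nrow(pm), 2L)  # one record per district
  expect_equal(sum(pm$actual_length_dA), 400)
  expect_equal(sum(pm$ratio_R), 1)
  # idempotence
  expect_equal(dissolve_records(pm)[, 1:5], pm[, 1:5])
})

test_that("activity region is the exact dilation of the footprints", {
  b1 <- list(building("b1", c(0, 0)))
  reg <- activity_region(b1, 200)
  expect_equal(region_area(reg), pi * 200^2, tolerance = 0.01)
  # two overlapping discs merge: midpoint is covered, area is subadditive
  b2 <- list(building("b1", c(0, 0)), building("b2", c(100, 0)))
  reg2 <- activity_region(b2, 200)
  expect_true(region_contains(reg2, rbind(c(50, 0))))
  expect_lt(region_area(reg2), 2 * pi * 200^2)
  expect_error(activity_region(b1, -5), "positive")
  # empty building list -> empty region
  reg0 <- activity_region(list(), 200)
  expect_equal(region_area(reg0), 0)
  expect_false(region_contains(reg0, rbind(c(0, 0))))
})

test_that("region membership matches the nearest-distance oracle", {
  set.seed(404)
  blds <- lapply(1:40, function(i) {
    if (i %% 5 == 0) {
      c0 <- runif(2, 200, 1800)
      building(paste0("b", i), rbind(c0 + c(-15, -15), c0 + c(15, -15),
                                     c0 + c(15, 15), c0 + c(-15, 15)))
    } else {
      building(paste0("b", i), runif(2, 0, 2000))
    }
  })
  reg <- activity_region(blds, 200)
  probes <- matrix(runif(2000, -200, 2200), ncol = 2)
  got <- region_contains(reg, probes)
  ora <- oracle_nearest_distance(probes, lapply(blds, `[[`, "geometry")) <= 200
  expect_equal(got, ora)
})

test_that("buffer regions and road selection are monotone in the distance", {
  set.seed(505)
  blds <- lapply(1:20, function(i) building(paste0("b", i), runif(2, 0, 1000)))
  probes <- matrix(runif(400, -300, 1300), ncol = 2)
  r1 <- activity_region(blds, 150); r2 <- activity_region(blds, 300)
  m1 <- region_contains(r1, probes); m2 <- region_contains(r2, probes)
  expect_true(all(m2[m1]))
  roads <- lapply(1:30, function(i) {
    a <- runif(2, -200, 1200)
    road_segment(paste0("r", i), rbind(a, a + runif(2, -300, 300)),
                 geoid_length = 10)
  })
  s1 <- select_roads_in_region(roads, r1)
  s2 <- select_roads_in_region(roads, r2)
  ids <- function(rs) vapply(rs, `[[`, character(1), "cts_id")
  expect_true(all(ids(s1) %in% ids(s2)))
})

test_that("road selection equals the distance rule", {
  blds <- list(building("b", c(500, 500)))
  reg <- activity_region(blds, 200)
  through <- road_segment("a", rbind(c(400, 500), c(600, 500)), geoid_length = 200)
  nearby <- road_segment("b", rbind(c(500, 650), c(900, 650)), geoid_length = 400)
  faraway <- road_segment("c", rbind(c(1000, 1000), c(1400, 1000)), geoid_length = 400)
  kept <- select_roads_in_region(list(through, nearby, faraway), reg)
  expect_equal(vapply(kept, `[[`, character(1), "cts_id"), c("a", "b"))
  # randomised instances against the pairwise-distance oracle
  set.seed(606)
  blds <- lapply(1:25, function(i) building(paste0("b", i), runif(2, 0, 2000)))
  reg <- activity_region(blds, 200)
  roads <- lapply(1:40, function(i) {
    a <- runif(2, 0, 2000)
    road_segment(paste0("r", i), rbind(a, a + runif(2, -400, 400)),
                 geoid_length = 10)
  })
  kept_ids <- vapply(select_roads_in_region(roads, reg), `[[`, character(1), "cts_id")
  fps <- lapply(blds, `[[`, "geometry")
  want <- vapply(roads, function(rd) {
    # sample the polyline densely; the oracle works on points
    t <- seq(0, 1, length.out = 2001)
    pts <- cbind(rd$geometry[1, 1] + t * diff(rd$geometry[, 1]),
                 rd$geometry[1, 2] + t * diff(rd$geometry[, 2]))
    min(oracle_nearest_distance(pts, fps)) <= 200
  }, logical(1))
  expect_setequal(kept_ids, vapply(roads, `[[`, character(1), "cts_id")[want])
})

test_that("geoid-length filter is strict at the threshold", {
  mk <- function(id, dG) road_segment(id, rbind(c(0, 0), c(0, dG)), dG)
  roads <- list(mk("a", 1.0), mk("b", 1.0001), mk("c", 0.5), mk("d", 25))
  kept <- filter_geoid_length(roads, 1)
  expect_equal(vapply(kept, `[[`, character(1), "cts_id"), c("b", "d"))
  set.seed(707)
  dGs <- runif(200, 0.5, 1.5)
  roads <- lapply(seq_along(dGs), function(i) mk(paste0("r", i), dGs[i]))
  expect_length(filter_geoid_length(roads, 1), sum(dGs > 1))
})

test_that("invalid polygons are rejected", {
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(district("bad", bowtie, 1), "self-intersects")
  expect_error(district("flat", rbind(c(0, 0), c(1, 0), c(2, 0)), 1), "area")
})
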