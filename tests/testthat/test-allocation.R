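test_that("inverse-distance weighting interpolates between the endpoints", {
  expect_equal(idw_interpolate(7, 7, 3, 12), 7)
  expect_equal(idw_interpolate(3, 9, 0, 10), 3)
  expect_equal(idw_interpolate(0, 10, 4, 4), 5)
  set.seed(1)
  for (i in 1:20) {
    EX <- runif(1, 0, 100); EZ <- runif(1, 0, 100)
    d1 <- runif(1, 0, 50); d2 <- runif(1, 0, 50)
    EY <- idw_interpolate(EX, EZ, d1, d2)
    expect_gte(EY, min(EX, EZ)); expect_lte(EY, max(EX, EZ))
  }
  expect_error(idw_interpolate(1, 2, 0, 0), "degenerate")
})

test_that("length ratio and adjusted emission reproduce the worked street split", {
  dG <- 82.0047
  expect_equal(round_report(length_ratio(70.5128, dG), "ratio"), 0.8599)
  expect_equal(round_report(length_ratio(11.4920, dG), "ratio"), 0.1401)
  expect_equal(length_ratio(5, 5), 1)
  R1 <- length_ratio(70.5128, dG); R2 <- length_ratio(11.4920, dG)
  expect_equal(round_report(adjust_emission(7101.74, R1), "emission"), 6106.52)
  expect_equal(round_report(adjust_emission(39327.33, R1), "emission"), 33816.11)
  expect_equal(round_report(adjust_emission(7101.74, R2), "emission"), 995.23)
  expect_equal(round_report(adjust_emission(39327.33, R2), "emission"), 5511.27)
  expect_equal(adjust_emission(123.4, 1), 123.4)
  expect_error(length_ratio(10, 0), "denominator")
  expect_error(adjust_emission(-1, 0.5), "EO")
  expect_error(adjust_emission(1, 1.5), "R must")
})

test_that("rounding is a reporting convention, not an arithmetic step", {
  # multiplying by the rounded ratio does NOT reproduce the reported portion
  R_rounded <- 0.8599
  expect_false(round(7101.74 * R_rounded, 2) == 6106.52)
  expect_equal(round_report(7101.74 * length_ratio(70.5128, 82.0047),
                            "emission"), 6106.52)
})

test_that("district totals accumulate adjusted emissions per vehicle and hour", {
  dd <- make_grid_districts(1, 1, cell = 1000)
  rd <- road_segment("r1", rbind(c(100, 100), c(600, 100)), geoid_length = 500)
  portions <- dissolve_records(split_roads(list(rd), dd))
  em <- make_emissions("r1", hours = 8, EO = 10)
  t1 <- district_totals(portions, em, 0:23)
  expect_equal(t1$district_totals$total_g_per_km, 10)
  # empty table -> no totals
  t0 <- district_totals(portions, em[0, ], 0:23)
  expect_equal(nrow(t0$district_totals), 0L)
  # unknown road ids are skipped and counted
  em2 <- rbind(em, make_emissions("ghost", hours = 8, EO = 99))
  t2 <- district_totals(portions, em2, 0:23)
  expect_equal(t2$skipped, 1L)
  expect_equal(t2$district_totals$total_g_per_km, 10)
})

test_that("district totals match the brute-force triple-loop oracle", {
  dd <- make_grid_districts(3, 1, cell = 1000)
  set.seed(42)
  roads <- lapply(1:10, function(i) {
    p1 <- c(runif(1, 0, 2800), runif(1, 0, 1000))
    p2 <- p1 + c(runif(1, 50, 1200), runif(1, -200, 200))
    p2 <- pmin(pmax(p2, 0), c(3000, 1000))
    g <- rbind(p1, p2)
    road_segment(paste0("r", i), g, geoid_length = polyline_length(g))
  })
  portions <- dissolve_records(split_roads(roads, dd))
  em <- data.frame(
    cts_id = sample(paste0("r", 1:10), 100, replace = TRUE),
    hour = sample(0:23, 100, replace = TRUE),
    vehicle_type = sample(VEHICLE_TYPES, 100, replace = TRUE),
    pollutant = sample(POLLUTANTS, 100, replace = TRUE),
    emission_g_per_km = runif(100, 0, 500), stringsAsFactors = FALSE)
  hrs <- c(7, 8, 9, 17, 18)
  got <- district_totals(portions, em, hrs)$totals
  got_v <- sort(got$emission_g_per_km)
  ora <- oracle_district_totals(portions, em, hrs)
  expect_equal(got_v, unname(ora))
})

test_that("totals are conserved, hour-monotone and scale-equivariant", {
  dd <- make_grid_districts(2, 2, cell = 1000)
  set.seed(43)
  roads <- lapply(1:15, function(i) {
    g <- matrix(runif(4, 0, 2000), ncol = 2)
    road_segment(paste0("r", i), g, geoid_length = polyline_length(g))
  })
  portions <- dissolve_records(split_roads(roads, dd))
  # conservation: ratios of an in-area road sum to 1, so EA sums to EO
  rsum <- rowsum(portions$ratio_R, portions$cts_id)
  expect_equal(unname(rsum[, 1]), rep(1, nrow(rsum)), tolerance = 1e-9)
  em <- make_emissions(paste0("r", 1:15), hours = c(3, 8, 15), EO = 7)
  tot <- district_totals(portions, em, 0:23)
  expect_equal(sum(tot$district_totals$total_g_per_km),
               sum(em$emission_g_per_km), tolerance = 1e-9)
  # enlarging the hour set never decreases a district total
  t_small <- district_totals(portions, em, 8)$district_totals
  t_big <- district_totals(portions, em, c(8, 15))$district_totals
  expect_true(all(t_big$total_g_per_km >=
                    t_small$total_g_per_km[match(paste(t_big$district, t_big$pollutant),
                                                 paste(t_small$district, t_small$pollutant))] - 1e-12))
  # scale equivariance
  em2 <- em; em2$emission_g_per_km <- em2$emission_g_per_km * 3.7
  t2 <- district_totals(portions, em2, 0:23)$district_totals
  expect_equal(t2$total_g_per_km, tot$district_totals$total_g_per_km * 3.7)
  # per-vehicle totals sum to the district total
  agg <- rowsum(tot$totals$emission_g_per_km,
                paste(tot$totals$district, tot$totals$pollutant))
  expect_equal(unname(agg[, 1]), tot$district_totals$total_g_per_km,
               tolerance = 1e-9)
})
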