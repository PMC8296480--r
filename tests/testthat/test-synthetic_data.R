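test_that("generation is deterministic given config and seed", {
  cfg <- city_config(n_roads = 40L, n_buildings = 60L, rng_seed = 123L)
  a <- generate_city(cfg)
  b <- generate_city(cfg)
  expect_identical(a$emissions, b$emissions)
  expect_identical(a$mortality, b$mortality)
  expect_identical(lapply(a$roads, `[[`, "geometry"),
                   lapply(b$roads, `[[`, "geometry"))
  # a different seed changes the city
  c2 <- generate_city(city_config(n_roads = 40L, n_buildings = 60L,
                                  rng_seed = 124L))
  expect_false(identical(a$emissions$emission_g_per_km,
                         c2$emissions$emission_g_per_km))
})

test_that("district tiling is disjoint, exhaustive, and correctly grouped", {
  cfg <- city_config(rng_seed = 5L)
  set.seed(5)
  dd <- generate_districts(cfg)
  expect_length(dd, 18L)
  areas <- vapply(dd, function(d) polygon_area(d$geometry), numeric(1))
  expect_equal(sum(areas), 18 * cfg$cell_m^2)
  pcts <- vapply(dd, function(d) d$population_pct, numeric(1))
  expect_equal(sum(pcts), 100, tolerance = 1e-6)
  expect_equal(sum(classify_group(pcts) == 1L), 7L)  # 7 of 18 residential
  groups <- vapply(dd, function(d) d$group, integer(1))
  expect_equal(groups, classify_group(pcts))
  # 2x2 case tiles the extent with unit cells
  cfg2 <- city_config(n_districts = 4L, grid_nx = 2L, grid_ny = 2L,
                      cell_m = 1000, residential_fraction = 0.5, rng_seed = 6L)
  set.seed(6)
  d4 <- generate_districts(cfg2)
  expect_length(d4, 4L)
  expect_equal(vapply(d4, function(d) polygon_area(d$geometry), numeric(1)),
               rep(1e6, 4))
})

test_that("roads respect their planted crossing/far/duplicate structure", {
  cfg <- city_config(n_roads = 100L, rng_seed = 31L)
  set.seed(31)
  dd <- generate_districts(cfg)
  rb <- generate_roads_and_buildings(cfg, dd)
  meta <- rb$road_meta
  expect_equal(sum(meta$crossing), 30L)
  expect_equal(sum(meta$far), 20L)
  # dG equals planar length, so single-district dissolved roads have R = 1
  portions <- dissolve_records(split_roads(rb$roads, dd))
  ndist <- table(portions$cts_id)
  single <- names(ndist)[ndist == 1L]
  expect_true(all(abs(portions$ratio_R[portions$cts_id %in% single] - 1) < 1e-9))
  # crossing roads produce >= 2 portions
  crossed <- names(ndist)[ndist >= 2L]
  expect_true(all(meta$cts_id[meta$crossing] %in% crossed))
  # far roads are dropped by the activity-buffer selection, near roads kept
  reg <- activity_region(rb$buildings, cfg$buffer_distance)
  kept <- vapply(select_roads_in_region(rb$roads, reg), `[[`, character(1),
                 "cts_id")
  expect_true(!any(meta$cts_id[meta$far] %in% kept))
  near_kept <- mean(meta$cts_id[!meta$far] %in% kept)
  expect_gte(near_kept, 0.95)
})

test_that("generated emissions honour the planted vehicle mix", {
  city <- small_city(seed = 41L)
  em <- city$emissions
  expect_true(all(em$emission_g_per_km >= 0))
  expect_true(all(em$hour %in% 0:23))
  expect_true(all(em$vehicle_type %in% VEHICLE_TYPES))
  # taxis emit no PM2.5 anywhere
  taxi_pm <- em[em$vehicle_type == "taxi" & em$pollutant == "PM2.5", ]
  expect_equal(nrow(taxi_pm), 0L)
  dd_tot <- district_totals(
    dissolve_records(split_roads(city$roads, city$districts)), em, 0:23)
  taxi_rows <- dd_tot$totals[dd_tot$totals$vehicle_type == "taxi" &
                               dd_tot$totals$pollutant == "PM2.5", ]
  expect_equal(nrow(taxi_rows), 0L)
  # citywide peak falls on a planted peak hour
  tot_by_hour <- rowsum(em$emission_g_per_km[em$pollutant == "NOx"],
                        em$hour[em$pollutant == "NOx"])
  peak <- as.integer(rownames(tot_by_hour)[which.max(tot_by_hour)])
  expect_true(peak %in% c(city$config$morning_peaks, city$config$evening_peaks))
  # PLB accounts for roughly its configured share of NOx
  nox <- em[em$pollutant == "NOx", ]
  plb_share <- sum(nox$emission_g_per_km[nox$vehicle_type == "PLB"]) /
    sum(nox$emission_g_per_km) * 100
  expect_gt(plb_share, 3); expect_lt(plb_share, 7)
  # heavy vehicles dominate: MGV+HGV and bus each well above light types
  shares <- rowsum(nox$emission_g_per_km, nox$vehicle_type)
  expect_gt(shares["MGV+HGV", 1], 3 * shares["private car", 1])
  expect_gt(shares["bus", 1], 3 * shares["private car", 1])
})

test_that("mortality carries the planted linear relation and outliers", {
  cfg <- city_config(n_roads = 80L, n_buildings = 150L, sigma = 0,
                     n_outliers = 0L, year_sd = 0, rng_seed = 51L)
  city <- generate_city(cfg)
  rep4 <- run_case_study(4, city)
  f <- rep4$fits$NOx$overall
  # noiseless line: slope and intercept recovered up to death-count rounding
  expect_equal(f$slope, cfg$beta_nox, tolerance = 0.02)
  expect_equal(f$intercept, cfg$alpha, tolerance = 0.02)
  expect_gt(f$pearson_R, 0.999)
  # with noise, fitted slope lies within a few standard errors of truth
  city2 <- small_city(seed = 52L)
  f2 <- run_case_study(4, city2)$fits$NOx$overall
  expect_lt(abs(f2$slope - city2$config$beta_nox), 4 * f2$slope_se)
  # planted outliers are flagged by the deviation mechanism
  cfg3 <- city_config(n_roads = 80L, n_buildings = 150L, sigma = 2,
                      rng_seed = 53L)
  city3 <- generate_city(cfg3)
  dev <- run_case_study(4, city3)$deviations$NOx
  flagged <- dev$results$district[dev$results$classification != "not_outlying"]
  expect_true(all(city3$truth$outlier_districts %in% flagged))
})

test_that("every generated artefact satisfies its type invariants", {
  city <- small_city(seed = 61L)
  v <- validate_inputs(city)
  expect_true(v$pass)
  expect_equal(nrow(v$findings), 0L)
  expect_equal(v$orphan_count, 0L)
  for (r in city$roads) {
    expect_gte(nrow(r$geometry), 2L)
    expect_gt(r$geoid_length, 0)
  }
  pops <- vapply(city$districts, function(d) d$population, numeric(1))
  expect_true(all(pops >= 0))
  expect_true(all(city$mortality$deaths >= 0))
  expect_true(all(city$mortality$population > 0))
  expect_true(all(city$mortality$year %in% 2015:2018))
})
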