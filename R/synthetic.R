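# Seeded synthetic-city generator.
#
# Emulates the structure of the study inputs -- a district tiling, a road
# network with source geoid lengths and occasional duplicate records, a
# clustered building layer, hourly per-vehicle NOx/PM2.5 emission tables with
# a double-peak diurnal cycle, and district mortality tables carrying a
# planted linear emission-mortality relation with noise and planted outlier
# districts -- at desk scale. It makes no attempt to mimic real geography or
# real emission magnitudes.

#' Configuration of a synthetic city
#'
#' Defaults are the study conditions the pipeline is exercised under: 18
#' districts on a 6 x 3 grid of 2 km cells, 7 of 18 districts residential
#' (population share >= 6\%), a double-peak diurnal cycle, heavy-goods and
#' bus emission bases 4.5x the light-vehicle bases, a minibus (PLB) share of
#' about 5\% of NOx and 12.5\% of PM2.5, no taxi PM2.5, and two planted
#' outlier districts (one high-mortality, one low-mortality).
#'
#' @param n_districts number of districts; must equal grid_nx * grid_ny.
#' @param grid_nx,grid_ny district grid dimensions.
#' @param cell_m district cell side, metres.
#' @param n_roads number of roads (cts ids).
#' @param road_length_range min/max road length, metres.
#' @param crossing_share share of roads built to cross a district border.
#' @param far_share share of roads placed farther than the activity buffer
#'   from every building (these carry a highway emission boost).
#' @param duplicate_share share of roads stored as two source records.
#' @param n_buildings number of building/podium footprints.
#' @param cluster_district_share share of districts that receive a building
#'   cluster.
#' @param cluster_sd spread of a building cluster, metres.
#' @param uniform_building_share share of buildings scattered uniformly
#'   instead of clustered.
#' @param buffer_distance activity-buffer radius, metres.
#' @param vehicle_weights_nox,vehicle_weights_pm named per-vehicle base
#'   weights (taxi PM2.5 weight 0 stands for the absent records).
#' @param scale_nox,scale_pm overall emission scale, g/km.
#' @param morning_peaks,evening_peaks named per-vehicle peak hours.
#' @param peak_trough_ratio diurnal peak over trough.
#' @param peak_width Gaussian peak width, hours.
#' @param road_factor_sdlog,noise_sdlog,night_factor_sdlog,shoulder_factor_sdlog
#'   lognormal sdlog of the per-road activity factor, the (mean-one)
#'   per-record noise, the (mean-one) neighbourhood-level off-peak (night/midday)
#'   idiosyncrasy -- night-active areas such as freight or nightlife blocks
#'   keep all their roads active off-peak -- and the per-road shoulder-hour
#'   idiosyncrasy (hours inside the refined 12-hour peak windows but outside
#'   the fixed 5-hour rush set: early-morning, early-afternoon and
#'   late-evening traffic varies more between roads than rush-hour traffic).
#' @param highway_factor emission boost of far roads.
#' @param alpha,beta_nox,beta_pm planted mortality intercept (per 100,000)
#'   and slopes (per g/km) of the linear emission-mortality relation.
#' @param sigma mortality noise SD, per 100,000.
#' @param year_sd per-year rate jitter, per 100,000.
#' @param years mortality years.
#' @param n_outliers,outlier_shifts number of planted outlier districts and
#'   their multiplicative mortality shifts.
#' @param total_population city population.
#' @param residential_fraction fraction of districts with population share
#'   >= 6\%.
#' @param dg_jitter_sd relative perturbation of stored geoid lengths
#'   (0 keeps dG exactly equal to planar length so ratio sums are exact).
#' @param rng_seed integer seed consumed by \code{\link{generate_city}}.
#' @return a list of class \code{"city_config"}.
#' @export
city_config <- function(n_districts = 18L, grid_nx = 6L, grid_ny = 3L,
                        cell_m = 2000,
                        n_roads = 200L, road_length_range = c(250, 1500),
                        crossing_share = 0.3, far_share = 0.2,
                        duplicate_share = 0.15,
                        n_buildings = 450L, cluster_district_share = 0.5,
                        cluster_sd = 300, uniform_building_share = 0.25,
                        buffer_distance = 200,
                        vehicle_weights_nox = c("private car" = 1, taxi = 1,
                                                SPB = 0.8, LV = 0.9, LGV = 1,
                                                "MGV+HGV" = 4.5, PLB = 0.72,
                                                bus = 4.5),
                        vehicle_weights_pm = c("private car" = 1, taxi = 0,
                                               SPB = 0.8, LV = 0.9, LGV = 1,
                                               "MGV+HGV" = 4.5, PLB = 1.81,
                                               bus = 4.5),
                        scale_nox = 50, scale_pm = 4,
                        morning_peaks = c("private car" = 8, taxi = 8, SPB = 8,
                                          PLB = 8, bus = 9, LGV = 9, LV = 9,
                                          "MGV+HGV" = 9),
                        evening_peaks = c("private car" = 18, taxi = 18,
                                          SPB = 18, PLB = 18, bus = 18,
                                          LGV = 16, LV = 16, "MGV+HGV" = 16),
                        peak_trough_ratio = 3, peak_width = 1.5,
                        road_factor_sdlog = 0.6, noise_sdlog = 0.3,
                        night_factor_sdlog = 1.1, shoulder_factor_sdlog = 1.3,
                        highway_factor = 1.5,
                        alpha = 80, beta_nox = 1.5e-4, beta_pm = 1.8e-3,
                        sigma = 6, year_sd = 1, years = 2015:2018,
                        n_outliers = 2L, outlier_shifts = c(0.5, -0.35),
                        total_population = 7.4e6,
                        residential_fraction = 7 / 18,
                        dg_jitter_sd = 0, rng_seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_districts != cfg$grid_nx * cfg$grid_ny) {
    stop("configuration error: n_districts must equal grid_nx * grid_ny")
  }
  stopifnot(cfg$n_roads > 0, cfg$n_buildings > 0, cfg$sigma >= 0,
            all(cfg$morning_peaks %in% 0:23), all(cfg$evening_peaks %in% 0:23))
  class(cfg) <- "city_config"
  cfg
}

#' Generate the district tiling
#'
#' Rectangular cells tiling the extent, named D01, D02, ... row-major.
#' Population percentages are drawn so that exactly
#' \code{round(residential_fraction * n)} districts have a share >= 6\%, and
#' the shares sum to 100.
#'
#' @param config a \code{city_config}.
#' @return list of \code{district} objects.
#' @export
generate_districts <- function(config) {
  n <- config$n_districts
  n_res <- round(config$residential_fraction * n)
  res_idx <- sort(sample.int(n, n_res))
  k <- n_res; m <- n - k
  if (6 * k > 100) stop("configuration error: cannot give ", k,
                        " districts >= 6% of the population")
  # rejection-sample percentages until rescaling to 100 preserves the 6% split
  pct <- NULL
  for (try in 1:100) {
    cand <- numeric(n)
    if (k) cand[res_idx] <- stats::runif(k, 6.3, 9)
    if (m) cand[-res_idx] <- stats::runif(m, 2, 5.5)
    cand <- cand / sum(cand) * 100
    ok <- (!k || all(cand[res_idx] >= 6)) && (!m || all(cand[-res_idx] < 6))
    if (ok) { pct <- cand; break }
  }
  if (is.null(pct)) {
    # deterministic construction for layouts the sampler cannot reach
    # (e.g. few districts, where residential shares must be large)
    base_r <- if (k) max(6.5, (100 - 5 * m) / k) else 0
    base_n <- if (m) (100 - k * base_r) / m else 0
    if (m && base_n <= 0) {
      stop("configuration error: infeasible residential_fraction for n_districts")
    }
    pct <- numeric(n)
    if (k) pct[res_idx] <- base_r
    if (m) pct[-res_idx] <- base_n
  }
  out <- vector("list", n)
  k <- 0L
  for (iy in seq_len(config$grid_ny)) {
    for (ix in seq_len(config$grid_nx)) {
      k <- k + 1L
      x0 <- (ix - 1L) * config$cell_m; y0 <- (iy - 1L) * config$cell_m
      ring <- rbind(c(x0, y0), c(x0 + config$cell_m, y0),
                    c(x0 + config$cell_m, y0 + config$cell_m),
                    c(x0, y0 + config$cell_m))
      out[[k]] <- district(sprintf("D%02d", k), ring,
                           population = pct[k] / 100 * config$total_population,
                           population_pct = pct[k])
    }
  }
  out
}

city_extent <- function(config) {
  c(0, 0, config$grid_nx * config$cell_m, config$grid_ny * config$cell_m)
}

#' Generate the road network and building layer
#'
#' Buildings are clustered in a subset of districts (plus a uniformly
#' scattered share). Roads are straight or gently bent polylines; a
#' configured share is built to cross a district border, a configured share
#' is placed beyond the activity buffer from every building (flagged
#' \code{far}), and the rest are anchored near buildings. Geoid lengths are
#' set to the computed planar length (optionally jittered), so allocation
#' ratio sums are exact by construction. A share of roads is stored as two
#' records partitioning the polyline, both carrying the full-street dG, to
#' exercise the dissolve step.
#'
#' @param config a \code{city_config}.
#' @param districts output of \code{\link{generate_districts}}.
#' @return list with \code{roads} (list of \code{road_segment}),
#'   \code{buildings} (list of \code{building}), and \code{road_meta}
#'   (data frame: cts_id, far, crossing, duplicated).
#' @export
generate_roads_and_buildings <- function(config, districts) {
  ext <- city_extent(config)
  buildings <- generate_buildings(config, districts, ext)
  bpts <- t(vapply(buildings, function(b) colMeans(b$geometry), numeric(2)))

  n <- config$n_roads
  n_cross <- round(config$crossing_share * n)
  n_far <- round(config$far_share * n)
  far_flag <- rep(FALSE, n); cross_flag <- rep(FALSE, n)
  cross_flag[seq_len(n_cross)] <- TRUE
  far_flag[n_cross + seq_len(n_far)] <- TRUE
  ord <- sample.int(n)  # shuffle so flags are not positional
  far_flag <- far_flag[ord]; cross_flag <- cross_flag[ord]

  region_margin <- 60  # keep far roads clearly beyond the buffer
  near_limit <- config$buffer_distance - 40
  geoms <- vector("list", n)
  for (i in seq_len(n)) {
    L <- stats::runif(1, config$road_length_range[1L], config$road_length_range[2L])
    geoms[[i]] <- draw_road(config, ext, bpts, L,
                            crossing = cross_flag[i], far = far_flag[i],
                            near_limit = near_limit,
                            far_limit = config$buffer_distance + region_margin)
  }
  ids <- sprintf("R%04d", seq_len(n))
  dup_flag <- stats::runif(n) < config$duplicate_share
  roads <- list()
  for (i in seq_len(n)) {
    g <- geoms[[i]]
    len <- polyline_length(g)
    dG <- len * if (config$dg_jitter_sd > 0)
      exp(stats::rnorm(1, 0, config$dg_jitter_sd)) else 1
    if (dup_flag[i] && nrow(g) == 2L) {
      frac <- stats::runif(1, 0.3, 0.7)
      mid <- g[1L, ] + frac * (g[2L, ] - g[1L, ])
      roads[[length(roads) + 1L]] <-
        road_segment(ids[i], rbind(g[1L, ], mid), dG,
                     record_id = paste0(ids[i], "a"))
      roads[[length(roads) + 1L]] <-
        road_segment(ids[i], rbind(mid, g[2L, ]), dG,
                     record_id = paste0(ids[i], "b"))
    } else {
      dup_flag[i] <- FALSE
      roads[[length(roads) + 1L]] <- road_segment(ids[i], g, dG)
    }
  }
  meta <- data.frame(cts_id = ids, far = far_flag, crossing = cross_flag,
                     duplicated = dup_flag, stringsAsFactors = FALSE)
  list(roads = roads, buildings = buildings, road_meta = meta)
}

generate_buildings <- function(config, districts, ext) {
  n_cl <- max(1L, round(config$cluster_district_share * length(districts)))
  cluster_districts <- sample(districts, n_cl)
  centres <- t(vapply(cluster_districts, function(d) colMeans(d$geometry[[1L]]),
                      numeric(2)))
  out <- vector("list", config$n_buildings)
  for (i in seq_len(config$n_buildings)) {
    if (stats::runif(1) < config$uniform_building_share) {
      p <- c(stats::runif(1, ext[1L], ext[3L]), stats::runif(1, ext[2L], ext[4L]))
    } else {
      c0 <- centres[sample.int(nrow(centres), 1L), ]
      p <- c0 + stats::rnorm(2, 0, config$cluster_sd)
      p <- pmin(pmax(p, ext[c(1L, 2L)] + 5), ext[c(3L, 4L)] - 5)
    }
    if (stats::runif(1) < 0.2) {
      half <- stats::runif(1, 10, 25)
      g <- rbind(p + c(-half, -half), p + c(half, -half),
                 p + c(half, half), p + c(-half, half))
      g[, 1L] <- pmin(pmax(g[, 1L], ext[1L]), ext[3L])
      g[, 2L] <- pmin(pmax(g[, 2L], ext[2L]), ext[4L])
    } else {
      g <- p
    }
    out[[i]] <- building(sprintf("B%05d", i), g,
                         height = stats::runif(1, 10, 120))
  }
  out
}

# draw one road polyline meeting its placement constraints (rejection loops
# with a capped iteration count; constraints soften once the cap is hit)
draw_road <- function(config, ext, bpts, L, crossing, far, near_limit,
                      far_limit) {
  borders_x <- config$cell_m * seq_len(config$grid_nx - 1L)
  borders_y <- config$cell_m * seq_len(config$grid_ny - 1L)
  for (try in 1:200) {
    strict <- try <= 120L
    if (crossing) {
      vertical <- length(borders_x) > 0L &&
        (length(borders_y) == 0L || stats::runif(1) < 0.5)
      if (vertical) {
        bx <- sample(borders_x, 1L)
        by <- stats::runif(1, ext[2L] + 50, ext[4L] - 50)
        base_ang <- 0
      } else {
        bx <- stats::runif(1, ext[1L] + 50, ext[3L] - 50)
        by <- sample(borders_y, 1L)
        base_ang <- pi / 2
      }
      ang <- base_ang + stats::runif(1, -0.6, 0.6)
      ctr <- c(bx, by)
      p1 <- ctr - L / 2 * c(cos(ang), sin(ang))
      p2 <- ctr + L / 2 * c(cos(ang), sin(ang))
      g <- rbind(p1, p2)
    } else {
      if (far || nrow(bpts) == 0L) {
        p1 <- c(stats::runif(1, ext[1L], ext[3L]), stats::runif(1, ext[2L], ext[4L]))
      } else {
        b <- bpts[sample.int(nrow(bpts), 1L), ]
        off_ang <- stats::runif(1, 0, 2 * pi)
        p1 <- b + stats::runif(1, 0, near_limit * 0.6) * c(cos(off_ang), sin(off_ang))
      }
      ang <- stats::runif(1, 0, 2 * pi)
      # keep the whole segment inside one cell: start and end in the same cell
      p2 <- p1 + L * c(cos(ang), sin(ang))
      g <- rbind(p1, p2)
      same_cell <- all(floor(g[, 1L] / config$cell_m) == floor(g[1L, 1L] / config$cell_m)) &&
        all(floor(g[, 2L] / config$cell_m) == floor(g[1L, 2L] / config$cell_m))
      if (!same_cell) next
    }
    inside <- all(g[, 1L] >= ext[1L] & g[, 1L] <= ext[3L] &
                  g[, 2L] >= ext[2L] & g[, 2L] <= ext[4L])
    if (!inside) next
    if (nrow(bpts) > 0L && (strict || far)) {
      dmin <- min(dist_points_to_polyline(bpts, g))
      if (far && dmin <= far_limit) next
      if (!far && strict && dmin > near_limit) next
    }
    return(g)
  }
  g  # last attempt, constraints softened
}

offpeak_hours <- function() setdiff(0:23, sort(unique(unlist(PH2))))

shoulder_hours <- function() setdiff(sort(unique(unlist(PH2))), PH1)

#' Generate the hourly per-vehicle emission table
#'
#' For every road, hour, vehicle type and pollutant the original emission is
#'   EO = scale * weight(vehicle, pollutant) * diurnal(vehicle, hour)
#'        * road factor * lognormal record noise,
#' with the diurnal shape a double-peak curve (morning and evening Gaussian
#' bumps over a trough), a per-road lognormal off-peak idiosyncrasy applied
#' to hours outside both refined peak-hour windows, and a highway boost on
#' far-from-buildings roads. Taxi PM2.5 rows are absent from the table (the
#' inventory records none); heavy-goods and bus weights are 4.5x the
#' light-vehicle weights.
#'
#' @param config a \code{city_config}.
#' @param roads road list (only \code{cts_id}s are used).
#' @param road_meta optional meta data frame flagging far roads.
#' @return emission data frame with columns \code{cts_id}, \code{hour},
#'   \code{vehicle_type}, \code{pollutant}, \code{emission_g_per_km}.
#' @export
generate_emissions <- function(config, roads, road_meta = NULL) {
  ids <- unique(vapply(roads, function(r) r$cts_id, character(1)))
  nr <- length(ids)
  far <- if (is.null(road_meta)) rep(FALSE, nr) else
    road_meta$far[match(ids, road_meta$cts_id)]
  road_factor <- stats::rlnorm(nr, 0, config$road_factor_sdlog) *
    ifelse(far, config$highway_factor, 1)
  # mean-one idiosyncrasy factors: they redistribute emission across roads
  # without inflating the expected diurnal shape
  mean1 <- function(n, sdlog) stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  # night activity varies at neighbourhood level (grid cell of the road's
  # first vertex): night-active areas stay active across all their roads,
  # so off-peak emission does not average out within a district
  blk <- vapply(ids, function(id) {
    g <- roads[[match(id, vapply(roads, `[[`, character(1), "cts_id"))]]$geometry
    paste(floor(g[1L, 1L] / config$cell_m), floor(g[1L, 2L] / config$cell_m))
  }, character(1))
  ublk <- unique(blk)
  night_factor <- mean1(length(ublk), config$night_factor_sdlog)[match(blk, ublk)] *
    mean1(nr, 0.3)
  shoulder_factor <- mean1(nr, config$shoulder_factor_sdlog)
  off <- offpeak_hours()

  shape <- function(v) {
    h <- 0:23
    g <- exp(-0.5 * ((h - config$morning_peaks[[v]]) / config$peak_width)^2) +
      0.85 * exp(-0.5 * ((h - config$evening_peaks[[v]]) / config$peak_width)^2)
    1 + (config$peak_trough_ratio - 1) * g / max(g)
  }
  rows <- list()
  for (p in POLLUTANTS) {
    wts <- if (p == "NOx") config$vehicle_weights_nox else config$vehicle_weights_pm
    scale <- if (p == "NOx") config$scale_nox else config$scale_pm
    for (v in VEHICLE_TYPES) {
      if (wts[[v]] == 0) next  # absent from the source inventory
      prof <- shape(v)
      # shoulder idiosyncrasy spares hours adjacent to this vehicle's peaks,
      # which behave like the rush hours themselves
      near_peak <- c(config$morning_peaks[[v]] + (-1:1),
                     config$evening_peaks[[v]] + (-1:1))
      shl <- setdiff(shoulder_hours(), near_peak)
      base <- outer(road_factor, prof * scale * wts[[v]])  # nr x 24
      base[, off + 1L] <- base[, off + 1L] * night_factor
      base[, shl + 1L] <- base[, shl + 1L] * shoulder_factor
      noise <- matrix(mean1(nr * 24L, config$noise_sdlog), nr, 24L)
      eo <- base * noise
      rows[[length(rows) + 1L]] <- data.frame(
        cts_id = rep(ids, 24L), hour = rep(0:23, each = nr),
        vehicle_type = v, pollutant = p,
        emission_g_per_km = as.vector(eo), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate district mortality tables with a planted linear relation
#'
#' For each pollutant, the target actual rate of district d is
#'   MRA_d = alpha + beta * E_d + Normal(0, sigma),
#' floored at 0.5 per 100,000, where E_d is the district's case-4 emission
#' total. Planted outlier districts receive an additional multiplicative
#' shift. Rates are converted to four years of integer death counts
#' (consistent with district population, with small per-year jitter) and the
#' counts split over the pollutant's disease catalogue by fixed shares.
#'
#' @param config a \code{city_config}.
#' @param case4_totals data frame with columns district, pollutant,
#'   total_g_per_km (the case-4 district totals of the generated city).
#' @param districts district list (for names and populations).
#' @return mortality data frame (district, pollutant_context, year,
#'   icd_group, deaths, population) with attribute \code{"truth"}: the
#'   planted alpha/beta/sigma, outlier districts and shifts, and the exact
#'   target rates.
#' @export
generate_mortality <- function(config, case4_totals, districts) {
  dn <- vapply(districts, function(d) d$name, character(1))
  pop <- vapply(districts, function(d) d$population, numeric(1))
  out_idx <- if (config$n_outliers > 0L)
    sort(sample.int(length(dn), config$n_outliers)) else integer(0)
  shifts <- stats::setNames(rep(0, length(dn)), dn)
  if (length(out_idx)) {
    shifts[out_idx] <- rep_len(config$outlier_shifts, length(out_idx))
  }
  # NOx disease mix dominated by lung cancers; PM2.5 spread wider over the
  # larger catalogue, pneumonia heaviest
  mix <- list(
    NOx = c("A15-16" = 0.02, "C33-34" = 0.614,
            "J00-06/J30-39/J60-98" = 0.118, "J40-47" = 0.248),
    `PM2.5` = c("A15-16" = 0.005, "C33-34" = 0.186, "E10-14" = 0.07,
                "I20/I23-25" = 0.11, "I26" = 0.009, "I60-69" = 0.16,
                "J00-06/J30-39/J60-98" = 0.02, "J12-18" = 0.405,
                "J20-22" = 0.015, "J40-47" = 0.02)
  )
  rows <- list()
  truth_rates <- list()
  for (p in POLLUTANTS) {
    tp <- case4_totals[case4_totals$pollutant == p, , drop = FALSE]
    E <- stats::setNames(rep(0, length(dn)), dn)
    E[tp$district] <- tp$total_g_per_km
    beta <- if (p == "NOx") config$beta_nox else config$beta_pm
    mra <- config$alpha + beta * E + stats::rnorm(length(dn), 0, config$sigma)
    mra <- pmax(mra * (1 + shifts), 0.5)
    truth_rates[[p]] <- mra
    for (i in seq_along(dn)) {
      yr_rates <- pmax(mra[i] + stats::rnorm(length(config$years), 0,
                                             config$year_sd), 0)
      for (k in seq_along(config$years)) {
        total_deaths <- round(yr_rates[k] / 1e5 * pop[i])
        deaths <- largest_remainder(total_deaths, mix[[p]])
        rows[[length(rows) + 1L]] <- data.frame(
          district = dn[i], pollutant_context = p,
          year = config$years[k], icd_group = names(mix[[p]]),
          deaths = deaths, population = pop[i], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(
    alpha = config$alpha, beta_nox = config$beta_nox, beta_pm = config$beta_pm,
    sigma = config$sigma, outlier_districts = dn[out_idx],
    outlier_shifts = shifts[out_idx], target_rates = truth_rates)
  out
}

# deterministic integer split of `total` by `shares` (largest remainder)
largest_remainder <- function(total, shares) {
  raw <- total * shares / sum(shares)
  base <- floor(raw)
  left <- round(total - sum(base))
  if (left > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[add] <- base[add] + 1
  }
  as.numeric(base)
}

#' Generate a complete synthetic city
#'
#' Seeds the RNG from \code{config$rng_seed} (so identical configurations
#' yield identical cities), generates districts, roads, buildings and the
#' emission table, computes the case-4 district totals (geoid-length filter,
#' split, dissolve, activity-buffer road selection, refined peak hours per
#' district group), and plants the mortality tables on those totals.
#'
#' @param config a \code{city_config}.
#' @return an object of class \code{"synthetic_city"}: list with
#'   \code{config}, \code{districts}, \code{roads}, \code{buildings},
#'   \code{road_meta}, \code{emissions}, \code{mortality}, \code{truth}.
#' @export
generate_city <- function(config = city_config()) {
  set.seed(config$rng_seed)
  districts <- generate_districts(config)
  rb <- generate_roads_and_buildings(config, districts)
  emissions <- generate_emissions(config, rb$roads, rb$road_meta)
  c4 <- apportion_case_totals(rb$roads, districts, emissions,
                              case_id = 4L, buildings = rb$buildings,
                              buffer_distance = config$buffer_distance)
  mortality <- generate_mortality(config, c4$district_totals, districts)
  structure(list(config = config, districts = districts, roads = rb$roads,
                 buildings = rb$buildings, road_meta = rb$road_meta,
                 emissions = emissions, mortality = mortality,
                 truth = attr(mortality, "truth")),
            class = "synthetic_city")
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat(sprintf(
    "Synthetic city: %d districts, %d road records (%d roads), %d buildings,\n",
    length(x$districts), length(x$roads),
    length(unique(vapply(x$roads, `[[`, character(1), "cts_id"))),
    length(x$buildings)))
  cat(sprintf("  %d emission records, %d mortality rows (seed %d)\n",
              nrow(x$emissions), nrow(x$mortality), x$config$rng_seed))
  invisible(x)
}
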