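# Reading and writing the interchange formats: GeoJSON FeatureCollections
# for the three geometry layers, CSV for the emission and mortality tables.
# Coordinates are written as they are stored (planar metres); the coordinate
# frame is a property of the dataset, declared in the bundle manifest.

fc <- function(features) {
  list(type = "FeatureCollection", features = features)
}

feature <- function(geometry, properties) {
  list(type = "Feature", geometry = geometry, properties = properties)
}

close_ring <- function(ring) rbind(ring, ring[1L, , drop = FALSE])

#' Write roads to a GeoJSON file
#' @param roads list of \code{road_segment}s.
#' @param path output file.
#' @export
write_roads_geojson <- function(roads, path) {
  feats <- lapply(roads, function(r) {
    feature(list(type = "LineString", coordinates = r$geometry),
            list(CTS_ID = r$cts_id, RECORD_ID = r$record_id,
                 GEOID_LEN = r$geoid_length))
  })
  jsonlite::write_json(fc(feats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read roads from a GeoJSON file
#' @param path GeoJSON file with LineString features carrying CTS_ID and
#'   GEOID_LEN properties.
#' @return list of \code{road_segment}s.
#' @export
read_roads_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  lapply(j$features, function(f) {
    coords <- do.call(rbind, lapply(f$geometry$coordinates, unlist))
    p <- f$properties
    road_segment(p$CTS_ID, coords, p$GEOID_LEN,
                 record_id = if (is.null(p$RECORD_ID)) p$CTS_ID else p$RECORD_ID)
  })
}

#' Write districts to a GeoJSON file
#' @param districts list of \code{district}s.
#' @param path output file.
#' @export
write_districts_geojson <- function(districts, path) {
  feats <- lapply(districts, function(d) {
    feature(list(type = "Polygon",
                 coordinates = lapply(d$geometry, close_ring)),
            list(NAME = d$name, POPULATION = d$population,
                 POPULATION_PCT = d$population_pct, GROUP = d$group))
  })
  jsonlite::write_json(fc(feats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read districts from a GeoJSON file
#' @param path GeoJSON file with Polygon features carrying NAME and
#'   POPULATION properties.
#' @export
read_districts_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  lapply(j$features, function(f) {
    rings <- lapply(f$geometry$coordinates, function(ring)
      do.call(rbind, lapply(ring, unlist)))
    p <- f$properties
    district(p$NAME, rings, p$POPULATION,
             population_pct = if (is.null(p$POPULATION_PCT)) NA_real_ else
               p$POPULATION_PCT,
             group = if (is.null(p$GROUP)) NULL else p$GROUP)
  })
}

#' Write buildings to a GeoJSON file
#' @param buildings list of \code{building}s.
#' @param path output file.
#' @export
write_buildings_geojson <- function(buildings, path) {
  feats <- lapply(buildings, function(b) {
    geom <- if (nrow(b$geometry) == 1L) {
      list(type = "Point", coordinates = as.numeric(b$geometry[1L, ]))
    } else {
      list(type = "Polygon", coordinates = list(close_ring(b$geometry)))
    }
    feature(geom, list(ID = b$id, HEIGHT = b$height))
  })
  jsonlite::write_json(fc(feats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read buildings from a GeoJSON file
#' @param path GeoJSON file with Point or Polygon features.
#' @export
read_buildings_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  lapply(j$features, function(f) {
    g <- if (f$geometry$type == "Point") {
      unlist(f$geometry$coordinates)
    } else {
      do.call(rbind, lapply(f$geometry$coordinates[[1L]], unlist))
    }
    p <- f$properties
    building(p$ID, g, height = if (is.null(p$HEIGHT)) NA_real_ else p$HEIGHT)
  })
}

#' Write / read the emission table CSV
#'
#' Columns: CTS_ID, HOUR, VEHICLE_TYPE, POLLUTANT, EMISSION_G_PER_KM.
#' @param emissions emission data frame.
#' @param path CSV file.
#' @export
write_emissions <- function(emissions, path) {
  out <- data.frame(CTS_ID = emissions$cts_id, HOUR = emissions$hour,
                    VEHICLE_TYPE = emissions$vehicle_type,
                    POLLUTANT = emissions$pollutant,
                    EMISSION_G_PER_KM = emissions$emission_g_per_km)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emissions
#' @export
read_emissions <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(cts_id = as.character(x$CTS_ID), hour = as.integer(x$HOUR),
             vehicle_type = x$VEHICLE_TYPE, pollutant = x$POLLUTANT,
             emission_g_per_km = as.numeric(x$EMISSION_G_PER_KM),
             stringsAsFactors = FALSE)
}

#' Write / read the mortality table CSV
#'
#' Columns: DISTRICT, POLLUTANT_CONTEXT, YEAR, ICD_GROUP, DEATHS, POPULATION.
#' @param mortality mortality data frame.
#' @param path CSV file.
#' @export
write_mortality <- function(mortality, path) {
  out <- data.frame(DISTRICT = mortality$district,
                    POLLUTANT_CONTEXT = mortality$pollutant_context,
                    YEAR = mortality$year, ICD_GROUP = mortality$icd_group,
                    DEATHS = mortality$deaths,
                    POPULATION = mortality$population)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mortality
#' @export
read_mortality <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(district = as.character(x$DISTRICT),
             pollutant_context = x$POLLUTANT_CONTEXT,
             year = as.integer(x$YEAR), icd_group = x$ICD_GROUP,
             deaths = as.numeric(x$DEATHS),
             population = as.numeric(x$POPULATION), stringsAsFactors = FALSE)
}

#' Write a full city bundle to a directory
#'
#' Three GeoJSON layers, two CSV tables and a JSON manifest recording the
#' generating configuration and seed.
#' @param city a \code{synthetic_city} (or compatible bundle).
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_city_bundle <- function(city, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_roads_geojson(city$roads, file.path(dir, "roads.geojson"))
  write_districts_geojson(city$districts, file.path(dir, "districts.geojson"))
  write_buildings_geojson(city$buildings, file.path(dir, "buildings.geojson"))
  write_emissions(city$emissions, file.path(dir, "emissions.csv"))
  write_mortality(city$mortality, file.path(dir, "mortality.csv"))
  manifest <- list(created = "trafshed",
                   crs = "local planar metres",
                   config = unclass(city$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a city bundle from a directory
#' @param dir directory written by \code{\link{write_city_bundle}}.
#' @export
read_city_bundle <- function(dir) {
  list(roads = read_roads_geojson(file.path(dir, "roads.geojson")),
       districts = read_districts_geojson(file.path(dir, "districts.geojson")),
       buildings = read_buildings_geojson(file.path(dir, "buildings.geojson")),
       emissions = read_emissions(file.path(dir, "emissions.csv")),
       mortality = read_mortality(file.path(dir, "mortality.csv")))
}

#' Write district emission totals as CSV
#'
#' One row per (district, pollutant, vehicle type) plus a TOTAL row per
#' (district, pollutant); emissions rounded to 2 decimal places for report
#' purposes.
#' @param totals,district_totals outputs of \code{\link{district_totals}} or
#'   a \code{case_study_report}.
#' @param path CSV file.
#' @export
write_totals <- function(totals, district_totals, path) {
  a <- data.frame(DISTRICT = totals$district, POLLUTANT = totals$pollutant,
                  VEHICLE_TYPE = totals$vehicle_type,
                  EMISSION_G_PER_KM = round_report(totals$emission_g_per_km,
                                                   "emission"))
  b <- data.frame(DISTRICT = district_totals$district,
                  POLLUTANT = district_totals$pollutant,
                  VEHICLE_TYPE = "TOTAL",
                  EMISSION_G_PER_KM = round_report(district_totals$total_g_per_km,
                                                   "emission"))
  out <- rbind(a, b)
  out <- out[order(out$DISTRICT, out$POLLUTANT, out$VEHICLE_TYPE != "TOTAL",
                   out$VEHICLE_TYPE), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write the deviation analysis as CSV
#'
#' Columns DISTRICT, POLLUTANT, MRP, MRA, PD_PCT, CLASSIFICATION.
#' @param deviations the \code{deviations} element of a case-4 report.
#' @param path CSV file.
#' @export
write_deviations <- function(deviations, path) {
  rows <- lapply(deviations, function(d) {
    data.frame(DISTRICT = d$results$district, POLLUTANT = d$results$pollutant,
               MRP = round(d$results$MRP, 2), MRA = round(d$results$MRA, 2),
               PD_PCT = round(d$results$PD, 2),
               CLASSIFICATION = d$results$classification)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
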