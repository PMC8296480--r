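# Case-study orchestration: filter -> split -> dissolve -> (buffer-select)
# -> hour-filter -> district totals -> association -> (deviation analysis).

#' District emission totals for one case study
#'
#' The shared apportionment path of all case studies: strict geoid-length
#' filter (> 1 m), road-district split, dissolve, optional activity-buffer
#' road selection (case 4), then hour-filtered totals with the refined hour
#' sets applied per district group for cases 3 and 4.
#'
#' @param roads list of \code{road_segment}s.
#' @param districts list of \code{district}s (with groups assigned).
#' @param emissions emission data frame.
#' @param case_id 1..4.
#' @param buildings building list (required for case 4).
#' @param buffer_distance activity-buffer radius, metres.
#' @param min_geoid_length geoid-length threshold, metres (strict).
#' @return list with \code{totals}, \code{district_totals}, \code{portions},
#'   \code{counts} (roads in/after filter/after selection, skipped emission
#'   rows).
#' @export
apportion_case_totals <- function(roads, districts, emissions, case_id,
                                  buildings = NULL, buffer_distance = 200,
                                  min_geoid_length = 1) {
  n_in <- length(roads)
  roads <- filter_geoid_length(roads, min_geoid_length)
  n_filtered <- length(roads)
  cfg <- case_study_config(case_id)
  if (cfg$apply_buffer) {
    if (is.null(buildings)) stop("case 4 needs the building layer")
    region <- activity_region(buildings, buffer_distance)
    roads <- select_roads_in_region(roads, region)
  }
  n_selected <- length(roads)
  portions <- dissolve_records(split_roads(roads, districts))

  groups <- vapply(districts, function(d) d$group, integer(1))
  names(groups) <- vapply(districts, function(d) d$name, character(1))
  # emission rows unmatched by any portion of the considered road set
  skipped <- sum(!(emissions$cts_id %in% portions$cts_id))
  res <- list()
  for (g in 1:2) {
    dg <- names(groups)[groups == g]
    if (length(dg) == 0L) next
    pg <- portions[portions$district %in% dg, , drop = FALSE]
    tg <- district_totals(pg, emissions, hour_set(case_id, g))
    res[[length(res) + 1L]] <- tg
  }
  totals <- do.call(rbind, lapply(res, `[[`, "totals"))
  dtot <- do.call(rbind, lapply(res, `[[`, "district_totals"))
  if (!is.null(dtot)) {
    dtot <- dtot[order(dtot$district, dtot$pollutant), , drop = FALSE]
    rownames(dtot) <- NULL
  }
  list(totals = totals, district_totals = dtot, portions = portions,
       counts = c(roads_input = n_in, roads_after_length_filter = n_filtered,
                  roads_considered = n_selected,
                  roads_dropped_by_buffer = n_filtered - n_selected,
                  emission_rows_skipped = as.integer(skipped)))
}

#' Actual district mortality rates from a mortality table
#'
#' Sums deaths over the disease catalogue within each district and year,
#' then averages the per-year rates.
#'
#' @param mortality data frame with columns \code{district},
#'   \code{pollutant_context}, \code{year}, \code{icd_group}, \code{deaths},
#'   \code{population}.
#' @param pollutant "NOx" or "PM2.5".
#' @param catalogue character vector of ICD groups to include; defaults to
#'   the pollutant's catalogue.
#' @return named vector of averaged rates (per 100,000) by district.
#' @export
district_mortality_rates <- function(mortality, pollutant,
                                     catalogue = DISEASE_CATALOGUE[[pollutant]]) {
  m <- mortality[mortality$pollutant_context == pollutant &
                   mortality$icd_group %in% catalogue, , drop = FALSE]
  vapply(split(m, m$district), function(d) {
    yearly <- rowsum(d$deaths, d$year)
    pop <- d$population[match(rownames(yearly), d$year)]
    mean(mortality_rate(yearly[, 1L], pop))
  }, numeric(1))
}

#' Run one case study end-to-end
#'
#' Executes the full pipeline on a city (a \code{synthetic_city} or a list
#' with elements \code{roads}, \code{districts}, \code{buildings},
#' \code{emissions}, \code{mortality}): apportionment (see
#' \code{\link{apportion_case_totals}}), the emission-mortality regression
#' (overall and per district group) for each pollutant, and -- for case 4 --
#' the percentage-of-deviation outlier analysis with coefficients refitted
#' from this run's own overall regression.
#'
#' The pipeline itself is deterministic: identical inputs give identical
#' reports.
#'
#' @param case_id 1..4.
#' @param city the input bundle.
#' @param buffer_distance activity-buffer radius, metres.
#' @param pd_orientation PD sign convention (see
#'   \code{\link{percentage_deviation}}).
#' @param sd_divisor SD divisor of the deviation band.
#' @return object of class \code{"case_study_report"}.
#' @export
run_case_study <- function(case_id, city, buffer_distance = 200,
                           pd_orientation = "actual_high_positive",
                           sd_divisor = "n-1") {
  app <- apportion_case_totals(city$roads, city$districts, city$emissions,
                               case_id, buildings = city$buildings,
                               buffer_distance = buffer_distance)
  dn <- vapply(city$districts, function(d) d$name, character(1))
  grp <- stats::setNames(vapply(city$districts, function(d) d$group, integer(1)), dn)
  fits <- list(); deviations <- list(); tables <- list()
  for (p in POLLUTANTS) {
    mra <- district_mortality_rates(city$mortality, p)
    tp <- app$district_totals[app$district_totals$pollutant == p, , drop = FALSE]
    E <- stats::setNames(rep(0, length(dn)), dn)
    E[tp$district] <- tp$total_g_per_km
    tab <- data.frame(district = dn, pollutant = p, group = grp[dn],
                      emission_g_per_km = E[dn], MRA = mra[dn],
                      stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    tables[[p]] <- tab
    fit_all <- fit_association(tab$emission_g_per_km, tab$MRA, tab$district)
    fit_g <- lapply(1:2, function(g) {
      sub <- tab[tab$group == g, , drop = FALSE]
      if (nrow(sub) >= 3L && diff(range(sub$emission_g_per_km)) > 0) {
        fit_association(sub$emission_g_per_km, sub$MRA, sub$district)
      } else NULL
    })
    fits[[p]] <- list(overall = fit_all, group1 = fit_g[[1L]],
                      group2 = fit_g[[2L]])
    if (identical(as.integer(case_id), 4L)) {
      deviations[[p]] <- deviation_analysis(
        tab$district, tab$emission_g_per_km, tab$MRA, pollutant = p,
        coefficients = c(slope = fit_all$slope, intercept = fit_all$intercept),
        orientation = pd_orientation, sd_divisor = sd_divisor)
    }
  }
  structure(list(case_id = as.integer(case_id),
                 config = case_study_config(case_id),
                 district_table = do.call(rbind, tables),
                 totals = app$totals, district_totals = app$district_totals,
                 counts = app$counts, fits = fits, deviations = deviations,
                 buffer_distance = buffer_distance,
                 pd_orientation = pd_orientation),
            class = "case_study_report")
}

#' @export
print.case_study_report <- function(x, ...) {
  cat(sprintf("Case study %d report\n", x$case_id))
  cat(sprintf("  roads: %d input, %d after length filter, %d considered\n",
              x$counts["roads_input"], x$counts["roads_after_length_filter"],
              x$counts["roads_considered"]))
  for (p in names(x$fits)) {
    f <- x$fits[[p]]$overall
    cat(sprintf("  %s: R = %.3f, RMSE = %.2f, slope = %.4g, p = %.3g (n = %d)\n",
                p, f$pearson_R, f$RMSE, f$slope, f$p_value, f$n))
  }
  if (length(x$deviations)) {
    for (p in names(x$deviations)) {
      d <- x$deviations[[p]]
      out <- d$results[d$results$classification != "not_outlying", ]
      cat(sprintf("  %s outlying districts: %s\n", p,
                  if (nrow(out)) paste0(out$district, " (",
                                        sprintf("%+.1f%%", out$PD), ")",
                                        collapse = ", ") else "none"))
    }
  }
  invisible(x)
}

#' @export
summary.case_study_report <- function(object, ...) {
  print(object)
  cat("\nPer-district table (rounded for display):\n")
  tab <- object$district_table
  tab$emission_g_per_km <- round_report(tab$emission_g_per_km, "emission")
  tab$MRA <- round(tab$MRA, 2)
  print(tab, row.names = FALSE)
  invisible(object)
}

#' Validate an input bundle
#'
#' Schema and referential-integrity checks mirroring upstream QA/QC: road,
#' district and building geometry validity, emission hour range 0..23,
#' non-negative emissions, known vehicle types and pollutants, emission road
#' ids resolvable against the network (orphans are warnings, not errors),
#' and mortality counts/population sanity.
#'
#' @param city input bundle (as for \code{\link{run_case_study}}).
#' @return list with \code{pass} (no error-level findings),
#'   \code{findings} data frame (severity, table, row, message), and
#'   \code{orphan_count}.
#' @export
validate_inputs <- function(city) {
  findings <- list()
  note <- function(severity, table, row, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      severity = severity, table = table, row = row, message = message,
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(city$roads)) {
    r <- city$roads[[i]]
    if (!inherits(r, "road_segment")) {
      ok <- tryCatch({road_segment(r$cts_id, r$geometry, r$geoid_length); TRUE},
                     error = function(e) {note("error", "roads", i,
                                               conditionMessage(e)); FALSE})
      if (!ok) next
    }
  }
  for (i in seq_along(city$districts)) {
    d <- city$districts[[i]]
    ok <- tryCatch({validate_polygon(d$geometry); TRUE},
                   error = function(e) {note("error", "districts", i,
                                             conditionMessage(e)); FALSE})
    if (ok && d$population < 0) note("error", "districts", i,
                                     "negative population")
  }
  em <- city$emissions
  bad_hour <- which(!(em$hour %in% 0:23))
  for (i in bad_hour) note("error", "emissions", i,
                           sprintf("hour %s outside 0..23", em$hour[i]))
  bad_eo <- which(!is.finite(em$emission_g_per_km) | em$emission_g_per_km < 0)
  for (i in bad_eo) note("error", "emissions", i, "negative or non-finite emission")
  bad_v <- which(!(em$vehicle_type %in% VEHICLE_TYPES))
  for (i in bad_v) note("error", "emissions", i,
                        sprintf("unknown vehicle type '%s'", em$vehicle_type[i]))
  bad_p <- which(!(em$pollutant %in% POLLUTANTS))
  for (i in bad_p) note("error", "emissions", i,
                        sprintf("unknown pollutant '%s'", em$pollutant[i]))
  road_ids <- unique(vapply(city$roads, function(r) r$cts_id, character(1)))
  orphans <- setdiff(unique(em$cts_id), road_ids)
  orphan_count <- sum(em$cts_id %in% orphans)
  if (orphan_count > 0L) {
    note("warning", "emissions", NA_integer_,
         sprintf("%d emission rows reference %d unknown road ids",
                 orphan_count, length(orphans)))
  }
  mo <- city$mortality
  if (!is.null(mo)) {
    bad_d <- which(mo$deaths < 0)
    for (i in bad_d) note("error", "mortality", i, "negative death count")
    bad_pop <- which(mo$population <= 0)
    for (i in bad_pop) note("error", "mortality", i, "non-positive population")
  }
  findings <- if (length(findings)) do.call(rbind, findings) else
    data.frame(severity = character(), table = character(),
               row = integer(), message = character(), stringsAsFactors = FALSE)
  list(pass = !any(findings$severity == "error"), findings = findings,
       orphan_count = orphan_count)
}
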