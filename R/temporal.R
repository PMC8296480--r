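# Diurnal profiles, peak hours and the four case-study hour sets.
#
# Hours are the integer labels 0..23 of hourly bins; "5-9 am inclusive"
# means bins {5,...,9} and "2-8 pm inclusive" bins {14,...,20}.

#' The fixed first peak-hour set (PH1)
#'
#' The five busiest clock hours of the diurnal cycle: 7, 8 and 9 am plus
#' 5 and 6 pm. PH1 is a fixed definition, not re-derived from data.
#' @export
PH1 <- c(7L, 8L, 9L, 17L, 18L)

#' The refined, district-group-dependent peak-hour sets (PH2)
#'
#' Twelve hours for each residential group: 5-9 am and 2-8 pm for group 1
#' (residential) districts, 5-10 am and 2-7 pm for group 2
#' (non-residential) districts.
#' @export
PH2 <- list(`1` = c(5:9, 14:20), `2` = c(5:10, 14:19))

#' Hour set of a case study
#'
#' Case 1 uses all 24 hours; case 2 the fixed 5-hour PH1; cases 3 and 4 the
#' 12-hour PH2 set of the district group (case 4 reuses the case-3 hours and
#' differs only by the activity-buffer road selection).
#'
#' @param case_id 1, 2, 3 or 4.
#' @param group district residential group, 1 or 2 (ignored for cases 1-2).
#' @return sorted integer vector of hours.
#' @export
hour_set <- function(case_id, group = 1L) {
  if (!case_id %in% 1:4) stop("configuration error: case_id must be 1..4")
  if (!group %in% 1:2) stop("configuration error: group must be 1 or 2")
  switch(case_id, 0:23, PH1, PH2[[as.character(group)]],
         PH2[[as.character(group)]])
}

#' Case-study configuration
#'
#' @param case_id 1, 2, 3 or 4.
#' @return list with \code{case_id}, the hour sets for both district groups,
#'   and \code{apply_buffer} (TRUE only for case 4).
#' @export
case_study_config <- function(case_id) {
  list(case_id = as.integer(case_id),
       hour_set_group1 = hour_set(case_id, 1L),
       hour_set_group2 = hour_set(case_id, 2L),
       apply_buffer = identical(as.integer(case_id), 4L))
}

#' Diurnal emission profile of one vehicle type
#'
#' Sums the emission figures of all records of the given pollutant and
#' vehicle type within each hour, over all roads.
#'
#' @param emissions emission data frame.
#' @param pollutant "NOx" or "PM2.5".
#' @param vehicle_type one of \code{\link{VEHICLE_TYPES}}.
#' @return numeric vector of 24 hourly totals, names "0".."23".
#' @export
diurnal_profile <- function(emissions, pollutant, vehicle_type) {
  sel <- emissions$pollutant == pollutant & emissions$vehicle_type == vehicle_type
  v <- numeric(24)
  names(v) <- as.character(0:23)
  if (any(sel)) {
    s <- rowsum(emissions$emission_g_per_km[sel],
                as.character(emissions$hour[sel]))
    v[rownames(s)] <- s[, 1L]
  }
  v
}

#' Peak hour of a diurnal profile
#'
#' Hour with the maximum total; ties are broken deterministically by the
#' earliest hour.
#' @param profile numeric vector of 24 hourly totals.
#' @return integer hour in 0..23.
#' @export
find_peak_hour <- function(profile) {
  if (length(profile) != 24L) stop("profile must have 24 hourly values")
  if (all(profile == 0)) stop("no peak: profile is all zero")
  as.integer(which.max(profile) - 1L)
}

#' Filter an emission table to a set of hours
#'
#' @param emissions emission data frame.
#' @param hours integer hours to keep.
#' @export
filter_by_hours <- function(emissions, hours) {
  emissions[emissions$hour %in% hours, , drop = FALSE]
}
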