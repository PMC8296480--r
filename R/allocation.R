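# Emission apportionment: along-road interpolation, length-ratio allocation
# and district totals.
#
# Emission tables are plain data frames with columns
#   cts_id, hour (0-23), vehicle_type, pollutant ("NOx"/"PM2.5"),
#   emission_g_per_km (the original per-road figure EO)
# matching the CSV schema read by read_emissions().

#' The eight vehicle-type labels of the emission inventory
#' @export
VEHICLE_TYPES <- c("private car", "taxi", "SPB", "LV", "LGV",
                   "MGV+HGV", "PLB", "bus")

#' Pollutant labels
#' @export
POLLUTANTS <- c("NOx", "PM2.5")

#' Inverse-distance-weighted value between two points on a road
#'
#' Linear interpolation of an emission value at a position Y lying between
#' two positions X and Z with known values, weighted by the distances
#' d1 = |XY| and d2 = |YZ|:
#'   EY = (EX * d2 + EZ * d1) / (d1 + d2).
#' Under the uniform-distribution assumption the allocation pipeline itself
#' uses pure length-ratio apportionment; this utility is the along-line
#' estimator for point values.
#'
#' @param EX,EZ values at the end positions (g/km).
#' @param d1,d2 distances from Y to X and Z respectively, metres, not both 0.
#' @return interpolated value EY, always between EX and EZ.
#' @export
idw_interpolate <- function(EX, EZ, d1, d2) {
  if (any(d1 < 0) || any(d2 < 0)) stop("distances must be non-negative")
  if (any(d1 + d2 == 0)) stop("degenerate interval: d1 + d2 must be positive")
  (EX * d2 + EZ * d1) / (d1 + d2)
}

#' Length ratio of a road portion
#'
#' R = dA / dG: clipped planar length over source geoid length. Returned at
#' full precision; reports round to 4 decimal places (see
#' \code{\link{round_report}}).
#'
#' @param dA actual (clipped) length, metres, >= 0.
#' @param dG geoid length, metres, > 0.
#' @export
length_ratio <- function(dA, dG) {
  if (any(dG <= 0)) stop("invalid denominator: geoid length dG must be > 0")
  if (any(dA < 0)) stop("dA must be >= 0")
  dA / dG
}

#' Adjusted portion emission
#'
#' EA = R * EO: the share of a road's emission attributed to one district.
#' Full precision internally; reporting rounds to 2 decimal places.
#'
#' @param EO original road emission, g/km, >= 0.
#' @param R length ratio in [0, 1] (a small tolerance absorbs float error).
#' @param tol tolerance on the upper bound of R.
#' @export
adjust_emission <- function(EO, R, tol = 1e-9) {
  if (any(EO < 0)) stop("EO must be >= 0")
  if (any(R < 0) || any(R > 1 + tol)) stop("R must lie in [0, 1]")
  R * EO
}

#' Rounding conventions for reported tables
#'
#' Lengths and ratios are reported to 4 decimal places, emissions to 2; all
#' internal arithmetic stays at full precision (rounding a ratio before
#' multiplying would corrupt the reported portion emissions).
#' @param x numeric vector.
#' @param what one of "ratio", "length" (4 dp) or "emission" (2 dp).
#' @export
round_report <- function(x, what = c("ratio", "length", "emission")) {
  what <- match.arg(what)
  round(x, if (what == "emission") 2L else 4L)
}

#' District emission totals over a set of hours
#'
#' Joins an emission table with dissolved road portions and accumulates, for
#' every district and pollutant, the per-vehicle totals
#'   EVi = sum over roads j of R_{j,district} * EO_{j,Vi,hour}
#' restricted to hours in \code{hour_set}, and the grand total
#'   E = sum over the eight vehicle types of EVi.
#' Hourly records are summed (period totals), never averaged. Emission rows
#' whose \code{cts_id} matches no portion are skipped and counted.
#'
#' @param portions dissolved portion data frame
#'   (\code{\link{dissolve_records}}).
#' @param emissions emission data frame (see module header).
#' @param hour_set integer hours in 0..23 to include.
#' @return a list with \code{totals} (data frame: district, pollutant,
#'   vehicle_type, emission_g_per_km), \code{district_totals} (data frame:
#'   district, pollutant, total_g_per_km), and \code{skipped} (count of
#'   unmatched emission rows).
#' @export
district_totals <- function(portions, emissions, hour_set = 0:23) {
  if (!all(hour_set %in% 0:23)) stop("hour_set must lie within 0..23")
  em <- emissions[emissions$hour %in% hour_set, , drop = FALSE]
  known <- em$cts_id %in% portions$cts_id
  skipped <- sum(!known)
  em <- em[known, , drop = FALSE]
  if (nrow(em) == 0L || nrow(portions) == 0L) {
    totals <- data.frame(district = character(), pollutant = character(),
                         vehicle_type = character(),
                         emission_g_per_km = numeric(),
                         stringsAsFactors = FALSE)
    dt <- data.frame(district = character(), pollutant = character(),
                     total_g_per_km = numeric(), stringsAsFactors = FALSE)
    return(list(totals = totals, district_totals = dt, skipped = skipped))
  }
  # expand: each emission row contributes R * EO to every portion of its road
  pidx <- split(seq_len(nrow(portions)), portions$cts_id)
  reps <- lengths(pidx)[em$cts_id]
  ei <- rep(seq_len(nrow(em)), reps)
  pi <- unlist(pidx[em$cts_id], use.names = FALSE)
  ea <- portions$ratio_R[pi] * em$emission_g_per_km[ei]
  key <- paste(portions$district[pi], em$pollutant[ei], em$vehicle_type[ei],
               sep = "\r")
  agg <- rowsum(ea, key)
  parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  totals <- data.frame(district = parts[, 1L], pollutant = parts[, 2L],
                       vehicle_type = parts[, 3L],
                       emission_g_per_km = as.numeric(agg[, 1L]),
                       stringsAsFactors = FALSE)
  totals <- totals[order(totals$district, totals$pollutant, totals$vehicle_type), ]
  rownames(totals) <- NULL
  dkey <- paste(totals$district, totals$pollutant, sep = "\r")
  dagg <- rowsum(totals$emission_g_per_km, dkey)
  dparts <- do.call(rbind, strsplit(rownames(dagg), "\r", fixed = TRUE))
  dt <- data.frame(district = dparts[, 1L], pollutant = dparts[, 2L],
                   total_g_per_km = as.numeric(dagg[, 1L]),
                   stringsAsFactors = FALSE)
  dt <- dt[order(dt$district, dt$pollutant), ]
  rownames(dt) <- NULL
  list(totals = totals, district_totals = dt, skipped = skipped)
}
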