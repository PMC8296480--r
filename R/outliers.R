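# Percentage-of-deviation outlier detection against the case-4 regression.

#' Reference prediction coefficients
#'
#' Published slope/intercept pairs of the case-4 best-fit lines
#' (mortality per 100,000 vs district emission total in g/km); used as
#' defaults by \code{\link{predict_mortality}} when no refitted coefficients
#' are supplied. On any new dataset the pipeline refits these from its own
#' case-4 regression.
#' @export
DEFAULT_MRP_COEF <- list(
  NOx = c(slope = 3.23e-8, intercept = 62.43),
  `PM2.5` = c(slope = 2.79e-6, intercept = 226.32)
)

#' Predicted mortality rate (MRP) from an emission total
#'
#' MRP = slope * E + intercept.
#'
#' @param E district emission total, g/km, >= 0.
#' @param pollutant "NOx" or "PM2.5" (selects the default coefficients).
#' @param coefficients named vector \code{c(slope=, intercept=)}; defaults to
#'   \code{DEFAULT_MRP_COEF[[pollutant]]}.
#' @return predicted rate per 100,000 (vectorised in \code{E}).
#' @export
predict_mortality <- function(E, pollutant = c("NOx", "PM2.5"),
                              coefficients = NULL) {
  pollutant <- match.arg(pollutant)
  if (is.null(coefficients)) coefficients <- DEFAULT_MRP_COEF[[pollutant]]
  if (any(E < 0)) stop("emission total must be >= 0")
  unname(coefficients["slope"] * E + coefficients["intercept"])
}

#' Percentage of deviation between predicted and actual mortality (PD)
#'
#' Relative gap between the predicted rate MRP and the actual rate MRA, in
#' percent of MRA. Two orientations are supported and the choice is explicit
#' because the two conventions circulate with opposite signs:
#' \describe{
#'   \item{"actual_high_positive" (default)}{PD = (MRA - MRP) / MRA * 100;
#'     positive when actual mortality exceeds the prediction.}
#'   \item{"predicted_high_positive"}{PD = (MRP - MRA) / MRA * 100; the
#'     literal reading of the defining formula.}
#' }
#' Classification downstream is semantic (which rate exceeds which), so the
#' orientation only flips signs, never labels.
#'
#' @param MRP predicted rate per 100,000.
#' @param MRA actual rate per 100,000, > 0.
#' @param orientation sign convention, see above.
#' @return PD in percent (vectorised).
#' @export
percentage_deviation <- function(MRP, MRA,
                                 orientation = c("actual_high_positive",
                                                 "predicted_high_positive")) {
  orientation <- match.arg(orientation)
  if (any(MRA <= 0)) stop("actual mortality rate must be > 0")
  pd <- (MRP - MRA) / MRA * 100
  if (orientation == "actual_high_positive") -pd else pd
}

#' Mean +/- 1 SD thresholds on the percentage deviations
#'
#' PDA is the mean PD over the districts and SD its standard deviation
#' (sample, divisor N-1, by default: the districts are treated as a
#' statistical sample); the non-outlying band is [PDA - SD, PDA + SD].
#'
#' @param PDs numeric vector of percentage deviations (N >= 2).
#' @param sd_divisor "n-1" (default) or "n".
#' @return list with \code{PDA}, \code{SD}, \code{lower}, \code{upper},
#'   \code{N}, class \code{"deviation_thresholds"}.
#' @export
deviation_thresholds <- function(PDs, sd_divisor = c("n-1", "n")) {
  sd_divisor <- match.arg(sd_divisor)
  N <- length(PDs)
  if (N < 2L) stop("insufficient data: need at least 2 deviations")
  PDA <- mean(PDs)
  SD <- if (sd_divisor == "n-1") stats::sd(PDs) else
    sqrt(mean((PDs - PDA)^2))
  structure(list(PDA = PDA, SD = SD, lower = PDA - SD, upper = PDA + SD,
                 N = N, sd_divisor = sd_divisor),
            class = "deviation_thresholds")
}

#' @export
print.deviation_thresholds <- function(x, ...) {
  cat(sprintf(
    "PD thresholds (N = %d): PDA = %.2f%%, SD = %.2f%%, band [%.2f%%, %.2f%%]\n",
    x$N, x$PDA, x$SD, x$lower, x$upper))
  invisible(x)
}

#' Classify outlying districts by the PD band
#'
#' A district is outlying iff its PD lies outside the closed band
#' [PDA - SD, PDA + SD] (closed endpoints, so an all-equal sample with
#' SD = 0 yields no outliers). Outlying districts are labelled by which rate
#' exceeds which: \code{"mortality_exceeds_prediction"} (MRA > MRP) or
#' \code{"prediction_exceeds_mortality"} (MRP > MRA); all others are
#' \code{"not_outlying"}.
#'
#' @param results data frame with columns \code{district}, \code{MRP},
#'   \code{MRA}, \code{PD}.
#' @param thresholds a \code{deviation_thresholds} object computed from the
#'   same PDs.
#' @return the input with an added \code{classification} column.
#' @export
classify_outliers <- function(results, thresholds) {
  outside <- results$PD < thresholds$lower | results$PD > thresholds$upper
  results$classification <- ifelse(
    !outside, "not_outlying",
    ifelse(results$MRA > results$MRP, "mortality_exceeds_prediction",
           "prediction_exceeds_mortality"))
  results
}

#' Full deviation analysis for one pollutant
#'
#' Computes MRP from the supplied coefficients, PDs, the mean +/- 1 SD band
#' and the outlier classification in one step.
#'
#' @param district district names.
#' @param E emission totals (g/km).
#' @param MRA actual mortality rates (per 100,000).
#' @param pollutant "NOx" or "PM2.5".
#' @param coefficients slope/intercept; defaults per pollutant.
#' @param orientation PD sign convention (see
#'   \code{\link{percentage_deviation}}).
#' @param sd_divisor SD divisor for the band.
#' @return list with \code{results} (classified data frame) and
#'   \code{thresholds}.
#' @export
deviation_analysis <- function(district, E, MRA, pollutant = c("NOx", "PM2.5"),
                               coefficients = NULL,
                               orientation = "actual_high_positive",
                               sd_divisor = "n-1") {
  pollutant <- match.arg(pollutant)
  MRP <- predict_mortality(E, pollutant, coefficients)
  PD <- percentage_deviation(MRP, MRA, orientation)
  res <- data.frame(district = as.character(district), pollutant = pollutant,
                    MRP = MRP, MRA = MRA, PD = PD, stringsAsFactors = FALSE)
  th <- deviation_thresholds(PD, sd_divisor)
  list(results = classify_outliers(res, th), thresholds = th)
}
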