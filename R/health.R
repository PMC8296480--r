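# Mortality rates, district grouping, and the emission-mortality
# least-squares association.

#' Disease catalogues (ICD-10 groups) per pollutant context
#'
#' The groups whose death counts enter the mortality rate for each pollutant.
#' The NOx catalogue covers respiratory tuberculosis, lung/trachea/bronchus
#' cancers, remaining respiratory diseases and chronic lower respiratory
#' diseases; the PM2.5 catalogue adds diabetes, ischaemic heart disease,
#' pulmonary embolism, cerebrovascular diseases, pneumonia and other acute
#' lower respiratory infections.
#' @export
DISEASE_CATALOGUE <- list(
  NOx = c("A15-16", "C33-34", "J00-06/J30-39/J60-98", "J40-47"),
  `PM2.5` = c("A15-16", "C33-34", "E10-14", "I20/I23-25", "I26", "I60-69",
              "J00-06/J30-39/J60-98", "J12-18", "J20-22", "J40-47")
)

#' Mortality rate per 100,000 population
#'
#' @param deaths death count (>= 0).
#' @param population resident count (> 0).
#' @return deaths / population * 100000.
#' @export
mortality_rate <- function(deaths, population) {
  if (any(population <= 0)) stop("population must be > 0")
  if (any(deaths < 0)) stop("deaths must be >= 0")
  deaths / population * 1e5
}

#' Averaged mortality rate over the available years (MRA)
#'
#' Arithmetic mean of the per-year rates (each year's deaths over that year's
#' population), not the pooled-count rate. Deaths across the disease
#' catalogue are summed within each year before the rate is taken.
#'
#' @param yearly_deaths named numeric vector of per-year death counts (counts
#'   already aggregated over the disease catalogue), or a data frame with
#'   columns \code{year} and \code{deaths} (rows per ICD group are summed
#'   within year).
#' @param population population count (single value, or named per-year
#'   vector aligned with the years).
#' @return averaged rate per 100,000.
#' @export
averaged_rate <- function(yearly_deaths, population) {
  if (is.data.frame(yearly_deaths)) {
    s <- rowsum(yearly_deaths$deaths, yearly_deaths$year)
    yearly_deaths <- stats::setNames(as.numeric(s[, 1L]), rownames(s))
  }
  if (length(yearly_deaths) == 0L) stop("empty data: no years present")
  if (length(population) > 1L) {
    population <- population[names(yearly_deaths)]
  }
  mean(mortality_rate(yearly_deaths, population))
}

#' Residential-group classification of a district
#'
#' Group 1 (residential) iff the district holds 6\% or more of the city
#' population; otherwise group 2 (non-residential). The 6\% threshold is
#' inclusive.
#' @param population_pct percentage of city total, in [0, 100].
#' @return integer 1 or 2 (vectorised).
#' @export
classify_group <- function(population_pct) {
  if (any(population_pct < 0 | population_pct > 100)) {
    stop("population_pct must lie in [0, 100]")
  }
  ifelse(population_pct >= 6, 1L, 2L)
}

#' Least-squares association between district emissions and mortality
#'
#' Ordinary least squares of the district mortality rate (per 100,000) on the
#' district emission total (g/km), with the summaries used for model
#' comparison: Pearson correlation R, root-mean-square error of the fit
#' (divisor n by default -- a descriptive error, not an unbiased sigma
#' estimate), and the two-sided p-value of the zero-slope test.
#'
#' @param x district emission totals (g/km).
#' @param y district mortality rates (per 100,000).
#' @param names optional district names for the observations.
#' @param rmse_divisor "n" (default) or "n-2".
#' @return an object of class \code{"em_fit"}: list with \code{slope},
#'   \code{intercept}, \code{pearson_R}, \code{RMSE}, \code{p_value},
#'   \code{n}, \code{slope_se}, the underlying \code{lm} fit and the data.
#' @examples
#' f <- fit_association(1:5, 2 * (1:5) + 1)
#' coef(f)        # intercept 1, slope 2
#' f$pearson_R    # 1
#' @export
fit_association <- function(x, y, names = NULL, rmse_divisor = c("n", "n-2")) {
  rmse_divisor <- match.arg(rmse_divisor)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (!is.null(names)) names <- names[ok]
  n <- length(x)
  if (n < 2L) stop("insufficient data: need at least 2 districts")
  if (diff(range(x)) == 0) stop("degenerate predictor: emission totals are constant")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits warn about perfection
  res <- stats::residuals(fit)
  div <- if (rmse_divisor == "n") n else max(n - 2L, 1L)
  p <- if (n >= 3L) sm$coefficients["x", "Pr(>|t|)"] else NA_real_
  structure(list(
    slope = unname(stats::coef(fit)["x"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    pearson_R = stats::cor(x, y),
    RMSE = sqrt(sum(res^2) / div),
    p_value = unname(p),
    slope_se = unname(sm$coefficients["x", "Std. Error"]),
    n = n, lm = fit,
    data = data.frame(name = if (is.null(names)) as.character(seq_len(n)) else
      as.character(names), x = x, y = y, stringsAsFactors = FALSE),
    rmse_divisor = rmse_divisor
  ), class = "em_fit")
}

#' @export
print.em_fit <- function(x, ...) {
  cat("Emission-mortality least-squares association\n")
  cat(sprintf("  n = %d districts\n", x$n))
  cat(sprintf("  mortality = %.6g * emission + %.6g\n", x$slope, x$intercept))
  cat(sprintf("  Pearson R = %.3f   RMSE = %.3f   p = %.4g\n",
              x$pearson_R, x$RMSE, x$p_value))
  invisible(x)
}

#' @export
summary.em_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying linear model:\n")
  print(summary(object$lm)$coefficients)
  invisible(object)
}

#' @export
coef.em_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict mortality rates from emission totals
#' @param object an \code{em_fit}.
#' @param newdata numeric emission totals (g/km); defaults to the fitted data.
#' @param ... unused.
#' @export
predict.em_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data$x
  object$intercept + object$slope * as.numeric(newdata)
}

#' @export
residuals.em_fit <- function(object, ...) {
  stats::setNames(object$data$y - predict(object), object$data$name)
}

#' Confidence interval for the slope
#' @param object an \code{em_fit}.
#' @param parm ignored (slope only).
#' @param level confidence level.
#' @param ... unused.
#' @export
confint.em_fit <- function(object, parm = "slope", level = 0.95, ...) {
  ci <- stats::confint(object$lm, "x", level = level)
  stats::setNames(as.numeric(ci), c("lower", "upper"))
}

#' Scatter plot of the association with the best-fit line
#' @param x an \code{em_fit}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.em_fit <- function(x, ...) {
  graphics::plot(x$data$x, x$data$y,
                 xlab = "district emission total (g/km)",
                 ylab = "mortality rate (per 100,000)", ...)
  graphics::abline(x$intercept, x$slope, col = "deeppink", lwd = 2)
  invisible(x)
}
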