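#' @include AllClasses.R
NULL

#' Daily weight change from baseline
#'
#' delta(d) = weight(d) - baseline, in grams; the withdrawal weight (one
#' week after the last injection) is handled the same way.
#'
#' @param baseline_g Baseline body weight (grams, > 0).
#' @param daily_g Numeric vector of daily weights (grams).
#' @return Numeric vector of daily changes (grams).
#' @export
weightChangeSeries <- function(baseline_g, daily_g) {
  stopifnot(baseline_g > 0, all(daily_g > 0))
  daily_g - baseline_g
}

#' Coefficient of variation (percent)
#'
#' CV = SD / |mean| x 100. Either raw values (sample SD, n - 1
#' denominator) or a precomputed (mean, sd) pair can be supplied. Several
#' treatment groups have negative mean weight change, so the absolute mean
#' is used, keeping the CV positive.
#'
#' @param values Numeric vector (n >= 2), or NULL when mean/sd are given.
#' @param mean,sd Precomputed summary statistics.
#' @return CV in percent.
#' @export
coefficientOfVariation <- function(values = NULL, mean = NULL, sd = NULL) {
  if (!is.null(values)) {
    stopifnot(length(values) >= 2L)
    mean <- base::mean(values)
    sd <- stats::sd(values)
  }
  if (is.null(mean) || is.null(sd))
    stop("supply either values or both mean and sd")
  if (mean == 0) stop("undefined CV: mean is zero")
  sd / abs(mean) * 100
}

#' High-fat-diet preference index
#'
#' preference = hfd / (hfd + chow), in [0, 1]; 0.5 indicates indifference.
#' Zero total intake yields NA (undefined preference).
#'
#' @param hfd_g High-fat-diet intake (grams, >= 0).
#' @param chow_g Chow intake (grams, >= 0).
#' @return Preference index, or NA when total intake is zero.
#' @export
hfdPreference <- function(hfd_g, chow_g) {
  stopifnot(all(hfd_g >= 0), all(chow_g >= 0))
  total <- hfd_g + chow_g
  ifelse(total > 0, hfd_g / total, NA_real_)
}

#' Pearson correlation between daily stereotypy and locomotion
#'
#' The characteristic signature of sensitization: the fraction of time in
#' stereotypy rises across treatment days while locomotion falls, giving a
#' strongly negative Pearson r on the paired daily means.
#'
#' @param daily_stereotypy,daily_locomotion Equal-length numeric vectors
#'   (>= 3 days) of daily mean occupancy fractions.
#' @return Pearson r, or NA when either series has zero variance.
#' @export
behaviorCorrelation <- function(daily_stereotypy, daily_locomotion) {
  stopifnot(length(daily_stereotypy) == length(daily_locomotion),
            length(daily_stereotypy) >= 3L)
  if (stats::sd(daily_stereotypy) == 0 || stats::sd(daily_locomotion) == 0)
    return(NA_real_)
  stats::cor(daily_stereotypy, daily_locomotion)
}

#' Bundled weight-change summary table
#'
#' Per-drug, per-sex mean and SD of the 7-day weight change (grams) with
#' the published CV column, transcribed from the study's summary table.
#'
#' @return data.frame with columns drug, sex, mean_g, sd_g,
#'   cv_printed_pct.
#' @export
weightChangeTable <- function() {
  utils::read.csv(system.file("extdata", "weight_change_summary.csv",
                              package = "PoseEthogram"),
                  stringsAsFactors = FALSE)
}

#' Bundled 4-hour food intake table
#'
#' Per-drug, per-sex HFD and chow intake (grams over 4 h) with the
#' published preference index. \code{preference_consistent} marks the
#' cells where the aggregate formula hfd/(hfd+chow) reproduces the printed
#' index to within 0.015 (all female cells and two male cells); the
#' remaining male cells were most likely computed per day and then
#' averaged from unpublished per-day intakes, and are flagged rather than
#' reproduced.
#'
#' @return data.frame with columns drug, sex, hfd_g, chow_g, total_g,
#'   total_sem_g, preference_printed, preference_consistent.
#' @export
intakeTable <- function() {
  utils::read.csv(system.file("extdata", "intake_summary.csv",
                              package = "PoseEthogram"),
                  stringsAsFactors = FALSE)
}

#' CV agreement bounds under printed rounding
#'
#' The summary table prints mean and SD to two decimals; the implied CV is
#' therefore only known to within the interval obtained by perturbing mean
#' and SD by +/- 0.005. Used to check recomputed CVs against the printed
#' column without overstating the available precision.
#'
#' @param mean_g,sd_g Printed mean and SD (grams).
#' @param digits Decimals the table prints, default 2.
#' @return Numeric c(lower, upper) CV bounds in percent.
#' @export
cvRoundingBounds <- function(mean_g, sd_g, digits = 2) {
  h <- 0.5 * 10^(-digits)
  am <- abs(mean_g)
  c(lower = (sd_g - h) / (am + h) * 100,
    upper = (sd_g + h) / max(am - h, .Machine$double.eps) * 100)
}
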