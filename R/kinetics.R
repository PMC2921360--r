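# Activity-rate, specific-activity, inhibition and inactivation-kinetics
# computations for fluorogenic proteinase assays.

#' Initial hydrolysis rate from a fluorescence time course
#'
#' Least-squares slope of fluorescence (RFU) against time (min) over the
#' supplied window; a negative slope is clamped to zero with a warning
#' (fluorescence release cannot be negative).
#'
#' @param times Time points in minutes (>= 3).
#' @param rfu Fluorescence readings.
#' @return Initial rate in RFU/min.
#' @export
hydrolysis_rate <- function(times, rfu) {
  stopifnot(length(times) == length(rfu))
  if (length(times) < 3L)
    stop("need at least 3 points for a rate", call. = FALSE)
  slope <- unname(stats::coef(stats::lm(rfu ~ times))[2])
  if (is.na(slope)) slope <- 0
  if (abs(slope) < 1e-12) slope <- 0  # constant series, up to rounding
  if (slope < 0) {
    warning("negative slope clamped to 0 RFU/min")
    slope <- 0
  }
  slope
}

#' Specific activity and fold ratio
#'
#' `specific_activity()` normalizes a rate to protein amount (RFU/min/mg).
#' `fold_ratio()` compares two activities; with `report_mode = "order"` the
#' ratio is rounded to the nearest ten, the resolution at which order-of-
#' magnitude statements ("40 times lower") are made.
#'
#' @param rate Activity in RFU/min.
#' @param protein_mg Protein amount in mg (> 0).
#' @return `specific_activity()`: RFU/min/mg. `fold_ratio()`: dimensionless
#'   ratio `a / b`.
#' @examples
#' fold_ratio(5471, 141, report_mode = "order")  # 40
#' @export
specific_activity <- function(rate, protein_mg) {
  if (any(protein_mg <= 0)) stop("protein amount must be > 0", call. = FALSE)
  rate / protein_mg
}

#' @rdname specific_activity
#' @param a,b Activities to compare (ratio `a / b`).
#' @param report_mode `"exact"` (default) or `"order"` (nearest ten).
#' @export
fold_ratio <- function(a, b, report_mode = c("exact", "order")) {
  report_mode <- match.arg(report_mode)
  if (any(b <= 0)) stop("denominator activity must be > 0", call. = FALSE)
  r <- a / b
  if (report_mode == "order") r <- round(r / 10) * 10
  r
}

#' Compare control and treated replicate activities
#'
#' Percent inhibition from arm means, with a Welch two-sample t-test (the
#' unequal-variance form of Student's t) and a significance flag at
#' p <= 0.05.
#'
#' @param control,treated Numeric replicate activities (>= 2 each).
#' @param alpha Significance level (default 0.05).
#' @return A list of class `activity_comparison`: means, SEMs, ns,
#'   `percent_inhibition`, `p_value`, `significant`.
#' @export
inhibition <- function(control, treated, alpha = 0.05) {
  if (length(control) < 2L || length(treated) < 2L)
    stop("need >= 2 replicates per arm", call. = FALSE)
  mean_a <- mean(control); mean_b <- mean(treated)
  pct <- if (mean_a > 0) (1 - mean_b / mean_a) * 100 else NA_real_
  if (is.na(pct)) warning("control mean is 0; percent inhibition undefined")
  p <- if (stats::sd(control) == 0 && stats::sd(treated) == 0) {
    if (mean_a == mean_b) 1 else 0
  } else stats::t.test(control, treated, var.equal = FALSE)$p.value
  structure(list(
    mean_a = mean_a, sem_a = stats::sd(control) / sqrt(length(control)),
    n_a = length(control),
    mean_b = mean_b, sem_b = stats::sd(treated) / sqrt(length(treated)),
    n_b = length(treated),
    percent_inhibition = pct, p_value = p,
    significant = !is.na(p) && p <= alpha
  ), class = "activity_comparison")
}

#' @export
print.activity_comparison <- function(x, ...) {
  cat(sprintf(
    "<activity comparison> %.1f +/- %.1f (n=%d) vs %.1f +/- %.1f (n=%d): %.1f%% inhibition, p = %.3g%s\n",
    x$mean_a, x$sem_a, x$n_a, x$mean_b, x$sem_b, x$n_b,
    x$percent_inhibition, x$p_value,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Fit apparent first-order inactivation
#'
#' Linear regression of log(activity) on time: under apparent first-order
#' kinetics activity decays as `A0 * exp(-k1 * t)`, so ln(activity) falls
#' on a straight line with slope `-k1`. The half-life is `ln 2 / k1`.
#' Non-positive activity readings cannot enter the log fit and are dropped
#' with a warning. The inactivation constant is held per minute (half-lives
#' are conventionally quoted in minutes); the per-second value is also
#' reported.
#'
#' @param times Time points in minutes.
#' @param activity Remaining activities (RFU/min or % of initial), >= 3
#'   positive values.
#' @return An object of class `kinetic_fit`: `k1_per_min`, `k1_per_sec`,
#'   `half_life_min` (`Inf` when `k1 <= 0`), `r_squared`, `n_points`,
#'   `n_dropped`.
#' @examples
#' t <- seq(0, 14, by = 2)
#' fit_inactivation(t, 100 * exp(-log(2) / 8 * t))$half_life_min  # 8
#' @export
fit_inactivation <- function(times, activity) {
  stopifnot(length(times) == length(activity))
  keep <- activity > 0
  if (any(!keep))
    warning(sum(!keep), " non-positive activity value(s) excluded from log fit")
  times <- times[keep]; activity <- activity[keep]
  if (length(times) < 3L)
    stop("need at least 3 positive activity values", call. = FALSE)
  fit <- stats::lm(log(activity) ~ times)
  slope <- unname(stats::coef(fit)[2])
  k1 <- -slope
  ss_tot <- sum((log(activity) - mean(log(activity)))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(
    k1_per_min = k1,
    k1_per_sec = k1 / 60,
    half_life_min = if (k1 > 0) log(2) / k1 else Inf,
    r_squared = r2,
    n_points = length(times),
    n_dropped = sum(!keep)
  ), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic fit> k1 = %.4g min^-1 (%.4g s^-1), half-life %.3g min, R^2 = %.4f (n = %d)\n",
    x$k1_per_min, x$k1_per_sec, x$half_life_min, x$r_squared, x$n_points))
  invisible(x)
}

#' pH-activity profile summary
#'
#' Reports the optimum pH (ties reported as a range) and the activity curve
#' normalized to percent of maximum.
#'
#' @param ph pH values.
#' @param activity Activities at each pH.
#' @return A list: `optimum` (single pH, or `c(lo, hi)` range on ties),
#'   `curve` (data frame `ph`, `activity`, `percent`), `degenerate`
#'   (`TRUE` when only one point was supplied).
#' @examples
#' ph_profile(c(3.5, 4.5, 5.5), c(40, 100, 60))$optimum  # 4.5
#' @export
ph_profile <- function(ph, activity) {
  stopifnot(length(ph) == length(activity))
  if (!length(ph)) stop("empty pH profile", call. = FALSE)
  o <- order(ph)
  ph <- ph[o]; activity <- activity[o]
  mx <- max(activity)
  at_max <- ph[activity == mx]
  optimum <- if (length(at_max) == 1L) at_max else range(at_max)
  list(
    optimum = optimum,
    curve = data.frame(ph = ph, activity = activity,
                       percent = 100 * activity / mx),
    degenerate = length(ph) == 1L
  )
}
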