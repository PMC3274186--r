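#' Daily calorie bands by activity class
#'
#' The three activity classes and their kcal/day-per-kg bands used to turn
#' a rounded standard weight into a daily calorie target: light 25--30,
#' normal 30--35, hard 35--40.
#'
#' @return A data frame with columns `activity`, `low`, `high`.
#' @export
#' @examples
#' activity_bands()
activity_bands <- function() {
  data.frame(activity = c("light", "normal", "hard"),
             low = c(25, 30, 35), high = c(30, 35, 40))
}

#' Standard weight from height
#'
#' Computes the standard (reference) weight as height squared times a
#' sex-specific factor: 21 for women, by convention 22 for men. For a
#' 1.65 m woman this gives 1.65^2 x 21 = 57.1725 kg, unrounded.
#'
#' The male factor is an extrapolation: the classical worked example uses
#' only the female constant, and 22 is the conventional companion value
#' for this standard-weight formula. It can be overridden via `factors`.
#'
#' @param height Height in meters, > 0.
#' @param sex `"female"` or `"male"`.
#' @param factors Named numeric vector of per-sex factors.
#' @return Standard weight in kg, unrounded.
#' @export
#' @examples
#' standard_weight(1.65, "female")  # 57.1725
standard_weight <- function(height, sex = c("female", "male"),
                            factors = c(female = 21, male = 22)) {
  sex <- match.arg(sex)
  if (!is.numeric(height) || any(height <= 0))
    stop("height must be a positive number of meters")
  height^2 * factors[[sex]]
}

#' Round a standard weight up to whole kilograms
#'
#' The daily calorie target is computed from the standard weight rounded
#' up to the next whole kilogram (57.1725 kg is treated as "about 58 kg").
#'
#' @param weight Standard weight in kg, > 0.
#' @return Integer kilograms.
#' @export
#' @examples
#' round_standard_weight(57.1725)  # 58
round_standard_weight <- function(weight) {
  if (!is.numeric(weight) || any(weight <= 0))
    stop("weight must be positive")
  ceiling(weight)
}

#' Daily calorie target from weight and activity class
#'
#' Multiplies the rounded standard weight by the kcal/day-per-kg rate of
#' the activity band. Each band is a range (e.g. 25--30 for light
#' activity); `band_point` selects the position within it, with the
#' default 0 taking the lower bound, as in the classical worked example
#' (58 kg, light activity: 58 x 25 = 1450 kcal/day).
#'
#' @param weight Rounded standard weight in kg, > 0.
#' @param activity `"light"`, `"normal"` or `"hard"`.
#' @param band_point Fraction in [0, 1] locating the rate within the
#'   band: 0 = lower bound, 1 = upper bound.
#' @return Daily calorie target in kcal/day.
#' @export
#' @examples
#' daily_calories(58, "light")       # 1450
#' daily_calories(58, "light", 1)    # 1740
daily_calories <- function(weight, activity = c("light", "normal", "hard"),
                           band_point = 0) {
  activity <- match.arg(activity)
  if (!is.numeric(weight) || any(weight <= 0))
    stop("weight must be positive")
  if (!is.numeric(band_point) || band_point < 0 || band_point > 1)
    stop("band_point must be in [0, 1]")
  band <- activity_bands()
  band <- band[band$activity == activity, ]
  weight * (band$low + band_point * (band$high - band$low))
}

#' Daily calorie target straight from body information
#'
#' Convenience pipeline: standard weight from height and sex, rounded up
#' to whole kg, multiplied by the activity band rate.
#'
#' @inheritParams standard_weight
#' @inheritParams daily_calories
#' @return A list with components `standard_weight` (kg, unrounded),
#'   `rounded_weight` (kg) and `daily_calories` (kcal/day).
#' @export
#' @examples
#' calorie_target(1.65, "female", "light")
calorie_target <- function(height, sex = c("female", "male"),
                           activity = c("light", "normal", "hard"),
                           band_point = 0) {
  sw <- standard_weight(height, sex)
  rw <- round_standard_weight(sw)
  list(standard_weight = sw, rounded_weight = rw,
       daily_calories = daily_calories(rw, activity, band_point))
}
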