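#' Default feature ranges for the synthetic generator
#'
#' Per-feature (min, max) spans within which synthetic records are drawn.
#' The defaults are the spans of the published example records, so
#' generated data resembles them: time 5--23 h, blood sugar 50--423
#' mg/dL, systolic 100--180 mmHg, diastolic 50--100 mmHg, exercise
#' 0--500 kcal, meal 0--680 kcal, daily calorie target 150--2439 kcal.
#'
#' @return A named list of length-2 numeric vectors `c(min, max)`.
#' @export
default_feature_ranges <- function() {
  list(time = c(5, 23),
       blood_sugar = c(50, 423),
       systolic = c(100, 180),
       diastolic = c(50, 100),
       exercise = c(0, 500),
       meal = c(0, 680),
       target_calories = c(150, 2439))
}

#' Generate labeled synthetic patient records
#'
#' Draws seeded synthetic observation records structured like the
#' advisory engine's experimental data: a sample (training) set and a
#' test set of labeled records. Features are uniform within their ranges,
#' with two structural constraints mirroring real measurement sessions:
#' systolic pressure always exceeds diastolic, and at most one of the
#' exercise and meal energies is nonzero per record (a session is either
#' a normal reading, an after-exercise reading or an after-meal reading,
#' each equally likely).
#'
#' Labels are assigned by the rule engine. In `"rule_consistent"` mode
#' they are kept as-is, so the rule-based recommender scores a perfect
#' match by construction. In `"noisy"` mode each label is flipped, with
#' probability `noise_p`, to a uniformly random different code —
#' emulating labels assigned independently of the rules, the situation
#' in which comparing recommenders is informative.
#'
#' @param n_sample,n_test Number of sample and test records (>= 1).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param label_mode `"rule_consistent"` or `"noisy"`.
#' @param noise_p Label-flip probability in [0, 1]; required in noisy
#'   mode.
#' @param rules Rule set used to assign labels.
#' @param ranges Per-feature ranges, as [default_feature_ranges()].
#' @return A list with labeled `"obs_records"` components `sample` and
#'   `test`.
#' @export
#' @examples
#' sets <- generate_records(n_sample = 20, n_test = 10, seed = 1)
#' mean(recommend_treatment(sets$test) == sets$test$treatment)  # 1
generate_records <- function(n_sample = 200L, n_test = 100L, seed = NULL,
                             label_mode = c("rule_consistent", "noisy"),
                             noise_p = NULL, rules = default_ruleset(),
                             ranges = default_feature_ranges()) {
  label_mode <- match.arg(label_mode)
  if (n_sample < 1 || n_test < 1) stop("n_sample and n_test must be >= 1")
  if (label_mode == "noisy") {
    if (is.null(noise_p) || !is.numeric(noise_p) || noise_p < 0 || noise_p > 1)
      stop("noisy mode requires noise_p in [0, 1]")
  } else if (!is.null(noise_p)) {
    stop("noise_p is only meaningful with label_mode = 'noisy'")
  }
  feats <- record_features()
  if (!all(feats %in% names(ranges)))
    stop("ranges must cover all seven record features")
  for (f in feats)
    if (ranges[[f]][1] > ranges[[f]][2])
      stop("invalid range for ", f, ": min > max")
  if (ranges$systolic[2] <= ranges$diastolic[1])
    stop("systolic range must extend above the diastolic minimum")

  if (!is.null(seed)) set.seed(seed)
  n <- n_sample + n_test
  ru <- function(f) stats::runif(n, ranges[[f]][1], ranges[[f]][2])

  systolic <- ru("systolic")
  # diastolic drawn below the record's systolic so the invariant holds
  diastolic <- stats::runif(n, ranges$diastolic[1],
                            pmin(ranges$diastolic[2], systolic))
  mode <- sample(c("normal", "after_exercise", "after_meal"), n,
                 replace = TRUE)
  exercise <- ifelse(mode == "after_exercise", ru("exercise"), 0)
  meal <- ifelse(mode == "after_meal", ru("meal"), 0)

  df <- data.frame(time = ru("time"), blood_sugar = ru("blood_sugar"),
                   systolic = systolic, diastolic = diastolic,
                   exercise = exercise, meal = meal,
                   target_calories = ru("target_calories"))
  df$treatment <- recommend_treatment(df, rules)
  if (label_mode == "noisy" && noise_p > 0) {
    flip <- stats::runif(n) < noise_p
    if (any(flip)) {
      # uniform over the four codes other than the current one
      shift <- sample.int(4, sum(flip), replace = TRUE)
      df$treatment[flip] <- as.integer(
        (df$treatment[flip] - 1L + shift) %% 5L + 1L)
    }
  }
  df <- validate_records(df, labeled = TRUE)
  list(sample = df[seq_len(n_sample), , drop = FALSE] |> validate_records(),
       test = {
         te <- df[n_sample + seq_len(n_test), , drop = FALSE]
         rownames(te) <- NULL
         validate_records(te)
       })
}
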