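#' Treatment action codes
#'
#' The five-way treatment action set used throughout the advisory engine:
#' \tabular{ll}{
#'   1 \tab more exercise \cr
#'   2 \tab eat more (a meal or snack) \cr
#'   3 \tab emergency (rest) \cr
#'   4 \tab take insulin \cr
#'   5 \tab normal (maintenance)
#' }
#'
#' @return A named integer vector mapping label to code.
#' @export
#' @examples
#' treatment_codes()
treatment_codes <- function() {
  c(more_exercise = 1L, eat_more = 2L, rest = 3L, take_insulin = 4L,
    maintain = 5L)
}

#' Human-readable label for a treatment code
#'
#' @param code Integer vector of treatment codes in 1..5.
#' @return Character vector of labels.
#' @export
#' @examples
#' treatment_label(c(1, 5))
treatment_label <- function(code) {
  labels <- c("more exercise", "eat more", "emergency (rest)",
              "take insulin", "normal (maintenance)")
  code <- as.integer(code)
  if (any(!code %in% 1:5, na.rm = TRUE))
    stop("treatment code must be in 1..5")
  labels[code]
}

# Feature columns of an observation record, in canonical order.
record_features <- function() {
  c("time", "blood_sugar", "systolic", "diastolic", "exercise", "meal",
    "target_calories")
}

#' Construct a set of observation records
#'
#' Builds and validates a data frame of time-stamped observation records,
#' the common currency of the rule engine, the KNN classifier and the
#' evaluation harness. Each record holds seven numeric features — hour of
#' day, blood sugar (mg/dL), systolic and diastolic blood pressure (mmHg),
#' exercise and meal energy (kcal), and the daily target calorie intake
#' (kcal) — plus an optional treatment code in 1..5.
#'
#' @param time Hour of day, real in [0, 24].
#' @param blood_sugar Blood sugar in mg/dL.
#' @param systolic,diastolic Blood pressure in mmHg; systolic must exceed
#'   diastolic in every record.
#' @param exercise,meal Energy in kcal.
#' @param target_calories Daily calorie target in kcal.
#' @param treatment Optional treatment codes (1..5), `NA` permitted.
#' @return A data frame of class `"obs_records"`.
#' @export
#' @examples
#' obs_records(time = 5, blood_sugar = 84, systolic = 140, diastolic = 69,
#'             exercise = 240, meal = 0, target_calories = 1267,
#'             treatment = 5)
obs_records <- function(time, blood_sugar, systolic, diastolic, exercise,
                        meal, target_calories, treatment = NA_integer_) {
  df <- data.frame(time = as.numeric(time),
                   blood_sugar = as.numeric(blood_sugar),
                   systolic = as.numeric(systolic),
                   diastolic = as.numeric(diastolic),
                   exercise = as.numeric(exercise),
                   meal = as.numeric(meal),
                   target_calories = as.numeric(target_calories))
  df$treatment <- as.integer(treatment)
  validate_records(df)
}

#' Validate observation records
#'
#' Checks the record invariants: all seven features finite and
#' non-negative, time within [0, 24], systolic above diastolic, and any
#' treatment code in 1..5. Violations raise an error naming the offending
#' row and column.
#'
#' @param df Data frame with the seven feature columns and optionally a
#'   `treatment` column.
#' @param labeled If `TRUE`, every record must carry a treatment code.
#' @param raw If `TRUE` (the default), enforce the raw-record invariant
#'   that systolic pressure exceeds diastolic; min-max normalized records
#'   need not satisfy it.
#' @return `df`, classed `"obs_records"`, invisibly usable downstream.
#' @export
validate_records <- function(df, labeled = FALSE, raw = TRUE) {
  feats <- record_features()
  missing_cols <- setdiff(feats, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!"treatment" %in% names(df)) df$treatment <- rep(NA_integer_, nrow(df))

  fail <- function(row, col, why)
    stop(sprintf("invalid value at row %d, column '%s': %s", row, col, why))

  for (col in feats) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      fail(if (is.na(bad)) 1L else bad, col, "non-numeric")
    }
    if (anyNA(v) || any(!is.finite(v)))
      fail(which(!is.finite(v))[1], col, "non-finite")
    if (any(v < 0)) fail(which(v < 0)[1], col, "negative")
  }
  if (any(df$time > 24))
    fail(which(df$time > 24)[1], "time", "hour of day must be in [0, 24]")
  if (raw && any(df$systolic <= df$diastolic))
    fail(which(df$systolic <= df$diastolic)[1], "systolic",
         "systolic must exceed diastolic")
  tr <- df$treatment
  if (any(!is.na(tr) & !tr %in% 1:5))
    fail(which(!is.na(tr) & !tr %in% 1:5)[1], "treatment",
         "treatment code must be in 1..5")
  if (labeled && anyNA(tr))
    fail(which(is.na(tr))[1], "treatment", "label required but missing")

  df <- df[c(feats, "treatment")]
  class(df) <- c("obs_records", "data.frame")
  df
}

#' Read observation records from a delimited file
#'
#' Reads a comma-separated file with a mandatory header naming the seven
#' feature columns (`time, blood_sugar, systolic, diastolic, exercise,
#' meal, target_calories`) and optionally `treatment`. Thousands
#' separators inside numeric fields (`"1,267"`) are accepted, matching the
#' way published record tables are often typeset; quoting protects the
#' embedded comma.
#'
#' @param path Path to the file.
#' @param labeled If `TRUE`, require a treatment code on every record.
#' @param raw If `TRUE` (the default), enforce the raw-record invariant
#'   systolic > diastolic; set to `FALSE` for files of already-normalized
#'   records.
#' @return An `"obs_records"` data frame, one row per data line, in file
#'   order.
#' @export
#' @examples
#' path <- system.file("extdata", "table4.csv", package = "glucadvisor")
#' read_records(path, labeled = TRUE)
read_records <- function(path, labeled = FALSE, raw = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  expected <- record_features()
  missing_cols <- setdiff(expected, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  has_label <- "treatment" %in% names(df)
  keep <- c(expected, if (has_label) "treatment")
  df <- df[keep]
  for (col in names(df)) {
    cells <- gsub(",", "", df[[col]], fixed = TRUE)
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(num) & !(col == "treatment" & cells %in% c("", "NA")))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                   bad[1], col, df[[col]][bad[1]]))
    df[[col]] <- num
  }
  if (!has_label) df$treatment <- rep(NA_integer_, nrow(df)) else
    df$treatment <- as.integer(df$treatment)
  validate_records(df, labeled = labeled, raw = raw)
}

#' Write observation records to a delimited file
#'
#' Writes a comma-separated file re-readable by [read_records()]. Numeric
#' fields are rendered plainly, without thousands separators. A dataset
#' with no treatment codes is written without the `treatment` column.
#'
#' @param df An `"obs_records"` data frame (or coercible via
#'   [validate_records()]).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_records <- function(df, path) {
  df <- validate_records(df)
  if (all(is.na(df$treatment))) df$treatment <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.obs_records <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Observation records: %d record%s%s\n", n,
              if (n == 1) "" else "s",
              if (all(!is.na(x$treatment))) " (labeled)" else ""))
  print.data.frame(x, ...)
  invisible(x)
}
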