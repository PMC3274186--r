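#' Diagnose glucose status from fasting and post-meal readings
#'
#' Classifies a patient's glucose status from the fasting plasma glucose
#' (FPG) and, where available, the blood sugar measured 2 hours after a
#' meal, following the standard diagnostic grid:
#' \itemize{
#'   \item FPG below 70 mg/dL: low blood sugar (no post-meal value needed;
#'     dominates every other row);
#'   \item FPG below 100 and post-meal below 140: normal;
#'   \item FPG over 126 and post-meal over 200: abnormally high;
#'   \item FPG below 100 and post-meal 140--199: impaired glucose
#'     tolerance (IGT);
#'   \item FPG 100--125 and post-meal below 140: impaired fasting glucose
#'     (IFG).
#' }
#' Combinations the grid does not cover (e.g. FPG 110 with post-meal 250)
#' return `"unclassified"` rather than raising an error.
#'
#' @param fpg Fasting plasma glucose in mg/dL, > 0.
#' @param post_meal_2h Blood sugar 2 h after a meal in mg/dL, or `NA`.
#' @return One of `"low"`, `"normal"`, `"abnormally_high"`, `"IGT"`,
#'   `"IFG"`, `"unclassified"`.
#' @export
#' @examples
#' diagnose_glucose(90, 130)   # "normal"
#' diagnose_glucose(65)        # "low"
#' diagnose_glucose(110, 130)  # "IFG"
diagnose_glucose <- function(fpg, post_meal_2h = NA_real_) {
  if (!is.numeric(fpg) || length(fpg) != 1 || !is.finite(fpg) || fpg <= 0)
    stop("fpg must be a single positive number (mg/dL)")
  pm <- post_meal_2h
  if (fpg < 70) return("low")
  if (is.na(pm)) return("unclassified")
  if (fpg < 100 && pm < 140) return("normal")
  if (fpg > 126 && pm > 200) return("abnormally_high")
  if (fpg < 100 && pm >= 140 && pm <= 199) return("IGT")
  if (fpg >= 100 && fpg <= 125 && pm < 140) return("IFG")
  "unclassified"
}

#' Construct a treatment rule set
#'
#' A rule set is an ordered collection of threshold rules evaluated
#' against a record's hour of day and blood sugar. Each rule carries a
#' set of inclusive time windows, a single strict comparison on blood
#' sugar, and the treatment code it emits. The first rule (in the given
#' order) whose window contains the record's hour and whose comparison
#' holds determines the recommendation; if none fires, `default_action`
#' (maintenance) is returned.
#'
#' @param rules A list of rules, each a list with components `windows`
#'   (two-column matrix of inclusive [start, end] hours within [0, 24]),
#'   `op` (`"<"` or `">"`), `threshold` (mg/dL) and `action` (code 1..5).
#' @param default_action Treatment code when no rule fires.
#' @return An object of class `"treatment_rules"`.
#' @seealso [default_ruleset()] for the packaged clinical defaults.
#' @export
treatment_rules <- function(rules, default_action = 5L) {
  stopifnot(is.list(rules), length(rules) >= 1)
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    if (!all(c("windows", "op", "threshold", "action") %in% names(r)))
      stop("rule ", i, " must have windows, op, threshold, action")
    w <- r$windows
    if (!is.matrix(w) || ncol(w) != 2 || any(w < 0) || any(w > 24) ||
        any(w[, 1] > w[, 2]))
      stop("rule ", i, ": windows must be [start, end] pairs within [0, 24]")
    if (!r$op %in% c("<", ">"))
      stop("rule ", i, ": op must be '<' or '>'")
    if (!r$action %in% 1:5)
      stop("rule ", i, ": action must be a treatment code in 1..5")
  }
  if (!default_action %in% 1:5) stop("default_action must be in 1..5")
  structure(list(rules = rules, default_action = as.integer(default_action)),
            class = "treatment_rules")
}

#' The packaged clinical rule set
#'
#' Encodes the time-windowed blood-sugar treatment rules with an explicit
#' precedence order. The assumed daily schedule has meals at 7:00, 12:00
#' and 18:00 and sleep at 24:00; the fasting windows precede meals and the
#' post-meal windows sit 4 hours after them. In precedence order:
#' \enumerate{
#'   \item at any hour, blood sugar below 70 mg/dL: rest (code 3) — the
#'     emergency rule dominates everything;
#'   \item fasting windows 0--7, 9--12, 14--18, 20--23: over 126 mg/dL,
#'     more exercise (code 1);
#'   \item before sleeping, 22--24: below 120 mg/dL, eat more (code 2);
#'   \item 4 hours after meals, 9--12, 15--17, 20--23: over 140 mg/dL,
#'     more exercise (code 1); below 100 mg/dL, eat more (code 2);
#'   \item at any hour, over 180 mg/dL: take insulin (code 4);
#'   \item otherwise maintain (code 5).
#' }
#' Window bounds are inclusive, thresholds strict. Hours 8, 13 and 19
#' fall in no window and are governed only by the always-rules. Placing
#' the window rules above the always-insulin rule is what lets a fasting
#' reading of, say, 199 mg/dL at 7:00 yield "more exercise" rather than
#' "take insulin": persistent highs in fasting windows are managed by
#' exercise first, with insulin reserved for highs the windows do not
#' explain.
#'
#' @return A `"treatment_rules"` object.
#' @export
#' @examples
#' rules <- default_ruleset()
#' recommend_treatment(obs_records(19, 300, 164, 68, 0, 0, 600), rules)  # 4
default_ruleset <- function() {
  win <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  treatment_rules(list(
    list(name = "emergency low", windows = win(0, 24),
         op = "<", threshold = 70, action = 3L),
    list(name = "fasting high", windows = win(0, 7, 9, 12, 14, 18, 20, 23),
         op = ">", threshold = 126, action = 1L),
    list(name = "before-sleep low", windows = win(22, 24),
         op = "<", threshold = 120, action = 2L),
    list(name = "post-meal high", windows = win(9, 12, 15, 17, 20, 23),
         op = ">", threshold = 140, action = 1L),
    list(name = "post-meal low", windows = win(9, 12, 15, 17, 20, 23),
         op = "<", threshold = 100, action = 2L),
    list(name = "always insulin", windows = win(0, 24),
         op = ">", threshold = 180, action = 4L)
  ), default_action = 5L)
}

#' Rule-based treatment recommendation
#'
#' Applies a rule set to observation records and returns the recommended
#' treatment code for each, evaluating rules in precedence order and
#' taking the first that fires. Total over its domain: every hour in
#' [0, 24] and non-negative blood sugar yields a code in 1..5.
#'
#' @param records An `"obs_records"` data frame (or anything
#'   [validate_records()] accepts).
#' @param rules A `"treatment_rules"` object; defaults to the packaged
#'   clinical rule set.
#' @return Integer vector of treatment codes, one per record.
#' @export
#' @examples
#' recommend_treatment(obs_records(7, 50, 140, 65, 300, 0, 1344))  # 3
recommend_treatment <- function(records, rules = default_ruleset()) {
  records <- validate_records(records)
  stats::predict(rules, records)
}

#' @describeIn treatment_rules Predict treatment codes for new records.
#' @param object A `"treatment_rules"` object.
#' @param newdata Records to classify.
#' @param ... Unused.
#' @export
predict.treatment_rules <- function(object, newdata, ...) {
  newdata <- validate_records(newdata)
  t <- newdata$time
  bs <- newdata$blood_sugar
  if (any(t < 0 | t > 24)) stop("time must be within [0, 24]")
  out <- rep(object$default_action, length(t))
  decided <- rep(FALSE, length(t))
  for (r in object$rules) {
    w <- r$windows
    in_window <- rep(FALSE, length(t))
    for (i in seq_len(nrow(w)))
      in_window <- in_window | (t >= w[i, 1] & t <= w[i, 2])
    fires <- in_window & if (r$op == "<") bs < r$threshold else bs > r$threshold
    hit <- fires & !decided
    out[hit] <- r$action
    decided <- decided | hit
  }
  out
}

#' @export
print.treatment_rules <- function(x, ...) {
  cat(sprintf("Treatment rule set: %d rules, default action %d (%s)\n",
              length(x$rules), x$default_action,
              treatment_label(x$default_action)))
  for (i in seq_along(x$rules)) {
    r <- x$rules[[i]]
    wins <- paste(apply(r$windows, 1, function(w)
      sprintf("%g-%g", w[1], w[2])), collapse = ", ")
    cat(sprintf("  %d. [%s] hours %s: blood sugar %s %g -> %d (%s)\n",
                i, if (is.null(r$name)) "" else r$name, wins, r$op,
                r$threshold, r$action, treatment_label(r$action)))
  }
  invisible(x)
}
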