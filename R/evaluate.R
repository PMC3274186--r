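#' Score predictions against true treatment labels
#'
#' Elementwise match scoring: each record contributes 1 if the predicted
#' treatment code equals the true label and 0 otherwise; the match count
#' and the accuracy fraction summarize the vector.
#'
#' @param predictions Integer vector of predicted treatment codes.
#' @param labels Integer vector of true codes, same length.
#' @param method Optional identifier carried into the result.
#' @return An object of class `"eval_result"`: a list with `method`,
#'   `matches`, `total`, `accuracy` and the binary `per_record` vector.
#' @export
#' @examples
#' score_predictions(c(1, 2, 3), c(1, 2, 4))  # 2 of 3
score_predictions <- function(predictions, labels, method = "unnamed") {
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length (",
         length(predictions), " vs ", length(labels), ")")
  if (length(labels) == 0) stop("cannot score an empty set")
  if (any(!predictions %in% 1:5) || any(!labels %in% 1:5))
    stop("treatment codes must be in 1..5")
  per_record <- as.integer(predictions == labels)
  structure(list(method = method,
                 matches = sum(per_record),
                 total = length(per_record),
                 accuracy = mean(per_record),
                 per_record = per_record),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("%s: %d / %d matches (accuracy %.3f)\n",
              x$method, x$matches, x$total, x$accuracy))
  invisible(x)
}

#' Compare the rule-based and KNN recommenders on a common test set
#'
#' Runs the rule engine and the KNN classifier — raw and min-max
#' normalized, for each requested k — on the same labeled test set and
#' scores every configuration against the test labels. The KNN memory is
#' the sample set; normalization bounds are fitted on the sample only.
#' The comparison is fully deterministic given its inputs.
#'
#' @param sample Labeled sample (training) records, the KNN memory.
#' @param test Labeled test records.
#' @param ks Neighbor counts to evaluate (default 1, 3, 5).
#' @param rules Rule set for the rule-based recommender.
#' @return A data frame of class `"method_comparison"` with one row per
#'   configuration: `method`, `k`, `normalized`, `matches`, `total`,
#'   `accuracy`. Row order: rule-based first, then raw KNN by k, then
#'   normalized KNN by k.
#' @export
#' @examples
#' tbl4 <- read_records(system.file("extdata", "table4.csv",
#'                                  package = "glucadvisor"), labeled = TRUE)
#' compare_methods(tbl4, tbl4, ks = c(1, 3))
compare_methods <- function(sample, test, ks = c(1L, 3L, 5L),
                            rules = default_ruleset()) {
  sample <- validate_records(sample, labeled = TRUE)
  test <- validate_records(test, labeled = TRUE)
  ks <- sort(unique(as.integer(ks)))

  rows <- list()
  add <- function(method, k, normalized, sc)
    rows[[length(rows) + 1]] <<- data.frame(
      method = method, k = if (is.na(k)) NA_integer_ else k,
      normalized = normalized, matches = sc$matches, total = sc$total,
      accuracy = sc$accuracy)

  rule_pred <- recommend_treatment(test, rules)
  add("rules", NA, FALSE,
      score_predictions(rule_pred, test$treatment, "rules"))
  for (normalized in c(FALSE, TRUE)) {
    for (k in ks) {
      fit <- knn_advisor(sample, k = k, normalize = normalized)
      pred <- predict(fit, test)
      label <- sprintf("knn%s k=%d", if (normalized) " (normalized)" else "", k)
      add("knn", k, normalized,
          score_predictions(pred, test$treatment, label))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("method_comparison", "data.frame")
  out
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Recommender comparison on", x$total[1], "test records:\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
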