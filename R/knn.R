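#' Euclidean distance between two feature vectors
#'
#' Plain Euclidean distance, the dissimilarity used by the KNN
#' recommender over the seven record features (time, blood sugar,
#' systolic, diastolic, exercise, meal, target calories).
#'
#' @param x,y Numeric vectors of equal length.
#' @return Non-negative scalar distance.
#' @export
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4))  # 5
euclidean_distance <- function(x, y) {
  if (length(x) != length(y))
    stop("dimension mismatch: ", length(x), " vs ", length(y))
  sqrt(sum((as.numeric(x) - as.numeric(y))^2))
}

#' Fit min-max normalization bounds on a sample dataset
#'
#' Scans the sample (training) records and stores each feature's minimum
#' and maximum. These bounds rescale every feature to [0, 1]; the
#' treatment label is never normalized. A feature whose maximum equals
#' its minimum is flagged degenerate and maps to 0 downstream, so it
#' contributes nothing to any distance.
#'
#' @param sample A non-empty `"obs_records"` data frame.
#' @return An object of class `"minmax_params"` with components `min`,
#'   `max` (named numeric vectors) and `degenerate` (logical).
#' @export
#' @examples
#' tbl4 <- read_records(system.file("extdata", "table4.csv",
#'                                  package = "glucadvisor"))
#' fit_normalization(tbl4)
fit_normalization <- function(sample) {
  sample <- validate_records(sample, raw = FALSE)
  if (nrow(sample) == 0) stop("cannot fit normalization on an empty dataset")
  feats <- record_features()
  mins <- vapply(sample[feats], min, numeric(1))
  maxs <- vapply(sample[feats], max, numeric(1))
  structure(list(min = mins, max = maxs, degenerate = maxs == mins),
            class = "minmax_params")
}

#' Construct normalization bounds directly
#'
#' Builds a `"minmax_params"` object from explicit per-feature bounds,
#' useful when the bounds are known from a published table rather than
#' refit from data.
#'
#' @param min,max Named numeric vectors covering the seven record
#'   features.
#' @return A `"minmax_params"` object.
#' @export
minmax_params <- function(min, max) {
  feats <- record_features()
  if (!all(feats %in% names(min)) || !all(feats %in% names(max)))
    stop("min and max must name all seven record features")
  min <- min[feats]; max <- max[feats]
  if (any(max < min)) stop("max must be >= min for every feature")
  structure(list(min = min, max = max, degenerate = max == min),
            class = "minmax_params")
}

#' @export
print.minmax_params <- function(x, ...) {
  cat("Min-max normalization bounds (fitted on sample data):\n")
  print(data.frame(min = x$min, max = x$max, degenerate = x$degenerate))
  invisible(x)
}

#' Min-max normalize observation records
#'
#' Rescales each feature to (value - min) / (max - min) using bounds
#' fitted on the sample data, clamping to [0, 1]: query values above the
#' sample maximum map to 1, values below the sample minimum to 0.
#' Degenerate features (max = min) map to 0. The treatment column is
#' copied unchanged.
#'
#' @param records Records to normalize.
#' @param params A `"minmax_params"` object from [fit_normalization()] or
#'   [minmax_params()].
#' @return Normalized `"obs_records"` data frame.
#' @export
normalize_records <- function(records, params) {
  if (!inherits(params, "minmax_params"))
    stop("params must be a 'minmax_params' object")
  records <- validate_records(records, raw = FALSE)
  for (col in record_features()) {
    if (params$degenerate[[col]]) {
      records[[col]] <- rep(0, nrow(records))
    } else {
      z <- (records[[col]] - params$min[[col]]) /
        (params$max[[col]] - params$min[[col]])
      records[[col]] <- pmin(1, pmax(0, z))
    }
  }
  # normalized records no longer satisfy raw-record invariants
  # (systolic > diastolic); keep the container but skip re-validation
  class(records) <- c("obs_records", "data.frame")
  records
}

#' Fit a k-nearest-neighbor treatment advisor
#'
#' Stores a labeled sample (training) dataset as classifier memory,
#' optionally with min-max normalization bounds fitted on it. Prediction
#' finds, for each query record, the k sample records at smallest
#' Euclidean distance over the seven features and recommends the
#' plurality treatment code among their labels.
#'
#' Determinism: sample records at exactly equal distance are taken in
#' dataset order; a tied vote is resolved in favor of the tied code whose
#' nearest supporting neighbor is closest (so the behavior degenerates
#' gracefully to k = 1).
#'
#' @param sample Labeled `"obs_records"` data frame (every record must
#'   carry a treatment code); at least `k` records.
#' @param k Number of neighbors (typically 1, 3 or 5).
#' @param normalize If `TRUE`, fit min-max bounds on the sample and apply
#'   them (with clamping) to both the sample and every query.
#' @return An object of class `"knn_advisor"`.
#' @export
#' @examples
#' tbl4 <- read_records(system.file("extdata", "table4.csv",
#'                                  package = "glucadvisor"), labeled = TRUE)
#' fit <- knn_advisor(tbl4, k = 3, normalize = TRUE)
#' predict(fit, tbl4[1, ])
knn_advisor <- function(sample, k = 3L, normalize = TRUE) {
  sample <- validate_records(sample, labeled = TRUE)
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (nrow(sample) < k)
    stop("k (", k, ") exceeds the sample size (", nrow(sample), ")")
  params <- if (normalize) fit_normalization(sample) else NULL
  memory <- if (normalize) normalize_records(sample, params) else sample
  structure(list(sample = sample,
                 memory = as.matrix(memory[record_features()]),
                 labels = sample$treatment,
                 k = k, normalize = normalize, params = params),
            class = "knn_advisor")
}

# Majority vote over the k nearest rows of `memory` for one query vector.
# Returns the full audit trail (neighbors, distances, tally).
vote_one <- function(query, memory, labels, k) {
  d2 <- colSums((t(memory) - query)^2)
  ord <- order(d2, seq_along(d2))  # stable: distance, then dataset order
  nn <- ord[seq_len(k)]
  tally <- table(labels[nn])
  top <- names(tally)[tally == max(tally)]
  if (length(top) > 1) {
    # tie: the tied code backed by the single nearest neighbor wins
    first_rank <- vapply(top, function(v)
      min(which(labels[nn] == v)), integer(1))
    top <- top[which.min(first_rank)]
  }
  list(predicted = as.integer(top),
       neighbor_indices = nn,
       neighbor_distances = sqrt(d2[nn]),
       tally = as.integer(tally) |> stats::setNames(names(tally)))
}

#' @describeIn knn_advisor Predict treatment codes for query records.
#' @param object A fitted `"knn_advisor"`.
#' @param newdata Query records.
#' @param details If `TRUE`, return a list of vote results (predicted
#'   code, neighbor indices, neighbor distances, per-code tally) instead
#'   of the bare code vector.
#' @param ... Unused.
#' @export
predict.knn_advisor <- function(object, newdata, details = FALSE, ...) {
  newdata <- validate_records(newdata, raw = FALSE)
  if (object$normalize)
    newdata <- normalize_records(newdata, object$params)
  q <- as.matrix(newdata[record_features()])
  votes <- lapply(seq_len(nrow(q)), function(i)
    vote_one(q[i, ], object$memory, object$labels, object$k))
  if (details) votes else vapply(votes, `[[`, integer(1), "predicted")
}

#' One-shot KNN treatment recommendation with audit trail
#'
#' Convenience wrapper fitting a [knn_advisor()] on `sample` and
#' returning the full vote result for a single query record: the
#' predicted code, the indices and distances of the k nearest sample
#' records, and the per-code vote tally.
#'
#' @param query A single observation record.
#' @param sample Labeled sample dataset (classifier memory).
#' @param k Number of neighbors.
#' @param normalize Apply min-max normalization fitted on `sample`.
#' @return A list of class `"knn_vote"` with components `predicted`,
#'   `neighbor_indices`, `neighbor_distances`, `tally`, `k`,
#'   `normalized`.
#' @export
knn_recommend <- function(query, sample, k = 3L, normalize = TRUE) {
  query <- validate_records(query)
  if (nrow(query) != 1) stop("query must be a single record")
  fit <- knn_advisor(sample, k = k, normalize = normalize)
  res <- predict(fit, query, details = TRUE)[[1]]
  res$k <- fit$k
  res$normalized <- normalize
  class(res) <- "knn_vote"
  res
}

#' @export
print.knn_vote <- function(x, ...) {
  cat(sprintf("KNN recommendation (k = %d, %s data): %d (%s)\n", x$k,
              if (x$normalized) "normalized" else "raw", x$predicted,
              treatment_label(x$predicted)))
  cat("  neighbors (sample row: distance):",
      paste(sprintf("%d: %.4g", x$neighbor_indices, x$neighbor_distances),
            collapse = ", "), "\n")
  cat("  votes:", paste(sprintf("code %s x%d", names(x$tally), x$tally),
                        collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.knn_advisor <- function(x, ...) {
  cat(sprintf("KNN treatment advisor: k = %d, %s features, %d sample records\n",
              x$k, if (x$normalize) "min-max normalized" else "raw",
              nrow(x$sample)))
  invisible(x)
}

#' @export
summary.knn_advisor <- function(object, ...) {
  cat(sprintf("KNN treatment advisor (k = %d, %s)\n", object$k,
              if (object$normalize) "min-max normalized features"
              else "raw features"))
  cat("Sample label distribution:\n")
  print(table(treatment = object$labels))
  if (object$normalize) print(object$params)
  invisible(object)
}
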