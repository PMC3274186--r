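# Independent brute-force oracles and random-record helpers for the suite.

feature_cols <- c("time", "blood_sugar", "systolic", "diastolic",
                  "exercise", "meal", "target_calories")

# Random raw observation records built directly from runif, independent of
# the package's own generator.
random_record_df <- function(n, labeled = TRUE) {
  systolic <- runif(n, 101, 180)
  df <- data.frame(
    time = runif(n, 0, 24),
    blood_sugar = runif(n, 40, 400),
    systolic = systolic,
    diastolic = runif(n, 50, pmin(100, systolic - 1)),
    exercise = runif(n, 0, 500),
    meal = runif(n, 0, 680),
    target_calories = runif(n, 150, 2500))
  df$treatment <- if (labeled) sample(1:5, n, replace = TRUE) else NA_integer_
  df
}

# Exhaustive-search KNN oracle: normalization, distances, neighbor
# selection and vote all recoded from scratch. `dist_fun` lets the vote be
# recomputed under a monotone transform of the distance.
oracle_knn <- function(sample_df, query_df, k, normalize,
                       dist_fun = function(d2) sqrt(d2)) {
  xs <- as.matrix(sample_df[feature_cols])
  xq <- as.matrix(query_df[feature_cols])
  if (normalize) {
    lo <- apply(xs, 2, min); hi <- apply(xs, 2, max)
    scale_mat <- function(m) {
      for (j in seq_along(lo)) {
        m[, j] <- if (hi[j] == lo[j]) 0 else
          pmin(1, pmax(0, (m[, j] - lo[j]) / (hi[j] - lo[j])))
      }
      m
    }
    xs <- scale_mat(xs); xq <- scale_mat(xq)
  }
  labels <- sample_df$treatment
  apply(xq, 1, function(q) {
    d2 <- apply(xs, 1, function(s) sum((s - q)^2))
    d <- dist_fun(d2)
    nn <- order(d, seq_along(d))[seq_len(k)]
    votes <- labels[nn]
    tally <- table(votes)
    winners <- as.integer(names(tally)[tally == max(tally)])
    if (length(winners) == 1) return(winners)
    # tie rule: winner backed by the closest neighbor
    first <- sapply(winners, function(w) min(which(votes == w)))
    winners[which.min(first)]
  })
}

table4 <- function() {
  read_records(system.file("extdata", "table4.csv", package = "glucadvisor"),
               labeled = TRUE)
}

table6 <- function() {
  read_records(system.file("extdata", "table6.csv", package = "glucadvisor"),
               labeled = TRUE, raw = FALSE)
}

# Per-feature sample bounds that reproduce the published normalized table
# (the target-calories bounds are not recoverable; values here span the
# printed raw data and that column is excluded from cell-exact checks).
table4_bounds <- function() {
  minmax_params(
    min = c(time = 5, blood_sugar = 50, systolic = 100, diastolic = 50,
            exercise = 0, meal = 0, target_calories = 150),
    max = c(time = 23, blood_sugar = 423, systolic = 180, diastolic = 100,
            exercise = 500, meal = 680, target_calories = 2439))
}

# Labeled datasets for the normalization-benefit check: features on wildly
# different scales (hours vs hundreds of mmHg vs thousands of kcal) with a
# label that depends on every feature. Each record's label is the quintile
# of the mean of its range-scaled features, so proximity in *normalized*
# space is informative about the label while raw Euclidean distance is
# dominated by the widest axes.
scale_imbalanced_sets <- function(seed, n_sample = 150, n_test = 75) {
  sets <- generate_records(n_sample = n_sample, n_test = n_test, seed = seed)
  rng <- default_feature_ranges()
  relabel <- function() {
    pooled <- rbind(as.data.frame(sets$sample), as.data.frame(sets$test))
    z <- sapply(feature_cols, function(f)
      (pooled[[f]] - rng[[f]][1]) / diff(rng[[f]]))
    s <- rowMeans(z)
    lab <- as.integer(cut(s, breaks = quantile(s, probs = seq(0, 1, 0.2)),
                          include.lowest = TRUE))
    pooled$treatment <- lab
    list(sample = validate_records(pooled[seq_len(n_sample), ], labeled = TRUE),
         test = validate_records(pooled[n_sample + seq_len(n_test), ],
                                 labeled = TRUE))
  }
  relabel()
}
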