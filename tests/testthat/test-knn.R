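test_that("Euclidean distance matches hand values and stats::dist", {
  expect_equal(euclidean_distance(rep(0, 7), rep(0, 7)), 0)
  x <- c(3, 4, 0, 0, 0, 0, 0)
  expect_equal(euclidean_distance(rep(0, 7), x), 5)
  expect_error(euclidean_distance(1:3, 1:4), "dimension")
  t4 <- table4()
  m <- as.matrix(t4[feature_cols])
  d12 <- euclidean_distance(m[1, ], m[2, ])
  expect_equal(d12, as.matrix(stats::dist(m))[1, 2])
  # full pairwise agreement with stats::dist on the fixture
  ours <- outer(1:10, 1:10, Vectorize(function(i, j)
    euclidean_distance(m[i, ], m[j, ])))
  expect_equal(ours, as.matrix(stats::dist(m)), ignore_attr = TRUE)
})

test_that("distance is a metric on the fixture records", {
  m <- as.matrix(table4()[feature_cols])
  n <- nrow(m)
  d <- outer(1:n, 1:n, Vectorize(function(i, j)
    euclidean_distance(m[i, ], m[j, ])))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
})

test_that("normalization bounds are the per-feature sample min and max", {
  t4 <- table4()
  p <- fit_normalization(t4)
  expect_equal(unname(p$min["time"]), 5)
  expect_equal(unname(p$max["time"]), 23)
  expect_equal(unname(p$min["blood_sugar"]), 50)
  expect_equal(unname(p$max["blood_sugar"]), 300)
  expect_false(any(p$degenerate))
  one <- fit_normalization(t4[1, ])
  expect_true(all(one$degenerate))
  expect_equal(unname(one$min), unname(one$max))
  expect_error(fit_normalization(t4[0, ]), "empty")
})

test_that("min-max normalization rescales, clamps and skips the label", {
  p <- table4_bounds()
  r <- obs_records(11, 75, 161, 75, 0, 0, 1653, 2)
  nr <- normalize_records(r, p)
  expect_equal(nr$time, (11 - 5) / 18, tolerance = 1e-12)
  expect_equal(round(nr$time, 3), 0.333)
  expect_equal(nr$treatment, 2L)  # label untouched
  # clamping: values beyond the sample bounds hit 0 / 1
  hi <- normalize_records(obs_records(23, 500, 200, 120, 600, 700, 3000), p)
  expect_true(all(as.numeric(hi[feature_cols]) <= 1))
  expect_equal(hi$blood_sugar, 1)
  expect_equal(hi$target_calories, 1)
  lo <- normalize_records(obs_records(2, 30, 100, 50, 0, 0, 100), p)
  expect_equal(lo$time, 0)      # below sample min clamps to 0
  expect_equal(lo$systolic, 0)  # at the sample min maps to 0
  # degenerate feature maps to 0
  pd <- minmax_params(min = p$min, max = replace(p$max, "exercise", 0))
  expect_equal(normalize_records(obs_records(11, 75, 161, 75, 300, 0, 1653),
                                 pd)$exercise, 0)
})

test_that("the published normalized table is reconstructed cell by cell", {
  t4 <- table4()
  t6 <- table6()
  norm <- normalize_records(t4, table4_bounds())
  # the target-calories bounds are not recoverable from the printed table
  # and the first blood-sugar cell is a misprint; all other cells in the
  # six reconstructible columns must agree at the printed precision
  cols <- c("time", "blood_sugar", "systolic", "diastolic", "exercise", "meal")
  checked <- 0
  for (col in cols) {
    for (i in 1:10) {
      if (col == "blood_sugar" && i == 1) next
      expect_lt(abs(norm[[col]][i] - t6[[col]][i]), 1e-3,
                label = sprintf("|computed - printed| for %s row %d", col, i))
      checked <- checked + 1
    }
  }
  expect_gte(checked, 50)
  expect_equal(norm$treatment, t6$treatment)
})

test_that("normalization maps [0,1] data to itself once clamped", {
  norm1 <- normalize_records(table4(), table4_bounds())
  m1 <- as.matrix(norm1[feature_cols])
  expect_true(all(m1 >= 0 & m1 <= 1))
  # normalizing the fitting sample itself attains 0 and 1 in every
  # non-degenerate feature
  fitted <- fit_normalization(table4())
  self_norm <- as.matrix(normalize_records(table4(), fitted)[feature_cols])
  expect_equal(unname(apply(self_norm, 2, min)), rep(0, 7))
  expect_equal(unname(apply(self_norm, 2, max)), rep(1, 7))
  # unit bounds act as the identity on already-normalized data, so a
  # second pass changes nothing
  unit <- minmax_params(min = setNames(rep(0, 7), feature_cols),
                        max = setNames(rep(1, 7), feature_cols))
  norm2 <- normalize_records(norm1, unit)
  expect_equal(as.matrix(norm2[feature_cols]), m1, tolerance = 1e-12)
  expect_equal(as.matrix(normalize_records(norm2, unit)[feature_cols]), m1,
               tolerance = 1e-12)
})

test_that("KNN agrees with the exhaustive brute-force oracle", {
  withr::local_seed(7)
  for (n in c(10, 30, 50)) {
    sample_df <- validate_records(random_record_df(n))
    query_df <- validate_records(random_record_df(12))
    for (k in c(1, 3, 5)) {
      for (normalize in c(FALSE, TRUE)) {
        fit <- knn_advisor(sample_df, k = k, normalize = normalize)
        got <- predict(fit, query_df)
        want <- oracle_knn(sample_df, query_df, k, normalize)
        expect_equal(got, want,
                     info = sprintf("n=%d k=%d normalize=%s", n, k, normalize))
      }
    }
  }
})

test_that("the vote is invariant under a monotone transform of the distance", {
  withr::local_seed(11)
  sample_df <- validate_records(random_record_df(40))
  query_df <- validate_records(random_record_df(15))
  for (k in c(1, 3, 5)) {
    with_root <- oracle_knn(sample_df, query_df, k, TRUE)
    without_root <- oracle_knn(sample_df, query_df, k, TRUE,
                               dist_fun = identity)
    expect_equal(with_root, without_root)
    expect_equal(predict(knn_advisor(sample_df, k = k), query_df), with_root)
  }
})

test_that("self-match, unanimous votes and size errors behave as specified", {
  t4 <- table4()
  # a query identical to a sample record wins at distance zero for k = 1
  for (i in c(1, 4, 8)) {
    v <- knn_recommend(t4[i, ], t4, k = 1, normalize = FALSE)
    expect_equal(v$predicted, t4$treatment[i])
    expect_equal(v$neighbor_distances, 0)
    expect_equal(v$neighbor_indices, i)
  }
  # unanimous neighbors win regardless of tie rules
  unan <- validate_records(data.frame(time = c(1, 2, 3), blood_sugar = 100,
                                      systolic = 130, diastolic = 80,
                                      exercise = 0, meal = 0,
                                      target_calories = 1500,
                                      treatment = 2L))
  q <- obs_records(2, 100, 130, 80, 0, 0, 1500)
  res <- knn_recommend(q, unan, k = 3, normalize = FALSE)
  expect_equal(res$predicted, 2L)
  expect_equal(sum(res$tally), 3)
  expect_error(knn_advisor(t4, k = 11), "exceeds")
  expect_error(knn_advisor(t4[, -8] |> as.data.frame(), k = 1), "label")
})

test_that("vote ties fall to the code backed by the nearest neighbor", {
  # three neighbors at three distinct labels: the closest one's label wins
  mem <- validate_records(data.frame(
    time = c(10, 10, 10), blood_sugar = c(101, 103, 106),
    systolic = 130, diastolic = 80, exercise = 0, meal = 0,
    target_calories = 1500, treatment = c(4L, 1L, 2L)))
  q <- obs_records(10, 100, 130, 80, 0, 0, 1500)
  res <- knn_recommend(q, mem, k = 3, normalize = FALSE)
  expect_equal(res$predicted, 4L)
  expect_equal(res$neighbor_indices, c(1L, 2L, 3L))
  # equal distances resolve in stable dataset order
  twin <- validate_records(data.frame(
    time = c(10, 10), blood_sugar = c(102, 98),  # equidistant from 100
    systolic = 130, diastolic = 80, exercise = 0, meal = 0,
    target_calories = 1500, treatment = c(5L, 1L)))
  res2 <- knn_recommend(q, twin, k = 1, normalize = FALSE)
  expect_equal(res2$predicted, 5L)
  expect_equal(res2$neighbor_indices, 1L)
})

test_that("the nearest-neighbor route cross-checks against class::knn", {
  withr::local_seed(3)
  sample_df <- validate_records(random_record_df(60))
  query_df <- validate_records(random_record_df(30))
  ours <- predict(knn_advisor(sample_df, k = 1, normalize = FALSE), query_df)
  ref <- class::knn(sample_df[feature_cols], query_df[feature_cols],
                    cl = factor(sample_df$treatment), k = 1)
  expect_equal(ours, as.integer(as.character(ref)))
})
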