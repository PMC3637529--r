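test_that("extreme-day labeling selects k top and bottom days, dropping the middle", {
  scores <- c(41, 7, 93, 28, 66, 12, 85, 52, 3, 77, 60, 19, 34, 71, 48,
              90, 25, 56, 9, 81, 37, 63, 15, 95, 44)   # 25 distinct values
  lab <- label_extreme_days(scores, k = 9)
  expect_equal(nrow(lab), 18)
  expect_equal(sum(lab$label == "high"), 9)
  expect_equal(sum(lab$label == "low"), 9)
  expect_true(all(lab$score[lab$label == "high"] >
                    max(lab$score[lab$label == "low"])))
  expect_setequal(setdiff(seq_along(scores), lab$day),
                  which(rank(scores) %in% 10:16))       # middle 7 dropped
})

test_that("tie-straddling selection matches the enumeration oracle", {
  set.seed(40)
  for (i in 1:30) {
    n <- sample(8:12, 1)
    scores <- sample(1:5, n, replace = TRUE)   # heavy ties
    if (sd(scores) == 0) next
    k <- sample(2:3, 1)
    lab <- label_extreme_days(scores, k = k)
    oracle <- extreme_oracle(scores, k)
    expect_equal(sort(lab$day[lab$label == "low"]), oracle$low)
    expect_equal(sort(lab$day[lab$label == "high"]), oracle$high)
  }
})

test_that("constant or short series are dropped with a reason", {
  lab <- label_extreme_days(rep(0, 25), k = 9)
  expect_equal(nrow(lab), 0)
  expect_match(attr(lab, "dropped_reason"), "constant")
  lab2 <- label_extreme_days(c(1, 2, 3), k = 9)
  expect_match(attr(lab2, "dropped_reason"), "fewer")
})

test_that("ambiguity exclusion removes shared score values from both sets", {
  labeled <- tibble::tibble(
    subject_id = "S1",
    day = 1:8,
    score = c(10, 20, 40, 40, 40, 60, 70, 80),
    label = c("low", "low", "low", "low", "high", "high", "high", "high")
  )
  res <- exclude_ambiguous(labeled)
  # Brute force: 40 appears in both sets, so days 3, 4, 5 all go.
  expect_setequal(res$cases$day, c(1, 2, 6, 7, 8))
  expect_setequal(res$log$day, c(3, 4, 5))

  distinct <- tibble::tibble(subject_id = "S2", day = 1:6,
                             score = c(1, 2, 3, 7, 8, 9),
                             label = rep(c("low", "high"), each = 3))
  res2 <- exclude_ambiguous(distinct)
  expect_equal(nrow(res2$cases), 6)
  expect_equal(nrow(res2$log), 0)

  all_shared <- tibble::tibble(subject_id = "S3", day = 1:4,
                               score = c(5, 5, 5, 5),
                               label = c("low", "low", "high", "high"))
  res3 <- exclude_ambiguous(all_shared)
  expect_equal(nrow(res3$cases), 0)
  expect_true(any(grepl("subject removed", res3$log$reason)))
})

test_that("patient dataset carries 18 cases per subject before exclusion", {
  cfg <- tiny_config(seed = 50)
  views <- build_analysis_views(generate_cohort(cfg))
  ds <- extreme_day_dataset(views$smoothed, "patient", k = 9)
  expect_equal(ds$n_pre_exclusion, 18 * cfg$n_patients)
  expect_true(all(table(ds$cases$subject_id) <= 18))
  expect_setequal(ds$feature_names, cfg$analyte_names)
  # No retained score value sits in both of a subject's sets.
  for (sid in unique(ds$cases$subject_id)) {
    sub <- ds$cases[ds$cases$subject_id == sid, ]
    expect_length(intersect(sub$score[sub$label == "high"],
                            sub$score[sub$label == "low"]), 0)
  }
})

test_that("zero-fatigue controls contribute no cases and are logged", {
  cfg <- tiny_config(seed = 51)
  views <- build_analysis_views(generate_cohort(cfg))
  ds <- extreme_day_dataset(views$smoothed, "control", k = 9)
  zero <- subject_profiles(cfg)$subject_id[subject_profiles(cfg)$zero_fatigue]
  expect_length(intersect(unique(ds$cases$subject_id), zero), 0)
  expect_true(all(zero %in% ds$exclusion_log$subject_id))
})

test_that("the linear SVM separates a separable toy and rejects one-class data", {
  set.seed(60)
  n <- 40
  cases <- tibble::tibble(
    subject_id = "T", day = 1:n,
    score = seq_len(n),
    label = rep(c("low", "high"), each = n / 2),
    f1 = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
    f2 = rnorm(n)
  )
  ds <- list(cases = cases, feature_names = c("f1", "f2"))
  fit <- train_linear_classifier(ds, cost = 1)
  pred <- predict(fit, as.matrix(cases[, c("f1", "f2")]))
  expect_equal(mean(pred == cases$label), 1)
  expect_gt(abs(fit$weights["f1"]), abs(fit$weights["f2"]))

  ds1 <- list(cases = cases[cases$label == "low", ],
              feature_names = c("f1", "f2"))
  expect_error(train_linear_classifier(ds1), "both classes")
})

test_that("randomly permuted labels give chance-level cross-validation", {
  set.seed(61)
  n <- 500
  cases <- tibble::tibble(
    subject_id = rep(sprintf("S%02d", 1:10), each = n / 10),
    day = rep(1:(n / 10), 10),
    score = rnorm(n),
    label = sample(rep(c("low", "high"), n / 2)),
    f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n)
  )
  ds <- structure(list(cases = cases, feature_names = c("f1", "f2", "f3"),
                       k = 25, group = "toy"),
                  class = "extreme_day_dataset")
  fit <- train_linear_classifier(ds)
  train_acc <- mean(predict(fit, ds) == cases$label)
  expect_lt(train_acc, 0.75)           # noise cannot be memorized linearly
  cv <- cross_validate(ds, folds = 10, seed = 2)
  band <- 1.96 * 100 * sqrt(0.25 / n)
  expect_lt(abs(cv$accuracy - 50), band + 2)
})

test_that("cross-validation folds partition the cases and are stratified", {
  cfg <- tiny_config(seed = 52)
  views <- build_analysis_views(generate_cohort(cfg))
  ds <- extreme_day_dataset(views$smoothed, "patient")
  cv <- cross_validate(ds, folds = 10, seed = 7)
  expect_equal(nrow(cv$folds), nrow(ds$cases))
  expect_setequal(unique(cv$folds$fold), 1:10)
  counts <- table(cv$folds$fold, cv$folds$label)
  expect_true(max(counts) - min(counts) <= 1)   # stratified balance
  # Same seed, same folds; different seed, different folds.
  expect_identical(cv$folds, cross_validate(ds, folds = 10, seed = 7)$folds)
  expect_false(identical(cv$folds$fold,
                         cross_validate(ds, folds = 10, seed = 8)$folds$fold))
  expect_error(cross_validate(ds, folds = nrow(ds$cases) + 1), "folds")
})

test_that("grouped cross-validation keeps whole subjects in one fold", {
  cfg <- tiny_config(seed = 53)
  views <- build_analysis_views(generate_cohort(cfg))
  ds <- extreme_day_dataset(views$smoothed, "patient")
  cv <- cross_validate(ds, folds = 5, seed = 3, grouped = TRUE)
  spread <- tapply(cv$folds$fold, cv$folds$subject_id,
                   function(f) length(unique(f)))
  expect_true(all(spread == 1))
})

test_that("with equal class counts accuracy equals the mean of the recalls", {
  cfg <- tiny_config(seed = 54)
  views <- build_analysis_views(generate_cohort(cfg))
  ds <- extreme_day_dataset(views$smoothed, "patient")
  cv <- cross_validate(ds, folds = 10, seed = 4)
  expect_equal(cv$n_low, cv$n_high)
  expect_equal(cv$accuracy, (cv$recall_low + cv$recall_high) / 2)
})

test_that("transfer evaluation applies the frozen model and keeps the books", {
  cfg <- tiny_config(seed = 55)
  views <- build_analysis_views(generate_cohort(cfg))
  ds_p <- extreme_day_dataset(views$smoothed, "patient")
  ds_c <- extreme_day_dataset(views$smoothed, "control")
  fit <- train_linear_classifier(ds_p)

  self <- transfer_evaluate(fit, ds_p)
  pred <- predict(fit, ds_p)
  expect_equal(self$accuracy, 100 * mean(pred == ds_p$cases$label))

  rep_c <- transfer_evaluate(fit, ds_c)
  expect_equal(rep_c$n_low, sum(ds_c$cases$label == "low"))
  expect_equal(rep_c$n_high, sum(ds_c$cases$label == "high"))
  expect_equal(rep_c$n, nrow(ds_c$cases))

  ds_bad <- ds_c
  ds_bad$feature_names <- rev(ds_bad$feature_names)
  expect_error(transfer_evaluate(fit, ds_bad), "feature mismatch")
})

test_that("decision weights localize the planted signal on leptin", {
  hits <- 0
  for (s in 1:5) {
    cfg <- tiny_config(seed = 500 + s)
    views <- build_analysis_views(generate_cohort(cfg))
    ds <- extreme_day_dataset(views$smoothed, "patient")
    fit <- train_linear_classifier(ds)
    rank_leptin <- which(names(sort(abs(fit$weights), decreasing = TRUE)) ==
                           "leptin")
    hits <- hits + (rank_leptin <= 4)   # top third of 12 features
  }
  expect_gte(hits, 3)
})

test_that("day-level CV is at least as optimistic as subject-grouped CV", {
  day_acc <- c(); grp_acc <- c()
  for (s in 1:5) {
    cfg <- tiny_config(seed = 600 + s)
    views <- build_analysis_views(generate_cohort(cfg))
    ds <- extreme_day_dataset(views$smoothed, "patient")
    day_acc <- c(day_acc, cross_validate(ds, 10, seed = s)$accuracy)
    grp_acc <- c(grp_acc, cross_validate(ds, 10, seed = s,
                                         grouped = TRUE)$accuracy)
  }
  expect_gte(mean(day_acc), mean(grp_acc) - 1)
})
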