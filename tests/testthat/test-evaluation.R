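# Splits, folds, metrics, scenarios, study grid.

test_that("stratified split partitions the data at the requested ratio", {
  s <- dummy_segments(rep(100, 10))                # 1000 segments
  sp <- split_dataset(s, 0.8, seed = 4)
  expect_identical(n_segments(sp$train), 800L)
  expect_identical(n_segments(sp$test), 200L)
  # partition: disjoint by provenance, exhaustive
  key <- function(x) paste(x$recording_id, x$start)
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  expect_setequal(c(key(sp$train), key(sp$test)), key(s))
  # per-subject share within one segment of 0.8 x count
  for (lab in 0:9)
    expect_lte(abs(sum(sp$train$subject == lab) - 80), 1)

  expect_warning(split_dataset(dummy_segments(c(3, 50)), 0.8, 1),
                 "stratification")
  expect_error(split_dataset(s, 1.2, 1), "train_fraction")
})

test_that("k-fold partition is balanced, stratified, and exhaustive", {
  s <- dummy_segments(rep(50, 16))                 # 800 segments
  folds <- kfold_partition(s, 5, seed = 9)
  expect_length(folds, 5)
  sizes <- vapply(folds, function(f) n_segments(f$val), 0L)
  expect_identical(sizes, rep(160L, 5))            # five equal subsets
  # every segment validated exactly once
  all_idx <- sort(unlist(lapply(folds, `[[`, "val_idx")))
  expect_identical(all_idx, seq_len(800L))
  # stratification: every subject appears in every validation fold
  for (f in folds)
    expect_identical(sort(unique(f$val$subject)), 0:15)
  # train/val complementary within each fold
  for (f in folds)
    expect_identical(n_segments(f$train) + n_segments(f$val), 800L)

  # uneven totals still balance within one segment
  s2 <- dummy_segments(c(7, 9, 11))
  sizes2 <- vapply(kfold_partition(s2, 4, 1), function(f)
    n_segments(f$val), 0L)
  expect_lte(max(sizes2) - min(sizes2), 1L)

  expect_error(kfold_partition(s2, 1, 1), "invalid-k")
  expect_error(kfold_partition(s2, 100, 1), "invalid-k")
})

test_that("confusion matrices match a brute-force tally", {
  expect_identical(unname(diag(confusion_matrix(0:2, 0:2, 3))), rep(1L, 3))
  cm <- confusion_matrix(c(0L, 0L), c(1L, 1L), 2)
  expect_identical(cm[1, 2], 2L)
  expect_identical(sum(cm), 2L)

  withr::with_seed(7, {
    y_t <- sample.int(5, 200, replace = TRUE) - 1L
    y_p <- sample.int(5, 200, replace = TRUE) - 1L
    cm <- confusion_matrix(y_t, y_p, 5)
    for (i in 0:4) for (j in 0:4)
      expect_identical(cm[i + 1, j + 1], sum(y_t == i & y_p == j))
  })
  expect_error(confusion_matrix(0:2, 0:1, 3), "input error")
  expect_error(confusion_matrix(c(0L, 5L), c(0L, 1L), 3), "input error")
})

test_that("metrics reproduce the worked 3x3 example", {
  cm <- confusion_matrix(rep(0:2, c(5, 5, 5)),
                         c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 0, 2, 2, 2, 2), 3)
  expect_identical(unname(unclass(cm)),
                   matrix(c(4L, 0L, 1L, 1L, 5L, 0L, 0L, 0L, 4L), 3))
  m <- compute_metrics(cm)
  expect_equal(m$average_accuracy, 100 * 41 / 45, tolerance = 1e-12)
  expect_equal(m$macro_precision, 100 * mean(c(4 / 5, 5 / 6, 1)),
               tolerance = 1e-12)
  expect_equal(m$macro_recall, 100 * mean(c(0.8, 1, 0.8)), tolerance = 1e-12)
  expect_equal(m$macro_f1, 2 * m$macro_precision * m$macro_recall /
                 (m$macro_precision + m$macro_recall), tolerance = 1e-12)
  expect_equal(m$plain_accuracy, 100 * 13 / 15, tolerance = 1e-12)

  perfect <- compute_metrics(confusion_matrix(0:2, 0:2, 3))
  expect_equal(unname(unlist(perfect[1:5])), rep(100, 5))
})

test_that("metrics are symmetric under transposition and guard degenerates", {
  withr::with_seed(11, {
    for (i in 1:20) {
      K <- sample(2:8, 1)
      cm <- random_confusion(K)
      m <- compute_metrics(cm)
      cm_t <- cm
      cm_t[, ] <- t(unclass(cm))
      mt <- compute_metrics(cm_t)
      expect_equal(m$macro_precision, mt$macro_recall, tolerance = 1e-12)
      expect_equal(m$macro_recall, mt$macro_precision, tolerance = 1e-12)
    }
  })
  # class never predicted -> zero-denominator precision flagged, contributes 0
  cm <- confusion_matrix(c(0L, 1L, 1L), c(0L, 0L, 0L), 2)
  expect_warning(m <- compute_metrics(cm), "zero-denominator")
  expect_identical(unname(m$zero_denominator$precision), 1L)
  expect_equal(m$macro_precision, 100 * mean(c(1 / 3, 0)), tolerance = 1e-12)
  expect_error(compute_metrics(confusion_matrix(integer(0), integer(0), 2)),
               "invalid-input")
})

test_that("scenarios assemble the right task unions", {
  sets <- list(
    dummy_segments(c(5, 5), seed = 1), dummy_segments(c(4, 4), seed = 2),
    dummy_segments(c(3, 3), seed = 3), dummy_segments(c(2, 2), seed = 4)
  )
  for (i in seq_along(sets)) {
    sets[[i]]$task <- rep(c("rest","level1","level2","level3")[i], n_segments(sets[[i]]))
    sets[[i]]$recording_id <- paste0(sets[[i]]$recording_id, c("rest","level1","level2","level3")[i])
  }
  all <- concat_segments(sets)
  expect_identical(unique(build_scenario(all, "rest")$task), "rest")
  game <- build_scenario(all, "game_fusion")
  expect_identical(n_segments(game), 8L + 6L + 4L)
  fusion <- build_scenario(all, "all_fusion")
  expect_identical(n_segments(fusion), n_segments(game) + 10L)
  expect_error(build_scenario(sets[[1]], "level2"), "scenario error")
  expect_error(build_scenario(all, "bogus"), "scenario error")
})

test_that("the study grid enumerates exactly 104 deterministic cases", {
  cases <- enumerate_cases()
  expect_identical(nrow(cases), 104L)
  expect_identical(cases$case_id, 1:104)
  expect_identical(enumerate_cases(), cases)       # deterministic
  one <- enumerate_cases("A")
  expect_identical(nrow(one), 52L)
  per <- table(one$scenario)
  expect_identical(as.integer(per[c("rest", "level1", "level2", "level3")]),
                   rep(11L, 4))
  expect_identical(as.integer(per[c("game_fusion", "all_fusion")]),
                   rep(4L, 2))
  rest <- one[one$scenario == "rest", "regions"]
  expect_identical(sum(nchar(rest) == 3), 6L)      # six region pairs
  expect_identical(sum(nchar(rest) == 1), 4L)      # four single regions
  fus <- one[one$scenario == "game_fusion", "regions"]
  expect_setequal(fus, c("F,C,P,O", "F,P", "C,O", "C,P"))
})

test_that("cross-validated cases recover a separable toy cohort", {
  segs <- small_cohort_segments()                  # 4 subjects, strong
  case <- list(variant = "A", scenario = "rest", regions = "F,C,P,O")
  tc <- train_config(max_epochs = 10, batch_size = 8, seed = 2)
  cv <- run_cv_case(case, segs, tc, k = 4, seed = 3)
  expect_length(cv$per_fold, 4)
  expect_gte(cv$mean[["plain_accuracy"]], 90)
  expect_gte(cv$mean[["average_accuracy"]], cv$mean[["plain_accuracy"]])

  # shuffled-label control collapses to chance
  shuffled <- segs
  shuffled$subject <- withr::with_seed(8, sample(segs$subject))
  cvs <- run_cv_case(case, shuffled, tc, k = 4, seed = 3)
  expect_lt(cvs$mean[["plain_accuracy"]], 25 + 20)  # chance 25%, wide MC band
})

test_that("more channels never hurt, trendwise over seeds", {
  # all 8 channels >= a 4-channel region pair >= one of its single regions,
  # on means over three fold seeds (small slack for Monte-Carlo noise)
  segs <- small_cohort_segments()
  acc_for <- function(regions, seed) {
    case <- list(variant = "A", scenario = "rest",
                 regions = paste(regions, collapse = ","))
    cv <- run_cv_case(case, segs,
                      train_config(max_epochs = 8, batch_size = 8,
                                   seed = seed),
                      k = 3, seed = seed)
    cv$mean[["plain_accuracy"]]
  }
  seeds <- c(31, 32, 33)
  a8 <- mean(vapply(seeds, function(s) acc_for(c("F", "C", "P", "O"), s), 0))
  a4 <- mean(vapply(seeds, function(s) acc_for(c("C", "O"), s), 0))
  a2 <- mean(vapply(seeds, function(s) acc_for("O", s), 0))
  expect_gte(a8, a4 - 3)
  expect_gte(a4, a2 - 3)
})

test_that("finalization scores untouched test segments and guards leakage", {
  segs <- small_cohort_segments()
  sp <- split_dataset(segs, 0.8, seed = 12)
  case <- list(variant = "A", scenario = "rest", regions = "F,C,P,O")
  fin <- finalize_case(case, sp$train, sp$test,
                       train_config(10, batch_size = 8, seed = 4),
                       seed = 5, val_fraction = 0.15)
  expect_s3_class(fin$metrics, "metrics_report")
  expect_gte(fin$metrics$plain_accuracy, 80)
  expect_identical(sum(fin$confusion), n_segments(sp$test))

  # overlapping pools are rejected
  expect_error(finalize_case(case, segs, sp$test, train_config(2, seed = 1)),
               "leakage")
  # single-subject test set is rejected, not silently perfect
  solo <- subset_segments(sp$test, sp$test$subject == 0)
  expect_error(finalize_case(case, sp$train, solo, train_config(2, seed = 1)),
               "at least 2 subjects")
})
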