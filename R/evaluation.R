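#' Stratified train/test split of a segment set
#'
#' Segments are split subject-by-subject so every class keeps (close to)
#' the requested proportion on each side. The split is a pure function of
#' the seed.
#'
#' @param s A [segment_set()].
#' @param train_fraction Proportion assigned to training, in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` segment sets; together they
#'   partition the input.
#' @export
split_dataset <- function(s, train_fraction = 0.8, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must lie strictly between 0 and 1")
  n <- n_segments(s)
  counts <- table(s$subject)
  if (any(counts < 5))
    warnf("stratification warning: subject(s) %s have fewer than 5 segments",
          paste(names(counts)[counts < 5], collapse = ", "))
  train_idx <- local_seed(seed, {
    unlist(lapply(unique(s$subject), function(lab) {
      idx <- which(s$subject == lab)
      idx <- sample(idx)
      idx[seq_len(round(train_fraction * length(idx)))]
    }))
  })
  train_idx <- sort(train_idx)
  list(train = subset_segments(s, train_idx),
       test = subset_segments(s, setdiff(seq_len(n), train_idx)))
}

#' Stratified k-fold partition
#'
#' Assigns segments to `k` folds, balancing fold sizes globally (equal
#' within one segment) and per subject (so every class appears in every
#' validation fold). Yields the standard rotation: fold `i` is validation,
#' the remaining `k - 1` folds are training.
#'
#' @param train A [segment_set()] (the training portion of the data).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of `k` elements, each with `train`, `val`, and the
#'   validation indices `val_idx` into the input set; also carries the
#'   full `assignment` vector as an attribute.
#' @export
kfold_partition <- function(train, k = 5, seed = 1) {
  n <- n_segments(train)
  if (k < 2) stopf("invalid-k: need k >= 2")
  if (k > n) stopf("invalid-k: k = %d exceeds %d segments", k, n)
  assignment <- integer(n)
  sizes <- integer(k)
  local_seed(seed, {
    for (lab in sample(unique(train$subject))) {
      idx <- sample(which(train$subject == lab))
      for (i in idx) {
        f <- order(sizes, runif(k))[1]  # smallest fold, random tie-break
        assignment[i] <- f
        sizes[f] <- sizes[f] + 1L
      }
    }
  })
  folds <- lapply(seq_len(k), function(f) {
    val_idx <- which(assignment == f)
    list(train = subset_segments(train, which(assignment != f)),
         val = subset_segments(train, val_idx),
         val_idx = val_idx)
  })
  attr(folds, "assignment") <- assignment
  folds
}

#' Confusion matrix
#'
#' @param y_true,y_pred Integer label vectors in `[0, K)`.
#' @param K Number of classes.
#' @return K x K integer matrix of class `confusion_matrix`; rows are
#'   true classes, columns predicted classes.
#' @export
confusion_matrix <- function(y_true, y_pred, K) {
  if (length(y_true) != length(y_pred))
    stopf("input error: label vectors differ in length")
  if (any(c(y_true, y_pred) < 0 | c(y_true, y_pred) >= K))
    stopf("input error: labels outside [0, %d)", K)
  cm <- matrix(0L, K, K, dimnames = list(true = 0:(K - 1), pred = 0:(K - 1)))
  for (t in seq_along(y_true))
    cm[y_true[t] + 1L, y_pred[t] + 1L] <- cm[y_true[t] + 1L, y_pred[t] + 1L] + 1L
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Multiclass identification metrics
#'
#' One-vs-rest macro metrics, all expressed as percentages:
#' * `average_accuracy`: mean over classes of binary accuracy
#'   `(TP_k + TN_k) / total`;
#' * `macro_precision` / `macro_recall`: means of per-class precision and
#'   recall (a class with zero denominator contributes 0 and is flagged);
#' * `macro_f1`: harmonic mean of the two macro values (not the mean of
#'   per-class F1);
#' * `plain_accuracy`: `trace / total`, reported as a diagnostic because
#'   the macro-averaged one-vs-rest accuracy is systematically higher for
#'   large K.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `metrics_report`.
#' @export
compute_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) stopf("invalid-input: empty confusion matrix")
  K <- nrow(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  safe_ratio <- function(num, den) ifelse(den > 0, num / den, 0)
  zero_prec <- (tp + fp) == 0
  zero_rec <- (tp + fn) == 0
  if (any(zero_prec) || any(zero_rec))
    warnf("zero-denominator class(es) contribute 0 to the macro average")
  precision <- 100 * mean(safe_ratio(tp, tp + fp))
  recall <- 100 * mean(safe_ratio(tp, tp + fn))
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(
    list(
      average_accuracy = 100 * mean((tp + tn) / total),
      macro_precision = precision,
      macro_recall = recall,
      macro_f1 = f1,
      plain_accuracy = 100 * sum(tp) / total,
      zero_denominator = list(precision = which(zero_prec) - 1L,
                              recall = which(zero_rec) - 1L)
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<metrics_report> avg accuracy %.2f%% | macro precision %.2f%% | ",
    "macro recall %.2f%% | macro F1 %.2f%% | plain accuracy %.2f%%\n"),
    x$average_accuracy, x$macro_precision, x$macro_recall, x$macro_f1,
    x$plain_accuracy))
  invisible(x)
}

metrics_vector <- function(m) {
  c(average_accuracy = m$average_accuracy,
    macro_precision = m$macro_precision,
    macro_recall = m$macro_recall,
    macro_f1 = m$macro_f1,
    plain_accuracy = m$plain_accuracy)
}

scenario_levels <- c("rest", "level1", "level2", "level3",
                     "game_fusion", "all_fusion")

scenario_tasks <- function(scenario) {
  switch(scenario,
    rest = "rest", level1 = "level1", level2 = "level2", level3 = "level3",
    game_fusion = c("level1", "level2", "level3"),
    all_fusion = task_levels,
    stopf("scenario error: unknown scenario '%s'", scenario)
  )
}

#' Assemble the segment pool for a task scenario
#'
#' Individual scenarios keep one task's segments; `game_fusion`
#' concatenates the three game levels; `all_fusion` adds the resting
#' state. Provenance is retained.
#'
#' @param segments A [segment_set()] containing all tasks.
#' @param scenario One of `"rest"`, `"level1"`, `"level2"`, `"level3"`,
#'   `"game_fusion"`, `"all_fusion"`.
#' @return A [segment_set()] restricted to the scenario's tasks.
#' @export
build_scenario <- function(segments, scenario) {
  tasks <- scenario_tasks(scenario)
  missing <- setdiff(tasks, unique(segments$task))
  if (length(missing))
    stopf("scenario error: task(s) %s absent from data",
          paste(missing, collapse = ", "))
  subset_segments(segments, segments$task %in% tasks)
}

region_pairs <- list(c("F", "C"), c("F", "O"), c("F", "P"),
                     c("C", "O"), c("C", "P"), c("P", "O"))
fusion_pairs <- list(c("F", "P"), c("C", "O"), c("C", "P"))
all_regions <- c("F", "C", "P", "O")

#' Enumerate the channel-reduction study grid
#'
#' For each model variant: the four individual-task scenarios are
#' crossed with all 8 channels, the 6 two-region (4-channel)
#' combinations, and the 4 single regions; the two fusion scenarios are
#' crossed with all 8 channels and the 3 selected two-region
#' combinations (frontal+parietal, central+occipital, central+parietal).
#' Totals 104 cases for both variants: 2 x [4 x (1+6+4) + 2 x (1+3)].
#'
#' @param variants Character vector of model variants to include.
#' @return Data frame with columns `case_id`, `variant`, `scenario`,
#'   `regions` (comma-separated region codes).
#' @export
enumerate_cases <- function(variants = c("A", "B")) {
  rows <- list()
  for (v in variants) {
    for (sc in scenario_levels) {
      subsets <- if (sc %in% c("game_fusion", "all_fusion"))
        c(list(all_regions), fusion_pairs)
      else
        c(list(all_regions), region_pairs, as.list(all_regions))
      for (sub in subsets)
        rows[[length(rows) + 1L]] <-
          data.frame(variant = v, scenario = sc,
                     regions = paste(sub, collapse = ","))
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(case_id = seq_len(nrow(out)), out)
  out
}

case_regions <- function(case) strsplit(case$regions, ",")[[1]]

# Region selection + CAR, the per-case tail of the fixed pipeline.
prepare_case_segments <- function(segments, regions) {
  apply_car(select_regions(segments, regions))
}

#' Run one study case under k-fold cross-validation
#'
#' Applies region selection and CAR for the case, partitions the training
#' pool into `k` stratified folds, and for each fold fits normalization
#' statistics on the fold's training side, trains a fresh model, and
#' evaluates on the validation fold.
#'
#' @param case One row of [enumerate_cases()] (data frame or list with
#'   `variant`, `scenario`, `regions`).
#' @param train_pool The scenario's training segment pool (all 8
#'   channels; see [build_scenario()] and [split_dataset()]).
#' @param tc A [train_config()].
#' @param k Number of folds.
#' @param seed Seed for fold assignment and per-fold training.
#' @param verbose Print per-epoch training progress.
#' @return An object of class `cv_result`: per-fold metrics reports plus
#'   mean and sample SD (n-1) per metric.
#' @export
run_cv_case <- function(case, train_pool, tc = train_config(), k = 5,
                        seed = 1, verbose = FALSE) {
  segs <- prepare_case_segments(train_pool, case_regions(case))
  n_classes <- length(unique(segs$subject))
  seeds <- derive_seeds(seed, k + 1)
  folds <- kfold_partition(segs, k, seeds[k + 1])
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    stats <- fit_normalization(folds[[f]]$train)
    tr <- apply_normalization(folds[[f]]$train, stats)
    va <- apply_normalization(folds[[f]]$val, stats)
    cfg <- model_config(case$variant, length(segs$channels), n_classes)
    tc_f <- tc
    tc_f$seed <- seeds[f]
    fit <- train_model(build_model(cfg), tr, va, tc_f, verbose = verbose)
    pred <- predict(fit, va)
    per_fold[[f]] <- compute_metrics(
      confusion_matrix(va$subject, pred$labels, n_classes))
  }
  tab <- do.call(rbind, lapply(per_fold, metrics_vector))
  structure(
    list(case = case, per_fold = per_fold,
         mean = colMeans(tab), sd = apply(tab, 2, sd), k = k),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s / %s / regions %s (%d folds)\n",
              x$case$variant, x$case$scenario, x$case$regions, x$k))
  for (m in names(x$mean))
    cat(sprintf("  %-18s %6.2f +/- %.2f %%\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}

#' Train and test the final model for a case
#'
#' Retrains on the full training pool, holding out an internal stratified
#' `val_fraction` for checkpoint selection (the retrain step needs a
#' validation signal), and reports metrics on the untouched test
#' segments. Normalization statistics come from the internal training
#' portion only.
#'
#' @param case A study case (see [run_cv_case()]).
#' @param train_pool,test_pool Scenario segment pools (all 8 channels)
#'   from [split_dataset()].
#' @param tc A [train_config()].
#' @param seed Integer seed.
#' @param val_fraction Internal holdout fraction for checkpointing.
#' @param verbose Print per-epoch training progress.
#' @return List with `metrics` (a `metrics_report`), `confusion`, the
#'   trained `model`, and the `case`.
#' @export
finalize_case <- function(case, train_pool, test_pool, tc = train_config(),
                          seed = 1, val_fraction = 0.1, verbose = FALSE) {
  if (length(unique(test_pool$subject)) < 2)
    stopf("invalid-data: test subset must contain at least 2 subjects")
  overlap <- intersect(
    paste(train_pool$recording_id, train_pool$start),
    paste(test_pool$recording_id, test_pool$start))
  if (length(overlap))
    stopf("leakage: %d segments shared between train and test pools",
          length(overlap))
  regions <- case_regions(case)
  tr_all <- prepare_case_segments(train_pool, regions)
  te <- prepare_case_segments(test_pool, regions)
  n_classes <- length(unique(tr_all$subject))
  seeds <- derive_seeds(seed, 2)
  inner <- split_dataset(tr_all, 1 - val_fraction, seeds[1])
  stats <- fit_normalization(inner$train)
  tr <- apply_normalization(inner$train, stats)
  va <- apply_normalization(inner$test, stats)
  te <- apply_normalization(te, stats)
  cfg <- model_config(case$variant, length(tr_all$channels), n_classes)
  tc_f <- tc
  tc_f$seed <- seeds[2]
  fit <- train_model(build_model(cfg), tr, va, tc_f, verbose = verbose)
  pred <- predict(fit, te)
  cm <- confusion_matrix(te$subject, pred$labels, n_classes)
  list(case = case, metrics = compute_metrics(cm), confusion = cm,
       model = fit)
}
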