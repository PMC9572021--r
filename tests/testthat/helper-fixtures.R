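# Shared fixtures: all synthetic, built in code at test time.

# Toy separable segment set: each class has a distinct dominant frequency,
# so a working classifier must reach ~100% on it.
toy_segments <- function(n_per_class = 30, n_classes = 3, L = 250, C = 2,
                         fs = 250, freqs = c(5, 11, 23, 37), noise = 0.3,
                         seed = 1) {
  withr::with_seed(seed, {
    n <- n_per_class * n_classes
    data <- array(0, c(C, L, n))
    y <- integer(n)
    t <- (0:(L - 1)) / fs
    i <- 0
    for (k in seq_len(n_classes)) {
      for (j in seq_len(n_per_class)) {
        i <- i + 1
        for (c in seq_len(C))
          data[c, , i] <- sin(2 * pi * freqs[k] * t + runif(1, 0, 2 * pi)) +
            noise * rnorm(L)
        y[i] <- k - 1L
      }
    }
    segment_set(data, c("F3", "F4", "C3", "C4")[seq_len(C)], fs, y,
                rep("rest", n), rep(0L, n), sprintf("toy%d", y), L, L)
  })
}

# Random-valued segment set with controllable per-subject counts, for
# split/fold bookkeeping tests (content is irrelevant there).
dummy_segments <- function(counts, L = 40, C = 2, seed = 1) {
  withr::with_seed(seed, {
    n <- sum(counts)
    subject <- rep(seq_along(counts) - 1L, counts)
    segment_set(array(rnorm(C * L * n), c(C, L, n)),
                c("C3", "C4", "O1", "O2")[seq_len(C)], 1000, subject,
                rep("rest", n),
                start = unlist(lapply(counts, function(k) 500L * (seq_len(k) - 1L))),
                recording_id = sprintf("s%d_rest", subject), L, L)
  })
}

# Small simulated cohort, memoized across test files (generation is the
# expensive part). Rest-task only, reduced rate and duration.
.fixture_cache <- new.env(parent = emptyenv())

small_cohort_segments <- function(n_subjects = 4, seed = 5, fs = 250,
                                  duration_s = 60, preset = "strong") {
  key <- paste("cohort", n_subjects, seed, fs, duration_s, preset, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cohort <- make_cohort(n_subjects, seed, preset)
  profiles <- default_profiles(duration_s)
  recs <- lapply(cohort, function(s)
    simulate_recording(s, profiles$rest, fs_hz = fs, seed = s$seed))
  segs <- preprocess_recordings(recs, filter_spec(), 1000, 500)
  .fixture_cache[[key]] <- segs
  segs
}

# Independent brute-force implementation of the one-vs-rest metrics,
# written as explicit per-class loops (the oracle for compute_metrics).
oracle_metrics <- function(cm) {
  K <- nrow(cm)
  total <- sum(cm)
  acc <- prec <- rec <- numeric(K)
  for (k in seq_len(K)) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    acc[k] <- (tp + tn) / total
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
  }
  P <- 100 * sum(prec) / K
  R <- 100 * sum(rec) / K
  list(average_accuracy = 100 * sum(acc) / K,
       macro_precision = P, macro_recall = R,
       macro_f1 = if (P + R > 0) 2 * P * R / (P + R) else 0,
       plain_accuracy = 100 * sum(diag(cm)) / total)
}

random_confusion <- function(K, n = 200) {
  y_true <- sample.int(K, n, replace = TRUE) - 1L
  y_pred <- sample.int(K, n, replace = TRUE) - 1L
  confusion_matrix(y_true, y_pred, K)
}

# RMS helper for filter tests.
rms <- function(x) sqrt(mean(x^2))

make_recording <- function(data, fs = 1000, subject = 0L, task = "rest") {
  recording(data, MONTAGE[seq_len(nrow(data))], fs, subject, task)
}
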