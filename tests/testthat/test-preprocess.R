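# Segmentation, CAR, region selection, normalization.

test_that("CAR reproduces worked examples and the zero-sum identity", {
  r2 <- make_recording(matrix(c(10, 20), 2, 1))
  expect_equal(apply_car(r2)$data, matrix(c(-5, 5), 2, 1))

  r4 <- make_recording(matrix(c(1, 2, 3, 6), 4, 1))
  expect_equal(apply_car(r4)$data, matrix(c(-2, -1, 0, 3), 4, 1))

  withr::with_seed(1, {
    for (i in 1:20) {
      m <- matrix(rnorm(8 * 50, sd = 100), 8)
      out <- apply_car(make_recording(m))$data
      expect_lt(max(abs(colSums(out))) / max(1, max(abs(m))), 1e-9)
    }
  })
  expect_error(apply_car(make_recording(matrix(1, 1, 10))), "invalid-CAR")
})

test_that("CAR on segment sets matches CAR on the underlying matrices", {
  s <- dummy_segments(c(3, 3), C = 4)
  out <- apply_car(s)
  for (i in seq_len(n_segments(s)))
    expect_equal(out$data[, , i], sweep(s$data[, , i], 2,
                                        colMeans(s$data[, , i])),
                 tolerance = 1e-12)
})

test_that("region selection resolves montage channels in fixed order", {
  rec <- make_recording(matrix(seq_len(8 * 10), 8))
  fc <- select_regions(rec, c("F", "C"))
  expect_identical(fc$channels, c("F3", "F4", "C3", "C4"))
  # request order must not matter
  cf <- select_regions(rec, c("C", "F"))
  expect_identical(cf$channels, fc$channels)
  all8 <- select_regions(rec, c("F", "C", "P", "O"))
  expect_identical(all8$data, rec$data)
  expect_error(select_regions(rec, character(0)), "invalid-selection")
  expect_error(select_regions(rec, "X"), "invalid-selection")
})

test_that("segment counts follow floor((T - window)/step) + 1", {
  for (tc in list(c(999, 0), c(1000, 1), c(1500, 2), c(60000, 119))) {
    rec <- make_recording(matrix(0, 2, tc[1]))
    if (tc[2] == 0) {
      expect_warning(s <- segment_recording(rec, 1000, 500), "too short")
    } else {
      s <- segment_recording(rec, 1000, 500)
    }
    expect_identical(n_segments(s), as.integer(tc[2]))
  }
  expect_error(segment_recording(make_recording(matrix(0, 2, 100)), 0, 10),
               "invalid-segmentation")
  expect_error(segment_recording(make_recording(matrix(0, 2, 100)), 50, 0),
               "invalid-segmentation")
  expect_error(segment_recording(make_recording(matrix(0, 2, 100)), 50, 60),
               "invalid-segmentation")
})

test_that("segments carry lossless provenance and half-open windows", {
  rec <- make_recording(matrix(rep(0:2499, each = 2), 2), subject = 3L,
                        task = "level2")
  s <- segment_recording(rec, 1000, 500)
  expect_identical(s$start, c(0L, 500L, 1000L, 1500L))
  expect_identical(unique(s$subject), 3L)
  expect_identical(unique(s$task), "level2")
  # window k covers samples [k*step, k*step + window): check the content
  for (k in seq_len(n_segments(s)))
    expect_equal(s$data[1, , k], (s$start[k]):(s$start[k] + 999))
  # provenance triples are unique
  key <- paste(s$recording_id, s$task, s$start)
  expect_identical(anyDuplicated(key), 0L)
})

test_that("normalization implements the z-score with pooled training moments", {
  expect_equal((7 - 5) / 2, 1)  # the hand example the transform must match
  s <- dummy_segments(c(4, 4), L = 30, C = 2, seed = 3)
  s$data[1, , ] <- s$data[1, , ] * 2 + 5
  st <- fit_normalization(s)
  flat1 <- as.vector(s$data[1, , ])
  expect_equal(st$mu[1], mean(flat1), tolerance = 1e-12)
  expect_equal(st$sigma[1], sd(flat1), tolerance = 1e-12)

  norm <- apply_normalization(s, st)
  expect_true(norm$normalized)
  for (c in 1:2) {
    pooled <- as.vector(norm$data[c, , ])
    expect_equal(mean(pooled), 0, tolerance = 1e-6)
    expect_equal(sd(pooled), 1, tolerance = 1e-6)
  }

  # a test set shifted by 3 sigma lands at pooled mean ~3
  shifted <- s
  shifted$data <- s$data + 3 * st$sigma  # recycles over channels
  norm_s <- apply_normalization(shifted, st)
  expect_equal(mean(norm_s$data[1, , ]), 3, tolerance = 1e-6)

  # constant channel: sigma floored, output zero
  s2 <- s
  s2$data[2, , ] <- 4
  st2 <- fit_normalization(s2)
  expect_identical(st2$sigma[2], 1e-8)
  expect_true(all(apply_normalization(s2, st2)$data[2, , ] == 0))

  expect_error(fit_normalization(subset_segments(s, integer(0))),
               "invalid-fit")
  bad <- dummy_segments(c(2, 2), C = 4)
  expect_error(apply_normalization(bad, st), "shape error")
})

test_that("the full front pipeline keeps shapes and kills line noise", {
  co <- make_cohort(2, 23)
  profs <- default_profiles(duration_s = 8)
  recs <- unlist(lapply(co, function(s)
    list(simulate_recording(s, profs$rest, fs_hz = 250, seed = s$seed),
         simulate_recording(s, profs$level1, fs_hz = 250,
                            seed = s$seed + 1))), recursive = FALSE)
  segs <- preprocess_recordings(recs, filter_spec(), 500, 250)
  expect_identical(dim(segs$data)[1:2], c(8L, 500L))
  expect_identical(n_segments(segs), 4L * 7L)  # 4 recordings x 7 windows
  expect_setequal(unique(segs$task), c("rest", "level1"))
  # powerline removed: 50 Hz no longer dominates its neighborhood
  x <- as.vector(segs$data[1, , 1])
  expect_lt(band_power(x, 250, c(49, 51), 256),
            band_power(x, 250, c(8, 13), 256))
})
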