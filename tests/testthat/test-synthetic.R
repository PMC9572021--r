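# Cohort generator: determinism, distinctness, spectral structure.

test_that("make_cohort is deterministic, distinct, and validates input", {
  co <- make_cohort(21, 7)
  expect_length(co, 21)
  expect_identical(vapply(co, `[[`, 0L, "subject_id"), 0:20)

  co2 <- make_cohort(21, 7)
  expect_identical(co, co2)                       # field-for-field

  co3 <- make_cohort(21, 8)
  peaks7 <- vapply(co, `[[`, 0, "alpha_peak_hz")
  peaks8 <- vapply(co3, `[[`, 0, "alpha_peak_hz")
  expect_true(any(peaks7 != peaks8))

  expect_gt(min(diff(sort(peaks7))), 0)           # pairwise distinct
  expect_true(all(peaks7 >= 8 & peaks7 <= 13))
  for (s in co) {
    expect_true(all(s$band_amplitudes > 0))
    expect_true(all(s$topography > 0))
  }
  expect_error(make_cohort(1, 1), "invalid-cohort")
})

test_that("simulated recordings are deterministic and well-formed", {
  sig <- make_cohort(3, 11)[[2]]
  prof <- default_profiles(duration_s = 8)$rest
  r1 <- simulate_recording(sig, prof, fs_hz = 250, seed = 99)
  r2 <- simulate_recording(sig, prof, fs_hz = 250, seed = 99)
  expect_identical(r1$data, r2$data)              # bit-identical
  expect_identical(r1$channels, MONTAGE)
  expect_identical(dim(r1$data), c(8L, 2000L))
  expect_true(all(is.finite(r1$data)))
  expect_error(simulate_recording(sig, prof, fs_hz = 100), "fs_hz")
})

test_that("the PSD shows the subject's alpha peak where it was planted", {
  co <- make_cohort(4, 31)
  prof <- default_profiles(duration_s = 40)$rest
  for (sig in co[1:2]) {
    rec <- simulate_recording(sig, prof, fs_hz = 500, seed = sig$seed)
    p <- welch_psd(rec$data[7, ], 500, nperseg = 512)  # O1
    res <- 500 / 512
    sel <- p$freq >= 8 & p$freq <= 13
    peak <- p$freq[sel][which.max(p$psd[sel])]
    expect_lt(abs(peak - sig$alpha_peak_hz), res + 1e-9)
  }
})

test_that("task load suppresses alpha and powerline behaves as configured", {
  sig <- make_cohort(3, 13)[[1]]
  profs <- default_profiles(duration_s = 20)
  rest <- simulate_recording(sig, profs$rest, fs_hz = 500, seed = 21)
  # force full-duration level3 so durations match
  l3 <- task_profile("level3", profs$level3$alpha_factor,
                     profs$level3$beta_factor, profs$level3$gamma_factor,
                     20, 1)
  hard <- simulate_recording(sig, l3, fs_hz = 500, seed = 22)
  a_rest <- band_power(rest$data[7, ], 500, "alpha", 1024)
  a_hard <- band_power(hard$data[7, ], 500, "alpha", 1024)
  expect_lt(a_hard, a_rest)                       # alpha suppression
  b_rest <- band_power(rest$data[3, ], 500, "beta", 1024)
  b_hard <- band_power(hard$data[3, ], 500, "beta", 1024)
  expect_gt(b_hard, b_rest)                       # beta enhancement

  quiet <- simulate_recording(sig, profs$rest, fs_hz = 500,
                              powerline_amp = 0, seed = 23)
  loud <- simulate_recording(sig, profs$rest, fs_hz = 500,
                             powerline_amp = 8, seed = 23)
  p_quiet <- welch_psd(quiet$data[1, ], 500, 1024)
  p_loud <- welch_psd(loud$data[1, ], 500, 1024)
  at50 <- which.min(abs(p_quiet$freq - 50))
  nbr <- which.min(abs(p_quiet$freq - 46))
  expect_lt(p_quiet$psd[at50], 3 * p_quiet$psd[nbr])   # no visible line
  expect_gt(p_loud$psd[at50], 10 * p_loud$psd[nbr])    # clear line
})

test_that("relative band powers across regions follow the topography", {
  # with no per-subject topography jitter the prototype ordering is exact:
  # alpha strongest occipital, delta strongest frontal
  sig <- make_cohort(2, 17, topo_sdlog = 1e-6)[[1]]
  rec <- simulate_recording(sig, default_profiles(30)$rest, fs_hz = 500,
                            seed = 3)
  region_power <- function(band) {
    vapply(c("F", "C", "P", "O"), function(rg) {
      idx <- match(REGIONS[[rg]], rec$channels)
      mean(vapply(idx, function(i)
        band_power(rec$data[i, ], 500, band, 1024), 0))
    }, 0)
  }
  alpha <- region_power("alpha")
  expect_identical(names(which.max(alpha)), "O")
  expect_gt(alpha[["O"]], alpha[["F"]])
  delta <- region_power("delta")
  expect_gt(delta[["F"]], delta[["O"]])
})

test_that("sessions cover the four tasks and honor completion probability", {
  sig <- make_cohort(2, 19)[[1]]
  profs <- default_profiles(duration_s = 6)
  recs <- simulate_session(sig, profs, seed = 4, fs_hz = 250)
  expect_named(recs, c("rest", "level1", "level2", "level3"))
  expect_true(all(vapply(recs, function(r) identical(r$channels, MONTAGE),
                         TRUE)))
  expect_error(simulate_session(sig, profs[c(1, 1, 2, 3)], seed = 1),
               "invalid-protocol")

  # completion_prob = 1 reaches nominal duration exactly
  full <- simulate_recording(sig, task_profile("level3", duration_s = 6,
                                               completion_prob = 1),
                             fs_hz = 250, seed = 8)
  expect_identical(ncol(full$data), 1500L)

  # Monte-Carlo completion fraction approximates 13/21
  p <- 13 / 21
  l3 <- task_profile("level3", duration_s = 4, completion_prob = p)
  done <- vapply(1:60, function(s)
    simulate_recording(sig, l3, fs_hz = 200, seed = 1000 + s)$meta$completed,
    TRUE)
  expect_lt(abs(mean(done) - p), 3 * sqrt(p * (1 - p) / 60))
})

test_that("wider alpha dispersion improves downstream identification", {
  # separability knob, trendwise over three dispersion levels x two seeds
  acc_for <- function(spread, seed) {
    co <- make_cohort(4, seed, "weak", alpha_spread = spread,
                      amp_sdlog = 0.03, topo_sdlog = 0.03)
    profs <- default_profiles(duration_s = 22)
    recs <- lapply(co, function(s)
      simulate_recording(s, profs$rest, fs_hz = 250, seed = s$seed))
    segs <- apply_car(preprocess_recordings(recs, filter_spec(), 1000, 500))
    folds <- kfold_partition(segs, 4, seed)
    st <- fit_normalization(folds[[1]]$train)
    tr <- apply_normalization(folds[[1]]$train, st)
    va <- apply_normalization(folds[[1]]$val, st)
    fit <- train_model(build_model(model_config("A", 8, 4)), tr, va,
                       train_config(max_epochs = 8, batch_size = 8, seed = seed))
    mean(predict(fit, va)$labels == va$subject)
  }
  spreads <- c(0.25, 1.5, 4.5)
  acc <- vapply(spreads, function(sp)
    mean(vapply(c(61, 62), function(s) acc_for(sp, s), 0)), 0)
  expect_gte(acc[2], acc[1] - 0.05)
  expect_gte(acc[3], acc[2] - 0.05)
  expect_gt(acc[3], acc[1])                       # overall trend is real
})
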