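#' @name synthetic
#' @title Synthetic EEG cohort generation
#' @description
#' The generator emulates the statistical structure that the
#' identification pipeline exploits: each subject carries a stable
#' spectral signature (an individual alpha-peak frequency, per-band
#' amplitudes, and a scalp topography over the four regions), on top of a
#' 1/f background, 50 Hz powerline interference, and slow drift. Task
#' load modulates the rhythms: alpha is suppressed and beta/gamma
#' enhanced as game difficulty rises. Oscillations are band-pass filtered
#' white noise, not sinusoids, so no two epochs repeat.
NULL

# Prototype region x band topography gains (rows F,C,P,O).
topo_prototype <- function() {
  m <- rbind(
    F = c(delta = 1.3, theta = 1.2, alpha = 0.7, beta = 1.0, gamma = 1.0),
    C = c(delta = 1.0, theta = 1.0, alpha = 0.9, beta = 1.2, gamma = 1.1),
    P = c(delta = 0.9, theta = 0.9, alpha = 1.3, beta = 1.0, gamma = 1.0),
    O = c(delta = 0.8, theta = 0.9, alpha = 1.6, beta = 0.9, gamma = 0.9)
  )
  m
}

# Baseline per-band RMS amplitudes in microvolts (eyes-closed adult EEG,
# alpha-dominant posteriorly).
base_band_amplitudes <- c(delta = 8, theta = 6, alpha = 12, beta = 5,
                          gamma = 2.5)

#' Generate a cohort of subject spectral signatures
#'
#' Draws `n_subjects` pairwise-distinct signatures. Two presets control
#' how separable subjects are: `"strong"` spreads alpha peaks across most
#' of the alpha band and draws widely varying amplitudes/topographies;
#' `"weak"` confines peaks to a narrow range with mild amplitude
#' variation, making identification genuinely hard.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Integer seed; the cohort is a pure function of
#'   `(n_subjects, seed, preset, ...)`.
#' @param preset `"strong"` or `"weak"` separability preset.
#' @param alpha_spread Width in Hz of the interval (centered at 10.5 Hz,
#'   clipped to the alpha band) over which subject alpha peaks are spread.
#'   Defaults: 4.6 (strong), 2.2 (weak).
#' @param amp_sdlog Log-SD of per-subject band-amplitude variation.
#'   Defaults: 0.8 (strong), 0.4 (weak). The strong default gives a
#'   spread factor of about 2.2x between subjects, consistent with the
#'   order-of-magnitude variation of absolute band power across healthy
#'   adults.
#' @param topo_sdlog Log-SD of per-subject topography variation.
#'   Defaults: 0.6 (strong), 0.3 (weak).
#' @return List of `eeg_signature` objects with `subject_id` 0 ..
#'   `n_subjects - 1`.
#' @export
make_cohort <- function(n_subjects, seed, preset = c("strong", "weak"),
                        alpha_spread = NULL, amp_sdlog = NULL,
                        topo_sdlog = NULL) {
  preset <- match.arg(preset)
  if (n_subjects < 2)
    stopf("invalid-cohort: need at least 2 subjects, got %d", n_subjects)
  alpha_spread <- alpha_spread %||% switch(preset, strong = 4.6, weak = 2.2)
  amp_sdlog <- amp_sdlog %||% switch(preset, strong = 0.8, weak = 0.4)
  topo_sdlog <- topo_sdlog %||% switch(preset, strong = 0.6, weak = 0.3)

  local_seed(seed, {
    lo <- max(EEG_BANDS$alpha[1] + 0.2, 10.5 - alpha_spread / 2)
    hi <- min(EEG_BANDS$alpha[2] - 0.2, 10.5 + alpha_spread / 2)
    # evenly spaced then jittered and permuted: guarantees distinct peaks
    peaks <- seq(lo, hi, length.out = n_subjects)
    jit <- min(0.04, (hi - lo) / (4 * n_subjects))
    peaks <- sample(peaks + runif(n_subjects, -jit, jit))
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
    proto <- topo_prototype()
    lapply(seq_len(n_subjects), function(i) {
      amps <- base_band_amplitudes * exp(rnorm(5, 0, amp_sdlog))
      topo <- proto * exp(matrix(rnorm(length(proto), 0, topo_sdlog),
                                 nrow(proto)))
      dimnames(topo) <- dimnames(proto)
      structure(
        list(
          subject_id = i - 1L,
          alpha_peak_hz = peaks[i],
          band_amplitudes = amps,
          topography = topo,
          noise_scale = runif(1, 2, 4),
          seed = sub_seeds[i]
        ),
        class = "eeg_signature"
      )
    })
  })
}

#' @export
print.eeg_signature <- function(x, ...) {
  cat(sprintf(
    "<eeg_signature> subject %d: alpha peak %.2f Hz, noise %.2f uV\n",
    x$subject_id, x$alpha_peak_hz, x$noise_scale
  ))
  invisible(x)
}

#' Task load profile
#'
#' Describes how one task of the acquisition protocol modulates the
#' subject's rhythms: cognitive load suppresses alpha and enhances
#' beta/gamma. `completion_prob` below 1 models subjects who abandon the
#' hardest game level before its nominal end.
#'
#' @param task_id One of `"rest"`, `"level1"`, `"level2"`, `"level3"`.
#' @param alpha_factor,beta_factor,gamma_factor Positive multipliers on
#'   the subject's band amplitudes.
#' @param duration_s Nominal task duration in seconds.
#' @param completion_prob Probability in (0, 1] that the full nominal
#'   duration is recorded.
#' @return An object of class `task_profile`.
#' @export
task_profile <- function(task_id, alpha_factor = 1, beta_factor = 1,
                         gamma_factor = 1, duration_s = 60,
                         completion_prob = 1) {
  check_task_id(task_id)
  if (alpha_factor <= 0 || beta_factor <= 0 || gamma_factor <= 0)
    stopf("invalid-profile: band factors must be positive")
  if (duration_s <= 0)
    stopf("invalid-profile: duration_s must be positive")
  if (completion_prob <= 0 || completion_prob > 1)
    stopf("invalid-profile: completion_prob must be in (0, 1]")
  structure(
    list(task_id = task_id, alpha_factor = alpha_factor,
         beta_factor = beta_factor, gamma_factor = gamma_factor,
         duration_s = duration_s, completion_prob = completion_prob),
    class = "task_profile"
  )
}

#' Default acquisition protocol
#'
#' Four tasks of 60 s nominal duration: eyes-closed rest followed by
#' three game levels of rising difficulty. Alpha suppression deepens and
#' beta/gamma enhancement grows with the level; the hardest level is
#' completed with probability 13/21, mirroring a cohort in which 8 of 21
#' players abandoned it.
#'
#' @param duration_s Nominal duration of each task in seconds.
#' @param level3_completion Completion probability of the hardest level.
#' @return Named list of four [task_profile] objects.
#' @export
default_profiles <- function(duration_s = 60, level3_completion = 13 / 21) {
  list(
    rest   = task_profile("rest",   1.00, 1.0, 1.0, duration_s, 1),
    level1 = task_profile("level1", 0.80, 1.2, 1.1, duration_s, 1),
    level2 = task_profile("level2", 0.65, 1.4, 1.25, duration_s, 1),
    level3 = task_profile("level3", 0.50, 1.6, 1.4, duration_s,
                          level3_completion)
  )
}

# Unit-RMS band-limited noise: white noise through a zero-phase
# Butterworth high/low cascade. Broad bands use gentle (order-2) edges;
# the alpha component uses steep (order-6) edges so each subject shows a
# distinct narrow spectral peak above the 1/f background.
band_noise <- function(n, fs, lo, hi, order = 2) {
  x <- rnorm(n)
  hp <- butter_design(order, lo, fs, "high")
  lp <- butter_design(order, hi, fs, "low")
  y <- filtfilt(lp$b, lp$a, filtfilt(hp$b, hp$a, x))
  y / sqrt(mean(y^2))
}

# Unit-RMS 1/f ("pink") background via FFT amplitude shaping.
pink_noise <- function(n, fs) {
  x <- rnorm(n)
  X <- fft(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  w <- 1 / sqrt(pmax(f, 1))  # flatten below 1 Hz
  y <- Re(fft(X * w, inverse = TRUE)) / n
  y <- y - mean(y)
  y / sqrt(mean(y^2))
}

#' Simulate one subject x task recording
#'
#' Sums band-limited oscillations (the alpha component centered at the
#' subject's individual peak), a 1/f background, a 50 Hz powerline
#' sinusoid, and slow drift plus a constant offset, per channel of the
#' eight-channel montage. Channel gains come from the subject topography;
#' alpha/beta/gamma amplitudes are multiplied by the task factors. For
#' tasks with `completion_prob < 1`, a Bernoulli draw decides premature
#' termination, which truncates the duration to a uniform fraction in
#' [0.4, 1] of nominal (rounded to whole seconds).
#'
#' @param sig An `eeg_signature`.
#' @param profile A [task_profile].
#' @param fs_hz Sampling rate in Hz (>= 200).
#' @param powerline_amp Amplitude of the 50 Hz interference in microvolts.
#' @param seed Integer seed; the recording is bit-reproducible under it.
#' @return An [recording()] with all eight montage channels.
#' @export
simulate_recording <- function(sig, profile, fs_hz = 1000,
                               powerline_amp = 2, seed = sig$seed) {
  if (fs_hz < 200) stopf("fs_hz must be >= 200")
  if (profile$duration_s <= 0)
    stopf("invalid-profile: non-positive duration")
  local_seed(seed, {
    dur <- profile$duration_s
    completed <- runif(1) <= profile$completion_prob
    if (!completed) dur <- dur * runif(1, 0.4, 1.0)
    dur <- max(2, round(dur))  # whole seconds keeps EDF records exact
    n <- as.integer(round(dur * fs_hz))
    t <- (0:(n - 1)) / fs_hz

    task_factor <- c(delta = 1, theta = 1,
                     alpha = profile$alpha_factor,
                     beta = profile$beta_factor,
                     gamma = profile$gamma_factor)
    bands <- EEG_BANDS
    bands$alpha <- c(sig$alpha_peak_hz - 0.8, sig$alpha_peak_hz + 0.8)
    band_order <- c(delta = 2, theta = 2, alpha = 6, beta = 2, gamma = 2)

    data <- matrix(0, length(MONTAGE), n)
    for (ci in seq_along(MONTAGE)) {
      region <- channel_region(MONTAGE[ci])
      x <- numeric(n)
      for (b in names(bands)) {
        amp <- sig$band_amplitudes[[b]] * sig$topography[region, b] *
          task_factor[[b]]
        x <- x + amp * band_noise(n, fs_hz, bands[[b]][1], bands[[b]][2],
                                  band_order[[b]])
      }
      x <- x + sig$noise_scale * pink_noise(n, fs_hz)
      x <- x + powerline_amp * sin(2 * pi * 50 * t + runif(1, 0, 2 * pi))
      x <- x + 15 * sin(2 * pi * 0.1 * t + runif(1, 0, 2 * pi)) +
        runif(1, -10, 10)
      data[ci, ] <- x
    }
    recording(
      data, MONTAGE, fs_hz, sig$subject_id, profile$task_id,
      meta = list(completed = completed, nominal_duration_s =
                    profile$duration_s, seed = seed,
                  powerline_amp = powerline_amp)
    )
  })
}

#' Simulate a full session (all four tasks) for one subject
#'
#' @param sig An `eeg_signature`.
#' @param profiles List of four [task_profile]s covering each task once
#'   (see [default_profiles()]).
#' @param seed Integer seed; per-task child seeds are derived from it.
#' @param fs_hz,powerline_amp Passed to [simulate_recording()].
#' @return Named list of [recording()]s, one per task.
#' @export
simulate_session <- function(sig, profiles = default_profiles(),
                             seed = sig$seed, fs_hz = 1000,
                             powerline_amp = 2) {
  ids <- vapply(profiles, function(p) p$task_id, character(1))
  if (anyDuplicated(ids) || !setequal(ids, task_levels))
    stopf("invalid-protocol: profiles must cover each of %s exactly once",
          paste(task_levels, collapse = ", "))
  seeds <- derive_seeds(seed, length(profiles))
  recs <- lapply(seq_along(profiles), function(i)
    simulate_recording(sig, profiles[[i]], fs_hz, powerline_amp, seeds[i]))
  names(recs) <- ids
  recs[task_levels]
}
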