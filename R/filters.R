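#' Filtering specification for the preprocessing cascade
#'
#' Captures the fixed conditioning stages applied to every raw recording:
#' a powerline notch followed by a band-pass built from cascaded
#' Butterworth high-pass and low-pass sections. Defaults follow common
#' clinical-EEG practice: 50 Hz notch, 0.5--95 Hz passband.
#'
#' @param notch_hz Notch center frequency in Hz.
#' @param bp_low_hz High-pass cutoff (lower passband edge) in Hz.
#' @param bp_high_hz Low-pass cutoff (upper passband edge) in Hz.
#' @param order Butterworth order per section; must be even and >= 2.
#' @param notch_q Quality factor of the second-order IIR notch.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(notch_hz = 50, bp_low_hz = 0.5, bp_high_hz = 95,
                        order = 4, notch_q = 30) {
  if (!(bp_low_hz > 0 && bp_low_hz < bp_high_hz))
    stopf("invalid-filter: need 0 < bp_low_hz < bp_high_hz")
  if (order < 2 || order %% 2 != 0)
    stopf("invalid-filter: order must be even and >= 2")
  if (notch_q <= 0) stopf("invalid-filter: notch_q must be positive")
  structure(
    list(notch_hz = notch_hz, bp_low_hz = bp_low_hz,
         bp_high_hz = bp_high_hz, order = order, notch_q = notch_q),
    class = "filter_spec"
  )
}

check_spec_fs <- function(spec, fs_hz, need_notch = TRUE, need_bp = TRUE) {
  if (need_notch && spec$notch_hz >= fs_hz / 2)
    stopf("invalid-filter: notch_hz (%g) must be below Nyquist (%g)",
          spec$notch_hz, fs_hz / 2)
  if (need_bp && spec$bp_high_hz >= fs_hz / 2)
    stopf("invalid-filter: bp_high_hz (%g) must be below Nyquist (%g)",
          spec$bp_high_hz, fs_hz / 2)
  invisible(spec)
}

# Polynomial coefficients (descending powers) from complex roots.
poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (root in r) p <- c(p, 0 + 0i) - root * c(0 + 0i, p)
  p
}

#' Design a digital Butterworth filter
#'
#' Analog Butterworth prototype mapped to the z-domain with the bilinear
#' transform (cutoff prewarped), as in standard signal-processing
#' references. Gain is normalized to exactly 1 at DC (low-pass) or Nyquist
#' (high-pass), which places the -3 dB point at `fc`.
#'
#' @param order Filter order.
#' @param fc Cutoff (-3 dB) frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param type `"low"` or `"high"`.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_design <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (fc <= 0 || fc >= fs / 2)
    stopf("invalid-filter: cutoff %g Hz outside (0, fs/2)", fc)
  W <- tan(pi * fc / fs)
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  p <- if (type == "low") W * proto else W / proto
  zp <- (1 + p) / (1 - p)
  zz <- rep(if (type == "low") -1 else 1, order)
  a <- Re(poly_from_roots(zp))
  b <- Re(poly_from_roots(zz))
  # unit gain in the passband reference point
  ref <- if (type == "low") rep(1, order + 1) else (-1)^(0:order)
  g <- sum(a * ref) / sum(b * ref)
  list(b = b * g, a = a)
}

#' Design a second-order IIR notch filter
#'
#' Constrained biquad notch (audio-EQ-cookbook form): unit gain far from
#' the notch, a true zero on the unit circle at `f0`.
#'
#' @param f0 Notch center frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param q Quality factor; bandwidth is roughly `f0/q`.
#' @return List with `b` and `a` coefficients.
#' @export
notch_design <- function(f0, fs, q = 30) {
  if (f0 <= 0 || f0 >= fs / 2)
    stopf("invalid-filter: notch frequency %g Hz outside (0, fs/2)", f0)
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  a0 <- 1 + alpha
  list(
    b = c(1, -2 * cos(w0), 1) / a0,
    a = c(1, -2 * cos(w0) / a0, (1 - alpha) / a0)
  )
}

# Steady-state filter state for a step of unit height (direct form II
# transposed), so filtering a constant produces its steady-state output
# from the first sample.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  b <- b / a[1]
  a <- a / a[1]
  if (n == 1) return(numeric(0))
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[2:n]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  solve(diag(n - 1) - t(comp), b[2:n] - a[2:n] * b[1])
}

#' Zero-phase IIR filtering
#'
#' Forward-backward application of an IIR filter with odd-reflection edge
#' padding and steady-state initial conditions, eliminating phase
#' distortion and startup transients (the usual `filtfilt` construction).
#'
#' @param b,a Filter coefficients.
#' @param x Numeric signal vector.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt <- function(b, a, x) {
  n <- max(length(a), length(b))
  pad <- 3L * n
  if (length(x) <= pad)
    stopf("signal too short for zero-phase filtering (need > %d samples)", pad)
  nx <- length(x)
  pre <- 2 * x[1] - x[(pad + 1):2]
  post <- 2 * x[nx] - x[(nx - 1):(nx - pad)]
  ext <- c(pre, x, post)
  zi <- lfilter_zi(b, a)
  y <- iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(iir_filter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1):(pad + nx)]
}

# Single-pass causal filtering with steady-state initial conditions.
iir_filter <- function(b, a, x) {
  zi <- lfilter_zi(b, a)
  iir_filter_cpp(b, a, x, zi * x[1])
}

#' Frequency response magnitude of a digital filter
#'
#' @param b,a Filter coefficients.
#' @param f Frequencies in Hz at which to evaluate.
#' @param fs Sampling rate in Hz.
#' @return `|H(f)|` at each requested frequency.
#' @export
filter_response <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  num <- vapply(z, function(zz) sum(b * zz^(seq_along(b) - 1)), complex(1))
  den <- vapply(z, function(zz) sum(a * zz^(seq_along(a) - 1)), complex(1))
  Mod(num / den)
}

# Apply a filtering function row-wise over a channels x time matrix.
filter_rows <- function(mat, fun) {
  out <- mat
  for (i in seq_len(nrow(mat))) out[i, ] <- fun(mat[i, ])
  out
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with a Hann window and half-overlapping
#' segments.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length in samples.
#' @return List with frequency vector `freq` (Hz) and PSD `psd`
#'   (power per Hz, one-sided).
#' @export
welch_psd <- function(x, fs, nperseg = 2048) {
  nperseg <- min(nperseg, length(x))
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, length(x) - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / nperseg)
  scale <- fs * sum(w^2)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[1:nfreq]
    p <- Mod(X)^2 / scale
    # one-sided: double everything except DC (and Nyquist when present)
    p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]
    acc <- acc + p
  }
  list(freq = (0:(nfreq - 1L)) * fs / nperseg, psd = acc / length(starts))
}

#' Band power of a signal
#'
#' Integrates the Welch PSD over a frequency band by the trapezoid rule.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param band Numeric `c(low, high)` in Hz, or the name of a band in
#'   [EEG_BANDS].
#' @param nperseg Welch segment length.
#' @return Band power in signal-units squared.
#' @export
band_power <- function(x, fs, band, nperseg = 2048) {
  if (is.character(band)) band <- EEG_BANDS[[band]]
  p <- welch_psd(x, fs, nperseg)
  sel <- p$freq >= band[1] & p$freq <= band[2]
  if (sum(sel) < 2) return(0)
  f <- p$freq[sel]
  y <- p$psd[sel]
  sum(diff(f) * (head(y, -1) + y[-1]) / 2)
}
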