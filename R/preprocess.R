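#' Apply time-gain compensation
#'
#' Multiplies each depth sample by a linear-in-depth gain of
#' `tgc_slope` dB per sample: sample at depth index `d` (0-based) is scaled
#' by `10^(tgc_slope * d / 20)`. Compensates the attenuation of deeper
#' echoes before filtering.
#'
#' @param frame An [rf_frame].
#' @param config A [preprocess_config].
#' @return An [rf_frame] of identical shape.
#' @export
apply_tgc <- function(frame, config) {
  stopifnot(inherits(frame, "rf_frame"), inherits(config, "preprocess_config"))
  n_depth <- ncol(frame$samples)
  gain <- 10^(config$tgc_slope * (seq_len(n_depth) - 1) / 20)
  out <- frame$samples * rep(gain, each = nrow(frame$samples))
  rf_frame(out, frame$sampling_rate, frame$frame_time)
}

#' Design the bandpass FIR filter
#'
#' Window-method (Hamming) linear-phase FIR bandpass design, the filter that
#' replaces the conventional Gaussian filter in this preprocessing chain.
#' Delegates to [signal::fir1()].
#'
#' @param taps Odd number of coefficients (filter order `taps - 1`).
#' @param f_low,f_high Cutoffs in Hz.
#' @param fs Sampling rate in Hz; the band must lie inside `(0, fs/2)`.
#' @return Numeric vector of `taps` symmetric coefficients.
#' @export
design_bandpass_fir <- function(taps = 101L, f_low = 2e6, f_high = 8e6, fs) {
  taps <- as.integer(taps)
  if (taps %% 2L == 0L || taps < 3L) stopf("`taps` must be odd and >= 3")
  if (!(f_low > 0 && f_low < f_high && f_high < fs / 2)) {
    stopf("band [%g, %g] Hz must lie inside (0, %g) Hz", f_low, f_high, fs / 2)
  }
  w <- c(f_low, f_high) / (fs / 2)
  coef <- signal::fir1(taps - 1L, w, type = "pass",
                       window = signal::hamming(taps))
  as.numeric(coef)
}

#' Bandpass filter an RF frame
#'
#' Convolves every channel with a causal FIR filter and realigns the output
#' by the `(taps - 1) / 2` group delay so echo positions are preserved.
#' Edge samples are implicitly zero-padded; output length equals input
#' length.
#'
#' @param frame An [rf_frame].
#' @param coefficients FIR coefficient vector (odd length).
#' @return Filtered [rf_frame].
#' @export
bandpass_filter <- function(frame, coefficients) {
  stopifnot(inherits(frame, "rf_frame"))
  taps <- length(coefficients)
  n_depth <- ncol(frame$samples)
  if (n_depth < taps) {
    stopf("frame depth (%d) shorter than filter (%d taps)", n_depth, taps)
  }
  delay <- (taps - 1L) %/% 2L
  out <- t(apply(frame$samples, 1L, function(x) {
    full <- stats::convolve(x, rev(coefficients), type = "open")
    full[(delay + 1L):(delay + n_depth)]
  }))
  rf_frame(out, frame$sampling_rate, frame$frame_time)
}

# Analytic-signal envelope of the rows of a matrix, via the one-sided
# spectrum construction (FFT, double positive frequencies, inverse FFT).
analytic_envelope <- function(x) {
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n %/% 2L + 1L)] <- 1
    h[2:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) %/% 2L)] <- 2
  }
  spec <- stats::mvfft(t(x)) * h
  Mod(stats::mvfft(spec, inverse = TRUE)) / n
}

#' Detect the echo envelope
#'
#' Per-channel magnitude of the analytic signal (Hilbert-transform
#' envelope). Output is non-negative everywhere.
#'
#' @param frame A bandpass-filtered [rf_frame].
#' @return An [rf_frame] holding the envelope.
#' @export
detect_envelope <- function(frame) {
  stopifnot(inherits(frame, "rf_frame"))
  env <- t(analytic_envelope(frame$samples))
  rf_frame(env, frame$sampling_rate, frame$frame_time)
}

#' Log-compress an envelope
#'
#' Maps the envelope to decibels relative to the frame maximum,
#' `20 log10(x / x_max)`, clipped to `[-dynamic_range, 0]`, then (optionally)
#' min-max rescaled to `[0, 1]`. Monotone non-decreasing in the input, so
#' echo ordering survives compression. An all-zero frame maps to the floor,
#' not an error.
#'
#' @param frame Non-negative envelope [rf_frame].
#' @param config A [preprocess_config].
#' @return An [envelope_image].
#' @export
log_compress <- function(frame, config) {
  stopifnot(inherits(frame, "rf_frame"), inherits(config, "preprocess_config"))
  x <- frame$samples
  if (any(x < 0)) stopf("log compression expects a non-negative envelope")
  dr <- config$dynamic_range
  xmax <- max(x)
  if (xmax <= 0) {
    db <- matrix(-dr, nrow(x), ncol(x))
  } else {
    floor_amp <- xmax * 10^(-(dr + 20) / 20)
    db <- 20 * log10(pmax(x, floor_amp) / xmax)
    db <- pmin(pmax(db, -dr), 0)
  }
  if (config$normalize) {
    rng <- range(db)
    if (rng[2] > rng[1]) {
      db <- (db - rng[1]) / (rng[2] - rng[1])
    } else {
      db <- matrix(0, nrow(db), ncol(db))
    }
  }
  envelope_image(db, normalized = config$normalize, dynamic_range = dr)
}

#' Full RF preprocessing chain
#'
#' Composition, in fixed order, of time-gain compensation, FIR bandpass
#' filtering, envelope detection, and log compression. Deterministic:
#' identical frames yield bitwise-identical images.
#'
#' @param frame An [rf_frame].
#' @param config A [preprocess_config].
#' @return An [envelope_image] of shape `n_channels x n_depth`.
#' @export
preprocess <- function(frame, config = preprocess_config()) {
  if (frame$sampling_rate <= 2 * config$f_high) {
    stopf("sampling rate %g Hz violates Nyquist for the %g Hz band edge",
          frame$sampling_rate, config$f_high)
  }
  coef <- design_bandpass_fir(config$fir_taps, config$f_low, config$f_high,
                              frame$sampling_rate)
  frame |>
    apply_tgc(config) |>
    bandpass_filter(coef) |>
    detect_envelope() |>
    log_compress(config)
}
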