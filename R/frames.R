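#' Raw A-mode RF ultrasound frame
#'
#' An RF frame holds one pulse-echo acquisition from every transducer of the
#' armband: a real matrix with one row per channel (scanline) and one column
#' per depth sample, together with the sampling rate that fixes the depth
#' axis.
#'
#' @param samples Real matrix, `n_channels x n_depth`, arbitrary amplitude
#'   units.
#' @param sampling_rate Sampling rate of the depth axis in Hz. Must exceed
#'   twice the highest frequency of interest (16 MHz for the 2-8 MHz band).
#' @param frame_time Acquisition time of the frame within the recording, in
#'   seconds.
#' @return An object of class `rf_frame`.
#' @export
rf_frame <- function(samples, sampling_rate, frame_time = 0) {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stopf("`samples` must be a numeric matrix (channels x depth)")
  }
  if (!all(is.finite(samples))) {
    stopf("RF frame contains non-finite samples")
  }
  if (nrow(samples) < 1L) stopf("RF frame needs at least one channel")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stopf("`sampling_rate` must be a positive number of Hz")
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_count = nrow(samples), frame_time = frame_time),
    class = "rf_frame"
  )
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> %d channels x %d depth samples @ %.1f MHz\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate / 1e6))
  invisible(x)
}

#' RF preprocessing configuration
#'
#' Parameters of the standard A-mode preprocessing chain: time-gain
#' compensation, FIR bandpass filtering, envelope detection, and log
#' compression.
#'
#' @param tgc_slope Time-gain compensation slope in dB per depth sample
#'   (linear-in-depth gain). Default 0 (no depth gain).
#' @param fir_taps Number of FIR filter taps; must be odd. Default 101.
#' @param f_low,f_high Bandpass cutoff frequencies in Hz. Defaults 2 MHz and
#'   8 MHz, bracketing the 5 MHz transducer band.
#' @param dynamic_range Log-compression dynamic range in dB. Default 50.
#' @param normalize If `TRUE` (default), min-max rescale each compressed
#'   frame to `[0, 1]`, the scale the networks consume.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(tgc_slope = 0, fir_taps = 101L,
                              f_low = 2e6, f_high = 8e6,
                              dynamic_range = 50, normalize = TRUE) {
  fir_taps <- as.integer(fir_taps)
  if (fir_taps < 3L || fir_taps %% 2L == 0L) {
    stopf("`fir_taps` must be an odd integer >= 3 (got %d)", fir_taps)
  }
  if (!(f_low > 0 && f_low < f_high)) {
    stopf("need 0 < f_low < f_high (got %g, %g)", f_low, f_high)
  }
  if (tgc_slope < 0) stopf("`tgc_slope` must be >= 0 dB/sample")
  if (dynamic_range <= 0) stopf("`dynamic_range` must be positive dB")
  structure(
    list(tgc_slope = tgc_slope, fir_taps = fir_taps, f_low = f_low,
         f_high = f_high, dynamic_range = dynamic_range,
         normalize = isTRUE(normalize)),
    class = "preprocess_config"
  )
}

#' Log-compressed envelope image
#'
#' The preprocessed network input: a `n_channels x width` matrix of
#' log-compressed echo envelopes, optionally min-max normalized to `[0, 1]`.
#'
#' @param pixels Numeric matrix of compressed envelope values.
#' @param normalized Whether values were rescaled to `[0, 1]`.
#' @param dynamic_range Dynamic range (dB) used during compression.
#' @return An object of class `envelope_image`.
#' @export
envelope_image <- function(pixels, normalized, dynamic_range) {
  if (!all(is.finite(pixels))) stopf("envelope image contains non-finite values")
  structure(
    list(pixels = pixels, width = ncol(pixels), normalized = normalized,
         dynamic_range = dynamic_range),
    class = "envelope_image"
  )
}

#' @export
print.envelope_image <- function(x, ...) {
  cat(sprintf("<envelope_image> %d x %d, range [%.3f, %.3f]\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)))
  invisible(x)
}
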