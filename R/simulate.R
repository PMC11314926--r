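#' Tissue model for the synthetic A-mode simulator
#'
#' Describes the gesture-conditional echo anatomy the simulator emulates:
#' each of the six finger gestures deforms the forearm so that a distinct
#' pattern of strong reflectors (muscle/tendon boundaries) appears along the
#' scanlines, and wrist rotation displaces every reflector in depth by
#' `angle_coupling` mm per degree.
#'
#' @param reflector_depths List of 6 numeric vectors, reflector depths in mm
#'   for each gesture class (classes 0..5).
#' @param reflector_amps List of 6 numeric vectors, relative echo amplitudes
#'   matching `reflector_depths`.
#' @param channel_amps 6 x n_channels matrix of per-gesture, per-channel
#'   amplitude factors (which scanlines see the contracted muscles).
#' @param channel_jitter_mm Length-n_channels vector of fixed per-channel
#'   depth offsets (mm), modelling transducer placement along the armband.
#' @param angle_coupling Depth displacement per degree of wrist rotation, in
#'   mm/degree, applied to every reflector.
#' @param speckle_amp Relative amplitude of the diffuse scatterer
#'   background.
#' @param speed_of_sound Speed of sound in m/s.
#' @return Object of class `tissue_model`.
#' @export
tissue_model <- function(reflector_depths, reflector_amps, channel_amps,
                         channel_jitter_mm, angle_coupling = 0.005,
                         speckle_amp = 0.08, speed_of_sound = 1540) {
  stopifnot(length(reflector_depths) == 6L, length(reflector_amps) == 6L,
            nrow(channel_amps) == 6L)
  for (g in 1:6) {
    stopifnot(length(reflector_depths[[g]]) == length(reflector_amps[[g]]))
  }
  key <- vapply(reflector_depths, function(d) paste(round(d, 4), collapse = ","), "")
  if (anyDuplicated(key)) stopf("gesture depth patterns must be pairwise distinct")
  structure(
    list(reflector_depths = reflector_depths, reflector_amps = reflector_amps,
         channel_amps = channel_amps, channel_jitter_mm = channel_jitter_mm,
         angle_coupling = angle_coupling, speckle_amp = speckle_amp,
         speed_of_sound = speed_of_sound),
    class = "tissue_model"
  )
}

#' Default tissue model
#'
#' Six hand-crafted reflector patterns in the 3-14.5 mm depth range (well
#' inside the imaging window at the default 40 MHz / 1632-sample and the
#' reduced 20 MHz / 408-sample geometries), with gesture-specific channel
#' amplitude profiles for class separability and a rotation coupling of
#' 0.005 mm/degree (about 0.26 depth samples per degree at any sampling
#' rate, so the +-80 degree rotation sweeps roughly +-20 samples at 40 MHz).
#'
#' @param n_channels Number of transducers (default 8).
#' @inheritParams tissue_model
#' @return A `tissue_model`.
#' @export
default_tissue_model <- function(n_channels = 8L, angle_coupling = 0.005,
                                 speckle_amp = 0.08) {
  depths <- list(
    c(4.0, 7.0, 10.0, 13.0),   # RS  rest
    c(3.0, 6.2, 9.5, 12.0),    # FP  fine pinch
    c(4.8, 6.0, 11.0, 13.8),   # KG  key grip
    c(3.5, 8.0, 9.0, 14.0),    # TG  tripod grip
    c(5.5, 7.5, 11.8, 12.8),   # IP  index point
    c(3.2, 5.2, 8.5, 11.5)     # PG  power grip
  )
  amps <- list(
    c(1.0, 0.9, 0.8, 0.7),
    c(0.8, 1.0, 0.9, 0.6),
    c(0.9, 0.7, 1.0, 0.8),
    c(1.0, 0.8, 0.6, 0.9),
    c(0.7, 1.0, 0.8, 0.9),
    c(0.9, 0.8, 1.0, 0.7)
  )
  ch <- seq_len(n_channels)
  channel_amps <- t(vapply(1:6, function(g) {
    0.6 + 0.4 * cos(2 * pi * (ch - 1) / n_channels + g * pi / 3)
  }, numeric(n_channels)))
  jitter <- 0.2 * sin(2 * pi * (ch - 1) / n_channels)
  tissue_model(depths, amps, channel_amps, jitter,
               angle_coupling = angle_coupling, speckle_amp = speckle_amp)
}

#' Gesture labels
#' @return Character vector of the six gesture codes.
#' @export
gesture_labels <- function() c("RS", "FP", "KG", "TG", "IP", "PG")

#' Session-dependent distribution shift
#'
#' Inter-session shift is parameterized by one scalar magnitude `m >= 0`
#' mapped monotonically to five physical effects of re-donning the armband
#' and elapsed time: a multiplicative gain change, a depth displacement
#' (probe coupling pressure), a rotation of the armband around the forearm
#' (which shifts the per-channel amplitude profile), a higher additive
#' noise floor, and a re-randomized speckle background. `m = 0` is the
#' identity (session 1).
#'
#' @param magnitude Scalar shift magnitude `m >= 0`.
#' @param speckle_seed Integer seed of the session's scatterer background.
#' @return Object of class `session_shift` with fields `gain_scale`,
#'   `depth_offset_mm`, `channel_offset`, `noise_sigma`, `speckle_seed`,
#'   `magnitude`.
#' @export
session_shift <- function(magnitude = 0, speckle_seed = 0L) {
  if (magnitude < 0) stopf("shift magnitude must be >= 0")
  structure(
    list(magnitude = magnitude,
         gain_scale = 1 + 0.8 * magnitude,
         depth_offset_mm = 2.5 * magnitude,
         channel_offset = 0.6 * magnitude,
         noise_sigma = 0.5 * magnitude,
         speckle_seed = as.integer(speckle_seed)),
    class = "session_shift"
  )
}

# Circularly interpolated per-channel amplitude profile after rotating the
# armband by `offset` channel widths.
rotate_channel_profile <- function(profile, offset) {
  n <- length(profile)
  p <- (seq_len(n) - 1 + offset) %% n
  i0 <- floor(p)
  frac <- p - i0
  (1 - frac) * profile[(i0 %% n) + 1] + frac * profile[((i0 + 1) %% n) + 1]
}

#' Acquisition protocol configuration
#'
#' The recording protocol the simulator reproduces: each of the six gestures
#' is held for `seconds_per_gesture` seconds while the wrist rotates
#' sinusoidally at `rotation_frequency` Hz with amplitude
#' `rotation_amplitude` degrees.
#'
#' @param seconds_per_gesture Seconds each gesture is performed (default 50).
#' @param frame_rate Frames per second (default 10).
#' @param rotation_frequency Wrist rotation frequency in Hz (default 0.5).
#' @param rotation_amplitude Rotation amplitude in degrees (default 80).
#' @param n_channels Number of transducers (default 8).
#' @param n_depth Depth samples per scanline (default 1632).
#' @param sampling_rate RF sampling rate in Hz (default 40 MHz).
#' @param base_noise Additive white-noise sigma present in every session.
#' @return Object of class `protocol_config`.
#' @export
protocol_config <- function(seconds_per_gesture = 50, frame_rate = 10,
                            rotation_frequency = 0.5, rotation_amplitude = 80,
                            n_channels = 8L, n_depth = 1632L,
                            sampling_rate = 40e6, base_noise = 0.05) {
  stopifnot(seconds_per_gesture > 0, frame_rate > 0, rotation_frequency > 0,
            n_depth >= 101L, sampling_rate > 16e6)
  structure(
    list(seconds_per_gesture = seconds_per_gesture, frame_rate = frame_rate,
         rotation_frequency = rotation_frequency,
         rotation_amplitude = rotation_amplitude,
         n_channels = as.integer(n_channels), n_depth = as.integer(n_depth),
         sampling_rate = sampling_rate, base_noise = base_noise,
         gestures = gesture_labels()),
    class = "protocol_config"
  )
}

gabor_pulse <- function(fs, f0 = 5e6, sigma_t = 0.625e-6) {
  half <- ceiling(3 * sigma_t * fs)
  t <- (-half:half) / fs
  cos(2 * pi * f0 * t) * exp(-t^2 / (2 * sigma_t^2))
}

# Diffuse scatterer background for one session: sparse random reflectivity
# per channel, fixed by the session's speckle seed.
speckle_background <- function(protocol, tissue, speckle_seed) {
  with_seed(speckle_seed + 777L, {
    n <- protocol$n_depth
    bg <- matrix(0, protocol$n_channels, n)
    n_scat <- max(8L, n %/% 12L)
    for (ch in seq_len(protocol$n_channels)) {
      pos <- sample.int(n, n_scat)
      bg[ch, pos] <- stats::rnorm(n_scat, 0, tissue$speckle_amp)
    }
    bg
  })
}

depth_to_sample <- function(depth_mm, fs, c_sound) {
  round(2 * (depth_mm * 1e-3) * fs / c_sound) + 1L
}

#' Simulate one RF frame
#'
#' Places the gesture's reflector train at angle-displaced, shift-offset
#' depths on every channel, adds the session's fixed speckle background,
#' convolves each scanline with a 5 MHz Gabor pulse, applies the session
#' gain, and adds white noise. Reflectors displaced outside the imaging
#' window are clipped and flagged in the frame's metadata.
#'
#' @param gesture Gesture class in 0..5.
#' @param angle Wrist rotation angle in degrees.
#' @param tissue A [tissue_model].
#' @param shift A [session_shift].
#' @param protocol A [protocol_config].
#' @param seed Integer seed for the frame's noise.
#' @param speckle Optional precomputed speckle background (recomputed from
#'   `shift$speckle_seed` when `NULL`).
#' @param frame_time Frame timestamp in seconds.
#' @return An [rf_frame]; attribute `clipped` flags out-of-window
#'   reflectors.
#' @export
simulate_frame <- function(gesture, angle, tissue, shift, protocol,
                           seed = 0L, speckle = NULL, frame_time = 0) {
  if (!(gesture %in% 0:5)) stopf("`gesture` must be in 0..5")
  fs <- protocol$sampling_rate
  cs <- tissue$speed_of_sound
  n <- protocol$n_depth
  nch <- protocol$n_channels
  g1 <- gesture + 1L
  if (is.null(speckle)) speckle <- speckle_background(protocol, tissue, shift$speckle_seed)

  depths <- tissue$reflector_depths[[g1]] +
    tissue$angle_coupling * angle + shift$depth_offset_mm
  amps <- tissue$reflector_amps[[g1]]
  clipped <- FALSE
  train <- speckle
  ch_profile <- rotate_channel_profile(tissue$channel_amps[g1, ],
                                       shift$channel_offset)
  for (ch in seq_len(nch)) {
    d_ch <- depths + tissue$channel_jitter_mm[ch]
    idx <- depth_to_sample(d_ch, fs, cs)
    bad <- idx < 1L | idx > n
    if (any(bad)) clipped <- TRUE
    ok <- which(!bad)
    if (length(ok)) {
      a <- amps[ok] * ch_profile[ch]
      train[ch, idx[ok]] <- train[ch, idx[ok]] + a
    }
  }
  pulse <- gabor_pulse(fs)
  half <- (length(pulse) - 1L) %/% 2L
  rf <- t(apply(train, 1L, function(x) {
    full <- stats::convolve(x, rev(pulse), type = "open")
    full[(half + 1L):(half + n)]
  }))
  rf <- rf * shift$gain_scale
  sigma <- protocol$base_noise + shift$noise_sigma
  if (sigma > 0) {
    rf <- rf + with_seed(seed, matrix(stats::rnorm(nch * n, 0, sigma), nch, n))
  }
  out <- rf_frame(rf, fs, frame_time)
  attr(out, "clipped") <- clipped
  out
}

#' Generate one labeled session
#'
#' Simulates the full protocol for one session: the six gestures performed
#' back to back, each for `seconds_per_gesture` seconds at `frame_rate`
#' frames per second, with the sinusoidal wrist-rotation trace running over
#' global session time. Every frame is preprocessed to its envelope image.
#' Within each gesture block, contiguous time segments are tagged
#' train/validation/test (default fractions 60/20/20).
#'
#' @param protocol A [protocol_config].
#' @param tissue A [tissue_model].
#' @param shift A [session_shift].
#' @param seed Session seed (fixes all frame noise).
#' @param session Session index stored with every frame.
#' @param preprocess_cfg A [preprocess_config] for the envelope images.
#' @param split_fractions Train/validation/test fractions, summing to 1.
#' @param keep_rf Keep the raw RF frames (memory-heavy; default `FALSE`).
#' @return Object of class `amode_session` with fields `envelope`
#'   (`n x channels x width` array), `gesture` (0..5), `angle` (degrees),
#'   `session`, `split`, `frame_time`.
#' @export
generate_session <- function(protocol, tissue, shift, seed = 0L, session = 1L,
                             preprocess_cfg = preprocess_config(),
                             split_fractions = c(0.6, 0.2, 0.2),
                             keep_rf = FALSE) {
  stopifnot(abs(sum(split_fractions) - 1) < 1e-9)
  per_gesture <- round(protocol$seconds_per_gesture * protocol$frame_rate)
  n_frames <- per_gesture * 6L
  speckle <- speckle_background(protocol, tissue, shift$speckle_seed)
  coef <- design_bandpass_fir(preprocess_cfg$fir_taps, preprocess_cfg$f_low,
                              preprocess_cfg$f_high, protocol$sampling_rate)

  env <- array(0, dim = c(n_frames, protocol$n_channels, protocol$n_depth))
  rf_store <- if (keep_rf) array(0, dim = dim(env)) else NULL
  gesture <- integer(n_frames)
  angle <- numeric(n_frames)
  tsec <- numeric(n_frames)
  split <- character(n_frames)
  n_tr <- round(split_fractions[1] * per_gesture)
  n_va <- round(split_fractions[2] * per_gesture)
  seg <- c(rep("train", n_tr), rep("validation", n_va),
           rep("test", per_gesture - n_tr - n_va))

  frame_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_frames))
  i <- 0L
  for (g in 0:5) {
    for (k in seq_len(per_gesture)) {
      i <- i + 1L
      tsec[i] <- (i - 1L) / protocol$frame_rate
      angle[i] <- protocol$rotation_amplitude *
        sin(2 * pi * protocol$rotation_frequency * tsec[i])
      gesture[i] <- g
      split[i] <- seg[k]
      fr <- simulate_frame(g, angle[i], tissue, shift, protocol,
                           seed = frame_seeds[i], speckle = speckle,
                           frame_time = tsec[i])
      if (keep_rf) rf_store[i, , ] <- fr$samples
      fr <- apply_tgc(fr, preprocess_cfg)
      fr <- bandpass_filter(fr, coef)
      fr <- detect_envelope(fr)
      img <- log_compress(fr, preprocess_cfg)
      env[i, , ] <- img$pixels
    }
  }
  structure(
    list(envelope = env, gesture = gesture, angle = angle,
         session = as.integer(session), split = split, frame_time = tsec,
         rf = rf_store, protocol = protocol, shift = shift, seed = seed),
    class = "amode_session"
  )
}

#' Generate a three-session study
#'
#' Session 1 is the identity-shift source session; sessions 2 and 3 carry
#' shifts of magnitude `m2` and `m3` (`0 <= m2 <= m3`), emulating the
#' growing inter-session drift between acquisitions. All sessions share one
#' tissue model; session 1 frames are independent of `m2`, `m3`.
#'
#' @param protocol A [protocol_config].
#' @param tissue A [tissue_model].
#' @param shift_magnitudes Numeric `c(m2, m3)`, default `c(0.3, 0.6)`.
#' @param seed Master seed for the study.
#' @param preprocess_cfg A [preprocess_config].
#' @param keep_rf Keep raw RF arrays.
#' @return Object of class `amode_study`: list of three `amode_session`s
#'   plus the generating configuration.
#' @export
generate_study <- function(protocol = protocol_config(),
                           tissue = default_tissue_model(),
                           shift_magnitudes = c(0.3, 0.6), seed = 0L,
                           preprocess_cfg = preprocess_config(),
                           keep_rf = FALSE) {
  m2 <- shift_magnitudes[1]; m3 <- shift_magnitudes[2]
  if (m3 < m2 || m2 < 0) stopf("need 0 <= m2 <= m3 (got %g, %g)", m2, m3)
  base <- fold_seed(seed)
  shifts <- list(
    session_shift(0, speckle_seed = base),
    session_shift(m2, speckle_seed = if (m2 > 0) base + 1L else base),
    session_shift(m3, speckle_seed = if (m3 > 0) base + 2L else base)
  )
  sessions <- lapply(1:3, function(s) {
    generate_session(protocol, tissue, shifts[[s]], seed = base + 100L * s,
                     session = s, preprocess_cfg = preprocess_cfg,
                     keep_rf = keep_rf)
  })
  structure(
    list(sessions = sessions, protocol = protocol, tissue = tissue,
         shift_magnitudes = c(m2 = m2, m3 = m3), seed = seed,
         preprocess_cfg = preprocess_cfg, schema_version = 1L),
    class = "amode_study"
  )
}

#' @export
print.amode_study <- function(x, ...) {
  n <- vapply(x$sessions, function(s) length(s$gesture), integer(1))
  cat(sprintf("<amode_study> 3 sessions x %d frames, shift m2=%.2f m3=%.2f, seed %s\n",
              n[1], x$shift_magnitudes[1], x$shift_magnitudes[2],
              format(x$seed)))
  invisible(x)
}
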