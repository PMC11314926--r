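# Shared reduced-scale fixtures, built once per test session. The reduced
# geometry keeps the physics of the default study (same band, same tissue
# depths in mm, same rotation protocol) at a quarter of the sampling rate
# and a fraction of the recording length, so tests stay fast.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# 408-sample window at 20 MHz (~15.7 mm), 10 s per gesture at 4 Hz.
reduced_protocol <- function() {
  protocol_config(seconds_per_gesture = 10, frame_rate = 4,
                  n_depth = 408L, sampling_rate = 20e6)
}

reduced_spec <- function() {
  architecture_spec(input_width = 408L, pool_sizes = c(2L, 2L, 2L, 1L))
}

# Even smaller: 204-sample window, 4 s per gesture at 2 Hz. Deep reflectors
# fall outside this window (clipped); enough structure survives for
# mechanism tests that do not assert accuracy floors.
tiny_protocol <- function() {
  protocol_config(seconds_per_gesture = 4, frame_rate = 2,
                  n_depth = 204L, sampling_rate = 20e6)
}

tiny_spec <- function() {
  architecture_spec(input_width = 204L, pool_sizes = c(2L, 2L, 1L, 1L))
}

fixture_study <- function() {
  fixture("study", function() {
    generate_study(reduced_protocol(), default_tissue_model(),
                   c(0.3, 0.6), seed = 11)
  })
}

fixture_tiny_study <- function() {
  fixture("tiny_study", function() {
    generate_study(tiny_protocol(), default_tissue_model(),
                   c(0.3, 0.6), seed = 5)
  })
}

# Like the tiny study but at 3 frames per second, so every split sees more
# than one distinct wrist angle (needed wherever R^2 is computed).
fixture_small_study <- function() {
  fixture("small_study", function() {
    generate_study(protocol_config(seconds_per_gesture = 4, frame_rate = 3,
                                   n_depth = 204L, sampling_rate = 20e6),
                   default_tissue_model(), c(0.3, 0.6), seed = 6)
  })
}

fixture_tiny_source_net <- function() {
  fixture("tiny_source_net", function() {
    src <- session_domain(fixture_tiny_study(), 1, labeled = TRUE)
    select_model(train_source(src, tiny_spec(), "classify", seed = 7,
                              epochs = 5, batch = 16))
  })
}

flatten_session <- function(s) {
  matrix(s$envelope, dim(s$envelope)[1], prod(dim(s$envelope)[2:3]))
}

# Nearest-centroid gesture classifier on flattened envelopes: the
# model-free separability probe.
centroid_classifier <- function(x_train, y_train) {
  cent <- vapply(0:5, function(g) {
    colMeans(x_train[y_train == g, , drop = FALSE])
  }, numeric(ncol(x_train)))
  function(x) {
    apply(x, 1L, function(v) which.min(colSums((cent - v)^2)) - 1L)
  }
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), tol)
}
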