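# Study container I/O, the optional external-dataset importer, and the
# top-level pipeline driver.

STUDY_SCHEMA_VERSION <- 1L

#' Write a study container
#'
#' Serializes an `amode_study` to a single schema-versioned container file
#' (RDS serialization).
#'
#' @param study An `amode_study`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "amode_study"))
  study$schema_version <- STUDY_SCHEMA_VERSION
  saveRDS(study, path)
  invisible(path)
}

#' Read and validate a study container
#'
#' Opens a container written by [write_study()], checking the schema
#' version, the presence of all sessions, and the length consistency of
#' every per-frame array.
#'
#' @param path Container file path.
#' @return An `amode_study`.
#' @export
read_study <- function(path) {
  if (!file.exists(path)) stopf("study container '%s' does not exist", path)
  study <- readRDS(path)
  if (!inherits(study, "amode_study")) stopf("'%s' is not a study container", path)
  v <- study$schema_version %||% -1L
  if (v != STUDY_SCHEMA_VERSION) {
    stopf("unsupported study schema version %s (reader supports %d)",
          v, STUDY_SCHEMA_VERSION)
  }
  present <- which(!vapply(study$sessions, is.null, logical(1)))
  if (!identical(present, 1:3)) {
    stopf("missing session group(s); present: %s", paste(present, collapse = ", "))
  }
  for (s in 1:3) {
    ses <- study$sessions[[s]]
    n <- dim(ses$envelope)[1]
    for (fld in c("gesture", "angle", "split", "frame_time")) {
      if (length(ses[[fld]]) != n) {
        stopf("integrity error in session %d: array '%s' has length %d, expected %d",
              s, fld, length(ses[[fld]]), n)
      }
    }
  }
  study
}

#' Import the external armband dataset (optional)
#'
#' Convenience importer for a locally downloaded copy of the public
#' three-session A-mode armband dataset. The caller supplies a mapping
#' configuration describing where each per-session RF array and label
#' vector lives (as delimited text exports); only the ultrasound modality
#' is read. Never required by any test: without the files this function
#' fails with an actionable message.
#'
#' @param path Directory holding the exported dataset.
#' @param mapping List with one entry per session (`session1`..`session3`),
#'   each naming `rf` (semicolon-free CSV of `n_frames x (channels*depth)`
#'   rows), `gesture`, `angle` files, plus top-level `n_channels`,
#'   `sampling_rate`, `rotation_amplitude`.
#' @param preprocess_cfg A [preprocess_config] applied to the imported RF.
#' @return An `amode_study`.
#' @export
import_ultrapro <- function(path, mapping,
                            preprocess_cfg = preprocess_config()) {
  if (!dir.exists(path)) {
    stopf(paste("dataset directory '%s' not found; download the public",
                "armband dataset, export the RF arrays to CSV, and point",
                "`mapping` at them"), path)
  }
  nch <- mapping$n_channels %||% 8L
  fs <- mapping$sampling_rate %||% 40e6
  sessions <- vector("list", 3L)
  for (s in 1:3) {
    m <- mapping[[paste0("session", s)]]
    if (is.null(m)) stopf("mapping lacks entry 'session%d'", s)
    for (fld in c("rf", "gesture", "angle")) {
      fp <- file.path(path, m[[fld]])
      if (!file.exists(fp)) stopf("mapped file '%s' is absent", fp)
    }
    rf <- as.matrix(utils::read.csv(file.path(path, m$rf), header = FALSE))
    gesture <- utils::read.csv(file.path(path, m$gesture), header = FALSE)[, 1]
    angle <- utils::read.csv(file.path(path, m$angle), header = FALSE)[, 1]
    n <- nrow(rf)
    depth <- ncol(rf) / nch
    if (depth != round(depth)) stopf("RF row length not divisible by %d channels", nch)
    env <- array(0, dim = c(n, nch, depth))
    for (i in seq_len(n)) {
      fr <- rf_frame(matrix(rf[i, ], nch, depth, byrow = TRUE), fs)
      env[i, , ] <- preprocess(fr, preprocess_cfg)$pixels
    }
    split <- character(n)
    for (g in unique(gesture)) {
      idx <- which(gesture == g)
      k <- length(idx)
      n_tr <- round(0.6 * k); n_va <- round(0.2 * k)
      split[idx] <- c(rep("train", n_tr), rep("validation", n_va),
                      rep("test", k - n_tr - n_va))
    }
    sessions[[s]] <- structure(
      list(envelope = env, gesture = as.integer(gesture), angle = angle,
           session = s, split = split, frame_time = seq_len(n) - 1,
           rf = NULL),
      class = "amode_session")
  }
  structure(
    list(sessions = sessions,
         protocol = protocol_config(n_channels = nch, n_depth = depth,
                                    sampling_rate = fs,
                                    rotation_amplitude = mapping$rotation_amplitude %||% 80),
         tissue = NULL, shift_magnitudes = c(m2 = NA, m3 = NA),
         seed = NA, preprocess_cfg = preprocess_cfg,
         schema_version = STUDY_SCHEMA_VERSION),
    class = "amode_study")
}

#' Pipeline configuration
#'
#' One declarative block for the whole pipeline. Unknown keys are rejected
#' before any computation.
#'
#' @param master_seed Master seed for everything downstream.
#' @param protocol A [protocol_config].
#' @param tissue A [tissue_model].
#' @param shift_magnitudes `c(m2, m3)`.
#' @param preprocess A [preprocess_config].
#' @param spec An [architecture_spec].
#' @param hyper A [uda_hyperparams].
#' @param plan A [benchmark_plan].
#' @param algorithms Adaptation algorithms for the report.
#' @param ... Rejected: no unknown keys.
#' @return Object of class `run_config`.
#' @export
run_config <- function(master_seed = 0L, protocol = protocol_config(),
                       tissue = default_tissue_model(),
                       shift_magnitudes = c(0.3, 0.6),
                       preprocess = preprocess_config(),
                       spec = architecture_spec(),
                       hyper = uda_hyperparams(),
                       plan = benchmark_plan(),
                       algorithms = c("dann", "shot_original"), ...) {
  extra <- list(...)
  if (length(extra)) {
    stopf("unknown configuration key(s): %s", paste(names(extra), collapse = ", "))
  }
  structure(list(master_seed = master_seed, protocol = protocol,
                 tissue = tissue, shift_magnitudes = shift_magnitudes,
                 preprocess = preprocess, spec = spec, hyper = hyper,
                 plan = plan, algorithms = algorithms),
            class = "run_config")
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config, digits.d = 12)),
             collapse = "\n")
  # small stable rolling hash; enough to fingerprint a config in manifests
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Run the full pipeline
#'
#' simulate -> preprocess -> seeded benchmark -> adaptation matrix, writing
#' every artifact (study container, benchmark table, adaptation report,
#' improvement summary, provenance manifest with config hash and master
#' seed) under `out_dir`. Rerunning with the same config reproduces the
#' same report.
#'
#' @param config A [run_config].
#' @param out_dir Artifact directory (created if needed).
#' @return The adaptation report, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- generate_study(config$protocol, config$tissue,
                          config$shift_magnitudes, seed = config$master_seed,
                          preprocess_cfg = config$preprocess)
  write_study(study, file.path(out_dir, "study.rds"))
  bench <- run_task_benchmark(study, config$plan, config$spec)
  utils::write.csv(bench, file.path(out_dir, "benchmark.csv"),
                   row.names = FALSE)
  report <- run_adaptation_scenarios(study, config$plan, config$spec,
                                     algorithms = config$algorithms,
                                     hyper = config$hyper)
  utils::write.csv(as.data.frame(report$accuracy),
                   file.path(out_dir, "adaptation_matrix.csv"))
  utils::write.csv(improvement_summary(report),
                   file.path(out_dir, "improvement.csv"), row.names = FALSE)
  manifest <- list(config_hash = config_hash(config),
                   master_seed = config$master_seed,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   schema_version = STUDY_SCHEMA_VERSION)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  saveRDS(report, file.path(out_dir, "adaptation_report.rds"))
  invisible(report)
}
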