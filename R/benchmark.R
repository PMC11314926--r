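# Seeded performance benchmark and the adaptation-scenario matrix.

#' Draw benchmark seeds
#'
#' `n` seeds drawn uniformly from `[0, 2^32 - 1]` (returned as doubles,
#' since the range exceeds R's integer type), reproducible from the master
#' seed.
#'
#' @param n Number of seeds.
#' @param rng_master Master seed.
#' @return Numeric vector of `n` seeds.
#' @export
draw_seeds <- function(n, rng_master = 0L) {
  stopifnot(n >= 1)
  with_seed(rng_master, floor(stats::runif(n) * 2^32))
}

#' Classification accuracy
#'
#' @param predictions,labels Equal-length vectors.
#' @return Fraction of exact matches.
#' @export
accuracy <- function(predictions, labels) {
  if (!length(predictions)) stopf("empty prediction vector")
  if (length(predictions) != length(labels)) stopf("length mismatch")
  mean(predictions == labels)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` against the mean of the true values.
#'
#' @param predicted,truth Equal-length numeric vectors; the truth must have
#'   nonzero variance.
#' @return Scalar R-squared.
#' @export
r_squared <- function(predicted, truth) {
  if (length(truth) < 2L) stopf("need at least 2 samples")
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot <= 0) stopf("truth has zero variance; R^2 undefined")
  1 - sum((truth - predicted)^2) / ss_tot
}

#' Benchmark plan
#'
#' @param tasks Subset of `c("classify", "regress", "multitask")`.
#' @param n_models Models per task and session (default 10).
#' @param epochs,batch Training budget per model.
#' @param lr Named or scalar learning rate(s).
#' @param master_seed Seed from which the per-model seeds are drawn.
#' @param sd_flag_threshold Standard deviations above this are flagged
#'   (default 0.02, the 2-percentage-point convention).
#' @return Object of class `benchmark_plan`.
#' @export
benchmark_plan <- function(tasks = c("classify", "regress", "multitask"),
                           n_models = 10L, epochs = 20L, batch = 16L,
                           lr = 1e-3, master_seed = 0L,
                           sd_flag_threshold = 0.02) {
  structure(list(tasks = tasks, n_models = as.integer(n_models),
                 epochs = as.integer(epochs), batch = as.integer(batch),
                 lr = lr, master_seed = master_seed,
                 sd_flag_threshold = sd_flag_threshold),
            class = "benchmark_plan")
}

task_lr <- function(plan, task) {
  if (is.null(names(plan$lr))) plan$lr[1] else plan$lr[[task]] %||% 1e-3
}

#' Run the seeded task benchmark
#'
#' For every task and session: trains `n_models` networks with seeds drawn
#' from the master seed, evaluates each on that session's test split
#' (validation splits are never touched), and reports mean and standard
#' deviation of the task metric(s). Failed (diverged) runs are reported and
#' excluded.
#'
#' @param study An `amode_study`.
#' @param plan A [benchmark_plan].
#' @param spec An [architecture_spec] matching the study's frame width.
#' @param smoothing Label smoothing for classification losses.
#' @return Data frame with one row per task x session x metric: mean, sd,
#'   `sd_flagged`, `n_ok`.
#' @export
run_task_benchmark <- function(study, plan, spec, smoothing = 0) {
  stopifnot(inherits(study, "amode_study"), inherits(plan, "benchmark_plan"))
  seeds <- draw_seeds(plan$n_models, plan$master_seed)
  out <- NULL
  for (task in plan$tasks) {
    for (s in seq_along(study$sessions)) {
      dom <- session_domain(study, s, labeled = TRUE)
      te <- dom$split == "test"
      acc <- numeric(0); r2 <- numeric(0); failed <- 0L
      for (sd_i in seeds) {
        run <- tryCatch(
          train_source(dom, spec, task = task, seed = sd_i,
                       epochs = plan$epochs, batch = plan$batch,
                       lr = task_lr(plan, task), smoothing = smoothing),
          error = function(e) NULL)
        if (is.null(run)) { failed <- failed + 1L; next }
        net <- select_model(run)
        if (task != "regress") {
          pred <- predict(net, dom$x[te, , , drop = FALSE], type = "class")
          acc <- c(acc, accuracy(pred, dom$gesture[te]))
        }
        if (task != "classify") {
          pa <- predict(net, dom$x[te, , , drop = FALSE], type = "angle") *
            dom$rotation_amplitude
          r2 <- c(r2, r_squared(pa, dom$angle[te]))
        }
      }
      if (failed > 0L) {
        message(sprintf("benchmark: %d/%d runs failed for task %s session %d",
                        failed, plan$n_models, task, s))
      }
      mk <- function(metric, v) data.frame(
        task = task, session = s, metric = metric,
        mean = mean(v), sd = stats::sd(v),
        sd_flagged = stats::sd(v) > plan$sd_flag_threshold,
        n_ok = length(v))
      if (length(acc)) out <- rbind(out, mk("accuracy", acc))
      if (length(r2)) out <- rbind(out, mk("r_squared", r2))
    }
  }
  out
}

#' Run the adaptation scenarios
#'
#' The inter-session re-calibration matrix: session 1 is the source;
#' sessions 2 and 3 are the two target scenarios. The baseline row is the
#' best session-1 model (highest session-1 test accuracy among the seeded
#' runs) evaluated unchanged on the later sessions' test splits; each
#' algorithm row re-calibrates that model with the target session's train
#' split and evaluates on the same test split. Cells are means over
#' `n_adapt_seeds` adaptation seeds; the per-column best value is flagged.
#'
#' @param study An `amode_study`.
#' @param plan A [benchmark_plan] (`n_models` source models).
#' @param spec An [architecture_spec].
#' @param algorithms Character subset of `c("dann", "dann_ls", "vada",
#'   "vada_ls", "dirt_t", "shot_original", "shot_independent", "dann_gt",
#'   "dann_ss")`.
#' @param hyper A [uda_hyperparams].
#' @param n_adapt_seeds Adaptation repetitions per cell (default 3).
#' @param epochs Adaptation epochs (default the plan's).
#' @param smoothing Label smoothing used for the smoothed variants.
#' @return Object of class `adaptation_report`: accuracy matrix
#'   (rows = baseline + algorithms, columns = scenarios), best-flag matrix,
#'   and the source-model bookkeeping.
#' @export
run_adaptation_scenarios <- function(study, plan, spec,
                                     algorithms = c("dann", "shot_original"),
                                     hyper = uda_hyperparams(),
                                     n_adapt_seeds = 3L, epochs = NULL,
                                     smoothing = 0.1) {
  stopifnot(length(study$sessions) == 3L)
  epochs <- epochs %||% plan$epochs
  src <- session_domain(study, 1L, labeled = TRUE)
  seeds <- draw_seeds(plan$n_models, plan$master_seed)
  runs <- lapply(seeds, function(s) {
    train_source(src, spec, task = "classify", seed = s,
                 epochs = plan$epochs, batch = plan$batch,
                 lr = task_lr(plan, "classify"))
  })
  accs <- vapply(runs, function(r) evaluate_accuracy(select_model(r), src),
                 numeric(1))
  best <- which.max(accs)
  base_net <- select_model(runs[[best]])
  # the SHOT recipe initializes from label-smoothed source models
  ls_run <- train_source(src, spec, task = "classify", seed = seeds[best],
                         epochs = plan$epochs, batch = plan$batch,
                         lr = task_lr(plan, "classify"), smoothing = smoothing)
  ls_net <- select_model(ls_run)
  reg_init <- NULL
  if (any(algorithms %in% c("dann_gt", "dann_ss"))) {
    reg_run <- train_source(src, spec, task = "multitask", seed = seeds[best],
                            epochs = plan$epochs, batch = plan$batch,
                            lr = task_lr(plan, "classify"))
    reg_init <- select_model(reg_run)
  }
  aseeds <- draw_seeds(n_adapt_seeds, fold_seed(plan$master_seed) + 17L)
  scenarios <- c("session2", "session3")
  rows <- c("no_recalibration", algorithms)
  mat <- matrix(NA_real_, length(rows), length(scenarios),
                dimnames = list(rows, scenarios))
  for (sc in 1:2) {
    tgt <- session_domain(study, sc + 1L, labeled = FALSE)
    mat["no_recalibration", sc] <- evaluate_accuracy(base_net, tgt)
    for (alg in algorithms) {
      cell <- vapply(aseeds, function(s) {
        run <- switch(
          alg,
          dann = adapt_dann(src, tgt, init = base_net, hyper = hyper,
                            seed = s, epochs = epochs, batch = plan$batch,
                            lr = task_lr(plan, "classify")),
          dann_ls = adapt_dann(src, tgt, init = ls_net, hyper = hyper,
                               seed = s, epochs = epochs, batch = plan$batch,
                               lr = task_lr(plan, "classify"),
                               smoothing = smoothing),
          vada = adapt_vada(src, tgt, init = base_net, hyper = hyper,
                            seed = s, epochs = epochs, batch = plan$batch,
                            lr = task_lr(plan, "classify")),
          vada_ls = adapt_vada(src, tgt, init = ls_net, hyper = hyper,
                               seed = s, epochs = epochs, batch = plan$batch,
                               lr = task_lr(plan, "classify"),
                               smoothing = smoothing),
          dirt_t = {
            v <- adapt_vada(src, tgt, init = base_net, hyper = hyper,
                            seed = s, epochs = epochs, batch = plan$batch,
                            lr = task_lr(plan, "classify"))
            refine_dirt_t(v, tgt, hyper = hyper, seed = s,
                          batch = plan$batch, lr = task_lr(plan, "classify"))
          },
          shot_original = adapt_shot(ls_net, tgt, variant = "original",
                                     hyper = hyper, seed = s, epochs = epochs,
                                     batch = plan$batch,
                                     lr = task_lr(plan, "classify")),
          shot_independent = adapt_shot(ls_net, tgt, variant = "independent",
                                        hyper = hyper, seed = s,
                                        epochs = epochs, batch = plan$batch,
                                        lr = task_lr(plan, "classify")),
          dann_gt = adapt_dann_aux(src, tgt, init = reg_init,
                                   labels_mode = "ground_truth",
                                   hyper = hyper, seed = s, epochs = epochs,
                                   batch = plan$batch,
                                   lr = task_lr(plan, "classify"),
                                   target_angles = quarantined_labels(tgt)$angle),
          dann_ss = adapt_dann_aux(src, tgt, init = reg_init,
                                   labels_mode = "pca_ss", hyper = hyper,
                                   seed = s, epochs = epochs,
                                   batch = plan$batch,
                                   lr = task_lr(plan, "classify")),
          stopf("unknown algorithm '%s'", alg))
        evaluate_accuracy(select_model(run), tgt)
      }, numeric(1))
      mat[alg, sc] <- mean(cell)
    }
  }
  best_flag <- mat == rep(apply(mat, 2L, max), each = nrow(mat))
  structure(list(accuracy = mat, best = best_flag,
                 source_seed = seeds[best],
                 source_accuracy = accs[best],
                 n_adapt_seeds = n_adapt_seeds),
            class = "adaptation_report")
}

#' @export
print.adaptation_report <- function(x, ...) {
  cat("Re-calibration accuracy (rows: algorithms, columns: scenarios)\n")
  print(round(x$accuracy, 3))
  invisible(x)
}

#' Average improvement over the no-recalibration baseline
#'
#' For each algorithm, the mean over scenario columns of the change versus
#' the baseline row, in both conventions: relative percentage change
#' (`100 * (alg - base) / base`) and absolute percentage-point change.
#'
#' @param report An `adaptation_report` (or a bare accuracy matrix whose
#'   first row is the baseline).
#' @return Data frame with `algorithm`, `relative_pct`, `absolute_points`.
#' @export
improvement_summary <- function(report) {
  mat <- if (inherits(report, "adaptation_report")) report$accuracy else report
  base <- mat[1L, ]
  algs <- rownames(mat)[-1L]
  data.frame(
    algorithm = algs,
    relative_pct = vapply(algs, function(a) {
      100 * mean((mat[a, ] - base) / base)
    }, numeric(1)),
    absolute_points = vapply(algs, function(a) {
      100 * mean(mat[a, ] - base)
    }, numeric(1)),
    row.names = NULL
  )
}
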