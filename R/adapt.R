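# Unsupervised re-calibration algorithms: DANN, VADA, DIRT-T, SHOT (two
# variants), and DANN with auxiliary wrist-angle regression. All of them
# consume target frames only through `domain$x`; target gesture labels stay
# quarantined.

bind_batches <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}

add_grads <- function(g1, g2) {
  for (nm in names(g2)) g1[[nm]] <- g1[[nm]] + g2[[nm]]
  g1
}

resolve_init <- function(init, spec) {
  if (inherits(init, "train_run")) return(select_model(init))
  if (inherits(init, "amode_net")) return(init)
  if (is.null(init)) {
    if (is.null(spec)) stopf("supply `init` (a net or train_run) or `spec` for fresh weights")
    return(build_classifier(spec))
  }
  stopf("`init` must be an amode_net, a train_run, or NULL")
}

# Cycled target batches: reshuffled each epoch, recycled to cover the
# source epoch.
target_batch_plan <- function(n_target, n_batches, batch) {
  need <- n_batches * batch
  idx <- integer(0)
  while (length(idx) < need) idx <- c(idx, sample.int(n_target))
  split(idx[seq_len(need)], rep(seq_len(n_batches), each = batch))
}

mae_dpred <- function(pred, y) matrix(sign(pred - y) / length(y), ncol = 1)
mse_dpred <- function(pred, y) matrix(2 * (pred - y) / length(y), ncol = 1)

# Shared driver for the domain-adversarial family. `vada` switches on the
# cluster-assumption terms; `aux_mode` adds the two auxiliary regression
# objectives of the DANN-GT / DANN-SS variants.
adapt_adversarial <- function(source, target, init, hyper, seed, epochs,
                              batch, lr, smoothing, spec, vada,
                              aux_mode = NULL, target_angles = NULL,
                              reg_loss = "mae", algorithm = "dann") {
  stopifnot(inherits(source, "labeled_domain"),
            inherits(target, "unlabeled_domain"))
  tr_s <- domain_train_rows(source)
  tr_t <- which(target$split == "train")
  if (!length(tr_t)) tr_t <- seq_len(dim(target$x)[1])
  y_s <- source$gesture
  lam_d <- hyper$lambda_d
  lam_s <- if (vada) hyper$lambda_s else 0
  lam_t <- if (vada) hyper$lambda_t else 0
  lam_r <- 0
  ys_reg <- yt_reg <- NULL
  if (!is.null(aux_mode)) {
    if (aux_mode == "ground_truth") {
      lam_r <- hyper$lambda_r_gt
      if (is.null(target_angles)) {
        stopf("ground_truth mode needs `target_angles` (oracle wrist angles)")
      }
      ys_reg <- source$angle / source$rotation_amplitude
      yt_reg <- target_angles / target$rotation_amplitude
    } else {
      lam_r <- hyper$lambda_r_ss
      reg_loss <- "mae"   # outlier-robust loss is mandatory for the PCA signal
      ys_reg <- pca_pseudo_angle(source$x[tr_s, , , drop = FALSE],
                                 reference = source$angle[tr_s])
      ys_full <- rep(NA_real_, length(y_s)); ys_full[tr_s] <- ys_reg
      ys_reg <- ys_full
      yt_ss <- pca_pseudo_angle(target$x[tr_t, , , drop = FALSE])
      yt_reg <- rep(NA_real_, dim(target$x)[1]); yt_reg[tr_t] <- yt_ss
    }
  }
  dreg_fn <- if (reg_loss == "mae") mae_dpred else mse_dpred
  reg_val <- if (reg_loss == "mae") {
    function(p, y) mean(abs(p - y))
  } else function(p, y) mean((p - y)^2)
  uses_target <- lam_d > 0 || lam_t > 0 || !is.null(aux_mode)

  with_seed(seed, {
    net <- resolve_init(init, spec)
    if (!is.null(aux_mode) && !net$has_regression) {
      stopf("auxiliary-regression adaptation needs a network with a regression head")
    }
    disc <- NULL; disc_state <- NULL
    if (lam_d > 0) {
      disc <- build_discriminator(discriminator_spec(net$spec$bottleneck_units))
      disc_state <- adam_init(disc$params)
    }
    state <- adam_init(net$params)
    grl <- gradient_reversal(lam_d)
    history <- NULL
    checkpoints <- vector("list", epochs)
    for (ep in seq_len(epochs)) {
      sb <- batch_indices(tr_s, batch)
      tb <- if (uses_target) target_batch_plan(length(tr_t), length(sb), batch) else NULL
      terms <- NULL
      for (i in seq_along(sb)) {
        bi <- sb[[i]]
        ns <- length(bi)
        xs <- source$x[bi, , , drop = FALSE]
        if (uses_target) {
          ti <- tr_t[tb[[i]]]
          nt <- length(ti)
          xt <- target$x[ti, , , drop = FALSE]
          xall <- bind_batches(xs, xt)
        } else {
          ti <- integer(0); nt <- 0L
          xall <- xs
        }
        fw <- net_forward(net, xall, training = TRUE, keep_cache = TRUE)
        net <- fw$net
        srows <- seq_len(ns)
        trows <- if (nt) ns + seq_len(nt) else integer(0)
        ps <- fw$probs[srows, , drop = FALSE]
        ly <- cross_entropy(ps, y_s[bi], smoothing)
        dlog <- matrix(0, ns + nt, ncol(fw$probs))
        dlog[srows, ] <- cross_entropy_dlogits(ps, y_s[bi], smoothing)
        lct <- NA_real_
        if (vada && nt) {
          pt <- fw$probs[trows, , drop = FALSE]
          lct <- conditional_entropy(pt)
          if (lam_t > 0) {
            dlog[trows, ] <- dlog[trows, ] + lam_t * conditional_entropy_dlogits(pt)
          }
        }
        dreg <- NULL
        lrs <- lrt <- NA_real_
        if (lam_r > 0) {
          pr <- fw$reg[, 1]
          lrs <- reg_val(pr[srows], ys_reg[bi])
          lrt <- reg_val(pr[trows], yt_reg[ti])
          dreg <- matrix(0, ns + nt, 1)
          dreg[srows, ] <- lam_r * dreg_fn(pr[srows], ys_reg[bi])
          dreg[trows, ] <- lam_r * dreg_fn(pr[trows], yt_reg[ti])
        }
        ld <- NA_real_
        dz <- NULL
        if (lam_d > 0) {
          z <- fw$embedding
          dlab <- c(rep(0, ns), rep(1, nt))
          dfw <- disc_forward(disc, z, keep_cache = TRUE)
          ld <- bce_from_logits(dfw$logit[, 1], dlab)
          dbw <- disc_backward(disc, dfw$cache,
                               matrix(bce_dlogits(dfw$logit[, 1], dlab), ncol = 1))
          dst <- adam_step(disc$params, dbw$grads, disc_state, lr)
          disc$params <- dst$params; disc_state <- dst$state
          dz <- grl$backward(dbw$dz)
        }
        bw <- net_backward(net, fw$cache, dlogits = dlog, dreg = dreg, dz = dz)
        grads <- bw$grads
        lvs <- lvt <- NA_real_
        if (lam_s > 0 && hyper$eps_vat > 0) {
          vs <- vat_loss(net, xs, hyper)
          lvs <- vs$value
          dv <- lam_s * (vs$p_adv - vs$p0) / ns
          grads <- add_grads(grads, net_backward(net, vs$cache, dlogits = dv)$grads)
        }
        if (lam_t > 0 && hyper$eps_vat > 0 && nt) {
          xt_only <- target$x[ti, , , drop = FALSE]
          vt <- vat_loss(net, xt_only, hyper)
          lvt <- vt$value
          dv <- lam_t * (vt$p_adv - vt$p0) / nt
          grads <- add_grads(grads, net_backward(net, vt$cache, dlogits = dv)$grads)
        }
        st <- adam_step(net$params, grads, state, lr)
        net$params <- st$params; state <- st$state
        total <- ly +
          (if (is.finite(lam_d) && lam_d > 0) lam_d * ld else 0) +
          (if (vada) lam_s * (if (is.na(lvs)) 0 else lvs) +
             lam_t * ((if (is.na(lct)) 0 else lct) +
                      (if (is.na(lvt)) 0 else lvt)) else 0) +
          (if (lam_r > 0) lam_r * (lrs + lrt) else 0)
        if (!is.finite(total)) stopf("adaptation diverged (non-finite loss)")
        terms <- rbind(terms, c(loss = total, ly = ly, ld = ld, lct = lct,
                                lvs = lvs, lvt = lvt, lrs = lrs, lrt = lrt))
      }
      history <- rbind(history,
                       data.frame(epoch = ep, t(colMeans(terms, na.rm = TRUE))))
      checkpoints[[ep]] <- snapshot_net(net)
    }
    run <- new_train_run(algorithm, seed, history, checkpoints, net, "adam",
                         list(epochs = epochs, batch = batch, lr = lr,
                              smoothing = smoothing, hyper = hyper))
    run$discriminator <- disc
    run
  })
}

#' DANN re-calibration
#'
#' Domain-adversarial training: jointly minimizes the source classification
#' loss and, through a gradient reversal layer feeding the 48-d bottleneck
#' embeddings to the domain discriminator, maximizes domain confusion. The
#' discriminator itself descends the domain loss while the feature
#' extractor ascends it. With `lambda_d = 0` the procedure reduces exactly
#' to supervised source training.
#'
#' @param source A [labeled_domain] (session-1 data).
#' @param target An [unlabeled_domain] (later-session data, labels
#'   quarantined).
#' @param init Initialization: an `amode_net`, a `train_run` (its selected
#'   model), or `NULL` for fresh weights (then `spec` is required).
#' @param hyper A [uda_hyperparams].
#' @param seed,epochs,batch,lr Training controls (ADAM).
#' @param smoothing Label smoothing on the source loss.
#' @param spec Architecture for fresh initialization.
#' @return A `train_run` (selected checkpoint at minimum training loss).
#' @export
adapt_dann <- function(source, target, init = NULL, hyper = uda_hyperparams(),
                       seed = 0L, epochs = 20L, batch = 16L, lr = 1e-3,
                       smoothing = 0, spec = NULL) {
  adapt_adversarial(source, target, init, hyper, seed, epochs, batch, lr,
                    smoothing, spec, vada = FALSE, algorithm = "dann")
}

#' VADA re-calibration
#'
#' DANN plus the cluster-assumption terms: virtual adversarial loss on the
#' source (`lambda_s`), and conditional entropy plus virtual adversarial
#' loss on the target (`lambda_t`). With `lambda_s = lambda_t = 0` the
#' training trajectory coincides with [adapt_dann()] for equal seeds. All
#' loss terms are logged separately in the run history.
#'
#' @inheritParams adapt_dann
#' @return A `train_run`.
#' @export
adapt_vada <- function(source, target, init = NULL, hyper = uda_hyperparams(),
                       seed = 0L, epochs = 20L, batch = 16L, lr = 1e-3,
                       smoothing = 0, spec = NULL) {
  adapt_adversarial(source, target, init, hyper, seed, epochs, batch, lr,
                    smoothing, spec, vada = TRUE, algorithm = "vada")
}

#' DANN with auxiliary wrist-angle regression
#'
#' Adds two `lambda_r`-weighted regression objectives to the DANN
#' objective, one per domain. In `ground_truth` mode the supervisory
#' signals are the true wrist angles (the target's must be supplied
#' explicitly as `target_angles` — an oracle experiment; the quarantine is
#' never unsealed internally). In `pca_ss` mode both domains use the
#' normalized first principal component of their own frames
#' ([pca_pseudo_angle()]), and the outlier-robust mean absolute error is
#' mandatory.
#'
#' @inheritParams adapt_dann
#' @param labels_mode `"ground_truth"` (`lambda_r = 0.45`) or `"pca_ss"`
#'   (`lambda_r = 0.35`).
#' @param target_angles Oracle target angles (degrees), ground-truth mode
#'   only.
#' @param reg_loss `"mae"` (default) or `"mse"`; forced to `"mae"` in
#'   `pca_ss` mode.
#' @return A `train_run`.
#' @export
adapt_dann_aux <- function(source, target, init = NULL,
                           labels_mode = c("ground_truth", "pca_ss"),
                           hyper = uda_hyperparams(), seed = 0L, epochs = 20L,
                           batch = 16L, lr = 1e-3, smoothing = 0, spec = NULL,
                           target_angles = NULL, reg_loss = c("mae", "mse")) {
  labels_mode <- match.arg(labels_mode)
  reg_loss <- match.arg(reg_loss)
  adapt_adversarial(source, target, init, hyper, seed, epochs, batch, lr,
                    smoothing, spec, vada = FALSE, aux_mode = labels_mode,
                    target_angles = target_angles, reg_loss = reg_loss,
                    algorithm = if (labels_mode == "ground_truth") "dann-gt" else "dann-ss")
}

#' DIRT-T refinement
#'
#' Non-conservative refinement of a VADA-initialized model: for each round,
#' `refine_interval` gradient steps minimize the target-side
#' cluster-assumption loss `lambda_t * (entropy + VAT)` under a
#' `beta_t`-weighted KL leash to the frozen teacher (the previous model);
#' the teacher is then replaced by the Polyak (exponential moving) average
#' of the student. Source data are never touched.
#'
#' @param init A `train_run` (typically from [adapt_vada()]) or an
#'   `amode_net`.
#' @param target An [unlabeled_domain].
#' @param hyper A [uda_hyperparams] (`beta_t`, `refine_interval`,
#'   `refine_rounds`, `polyak_decay`).
#' @param seed,batch,lr Training controls (ADAM).
#' @return A `train_run` with one history row per refinement round and the
#'   final teacher in `$teacher`.
#' @export
refine_dirt_t <- function(init, target, hyper = uda_hyperparams(), seed = 0L,
                          batch = 16L, lr = 1e-3) {
  stopifnot(inherits(target, "unlabeled_domain"))
  if (hyper$refine_interval <= 0L) stopf("refinement interval B must be positive")
  tr_t <- which(target$split == "train")
  if (!length(tr_t)) tr_t <- seq_len(dim(target$x)[1])
  with_seed(seed, {
    student <- resolve_init(init, NULL)
    teacher <- student
    # the teacher is evaluated under the same batch statistics as the
    # student (no dropout), so the KL leash compares functions, not
    # normalization regimes
    teacher_eval <- function(tch, xb) {
      tch$spec$dropout_rate <- 0
      net_forward(tch, xb, training = TRUE)$probs
    }
    ema <- student$params
    state <- adam_init(student$params)
    history <- NULL
    checkpoints <- vector("list", hyper$refine_rounds)
    for (round in seq_len(hyper$refine_rounds)) {
      losses <- c()
      pool <- integer(0)
      for (step in seq_len(hyper$refine_interval)) {
        if (length(pool) < batch) pool <- c(pool, tr_t[sample.int(length(tr_t))])
        bi <- pool[seq_len(batch)]
        pool <- pool[-seq_len(batch)]
        xb <- target$x[bi, , , drop = FALSE]
        fw <- net_forward(student, xb, training = TRUE, keep_cache = TRUE)
        student <- fw$net
        p_teacher <- teacher_eval(teacher, xb)
        ent <- conditional_entropy(fw$probs)
        kl <- mean(kl_rows(p_teacher, fw$probs))
        dlog <- hyper$lambda_t * conditional_entropy_dlogits(fw$probs) +
          hyper$beta_t * (fw$probs - p_teacher) / nrow(fw$probs)
        grads <- net_backward(student, fw$cache, dlogits = dlog)$grads
        lv <- 0
        if (hyper$lambda_t > 0 && hyper$eps_vat > 0) {
          v <- vat_loss(student, xb, hyper)
          lv <- v$value
          dv <- hyper$lambda_t * (v$p_adv - v$p0) / nrow(v$p0)
          grads <- add_grads(grads, net_backward(student, v$cache, dlogits = dv)$grads)
        }
        st <- adam_step(student$params, grads, state, lr)
        student$params <- st$params; state <- st$state
        ema <- ema_update(ema, student$params, hyper$polyak_decay)
        losses <- c(losses, hyper$lambda_t * (ent + lv) + hyper$beta_t * kl)
      }
      teacher$params <- ema
      teacher$bn <- student$bn
      history <- rbind(history, data.frame(epoch = round, loss = mean(losses)))
      checkpoints[[round]] <- snapshot_net(student)
    }
    run <- new_train_run("dirt-t", seed, history, checkpoints, student, "adam",
                         list(batch = batch, lr = lr, hyper = hyper))
    run$teacher <- teacher
    run
  })
}

#' SHOT re-calibration (source-free)
#'
#' Source HypOthesis Transfer: the embedding classifier (the 48-to-6 output
#' layer) is frozen bitwise and only the feature extractor is retrained on
#' the unlabeled target with the information-maximization loss (conditional
#' entropy plus diversity) and a `beta_shot`-weighted cross-entropy against
#' prototype pseudo-labels, refreshed at the start of each of the first
#' `shot_label_epochs` epochs. Optimized with mini-batch gradient descent,
#' Nesterov momentum 0.9 and weight decay 1e-3. The `original` variant sums
#' all three terms in one gradient step; the `independent` variant applies
#' each term as its own objective in separate gradient steps per batch.
#'
#' @param source_model An `amode_net` or `train_run` trained on the source
#'   session (with label smoothing, following the SHOT recipe).
#' @param target An [unlabeled_domain].
#' @param variant `"original"` or `"independent"`.
#' @param hyper A [uda_hyperparams].
#' @param seed,epochs,batch,lr Training controls (SGD + Nesterov).
#' @return A `train_run` with pseudo-label history in `$pseudo`.
#' @export
adapt_shot <- function(source_model, target,
                       variant = c("original", "independent"),
                       hyper = uda_hyperparams(), seed = 0L, epochs = 20L,
                       batch = 16L, lr = 1e-3) {
  variant <- match.arg(variant)
  stopifnot(inherits(target, "unlabeled_domain"))
  net0 <- resolve_init(source_model, NULL)
  frozen <- c("out_W", "out_b")
  tr_t <- which(target$split == "train")
  if (!length(tr_t)) tr_t <- seq_len(dim(target$x)[1])
  with_seed(seed, {
    net <- net0
    trainable <- setdiff(names(net$params), frozen)
    state <- sgd_nesterov_init(net$params[trainable])
    pseudo <- NULL
    history <- NULL
    checkpoints <- vector("list", epochs)
    for (ep in seq_len(epochs)) {
      if (ep <= hyper$shot_label_epochs || is.null(pseudo)) {
        fw_all <- net_forward(net, target$x[tr_t, , , drop = FALSE],
                              training = FALSE)
        pseudo <- shot_pseudo_labels(fw_all$embedding, fw_all$probs,
                                     previous = if (ep == 1L) NULL else pseudo,
                                     distance = hyper$prototype_distance)
      }
      lab <- integer(dim(target$x)[1])
      lab[tr_t] <- pseudo$labels
      terms <- NULL
      for (bi in batch_indices(tr_t, batch)) {
        xb <- target$x[bi, , , drop = FALSE]
        yb <- lab[bi]
        if (variant == "original") {
          fw <- net_forward(net, xb, training = TRUE, keep_cache = TRUE)
          net <- fw$net
          sl <- shot_loss(fw$probs, yb, hyper)
          dlog <- conditional_entropy_dlogits(fw$probs) +
            diversity_dlogits(fw$probs) +
            hyper$beta_shot * cross_entropy_dlogits(fw$probs, yb)
          grads <- net_backward(net, fw$cache, dlogits = dlog)$grads
          st <- sgd_nesterov_step(net$params[trainable], grads[trainable],
                                  state, lr)
          net$params[trainable] <- st$params; state <- st$state
          terms <- rbind(terms, c(loss = sl$total, sl$terms))
        } else {
          vals <- c(entropy = NA_real_, diversity = NA_real_,
                    pseudo_ce = NA_real_)
          steps <- list(
            entropy = function(p) list(v = conditional_entropy(p),
                                       d = conditional_entropy_dlogits(p)),
            diversity = function(p) list(v = diversity_loss(p),
                                         d = diversity_dlogits(p)),
            pseudo_ce = function(p) list(v = cross_entropy(p, yb),
                                         d = hyper$beta_shot *
                                           cross_entropy_dlogits(p, yb))
          )
          for (nm in names(steps)) {
            fw <- net_forward(net, xb, training = TRUE, keep_cache = TRUE)
            net <- fw$net
            r <- steps[[nm]](fw$probs)
            vals[nm] <- r$v
            grads <- net_backward(net, fw$cache, dlogits = r$d)$grads
            st <- sgd_nesterov_step(net$params[trainable], grads[trainable],
                                    state, lr)
            net$params[trainable] <- st$params; state <- st$state
          }
          terms <- rbind(terms,
                         c(loss = unname(vals["entropy"] + vals["diversity"] +
                                           hyper$beta_shot * vals["pseudo_ce"]),
                           vals))
        }
      }
      if (!all(is.finite(terms[, "loss"]))) stopf("SHOT diverged (non-finite loss)")
      if (!identical(net$params$out_W, net0$params$out_W) ||
          !identical(net$params$out_b, net0$params$out_b)) {
        stopf("classifier head was modified during SHOT (frozen-head contract)")
      }
      history <- rbind(history, data.frame(epoch = ep, t(colMeans(terms))))
      checkpoints[[ep]] <- snapshot_net(net)
    }
    run <- new_train_run(paste0("shot-", variant), seed, history, checkpoints,
                         net, "sgd-nesterov",
                         list(epochs = epochs, batch = batch, lr = lr,
                              hyper = hyper))
    run$pseudo <- pseudo
    run
  })
}

#' PCA pseudo-angle
#'
#' Projects flattened envelope frames onto the first principal component of
#' their (mean-centered) frame matrix and min-max normalizes the projection
#' to `[-1, 1]`. Within a domain acquired under continuous wrist rotation
#' this projection is linearly related to the rotation angle, which makes
#' it usable as a free self-supervised regression signal.
#'
#' @param frames `n x d` matrix, or an `n x channels x width` array
#'   (flattened internally).
#' @param reference Optional known angles; the sign of the projection is
#'   chosen to correlate positively with them. Without a reference the sign
#'   is fixed deterministically from the loading vector.
#' @return Numeric vector in `[-1, 1]` (both endpoints attained).
#' @export
pca_pseudo_angle <- function(frames, reference = NULL) {
  if (length(dim(frames)) == 3L) {
    frames <- matrix(frames, dim(frames)[1], prod(dim(frames)[2:3]))
  }
  n <- nrow(frames)
  if (n < 3L) stopf("need at least 3 frames for a principal component")
  xc <- sweep(frames, 2L, colMeans(frames))
  if (sum(xc^2) <= .Machine$double.eps) stopf("frame batch is rank deficient")
  sv <- svd(xc, nu = 1L, nv = 1L)
  score <- sv$u[, 1] * sv$d[1]
  if (!is.null(reference)) {
    if (stats::cor(score, reference) < 0) score <- -score
  } else {
    load <- sv$v[, 1]
    if (load[which.max(abs(load))] < 0) score <- -score
  }
  rng <- range(score)
  if (rng[2] <= rng[1]) stopf("frame batch is rank deficient")
  2 * (score - rng[1]) / (rng[2] - rng[1]) - 1
}
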