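# Loss functions: supervised objectives, the homoscedastic multi-task
# weighting with the ln(1 + sigma^2) regularizer, and every term of the
# adaptation objectives (conditional entropy, VAT, diversity, domain BCE,
# SHOT). Probabilities are clamped at 1e-12 before logs.

PROB_FLOOR <- 1e-12

check_simplex <- function(p, tol = 1e-6) {
  if (!is.matrix(p)) stopf("probabilities must be a matrix (batch x classes)")
  if (any(p < -tol) || any(abs(rowSums(p) - 1) > tol)) {
    stopf("rows must lie on the probability simplex")
  }
}

#' Adaptation hyperparameters
#'
#' One config block holding every tunable of the adaptation objectives.
#' The adversarial weights default to the published optimum
#' (`lambda_d = 1e-2`, `lambda_s = 1`, `lambda_t = 1e-2`); the auxiliary
#' regression weight `lambda_r` defaults to 0.45 with ground-truth angles
#' and 0.35 with the PCA self-supervised signal.
#'
#' @param lambda_d Domain-loss weight (default 1e-2).
#' @param lambda_s Source VAT weight (default 1).
#' @param lambda_t Target cluster-assumption weight (default 1e-2).
#' @param beta_t DIRT-T Lagrange weight on the teacher KL (default 1e-2).
#' @param refine_interval DIRT-T gradient steps per teacher update
#'   (default 100).
#' @param refine_rounds DIRT-T refinement rounds (default 5).
#' @param polyak_decay Exponential weight-averaging decay (default 0.998).
#' @param beta_shot SHOT pseudo-label cross-entropy weight (default 0.3).
#' @param eps_vat VAT perturbation radius (default 1 on unit-normalized
#'   inputs).
#' @param xi_vat VAT power-iteration probe scale (default 1e-6).
#' @param n_power VAT power iterations (default 1).
#' @param lambda_r_gt,lambda_r_ss Auxiliary regression weights for
#'   ground-truth (0.45) and self-supervised (0.35) modes.
#' @param shot_label_epochs Epochs during which SHOT pseudo-labels are
#'   refreshed (default 5).
#' @param prototype_distance `"cosine"` (default) or `"euclidean"`.
#' @return Object of class `uda_hyperparams`.
#' @export
uda_hyperparams <- function(lambda_d = 1e-2, lambda_s = 1, lambda_t = 1e-2,
                            beta_t = 1e-2, refine_interval = 100L,
                            refine_rounds = 5L, polyak_decay = 0.998,
                            beta_shot = 0.3, eps_vat = 1, xi_vat = 1e-6,
                            n_power = 1L, lambda_r_gt = 0.45,
                            lambda_r_ss = 0.35, shot_label_epochs = 5L,
                            prototype_distance = c("cosine", "euclidean")) {
  vals <- c(lambda_d, lambda_s, lambda_t, beta_t, beta_shot, eps_vat, xi_vat,
            lambda_r_gt, lambda_r_ss)
  if (any(vals < 0)) stopf("adaptation hyperparameters must be non-negative")
  structure(
    list(lambda_d = lambda_d, lambda_s = lambda_s, lambda_t = lambda_t,
         beta_t = beta_t, refine_interval = as.integer(refine_interval),
         refine_rounds = as.integer(refine_rounds),
         polyak_decay = polyak_decay, beta_shot = beta_shot,
         eps_vat = eps_vat, xi_vat = xi_vat, n_power = as.integer(n_power),
         lambda_r_gt = lambda_r_gt, lambda_r_ss = lambda_r_ss,
         shot_label_epochs = as.integer(shot_label_epochs),
         prototype_distance = match.arg(prototype_distance)),
    class = "uda_hyperparams"
  )
}

#' Categorical cross-entropy with optional label smoothing
#'
#' Mean over the batch of `-sum_k q_k log p_k` with
#' `q = (1 - alpha) * onehot + alpha / K`.
#'
#' @param probabilities `n x K` matrix, rows on the simplex.
#' @param labels Integer class indices in `0..K-1`.
#' @param smoothing Label smoothing `alpha` in `[0, 1)`.
#' @return Scalar loss.
#' @export
cross_entropy <- function(probabilities, labels, smoothing = 0) {
  check_simplex(probabilities)
  n <- nrow(probabilities); K <- ncol(probabilities)
  stopifnot(length(labels) == n, smoothing >= 0, smoothing < 1)
  if (any(labels < 0 | labels >= K)) stopf("labels must be in 0..%d", K - 1)
  q <- matrix(smoothing / K, n, K)
  q[cbind(seq_len(n), labels + 1L)] <- q[cbind(seq_len(n), labels + 1L)] +
    (1 - smoothing)
  -mean(rowSums(q * log(pmax(probabilities, PROB_FLOOR))))
}

# Gradient of cross_entropy w.r.t. logits (softmax combined): (p - q)/n.
cross_entropy_dlogits <- function(probabilities, labels, smoothing = 0) {
  n <- nrow(probabilities); K <- ncol(probabilities)
  q <- matrix(smoothing / K, n, K)
  q[cbind(seq_len(n), labels + 1L)] <- q[cbind(seq_len(n), labels + 1L)] +
    (1 - smoothing)
  (probabilities - q) / n
}

#' Conditional entropy of classifier predictions
#'
#' Empirical estimate of the cluster-assumption penalty on unlabeled data:
#' mean over the batch of `-sum_k p_k log p_k`. Bounded in `[0, log K]`.
#'
#' @param probabilities `n x K` matrix, rows on the simplex.
#' @return Scalar entropy.
#' @export
conditional_entropy <- function(probabilities) {
  check_simplex(probabilities)
  -mean(rowSums(probabilities * log(pmax(probabilities, PROB_FLOOR))))
}

# d(conditional_entropy)/d(logits): p * (-log p - H_row) / n.
conditional_entropy_dlogits <- function(probabilities) {
  lp <- log(pmax(probabilities, PROB_FLOOR))
  H <- -rowSums(probabilities * lp)
  probabilities * (-lp - H) / nrow(probabilities)
}

#' Fair-diversity loss
#'
#' `sum_k phat_k log phat_k` where `phat` is the batch-mean prediction:
#' the negative entropy of the marginal, minimized (at `-log K`) when all
#' classes are predicted equally often. Equals
#' `KL(phat || uniform) - log K`.
#'
#' @param probabilities `n x K` matrix, rows on the simplex.
#' @return Scalar in `[-log K, 0]`.
#' @export
diversity_loss <- function(probabilities) {
  check_simplex(probabilities)
  phat <- colMeans(probabilities)
  sum(phat * log(pmax(phat, PROB_FLOOR)))
}

# d(diversity)/d(logits): chain through phat = mean over batch.
diversity_dlogits <- function(probabilities) {
  n <- nrow(probabilities)
  phat <- colMeans(probabilities)
  g <- (log(pmax(phat, PROB_FLOOR)) + 1) / n        # d/d phat_k
  inner <- probabilities * rep(g, each = n)
  inner - probabilities * rowSums(inner)
}

#' Domain discrimination loss
#'
#' Binary cross-entropy of discriminator logits against domain labels
#' (source = 0, target = 1), averaged over both batches.
#'
#' @param discriminator An `amode_disc`.
#' @param z_source,z_target Embedding batches (`n x 48`).
#' @return Scalar loss.
#' @export
domain_loss <- function(discriminator, z_source, z_target) {
  if (nrow(z_source) == 0L || nrow(z_target) == 0L) stopf("empty domain batch")
  z <- rbind(z_source, z_target)
  d <- c(rep(0, nrow(z_source)), rep(1, nrow(z_target)))
  logit <- disc_forward(discriminator, z)$logit[, 1]
  bce_from_logits(logit, d)
}

bce_from_logits <- function(logit, d) {
  # numerically stable: log(1 + exp(-|x|)) formulation
  mean((1 - d) * logit + log1p(exp(-abs(logit))) + pmax(-logit, 0))
}

bce_dlogits <- function(logit, d) {
  (stats::plogis(logit) - d) / length(logit)
}

#' Homoscedastic-uncertainty multi-task loss
#'
#' Combines the classification and regression task losses with learned task
#' variances: `sum_tau [ L_tau / (2 sigma_tau^2) + ln(1 + sigma_tau^2) ]`.
#' The modified regularizer `ln(1 + sigma^2)` is non-negative for every
#' variance, so the total loss cannot become negative for non-negative task
#' losses.
#'
#' @param loss_c,loss_r Non-negative task losses.
#' @param log_var Length-2 numeric, unconstrained log-variances
#'   `c(log sigma_c^2, log sigma_r^2)`.
#' @return List with `total`, per-task `weighted` terms, `regularizer`, and
#'   `grad_log_var` (gradient w.r.t. the log-variances).
#' @export
multitask_loss <- function(loss_c, loss_r, log_var = c(0, 0)) {
  if (loss_c < 0 || loss_r < 0) stopf("task losses must be non-negative")
  s2 <- exp(log_var)
  weighted <- c(loss_c, loss_r) / (2 * s2)
  reg <- log1p(s2)
  grad <- -c(loss_c, loss_r) / (2 * s2) + s2 / (1 + s2)
  list(total = sum(weighted) + sum(reg), weighted = weighted,
       regularizer = reg, grad_log_var = grad)
}

# ---- Virtual adversarial training -----------------------------------------

l2_normalize_rows <- function(r) {
  dm <- dim(r)
  flat <- matrix(r, dm[1])
  nrm <- sqrt(rowSums(flat^2))
  nrm[nrm == 0] <- 1
  array(flat / nrm, dim = dm)
}

kl_rows <- function(p, q) {
  rowSums(p * (log(pmax(p, PROB_FLOOR)) - log(pmax(q, PROB_FLOOR))))
}

#' Virtual adversarial loss
#'
#' Approximates `max_{||r|| <= eps} KL(h(x) || h(x + r))` by power
#' iteration: a random unit probe is refined along the gradient of the KL
#' divergence at scale `xi`, then the loss is evaluated at the adversarial
#' perturbation of radius `eps`, treating the clean prediction as constant.
#'
#' For an `amode_net` the gradient is obtained by backpropagation to the
#' input; any other model can be supplied as a list with elements
#' `predict(x) -> probs` and (optionally) `input_grad(x, p0) -> d KL / d x`
#' (a numeric central-difference fallback is used when absent).
#'
#' @param model An `amode_net` or a `list(predict = ..., input_grad = ...)`.
#' @param x Input batch (array for networks, matrix for generic models).
#' @param hyper A [uda_hyperparams].
#' @return List `value` (scalar loss), `r_adv` (the perturbation), and for
#'   networks `cache`/`p0`/`p_adv` for backpropagation.
#' @export
vat_loss <- function(model, x, hyper = uda_hyperparams()) {
  UseMethod("vat_loss")
}

#' @export
vat_loss.amode_net <- function(model, x, hyper = uda_hyperparams()) {
  if (hyper$eps_vat == 0) {
    return(list(value = 0, r_adv = array(0, dim = dim(x))))
  }
  p0 <- net_forward(model, x, training = FALSE)$probs
  d <- l2_normalize_rows(array(stats::rnorm(length(x)), dim = dim(x)))
  for (it in seq_len(hyper$n_power)) {
    xp <- x + hyper$xi_vat * d
    fw <- net_forward(model, xp, training = FALSE, keep_cache = TRUE)
    dlog <- (fw$probs - p0) / nrow(p0)        # grad of mean KL w.r.t. logits
    g <- net_backward(model, fw$cache, dlogits = dlog, need_dx = TRUE)$dx
    if (!all(is.finite(g))) {
      d <- l2_normalize_rows(array(stats::rnorm(length(x)), dim = dim(x)))
      next
    }
    d <- l2_normalize_rows(g)
  }
  r_adv <- hyper$eps_vat * d
  fw <- net_forward(model, x + r_adv, training = FALSE, keep_cache = TRUE)
  list(value = mean(kl_rows(p0, fw$probs)), r_adv = r_adv,
       p0 = p0, p_adv = fw$probs, cache = fw$cache)
}

#' @export
vat_loss.list <- function(model, x, hyper = uda_hyperparams()) {
  if (hyper$eps_vat == 0) {
    return(list(value = 0, r_adv = array(0, dim = dim(x))))
  }
  p0 <- model$predict(x)
  grad_fn <- model$input_grad %||% function(xx, p0) {
    g <- array(0, dim = dim(xx))
    h <- 1e-5
    for (i in seq_along(xx)) {
      xp <- xx; xp[i] <- xp[i] + h
      xm <- xx; xm[i] <- xm[i] - h
      g[i] <- (mean(kl_rows(p0, model$predict(xp))) -
               mean(kl_rows(p0, model$predict(xm)))) / (2 * h)
    }
    g
  }
  d <- l2_normalize_rows(array(stats::rnorm(length(x)), dim = dim(x) %||% length(x)))
  for (it in seq_len(hyper$n_power)) {
    d <- l2_normalize_rows(grad_fn(x + hyper$xi_vat * d, p0))
  }
  r_adv <- hyper$eps_vat * d
  list(value = mean(kl_rows(p0, model$predict(x + r_adv))), r_adv = r_adv)
}

# ---- SHOT ------------------------------------------------------------------

#' SHOT prototype pseudo-labels
#'
#' Round 0: class prototypes are the prediction-probability-weighted means
#' of the embeddings, and each sample is pseudo-labelled by its nearest
#' prototype (cosine distance by default). Subsequent rounds recompute
#' prototypes from the previous round's hard pseudo-labels. Ties break to
#' the lowest class index; a class with no weight mass keeps its previous
#' prototype.
#'
#' @param embeddings `n x d` embedding matrix.
#' @param probabilities `n x K` prediction matrix (round 0 weights).
#' @param previous `NULL` for round 0, else the previous result (list with
#'   `labels` and `prototypes`).
#' @param distance `"cosine"` or `"euclidean"`.
#' @return List with `labels` (0-based), `prototypes` (`K x d`), and
#'   `empty_classes`.
#' @export
shot_pseudo_labels <- function(embeddings, probabilities, previous = NULL,
                               distance = c("cosine", "euclidean")) {
  distance <- match.arg(distance)
  K <- ncol(probabilities)
  d <- ncol(embeddings)
  prototypes <- matrix(0, K, d)
  empty <- logical(K)
  if (is.null(previous)) {
    w <- probabilities
  } else {
    w <- matrix(0, nrow(embeddings), K)
    w[cbind(seq_len(nrow(embeddings)), previous$labels + 1L)] <- 1
  }
  for (k in seq_len(K)) {
    mass <- sum(w[, k])
    if (mass <= .Machine$double.eps) {
      empty[k] <- TRUE
      prototypes[k, ] <- if (!is.null(previous)) previous$prototypes[k, ] else 0
    } else {
      prototypes[k, ] <- colSums(embeddings * w[, k]) / mass
    }
  }
  dist <- prototype_distances(embeddings, prototypes, distance)
  labels <- apply(dist, 1L, which.min) - 1L   # which.min ties -> lowest index
  list(labels = as.integer(labels), prototypes = prototypes,
       empty_classes = which(empty))
}

prototype_distances <- function(z, proto, distance) {
  if (distance == "cosine") {
    zn <- z / pmax(sqrt(rowSums(z^2)), 1e-12)
    pn <- proto / pmax(sqrt(rowSums(proto^2)), 1e-12)
    1 - zn %*% t(pn)
  } else {
    zz <- rowSums(z^2)
    pp <- rowSums(proto^2)
    outer(zz, pp, "+") - 2 * z %*% t(proto)
  }
}

#' SHOT objective value
#'
#' `conditional_entropy + diversity_loss + beta * cross_entropy(probs,
#' pseudo_labels)`, all three minimized jointly. With `beta_shot = 0` this
#' reduces to the information-maximization loss.
#'
#' @param probabilities `n x K` prediction matrix.
#' @param pseudo_labels Integer pseudo-labels (0-based).
#' @param hyper A [uda_hyperparams].
#' @return List with `total` and the three `terms`.
#' @export
shot_loss <- function(probabilities, pseudo_labels, hyper = uda_hyperparams()) {
  ent <- conditional_entropy(probabilities)
  div <- diversity_loss(probabilities)
  ce <- cross_entropy(probabilities, pseudo_labels, smoothing = 0)
  list(total = ent + div + hyper$beta_shot * ce,
       terms = c(entropy = ent, diversity = div, pseudo_ce = ce))
}
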