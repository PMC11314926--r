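# Supervised source training and shared training-run machinery.

# A training run records per-epoch losses and a checkpoint per epoch;
# the selected checkpoint minimizes the algorithm's own training loss.
new_train_run <- function(algorithm, seed, history, checkpoints, template_net,
                          optimizer, config = list()) {
  sel <- select_epoch(history$loss)
  net <- restore_checkpoint(template_net, checkpoints[[sel]])
  structure(
    list(algorithm = algorithm, seed = seed, history = history,
         checkpoints = checkpoints, selected_epoch = sel, net = net,
         optimizer = optimizer, config = config),
    class = "train_run"
  )
}

select_epoch <- function(losses) {
  if (!length(losses)) stopf("no completed epochs to select from")
  which.min(losses)   # ties resolve to the earliest epoch
}

snapshot_net <- function(net) {
  list(params = net$params, bn = net$bn, uncertainty = net$uncertainty)
}

restore_checkpoint <- function(net, ck) {
  net$params <- ck$params
  net$bn <- ck$bn
  net$uncertainty <- ck$uncertainty
  net
}

#' Select the checkpoint with minimum training loss
#'
#' Returns the network at the epoch that minimized the run's own training
#' objective; ties resolve to the earliest epoch.
#'
#' @param run A `train_run`.
#' @return An `amode_net`.
#' @export
select_model <- function(run) {
  stopifnot(inherits(run, "train_run"))
  run$net
}

#' @export
print.train_run <- function(x, ...) {
  cat(sprintf("<train_run> %s, %d epochs, selected epoch %d (loss %.4f)\n",
              x$algorithm, nrow(x$history), x$selected_epoch,
              x$history$loss[x$selected_epoch]))
  invisible(x)
}

domain_train_rows <- function(domain) {
  which(domain$split == "train")
}

batch_indices <- function(idx, batch) {
  idx <- idx[sample.int(length(idx))]
  split(idx, ceiling(seq_along(idx) / batch))
}

#' Train a network on the labeled source domain
#'
#' Supervised training on the domain's train split: 20 epochs, batch 16,
#' ADAM, with the task-appropriate loss — cross-entropy (optionally label
#' smoothed) for gesture classification, mean squared error on normalized
#' angles for regression, or the homoscedastic-uncertainty weighted sum for
#' the multi-task setting. Deterministic given `(seed, data, config)`.
#'
#' @param domain A [labeled_domain].
#' @param spec An [architecture_spec].
#' @param task `"classify"`, `"regress"`, or `"multitask"`.
#' @param seed Run seed (fixes initialization, shuffling, dropout).
#' @param epochs,batch,lr Training budget and ADAM learning rate.
#' @param smoothing Label smoothing for the classification loss.
#' @return A `train_run`.
#' @export
train_source <- function(domain, spec = architecture_spec(),
                         task = c("classify", "regress", "multitask"),
                         seed = 0L, epochs = 20L, batch = 16L, lr = 1e-3,
                         smoothing = 0) {
  task <- match.arg(task)
  stopifnot(inherits(domain, "labeled_domain"))
  tr <- domain_train_rows(domain)
  if (!length(tr)) stopf("domain has no train split rows")
  y <- domain$gesture
  yr <- domain$angle / domain$rotation_amplitude
  with_seed(seed, {
    net <- build_classifier(spec)
    if (task != "classify") {
      net <- attach_regression_head(net, multitask = (task == "multitask"))
    }
    opt_params <- net$params
    if (task == "multitask") opt_params$..log_var <- net$uncertainty
    state <- adam_init(opt_params)
    history <- NULL
    checkpoints <- vector("list", epochs)
    for (ep in seq_len(epochs)) {
      ep_loss <- c()
      for (bi in batch_indices(tr, batch)) {
        xb <- domain$x[bi, , , drop = FALSE]
        fw <- net_forward(net, xb, training = TRUE, keep_cache = TRUE)
        net <- fw$net
        n <- length(bi)
        dlog <- NULL; dreg <- NULL; dunc <- NULL
        if (task == "classify") {
          loss <- cross_entropy(fw$probs, y[bi], smoothing)
          dlog <- cross_entropy_dlogits(fw$probs, y[bi], smoothing)
        } else if (task == "regress") {
          res <- fw$reg[, 1] - yr[bi]
          loss <- mean(res^2)
          dreg <- matrix(2 * res / n, n, 1)
        } else {
          lc <- cross_entropy(fw$probs, y[bi], smoothing)
          res <- fw$reg[, 1] - yr[bi]
          lrr <- mean(res^2)
          mt <- multitask_loss(lc, lrr, net$uncertainty)
          loss <- mt$total
          s2 <- exp(net$uncertainty)
          dlog <- cross_entropy_dlogits(fw$probs, y[bi], smoothing) / (2 * s2[1])
          dreg <- matrix(2 * res / n / (2 * s2[2]), n, 1)
          dunc <- mt$grad_log_var
        }
        if (!is.finite(loss)) stopf("training diverged (non-finite loss)")
        bw <- net_backward(net, fw$cache, dlogits = dlog, dreg = dreg)
        g <- bw$grads
        p <- net$params
        if (task == "multitask") {
          p$..log_var <- net$uncertainty
          g$..log_var <- dunc
        }
        st <- adam_step(p, g, state, lr)
        state <- st$state
        if (task == "multitask") {
          net$uncertainty <- st$params$..log_var
          st$params$..log_var <- NULL
        }
        net$params <- st$params
        ep_loss <- c(ep_loss, loss)
      }
      history <- rbind(history, data.frame(epoch = ep, loss = mean(ep_loss)))
      checkpoints[[ep]] <- snapshot_net(net)
    }
    new_train_run(paste0("source-", task), seed, history, checkpoints, net,
                  "adam", list(epochs = epochs, batch = batch, lr = lr,
                               smoothing = smoothing, task = task))
  })
}

#' Classification accuracy of a network on a domain split
#'
#' @param net An `amode_net`.
#' @param domain A [labeled_domain] or [unlabeled_domain] (evaluation
#'   unseals the quarantined labels).
#' @param split Split to evaluate on (default `"test"`).
#' @return Fraction of correct gesture predictions.
#' @export
evaluate_accuracy <- function(net, domain, split = "test") {
  keep <- domain$split %in% split
  if (!any(keep)) stopf("no frames in split '%s'", paste(split, collapse = ","))
  y <- if (inherits(domain, "unlabeled_domain")) {
    quarantined_labels(domain)$gesture
  } else domain$gesture
  pred <- predict(net, domain$x[keep, , , drop = FALSE], type = "class")
  accuracy(pred, y[keep])
}
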