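# Optimizers operating on named lists of parameter arrays.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

sgd_nesterov_init <- function(params) {
  list(v = lapply(params, function(p) p * 0))
}

# Nesterov momentum with decoupled-style weight decay added to the raw
# gradient (the convention of the SHOT training recipe).
sgd_nesterov_step <- function(params, grads, state, lr = 1e-3, momentum = 0.9,
                              weight_decay = 1e-3) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- g + weight_decay * params[[nm]]
    state$v[[nm]] <- momentum * state$v[[nm]] + g
    params[[nm]] <- params[[nm]] - lr * (g + momentum * state$v[[nm]])
  }
  list(params = params, state = state)
}

# Exponential moving average of parameters (Polyak averaging).
ema_update <- function(avg, params, decay) {
  for (nm in names(params)) {
    avg[[nm]] <- decay * avg[[nm]] + (1 - decay) * params[[nm]]
  }
  avg
}
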