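# Layer primitives for the compact CNN and its adaptation heads.
#
# All layers operate on plain R arrays and return explicit caches so that
# gradients (including gradients with respect to the *input*, needed by
# virtual adversarial training and gradient reversal) can be propagated by
# hand. Convolution inputs have shape (m, C_in, W): the 8-row scanline axis
# is folded into the batch axis m because every kernel is 1-D along width
# with stride 1 along height.

# ---- 1-D convolution -------------------------------------------------------

# weight: (C_out, C_in * k) with input channel fastest; bias: length C_out.
conv1d_forward <- function(x, weight, bias, k, stride = 1L,
                           padding = c(0L, 0L)) {
  dm <- dim(x)
  m <- dm[1]; cin <- dm[2]; w <- dm[3]
  pl <- padding[1]; pr <- padding[2]
  wp <- w + pl + pr
  if (pl > 0 || pr > 0) {
    xp <- array(0, dim = c(m, cin, wp))
    xp[, , (pl + 1L):(pl + w)] <- x
  } else xp <- x
  wout <- (wp - k) %/% stride + 1L
  cout <- nrow(weight)
  y <- array(0, dim = c(m, cout, wout))
  cols <- vector("list", wout)
  for (j in seq_len(wout)) {
    idx <- (j - 1L) * stride + seq_len(k)
    col <- xp[, , idx, drop = FALSE]
    dim(col) <- c(m, cin * k)
    cols[[j]] <- col
    y[, , j] <- col %*% t(weight) + rep(bias, each = m)
  }
  list(out = y, cache = list(cols = cols, dims = dm, k = k, stride = stride,
                             padding = padding, wp = wp))
}

conv1d_backward <- function(dy, weight, cache) {
  dm <- cache$dims
  m <- dm[1]; cin <- dm[2]; w <- dm[3]
  k <- cache$k; stride <- cache$stride
  pl <- cache$padding[1]
  wout <- dim(dy)[3]
  dW <- matrix(0, nrow(weight), ncol(weight))
  db <- numeric(nrow(weight))
  dxp <- array(0, dim = c(m, cin, cache$wp))
  for (j in seq_len(wout)) {
    dyj <- dy[, , j, drop = TRUE]
    if (is.null(dim(dyj))) dyj <- matrix(dyj, m, nrow(weight))
    dW <- dW + t(dyj) %*% cache$cols[[j]]
    db <- db + colSums(dyj)
    dcol <- dyj %*% weight
    dim(dcol) <- c(m, cin, k)
    idx <- (j - 1L) * stride + seq_len(k)
    dxp[, , idx] <- dxp[, , idx, drop = FALSE] + dcol
  }
  dx <- dxp[, , (pl + 1L):(pl + w), drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# ---- Batch normalization ---------------------------------------------------

# Normalizes per channel over (batch, width). x: (m, C, W) or matrix (m, C).
# Running statistics use exponential updates with momentum 0.1 and biased
# batch variance. Training with a single-sample batch is rejected (the batch
# variance degenerates).
bn_forward <- function(x, gamma, beta, running, training, eps = 1e-5,
                       momentum = 0.1) {
  is_mat <- is.matrix(x)
  if (is_mat) {
    dm <- dim(x)
    x <- array(x, dim = c(dm[1], dm[2], 1L))
  }
  dm <- dim(x)
  m <- dm[1]; C <- dm[2]; W <- dm[3]
  n_eff <- m * W
  if (training) {
    if (m < 2L) stopf("batch normalization needs batch size >= 2 in training mode")
    xt <- aperm(x, c(1, 3, 2)); dim(xt) <- c(n_eff, C)
    mu <- colMeans(xt)
    var_ <- colMeans(xt^2) - mu^2
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * var_
  } else {
    mu <- running$mean
    var_ <- running$var
  }
  inv <- 1 / sqrt(var_ + eps)
  xhat <- sweep(x, 2L, mu, "-")
  xhat <- sweep(xhat, 2L, inv, "*")
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  if (is_mat) { dim(y) <- c(m, C); xh2 <- xhat } else xh2 <- xhat
  list(out = y, running = running,
       cache = list(xhat = xh2, inv = inv, gamma = gamma, n_eff = n_eff,
                    is_mat = is_mat, training = training))
}

bn_backward <- function(dy, cache) {
  xhat <- cache$xhat
  dm <- dim(xhat)
  m <- dm[1]; C <- dm[2]; W <- dm[3]
  if (is.matrix(dy)) dy <- array(dy, dim = c(nrow(dy), ncol(dy), 1L))
  n <- cache$n_eff
  ax <- function(a) { p <- aperm(a, c(1, 3, 2)); dim(p) <- c(n, C); p }
  dyf <- ax(dy); xhf <- ax(xhat)
  dgamma <- colSums(dyf * xhf)
  dbeta <- colSums(dyf)
  if (cache$training) {
    t1 <- sweep(dyf, 2L, dbeta / n, "-")
    t2 <- sweep(xhf, 2L, dgamma / n, "*")
    dxf <- sweep(t1 - t2, 2L, cache$gamma * cache$inv, "*")
  } else {
    dxf <- sweep(dyf, 2L, cache$gamma * cache$inv, "*")
  }
  dx <- array(dxf, dim = c(m, W, C))
  dx <- aperm(dx, c(1, 3, 2))
  if (cache$is_mat) dim(dx) <- c(m, C)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- Activations, pooling, dropout ----------------------------------------

leaky_relu_forward <- function(x, slope = 0.1) {
  y <- ifelse(x > 0, x, slope * x)
  list(out = y, cache = list(pos = x > 0, slope = slope))
}

leaky_relu_backward <- function(dy, cache) {
  dy * ifelse(cache$pos, 1, cache$slope)
}

# Width-only max pooling with window = stride = w. Ties resolve to the
# earliest position.
maxpool_forward <- function(x, w) {
  if (w == 1L) return(list(out = x, cache = list(identity = TRUE)))
  dm <- dim(x)
  wout <- dm[3] %/% w
  y <- array(-Inf, dim = c(dm[1], dm[2], wout))
  amax <- array(1L, dim = c(dm[1], dm[2], wout))
  for (j in seq_len(wout)) {
    base <- (j - 1L) * w
    for (kk in seq_len(w)) {
      v <- x[, , base + kk]
      sel <- v > y[, , j]
      y[, , j][sel] <- v[sel]
      amax[, , j][sel] <- kk
    }
  }
  list(out = y, cache = list(identity = FALSE, amax = amax, w = w, dims = dm))
}

maxpool_backward <- function(dy, cache) {
  if (cache$identity) return(dy)
  dm <- cache$dims
  dx <- array(0, dim = dm)
  w <- cache$w
  wout <- dim(dy)[3]
  for (j in seq_len(wout)) {
    base <- (j - 1L) * w
    for (kk in seq_len(w)) {
      sel <- cache$amax[, , j] == kk
      tmp <- dx[, , base + kk]
      tmp[sel] <- tmp[sel] + dy[, , j][sel]
      dx[, , base + kk] <- tmp
    }
  }
  dx
}

# Inverted dropout; the mask is drawn from the ambient RNG stream so a run
# seed makes training bitwise reproducible.
dropout_forward <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, cache = list(mask = NULL)))
  mask <- array(stats::runif(length(x)) >= p, dim = dim(x)) / (1 - p)
  list(out = x * mask, cache = list(mask = mask))
}

dropout_backward <- function(dy, cache) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

# ---- Fully connected, softmax ---------------------------------------------

fc_forward <- function(x, weight, bias) {
  list(out = x %*% t(weight) + rep(bias, each = nrow(x)),
       cache = list(x = x))
}

fc_backward <- function(dy, weight, cache) {
  list(dx = dy %*% weight, dW = t(dy) %*% cache$x, db = colSums(dy))
}

softmax <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Gradient reversal operation
#'
#' The layer that implements adversarial feature alignment in one backward
#' sweep: the forward pass is the identity, the backward pass multiplies the
#' incoming gradient by `-lambda`. Returned as an explicit forward/backward
#' pair consumed by the adaptation training loops.
#'
#' @param lambda Non-negative reversal coefficient.
#' @return List with functions `forward(x)` (identity) and `backward(g)`
#'   (returns `-lambda * g`).
#' @export
gradient_reversal <- function(lambda) {
  if (lambda < 0) stopf("`lambda` must be >= 0")
  list(forward = function(x) x,
       backward = function(g) -lambda * g)
}
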