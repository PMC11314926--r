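#' Architecture specification for the compact gesture CNN
#'
#' Four convolutional blocks (1-D kernels along the width/depth axis,
#' stride 1 along the 8-channel height axis), each block being
#' convolution -> pre-activation batch normalization -> Leaky ReLU ->
#' width-only max pooling -> dropout. Block 1 uses a valid convolution with
#' width-stride equal to its kernel; blocks 2-4 use same-padded stride-1
#' convolutions. A 256-to-48 bottleneck FC layer (with its own
#' pre-activation batch normalization) produces the 48-d embedding in which
#' all domain adaptation operates, followed by a 48-to-6 Softmax output.
#'
#' @param input_height Number of scanlines (8).
#' @param input_width Envelope image width (default 1632).
#' @param kernel_widths Kernel sizes of blocks 1-4, default `c(51, 23, 8, 4)`.
#' @param filters Filters per block, default 32 each.
#' @param pool_sizes Width-only max-pool windows, default `c(2, 2, 2, 4)`.
#' @param dropout_rate Dropout forget rate, default 0.1.
#' @param leaky_slope Leaky ReLU negative slope, default 0.1.
#' @param bottleneck_units Embedding width, default 48.
#' @param flatten_dim Required flattened feature dimension, default 256.
#' @param n_classes Number of gesture classes, default 6.
#' @param bottleneck_dropout Apply dropout after the bottleneck activation
#'   (default `TRUE`).
#' @return Object of class `architecture_spec`.
#' @export
architecture_spec <- function(input_height = 8L, input_width = 1632L,
                              kernel_widths = c(51L, 23L, 8L, 4L),
                              filters = c(32L, 32L, 32L, 32L),
                              pool_sizes = c(2L, 2L, 2L, 4L),
                              dropout_rate = 0.1, leaky_slope = 0.1,
                              bottleneck_units = 48L, flatten_dim = 256L,
                              n_classes = 6L, bottleneck_dropout = TRUE) {
  stopifnot(length(kernel_widths) == 4L, length(filters) == 4L,
            length(pool_sizes) == 4L)
  spec <- structure(
    list(input_height = as.integer(input_height),
         input_width = as.integer(input_width),
         kernel_widths = as.integer(kernel_widths),
         filters = as.integer(filters),
         pool_sizes = as.integer(pool_sizes),
         dropout_rate = dropout_rate, leaky_slope = leaky_slope,
         bottleneck_units = as.integer(bottleneck_units),
         flatten_dim = as.integer(flatten_dim),
         n_classes = as.integer(n_classes),
         bottleneck_dropout = isTRUE(bottleneck_dropout)),
    class = "architecture_spec"
  )
  spec$geometry <- spec_geometry(spec)   # validates
  spec
}

# Width bookkeeping through the four blocks; errors if the spec cannot
# reach the requested flatten dimension, reporting the achievable one.
spec_geometry <- function(spec) {
  w <- spec$input_width
  k1 <- spec$kernel_widths[1]
  if (w < k1) stopf("input width %d is narrower than block-1 kernel %d", w, k1)
  widths_conv <- integer(4)
  widths_pool <- integer(4)
  w <- (w - k1) %/% k1 + 1L           # valid, stride = kernel
  widths_conv[1] <- w
  for (b in 1:4) {
    if (b > 1) widths_conv[b] <- w    # same padding, stride 1
    p <- spec$pool_sizes[b]
    if (w < p) stopf("block %d pool window %d exceeds surviving width %d", b, p, w)
    w <- w %/% p
    widths_pool[b] <- w
  }
  achieved <- spec$filters[4] * spec$input_height * w
  if (achieved != spec$flatten_dim) {
    stopf("spec reaches a %d-d flattened feature space, not the required %d",
          achieved, spec$flatten_dim)
  }
  list(widths_conv = widths_conv, widths_pool = widths_pool,
       final_width = w)
}

he_init <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
}

#' Build the gesture classifier network
#'
#' Instantiates the architecture of [architecture_spec()] with
#' He-initialized weights (drawn from the ambient RNG stream, so wrap in a
#' seed for reproducibility). The default specification counts exactly
#' 50,582 trainable parameters.
#'
#' @param spec An [architecture_spec].
#' @return Object of class `amode_net`: parameter list, batch-norm running
#'   statistics, and the spec.
#' @export
build_classifier <- function(spec = architecture_spec()) {
  stopifnot(inherits(spec, "architecture_spec"))
  params <- list()
  bn <- list()
  cin <- 1L
  for (b in 1:4) {
    k <- spec$kernel_widths[b]; cout <- spec$filters[b]
    params[[paste0("conv", b, "_W")]] <- he_init(cout, cin * k)
    params[[paste0("conv", b, "_b")]] <- numeric(cout)
    params[[paste0("bn", b, "_gamma")]] <- rep(1, cout)
    params[[paste0("bn", b, "_beta")]] <- numeric(cout)
    bn[[paste0("bn", b)]] <- list(mean = numeric(cout), var = rep(1, cout))
    cin <- cout
  }
  params$fc_W <- he_init(spec$bottleneck_units, spec$flatten_dim)
  params$fc_b <- numeric(spec$bottleneck_units)
  params$bnf_gamma <- rep(1, spec$bottleneck_units)
  params$bnf_beta <- numeric(spec$bottleneck_units)
  bn$bnf <- list(mean = numeric(spec$bottleneck_units),
                 var = rep(1, spec$bottleneck_units))
  params$out_W <- he_init(spec$n_classes, spec$bottleneck_units)
  params$out_b <- numeric(spec$n_classes)
  structure(
    list(spec = spec, params = params, bn = bn,
         has_regression = FALSE, uncertainty = NULL),
    class = "amode_net"
  )
}

#' Attach the wrist-angle regression head
#'
#' Adds a single linear neuron (48 weights + 1 bias) in parallel with the
#' classification head, sharing the bottleneck embedding. The
#' classification path is untouched. With `multitask = TRUE`, two
#' homoscedastic-uncertainty log-variance parameters (one per task) are
#' added for automatic loss weighting.
#'
#' @param net An `amode_net`.
#' @param multitask Add the two uncertainty parameters.
#' @return The augmented `amode_net`.
#' @export
attach_regression_head <- function(net, multitask = FALSE) {
  stopifnot(inherits(net, "amode_net"))
  if (net$has_regression) stopf("regression head already attached")
  net$params$reg_W <- he_init(1L, net$spec$bottleneck_units)
  net$params$reg_b <- numeric(1)
  net$has_regression <- TRUE
  if (multitask) net$uncertainty <- c(log_var_c = 0, log_var_r = 0)
  net
}

#' Count trainable parameters
#'
#' Counts every trainable scalar: convolution weights and biases,
#' batch-norm scales and shifts, fully connected weights and biases, and
#' any task-uncertainty parameters. The default method sums the lengths of
#' all numeric elements of a (possibly nested) list, so a bare layer such
#' as `list(W = matrix(0, 48, 8192), b = numeric(48))` can be counted too.
#'
#' @param net An `amode_net`, a discriminator, or a list of numeric arrays.
#' @return Integer parameter count.
#' @export
count_parameters <- function(net) UseMethod("count_parameters")

#' @export
count_parameters.amode_net <- function(net) {
  count_parameters.default(net$params) + length(net$uncertainty)
}

#' @export
count_parameters.amode_disc <- function(net) {
  count_parameters.default(net$params)
}

#' @export
count_parameters.default <- function(net) {
  if (is.numeric(net)) return(length(net))
  if (is.list(net)) return(sum(vapply(net, count_parameters, numeric(1))))
  0L
}

# ---- Forward / backward ----------------------------------------------------

same_padding <- function(k) {
  total <- k - 1L
  c(total %/% 2L, total - total %/% 2L)
}

#' Forward pass through the gesture network
#'
#' @param net An `amode_net`.
#' @param x Input batch, array `n x height x width`.
#' @param training Training mode: batch statistics for normalization,
#'   active dropout (masks drawn from the ambient RNG stream).
#' @param keep_cache Retain intermediate activations for [net_backward()].
#' @return List with `probs` (`n x K`, rows on the simplex), `logits`,
#'   `embedding` (`n x 48`), `reg` (`n x 1` or `NULL`), `cache`, and `net`
#'   (with updated batch-norm running statistics when training).
#' @export
net_forward <- function(net, x, training = FALSE, keep_cache = FALSE) {
  spec <- net$spec
  n <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  stopifnot(H == spec$input_height, W == spec$input_width)
  a <- aperm(x, c(2, 1, 3))
  dim(a) <- c(H * n, 1L, W)
  p <- net$params
  cache <- if (keep_cache) list(n = n) else NULL
  for (b in 1:4) {
    k <- spec$kernel_widths[b]
    if (b == 1L) { stride <- k; pad <- c(0L, 0L) } else { stride <- 1L; pad <- same_padding(k) }
    cv <- conv1d_forward(a, p[[paste0("conv", b, "_W")]],
                         p[[paste0("conv", b, "_b")]], k, stride, pad)
    bnr <- bn_forward(cv$out, p[[paste0("bn", b, "_gamma")]],
                      p[[paste0("bn", b, "_beta")]], net$bn[[paste0("bn", b)]],
                      training)
    net$bn[[paste0("bn", b)]] <- bnr$running
    ac <- leaky_relu_forward(bnr$out, spec$leaky_slope)
    mp <- maxpool_forward(ac$out, spec$pool_sizes[b])
    dp <- dropout_forward(mp$out, spec$dropout_rate, training)
    a <- dp$out
    if (keep_cache) {
      cache[[paste0("b", b)]] <- list(conv = cv$cache, bn = bnr$cache,
                                      act = ac$cache, pool = mp$cache,
                                      drop = dp$cache)
    }
  }
  # flatten (H*n, C, Wf) -> (n, H*C*Wf), height grouped per sample
  dmf <- dim(a)
  af <- array(a, dim = c(H, n, dmf[2], dmf[3]))
  flat <- aperm(af, c(2, 1, 3, 4))
  dim(flat) <- c(n, H * dmf[2] * dmf[3])
  fc <- fc_forward(flat, p$fc_W, p$fc_b)
  bnf <- bn_forward(fc$out, p$bnf_gamma, p$bnf_beta, net$bn$bnf, training)
  net$bn$bnf <- bnf$running
  acf <- leaky_relu_forward(bnf$out, spec$leaky_slope)
  z_pre <- acf$out
  if (spec$bottleneck_dropout) {
    dpf <- dropout_forward(z_pre, spec$dropout_rate, training)
    z <- dpf$out
  } else {
    dpf <- list(cache = list(mask = NULL))
    z <- z_pre
  }
  outl <- fc_forward(z, p$out_W, p$out_b)
  logits <- outl$out
  probs <- softmax(logits)
  reg <- if (net$has_regression) fc_forward(z, p$reg_W, p$reg_b)$out else NULL
  if (keep_cache) {
    cache$flat_dims <- dmf
    cache$fc <- fc$cache; cache$bnf <- bnf$cache; cache$acf <- acf$cache
    cache$dropf <- dpf$cache
    cache$out <- outl$cache
    cache$z <- z
  }
  list(probs = probs, logits = logits, embedding = z, reg = reg,
       cache = cache, net = net)
}

#' Backward pass through the gesture network
#'
#' Accumulates gradients from any combination of upstream signals: a
#' gradient on the class logits, on the regression output, and/or directly
#' on the 48-d embedding (the path used by the domain discriminator through
#' gradient reversal).
#'
#' @param net An `amode_net`.
#' @param cache Cache from [net_forward()] with `keep_cache = TRUE`.
#' @param dlogits `n x K` gradient on the logits (or `NULL`).
#' @param dreg `n x 1` gradient on the regression output (or `NULL`).
#' @param dz `n x 48` gradient injected at the embedding (or `NULL`).
#' @param need_dx Also compute the gradient with respect to the input.
#' @return List `grads` (named like `net$params`) and `dx` (or `NULL`).
#' @export
net_backward <- function(net, cache, dlogits = NULL, dreg = NULL, dz = NULL,
                         need_dx = FALSE) {
  spec <- net$spec
  p <- net$params
  n <- cache$n
  grads <- lapply(p, function(a) array(0, dim = dim(a) %||% length(a)))
  dzt <- matrix(0, n, spec$bottleneck_units)
  if (!is.null(dlogits)) {
    ob <- fc_backward(dlogits, p$out_W, cache$out)
    grads$out_W <- grads$out_W + ob$dW
    grads$out_b <- grads$out_b + ob$db
    dzt <- dzt + ob$dx
  }
  if (!is.null(dreg)) {
    if (!net$has_regression) stopf("no regression head attached")
    rb <- fc_backward(dreg, p$reg_W, list(x = cache$z))
    grads$reg_W <- grads$reg_W + rb$dW
    grads$reg_b <- grads$reg_b + rb$db
    dzt <- dzt + rb$dx
  }
  if (!is.null(dz)) dzt <- dzt + dz
  if (spec$bottleneck_dropout) dzt <- dropout_backward(dzt, cache$dropf)
  dzt <- leaky_relu_backward(dzt, cache$acf)
  bnb <- bn_backward(dzt, cache$bnf)
  grads$bnf_gamma <- grads$bnf_gamma + bnb$dgamma
  grads$bnf_beta <- grads$bnf_beta + bnb$dbeta
  fb <- fc_backward(bnb$dx, p$fc_W, cache$fc)
  grads$fc_W <- grads$fc_W + fb$dW
  grads$fc_b <- grads$fc_b + fb$db
  # unflatten (n, H*C*Wf) -> (H*n, C, Wf)
  H <- spec$input_height
  dmf <- cache$flat_dims
  da <- array(fb$dx, dim = c(n, H, dmf[2], dmf[3]))
  da <- aperm(da, c(2, 1, 3, 4))
  dim(da) <- c(H * n, dmf[2], dmf[3])
  for (b in 4:1) {
    cc <- cache[[paste0("b", b)]]
    da <- dropout_backward(da, cc$drop)
    da <- maxpool_backward(da, cc$pool)
    da <- leaky_relu_backward(da, cc$act)
    bb <- bn_backward(da, cc$bn)
    grads[[paste0("bn", b, "_gamma")]] <- grads[[paste0("bn", b, "_gamma")]] + bb$dgamma
    grads[[paste0("bn", b, "_beta")]] <- grads[[paste0("bn", b, "_beta")]] + bb$dbeta
    if (b > 1L || need_dx) {
      cb <- conv1d_backward(bb$dx, p[[paste0("conv", b, "_W")]], cc$conv)
      da <- cb$dx
    } else {
      cb <- conv1d_backward(bb$dx, p[[paste0("conv", b, "_W")]], cc$conv)
    }
    grads[[paste0("conv", b, "_W")]] <- grads[[paste0("conv", b, "_W")]] + cb$dW
    grads[[paste0("conv", b, "_b")]] <- grads[[paste0("conv", b, "_b")]] + cb$db
  }
  dx <- NULL
  if (need_dx) {
    dxm <- cb$dx                      # (H*n, 1, W)
    W <- spec$input_width
    dxa <- array(dxm, dim = c(H, n, W))
    dx <- aperm(dxa, c(2, 1, 3))
  }
  list(grads = grads, dx = dx)
}

#' Predict from a trained network
#'
#' Evaluation-mode forward pass (running batch-norm statistics, dropout
#' inert); deterministic.
#'
#' @param object An `amode_net`.
#' @param x Input array `n x height x width`.
#' @param type One of `"prob"`, `"class"`, `"embedding"`, `"angle"`.
#' @param ... Unused.
#' @return Probabilities, 0-based class labels, embeddings, or predicted
#'   (normalized) angles.
#' @export
predict.amode_net <- function(object, x, type = c("prob", "class",
                                                  "embedding", "angle"), ...) {
  type <- match.arg(type)
  fw <- net_forward(object, x, training = FALSE)
  switch(type,
         prob = fw$probs,
         class = max.col(fw$probs, ties.method = "first") - 1L,
         embedding = fw$embedding,
         angle = {
           if (!object$has_regression) stopf("no regression head attached")
           fw$reg[, 1]
         })
}

# ---- Domain discriminator --------------------------------------------------

#' Discriminator specification
#'
#' @param input_dim Embedding dimension consumed (48).
#' @param hidden_units Hidden layer widths, default `c(32, 24, 16)`.
#' @param leaky_slope Hidden activation slope.
#' @return Object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(input_dim = 48L, hidden_units = c(32L, 24L, 16L),
                               leaky_slope = 0.1) {
  if (length(hidden_units) != 3L) stopf("discriminator has exactly three hidden layers")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_units = as.integer(hidden_units),
                 leaky_slope = leaky_slope),
            class = "discriminator_spec")
}

#' Build the domain discriminator
#'
#' Fully connected 48 -> 32 -> 24 -> 16 -> 1 stack with Leaky ReLU hidden
#' activations and a single sigmoid-interpretable domain logit.
#'
#' @param spec A [discriminator_spec].
#' @return Object of class `amode_disc`.
#' @export
build_discriminator <- function(spec = discriminator_spec()) {
  dims <- c(spec$input_dim, spec$hidden_units, 1L)
  params <- list()
  for (i in seq_len(length(dims) - 1L)) {
    params[[paste0("W", i)]] <- he_init(dims[i + 1L], dims[i])
    params[[paste0("b", i)]] <- numeric(dims[i + 1L])
  }
  structure(list(spec = spec, params = params, n_layers = length(dims) - 1L),
            class = "amode_disc")
}

disc_forward <- function(disc, z, keep_cache = FALSE) {
  p <- disc$params
  a <- z
  cache <- list()
  for (i in seq_len(disc$n_layers)) {
    fc <- fc_forward(a, p[[paste0("W", i)]], p[[paste0("b", i)]])
    if (i < disc$n_layers) {
      ac <- leaky_relu_forward(fc$out, disc$spec$leaky_slope)
      a <- ac$out
      if (keep_cache) cache[[i]] <- list(fc = fc$cache, act = ac$cache)
    } else {
      a <- fc$out
      if (keep_cache) cache[[i]] <- list(fc = fc$cache, act = NULL)
    }
  }
  list(logit = a, cache = cache)
}

disc_backward <- function(disc, cache, dlogit) {
  p <- disc$params
  grads <- list()
  da <- dlogit
  for (i in disc$n_layers:1) {
    if (i < disc$n_layers) da <- leaky_relu_backward(da, cache[[i]]$act)
    fb <- fc_backward(da, p[[paste0("W", i)]], cache[[i]]$fc)
    grads[[paste0("W", i)]] <- fb$dW
    grads[[paste0("b", i)]] <- fb$db
    da <- fb$dx
  }
  list(grads = grads, dz = da)
}
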