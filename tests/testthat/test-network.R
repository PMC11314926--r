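# Architecture: parameter census, shapes, heads, discriminator, gradient
# reversal, and numerical correctness of the backward pass.

test_that("parameter census reconciles layer by layer", {
  set.seed(1)
  net <- build_classifier(architecture_spec())
  expect_identical(count_parameters(net), 50582)
  p <- net$params
  convs_bns <- sum(lengths(p[grep("^conv|^bn[1-4]", names(p))]))
  bottleneck <- sum(lengths(p[c("fc_W", "fc_b", "bnf_gamma", "bnf_beta")]))
  output <- sum(lengths(p[c("out_W", "out_b")]))
  expect_equal(convs_bns, 37856)
  expect_equal(bottleneck, 12432)
  expect_equal(output, 294)
  # the flat fully connected layer the compact model replaces
  expect_equal(count_parameters(list(W = matrix(0, 48, 8192),
                                     b = numeric(48))), 393264)
  expect_equal(32 * 8 * 32, 8192)
  expect_equal(count_parameters(list(W = matrix(0, 1, 2), b = 0)), 3)
})

test_that("a spec that cannot reach the flatten dimension is rejected with the achievable one", {
  expect_error(architecture_spec(input_width = 3264L), "reaches a 512")
  expect_error(architecture_spec(input_width = 816L), "pool window")
  expect_error(architecture_spec(input_width = 40L), "narrower")
})

test_that("forward pass produces simplex outputs and a 48-d embedding", {
  spec <- tiny_spec()
  set.seed(2)
  net <- build_classifier(spec)
  x <- array(runif(5 * 8 * 204), dim = c(5, 8, 204))
  fw <- net_forward(net, x, training = TRUE, keep_cache = TRUE)
  expect_equal(dim(fw$probs), c(5L, 6L))
  expect_lt(max(abs(rowSums(fw$probs) - 1)), 1e-6)
  expect_equal(dim(fw$embedding), c(5L, 48L))
  # evaluation mode is deterministic (dropout inert)
  e1 <- net_forward(net, x)$probs
  e2 <- net_forward(net, x)$probs
  expect_identical(e1, e2)
  # batch-norm degeneracy guard
  expect_error(net_forward(net, x[1, , , drop = FALSE], training = TRUE),
               "batch size")
})

test_that("the regression head shares the embedding without touching classification", {
  set.seed(3)
  net <- build_classifier(tiny_spec())
  net2 <- attach_regression_head(net)
  expect_equal(count_parameters(net2) - count_parameters(net), 49)
  net3 <- attach_regression_head(net, multitask = TRUE)
  expect_equal(count_parameters(net3) - count_parameters(net), 51)
  expect_error(attach_regression_head(net2), "already")
  x <- array(runif(4 * 8 * 204), dim = c(4, 8, 204))
  expect_identical(net_forward(net, x)$probs, net_forward(net2, x)$probs)
  expect_equal(dim(net_forward(net2, x)$reg), c(4L, 1L))
})

test_that("discriminator matches its stated depth and arithmetic", {
  set.seed(4)
  disc <- build_discriminator()
  expect_identical(count_parameters(disc),
                   48 * 32 + 32 + 32 * 24 + 24 + 24 * 16 + 16 + 16 * 1 + 1)
  z <- matrix(rnorm(7 * 48), 7, 48)
  out <- usrecal:::disc_forward(disc, z)$logit
  expect_equal(dim(out), c(7L, 1L))
  expect_true(all(is.finite(out)))
  expect_error(discriminator_spec(hidden_units = c(32, 16)), "three")
})

test_that("gradient reversal is the identity forward and a sign flip backward", {
  grl <- gradient_reversal(1)
  x <- matrix(rnorm(6), 2, 3)
  expect_identical(grl$forward(x), x)
  g <- matrix(rnorm(6), 2, 3)
  expect_equal(grl$backward(g), -g)
  expect_equal(gradient_reversal(0)$backward(g), 0 * g)
  expect_error(gradient_reversal(-1), ">= 0")
  # composed through a scalar function f(u) = u^2: the gradient that reaches
  # the input is -lambda * f'(x), with f'(x) taken by finite differences
  f <- function(u) u^2
  lam <- 0.7
  x0 <- 1.3
  h <- 1e-6
  fd <- (f(x0 + h) - f(x0 - h)) / (2 * h)
  expect_equal(gradient_reversal(lam)$backward(fd), -lam * 2 * x0,
               tolerance = 1e-6)
})

test_that("network gradients match central finite differences", {
  spec <- architecture_spec(input_width = 102L, pool_sizes = c(2, 1, 1, 1),
                            kernel_widths = c(51, 3, 2, 2),
                            filters = c(4, 4, 4, 32), dropout_rate = 0)
  set.seed(5)
  net <- attach_regression_head(build_classifier(spec))
  n <- 5L
  x <- array(runif(n * 8 * 102), dim = c(n, 8, 102))
  y <- sample(0:5, n, replace = TRUE)
  yr <- runif(n, -1, 1)
  loss_of <- function(nn, xx = x) {
    fw <- net_forward(nn, xx, training = TRUE, keep_cache = TRUE)
    list(value = cross_entropy(fw$probs, y) + 0.5 * mean((fw$reg[, 1] - yr)^2),
         fw = fw)
  }
  r <- loss_of(net)
  dlog <- usrecal:::cross_entropy_dlogits(r$fw$probs, y)
  dreg <- matrix((r$fw$reg[, 1] - yr) / n, n, 1)
  bw <- net_backward(net, r$fw$cache, dlogits = dlog, dreg = dreg,
                     need_dx = TRUE)
  eps <- 1e-5
  set.seed(6)
  for (nm in names(net$params)) {
    for (i in sample(length(net$params[[nm]]), min(3, length(net$params[[nm]])))) {
      np <- net; np$params[[nm]][i] <- np$params[[nm]][i] + eps
      nm2 <- net; nm2$params[[nm]][i] <- nm2$params[[nm]][i] - eps
      fd <- (loss_of(np)$value - loss_of(nm2)$value) / (2 * eps)
      an <- bw$grads[[nm]][i]
      expect_lt(abs(fd - an) / max(abs(fd) + abs(an), 1e-6), 1e-3)
    }
  }
  # gradient with respect to the input (the path VAT relies on)
  for (probe in list(c(2, 3, 40), c(4, 7, 99))) {
    xp <- x; xp[probe[1], probe[2], probe[3]] <- xp[probe[1], probe[2], probe[3]] + eps
    xm <- x; xm[probe[1], probe[2], probe[3]] <- xm[probe[1], probe[2], probe[3]] - eps
    fd <- (loss_of(net, xp)$value - loss_of(net, xm)$value) / (2 * eps)
    expect_lt(abs(fd - bw$dx[probe[1], probe[2], probe[3]]) /
                max(abs(fd), 1e-6), 1e-3)
  }
})

test_that("discriminator gradients match finite differences", {
  set.seed(7)
  disc <- build_discriminator()
  z <- matrix(rnorm(6 * 48), 6, 48)
  d <- c(0, 0, 0, 1, 1, 1)
  loss_of <- function(dd) {
    usrecal:::bce_from_logits(usrecal:::disc_forward(dd, z)$logit[, 1], d)
  }
  fw <- usrecal:::disc_forward(disc, z, keep_cache = TRUE)
  bw <- usrecal:::disc_backward(disc, fw$cache,
                                matrix(usrecal:::bce_dlogits(fw$logit[, 1], d),
                                       ncol = 1))
  eps <- 1e-6
  for (nm in names(disc$params)) {
    for (i in sample(length(disc$params[[nm]]),
                     min(3, length(disc$params[[nm]])))) {
      dp <- disc; dp$params[[nm]][i] <- dp$params[[nm]][i] + eps
      dm <- disc; dm$params[[nm]][i] <- dm$params[[nm]][i] - eps
      fd <- (loss_of(dp) - loss_of(dm)) / (2 * eps)
      expect_lt(abs(fd - bw$grads[[nm]][i]) / max(abs(fd) + 1e-8, 1e-8), 1e-3)
    }
  }
})
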