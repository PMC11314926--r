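# Loss oracles: closed forms, identities, hand expansions, and the VAT
# power iteration against exhaustive direction search.

test_that("cross-entropy matches closed forms and a hand-expanded smoothed batch", {
  onehot <- diag(6)[c(1, 4), ]
  expect_equal(cross_entropy(onehot, c(0L, 3L)), 0, tolerance = 1e-9)
  expect_equal(cross_entropy(matrix(1 / 6, 3, 6), c(0L, 1L, 5L)), log(6),
               tolerance = 1e-9)
  # alpha = 0.1, 2-class batch, expanded term by term
  p <- matrix(c(0.7, 0.3,
                0.2, 0.8), 2, 2, byrow = TRUE)
  a <- 0.1
  q1 <- c(1 - a + a / 2, a / 2)          # label 0
  q2 <- c(a / 2, 1 - a + a / 2)          # label 1
  by_hand <- -mean(c(sum(q1 * log(p[1, ])), sum(q2 * log(p[2, ]))))
  expect_equal(cross_entropy(p, c(0L, 1L), smoothing = a), by_hand,
               tolerance = 1e-12)
  expect_error(cross_entropy(matrix(0.3, 2, 2), c(0L, 1L)), "simplex")
})

test_that("conditional entropy hits its closed-form anchors", {
  expect_equal(conditional_entropy(diag(6)[1:3, ]), 0, tolerance = 1e-9)
  expect_equal(conditional_entropy(matrix(1 / 6, 5, 6)), log(6),
               tolerance = 1e-12)
  half <- matrix(rep(c(0.5, 0.5, 0, 0, 0, 0), 4), 4, 6, byrow = TRUE)
  expect_equal(conditional_entropy(half), log(2), tolerance = 1e-9)
})

test_that("diversity loss equals its KL form and spans [-log K, 0]", {
  expect_equal(diversity_loss(matrix(1 / 6, 8, 6)), -log(6), tolerance = 1e-12)
  onehot <- matrix(rep(c(1, 0, 0, 0, 0, 0), 3), 3, 6, byrow = TRUE)
  expect_equal(diversity_loss(onehot), 0, tolerance = 1e-9)
  set.seed(8)
  for (i in 1:5) {
    P <- matrix(rexp(10 * 6), 10); P <- P / rowSums(P)
    phat <- colMeans(P)
    kl_form <- sum(phat * log(phat / (1 / 6))) - log(6)
    expect_equal(diversity_loss(P), kl_form, tolerance = 1e-6)
  }
})

test_that("domain loss matches hand-computed binary cross-entropy", {
  set.seed(9)
  disc <- build_discriminator()
  zs <- matrix(rnorm(2 * 48), 2, 48)
  zt <- matrix(rnorm(2 * 48), 2, 48)
  logit <- usrecal:::disc_forward(disc, rbind(zs, zt))$logit[, 1]
  p <- 1 / (1 + exp(-logit))
  by_hand <- -mean(c(log(1 - p[1:2]), log(p[3:4])))
  expect_equal(domain_loss(disc, zs, zt), by_hand, tolerance = 1e-9)
  # chance-level discriminator: ln 2
  flat <- disc
  for (nm in names(flat$params)) flat$params[[nm]][] <- 0
  expect_equal(domain_loss(flat, zs, zt), log(2), tolerance = 1e-12)
  expect_error(domain_loss(disc, zs[0, , drop = FALSE], zt), "empty")
})

test_that("multi-task loss is non-negative with the modified regularizer", {
  expect_equal(multitask_loss(0, 0, c(0, 0))$total, 2 * log(2),
               tolerance = 1e-12)
  set.seed(10)
  draws <- replicate(2000, {
    multitask_loss(rexp(1), rexp(1), rnorm(2, 0, 3))$total
  })
  expect_true(all(draws >= 0))
  # numerical minimization over the variance matches a grid-search oracle
  lc <- 0.8
  grid <- seq(0.01, 20, by = 0.001)
  s2_star <- grid[which.min(lc / (2 * grid) + log1p(grid))]
  root <- stats::uniroot(function(lv) multitask_loss(lc, 0, c(lv, 0))$grad_log_var[1],
                         c(-8, 8))$root
  expect_equal(exp(root), s2_star, tolerance = 1e-2)
})

test_that("VAT is zero at radius zero, non-negative, and near the exhaustive optimum", {
  W <- matrix(c(1.3, -0.7, -0.5, 0.9), 2, 2)
  toy <- list(predict = function(x) usrecal:::softmax(x %*% t(W)))
  x0 <- matrix(c(0.3, -0.2), 1, 2)
  expect_equal(vat_loss(toy, x0, uda_hyperparams(eps_vat = 0))$value, 0)
  hy <- uda_hyperparams(eps_vat = 0.05, n_power = 2)
  set.seed(11)
  v <- vat_loss(toy, x0, hy)
  expect_gte(v$value, 0)
  p0 <- toy$predict(x0)
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  grid_max <- max(vapply(th, function(a) {
    mean(usrecal:::kl_rows(p0, toy$predict(x0 + 0.05 * cbind(cos(a), sin(a)))))
  }, numeric(1)))
  expect_lt(abs(v$value - grid_max) / grid_max, 0.1)
  # network method is non-negative and finite on real inputs
  set.seed(12)
  net <- build_classifier(tiny_spec())
  x <- array(runif(4 * 8 * 204), dim = c(4, 8, 204))
  vn <- vat_loss(net, x, uda_hyperparams(eps_vat = 0.5))
  expect_gte(vn$value, 0)
  expect_true(is.finite(vn$value))
})

test_that("SHOT pseudo-labels recover separable clusters and a worked example", {
  # two well-separated Gaussian clusters with roughly correct probabilities
  set.seed(13)
  z <- rbind(matrix(rnorm(30 * 4, mean = 3), 30, 4),
             matrix(rnorm(30 * 4, mean = -3), 30, 4))
  truth <- rep(0:1, each = 30)
  p <- matrix(0.05, 60, 2)
  p[cbind(1:60, truth + 1)] <- 0.95
  # add noise to the probabilities without changing most argmaxes
  res <- shot_pseudo_labels(z, p)
  expect_equal(res$labels, truth)
  # embeddings exactly at a prototype are assigned to it
  z2 <- rbind(res$prototypes, z)
  p2 <- rbind(matrix(0.5, 2, 2), p)
  res2 <- shot_pseudo_labels(z2, p2)
  expect_equal(res2$labels[1:2], 0:1)
  # 6-sample worked example: weighted means and nearest-prototype by hand
  ze <- matrix(c(1, 0,
                 0.9, 0.1,
                 0, 1,
                 0.1, 0.9,
                 0.5, 0.5,
                 1, 1), 6, 2, byrow = TRUE)
  pe <- matrix(c(0.8, 0.2,
                 0.7, 0.3,
                 0.1, 0.9,
                 0.2, 0.8,
                 0.5, 0.5,
                 0.6, 0.4), 6, 2, byrow = TRUE)
  proto_hand <- rbind(colSums(ze * pe[, 1]) / sum(pe[, 1]),
                      colSums(ze * pe[, 2]) / sum(pe[, 2]))
  cosd <- function(a, b) 1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  lab_hand <- apply(ze, 1, function(v) {
    which.min(c(cosd(v, proto_hand[1, ]), cosd(v, proto_hand[2, ]))) - 1L
  })
  rese <- shot_pseudo_labels(ze, pe)
  expect_equal(rese$prototypes, proto_hand, tolerance = 1e-12)
  expect_equal(rese$labels, as.integer(lab_hand))
  # later rounds recompute prototypes from hard labels
  res_r1 <- shot_pseudo_labels(ze, pe, previous = rese)
  hard_proto <- rbind(colMeans(ze[rese$labels == 0, , drop = FALSE]),
                      colMeans(ze[rese$labels == 1, , drop = FALSE]))
  expect_equal(res_r1$prototypes, hard_proto, tolerance = 1e-12)
})

test_that("SHOT loss composes its three terms with the stated signs", {
  set.seed(14)
  P <- matrix(rexp(4 * 6), 4); P <- P / rowSums(P)
  lab <- c(0L, 1L, 2L, 3L)
  hy <- uda_hyperparams(beta_shot = 0.3)
  sl <- shot_loss(P, lab, hy)
  by_hand <- conditional_entropy(P) + diversity_loss(P) +
    0.3 * cross_entropy(P, lab)
  expect_equal(sl$total, by_hand, tolerance = 1e-12)
  # beta = 0 reduces to the information-maximization loss
  sl0 <- shot_loss(P, lab, uda_hyperparams(beta_shot = 0))
  expect_equal(sl0$total, conditional_entropy(P) + diversity_loss(P),
               tolerance = 1e-12)
  # a confident, balanced, pseudo-label-consistent batch sits near -log K
  Pstar <- diag(6)[rep(1:6, 2), ] * 0.994 + 0.001
  sl_star <- shot_loss(Pstar, rep(0:5, 2), hy)
  expect_lt(abs(sl_star$total - (-log(6))), 0.1)
})

test_that("loss-term logit gradients match finite differences", {
  set.seed(15)
  L <- matrix(rnorm(4 * 6), 4, 6)
  num <- function(fn) {
    g <- L * 0; h <- 1e-6
    for (i in seq_along(L)) {
      lp <- L; lp[i] <- lp[i] + h
      lm <- L; lm[i] <- lm[i] - h
      g[i] <- (fn(usrecal:::softmax(lp)) - fn(usrecal:::softmax(lm))) / (2 * h)
    }
    g
  }
  P <- usrecal:::softmax(L)
  expect_lt(max(abs(num(conditional_entropy) -
                      usrecal:::conditional_entropy_dlogits(P))), 1e-6)
  expect_lt(max(abs(num(diversity_loss) -
                      usrecal:::diversity_dlogits(P))), 1e-6)
  lab <- c(2L, 0L, 5L, 1L)
  expect_lt(max(abs(num(function(p) cross_entropy(p, lab, 0.1)) -
                      usrecal:::cross_entropy_dlogits(P, lab, 0.1))), 1e-6)
})
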