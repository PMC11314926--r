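# Training drivers: determinism, model selection, reduction equivalences,
# SHOT contracts, DIRT-T properties, and the label quarantine.

test_that("source training is deterministic and learns the zero-shift session", {
  study <- fixture_tiny_study()
  src <- session_domain(study, 1, labeled = TRUE)
  r1 <- train_source(src, tiny_spec(), "classify", seed = 7, epochs = 3,
                     batch = 16)
  r2 <- train_source(src, tiny_spec(), "classify", seed = 7, epochs = 3,
                     batch = 16)
  expect_identical(select_model(r1)$params, select_model(r2)$params)
  expect_identical(r1$history$loss, r2$history$loss)
  # separable reduced-scale session reaches a high test accuracy
  big <- fixture_study()
  srcb <- session_domain(big, 1, labeled = TRUE)
  run <- fixture("source_run_reduced", function() {
    train_source(srcb, reduced_spec(), "classify", seed = 101, epochs = 20,
                 batch = 16)
  })
  expect_gte(evaluate_accuracy(select_model(run), srcb), 0.9)
})

test_that("multi-task training fits both heads with positive angle R^2", {
  big <- fixture_study()
  src <- session_domain(big, 1, labeled = TRUE)
  run <- fixture("multitask_run_reduced", function() {
    train_source(src, reduced_spec(), "multitask", seed = 101, epochs = 10,
                 batch = 16)
  })
  net <- select_model(run)
  te <- src$split == "test"
  pa <- predict(net, src$x[te, , , drop = FALSE], type = "angle") *
    src$rotation_amplitude
  expect_gt(r_squared(pa, src$angle[te]), 0)
  expect_gte(evaluate_accuracy(net, src), 0.5)
  expect_length(net$uncertainty, 2)
})

test_that("model selection takes the minimum-loss epoch, earliest on ties", {
  mk <- function(losses) {
    ck <- lapply(seq_along(losses), function(i) list(params = list(w = i),
                                                     bn = NULL,
                                                     uncertainty = NULL))
    usrecal:::new_train_run("toy", 0, data.frame(epoch = seq_along(losses),
                                                 loss = losses),
                            ck, list(params = list(w = 0)), "adam")
  }
  expect_equal(mk(c(3, 2, 1))$selected_epoch, 3L)
  expect_equal(mk(c(3, 1, 2))$selected_epoch, 2L)
  expect_equal(mk(c(2, 1, 1))$selected_epoch, 2L)
  expect_error(usrecal:::select_epoch(numeric(0)), "no completed")
})

test_that("DANN with lambda_d = 0 reproduces source-only training exactly", {
  study <- fixture_tiny_study()
  src <- session_domain(study, 1, labeled = TRUE)
  tgt <- session_domain(study, 2, labeled = FALSE)
  base <- train_source(src, tiny_spec(), "classify", seed = 21, epochs = 3,
                       batch = 16)
  red <- adapt_dann(src, tgt, init = NULL, spec = tiny_spec(),
                    hyper = uda_hyperparams(lambda_d = 0), seed = 21,
                    epochs = 3, batch = 16)
  expect_equal(red$history$loss, base$history$loss, tolerance = 1e-12)
  expect_identical(select_model(red)$params, select_model(base)$params)
})

test_that("VADA with lambda_s = lambda_t = 0 reproduces DANN's loss trace", {
  study <- fixture_tiny_study()
  src <- session_domain(study, 1, labeled = TRUE)
  tgt <- session_domain(study, 2, labeled = FALSE)
  net <- fixture_tiny_source_net()
  dn <- adapt_dann(src, tgt, init = net, seed = 31, epochs = 3, batch = 16)
  vd <- adapt_vada(src, tgt, init = net,
                   hyper = uda_hyperparams(lambda_s = 0, lambda_t = 0),
                   seed = 31, epochs = 3, batch = 16)
  expect_equal(vd$history$loss, dn$history$loss, tolerance = 1e-12)
  expect_equal(vd$history$ly, dn$history$ly, tolerance = 1e-12)
  expect_equal(vd$history$ld, dn$history$ld, tolerance = 1e-12)
})

test_that("VADA logs every term finitely and lowers target conditional entropy", {
  study <- fixture_tiny_study()
  src <- session_domain(study, 1, labeled = TRUE)
  tgt <- session_domain(study, 3, labeled = FALSE)
  net <- fixture_tiny_source_net()
  run <- adapt_vada(src, tgt, init = net,
                    hyper = uda_hyperparams(eps_vat = 0.5), seed = 33,
                    epochs = 5, batch = 16)
  for (cl in c("loss", "ly", "ld", "lct", "lvs", "lvt")) {
    expect_true(all(is.finite(run$history[[cl]])), info = cl)
  }
  xt <- tgt$x[tgt$split == "train", , , drop = FALSE]
  ent0 <- conditional_entropy(predict(net, xt, type = "prob"))
  ent1 <- conditional_entropy(predict(select_model(run), xt, type = "prob"))
  expect_lt(ent1, ent0)
})

test_that("SHOT freezes the classifier head bitwise and its variants differ", {
  study <- fixture_tiny_study()
  tgt <- session_domain(study, 3, labeled = FALSE)
  net <- fixture_tiny_source_net()
  ro <- adapt_shot(net, tgt, "original", seed = 41, epochs = 3, batch = 16)
  expect_identical(select_model(ro)$params$out_W, net$params$out_W)
  expect_identical(select_model(ro)$params$out_b, net$params$out_b)
  ri <- adapt_shot(net, tgt, "independent", seed = 41, epochs = 3, batch = 16)
  expect_identical(select_model(ri)$params$out_W, net$params$out_W)
  expect_false(isTRUE(all.equal(ro$history$loss, ri$history$loss)))
  # feature extractor did move
  expect_false(identical(select_model(ro)$params$fc_W, net$params$fc_W))
})

test_that("SHOT pseudo-labels on a zero-shift target are at least as accurate as raw predictions", {
  study <- generate_study(reduced_protocol(), default_tissue_model(),
                          c(0, 0), seed = 61)
  src <- session_domain(study, 1, labeled = TRUE)
  run <- train_source(src, reduced_spec(), "classify", seed = 62,
                      epochs = 8, batch = 16, smoothing = 0.1)
  net <- select_model(run)
  tgt <- session_domain(study, 2, labeled = FALSE)
  keep <- tgt$split == "train"
  xt <- tgt$x[keep, , , drop = FALSE]
  fw <- net_forward(net, xt)
  pl <- shot_pseudo_labels(fw$embedding, fw$probs)
  truth <- quarantined_labels(tgt)$gesture[keep]
  acc_pred <- accuracy(max.col(fw$probs, ties.method = "first") - 1L, truth)
  acc_pseudo <- accuracy(pl$labels, truth)
  expect_gte(acc_pseudo, acc_pred)
})

test_that("DIRT-T descends the target cluster loss and the leash restrains drift", {
  study <- fixture_tiny_study()
  tgt <- session_domain(study, 3, labeled = FALSE)
  net <- fixture_tiny_source_net()
  hy <- uda_hyperparams(refine_interval = 40, refine_rounds = 2, eps_vat = 0)
  run <- refine_dirt_t(net, tgt, hyper = hy, seed = 43, batch = 16)
  xt <- tgt$x[tgt$split == "train", , , drop = FALSE]
  ent_before <- conditional_entropy(predict(net, xt, type = "prob"))
  ent_after <- conditional_entropy(predict(select_model(run), xt, type = "prob"))
  expect_lte(ent_after, ent_before)
  expect_error(refine_dirt_t(net, tgt,
                             hyper = uda_hyperparams(refine_interval = 0)),
               "positive")
  # a large KL leash keeps the student closer to the teacher than no leash
  tv_of <- function(beta) {
    h <- uda_hyperparams(beta_t = beta, refine_interval = 40,
                         refine_rounds = 1, eps_vat = 0)
    r <- refine_dirt_t(net, tgt, hyper = h, seed = 47, batch = 16, lr = 1e-4)
    ps <- predict(select_model(r), xt, type = "prob")
    pt <- predict(r$teacher, xt, type = "prob")
    mean(0.5 * rowSums(abs(ps - pt)))
  }
  expect_lt(tv_of(1e6), tv_of(0))
})

test_that("auxiliary-regression DANN needs a head and reduces to DANN at lambda_r = 0", {
  study <- fixture_tiny_study()
  src <- session_domain(study, 1, labeled = TRUE)
  tgt <- session_domain(study, 2, labeled = FALSE)
  net <- fixture_tiny_source_net()
  expect_error(adapt_dann_aux(src, tgt, init = net, labels_mode = "pca_ss",
                              seed = 51, epochs = 1),
               "regression head")
  reg_net <- fixture("tiny_multitask_net", function() {
    select_model(train_source(src, tiny_spec(), "multitask", seed = 7,
                              epochs = 4, batch = 16))
  })
  hy0 <- uda_hyperparams(lambda_r_gt = 0)
  ga <- adapt_dann_aux(src, tgt, init = reg_net, labels_mode = "ground_truth",
                       hyper = hy0, seed = 51, epochs = 2, batch = 16,
                       target_angles = quarantined_labels(tgt)$angle)
  dn <- adapt_dann(src, tgt, init = reg_net, seed = 51, epochs = 2, batch = 16)
  expect_equal(ga$history$loss, dn$history$loss, tolerance = 1e-12)
  # ground-truth mode: target regression loss decreases over training
  gt <- adapt_dann_aux(src, tgt, init = reg_net, labels_mode = "ground_truth",
                       seed = 52, epochs = 6, batch = 16,
                       target_angles = quarantined_labels(tgt)$angle)
  expect_lt(min(gt$history$lrt), gt$history$lrt[1] + 1e-9)
  expect_error(adapt_dann_aux(src, tgt, init = reg_net,
                              labels_mode = "ground_truth", seed = 1,
                              epochs = 1), "target_angles")
})

test_that("PCA pseudo-angles are deterministic, span [-1, 1], and track the simulator angle", {
  study <- fixture_study()
  s1 <- study$sessions[[1]]
  idx <- s1$gesture == 1L
  x <- s1$envelope[idx, , , drop = FALSE]
  pa1 <- pca_pseudo_angle(x)
  pa2 <- pca_pseudo_angle(x)
  expect_identical(pa1, pa2)
  expect_equal(range(pa1), c(-1, 1))
  expect_gte(abs(stats::cor(pa1, s1$angle[idx])), 0.7)
  expect_error(pca_pseudo_angle(matrix(1, 5, 4)), "rank deficient")
})

test_that("adaptation code never unseals quarantined labels", {
  # static audit: no adaptation routine references the quarantine accessor
  # or the private vault of the target domain
  for (fn in c("adapt_dann", "adapt_vada", "adapt_shot", "refine_dirt_t",
               "adapt_dann_aux", "adapt_adversarial")) {
    body_txt <- paste(deparse(body(getFromNamespace(fn, "usrecal"))),
                      collapse = "\n")
    expect_false(grepl("quarantined_labels|\\.vault", body_txt), label = fn)
  }
  # runtime audit: pca_ss adaptation works on a target whose vault is empty
  study <- fixture_tiny_study()
  src <- session_domain(study, 1, labeled = TRUE)
  s2 <- study$sessions[[2]]
  blind <- unlabeled_domain(s2$envelope, rep(0L, length(s2$gesture)),
                            rep(0, length(s2$angle)), s2$split,
                            rotation_amplitude = 80)
  reg_net <- fixture("tiny_multitask_net", function() {
    select_model(train_source(src, tiny_spec(), "multitask", seed = 7,
                              epochs = 4, batch = 16))
  })
  run <- adapt_dann_aux(src, blind, init = reg_net, labels_mode = "pca_ss",
                        seed = 53, epochs = 1, batch = 16)
  expect_s3_class(run, "train_run")
})
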