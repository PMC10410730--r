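test_that("augment is deterministic, shape-preserving, and has identity", {
  g <- tiny_glyphs(n_classes = 2L, image_size = 12L, n_per_class = 2L)
  x <- g$X[1, ]
  cfg <- augment_config()
  a1 <- augment(x, cfg, seed = 33L)
  expect_identical(a1, augment(x, cfg, seed = 33L))
  expect_length(a1, length(x))
  # collapsed ranges + p_apply = 1 give the identity bitwise
  id_cfg <- augment_config(occlusion = c(0, 0), rotation = c(0, 0),
                           scale = c(1, 1), p_apply = 1)
  expect_identical(augment(x, id_cfg, seed = 5L), x)
  # collapsed occlusion range: fraction of zeroed pixels within tolerance
  occ <- augment_config(occlusion = c(0.3, 0.3), rotation = c(0, 0),
                        scale = c(1, 1), p_apply = 1)
  ones <- rep(1, 16 * 16)
  fr <- mean(augment(ones, occ, seed = 2L) == 0)
  expect_lt(abs(fr - 0.3), 0.05)
  expect_error(augment_config(occlusion = c(0.5, 0.2)), class = "dm_config_error")
  expect_error(augment_config(scale = c(-1, 1)), class = "dm_config_error")
})

test_that("contrastive_loss matches hand values and limits", {
  # two pairs, positives identical, negatives orthogonal: -log(e/(e+2))
  Z <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  expect_equal(contrastive_loss(Z, tau = 1), -log(exp(1) / (exp(1) + 2)),
               tolerance = 1e-12)
  # all-equal similarities: the uniform limit log(2N - 1), exactly
  expect_equal(contrastive_loss(diag(4), tau = 1e8), log(3), tolerance = 1e-6)
  expect_gte(contrastive_loss(matrix(rnorm(12), 4, 3), tau = 0.5), 0)
  # invariant under permutation of pair order
  set.seed(3)
  Z6 <- matrix(rnorm(18), 6, 3)
  perm <- c(2, 3, 1)
  Zp <- Z6[c(perm, perm + 3), ]
  expect_equal(contrastive_loss(Zp, 0.7), contrastive_loss(Z6, 0.7),
               tolerance = 1e-12)
  expect_error(contrastive_loss(Z[1:2, , drop = FALSE]),
               class = "dm_insufficient_batch")
})

test_that("NT-Xent analytic gradient matches central differences", {
  set.seed(4)
  Z <- matrix(rnorm(24), 8, 3)
  g <- dendromod:::nt_xent(Z, 0.5, grad = TRUE)
  for (idx in list(c(1, 1), c(4, 2), c(8, 3))) {
    e <- matrix(0, 8, 3); e[idx[1], idx[2]] <- 1e-6
    num <- (dendromod:::nt_xent(Z + e, 0.5)$loss -
              dendromod:::nt_xent(Z - e, 0.5)$loss) / 2e-6
    expect_equal(g$dZ[idx[1], idx[2]], num, tolerance = 1e-6)
  }
})

test_that("stacking is layer-local: earlier layers stay bit-identical", {
  d <- to_one_vs_all(tiny_glyphs(n_classes = 4L, image_size = 8L), seed = 3L)
  cfg <- tmcl_config(width = 12L, epochs_cl = 2L, epochs_gain = 5L,
                     batch_pairs = 8L, proj_sizes = c(10L, 6L), seed = 2L)
  r2 <- stack_layers(d, n_layers = 2L, cfg = cfg, mode = "tmcl")
  r3 <- {
    # retrain 3 layers with the same config: layers 1-2 must be identical
    stack_layers(d, n_layers = 3L, cfg = cfg, mode = "tmcl")
  }
  expect_identical(param_fingerprint(r2$stack$layers[[1]]),
                   param_fingerprint(r3$stack$layers[[1]]))
  expect_identical(param_fingerprint(r2$stack$layers[[2]]),
                   param_fingerprint(r3$stack$layers[[2]]))
  expect_equal(nrow(r3$accuracy), 3L)
  # determinism of the whole procedure
  r3b <- stack_layers(d, n_layers = 3L, cfg = cfg, mode = "tmcl")
  expect_identical(param_fingerprint(r3$stack), param_fingerprint(r3b$stack))
})

test_that("gain phase trains above chance with a shared output unit", {
  d <- to_one_vs_all(tiny_glyphs(n_classes = 3L, image_size = 8L,
                                 n_per_class = 30L), seed = 9L)
  cfg <- tmcl_config(width = 24L, epochs_cl = 4L, epochs_gain = 50L,
                     batch_pairs = 12L, proj_sizes = c(12L, 8L), seed = 4L)
  r <- stack_layers(d, n_layers = 1L, cfg = cfg, mode = "tmcl")
  expect_gt(r$accuracy$mean_accuracy[1], 0.6)
  # one output unit per layer, shared across all tasks by construction
  expect_length(r$stack$ou[[1]]$w, 24L)
})

test_that("contrastive training lowers the loss on a held-out batch", {
  d <- to_one_vs_all(tiny_glyphs(n_classes = 3L, image_size = 8L,
                                 n_per_class = 30L), seed = 13L)
  cfg <- tmcl_config(width = 16L, epochs_cl = 10L, batch_pairs = 12L,
                     proj_sizes = c(12L, 8L), seed = 6L)
  # held-out probe: distinct augmented views of the same samples, compared
  # at the layer the trainer started from versus the layer it learned
  make_views <- function(W, xs) {
    idx <- d$test_idx[1:12]
    V1 <- sapply(idx, function(i) augment(d$X[i, ], cfg$augment, seed = 1000L + i))
    V2 <- sapply(idx, function(i) augment(d$X[i, ], cfg$augment, seed = 5000L + i))
    t(pmax(W %*% cbind(V1, V2) - xs, 0))
  }
  # identical initialization to the one train_layer_cl draws internally
  sd0 <- derive_seed(cfg$seed, "cl_layer1")
  W0 <- with_seed(sd0, matrix(rnorm(16 * ncol(d$X), sd = sqrt(2 / ncol(d$X))),
                              16, ncol(d$X)))
  trained <- dendromod:::train_layer_cl(
    dendromod:::new_tmcl_stack(ncol(d$X), names(d$labels)), d, 1L, cfg)
  l0 <- contrastive_loss(make_views(W0, 0), cfg$tau)
  l1 <- contrastive_loss(make_views(trained$W, trained$x_shift), cfg$tau)
  expect_lt(l1, l0)
})

test_that("mode and subset contracts are enforced", {
  d <- to_one_vs_all(tiny_glyphs(n_classes = 3L, image_size = 8L), seed = 1L)
  cfg <- tmcl_config(width = 8L, epochs_cl = 1L, epochs_gain = 2L,
                     batch_pairs = 4L, proj_sizes = c(6L, 4L), seed = 1L)
  expect_error(stack_layers(d, n_layers = 1L, cfg = cfg, mode = "bogus"))
  # rp mode trains no contrastive weights but still reports accuracies
  r <- stack_layers(d, n_layers = 2L, cfg = cfg, mode = "rp")
  expect_equal(r$stack$layers[[2]]$trained_mode, "rp")
  r2 <- stack_layers(d, n_layers = 2L, cfg = cfg, mode = "rp_on_tmcl")
  expect_equal(vapply(r2$stack$layers, `[[`, "", "trained_mode"),
               c("tmcl", "rp"))
})
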