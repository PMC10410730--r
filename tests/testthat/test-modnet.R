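test_that("forward_modulated evaluates the modulated rectifier exactly", {
  l <- modulated_layer(2L, 2L, tasks = "t")
  l$W <- diag(2); l$x_shift <- 0; l$b <- c(0, 0); l$gains$t <- c(1, 1)
  expect_equal(forward_modulated(l, "t", c(1, -2)), c(1, 0))
  # zero gain passes only the bias through the rectifier
  l$gains$t <- c(0, 0); l$b <- c(-1, 2)
  expect_equal(forward_modulated(l, "t", c(5, -3)), c(0, 2))
  # full hand evaluation: Wx=(3,1) -> shift -> gain -> bias -> relu
  l$W <- matrix(c(1, 1, 1, -1), 2, 2, byrow = TRUE)
  l$x_shift <- c(0.5, 0.5); l$gains$t <- c(2, 1); l$b <- c(0, -0.5)
  expect_equal(forward_modulated(l, "t", c(2, 1)), c(5, 0))
  expect_error(forward_modulated(l, "nope", c(1, 1)), class = "dm_task_unknown")
  expect_error(forward_modulated(l, "t", c(1, 2, 3)), class = "dm_shape_error")
})

test_that("identity reductions and the reparameterization identity hold", {
  # g = 1, x_shift = 0, b = 0 reduces to a plain rectified linear layer
  l <- modulated_layer(3L, 4L, tasks = "t", seed = 11L)
  l$x_shift <- 0; l$b <- rep(0, 4)
  X <- matrix(rnorm(30), 3)
  expect_equal(forward_modulated(l, "t", X), pmax(l$W %*% X, 0))
  # sigma(g(Wx - xs) + b) == sigma(g Wx + (b - g xs)) for 1000 random inputs
  set.seed(2)
  g <- runif(4, 0.5, 2); xs <- rnorm(4); b <- rnorm(4)
  W <- matrix(rnorm(12), 4, 3)
  X <- matrix(rnorm(3000), 3)
  lhs <- pmax(g * (W %*% X - xs) + b, 0)
  rhs <- pmax(g * (W %*% X) + (b - g * xs), 0)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("multitask training learns and respects degenerate-task errors", {
  d <- tiny_dataset(n_tasks = 4L, n_samples = 160L, seed = 5L)
  st <- tiny_stack(d, hidden = c(20L))
  res <- train_multitask(st, d, quick_cfg(epochs = 60L))
  acc <- res$accuracy$accuracy[res$accuracy$split == "test"]
  expect_gt(mean(acc), 0.6)   # well above balanced chance
  # zero learning rate leaves the stack (and its accuracy) unchanged
  res0 <- train_multitask(tiny_stack(d, hidden = c(20L)), d,
                          quick_cfg(epochs = 3L, lr = 0))
  expect_identical(param_fingerprint(res0$stack$layers),
                   param_fingerprint(tiny_stack(d, hidden = c(20L))$layers))
  # a task with one class is rejected
  bad <- d
  bad$labels$task01[] <- 0L; bad$labels$task01[bad$test_idx] <- rep(c(0L, 1L), length.out = length(bad$test_idx))
  expect_error(train_multitask(tiny_stack(bad), bad, quick_cfg(epochs = 1L)),
               class = "dm_degenerate_task")
})

test_that("the freezing contract is bitwise", {
  d <- tiny_dataset(n_tasks = 4L, seed = 6L)
  st <- tiny_stack(d, hidden = c(12L, 12L))
  pre <- train_multitask(st, d, quick_cfg(epochs = 15L))$stack
  before <- lapply(pre$layers, function(l) list(W = l$W, xs = l$x_shift, b = l$b))
  d2 <- tiny_dataset(n_tasks = 6L, seed = 99L)
  d2$labels <- d2$labels[5:6]
  names(d2$labels) <- c("new1", "new2")
  cfg <- quick_cfg(epochs = 15L, frozen = c("W", "x_shift", "b"))
  post <- train_transfer(pre, d2, cfg)
  after <- lapply(post$stack$layers, function(l) list(W = l$W, xs = l$x_shift, b = l$b))
  expect_identical(param_fingerprint(before), param_fingerprint(after))
  expect_identical(post$stack$head$w, pre$head$w)
  # new tasks actually gained trained parameters
  expect_false(all(post$stack$layers[[1]]$gains$new1 == 1))
  # unfreezing shared parameters in transfer mode is a config error
  expect_error(train_transfer(pre, d2, quick_cfg(epochs = 1L, frozen = "W")),
               class = "dm_config_error")
  # zero transfer tasks: empty table, nothing changes
  empty <- d2; empty$labels <- list()
  out <- train_transfer(pre, empty, cfg)
  expect_equal(nrow(out$accuracy), 0L)
  expect_identical(param_fingerprint(out$stack), param_fingerprint(pre))
})

test_that("readout baseline trains per-task rows on a shared trunk", {
  d <- tiny_dataset(n_tasks = 3L, seed = 12L)
  res <- readout_baseline(list(input_dim = 2L, hidden_sizes = c(16L), seed = 4L),
                          d, quick_cfg(epochs = 40L))
  expect_gt(mean(res$accuracy$accuracy[res$accuracy$split == "test"]), 0.6)
  # frozen trunk + new tasks: only readout rows change
  pre <- res$stack
  d2 <- tiny_dataset(n_tasks = 5L, seed = 31L)
  d2$labels <- d2$labels[4:5]; names(d2$labels) <- c("nt1", "nt2")
  post <- train_transfer(pre, d2, quick_cfg(epochs = 10L,
                                            frozen = c("W", "x_shift", "b", "gains")))
  expect_identical(param_fingerprint(lapply(pre$layers, `[[`, "W")),
                   param_fingerprint(lapply(post$stack$layers, `[[`, "W")))
  expect_identical(post$stack$head$w[names(d$labels)],
                   pre$head$w[names(d$labels)])
  expect_false(is.null(post$stack$head$w$nt1))
})

test_that("decision boundary normals match finite differences and lie in row(W1)", {
  d <- tiny_dataset(n_tasks = 2L, seed = 3L)
  st <- train_multitask(tiny_stack(d, hidden = c(10L, 8L)), d,
                        quick_cfg(epochs = 20L))$stack
  for (i in 1:5) {
    x <- with_seed(i, runif(2, -0.9, 0.9))
    nrm <- decision_boundary_normals(st, "task01", x)
    fd <- vapply(1:2, function(j) {
      e <- c(0, 0); e[j] <- 1e-5
      fa <- dendromod:::stack_forward(st, "task01", matrix(x + e))$a
      fb <- dendromod:::stack_forward(st, "task01", matrix(x - e))$a
      (fa - fb) / 2e-5
    }, numeric(1))
    expect_lt(max(abs(nrm - fd)), 1e-5)
    # residual of projection onto the row space of W1
    W1 <- st$layers[[1]]$W
    qrW <- qr(t(W1))
    Q <- qr.Q(qrW)[, seq_len(qrW$rank), drop = FALSE]
    resid <- nrm - Q %*% crossprod(Q, nrm)
    expect_lt(sqrt(sum(resid^2)), 1e-8)
  }
  # all first-layer units inactive -> zero normal
  st0 <- tiny_stack(d, hidden = c(6L))
  st0$layers[[1]]$b <- rep(-100, 6L)
  expect_equal(decision_boundary_normals(st0, "task01", c(0.1, 0.1)),
               c(0, 0))
  # a unit exactly on its kink is flagged
  stk <- tiny_stack(d, hidden = c(6L))
  stk$layers[[1]]$W[1, ] <- c(1, 0); stk$layers[[1]]$b <- rep(0, 6L)
  stk$layers[[1]]$W[-1, ] <- 0.5
  expect_error(decision_boundary_normals(stk, "task01", c(0, 1)),
               class = "dm_nondifferentiable")
})

test_that("training is bit-reproducible given the seed", {
  d <- tiny_dataset(n_tasks = 3L, seed = 21L)
  r1 <- train_multitask(tiny_stack(d), d, quick_cfg(epochs = 8L))
  r2 <- train_multitask(tiny_stack(d), d, quick_cfg(epochs = 8L))
  expect_identical(param_fingerprint(r1$stack), param_fingerprint(r2$stack))
  expect_identical(r1$accuracy, r2$accuracy)
})

test_that("stack serialization round-trips all parameters", {
  d <- tiny_dataset(n_tasks = 2L, seed = 4L)
  st <- train_multitask(tiny_stack(d, hidden = c(6L)), d,
                        quick_cfg(epochs = 5L))$stack
  f <- withr::local_tempfile(fileext = ".json")
  save_stack(st, f)
  st2 <- load_stack(f)
  x <- c(0.3, -0.4)
  expect_equal(dendromod:::stack_forward(st2, "task01", matrix(x))$a,
               dendromod:::stack_forward(st, "task01", matrix(x))$a,
               tolerance = 1e-12)
  expect_equal(st2$layers[[1]]$W, st$layers[[1]]$W, tolerance = 1e-12)
})
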