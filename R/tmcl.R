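#' Augmentation configuration
#'
#' Ranges for the stochastic input augmentations used by the contrastive
#' phase: occlusion (fraction of pixels zeroed by a random rectangle),
#' rotation (degrees), and isotropic scaling, composed independently with
#' probability `p_apply` each. All ranges include the identity, so the
#' identity augmentation stays reachable.
#'
#' @param occlusion Length-2 range of occluded pixel fraction in `[0, 1)`.
#' @param rotation Length-2 range of rotation angles, degrees.
#' @param scale Length-2 range of scale factors (> 0).
#' @param p_apply Probability that each transform is applied.
#' @return An `augment_config` list.
#' @export
augment_config <- function(occlusion = c(0, 0.25), rotation = c(-15, 15),
                           scale = c(0.85, 1.15), p_apply = 0.7) {
  chk <- function(r, nm, lo = -Inf, hi = Inf) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] ||
        r[1] < lo || r[2] > hi)
      dm_stop("dm_config_error", "degenerate %s range", nm)
  }
  chk(occlusion, "occlusion", 0, 1 - 1e-9)
  chk(rotation, "rotation")
  chk(scale, "scale", 1e-6)
  if (p_apply < 0 || p_apply > 1)
    dm_stop("dm_config_error", "p_apply must be in [0, 1]")
  structure(list(occlusion = occlusion, rotation = rotation, scale = scale,
                 p_apply = p_apply), class = "augment_config")
}

#' Apply a random augmentation to a square image
#'
#' Deterministic given `seed`. Rotation and scaling use nearest-neighbor
#' inverse mapping (zero padding); occlusion zeroes a random axis-aligned
#' rectangle covering approximately the drawn fraction of pixels.
#'
#' @param x Image as a numeric vector of length `s^2` (row-major) or an
#'   `s x s` matrix.
#' @param cfg An [augment_config()].
#' @param seed Integer seed.
#' @return Augmented image, same shape as the input.
#' @export
augment <- function(x, cfg, seed) {
  stopifnot(inherits(cfg, "augment_config"))
  was_vec <- is.null(dim(x))
  s <- if (was_vec) as.integer(round(sqrt(length(x)))) else nrow(x)
  if (was_vec && s * s != length(x))
    dm_stop("dm_shape_error", "vector image must have square length")
  img <- if (was_vec) matrix(x, s, s, byrow = TRUE) else x
  out <- with_seed(seed, {
    do_rot <- runif(1) < cfg$p_apply
    do_scl <- runif(1) < cfg$p_apply
    do_occ <- runif(1) < cfg$p_apply
    theta <- if (do_rot) runif(1, cfg$rotation[1], cfg$rotation[2]) * pi / 180 else 0
    fac <- if (do_scl) runif(1, cfg$scale[1], cfg$scale[2]) else 1
    res <- img
    if (theta != 0 || fac != 1) {
      ctr <- (s + 1) / 2
      co <- cos(-theta) / fac; si <- sin(-theta) / fac
      rr <- matrix(rep(seq_len(s), s), s, s)       # row index per cell
      cc <- t(rr)
      dr <- rr - ctr; dc <- cc - ctr
      sr <- round(ctr + co * dr - si * dc)
      sc <- round(ctr + si * dr + co * dc)
      ok <- sr >= 1 & sr <= s & sc >= 1 & sc <= s
      res <- matrix(0, s, s)
      res[ok] <- img[cbind(sr[ok], sc[ok])]
    }
    if (do_occ) {
      fr <- runif(1, cfg$occlusion[1], cfg$occlusion[2])
      npx <- max(0L, round(fr * s * s))
      if (npx > 0) {
        w0 <- sample.int(s, 1)
        h0 <- min(s, max(1L, round(npx / w0)))
        w0 <- min(s, max(1L, round(npx / h0)))
        r0 <- sample.int(s - h0 + 1L, 1)
        c0 <- sample.int(s - w0 + 1L, 1)
        res[r0:(r0 + h0 - 1L), c0:(c0 + w0 - 1L)] <- 0
      }
    }
    res
  })
  if (was_vec) as.vector(t(out)) else out
}

# NT-Xent loss with cosine similarity, rows of Z paired (i, i + N);
# returns the loss and, optionally, the gradient with respect to Z
nt_xent <- function(Z, tau, grad = FALSE) {
  n2 <- nrow(Z)
  if (n2 %% 2L != 0L || n2 < 4L)
    dm_stop("dm_insufficient_batch", "need >= 2 pairs (got %d rows)", n2)
  N <- n2 %/% 2L
  nrm <- sqrt(rowSums(Z^2))
  nrm[nrm == 0] <- 1e-12
  Zh <- Z / nrm
  S <- tcrossprod(Zh) / tau
  diag(S) <- -Inf                       # exclude self-similarity
  pos <- c(seq_len(N) + N, seq_len(N))  # index of each row's positive
  m <- apply(S, 1, max)
  E <- exp(S - m)
  rs <- rowSums(E)
  loss <- mean(-(S[cbind(seq_len(n2), pos)] - m) + log(rs))
  if (!grad) return(list(loss = loss))
  P <- E / rs
  M <- P / n2
  M[cbind(seq_len(n2), pos)] <- M[cbind(seq_len(n2), pos)] - 1 / n2
  dZh <- (M + t(M)) %*% Zh / tau
  dZ <- (dZh - Zh * rowSums(dZh * Zh)) / nrm
  list(loss = loss, dZ = dZ)
}

#' Normalized-temperature cross-entropy contrastive loss
#'
#' Rows of `Z` are L2-normalized internally; row `i` and row `i + N` are a
#' positive pair. The loss averages, over all `2N` anchors, the
#' cross-entropy of picking the positive among the `2N - 1` candidates
#' under cosine similarity at temperature `tau`.
#'
#' @param Z Numeric matrix (`2N x d`) of projected representations.
#' @param tau Positive temperature.
#' @return Non-negative scalar.
#' @export
contrastive_loss <- function(Z, tau = 0.5) {
  stopifnot(tau > 0)
  nt_xent(Z, tau)$loss
}

#' TMCL training configuration
#'
#' @param width Hidden units per layer.
#' @param tau NT-Xent temperature.
#' @param proj_sizes Two-layer projection head sizes (used only during the
#'   contrastive phase, discarded afterwards).
#' @param batch_pairs Positive pairs per contrastive batch.
#' @param epochs_cl Contrastive passes over the training split per layer.
#' @param lr_cl Contrastive learning rate.
#' @param epochs_gain,lr_gain,batch_gain Supervised gain-phase settings.
#' @param augment An [augment_config()].
#' @param seed Integer seed.
#' @return A `tmcl_config` list.
#' @export
tmcl_config <- function(width = 48L, tau = 0.5, proj_sizes = c(32L, 16L),
                        batch_pairs = 32L, epochs_cl = 4L, lr_cl = 0.05,
                        epochs_gain = 150L, lr_gain = 0.1, batch_gain = 32L,
                        augment = augment_config(), seed = 1L) {
  stopifnot(tau > 0, batch_pairs >= 2, length(proj_sizes) == 2)
  structure(list(width = as.integer(width), tau = tau,
                 proj_sizes = as.integer(proj_sizes),
                 batch_pairs = as.integer(batch_pairs),
                 epochs_cl = as.integer(epochs_cl), lr_cl = lr_cl,
                 epochs_gain = as.integer(epochs_gain), lr_gain = lr_gain,
                 batch_gain = as.integer(batch_gain),
                 augment = augment, seed = as.integer(seed)),
            class = "tmcl_config")
}

new_tmcl_stack <- function(input_dim, tasks) {
  structure(list(input_dim = as.integer(input_dim), tasks = tasks,
                 layers = list(), ou = list()),
            class = "tmcl_stack")
}

#' @export
print.tmcl_stack <- function(x, ...) {
  cat(sprintf("<tmcl_stack> %d -> %s, %d task(s)\n", x$input_dim,
              paste(vapply(x$layers, function(l) nrow(l$W), integer(1)),
                    collapse = " -> "),
              length(x$tasks)))
  invisible(x)
}

# forward through layers 1..l_max with per-column task modulations;
# task_cols: character vector (one task id per column) or NULL for no
# modulation (all gains 1)
tmcl_forward_below <- function(stack, X, l_max, task_cols = NULL) {
  H <- X
  if (l_max < 1) return(H)
  for (l in seq_len(l_max)) {
    layer <- stack$layers[[l]]
    U <- layer$W %*% H - layer$x_shift
    if (!is.null(task_cols)) {
      G <- vapply(task_cols, function(t) layer$gains[[t]], numeric(nrow(layer$W)))
      U <- G * U
    }
    H <- pmax(U, 0)
  }
  H
}

# contrastive phase for layer l: learns W_l, x_shift_l through a 2-layer
# projection head; positives combine input augmentations with (for
# mode "tmcl" and l >= 2) different task modulations in the layers below
train_layer_cl <- function(stack, data, l, cfg, task_subset = NULL) {
  if (length(stack$layers) != l - 1L)
    dm_stop("dm_config_error", "layers below %d must be trained first", l)
  tasks <- if (is.null(task_subset)) stack$tasks else task_subset
  use_mods <- l >= 2L
  if (use_mods && length(tasks) == 0L)
    dm_stop("dm_config_error", "task-similarity requires registered tasks")
  k_in <- if (l == 1L) stack$input_dim else nrow(stack$layers[[l - 1L]]$W)
  k <- cfg$width
  sd0 <- derive_seed(cfg$seed, paste0("cl_layer", l))
  W <- with_seed(sd0, matrix(rnorm(k * k_in, sd = sqrt(2 / k_in)), k, k_in))
  xs <- 0
  p1 <- cfg$proj_sizes[1]; p2 <- cfg$proj_sizes[2]
  P1 <- with_seed(derive_seed(sd0, "P1"), matrix(rnorm(p1 * k, sd = sqrt(2 / k)), p1, k))
  b1 <- rep(0, p1)
  P2 <- with_seed(derive_seed(sd0, "P2"), matrix(rnorm(p2 * p1, sd = sqrt(2 / p1)), p2, p1))
  b2 <- rep(0, p2)
  Xtr <- data$X[data$train_idx, , drop = FALSE]
  n_tr <- nrow(Xtr)
  N <- cfg$batch_pairs
  n_steps <- cfg$epochs_cl * max(1L, n_tr %/% N)
  vel <- new.env(parent = emptyenv())
  upd <- function(key, val, grad) {
    gn <- sqrt(sum(grad^2)); if (gn > 2) grad <- grad * (2 / gn)
    v <- (vel[[key]] %||% 0) * 0.9 - cfg$lr_cl * grad
    vel[[key]] <- v
    val + v
  }
  for (step in seq_len(n_steps)) {
    st_seed <- derive_seed(sd0, paste0("step", step))
    batch <- with_seed(st_seed, sample.int(n_tr, N, replace = n_tr < N))
    views <- matrix(0, ncol(Xtr), 2L * N)
    task_cols <- NULL
    if (use_mods) {
      task_cols <- character(2L * N)
      for (i in seq_len(N)) {
        tt <- with_seed(derive_seed(st_seed, paste0("task", i)), {
          if (length(tasks) >= 2) sample(tasks, 2) else rep(tasks, 2)
        })
        task_cols[i] <- tt[1]; task_cols[N + i] <- tt[2]
      }
    }
    for (i in seq_len(N)) {
      xi <- Xtr[batch[i], ]
      views[, i] <- augment(xi, cfg$augment, derive_seed(st_seed, paste0("a", i)))
      views[, N + i] <- augment(xi, cfg$augment, derive_seed(st_seed, paste0("b", i)))
    }
    Hb <- tmcl_forward_below(stack, views, l - 1L, task_cols)
    U <- W %*% Hb - xs
    Hl <- pmax(U, 0)
    Q <- pmax(P1 %*% Hl + b1, 0)
    Z <- P2 %*% Q + b2                    # p2 x 2N
    res <- nt_xent(t(Z), cfg$tau, grad = TRUE)
    dZ <- t(res$dZ)                       # p2 x 2N
    dQ <- crossprod(P2, dZ) * (Q > 0)
    dHl <- crossprod(P1, dQ) * (U > 0)
    P2 <- upd("P2", P2, tcrossprod(dZ, Q)); b2 <- upd("b2", b2, rowSums(dZ))
    P1 <- upd("P1", P1, tcrossprod(dQ, Hl)); b1 <- upd("b1", b1, rowSums(dQ))
    W <- upd("W", W, tcrossprod(dHl, Hb))
    xs <- upd("xs", xs, -sum(dHl))
  }
  list(W = W, x_shift = xs)
}

# supervised gain phase for layer l: learns per-task gains of layer l and
# one task-independent output unit (shared across tasks) by sigmoid BCE
train_layer_gains <- function(stack, data, l, cfg) {
  layer <- stack$layers[[l]]
  if (is.null(layer)) dm_stop("dm_config_error", "layer %d not built", l)
  tasks <- names(data$labels)
  k <- nrow(layer$W)
  gains <- stats::setNames(lapply(tasks, function(t) rep(1, k)), tasks)
  sd0 <- derive_seed(cfg$seed, paste0("gain_layer", l))
  w_ou <- with_seed(sd0, rnorm(k, sd = 1 / sqrt(k)))
  b_ou <- 0
  Xall <- t(data$X)
  dimnames(Xall) <- NULL
  vel <- new.env(parent = emptyenv())
  upd <- function(key, val, grad) {
    gn <- sqrt(sum(grad^2)); if (gn > 2) grad <- grad * (2 / gn)
    v <- (vel[[key]] %||% 0) * 0.9 - cfg$lr_gain * grad
    vel[[key]] <- v
    val + v
  }
  for (epoch in seq_len(cfg$epochs_gain)) {
    batches <- balanced_batches(data, cfg$batch_gain,
                                seed = derive_seed(sd0, paste0("ep", epoch)))
    for (batch in batches) {
      B <- nrow(batch)
      dw_acc <- 0; db_acc <- 0
      for (t in unique(batch$task_id)) {
        rows <- which(batch$task_id == t)
        Xb <- Xall[, batch$idx[rows], drop = FALSE]
        y <- batch$y[rows]
        Hb <- tmcl_forward_below(stack, Xb, l - 1L,
                                 rep(t, length(rows)))
        Ut <- layer$W %*% Hb - layer$x_shift
        pre <- gains[[t]] * Ut
        Hl <- pmax(pre, 0)
        a <- drop(crossprod(w_ou, Hl)) + b_ou
        p <- plogis(a)
        da <- (p - y) / B
        dHl <- outer(w_ou, da) * (pre > 0)
        gains[[t]] <- upd(paste0("g.", t), gains[[t]], rowSums(dHl * Ut))
        dw_acc <- dw_acc + drop(Hl %*% da)
        db_acc <- db_acc + sum(da)
      }
      w_ou <- upd("w_ou", w_ou, dw_acc)
      b_ou <- upd("b_ou", b_ou, db_acc)
    }
  }
  list(gains = gains, w_ou = w_ou, b_ou = b_ou)
}

# mean test accuracy through layer l's output unit, per task
tmcl_eval <- function(stack, data, l) {
  idx <- data$test_idx
  Xs <- t(data$X[idx, , drop = FALSE])
  layer <- stack$layers[[l]]
  ou <- stack$ou[[l]]
  acc <- vapply(names(data$labels), function(t) {
    Hb <- tmcl_forward_below(stack, Xs, l - 1L, rep(t, length(idx)))
    Hl <- pmax(layer$gains[[t]] * (layer$W %*% Hb - layer$x_shift), 0)
    p <- plogis(drop(crossprod(ou$w, Hl)) + ou$b)
    mean(as.integer(p > 0.5) == data$labels[[t]][idx])
  }, numeric(1))
  data.frame(task_id = names(data$labels), accuracy = unname(acc),
             stringsAsFactors = FALSE)
}

#' Greedy layer-wise task-modulated contrastive learning
#'
#' Builds a stack layer by layer. Per layer: (i) a contrastive phase
#' learns the feedforward weights -- positives are two augmentations of
#' the same sample, additionally passed through different task-gain
#' settings of the already-trained layers below (mode `"tmcl"`); (ii) a
#' supervised gain phase learns per-task gains for the new layer through a
#' task-independent output unit. No error gradients flow between layers;
#' parameters of earlier layers are bit-identical after later layers
#' train.
#'
#' Modes: `"tmcl"` (full algorithm), `"cl_no_task"` (contrastive learning
#' without similarity maximization across task modulations: both views of
#' a pair receive the same single task's modulation, equivalent to a
#' similarity subset of size 1), `"rp"` (random feedforward weights, gain
#' phase only), `"rp_on_tmcl"` (TMCL first layer, random weights above).
#'
#' @param data A [multitask_dataset()] of square images.
#' @param tasks Task ids used for modulation augmentation (defaults to all
#'   tasks in `data`).
#' @param n_layers Number of layers to stack.
#' @param cfg A [tmcl_config()].
#' @param mode See above.
#' @param task_subset_size Optional: only this many (seeded, random) tasks
#'   generate modulation positives; evaluation still covers all tasks.
#' @return List with `stack` (a `tmcl_stack`), `accuracy` (data.frame
#'   layer / mean_accuracy), `per_task` (per-layer tables).
#' @export
stack_layers <- function(data, tasks = names(data$labels), n_layers, cfg,
                         mode = c("tmcl", "cl_no_task", "rp", "rp_on_tmcl"),
                         task_subset_size = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_layers >= 1L)
  stack <- new_tmcl_stack(ncol(data$X), tasks)
  if (mode == "cl_no_task") task_subset_size <- 1L
  task_subset <- NULL
  if (!is.null(task_subset_size)) {
    task_subset <- with_seed(derive_seed(cfg$seed, "task_subset"),
                             sample(tasks, min(task_subset_size, length(tasks))))
  }
  acc_rows <- list(); per_task <- list()
  for (l in seq_len(n_layers)) {
    cl_mode <- switch(mode,
      tmcl = "tmcl", cl_no_task = "cl_no_task",
      rp = "rp", rp_on_tmcl = if (l == 1L) "tmcl" else "rp")
    if (cl_mode == "rp") {
      k_in <- if (l == 1L) stack$input_dim else nrow(stack$layers[[l - 1L]]$W)
      ff <- list(W = random_projection(k_in, cfg$width,
                                       seed = derive_seed(cfg$seed, paste0("rp", l)),
                                       sd = sqrt(2 / k_in))$W,
                 x_shift = 0)
    } else {
      ff <- train_layer_cl(stack, data, l, cfg, task_subset = task_subset)
    }
    stack$layers[[l]] <- list(W = ff$W, x_shift = ff$x_shift,
                              gains = NULL, trained_mode = cl_mode)
    gp <- train_layer_gains(stack, data, l, cfg)
    stack$layers[[l]]$gains <- gp$gains
    stack$ou[[l]] <- list(w = gp$w_ou, b = gp$b_ou)
    tab <- tmcl_eval(stack, data, l)
    per_task[[l]] <- tab
    acc_rows[[l]] <- data.frame(layer = l, mean_accuracy = mean(tab$accuracy))
  }
  list(stack = stack, accuracy = do.call(rbind, acc_rows),
       per_task = per_task)
}
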