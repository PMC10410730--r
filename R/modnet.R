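#' Gain-modulated layer parameters
#'
#' One dense layer of rectified-linear units whose input-output relation is
#' `y = relu(g_t * (W x - x_shift) + b)`: the weight matrix `W`, the
#' x-shift and the bias are shared across tasks, while each registered task
#' owns a gain vector `g_t` (one multiplicative factor per unit,
#' initialized at 1).
#'
#' @param k_in,k_out Input and output dimensionality.
#' @param tasks Character vector of task ids to register.
#' @param xshift_mode `"scalar"` (one shared x-shift per layer, the
#'   default) or `"per_unit"`.
#' @param seed Seed for the fan-in-normalized Gaussian weight init.
#' @return An object of class `modulated_layer`.
#' @export
modulated_layer <- function(k_in, k_out, tasks = character(),
                            xshift_mode = c("scalar", "per_unit"), seed = 1L) {
  xshift_mode <- match.arg(xshift_mode)
  # He-style fan-in scaling plus a small positive bias keep rectifier units
  # active at initialization, which matters for deeper stacks
  W <- with_seed(seed, matrix(rnorm(k_out * k_in, sd = sqrt(2 / k_in)), k_out, k_in))
  gains <- stats::setNames(
    lapply(tasks, function(t) rep(1, k_out)), tasks)
  structure(list(
    W = W,
    x_shift = if (xshift_mode == "scalar") 0 else rep(0, k_out),
    b = rep(0.1, k_out),
    gains = gains,
    k_in = as.integer(k_in), k_out = as.integer(k_out),
    xshift_mode = xshift_mode
  ), class = "modulated_layer")
}

layer_gain <- function(layer, task_id) {
  g <- layer$gains[[task_id]]
  if (is.null(g))
    dm_stop("dm_task_unknown", "task '%s' is not registered on this layer", task_id)
  g
}

#' Forward pass of one gain-modulated layer
#'
#' Computes `relu(g_t * (W x - x_shift) + b)` for the given task.
#'
#' @param layer A [modulated_layer()].
#' @param task_id Registered task id.
#' @param x Input vector of length `k_in`, or a `k_in x B` matrix of
#'   column inputs.
#' @return Activation vector of length `k_out` (or `k_out x B` matrix).
#' @export
forward_modulated <- function(layer, task_id, x) {
  g <- layer_gain(layer, task_id)
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  if (nrow(X) != layer$k_in)
    dm_stop("dm_shape_error", "input has %d rows, layer expects %d",
            nrow(X), layer$k_in)
  u <- layer$W %*% X - layer$x_shift
  pre <- g * u + layer$b
  h <- pmax(pre, 0)
  if (vec) drop(h) else h
}

#' Gain-modulated feedforward stack
#'
#' A sequence of [modulated_layer()]s followed by one of two heads: a
#' single `modulated_output_unit` with its own per-task gain (shared
#' readout weights), or `task_specific_readouts` with one readout row per
#' task (and no per-task gains anywhere -- the conventional multitask
#' baseline).
#'
#' @param input_dim Input dimensionality.
#' @param hidden_sizes Integer vector of hidden layer widths.
#' @param tasks Task ids to register.
#' @param head Head type.
#' @param xshift_mode Passed to [modulated_layer()].
#' @param seed Seed for all weight initializations.
#' @return An object of class `modulated_stack`.
#' @export
modulated_stack <- function(input_dim, hidden_sizes, tasks = character(),
                            head = c("modulated_output_unit", "task_specific_readouts"),
                            xshift_mode = c("scalar", "per_unit"), seed = 1L) {
  head <- match.arg(head)
  xshift_mode <- match.arg(xshift_mode)
  sizes <- c(input_dim, hidden_sizes)
  layers <- lapply(seq_along(hidden_sizes), function(l) {
    modulated_layer(sizes[l], sizes[l + 1], tasks, xshift_mode,
                    seed = derive_seed(seed, paste0("layer", l)))
  })
  k_top <- utils::tail(sizes, 1)
  head_par <- if (head == "modulated_output_unit") {
    list(type = head,
         w = with_seed(derive_seed(seed, "head"),
                       rnorm(k_top, sd = 1 / sqrt(k_top))),
         x_shift = 0, b = 0,
         gains = stats::setNames(as.list(rep(1, length(tasks))), tasks))
  } else {
    list(type = head,
         w = stats::setNames(lapply(seq_along(tasks), function(i) {
           with_seed(derive_seed(seed, paste0("readout_", tasks[i])),
                     rnorm(k_top, sd = 1 / sqrt(k_top)))
         }), tasks),
         b = stats::setNames(as.list(rep(0, length(tasks))), tasks))
  }
  structure(list(layers = layers, head = head_par, activation = "relu",
                 input_dim = as.integer(input_dim), seed = seed),
            class = "modulated_stack")
}

#' @export
print.modulated_stack <- function(x, ...) {
  cat(sprintf("<modulated_stack> %d -> %s, head: %s, %d task(s)\n",
              x$input_dim,
              paste(vapply(x$layers, `[[`, 1L, "k_out"), collapse = " -> "),
              x$head$type, length(stack_tasks(x))))
  invisible(x)
}

stack_tasks <- function(stack) {
  if (stack$head$type == "modulated_output_unit") names(stack$head$gains)
  else names(stack$head$w)
}

#' Register new tasks on a stack
#'
#' Adds gain vectors of 1 (modulated head: plus a head gain of 1; readout
#' head: plus a fresh readout row) for each unseen task id.
#'
#' @param stack A [modulated_stack()].
#' @param tasks Character task ids.
#' @param seed Seed for new readout rows.
#' @return The updated stack.
#' @export
register_tasks <- function(stack, tasks, seed = 1L) {
  new <- setdiff(tasks, stack_tasks(stack))
  modulated <- stack$head$type == "modulated_output_unit"
  for (t in new) {
    for (l in seq_along(stack$layers))
      stack$layers[[l]]$gains[[t]] <- rep(1, stack$layers[[l]]$k_out)
    if (modulated) {
      stack$head$gains[[t]] <- 1
    } else {
      k_top <- utils::tail(vapply(stack$layers, `[[`, 1L, "k_out"), 1)
      stack$head$w[[t]] <- with_seed(derive_seed(seed, paste0("readout_", t)),
                                     rnorm(k_top, sd = 1 / sqrt(k_top)))
      stack$head$b[[t]] <- 0
    }
  }
  stack
}

# full forward pass with cached intermediates (X is k_in x B)
stack_forward <- function(stack, task_id, X) {
  h <- list()
  u <- list()
  pre <- list()
  a_in <- X
  for (l in seq_along(stack$layers)) {
    layer <- stack$layers[[l]]
    g <- layer_gain(layer, task_id)
    u[[l]] <- layer$W %*% a_in - layer$x_shift
    pre[[l]] <- g * u[[l]] + layer$b
    h[[l]] <- pmax(pre[[l]], 0)
    a_in <- h[[l]]
  }
  hd <- stack$head
  if (hd$type == "modulated_output_unit") {
    s <- drop(crossprod(hd$w, a_in)) - hd$x_shift
    a <- hd$gains[[task_id]] * s + hd$b
  } else {
    w <- hd$w[[task_id]]
    if (is.null(w)) dm_stop("dm_task_unknown", "task '%s' has no readout", task_id)
    s <- NULL
    a <- drop(crossprod(w, a_in)) + hd$b[[task_id]]
  }
  list(h = h, u = u, pre = pre, head_s = s, a = a, X = X)
}

# gradients of the mean sigmoid-BCE loss of one task group; `scale` allows
# averaging over a larger enclosing batch
stack_grads <- function(stack, task_id, X, y, scale = 1 / length(y)) {
  fw <- stack_forward(stack, task_id, X)
  a <- fw$a
  p <- plogis(a)
  eps <- 1e-12
  loss <- -sum(y * log(p + eps) + (1 - y) * log(1 - p + eps)) * scale
  da <- (p - y) * scale
  L <- length(stack$layers)
  h_top <- if (L > 0) fw$h[[L]] else fw$X
  g <- list(layers = vector("list", L), head = list())
  hd <- stack$head
  if (hd$type == "modulated_output_unit") {
    gh <- hd$gains[[task_id]]
    g$head$gain <- sum(da * fw$head_s)
    g$head$w <- drop(h_top %*% (da * gh))
    g$head$x_shift <- -sum(da) * gh
    g$head$b <- sum(da)
    dh <- outer(hd$w, da * gh)
  } else {
    g$head$w <- drop(h_top %*% da)
    g$head$b <- sum(da)
    dh <- outer(hd$w[[task_id]], da)
  }
  if (L > 0) {
    for (l in rev(seq_len(L))) {
      layer <- stack$layers[[l]]
      gl <- layer_gain(layer, task_id)
      mask <- fw$pre[[l]] > 0
      dpre <- dh * mask
      du <- dpre * gl
      below <- if (l > 1) fw$h[[l - 1]] else fw$X
      g$layers[[l]] <- list(
        W = du %*% t(below),
        b = rowSums(dpre),
        gain = rowSums(dpre * fw$u[[l]]),
        x_shift = if (layer$xshift_mode == "scalar") -sum(du) else -rowSums(du)
      )
      dh <- crossprod(layer$W, du)
    }
  }
  list(loss = loss, grads = g)
}

#' Training configuration
#'
#' @param learning_rate Positive SGD step size.
#' @param epochs Positive integer; one epoch cycles every task once
#'   through [balanced_batches()].
#' @param batch_size Samples per batch.
#' @param seed Integer seed controlling batch order (and any init done by
#'   the caller).
#' @param frozen Character subset of `c("W", "x_shift", "b", "gains",
#'   "head")`; frozen parameters are bit-identical after training.
#' @param momentum SGD momentum in `[0, 1)`.
#' @param tasks_per_batch Optional override passed to [balanced_batches()].
#' @param grad_clip Per-parameter gradient L2-norm clip (stabilizes deep
#'   stacks); `Inf` disables.
#' @param warmup_epochs Initial epochs over which the learning rate ramps
#'   linearly from `learning_rate / warmup_epochs` to `learning_rate`;
#'   guards deep rectifier stacks against early unit death. Default 15%
#'   of `epochs`.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate, epochs, batch_size, seed = 1L,
                         frozen = character(), momentum = 0.9,
                         tasks_per_batch = NULL, grad_clip = 2,
                         warmup_epochs = ceiling(0.15 * epochs)) {
  stopifnot(learning_rate >= 0, epochs >= 1, batch_size >= 2,
            momentum >= 0, momentum < 1, grad_clip > 0)
  bad <- setdiff(frozen, c("W", "x_shift", "b", "gains", "head"))
  if (length(bad))
    dm_stop("dm_config_error", "unknown frozen parameter(s): %s",
            paste(bad, collapse = ", "))
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 frozen = frozen, momentum = momentum,
                 tasks_per_batch = tasks_per_batch, grad_clip = grad_clip,
                 warmup_epochs = as.integer(warmup_epochs)),
            class = "train_config")
}

# core SGD loop shared by the training entry points.
# trainable_tasks restricts which tasks' task-specific parameters move
# (shared parameters still follow `frozen`).
sgd_train <- function(stack, data, cfg, trainable_tasks = NULL) {
  tasks <- names(data$labels)
  for (t in tasks) {
    y <- data$labels[[t]][data$train_idx]
    if (length(unique(y)) < 2L)
      dm_stop("dm_degenerate_task", "task '%s' has a single class in training data", t)
  }
  stack <- register_tasks(stack, tasks, seed = derive_seed(cfg$seed, "register"))
  if (is.null(trainable_tasks)) trainable_tasks <- tasks
  frozen <- cfg$frozen
  modulated <- stack$head$type == "modulated_output_unit"
  lr_max <- cfg$learning_rate; mom <- cfg$momentum
  lr <- lr_max
  warm <- max(0L, cfg$warmup_epochs %||% 0L)
  clip <- cfg$grad_clip %||% Inf
  vel <- new.env(parent = emptyenv())
  upd <- function(key, value, grad) {
    if (is.finite(clip)) {
      gn <- sqrt(sum(grad^2))
      if (gn > clip) grad <- grad * (clip / gn)
    }
    v <- (vel[[key]] %||% 0) * mom - lr * grad
    vel[[key]] <- v
    value + v
  }
  Xall <- t(data$X)                  # features x samples
  dimnames(Xall) <- NULL             # keep gradients free of dimnames
  for (epoch in seq_len(cfg$epochs)) {
    lr <- if (warm > 0) lr_max * min(1, epoch / warm) else lr_max
    batches <- balanced_batches(
      data, cfg$batch_size,
      seed = derive_seed(cfg$seed, paste0("epoch", epoch)),
      tasks_per_batch = cfg$tasks_per_batch)
    for (batch in batches) {
      B <- nrow(batch)
      acc <- NULL
      per_task <- split(seq_len(B), batch$task_id)
      for (t in names(per_task)) {
        rows <- per_task[[t]]
        gr <- stack_grads(stack, t,
                          Xall[, batch$idx[rows], drop = FALSE],
                          batch$y[rows], scale = 1 / B)
        # task-specific parameter updates
        if (t %in% trainable_tasks && !("gains" %in% frozen) && modulated) {
          for (l in seq_along(stack$layers)) {
            stack$layers[[l]]$gains[[t]] <- upd(
              paste0("g", l, ".", t), stack$layers[[l]]$gains[[t]],
              gr$grads$layers[[l]]$gain)
          }
          stack$head$gains[[t]] <- upd(paste0("ghead.", t),
                                       stack$head$gains[[t]], gr$grads$head$gain)
        }
        if (t %in% trainable_tasks && !modulated && !("head" %in% frozen)) {
          stack$head$w[[t]] <- upd(paste0("rw.", t), stack$head$w[[t]], gr$grads$head$w)
          stack$head$b[[t]] <- upd(paste0("rb.", t), stack$head$b[[t]], gr$grads$head$b)
        }
        # shared gradients accumulate across task groups
        if (is.null(acc)) {
          acc <- gr$grads
        } else {
          for (l in seq_along(acc$layers)) {
            for (nm in c("W", "b", "x_shift"))
              acc$layers[[l]][[nm]] <- acc$layers[[l]][[nm]] + gr$grads$layers[[l]][[nm]]
          }
          if (modulated) {
            acc$head$w <- acc$head$w + gr$grads$head$w
            acc$head$x_shift <- acc$head$x_shift + gr$grads$head$x_shift
            acc$head$b <- acc$head$b + gr$grads$head$b
          }
        }
      }
      for (l in seq_along(stack$layers)) {
        if (!("W" %in% frozen))
          stack$layers[[l]]$W <- upd(paste0("W", l), stack$layers[[l]]$W,
                                     acc$layers[[l]]$W)
        if (!("b" %in% frozen))
          stack$layers[[l]]$b <- upd(paste0("b", l), stack$layers[[l]]$b,
                                     acc$layers[[l]]$b)
        if (!("x_shift" %in% frozen))
          stack$layers[[l]]$x_shift <- upd(paste0("xs", l), stack$layers[[l]]$x_shift,
                                           acc$layers[[l]]$x_shift)
      }
      if (modulated && !("head" %in% frozen)) {
        stack$head$w <- upd("hw", stack$head$w, acc$head$w)
        stack$head$x_shift <- upd("hxs", stack$head$x_shift, acc$head$x_shift)
        stack$head$b <- upd("hb", stack$head$b, acc$head$b)
      }
    }
  }
  stack
}

#' Per-task accuracy of a stack on a dataset split
#'
#' Predictions are `1` when the sigmoid of the head pre-activation exceeds
#' 0.5; at exactly 0.5 the negative ("all/other") class is predicted.
#'
#' @param stack A trained [modulated_stack()].
#' @param data A [multitask_dataset()].
#' @param split `"test"` or `"train"`.
#' @param seed Seed recorded in the output table.
#' @return data.frame with columns `task_id`, `split`, `accuracy`, `seed`.
#' @export
eval_accuracy <- function(stack, data, split = "test", seed = NA_integer_) {
  idx <- if (split == "test") data$test_idx else data$train_idx
  Xs <- t(data$X[idx, , drop = FALSE])
  out <- lapply(names(data$labels), function(t) {
    a <- stack_forward(stack, t, Xs)$a
    pred <- as.integer(plogis(a) > 0.5)
    data.frame(task_id = t, split = split,
               accuracy = mean(pred == data$labels[[t]][idx]),
               seed = seed, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Multitask training with task-specific gains
#'
#' Gradient descent on a sigmoid binary cross-entropy loss over balanced
#' batches: feedforward weights, x-shifts and biases are shared across
#' tasks while each task learns its own gain vectors (and head gain).
#'
#' @param stack A [modulated_stack()] (head `modulated_output_unit`).
#' @param data A [multitask_dataset()]; every task must carry both classes
#'   in the training split.
#' @param cfg A [train_config()].
#' @return List with `stack` (trained) and `accuracy` (per-task table from
#'   [eval_accuracy()], test and train splits).
#' @export
train_multitask <- function(stack, data, cfg) {
  stack <- sgd_train(stack, data, cfg)
  acc <- rbind(eval_accuracy(stack, data, "test", cfg$seed),
               eval_accuracy(stack, data, "train", cfg$seed))
  list(stack = stack, accuracy = acc)
}

#' Transfer learning: frozen shared parameters, new task-specific ones
#'
#' Shared weights, x-shifts, biases (and the shared head components) stay
#' bit-identical; only the new tasks' gains (modulated head) or readout
#' rows (readout head) are trained.
#'
#' @param stack A pretrained [modulated_stack()].
#' @param new_tasks A [multitask_dataset()] holding the transfer tasks.
#' @param cfg A [train_config()] whose `frozen` contains at least
#'   `c("W", "x_shift", "b")`.
#' @return List with `stack` and `accuracy` for the transfer tasks.
#' @export
train_transfer <- function(stack, new_tasks, cfg) {
  if (!all(c("W", "x_shift", "b") %in% cfg$frozen))
    dm_stop("dm_config_error",
            "transfer requires frozen to contain W, x_shift and b")
  if (length(new_tasks$labels) == 0L)
    return(list(stack = stack,
                accuracy = data.frame(task_id = character(0), split = character(0),
                                      accuracy = numeric(0), seed = integer(0))))
  if (stack$head$type == "modulated_output_unit")
    cfg$frozen <- union(cfg$frozen, "head") # shared head components frozen too
  old_tasks <- stack_tasks(stack)
  stack <- sgd_train(stack, new_tasks, cfg,
                     trainable_tasks = setdiff(names(new_tasks$labels), old_tasks))
  acc <- rbind(eval_accuracy(stack, new_tasks, "test", cfg$seed),
               eval_accuracy(stack, new_tasks, "train", cfg$seed))
  list(stack = stack, accuracy = acc)
}

#' Readout-baseline multitask training
#'
#' The conventional alternative: a shared trunk without per-task gains,
#' and one trainable readout row per task.
#'
#' @param trunk_spec List with `input_dim` and `hidden_sizes` (and
#'   optionally `seed`).
#' @param data A [multitask_dataset()].
#' @param cfg A [train_config()].
#' @return As [train_multitask()].
#' @export
readout_baseline <- function(trunk_spec, data, cfg) {
  stack <- modulated_stack(trunk_spec$input_dim, trunk_spec$hidden_sizes,
                           tasks = names(data$labels),
                           head = "task_specific_readouts",
                           seed = trunk_spec$seed %||% cfg$seed)
  cfg$frozen <- union(cfg$frozen, "gains")  # baseline has no gain modulation
  stack <- sgd_train(stack, data, cfg)
  acc <- rbind(eval_accuracy(stack, data, "test", cfg$seed),
               eval_accuracy(stack, data, "train", cfg$seed))
  list(stack = stack, accuracy = acc)
}

#' Local normal vector of the decision boundary
#'
#' Gradient of the head pre-activation with respect to the input at `x`:
#' the normal of the (locally linear) decision boundary segment containing
#' `x`. In a rectifier network this is always a linear combination of the
#' rows of the first-layer weight matrix.
#'
#' @param stack A [modulated_stack()].
#' @param task_id Registered task id.
#' @param x Input vector; must not put any unit exactly on its rectifier
#'   kink (pre-activation exactly zero).
#' @return Numeric vector of length `input_dim`.
#' @export
decision_boundary_normals <- function(stack, task_id, x) {
  fw <- stack_forward(stack, task_id, matrix(x, ncol = 1))
  for (l in seq_along(stack$layers)) {
    if (any(fw$pre[[l]] == 0))
      dm_stop("dm_nondifferentiable",
              "input sits exactly on a rectifier kink in layer %d", l)
  }
  hd <- stack$head
  v <- if (hd$type == "modulated_output_unit") hd$gains[[task_id]] * hd$w
       else hd$w[[task_id]]
  for (l in rev(seq_along(stack$layers))) {
    layer <- stack$layers[[l]]
    mask <- drop(fw$pre[[l]]) > 0
    v <- drop(crossprod(layer$W, v * mask * layer_gain(layer, task_id)))
  }
  v
}

#' Serialize a stack to JSON
#'
#' Writes all shared and task-specific parameters (17 significant digits,
#' enough to round-trip doubles) plus an architecture header.
#'
#' @param stack A [modulated_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_stack <- function(stack, path) {
  payload <- list(
    format = "dendromod_stack_v1",
    input_dim = stack$input_dim,
    head_type = stack$head$type,
    seed = stack$seed,
    layers = lapply(stack$layers, function(l)
      list(W = l$W, x_shift = l$x_shift, b = l$b, gains = l$gains,
           k_in = l$k_in, k_out = l$k_out, xshift_mode = l$xshift_mode)),
    head = stack$head
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a stack serialized by [save_stack()]
#'
#' @param path JSON file path.
#' @return A [modulated_stack()].
#' @export
load_stack <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, "dendromod_stack_v1"))
    dm_stop("dm_config_error", "not a dendromod stack file: %s", path)
  num <- function(x) as.numeric(unlist(x))
  layers <- lapply(p$layers, function(l) {
    structure(list(W = matrix(num(l$W), as.integer(l$k_out),
                              as.integer(l$k_in), byrow = TRUE),
                   x_shift = num(l$x_shift), b = num(l$b),
                   gains = lapply(l$gains, num),
                   k_in = as.integer(l$k_in), k_out = as.integer(l$k_out),
                   xshift_mode = l$xshift_mode[[1]]),
              class = "modulated_layer")
  })
  head <- p$head
  head$type <- head$type[[1]]
  if (identical(p$head_type, "modulated_output_unit")) {
    head$w <- num(head$w)
    head$x_shift <- num(head$x_shift)
    head$b <- num(head$b)
    head$gains <- lapply(head$gains, num)
  } else {
    head$w <- lapply(head$w, num)
    head$b <- lapply(head$b, num)
  }
  structure(list(layers = layers, head = head, activation = "relu",
                 input_dim = as.integer(p$input_dim), seed = p$seed[[1]]),
            class = "modulated_stack")
}
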