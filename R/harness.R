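#' Evaluate a frozen weight matrix with gain-only supervision
#'
#' The evaluation harness for unsupervised weight matrices: a single
#' hidden layer whose feedforward weights are the (frozen) candidate
#' matrix, a scalar shared x-shift and bias, and a single gain-modulated
#' output unit reached through identical (uniform) feedforward weights.
#' Only per-task gains, the head gain, and the scalar shared offsets are
#' trained.
#'
#' @param W A `weight_matrix` or plain matrix (k x n).
#' @param data A [multitask_dataset()] with n-dimensional inputs.
#' @param cfg A [train_config()]; its `frozen` is overridden to freeze `W`.
#' @return Mean test accuracy over tasks.
#' @export
frozen_weight_eval <- function(W, data, cfg) {
  Wm <- if (inherits(W, "weight_matrix")) W$W else W
  k <- nrow(Wm)
  stack <- modulated_stack(ncol(Wm), k, tasks = names(data$labels),
                           head = "modulated_output_unit",
                           xshift_mode = "scalar", seed = cfg$seed)
  stack$layers[[1]]$W <- Wm
  stack$head$w <- rep(1 / sqrt(k), k)   # identical feedforward weights
  cfg$frozen <- union(cfg$frozen, c("W", "head"))
  stack <- sgd_train(stack, data, cfg)
  mean(eval_accuracy(stack, data, "test", cfg$seed)$accuracy)
}

# keep only the named tasks of a multitask dataset
subset_tasks <- function(data, keep) {
  out <- data
  out$labels <- data$labels[keep]
  class(out) <- "multitask_dataset"
  out
}

#' Multitask experiment on the 48-task 2D benchmark
#'
#' Trains a gain-modulated stack on the two-dimensional multitask set and
#' returns the mean test accuracy. Learning rates follow a per-architecture
#' grid search: 0.1 for shallow stacks, 0.05 for four hidden layers.
#'
#' @param hidden_sizes Hidden layer widths.
#' @param seed Integer seed (controls data, init, batches).
#' @param n_tasks,n_samples Dataset size.
#' @param epochs,learning_rate Training length and step size; defaults
#'   depend on depth.
#' @return Mean test accuracy over tasks.
#' @export
multitask_2d_experiment <- function(hidden_sizes = c(50), seed = 1L,
                                    n_tasks = 48L, n_samples = 600L,
                                    epochs = 150L,
                                    learning_rate = if (length(hidden_sizes) >= 3) 0.05 else 0.1) {
  d <- gen_2d_multitask(n_tasks = n_tasks, n_samples = n_samples,
                        seed = derive_seed(seed, "data2d"))
  st <- modulated_stack(2L, hidden_sizes, tasks = names(d$labels), seed = seed)
  cfg <- train_config(learning_rate, epochs = epochs, batch_size = 96L,
                      seed = seed, tasks_per_batch = 8L)
  res <- train_multitask(st, d, cfg)
  mean(res$accuracy$accuracy[res$accuracy$split == "test"])
}

#' Transfer experiment: gain modulation versus task-specific readouts
#'
#' Scaled-down emulation of the transfer comparison: glyph one-vs-all
#' tasks, a two-hidden-layer trunk with a narrow top layer, pretraining on
#' a small task subset so the trunk discards information irrelevant to the
#' pretraining tasks, then transfer to the remaining tasks with shared
#' parameters frozen. Returns test accuracy of the gain-modulated transfer
#' and of the readout-baseline transfer.
#'
#' @param seed Integer seed.
#' @param hidden_sizes Trunk widths (narrow top layer by default).
#' @param n_classes Glyph classes; tasks are one-vs-all.
#' @param n_pretrain Tasks used for pretraining.
#' @param epochs_pre,epochs_transfer Training lengths.
#' @return Named numeric `c(modulated =, readout =)`.
#' @export
transfer_experiment <- function(seed = 1L, hidden_sizes = c(64L, 8L),
                                n_classes = 10L, n_pretrain = 2L,
                                epochs_pre = 350L, epochs_transfer = 400L) {
  g <- gen_glyph_images(n_classes, image_size = 12L, n_per_class = 30L,
                        seed = derive_seed(seed, "glyph"))
  d <- to_one_vs_all(g, seed = derive_seed(seed, "ova"))
  tasks <- names(d$labels)
  pre <- tasks[seq_len(n_pretrain)]
  new <- setdiff(tasks, pre)
  d_pre <- subset_tasks(d, pre)
  d_new <- subset_tasks(d, new)
  cfg <- train_config(0.1, epochs = epochs_pre,
                      batch_size = 8L * n_pretrain, seed = seed,
                      tasks_per_batch = n_pretrain)
  cfg_t <- train_config(0.2, epochs = epochs_transfer, batch_size = 32L,
                        seed = derive_seed(seed, "transfer"),
                        frozen = c("W", "x_shift", "b"),
                        tasks_per_batch = 4L)
  stm <- modulated_stack(ncol(d$X), hidden_sizes, tasks = pre, seed = seed)
  stm <- sgd_train(stm, d_pre, cfg)
  acc_m <- train_transfer(stm, d_new, cfg_t)$accuracy
  rb <- readout_baseline(list(input_dim = ncol(d$X),
                              hidden_sizes = hidden_sizes, seed = seed),
                         d_pre, cfg)
  acc_r <- train_transfer(rb$stack, d_new, cfg_t)$accuracy
  c(modulated = mean(acc_m$accuracy[acc_m$split == "test"]),
    readout = mean(acc_r$accuracy[acc_r$split == "test"]))
}

#' Build the spiking XOR network
#'
#' Two feedforward input channels (one per input pattern) drive two
#' disjoint halves of the hidden population; two context channels target
#' disjoint dendritic compartments of every neuron with small random
#' initial weights. The output neuron must learn to spike exactly when
#' input pattern and context disagree.
#'
#' @param seed Integer seed.
#' @param n_hidden Hidden neurons (split in two pattern groups).
#' @param n_comp Compartments per neuron (half per context channel).
#' @param w_ff Mean feedforward weight, pA per spike.
#' @param w_out_mu Mean output weight, pA per hidden spike.
#' @param w0 Upper bound of the uniform initial dendritic weights, nS.
#' @return A [dendritic_network()].
#' @export
build_xor_network <- function(seed = 1L, n_hidden = 24L, n_comp = 6L,
                              w_ff = 75, w_out_mu = 30, w0 = 0.1) {
  H <- n_hidden; half <- H %/% 2L
  with_seed(derive_seed(seed, "xor_net"), {
    Wff <- rbind(cbind(matrix(w_ff, half, 1) + rnorm(half, 0, 4), matrix(0, half, 1)),
                 cbind(matrix(0, H - half, 1),
                       matrix(w_ff, H - half, 1) + rnorm(H - half, 0, 4)))
    syn <- expand.grid(neuron = seq_len(H), comp = seq_len(n_comp))
    syn$channel <- ifelse(syn$comp <= n_comp %/% 2L, 1L, 2L)
    syn$w <- runif(nrow(syn), 0, w0)
    dendritic_network(Wff, n_comp = n_comp, n_ctx_channels = 2L,
                      synapses = syn, w_out_mu = w_out_mu,
                      params = list(tau_out = 10), seed = seed)
  })
}

#' XOR episode stream for the spiking network
#'
#' @param n_episodes Number of episodes.
#' @param seed Integer seed.
#' @return Stream list for [run_online_learning()].
#' @export
xor_stream <- function(n_episodes, seed = 1L) {
  ep <- gen_xor_episodes(n_episodes, seed)
  list(pixels = cbind(ifelse(ep$a == 0L, 1, 0), ifelse(ep$a == 1L, 1, 0)),
       ctx_channel = ep$b + 1L,
       label = ep$label)
}

#' Spiking XOR learning experiment
#'
#' @param seed Integer seed.
#' @param n_train,n_test Training and held-out episodes.
#' @param eta Learning rate of the four-factor rule.
#' @return Held-out accuracy after online learning.
#' @export
xor_spiking_experiment <- function(seed = 1L, n_train = 1500L,
                                   n_test = 200L, eta = 0.01) {
  net <- build_xor_network(seed)
  st <- xor_stream(n_train + n_test, derive_seed(seed, "xor_stream"))
  run_online_learning(net, st, n_train = n_train, n_test = n_test,
                      eta = eta, w_max = 0.55, seed = seed,
                      rate_scale = 30)$test_accuracy
}

#' Build a spiking one-vs-all classifier network
#'
#' Hidden neurons receive a candidate feedforward weight matrix (rows =
#' neurons) as somatic current weights; each of the `n_ctx` context
#' channels targets its own block of dendritic compartments in every
#' neuron with small random initial weights.
#'
#' @param W Weight matrix (k x n), e.g. from [delta_pmd()] or
#'   [random_projection()].
#' @param n_ctx Context channels (= tasks).
#' @param seed Integer seed.
#' @param comps_per_ctx Compartments per context channel per neuron.
#' @param w_out_mu Mean output weight.
#' @param w0 Initial dendritic weight bound.
#' @return A [dendritic_network()].
#' @export
build_spiking_classifier <- function(W, n_ctx, seed = 1L, comps_per_ctx = 3L,
                                     w_out_mu = 30, w0 = 0.1) {
  if (inherits(W, "weight_matrix")) W <- W$W
  H <- nrow(W)
  D <- comps_per_ctx * n_ctx
  with_seed(derive_seed(seed, "cls_net"), {
    syn <- expand.grid(neuron = seq_len(H), comp = seq_len(D))
    syn$channel <- as.integer(ceiling(syn$comp / comps_per_ctx))
    syn$w <- runif(nrow(syn), 0, w0)
    dendritic_network(W, n_comp = D, n_ctx_channels = n_ctx,
                      synapses = syn, w_out_mu = w_out_mu,
                      params = list(tau_out = 10), seed = seed)
  })
}

#' Calibrate the global feedforward scale of a spiking network
#'
#' Binary search for the scalar multiplier of the feedforward weight
#' matrix such that, without context input, a target fraction of the
#' hidden population fires for typical probe stimuli. The same
#' (deterministic) procedure is applied to every candidate weight matrix,
#' so comparisons between matrices are on equal footing.
#'
#' @param net A [dendritic_network()].
#' @param X Probe stimulus matrix (rows = samples).
#' @param rate_scale Spikes per unit intensity.
#' @param target_frac Target mean hidden spike count, as a fraction of the
#'   population size.
#' @param n_probe Probe samples.
#' @return Positive scalar `ff_scale`.
#' @export
calibrate_ff_scale <- function(net, X, rate_scale = 30, target_frac = 0.25,
                               n_probe = 6L) {
  probe <- function(sc) {
    mean(vapply(seq_len(min(n_probe, nrow(X))), function(s) {
      ff <- encode_image_burst(X[s, ], 45, rate_scale,
                               seed = derive_seed(net$seed, paste0("cal", s)))
      length(simulate_network(net, ff, duration = 80, ff_scale = sc)$hidden_spike_t)
    }, numeric(1)))
  }
  lo <- 0.01; hi <- 3000
  tgt <- target_frac * nrow(net$Wff)
  for (i in seq_len(24)) {
    mid <- sqrt(lo * hi)
    if (probe(mid) > tgt) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

#' Spiking one-vs-all experiment with a candidate weight matrix
#'
#' Glyph classes are presented as feedforward bursts; the active context
#' channel names the task. The output neuron must spike for samples not
#' of the task's class and stay silent for the class to be recognized.
#' Dendritic weights learn online via the four-factor rule.
#'
#' @param method `"dpmd"` or `"rp"` -- how the (frozen) feedforward matrix
#'   is obtained from the glyph data.
#' @param seed Integer seed.
#' @param n_classes Glyph classes (= tasks = context channels).
#' @param k Hidden neurons.
#' @param n_train,n_test Episodes.
#' @param eta Learning rate.
#' @return Held-out accuracy.
#' @export
spiking_ova_experiment <- function(method = c("dpmd", "rp"), seed = 1L,
                                   n_classes = 4L, k = 24L,
                                   n_train = 2200L, n_test = 200L,
                                   eta = 0.015) {
  method <- match.arg(method)
  g <- gen_glyph_images(n_classes, image_size = 8L, n_per_class = 30L,
                        seed = derive_seed(seed, "glyph"))
  n <- ncol(g$X)
  W <- if (method == "dpmd") {
    dx <- sample_differences(g$X, 600L, seed = derive_seed(seed, "dx"))
    delta_pmd(dx, k, eps = 2.5, delta = 8, seed = seed)$W
  } else {
    random_projection(n, k, seed = seed)
  }
  net <- build_spiking_classifier(W, n_ctx = n_classes, seed = seed,
                                  w0 = 0.15, w_out_mu = 25)
  sc <- calibrate_ff_scale(net, g$X)
  n_ep <- n_train + n_test
  st <- with_seed(derive_seed(seed, "ova_stream"), {
    task <- sample.int(n_classes, n_ep, replace = TRUE)
    is_target <- runif(n_ep) < 0.5
    idx <- vapply(seq_len(n_ep), function(i) {
      pool <- if (is_target[i]) which(g$class == task[i])
              else which(g$class != task[i])
      sample(pool, 1L)
    }, integer(1))
    list(pixels = g$X[idx, , drop = FALSE], ctx_channel = task,
         label = as.integer(!is_target))
  })
  run_online_learning(net, st, n_train = n_train, n_test = n_test,
                      eta = eta, eta_decay = 800, w_max = 0.55, seed = seed,
                      rate_scale = 30, ff_scale = sc)$test_accuracy
}
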