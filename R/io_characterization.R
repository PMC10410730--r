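#' Build an input-output curve for one modulation level
#'
#' Runs `n_trials` seeded episodes per input count and averages the output
#' spike counts. The count function decouples the op from any particular
#' neuron source: pass [dendritic_probe()] for the built-in simplified
#' neuron, or any closure around user-supplied data.
#'
#' @param count_fn Function `(input_count, seed) -> spike count`.
#' @param modulation_level Integer label (e.g. number of NMDA-driven
#'   compartments).
#' @param input_counts Sorted integer vector; negative values mean
#'   inhibitory inputs.
#' @param n_trials Trials averaged per input count (default 10).
#' @param seed Integer seed; trial seeds derive from it.
#' @return An `io_curve` object: list with `modulation_level`,
#'   `input_counts`, `mean_spike_counts`, `n_trials`.
#' @export
io_curve <- function(count_fn, modulation_level, input_counts,
                     n_trials = 10L, seed = 1L) {
  stopifnot(n_trials >= 1L)
  means <- vapply(input_counts, function(nf) {
    mean(vapply(seq_len(n_trials), function(tr) {
      count_fn(nf, derive_seed(seed, sprintf("io_%d_%d_%d", modulation_level, nf, tr)))
    }, numeric(1)))
  }, numeric(1))
  structure(list(modulation_level = as.integer(modulation_level),
                 input_counts = input_counts,
                 mean_spike_counts = means,
                 n_trials = as.integer(n_trials)),
            class = "io_curve")
}

#' Spike-count probe over the simplified dendritic neuron
#'
#' One hidden neuron with `n_comp` compartments; `modulation_level`
#' compartments receive a context burst. The feedforward input is a burst
#' of `|input_count|` spikes (excitatory for positive counts, inhibitory
#' for negative) through a single somatic synapse. Returns the somatic
#' spike count in a window around the burst.
#'
#' @param modulation_level Number of context-driven compartments.
#' @param w_ff Feedforward weight per spike, pA.
#' @param w_ctx Context synapse weight, nS.
#' @param n_comp Total compartments.
#' @param t0 Burst center, ms.
#' @param window Count window, ms.
#' @param params Overrides for [neuron_defaults()].
#' @return Function `(input_count, seed) -> spike count` for [io_curve()].
#' @export
dendritic_probe <- function(modulation_level, w_ff = 60, w_ctx = 0.12,
                            n_comp = 40L, t0 = 40, window = c(30, 90),
                            params = list()) {
  syn <- if (modulation_level > 0)
    data.frame(neuron = 1L, comp = seq_len(modulation_level), channel = 1L,
               w = w_ctx)
  else NULL
  function(input_count, seed) {
    net <- dendritic_network(matrix(sign(input_count + 0.5) * w_ff, 1, 1),
                             n_comp = n_comp, n_ctx_channels = 1L,
                             synapses = syn, params = params)
    ff <- encode_image_burst(1, t0 = t0, rate_scale = abs(input_count),
                             seed = derive_seed(seed, "ff"))
    ctx <- if (modulation_level > 0)
      encode_context_burst(TRUE, t0, seed = derive_seed(seed, "ctx"),
                           channel = 1L)
    else spike_train_set()
    s <- simulate_network(net, ff, ctx, duration = window[2] + 10)
    sum(s$hidden_spike_t >= window[1] & s$hidden_spike_t <= window[2])
  }
}

#' Extract spike-increment thresholds from an IO curve
#'
#' For each integer spike level `s`, the input count where the linear
#' interpolation of the curve crosses the mid-point `s + 0.5` between
#' discrete values. Exact grid hits return the grid point itself.
#'
#' @param curve An [io_curve()].
#' @return Numeric vector of crossing points (input-count units) in
#'   increasing order; `thresholds[i]` crosses level `i - 0.5`. Empty when
#'   the curve never reaches 0.5. Multiple crossings for one level raise
#'   an ambiguity error listing the candidates.
#' @export
extract_thresholds <- function(curve) {
  x <- curve$input_counts
  y <- curve$mean_spike_counts
  out <- numeric(0)
  s_max <- floor(max(y) - 0.5)
  for (s in 0:max(0, s_max)) {
    lev <- s + 0.5
    if (max(y) < lev) break
    cand <- numeric(0)
    for (i in seq_len(length(x) - 1)) {
      y0 <- y[i]; y1 <- y[i + 1]
      if (y0 == lev && (i == 1 || y[i - 1] < lev)) cand <- c(cand, x[i])
      else if ((y0 < lev && y1 >= lev) || (y0 > lev && y1 <= lev))
        cand <- c(cand, x[i] + (lev - y0) / (y1 - y0) * (x[i + 1] - x[i]))
    }
    if (y[length(y)] == lev && y[length(y) - 1] < lev)
      cand <- unique(c(cand, x[length(x)]))
    cand <- unique(cand)
    if (length(cand) > 1)
      dm_stop("dm_ambiguous_threshold",
              "level %.1f crossed %d times (at %s)", lev, length(cand),
              paste(signif(cand, 6), collapse = ", "))
    if (length(cand) == 1) out <- c(out, cand)
  }
  sort(out)
}

# predicted threshold positions under each rectified-linear modulation model;
# thresholds[i] of level m crosses y = i - 0.5
relu_thresholds <- function(variant, levels, n_per_level, par) {
  K <- length(levels)
  out <- vector("list", K)
  for (j in seq_len(K)) {
    s <- seq_len(n_per_level[j]) - 0.5
    out[[j]] <- switch(variant,
      gain_per_level_shared_bias = (s - par$b) / par$g[j],
      bias_per_level_shared_gain = (s - par$b[j]) / par$g,
      gain_per_level_shared_bias_xshift = par$x_shift + (s - par$b) / par$g[j])
  }
  out
}

#' Joint rectified-linear fits of threshold families
#'
#' Fits all modulation levels together by minimizing the summed squared
#' error between observed and model-predicted threshold positions, for one
#' of three parameterizations of `y = relu(g (x - x_shift) + b)`:
#' a curve-specific gain with shared bias, a curve-specific bias with
#' shared gain, or a curve-specific gain with shared bias plus a shared
#' x-shift. Multi-start local least squares (the shared-x-shift variant
#' additionally starts from the nested no-shift solution, which guarantees
#' its residual never exceeds the nested model's).
#'
#' @param thresholds_by_level Named list: modulation level -> numeric
#'   vector of thresholds (element `i` crossing level `i - 0.5`), from
#'   [extract_thresholds()]. At least 2 levels.
#' @param variant One of `"gain_per_level_shared_bias"`,
#'   `"bias_per_level_shared_gain"`, `"gain_per_level_shared_bias_xshift"`.
#' @param n_starts Number of random optimizer starts (>= 8).
#' @param seed Seed for the starts.
#' @return A `relu_fit` object: list with `variant`, `per_level_params`,
#'   `shared_params`, `residual`, `converged`.
#' @export
fit_relu_family <- function(thresholds_by_level,
                            variant = c("gain_per_level_shared_bias",
                                        "bias_per_level_shared_gain",
                                        "gain_per_level_shared_bias_xshift"),
                            n_starts = 8L, seed = 1L) {
  variant <- match.arg(variant)
  K <- length(thresholds_by_level)
  if (K < 2L) dm_stop("dm_data_error", "need thresholds for >= 2 levels")
  levels <- names(thresholds_by_level) %||% as.character(seq_len(K))
  n_per <- vapply(thresholds_by_level, length, integer(1))
  if (any(n_per == 0)) dm_stop("dm_data_error", "every level needs >= 1 threshold")
  obs <- unlist(thresholds_by_level, use.names = FALSE)

  unpack <- function(theta) {
    switch(variant,
      gain_per_level_shared_bias =
        list(g = exp(theta[seq_len(K)]), b = theta[K + 1]),
      bias_per_level_shared_gain =
        list(g = exp(theta[1]), b = theta[1 + seq_len(K)]),
      gain_per_level_shared_bias_xshift =
        list(g = exp(theta[seq_len(K)]), b = theta[K + 1],
             x_shift = theta[K + 2]))
  }
  objective <- function(theta) {
    pred <- unlist(relu_thresholds(variant, levels, n_per, unpack(theta)))
    sum((obs - pred)^2)
  }
  n_par <- switch(variant,
    gain_per_level_shared_bias = K + 1L,
    bias_per_level_shared_gain = K + 1L,
    gain_per_level_shared_bias_xshift = K + 2L)

  # data-driven start: slope of thresholds vs level index approximates 1/g
  slope0 <- vapply(thresholds_by_level, function(tt) {
    if (length(tt) >= 2) max(mean(diff(tt)), 1e-3) else max(abs(tt[1]), 1)
  }, numeric(1))
  base_start <- switch(variant,
    gain_per_level_shared_bias = c(log(1 / slope0), 0),
    bias_per_level_shared_gain = c(log(1 / mean(slope0)), rep(0, K)),
    gain_per_level_shared_bias_xshift = c(log(1 / slope0), 0, 0))

  starts <- list(base_start)
  with_seed(derive_seed(seed, "relu_starts"), {
    for (i in seq_len(max(0L, n_starts - length(starts))))
      starts[[length(starts) + 1L]] <- base_start + rnorm(n_par, sd = 0.5)
  })
  if (variant == "gain_per_level_shared_bias_xshift") {
    nested <- fit_relu_family(thresholds_by_level,
                              "gain_per_level_shared_bias",
                              n_starts = n_starts, seed = seed)
    starts[[length(starts) + 1L]] <-
      c(log(unlist(nested$per_level_params)), nested$shared_params$b, 0)
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, objective, method = "BFGS",
            control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    dm_stop("dm_fit_error", "all optimizer starts failed")
  polish <- tryCatch(
    stats::nlm(objective, best$par, gradtol = 1e-14, steptol = 1e-14,
               iterlim = 2000),
    error = function(e) NULL)
  if (!is.null(polish) && polish$minimum < best$value)
    best <- list(par = polish$estimate, value = polish$minimum,
                 convergence = 0L)
  par <- unpack(best$par)
  per_level <- switch(variant,
    gain_per_level_shared_bias = stats::setNames(as.list(par$g), levels),
    bias_per_level_shared_gain = stats::setNames(as.list(par$b), levels),
    gain_per_level_shared_bias_xshift = stats::setNames(as.list(par$g), levels))
  shared <- switch(variant,
    gain_per_level_shared_bias = list(b = par$b),
    bias_per_level_shared_gain = list(g = par$g),
    gain_per_level_shared_bias_xshift = list(b = par$b, x_shift = par$x_shift))
  structure(list(variant = variant, per_level_params = per_level,
                 shared_params = shared, residual = best$value,
                 converged = best$convergence == 0),
            class = "relu_fit")
}

#' @export
print.relu_fit <- function(x, ...) {
  cat(sprintf("<relu_fit> %s, residual %.6g\n", x$variant, x$residual))
  invisible(x)
}

#' Write an IO curve set to CSV
#'
#' @param curves List of [io_curve()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_io_curves <- function(curves, path) {
  rows <- lapply(curves, function(cv)
    data.frame(modulation_level = cv$modulation_level,
               input_count = cv$input_counts,
               mean_spike_count = cv$mean_spike_counts,
               n_trials = cv$n_trials))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read IO curves from CSV (any source)
#'
#' @param path CSV with columns `modulation_level`, `input_count`,
#'   `mean_spike_count`, `n_trials`.
#' @return List of [io_curve()] objects, one per modulation level.
#' @export
read_io_curves <- function(path) {
  df <- read.csv(path)
  lapply(split(df, df$modulation_level), function(d) {
    structure(list(modulation_level = d$modulation_level[1],
                   input_counts = d$input_count,
                   mean_spike_counts = d$mean_spike_count,
                   n_trials = d$n_trials[1]),
              class = "io_curve")
  })
}
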