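#' Default parameters of the simplified dendritic neuron model
#'
#' A phenomenological reduction: a leaky integrate-and-fire soma
#' star-coupled to `n_comp` passive dendritic compartments carrying
#' conductance-based AMPA + NMDA synapses (Jahr-Stevens Mg-block sigmoid),
#' with current-based feedforward synapses at the soma. The NMDA decay
#' time constant (70 ms) is chosen so a driven compartment sustains a
#' plateau on the 50-100 ms scale that outlasts somatic spikes.
#' Units: capacitance pF, conductance nS, voltage mV, time ms, current pA.
#'
#' @param ... Named overrides of any default listed below.
#' @return Named list of model parameters.
#' @export
neuron_defaults <- function(...) {
  p <- list(
    # soma (integrate-and-fire)
    c_m_soma = 150, g_l_soma = 10, e_l = -70, v_th = -50, v_reset = -65,
    t_ref = 3,
    # dendritic compartments, star-coupled to the soma
    c_m_dend = 10, g_l_dend = 1, g_c = 2,
    # current-based feedforward synapse kernel at the soma
    tau_ff = 3,
    # dendritic AMPA + NMDA synapses
    tau_ampa = 2, ampa_ratio = 0.2,
    tau_nmda_rise = 2, tau_nmda_decay = 70,
    mg_fac = 0.28, mg_gamma = 0.062, e_syn = 0,
    # optional static linear conductance at the soma (clamp probes)
    g_extra_soma = 0, e_extra_soma = -70,
    # output neuron: single-compartment integrate-and-fire
    c_m_out = 150, g_l_out = 10, v_th_out = -50, v_reset_out = -65,
    t_ref_out = 3, tau_out = 3,
    # plasticity trace time constants
    tau_pre = 25, tau_post = 25, tau_v = 50
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) dm_stop("dm_config_error", "unknown parameter(s): %s",
                           paste(bad, collapse = ", "))
  modifyList(p, over)
}

#' Construct a dendritic spiking network
#'
#' @param Wff Feedforward weight matrix (`H x n_ff`, pA per input spike
#'   after scaling); a `weight_matrix` from the delta decompositions or a
#'   plain matrix. Rows are hidden neurons.
#' @param n_comp Dendritic compartments per hidden neuron (paper-scale
#'   default 40).
#' @param n_ctx_channels Number of presynaptic context channels.
#' @param synapses Dendritic synapse table: data.frame with columns
#'   `neuron`, `comp`, `channel`, `w` (peak NMDA conductance, nS).
#' @param w_out Output weights (length `H`); default uniform `w_out_mu`
#'   with Gaussian variability sigma/mu = 0.1.
#' @param w_out_mu Mean output weight (pA per hidden spike).
#' @param seed Seed for the output weight draw.
#' @param params Parameter overrides, see [neuron_defaults()].
#' @return An object of class `dendritic_network`.
#' @export
dendritic_network <- function(Wff, n_comp = 40L, n_ctx_channels = 0L,
                              synapses = NULL, w_out = NULL, w_out_mu = 40,
                              seed = 1L, params = list()) {
  if (inherits(Wff, "weight_matrix")) Wff <- Wff$W
  stopifnot(is.matrix(Wff))
  H <- nrow(Wff)
  p <- do.call(neuron_defaults, params)
  if (p$v_reset >= p$v_th || p$v_reset_out >= p$v_th_out)
    dm_stop("dm_config_error", "v_reset must be below v_th")
  if (any(unlist(p[c("c_m_soma", "g_l_soma", "c_m_dend", "g_l_dend", "g_c",
                     "c_m_out", "g_l_out")]) <= 0))
    dm_stop("dm_config_error", "capacitances and conductances must be positive")
  p$n_comp <- as.integer(n_comp)
  p$n_ctx_channels <- as.integer(n_ctx_channels)
  if (is.null(synapses))
    synapses <- data.frame(neuron = integer(0), comp = integer(0),
                           channel = integer(0), w = numeric(0))
  stopifnot(all(c("neuron", "comp", "channel", "w") %in% names(synapses)))
  if (nrow(synapses) > 0) {
    stopifnot(all(synapses$neuron >= 1), all(synapses$neuron <= H),
              all(synapses$comp >= 1), all(synapses$comp <= n_comp),
              all(synapses$channel >= 1),
              all(synapses$channel <= n_ctx_channels))
  }
  if (is.null(w_out))
    w_out <- with_seed(derive_seed(seed, "w_out"),
                       rnorm(H, mean = w_out_mu, sd = 0.1 * w_out_mu))
  structure(list(Wff = Wff, synapses = synapses, w_out = w_out,
                 params = p, seed = seed),
            class = "dendritic_network")
}

#' @export
print.dendritic_network <- function(x, ...) {
  cat(sprintf("<dendritic_network> %d hidden x %d compartments, %d ff channels, %d ctx channels, %d plastic synapses\n",
              nrow(x$Wff), x$params$n_comp, ncol(x$Wff),
              x$params$n_ctx_channels, nrow(x$synapses)))
  invisible(x)
}

#' Spike train container
#'
#' Events as (channel, time) pairs sorted by time.
#'
#' @param channel Integer synapse/channel ids (>= 1).
#' @param t Spike times in ms (>= 0).
#' @return data.frame of class `spike_train_set`, sorted by `t`.
#' @export
spike_train_set <- function(channel = integer(0), t = numeric(0)) {
  stopifnot(length(channel) == length(t))
  if (length(t) && (any(t < 0) || any(channel < 1)))
    dm_stop("dm_input_error", "spike times must be >= 0 and channels >= 1")
  ord <- order(t)
  structure(data.frame(channel = as.integer(channel[ord]), t = t[ord]),
            class = c("spike_train_set", "data.frame"))
}

#' Write / read spike trains as CSV
#'
#' Columns `synapse_id`, `t_ms`.
#'
#' @param spikes A [spike_train_set()].
#' @param path CSV file path.
#' @return `path` (writer) or a [spike_train_set()] (reader).
#' @export
write_spike_train <- function(spikes, path) {
  utils::write.csv(data.frame(synapse_id = spikes$channel, t_ms = spikes$t),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path) {
  df <- utils::read.csv(path)
  spike_train_set(df$synapse_id, df$t_ms)
}

# width is the full width at half maximum of the Gaussian burst envelope
burst_sd <- function(width) width / (2 * sqrt(2 * log(2)))

#' Encode pixel intensities as feedforward spike bursts
#'
#' Each pixel (channel) emits a Poisson number of spikes with mean
#' `rate_scale * intensity`; spike times are Gaussian around `t0` with a
#' burst width (FWHM) of `width` ms.
#'
#' @param pixels Non-negative intensity vector (typically in `[0, 1]`).
#' @param t0 Burst center, ms.
#' @param rate_scale Expected spike count for a unit-intensity pixel.
#' @param seed Integer seed.
#' @param width Burst FWHM in ms (default 6).
#' @return A [spike_train_set()] with channel = pixel index.
#' @export
encode_image_burst <- function(pixels, t0, rate_scale, seed = 1L, width = 6) {
  if (any(pixels < 0))
    dm_stop("dm_input_error", "pixel intensities must be non-negative")
  with_seed(seed, {
    counts <- rpois(length(pixels), rate_scale * pixels)
    ch <- rep(seq_along(pixels), counts)
    tt <- pmax(0, rnorm(sum(counts), mean = t0, sd = burst_sd(width)))
    spike_train_set(ch, tt)
  })
}

#' Encode a context signal as a wide spike burst
#'
#' Active contexts emit a Poisson number of spikes (mean 60) with Gaussian
#' times of width 20 ms (FWHM) around `t0`; inactive contexts emit none.
#'
#' @param active Logical.
#' @param t0 Burst center, ms.
#' @param seed Integer seed.
#' @param channel Context channel id.
#' @param mean_count Mean spike count when active (default 60).
#' @param width Burst FWHM in ms (default 20).
#' @return A [spike_train_set()].
#' @export
encode_context_burst <- function(active, t0, seed = 1L, channel = 1L,
                                 mean_count = 60, width = 20) {
  if (!isTRUE(active)) return(spike_train_set())
  with_seed(seed, {
    n <- rpois(1, mean_count)
    spike_train_set(rep(channel, n),
                    pmax(0, rnorm(n, mean = t0, sd = burst_sd(width))))
  })
}

#' Episode protocol constants
#'
#' The decision protocol: the first feedforward spike opens a 50-ms
#' window; one or more output spikes within the (closed) window signal
#' "other", silence signals the target class. Feedforward bursts are 6 ms
#' wide, context bursts 20 ms wide with on average 60 spikes.
#'
#' @param window_ms Decision window length.
#' @param ff_width,ctx_width Burst FWHM, ms.
#' @param ctx_mean_count Mean context spike count when active.
#' @param t0 Feedforward burst center within an episode, ms.
#' @param ctx_lead Context burst center precedes the feedforward burst by
#'   this many ms, so the quasi-tonic dendritic state is established when
#'   the fast feedforward volley arrives.
#' @return Named list.
#' @export
episode_protocol <- function(window_ms = 50, ff_width = 6, ctx_width = 20,
                             ctx_mean_count = 60, t0 = 45, ctx_lead = 15) {
  list(window_ms = window_ms, ff_width = ff_width, ctx_width = ctx_width,
       ctx_mean_count = ctx_mean_count, t0 = t0, ctx_lead = ctx_lead)
}

#' Simulate the dendritic spiking network
#'
#' Exponential-Euler integration of all somata and dendritic compartments.
#'
#' @param net A [dendritic_network()].
#' @param ff_spikes Feedforward [spike_train_set()] (channels index
#'   columns of `net$Wff`).
#' @param ctx_spikes Context [spike_train_set()] (channels index the
#'   plastic dendritic synapse table).
#' @param duration Simulated time, ms.
#' @param dt Time step, ms (default 0.05).
#' @param record_dt Recording decimation, ms (default 1).
#' @param record_dend Record dendritic voltages (memory-heavy).
#' @param ff_scale Scalar multiplier applied to `Wff` (pA per spike).
#' @param clamp Somatic voltage clamp level (mV) or `NULL`; when clamped
#'   the clamp current of neuron 1 is recorded and no spikes are emitted.
#' @return List with spike times, recorded voltages, clamp current, and
#'   plasticity traces at the final time (`pre_trace`, `post_trace`,
#'   `v_dend_trace`).
#' @export
simulate_network <- function(net, ff_spikes = spike_train_set(),
                             ctx_spikes = spike_train_set(),
                             duration = 100, dt = 0.05, record_dt = 1,
                             record_dend = FALSE, ff_scale = 1,
                             clamp = NULL) {
  stopifnot(inherits(net, "dendritic_network"))
  if (dt <= 0 || dt > 1) dm_stop("dm_config_error", "dt must be in (0, 1] ms")
  res <- .sim_network_cpp(
    net$params, net$Wff * ff_scale,
    as.numeric(ff_spikes$t %||% numeric(0)),
    as.integer(ff_spikes$channel %||% integer(0)),
    as.numeric(ctx_spikes$t %||% numeric(0)),
    as.integer(ctx_spikes$channel %||% integer(0)),
    as.integer(net$synapses$neuron), as.integer(net$synapses$comp),
    as.integer(net$synapses$channel), as.numeric(net$synapses$w),
    as.numeric(net$w_out),
    duration, dt, record_dt, isTRUE(record_dend),
    if (is.null(clamp)) 0 else clamp, !is.null(clamp))
  if (any(!is.finite(res$v_soma)))
    dm_stop("dm_integration_error", "non-finite somatic voltage (neuron %d)",
            which(!is.finite(res$v_soma[nrow(res$v_soma), ]))[1])
  res
}

#' Classify an episode from output spikes in the decision window
#'
#' @param output_spikes Numeric spike times of the output neuron.
#' @param window Length-2 numeric `c(open, close)`; the interval is
#'   closed, so a spike exactly at `close` counts as inside.
#' @return `"other"` if at least one spike falls in the window,
#'   `"target_class"` otherwise.
#' @export
classify_window <- function(output_spikes, window) {
  stopifnot(length(window) == 2L)
  inside <- output_spikes >= window[1] & output_spikes <= window[2]
  if (any(inside)) "other" else "target_class"
}

# bounded, non-negative modulation of the low-pass dendritic depolarization
phi_voltage <- function(u, theta = 8) {
  u <- pmax(u, 0)
  u^2 / (u^2 + theta^2)
}

#' Four-factor plasticity update
#'
#' Per-synapse weight change: the product of the global error signal, the
#' low-pass postsynaptic spike trace of the neuron, the low-pass
#' presynaptic spike trace of the channel, and a bounded non-negative
#' modulation of the low-pass dendritic depolarization.
#'
#' @param net A [dendritic_network()] (supplies the synapse table).
#' @param sim A [simulate_network()] result (supplies the traces).
#' @param error Global scalar in `{-1, 0, 1}` (+1: spike was required but
#'   absent; -1: spike occurred but was forbidden).
#' @param eta Learning rate.
#' @param phi Voltage modulation function; default a saturating
#'   square law with half-activation at 8 mV of sustained depolarization.
#' @return Numeric vector of weight deltas, one per synapse table row.
#' @export
plasticity_update <- function(net, sim, error, eta, phi = phi_voltage) {
  syn <- net$synapses
  if (error == 0 || nrow(syn) == 0) return(numeric(nrow(syn)))
  pre <- sim$pre_trace[syn$channel]
  post <- sim$post_trace[syn$neuron]
  vmod <- phi(sim$v_dend_trace[cbind(syn$neuron, syn$comp)])
  eta * error * post * pre * vmod
}

#' Run one classification episode
#'
#' Encodes the sample and context, simulates, opens the decision window at
#' the first feedforward spike, and classifies.
#'
#' @param net A [dendritic_network()].
#' @param pixels Feedforward intensity vector.
#' @param ctx_channel Active context channel id, or `NA` for none.
#' @param seed Episode seed (controls both encoders).
#' @param rate_scale Spikes per unit intensity, see [encode_image_burst()].
#' @param protocol An [episode_protocol()].
#' @param dt Integration step.
#' @param ff_scale Feedforward weight scale.
#' @return List with `decision`, `window`, `n_out`, and the raw `sim`.
#' @export
run_episode <- function(net, pixels, ctx_channel, seed, rate_scale = 3,
                        protocol = episode_protocol(), dt = 0.05,
                        ff_scale = 1) {
  ff <- encode_image_burst(pixels, protocol$t0, rate_scale,
                           seed = derive_seed(seed, "ff"),
                           width = protocol$ff_width)
  ctx <- if (!is.na(ctx_channel))
    encode_context_burst(TRUE, protocol$t0 - (protocol$ctx_lead %||% 0),
                         seed = derive_seed(seed, "ctx"),
                         channel = ctx_channel,
                         mean_count = protocol$ctx_mean_count,
                         width = protocol$ctx_width)
  else spike_train_set()
  open <- if (nrow(ff)) min(ff$t) else protocol$t0
  duration <- open + protocol$window_ms + 10
  sim <- simulate_network(net, ff, ctx, duration = duration, dt = dt,
                          ff_scale = ff_scale)
  window <- c(open, open + protocol$window_ms)
  inside <- sim$output_spike_t >= window[1] & sim$output_spike_t <= window[2]
  list(decision = classify_window(sim$output_spike_t, window),
       window = window, n_out = sum(inside), sim = sim)
}

#' Online error-modulated Hebbian learning over an episode stream
#'
#' Feedforward weights stay frozen; only the dendritic AMPA+NMDA synapse
#' weights change, once per episode at window close, following
#' [plasticity_update()]. The error signal is emitted only on erroneous
#' firing: +1 when a required output spike was absent, -1 when a forbidden
#' output spike occurred.
#'
#' @param net A [dendritic_network()].
#' @param stream List with `pixels` (episode x feature matrix),
#'   `ctx_channel` (integer per episode, `NA` = none), `label` (1 = output
#'   must spike, 0 = must stay silent).
#' @param n_train Episodes used for training (the first `n_train` rows).
#' @param n_test Held-out episodes evaluated with plasticity off (the last
#'   `n_test` rows).
#' @param eta Learning rate; `eta = 0` leaves weights bit-identical.
#' @param eta_decay Episode scale of the 1/(1 + i/eta_decay) learning-rate
#'   decay; `Inf` (default) keeps `eta` constant.
#' @param w_max Upper weight clip (nS); weights stay in `[0, w_max]`.
#' @param seed Integer seed for episode encoding noise.
#' @param rate_scale,protocol,dt,ff_scale Passed to [run_episode()].
#' @param curve_every Record the moving training accuracy every this many
#'   episodes.
#' @return List with `net` (learned weights), `train_curve` (data.frame
#'   episode/accuracy moving average), `test_accuracy`.
#' @export
run_online_learning <- function(net, stream, n_train, n_test = 0L,
                                eta = 2, eta_decay = Inf, w_max = 0.6, seed = 1L,
                                rate_scale = 3, protocol = episode_protocol(),
                                dt = 0.05, ff_scale = 1, curve_every = 50L) {
  n_ep <- nrow(stream$pixels)
  stopifnot(n_train + n_test <= n_ep)
  ctx <- stream$ctx_channel
  if (any(!is.na(ctx) & (ctx < 1 | ctx > net$params$n_ctx_channels)))
    dm_stop("dm_task_unknown", "context channel outside the registered range")
  recent <- numeric(0)
  curve <- list()
  for (i in seq_len(n_train)) {
    ep <- run_episode(net, stream$pixels[i, ], ctx[i],
                      seed = derive_seed(seed, paste0("ep", i)),
                      rate_scale = rate_scale, protocol = protocol, dt = dt,
                      ff_scale = ff_scale)
    spiked <- ep$decision == "other"
    want <- stream$label[i] == 1L
    correct <- spiked == want
    error <- if (want && !spiked) 1 else if (!want && spiked) -1 else 0
    if (eta != 0 && error != 0) {
      eta_i <- if (is.finite(eta_decay)) eta / (1 + i / eta_decay) else eta
      dw <- plasticity_update(net, ep$sim, error, eta_i)
      net$synapses$w <- pmin(pmax(net$synapses$w + dw, 0), w_max)
    }
    recent <- c(recent, correct)
    if (length(recent) > 100) recent <- utils::tail(recent, 100)
    if (i %% curve_every == 0L)
      curve[[length(curve) + 1L]] <- data.frame(episode = i,
                                                accuracy = mean(recent))
  }
  test_acc <- NA_real_
  if (n_test > 0) {
    idx <- seq(n_ep - n_test + 1L, n_ep)
    ok <- vapply(idx, function(i) {
      ep <- run_episode(net, stream$pixels[i, ], ctx[i],
                        seed = derive_seed(seed, paste0("test", i)),
                        rate_scale = rate_scale, protocol = protocol,
                        dt = dt, ff_scale = ff_scale)
      (ep$decision == "other") == (stream$label[i] == 1L)
    }, logical(1))
    test_acc <- mean(ok)
  }
  list(net = net,
       train_curve = do.call(rbind, curve) %||%
         data.frame(episode = integer(0), accuracy = numeric(0)),
       test_accuracy = test_acc)
}

#' Effective somatic conductance under voltage clamp
#'
#' Repeats the same input at several holding potentials and returns, per
#' recorded time point, the least-squares slope of the clamp current
#' versus holding potential -- the total membrane conductance seen from
#' the soma.
#'
#' @param net A [dendritic_network()] (neuron 1 is probed).
#' @param ff_spikes,ctx_spikes Input [spike_train_set()]s.
#' @param holding_potentials At least two clamp levels, mV.
#' @param duration,dt,record_dt Passed to [simulate_network()].
#' @return data.frame with columns `t` and `g_eff` (nS).
#' @export
effective_conductance <- function(net, ff_spikes = spike_train_set(),
                                  ctx_spikes = spike_train_set(),
                                  holding_potentials = c(-75, -65),
                                  duration = 200, dt = 0.05, record_dt = 1) {
  if (length(holding_potentials) < 2L)
    dm_stop("dm_protocol_error", "need at least 2 holding potentials")
  sims <- lapply(holding_potentials, function(vh) {
    simulate_network(net, ff_spikes, ctx_spikes, duration = duration,
                     dt = dt, record_dt = record_dt, clamp = vh)
  })
  I <- sapply(sims, `[[`, "i_clamp")
  tvec <- sims[[1]]$t
  v <- holding_potentials - mean(holding_potentials)
  g <- as.numeric(I %*% v) / sum(v^2)
  data.frame(t = tvec, g_eff = g)
}
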