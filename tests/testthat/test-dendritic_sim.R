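test_that("rest state is a fixed point and parameters are validated", {
  net <- probe_net(m_mod = 1L)
  s <- simulate_network(net, duration = 100)
  expect_lt(max(abs(s$v_soma - net$params$e_l)), 1e-9)
  expect_lt(max(abs(s$v_out - net$params$e_l)), 1e-9)
  expect_length(s$hidden_spike_t, 0L)
  expect_error(dendritic_network(matrix(1, 1, 1), params = list(v_reset = -40)),
               class = "dm_config_error")
  expect_error(neuron_defaults(nonsense = 1), class = "dm_config_error")
})

test_that("burst encoders are seeded and match their stated statistics", {
  ff <- encode_image_burst(c(0.5, 0, 1), t0 = 30, rate_scale = 10, seed = 2L)
  expect_identical(ff, encode_image_burst(c(0.5, 0, 1), 30, 10, seed = 2L))
  expect_true(all(ff$channel != 2L))          # zero pixel emits nothing
  expect_length(encode_image_burst(rep(0, 5), 30, 10, seed = 1L)$t, 0L)
  expect_error(encode_image_burst(c(-0.1, 1), 30, 10), class = "dm_input_error")
  # spike count calibration: total count / (rate_scale * sum(I)) -> 1
  tot <- vapply(1:300, function(s)
    nrow(encode_image_burst(c(0.3, 0.7), 30, 20, seed = s)), numeric(1))
  expect_lt(abs(mean(tot) / 20 - 1), 0.05)
  # context burst: inactive empty; active mean near 60; width stat matches
  expect_equal(nrow(encode_context_burst(FALSE, 30)), 0L)
  ct <- lapply(1:200, function(s) encode_context_burst(TRUE, 100, seed = s))
  expect_lt(abs(mean(vapply(ct, nrow, numeric(1))) - 60), 2)
  times <- unlist(lapply(ct, `[[`, "t"))
  expect_lt(abs(stats::sd(times) - 20 / (2 * sqrt(2 * log(2)))), 0.5)
})

test_that("integration converges as the step shrinks", {
  net <- probe_net(m_mod = 2L, w_ctx = 0.3)
  ctx <- encode_context_burst(TRUE, 20, seed = 3L)
  v1 <- simulate_network(net, ctx_spikes = ctx, duration = 120, dt = 0.1)$v_soma
  v2 <- simulate_network(net, ctx_spikes = ctx, duration = 120, dt = 0.05)$v_soma
  dev <- max(abs(v1 - v2)) / diff(range(v2))
  expect_lt(dev, 0.01)
})

test_that("NMDA drive produces a sustained plateau and boosts spiking monotonically", {
  net <- probe_net(m_mod = 1L, w_ctx = 0.3, D = 4L)
  ctx <- encode_context_burst(TRUE, 30, seed = 2L)
  s <- simulate_network(net, ctx_spikes = ctx, duration = 250, record_dend = TRUE)
  vd <- s$v_dend[, 1]
  expect_gt(max(vd), -30)                     # regenerative depolarization
  plateau <- range(s$t[vd > -50])
  expect_gt(diff(plateau), 40)                # sustained on the 50-100 ms scale
  # paired simulations: spike count non-decreasing in driven compartments
  counts <- vapply(c(0L, 8L, 16L, 24L, 34L), function(m) {
    mean(vapply(1:5, function(sd) {
      net <- probe_net(m_mod = m, D = 40L, w_ctx = 0.12, w_ff = 60)
      ff <- encode_image_burst(1, 40, 60, seed = derive_seed(sd, "f"))
      ctx <- if (m > 0) encode_context_burst(TRUE, 40, seed = derive_seed(sd, "c"))
             else spike_train_set()
      s <- simulate_network(net, ff, ctx, duration = 100)
      sum(s$hidden_spike_t >= 30 & s$hidden_spike_t <= 90)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[5], counts[1])
})

test_that("classify_window follows the closed-interval convention", {
  expect_equal(classify_window(numeric(0), c(10, 60)), "target_class")
  expect_equal(classify_window(c(60), c(10, 60)), "other")   # edge inside
  expect_equal(classify_window(c(5, 61), c(10, 60)), "target_class")
  expect_equal(classify_window(c(30), c(10, 60)), "other")
})

test_that("the four-factor rule multiplies its factors exactly", {
  net <- probe_net(m_mod = 2L)
  sim <- list(pre_trace = c(0.2), post_trace = c(0.5),
              v_dend_trace = matrix(10, 1, 4))
  # phi = 1 surrogate: eta * error * post * pre
  dw <- plasticity_update(net, sim, error = 1, eta = 0.1,
                          phi = function(u) rep(1, length(u)))
  expect_equal(dw, rep(0.1 * 1 * 0.5 * 0.2, 2))
  expect_equal(plasticity_update(net, sim, error = 0, eta = 0.1),
               rep(0, 2))
  sim$pre_trace <- 0
  expect_equal(plasticity_update(net, sim, error = -1, eta = 0.1),
               rep(0, 2))
  sim$pre_trace <- c(0.2); sim$post_trace <- 0
  expect_equal(plasticity_update(net, sim, error = 1, eta = 5), rep(0, 2))
})

test_that("presynaptic traces decay exponentially after an isolated spike", {
  net <- probe_net(m_mod = 1L)
  ctx <- spike_train_set(1L, 10)
  tau <- net$params$tau_pre
  for (Tend in c(40, 80)) {
    s <- simulate_network(net, ctx_spikes = ctx, duration = Tend, dt = 0.05)
    expect_equal(s$pre_trace, exp(-(Tend - 10) / tau), tolerance = 1e-2)
  }
})

test_that("eta = 0 leaves weights bit-identical and accuracy at baseline", {
  net <- build_xor_network(seed = 3L, n_hidden = 8L)
  st <- xor_stream(30L, seed = 4L)
  r <- run_online_learning(net, st, n_train = 20L, n_test = 10L, eta = 0,
                           seed = 5L, rate_scale = 30)
  expect_identical(r$net$synapses$w, net$synapses$w)
  r2 <- run_online_learning(net, st, n_train = 0L, n_test = 10L, eta = 0,
                            seed = 5L, rate_scale = 30)
  expect_equal(r$test_accuracy, r2$test_accuracy)
  # unknown context channel is rejected
  bad <- st; bad$ctx_channel[1] <- 9L
  expect_error(run_online_learning(net, bad, n_train = 5L, seed = 1L),
               class = "dm_task_unknown")
})

test_that("effective conductance: passive closed form and additive shift", {
  net <- probe_net(m_mod = 1L, D = 4L)
  p <- net$params
  g_closed <- p$g_l_soma + 4 * p$g_c * p$g_l_dend / (p$g_c + p$g_l_dend)
  ec <- effective_conductance(net, duration = 200)
  expect_lt(abs(utils::tail(ec$g_eff, 1) - g_closed), 1e-6)
  net2 <- probe_net(m_mod = 1L, D = 4L, params = list(g_extra_soma = 5))
  ec2 <- effective_conductance(net2, duration = 200)
  expect_equal(utils::tail(ec2$g_eff, 1) - utils::tail(ec$g_eff, 1), 5,
               tolerance = 1e-9)
  expect_error(effective_conductance(net, holding_potentials = -70),
               class = "dm_protocol_error")
  # active NMDA input: conductance deviates during the burst, returns after
  # (baseline window taken after the clamp-onset transient has settled)
  net3 <- probe_net(m_mod = 2L, w_ctx = 0.4)
  ctx <- encode_context_burst(TRUE, 200, seed = 5L)
  ec3 <- effective_conductance(net3, ctx_spikes = ctx, duration = 700)
  base <- ec3$g_eff[ec3$t >= 120 & ec3$t <= 160]
  during <- ec3$g_eff[ec3$t >= 200 & ec3$t <= 280]
  late <- utils::tail(ec3$g_eff, 5)
  expect_gt(max(abs(during - mean(base))), 0.5)
  expect_lt(abs(mean(late) - mean(base)), 0.05)
})

test_that("spike trains round-trip through CSV", {
  st <- spike_train_set(c(3L, 1L, 2L), c(5.5, 1.25, 3))
  f <- tempfile(fileext = ".csv")
  write_spike_train(st, f)
  back <- read_spike_train(f)
  expect_equal(back$channel, st$channel)
  expect_equal(back$t, st$t)
  unlink(f)
})
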