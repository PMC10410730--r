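# small fixtures shared across test files; everything is generated in code

tiny_dataset <- function(n_tasks = 4L, n_samples = 120L, seed = 42L) {
  gen_2d_multitask(n_tasks = n_tasks, n_samples = n_samples, seed = seed)
}

tiny_glyphs <- function(n_classes = 4L, image_size = 8L, n_per_class = 20L,
                        seed = 42L) {
  gen_glyph_images(n_classes, image_size, n_per_class, seed = seed)
}

tiny_stack <- function(data, hidden = c(16L), seed = 7L,
                       head = "modulated_output_unit") {
  modulated_stack(ncol(data$X), hidden, tasks = names(data$labels),
                  head = head, seed = seed)
}

quick_cfg <- function(epochs = 20L, lr = 0.1, seed = 7L, ...) {
  train_config(lr, epochs = epochs, batch_size = 16L, seed = seed,
               tasks_per_batch = 2L, ...)
}

# single hidden neuron with D compartments, first m driven by context ch 1
probe_net <- function(m_mod = 0L, D = 4L, w_ctx = 0.3, w_ff = 60, ...) {
  syn <- if (m_mod > 0)
    data.frame(neuron = 1L, comp = seq_len(m_mod), channel = 1L, w = w_ctx)
  else NULL
  dendritic_network(matrix(w_ff, 1, 1), n_comp = D, n_ctx_channels = 1L,
                    synapses = syn, ...)
}
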