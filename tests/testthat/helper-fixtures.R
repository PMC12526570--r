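# Shared miniature configurations and generated fixtures.

# A deliberately tiny network for gradient checks and fast smoke fits:
# 100-sample windows at 10 Hz, 4-band self-similarity inputs.
tiny_model_config <- function(dropout = 0) {
  model_config(preset = "small", fs = 10, window_s = 10, dropout = dropout,
               stem_filters = 4, stem_kernel = 3, pool_size = 10,
               res_filters = 8, res_kernel = 3, csia_heads = 2,
               bilstm_units = c(4L, 3L), n_bands = 4, freq_heads = 2,
               ffn_width = 8, conv1x1_filters = 4, freq_bilstm_units = 3,
               common_dim = 8, channel_reduction = 2, fusion_heads = 2,
               fc1_units = 8,
               welch = welch_config(seg_len = 32, overlap = 0.5))
}

tiny_batch <- function(cfg, n = 4, seed = 1) {
  set.seed(seed)
  list(x = matrix(rnorm(n * cfg$window_samples), n),
       ssm = array(rnorm(n * cfg$n_bands^2), c(n, cfg$n_bands, cfg$n_bands)),
       y = rep_len(0:3, n))
}

# Short synthetic records for windowing tests (deterministic).
quick_dataset <- function(n_per_class, duration_s = 20, seed = 7) {
  make_dataset(n_per_class, sim_params(duration_s = duration_s, seed = seed))
}
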