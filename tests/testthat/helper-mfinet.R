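# shared fixtures: everything is generated in code at test time

# tiny 3-level configuration for fast structural tests
tiny_config <- function(...) {
  model_config(n_levels = 3L, input_size = 16L, base_width = 2L,
               mr_stages = 2L, mr_widths = c(2L, 3L, 4L),
               attn_reduction = 2L, ...)
}

# coordinate-coded image: value encodes (row, col), so alignment bugs show up
coded_image <- function(H, W) outer(seq_len(H) * 1000, seq_len(W), `+`)

random_feature <- function(H, W, C, N = 1L, seed = 1L) {
  set.seed(seed)
  array(stats::rnorm(H * W * C * N), c(H, W, C, N))
}

# zero every parameter of a bundle created by the init_* helpers
zero_params <- function(unit) {
  unit$params <- lapply(unit$params, function(a) {
    a[] <- 0
    a
  })
  unit
}

# small synthetic dataset shared across expensive tests
synth_samples <- function(n, size = 96L, first_seed = 100L) {
  lapply(seq_len(n), function(q)
    generate_sample(synth_config(image_size = c(size, size),
                                 seed = first_seed + q - 1L)))
}
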