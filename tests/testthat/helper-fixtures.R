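# Shared fixtures: all built in code, nothing read from disk.

# flat gray image
gray_img <- function(value = 0.5, side = 16L) {
  matrix(value, side, side)
}

# a hand-built dataset: `counts` is a named list genus_name -> number of
# specimens; every specimen gets exactly one image per view unless
# `drop_view`/`extra_view` name (specimen index, view) tweaks.
toy_dataset <- function(counts = list(A = 2, B = 2), side = 16L) {
  specimens <- list()
  g <- 0L
  for (name in names(counts)) {
    g <- g + 1L
    for (i in seq_len(counts[[name]])) {
      sid <- sprintf("%s_%02d", name, i)
      imgs <- stats::setNames(
        lapply(mv_views(), function(v) list(gray_img(g / 10 + i / 100, side))),
        mv_views())
      specimens[[length(specimens) + 1L]] <- new_specimen(sid, g, imgs)
    }
  }
  mv_dataset(specimens, names(counts))
}

# a small architecture (16x16 input) for fast trainer tests; two
# fully-connected layers so penultimate features exist
tiny_arch <- function(n_labels = 2L, side = 16L) {
  layers <- dplyr::bind_rows(
    layer_spec("input"),
    layer_spec("convolution", k = 5, S = 2, P = 0, C_out = 8),
    layer_spec("relu"),
    layer_spec("pooling", k = 2, S = 2, P = 0),
    layer_spec("normalization"),
    layer_spec("fully_connected", C_out = 32),
    layer_spec("relu"),
    layer_spec("dropout", rate = 0.5),
    layer_spec("fully_connected", C_out = 16),
    layer_spec("relu"),
    layer_spec("fully_connected", C_out = n_labels),
    layer_spec("softmax"),
    layer_spec("loss")
  )
  architecture(layers, input_size = side, input_channels = 1L,
               n_labels = n_labels)
}

# small synthetic problem matched to tiny_arch
tiny_split <- function(n_genera = 2L, per_genus = 6L, seed = 42L,
                       noise_sd = 0.02) {
  cfg <- synth_config(n_genera = n_genera, specimens_per_genus = per_genus,
                      image_size = 16L, noise_sd = noise_sd,
                      extra_picture_prob = 0, seed = seed)
  split_dataset(generate_dataset(cfg), seed = seed)
}

fast_hp <- function(iterations = 30L, seed = 1L) {
  hyperparams(iterations = iterations, batch_size = 8L,
              validation_interval = 10L, seed = seed)
}
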