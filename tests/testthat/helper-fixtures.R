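# Shared fixtures: all data is generated in code, sized for speed.

# Reduced encoder used throughout the suite.
tiny_encoder_config <- function(channels = 3L, window_len = 32L, seed = 1L,
                                hidden = 16L) {
  encoder_config(in_channels = channels, window_len = window_len,
                 conv_layers = 2L, conv_filters = 8L, kernel_len = 5L,
                 lstm_layers = 1L, lstm_hidden = hidden, seed = seed)
}

# A random (unstructured) window batch.
random_batch <- function(n, channels = 3L, window_len = 32L,
                         labels = seq_len(n), seed = NULL) {
  gen <- function() array(stats::rnorm(n * channels * window_len),
                          c(n, channels, window_len))
  w <- if (is.null(seed)) gen() else with_seed(seed, gen())
  window_batch(w, labels)
}

# Small well-separated synthetic dataset.
separable_data <- function(n_classes = 6L, channels = 3L, window_len = 32L,
                           windows_per_class = 30L, separation = 12,
                           noise = 0.5, seed = 42L) {
  generate_stream_data(synthetic_spec(
    n_classes = n_classes, channels = channels, window_len = window_len,
    class_separation = separation, noise_sigma = noise,
    windows_per_class = windows_per_class, train_fraction = 2 / 3,
    seed = seed))
}

# Brute-force per-class mean embedding (independent of prototype code).
naive_class_means <- function(embeddings, labels) {
  out <- list()
  for (k in sort(unique(labels))) {
    rows <- embeddings[labels == k, , drop = FALSE]
    m <- numeric(ncol(rows))
    for (i in seq_len(nrow(rows))) m <- m + rows[i, ]
    out[[as.character(k)]] <- m / nrow(rows)
  }
  out
}
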