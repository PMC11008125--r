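# Trained models are expensive; train each once per session and share.
.model_cache <- new.env(parent = emptyenv())

# Small model for unit tests: easy, well-separated patch set.
tiny_fit <- function() {
  if (is.null(.model_cache$tiny)) {
    ds <- sample_patch_dataset(120, patch_size = 64, seed = 101)
    model <- build_cnn(input_size = 64, seed = 102)
    .model_cache$tiny <- list(
      fit = train_cnn(model, ds$x, ds$y,
                      config = train_config(epochs = 3, seed = 103)),
      data = ds)
  }
  .model_cache$tiny
}

# Full-scale surrogate model: 2000 patches/class at 64 x 64.
acceptance_fit <- function() {
  if (is.null(.model_cache$acc)) {
    ds <- sample_patch_dataset(2000, patch_size = 64, seed = 201)
    model <- build_cnn(input_size = 64, seed = 202)
    .model_cache$acc <- list(
      fit = train_cnn(model, ds$x, ds$y,
                      config = train_config(epochs = 3, seed = 203)),
      data = ds)
  }
  .model_cache$acc
}
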