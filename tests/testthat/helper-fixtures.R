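# Shared fixtures, generated once per test session and memoised.

.fixture_env <- new.env(parent = emptyenv())

# A small corpus for exercising the end-to-end plumbing quickly.
tiny_corpus <- function() {
  if (is.null(.fixture_env$tiny)) {
    cfg <- generator_config(n_subjects = 8, prevalence = 0.5, effect_size = 2,
                            frames_per_clip = 4, frame_size = c(32, 32),
                            clip_seconds = 0.5, seed = 101)
    dir <- file.path(tempdir(), "mmdep-tiny")
    man <- generate_corpus(cfg, dir, overwrite = TRUE)
    .fixture_env$tiny <- list(cfg = cfg, manifest = man,
                              data = prepare_corpus_data(man))
  }
  .fixture_env$tiny
}

toy_tsnet_cfg <- function(...) {
  tsnet_config(base_channels = 4, attention_reduction = 2, sam_kernel = 3,
               feature_dim = 8, ...)
}

# Random small audio graph with given node count and feature dimension.
rand_graph <- function(n, d = 5, threshold = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  build_graph(matrix(rnorm(n * d), n, d), threshold = threshold)
}

rand_clip_batch <- function(n = 2, c = 1, t = 4, h = 32, w = 32, sd = 0.5) {
  array(rnorm(n * c * t * h * w, sd = sd), c(n, c, t, h, w))
}
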