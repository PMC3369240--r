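# Shared fixtures, built in code. The corpus/feature caches let several
# test files reuse the same deterministic synthetic data without repeating
# the expensive extraction.

.wpse_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .wpse_cache)) {
    assign(key, force(expr), envir = .wpse_cache)
  }
  get(key, envir = .wpse_cache)
}

# small balanced corpus + features used across stats/classifier tests
small_corpus <- function() {
  cached("small_corpus", generate_corpus(
    c(healthy = 8, qi_deficiency = 8, yin_deficiency = 8), seed = 2024
  ))
}

small_features <- function() {
  cached("small_features", batch_extract(small_corpus()))
}

# deterministic multi-sine + noise test signal
test_signal <- function(n = 4096, fs = 16000, seed = 1) {
  set.seed(seed)
  t <- (0:(n - 1)) / fs
  sin(2 * pi * 440 * t) + 0.5 * sin(2 * pi * 1800 * t) + 0.2 * rnorm(n)
}

# Gaussian feature table under the null: identical distribution in all
# groups, `n_bands` band columns, group sizes as named vector
null_feature_table <- function(n_per_group, n_bands, seed = 1) {
  set.seed(seed)
  groups <- rep(names(n_per_group), times = n_per_group)
  n <- length(groups)
  vals <- matrix(rnorm(n * n_bands), nrow = n)
  colnames(vals) <- band_key(5, (seq_len(n_bands) - 1) * 250,
                             seq_len(n_bands) * 250)
  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("N%04d", seq_len(n)), group = groups),
    tibble::as_tibble(vals)
  )
}
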