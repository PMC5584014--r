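# Small in-code fixtures shared across test files.

# tiny deterministic spectra set: n samples on a p-point descending axis
tiny_spectra <- function(n = 5, p = 20, seed = 42) {
  set.seed(seed)
  spectra_set(matrix(rnorm(n * p, mean = 0.5, sd = 0.1), n, p),
              seq(9000, 5000, length.out = p),
              sprintf("T%02d", seq_len(n)))
}

# tiny valid reference table
tiny_reference <- function(n = 5, seed = 42) {
  set.seed(seed)
  cls <- rep(c("sweet", "biomass"), length.out = n)
  s <- runif(n, 10, 40); c_ <- runif(n, 15, 25); h <- runif(n, 10, 20)
  l <- runif(n, 3, 8); a <- runif(n, 2, 5)
  reference_table(data.frame(
    sample_id = sprintf("T%02d", seq_len(n)), class = cls,
    soluble_sugar = s, cellulose = c_, hemicellulose = h,
    lignin = l, ash = a, tey = tey_total(s, c_, h)))
}

# planted-signal regression instance: y depends only on variables 10:12
planted_instance <- function(n = 60, p = 200, noise_sd = 0.01, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rowSums(X[, 10:12, drop = FALSE]) + rnorm(n, 0, noise_sd)
  list(X = X, y = y, informative = 10:12)
}

# minimal selection_result-compatible object for consensus tests
selection_result_for_test <- function(method, p, selected) {
  structure(list(method = method, scores = rep(0, p), threshold = NA_real_,
                 selected = as.integer(selected), diagnostics = list()),
            class = "selection_result")
}

# default-condition synthetic dataset, cached per (seed, noise kind) so
# multiple test files can reuse the expensive 147 x 1557 generation
.synth_cache <- new.env(parent = emptyenv())
cached_synthetic <- function(seed = 1, zero_noise_flag = FALSE) {
  key <- paste0("s", seed, "_", zero_noise_flag)
  if (is.null(.synth_cache[[key]])) {
    cfg <- pipeline_config(seed = seed)
    .synth_cache[[key]] <- synthetic_dataset(
      cfg, noise = if (zero_noise_flag) zero_noise() else cfg$noise)
  }
  .synth_cache[[key]]
}
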