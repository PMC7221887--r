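# Shared fixtures, built in code.

# tiny uniform grid for fast unit tests
tiny_grid <- function(n = 10, start = 0, width = 0.1)
  bucket_grid(start, start + n * width, width, drop_terminal = FALSE)

# random non-negative bucket_set with reproducible values
random_set <- function(n_samples, grid = tiny_grid(), seed = 1,
                       normalized = "raw") {
  set.seed(seed)
  bucket_set(matrix(stats::rexp(n_samples * grid$n_buckets),
                    nrow = n_samples),
             grid, sample_ids = sprintf("s%02d", seq_len(n_samples)),
             normalized = normalized)
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# best cosine match of each true spectrum among fitted rows
match_cosines <- function(true_spectra, BT)
  apply(abs(true_spectra %*% t(BT)) /
          outer(sqrt(rowSums(true_spectra^2)), sqrt(rowSums(BT^2))), 1L, max)
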