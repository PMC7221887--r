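test_that("the default grid reproduces the 154-bucket layout", {
  g <- bucket_grid()
  expect_equal(g$n_buckets, 154L)
  expect_equal(g$centers[1], 0.475)
  expect_equal(g$centers[154], 8.125)
  # without the terminal-interval rule the range holds one more bucket
  expect_equal(bucket_grid(drop_terminal = FALSE)$n_buckets, 155L)
})

test_that("invalid grids are rejected", {
  expect_error(bucket_grid(width = 0), "positive")
  expect_error(bucket_grid(width = -0.05), "positive")
  expect_error(bucket_grid(start_ppm = 2, end_ppm = 1), "smaller")
})

test_that("bucket_set validates shape, ids and finiteness", {
  g <- tiny_grid(3)
  expect_error(bucket_set(matrix(1, 2, 4), g), "3 buckets")
  expect_error(bucket_set(matrix(1, 2, 3), g, sample_ids = c("a", "a")),
               "duplicate")
  expect_error(bucket_set(matrix(c(1, NA, 1, 1, 1, 1), 2), g,
                          sample_ids = c("a", "b")), "non-finite")
})

test_that("bucket tables round-trip bit-identically through CSV", {
  g <- tiny_grid(3, start = 0.45, width = 0.05)
  x <- bucket_set(matrix(c(pi, 1/3, exp(1), sqrt(2), 2/7, 1e-17), 2,
                         byrow = TRUE),
                  g, sample_ids = c("a", "b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_bucket_table(x, path)
  y <- read_bucket_table(path)
  expect_identical(y$matrix, x$matrix)
  expect_identical(y$sample_ids, x$sample_ids)
  expect_equal(y$grid$centers, x$grid$centers, tolerance = 1e-12)
})

test_that("grid width is inferred from header spacing", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,0.475,0.525,0.575", "a,1,2,3"), path)
  expect_equal(read_bucket_table(path)$grid$width, 0.05)
})

test_that("a generated 82 x 154 table reads back with its shape and order", {
  ds <- generate_paired_dataset(n_train = 82, n_test = 1, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_bucket_table(ds$train, path)
  y <- read_bucket_table(path)
  expect_equal(dim(y$matrix), c(82L, 154L))
  # reader preserves file order of samples and buckets
  expect_identical(y$sample_ids, ds$train$sample_ids)
  expect_identical(colnames(y$matrix), colnames(ds$train$matrix))
})

test_that("malformed tables fail with located errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,0.05,0.15", "a,1,2", "b,3"), path)
  expect_error(read_bucket_table(path), "line 3")
  writeLines(c("sample_id,0.05,0.15", "a,1,x"), path)
  expect_error(read_bucket_table(path), "row 1, column 2")
  writeLines(c("sample_id,0.05,0.15,0.30", "a,1,2,3"), path)
  expect_error(read_bucket_table(path), "not uniformly spaced")
})

test_that("component libraries round-trip and are validated on read", {
  g <- bucket_grid()
  set.seed(4)
  S <- matrix(runif(2 * 154), 2)
  S <- S / sqrt(rowSums(S^2))
  lib <- component_library(S, g, labels = c("Macro 1", "Macro 2"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_component_library(lib, path)
  back <- read_component_library(path)
  expect_identical(back$spectra, lib$spectra)
  expect_identical(back$labels, lib$labels)

  # negative entry rejected
  txt <- readLines(path)
  bad <- sub("^Macro 1,[0-9.eE+-]+", "Macro 1,-0.1", txt[2])
  writeLines(c(txt[1], bad, txt[3]), path)
  expect_error(read_component_library(path), "non-negative")

  # a row scaled by 2 violates unit norm
  write_component_library(lib, path)
  txt <- readLines(path)
  fields <- strsplit(txt[2], ",")[[1]]
  scaled <- paste(c(fields[1], sprintf("%.17g", 2 * as.numeric(fields[-1]))),
                  collapse = ",")
  writeLines(c(txt[1], scaled, txt[3]), path)
  expect_error(read_component_library(path), "unit Euclidean norm")
})

test_that("selection reports round-trip through JSON", {
  x <- random_set(6, tiny_grid(12), seed = 9)
  rep <- scan_components(x, k_max = 2, n_restarts = 2, max_iter = 50,
                         keep_models = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  write_selection_report(rep, path)
  back <- read_selection_report(path)
  expect_equal(back$k_values, rep$k_values)
  expect_equal(back$rss_by_k, rep$rss_by_k)
  expect_equal(back$dw_matrix, rep$dw_matrix)
  expect_equal(back$dw_flagged, rep$dw_flagged)
  expect_equal(back$rss_threshold, rep$rss_threshold)
})

test_that("distribution matrices round-trip through CSV", {
  g <- tiny_grid(8)
  set.seed(21)
  S <- matrix(runif(2 * 8), 2); S <- S / sqrt(rowSums(S^2))
  lib <- component_library(S, g)
  x <- random_set(5, g, seed = 22, normalized = "pqn")
  d <- decompose_spectra(x, lib)
  path <- withr::local_tempfile(fileext = ".csv")
  write_distribution_matrix(d, path)
  back <- read_distribution_matrix(path, g)
  expect_identical(back$values, d$values)
  expect_identical(back$residual_norm, d$residual_norm)
  expect_identical(back$component_labels, d$component_labels)
})

test_that("raw spectra enforce monotone finite axes", {
  expect_error(raw_spectrum("a", c(1, 1, 2), c(0, 0, 0)), "monotone")
  expect_error(raw_spectrum("a", c(1, 2), c(0, Inf)), "finite")
  # descending (display-convention) input is stored ascending
  s <- raw_spectrum("a", c(3, 2, 1), c(10, 20, 30))
  expect_equal(s$ppm, c(1, 2, 3))
  expect_equal(s$intensity, c(30, 20, 10))
})
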