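test_that("bucketing the default grid yields 154 values", {
  ppm <- seq(0.3, 8.4, by = 0.001)
  s <- raw_spectrum("a", ppm, exp(-(ppm - 4)^2))
  v <- bucket_spectrum(s, bucket_grid())
  expect_length(v, 154L)
})

test_that("a constant spectrum buckets to c * width everywhere", {
  g <- tiny_grid(5, start = 1, width = 0.2)
  ppm <- seq(0.8, 2.4, by = 0.01)
  v <- bucket_spectrum(raw_spectrum("a", ppm, rep(2.5, length(ppm))), g)
  expect_equal(unname(v), rep(2.5 * 0.2, 5), tolerance = 1e-12)
})

test_that("a narrow unit-area peak lands in its bucket and area is conserved", {
  g <- bucket_grid()
  center <- g$centers[60]  # middle of bucket 60
  sigma <- 0.004           # far below the 0.05 ppm width
  ppm <- seq(0.3, 8.4, by = 5e-5)  # ~100x bucket resolution
  intens <- stats::dnorm(ppm, center, sigma)
  v <- bucket_spectrum(raw_spectrum("a", ppm, intens), g)
  expect_gt(v[60], 0.999)
  expect_lt(max(v[-60]), 1e-3)
  # total integral over the covered grid matches fine quadrature
  grid_lo <- g$start_ppm; grid_hi <- g$start_ppm + g$n_buckets * g$width
  inside <- ppm >= grid_lo & ppm <= grid_hi
  oracle <- sum(diff(ppm[inside]) *
                (intens[inside][-1] + intens[inside][-sum(inside)]) / 2)
  expect_equal(sum(v), oracle, tolerance = 1e-6)
})

test_that("bucketing is linear and conserves the covered integral", {
  g <- tiny_grid(20, start = 0, width = 0.05)
  ppm <- seq(-0.1, 1.1, by = 0.002)
  set.seed(5)
  f <- abs(stats::rnorm(length(ppm))) + sin(ppm * 6)^2
  h <- exp(-(ppm - 0.5)^2 / 0.01)
  va <- bucket_spectrum(raw_spectrum("f", ppm, f), g)
  vb <- bucket_spectrum(raw_spectrum("h", ppm, h), g)
  vab <- bucket_spectrum(raw_spectrum("fh", ppm, 2.5 * f + 0.7 * h), g)
  expect_equal(unname(vab), unname(2.5 * va + 0.7 * vb), tolerance = 1e-9)
  # conservation: sum of buckets = trapezoid integral over [0, 1]
  inside <- ppm >= 0 & ppm <= 1
  oracle <- sum(diff(ppm[inside]) * (f[inside][-1] + f[inside][-sum(inside)]) / 2)
  expect_equal(sum(va), oracle, tolerance = 1e-6 * abs(oracle))
})

test_that("bucketing rejects spectra that do not cover the grid", {
  g <- bucket_grid()
  ppm <- seq(1, 5, by = 0.01)
  expect_error(bucket_spectrum(raw_spectrum("a", ppm, ppm * 0 + 1), g),
               "does not cover")
})

test_that("PQN of a single sample is the identity with factor 1", {
  x <- random_set(1, seed = 3)
  r <- pqn_normalize(x)
  expect_equal(unname(r$dilution_factors), 1)
  expect_equal(r$normalized$matrix, x$matrix)
  expect_identical(r$normalized$normalized, "pqn")
})

test_that("PQN removes a pure dilation and reports proportional factors", {
  g <- tiny_grid(9)
  set.seed(2)
  base <- abs(stats::rnorm(9)) + 0.5
  x <- bucket_set(rbind(base, 3 * base), g, sample_ids = c("a", "b"))
  r <- pqn_normalize(x)
  expect_equal(unname(r$dilution_factors[2] / r$dilution_factors[1]), 3,
               tolerance = 1e-12)
  expect_equal(unname(r$normalized$matrix[1, ]),
               unname(r$normalized$matrix[2, ]), tolerance = 1e-12)
})

test_that("every normalized row has median quotient 1 against the reference", {
  x <- random_set(10, bucket_grid(), seed = 8)
  r <- pqn_normalize(x)
  eps <- 1e-12 * max(r$reference)
  sup <- r$reference > eps
  for (i in 1:10) {
    q <- r$normalized$matrix[i, sup] / r$reference[sup]
    expect_equal(stats::median(q), 1, tolerance = 1e-9)
  }
})

test_that("PQN is idempotent on dilution-model data and with a fixed reference", {
  g <- tiny_grid(15)
  set.seed(12)
  base <- abs(stats::rnorm(15)) + 0.2
  fac <- stats::rlnorm(8, 0, 0.5)
  x <- bucket_set(outer(fac, base), g)
  once <- pqn_normalize(x)
  twice <- pqn_normalize(once$normalized)
  expect_lt(max(abs(twice$normalized$matrix - once$normalized$matrix)), 1e-9)
  # arbitrary data, external (fixed) reference
  y <- random_set(6, g, seed = 13)
  ref <- apply(y$matrix, 2, stats::median)
  r1 <- pqn_normalize(y, "external", external_reference = ref)
  r2 <- pqn_normalize(r1$normalized, "external", external_reference = ref)
  expect_lt(max(abs(r2$normalized$matrix - r1$normalized$matrix)), 1e-9)
  expect_equal(unname(r2$dilution_factors), rep(1, 6), tolerance = 1e-12)
})

test_that("PQN rejects unusable references", {
  g <- tiny_grid(4)
  x <- bucket_set(matrix(1, 2, 4), g, sample_ids = c("a", "b"))
  expect_error(pqn_normalize(x, "external", external_reference = rep(0, 4)),
               "no support")
  expect_error(pqn_normalize(x, "external", external_reference = rep(1, 3)),
               "length")
  # sample with zero overlap on the reference support gets a named error
  y <- bucket_set(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)), g,
                  sample_ids = c("ok", "bad"))
  expect_error(pqn_normalize(y, "external",
                             external_reference = c(1, 1, 0, 0)), "bad")
})
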