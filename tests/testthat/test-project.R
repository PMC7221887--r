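make_library <- function(grid, seed = 1, k = 2) {
  set.seed(seed)
  S <- matrix(stats::runif(k * grid$n_buckets), k)
  component_library(S / sqrt(rowSums(S^2)), grid)
}

test_that("a consistent non-negative system is recovered exactly", {
  g <- bucket_grid()
  lib <- make_library(g, seed = 2)
  set.seed(3)
  D0 <- matrix(stats::rlnorm(8 * 2), 8)
  S <- bucket_set(D0 %*% lib$spectra, g, normalized = "pqn")
  d <- decompose_spectra(S, lib)
  expect_equal(unname(d$values), D0, tolerance = 1e-8)
  expect_lt(max(d$residual_norm), 1e-6)
})

test_that("an all-zero sample yields zero intensities and a flagged residual", {
  g <- tiny_grid(12)
  lib <- make_library(g, seed = 4)
  M <- rbind(2 * lib$spectra[1, ], 0)
  S <- bucket_set(M, g, sample_ids = c("a", "zero"), normalized = "pqn")
  d <- decompose_spectra(S, lib)
  expect_equal(unname(d$values[2, ]), c(0, 0))
  expect_true(is.na(d$residual_norm[2]))
  expect_identical(d$zero_samples, "zero")
})

test_that("per-sample NNLS beats an exhaustive grid-search oracle", {
  g <- bucket_grid()
  lib <- make_library(g, seed = 5)
  set.seed(6)
  D0 <- matrix(stats::runif(5 * 2, 0.5, 4), 5)
  S <- bucket_set(D0 %*% lib$spectra +
                    matrix(stats::rnorm(5 * 154, 0, 0.02), 5),
                  g, normalized = "pqn")
  S$matrix <- pmax(S$matrix, 0)
  d <- decompose_spectra(S, lib)
  C <- lib$spectra
  G <- C %*% t(C)
  grid_vals <- seq(0, 5, by = 0.01)
  for (i in 1:5) {
    s <- S$matrix[i, ]
    cs <- as.vector(C %*% s)
    # objective ||s - d C||^2 = ||s||^2 - 2 d.cs + d' G d on the grid
    o <- outer(grid_vals^2 * G[1, 1] - 2 * grid_vals * cs[1],
               grid_vals^2 * G[2, 2] - 2 * grid_vals * cs[2], "+") +
      2 * G[1, 2] * outer(grid_vals, grid_vals)
    best_grid <- min(o) + sum(s^2)
    obj_nnls <- sum((s - d$values[i, ] %*% C)^2)
    expect_lte(obj_nnls, best_grid + 1e-9)
    # within the objective resolution of the half-spacing grid displacement
    expect_lte(best_grid - obj_nnls,
               2 * sum(G^2)^0.5 * (0.005)^2 + 1e-9)
  }
})

test_that("least-squares homogeneity: scaling a sample scales its loadings", {
  g <- tiny_grid(30)
  lib <- make_library(g, seed = 7)
  set.seed(8)
  s <- abs(stats::rnorm(30))
  S <- bucket_set(rbind(s, 2 * s), g, sample_ids = c("x", "x2"),
                  normalized = "pqn")
  d <- decompose_spectra(S, lib)
  expect_equal(unname(d$values[2, ]), unname(2 * d$values[1, ]))
  expect_equal(d$residual_norm[1], d$residual_norm[2], tolerance = 1e-9)
})

test_that("the decomposition never does worse than predicting nothing", {
  g <- tiny_grid(40)
  lib <- make_library(g, seed = 9, k = 3)
  x <- random_set(15, g, seed = 10, normalized = "pqn")
  d <- decompose_spectra(x, lib)
  for (i in 1:15) {
    obj <- sum((x$matrix[i, ] - d$values[i, ] %*% lib$spectra)^2)
    expect_lte(obj, sum(x$matrix[i, ]^2) + 1e-12)
  }
  expect_true(all(d$values >= 0))
  expect_true(all(d$residual_norm >= 0 & d$residual_norm <= 100))
})

test_that("unconstrained mode solves the normal equations", {
  g <- tiny_grid(25)
  lib <- make_library(g, seed = 11)
  x <- random_set(6, g, seed = 12, normalized = "pqn")
  d <- decompose_spectra(x, lib, constraint = "unconstrained")
  ref <- t(solve(lib$spectra %*% t(lib$spectra),
                 lib$spectra %*% t(x$matrix)))
  expect_equal(unname(d$values), unname(ref), tolerance = 1e-10)
})

test_that("grid mismatches and raw inputs are caught", {
  g <- bucket_grid()
  lib <- make_library(g)
  shifted <- bucket_grid(start_ppm = 0.46)
  x <- bucket_set(matrix(1, 2, 154), shifted, sample_ids = c("a", "b"),
                  normalized = "pqn")
  expect_error(decompose_spectra(x, lib), "center differs")
  y <- random_set(2, g, seed = 14)  # normalized = "raw"
  expect_warning(decompose_spectra(y, lib), "not normalized")
})

test_that("cosine annotation behaves on the canonical cases", {
  v <- c(1, 2, 3, 0)
  expect_equal(annotate_component(v, v), 1)
  expect_equal(annotate_component(c(1, 0, 0, 0), c(0, 1, 0, 0)), 0)
  set.seed(15)
  comp <- make_macromolecule_spectrum(bucket_grid(), "lipid_like", seed = 3)
  noisy <- pmax(comp + stats::rnorm(154, 0, 0.01 * mean(comp)), 0)
  expect_gte(annotate_component(comp, noisy), 0.99)
  expect_error(annotate_component(rep(0, 4), v), "zero-norm")
  expect_error(annotate_component(v, c(1, 2)), "same bucket grid")
})

test_that("group comparison reproduces closed-form descriptives and exact tests", {
  g <- tiny_grid(5)
  lib <- make_library(g, seed = 16, k = 1)
  vals <- c(2, 4, 6, 101, 102, 103)
  S <- bucket_set(outer(vals, lib$spectra[1, ]), g,
                  sample_ids = sprintf("s%d", 1:6), normalized = "pqn")
  d <- decompose_spectra(S, lib)
  groups <- stats::setNames(rep(c("low", "high"), each = 3), S$sample_ids)
  gs <- group_compare(d, groups, test = "wilcoxon_rank_sum")
  low <- gs$summary[gs$summary$group == "low", ]
  expect_equal(low$n, 3)
  expect_equal(low$mean, 4)
  expect_equal(low$se, stats::sd(c(2, 4, 6)) / sqrt(3))
  expect_equal(low$se, 1.1547005, tolerance = 1e-6)
  # fully separated ranks, n = 3 vs 3: exact two-sided p = 2/20 = 0.1
  expect_equal(gs$tests$p_value, 0.1)
  expect_false(gs$tests$significant)
})

test_that("identical groups give p = 1 and Welch mode is available", {
  g <- tiny_grid(5)
  lib <- make_library(g, seed = 17, k = 1)
  vals <- c(1, 2, 3, 1, 2, 3)
  S <- bucket_set(outer(vals, lib$spectra[1, ]), g,
                  sample_ids = sprintf("s%d", 1:6), normalized = "pqn")
  d <- decompose_spectra(S, lib)
  groups <- stats::setNames(rep(c("a", "b"), each = 3), S$sample_ids)
  expect_equal(group_compare(d, groups)$tests$p_value, 1)
  expect_equal(group_compare(d, groups, test = "welch_t")$tests$p_value, 1)
})

test_that("group mapping is validated and >2 groups yield descriptives only", {
  g <- tiny_grid(5)
  lib <- make_library(g, seed = 18, k = 1)
  x <- random_set(6, g, seed = 19, normalized = "pqn")
  d <- decompose_spectra(x, lib)
  expect_error(group_compare(d, c(s01 = "a")), "unmapped")
  groups <- stats::setNames(rep(c("a", "b", "c"), 2), x$sample_ids)
  gs <- group_compare(d, groups)
  expect_null(gs$tests)
  expect_equal(sum(gs$summary$n), 6)
})
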