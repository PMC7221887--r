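# Decomposition of a large conventional-NMR bucket matrix S onto a frozen
# pure-spectra library C: per sample, d = argmin_{d >= 0} ||s - d %*% C||^2.
# Sharp small-molecule signal is deliberately NOT masked beforehand; it lands
# in the residual, whose per-sample relative norm is reported.

new_distribution_matrix <- function(values, sample_ids, component_labels,
                                    residual_norm, grid) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(sample_ids, component_labels)
  structure(list(values = values, sample_ids = as.character(sample_ids),
                 component_labels = as.character(component_labels),
                 residual_norm = as.numeric(residual_norm), grid = grid),
            class = "distribution_matrix")
}

#' Decompose a spectral matrix onto a frozen component library
#'
#' Solves, for every sample row `s_i` of `S`, the per-sample least-squares
#' problem `min ||s_i - d_i %*% C||^2` over the component intensities `d_i`,
#' non-negatively constrained by default (`"unconstrained"` uses the normal
#' equations).  The per-sample relative residual norm
#' `100 * ||s_i - d_i %*% C|| / ||s_i||` is recorded; with a conventional-NMR
#' input it mostly measures the sharp small-molecule signal that the
#' macromolecule library cannot (and should not) explain.  All-zero sample
#' rows get `d_i = 0` and a flagged (missing) residual norm.  Samples whose
#' residual norm exceeds 99% are flagged in `high_residual`, not dropped.
#'
#' @param S A [bucket_set()]; its grid must match the library grid (bucket
#'   centers within 1e-6 ppm).  A warning is issued if `S` is not
#'   PQN-normalized.
#' @param C A [component_library()].
#' @param constraint `"nonneg"` (default) or `"unconstrained"`.
#' @return An object of class `distribution_matrix`: `values`
#'   (samples x k, Matrix D), `sample_ids`, `component_labels`,
#'   `residual_norm` (percent, NA for all-zero samples), `grid`, plus
#'   attribute-like fields `zero_samples` and `high_residual`.
#' @export
decompose_spectra <- function(S, C, constraint = c("nonneg", "unconstrained")) {
  stopifnot(inherits(S, "bucket_set"), inherits(C, "component_library"))
  constraint <- match.arg(constraint)
  if (S$grid$n_buckets != C$grid$n_buckets)
    stop(sprintf("grid mismatch: data has %d buckets, library %d",
                 S$grid$n_buckets, C$grid$n_buckets), call. = FALSE)
  dev <- abs(S$grid$centers - C$grid$centers)
  if (max(dev) > 1e-6) {
    j <- which(dev > 1e-6)[1L]
    stop(sprintf(
      "grid mismatch: bucket %d center differs (%.6f vs %.6f ppm)",
      j, S$grid$centers[j], C$grid$centers[j]), call. = FALSE)
  }
  if (S$normalized == "raw")
    warning("S is not normalized; decomposing raw intensities mixes dilution into Matrix D",
            call. = FALSE)
  M <- S$matrix
  D_design <- t(C$spectra)                       # buckets x k
  if (constraint == "unconstrained" &&
      qr(D_design)$rank < ncol(D_design))
    stop("component library is rank deficient; unconstrained solve is not unique",
         call. = FALSE)
  zero <- rowSums(M != 0) == 0
  Dm <- matrix(0, nrow(M), nrow(C$spectra))
  if (any(!zero))
    Dm[!zero, ] <- t(nnls_multi(D_design, t(M[!zero, , drop = FALSE]),
                                nonneg = constraint == "nonneg"))
  resid <- M - Dm %*% C$spectra
  rn <- 100 * sqrt(rowSums(resid^2)) / sqrt(rowSums(M^2))
  rn[zero] <- NA_real_
  out <- new_distribution_matrix(Dm, S$sample_ids, C$labels, rn, S$grid)
  out$zero_samples <- S$sample_ids[zero]
  out$high_residual <- S$sample_ids[!is.na(rn) & rn > 99]
  out
}

#' @export
print.distribution_matrix <- function(x, ...) {
  cat(sprintf(
    "<distribution_matrix> %d samples x %d components (%s); median residual norm %.3g%%\n",
    nrow(x$values), ncol(x$values), paste(x$component_labels, collapse = ", "),
    stats::median(x$residual_norm, na.rm = TRUE)))
  if (length(x$high_residual))
    cat(" flagged (residual > 99%):", paste(x$high_residual, collapse = ", "),
        "\n")
  invisible(x)
}

#' Cosine similarity between a component and a reference spectrum
#'
#' Used to annotate mathematically extracted components against measured
#' reference spectra (e.g. a fish-oil reference for a lipid-like component,
#' a collagen reference for a polypeptide-like one) on the same bucket grid.
#'
#' @param component Numeric vector (a library row), non-zero.
#' @param reference Numeric vector on the same grid, non-zero.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
annotate_component <- function(component, reference) {
  component <- as.numeric(component); reference <- as.numeric(reference)
  if (length(component) != length(reference))
    stop("component and reference must be on the same bucket grid",
         call. = FALSE)
  nc <- sqrt(sum(component^2)); nr <- sqrt(sum(reference^2))
  if (nc == 0 || nr == 0)
    stop("cosine similarity is undefined for a zero-norm spectrum",
         call. = FALSE)
  sum(component * reference) / (nc * nr)
}

#' Similarity of every library component to every reference spectrum
#'
#' @param lib A [component_library()].
#' @param references Matrix of reference spectra (rows) on the same grid,
#'   with rownames as reference labels.
#' @return Matrix of cosine similarities, components x references.
#' @export
annotate_components <- function(lib, references) {
  stopifnot(inherits(lib, "component_library"))
  references <- as.matrix(references)
  out <- matrix(NA_real_, nrow(lib$spectra), nrow(references),
                dimnames = list(lib$labels, rownames(references)))
  for (i in seq_len(nrow(lib$spectra)))
    for (j in seq_len(nrow(references)))
      out[i, j] <- annotate_component(lib$spectra[i, ], references[j, ])
  out
}

#' Summarize and compare macromolecule intensities across sample groups
#'
#' Per component and group: n, mean, standard error, median and quartiles.
#' With exactly two groups a two-sample test is run per component
#' (Wilcoxon rank-sum by default, exact where the sample sizes permit and
#' ties are absent; Welch's t as the alternative), with a significance flag
#' at p < 0.05.  With more than two groups only descriptives are returned.
#'
#' @param D A `distribution_matrix` from [decompose_spectra()].
#' @param groups Either a named character vector (`sample_id -> label`) or a
#'   two-column data frame `(sample_id, label)`.  Every sample in `D` must
#'   be mapped.
#' @param test `"wilcoxon_rank_sum"` (default) or `"welch_t"`.
#' @return An object of class `group_summary` with `summary` (data frame of
#'   per-group descriptives), `tests` (data frame of per-component test
#'   results, or `NULL` for > 2 groups) and `test`.
#' @export
group_compare <- function(D, groups,
                          test = c("wilcoxon_rank_sum", "welch_t")) {
  stopifnot(inherits(D, "distribution_matrix"))
  test <- match.arg(test)
  if (is.data.frame(groups)) {
    if (ncol(groups) < 2L)
      stop("groups data frame needs columns (sample_id, label)", call. = FALSE)
    map <- stats::setNames(as.character(groups[[2L]]),
                           as.character(groups[[1L]]))
  } else map <- groups
  missing_ids <- setdiff(D$sample_ids, names(map))
  if (length(missing_ids))
    stop("unmapped sample ID(s): ",
         paste(utils::head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  lab <- factor(unname(map[D$sample_ids]))
  levs <- levels(lab)
  if (length(levs) < 2L)
    stop("need at least two groups", call. = FALSE)
  se <- function(v) stats::sd(v) / sqrt(length(v))
  rows <- list()
  for (comp in D$component_labels) {
    v <- D$values[, comp]
    for (g in levs) {
      vg <- v[lab == g]
      rows[[length(rows) + 1L]] <- data.frame(
        component = comp, group = g, n = length(vg), mean = mean(vg),
        se = se(vg), median = stats::median(vg),
        q1 = unname(stats::quantile(vg, 0.25)),
        q3 = unname(stats::quantile(vg, 0.75)),
        stringsAsFactors = FALSE)
    }
  }
  summary_df <- do.call(rbind, rows)
  tests <- NULL
  if (length(levs) == 2L) {
    n_by_group <- table(lab)
    if (any(n_by_group < 2L))
      stop("each group needs at least two samples for testing", call. = FALSE)
    trows <- lapply(D$component_labels, function(comp) {
      a <- D$values[lab == levs[1L], comp]
      b <- D$values[lab == levs[2L], comp]
      ht <- if (test == "wilcoxon_rank_sum")
        suppressWarnings(stats::wilcox.test(a, b))
      else stats::t.test(a, b)  # Welch by default
      data.frame(component = comp, statistic = unname(ht$statistic),
                 p_value = ht$p.value, significant = ht$p.value < 0.05,
                 stringsAsFactors = FALSE)
    })
    tests <- do.call(rbind, trows)
  }
  structure(list(summary = summary_df, tests = tests, test = test,
                 groups = levs),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> groups: %s\n", paste(x$groups, collapse = ", ")))
  print(x$summary, row.names = FALSE, digits = 4)
  if (!is.null(x$tests)) {
    cat(sprintf("two-group test: %s\n", x$test))
    print(x$tests, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
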