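#' Chemical-shift bucket grid
#'
#' Defines a uniform bucketing of the chemical-shift axis into fixed-width
#' intervals ("buckets").  Buckets are half-open intervals
#' \code{[lo, lo + width)} ordered by ascending ppm; a bucket is identified by
#' its center, printed with four decimals.  The number of intervals implied by
#' the range is \code{floor((end_ppm - start_ppm)/width + 0.5)};
#' \code{drop_terminal = TRUE} discards the final interval, which with the
#' defaults (0.45--8.20 ppm, 0.05 ppm width) gives the conventional 154-column
#' bucket matrix used throughout this package.
#'
#' @param start_ppm Lower edge of the bucketed region (ppm).
#' @param end_ppm Upper edge of the bucketed region (ppm).
#' @param width Bucket width (ppm), must be positive.
#' @param drop_terminal If `TRUE` (default), drop the last interval.
#' @return An object of class `bucket_grid` with fields `start_ppm`,
#'   `end_ppm`, `width`, `drop_terminal`, `n_buckets` and `centers`.
#' @examples
#' g <- bucket_grid()
#' g$n_buckets  # 154
#' @export
bucket_grid <- function(start_ppm = 0.45, end_ppm = 8.20, width = 0.05,
                        drop_terminal = TRUE) {
  stopifnot(is.numeric(start_ppm), is.numeric(end_ppm), is.numeric(width),
            length(start_ppm) == 1L, length(end_ppm) == 1L, length(width) == 1L,
            is.logical(drop_terminal), length(drop_terminal) == 1L)
  if (!is.finite(width) || width <= 0)
    stop("bucket width must be a positive finite number", call. = FALSE)
  if (!(start_ppm < end_ppm))
    stop("start_ppm must be smaller than end_ppm", call. = FALSE)
  n <- floor((end_ppm - start_ppm) / width + 0.5) - as.integer(drop_terminal)
  if (n < 1L)
    stop("grid defines no buckets; widen the ppm range or shrink the width",
         call. = FALSE)
  structure(
    list(start_ppm = start_ppm, end_ppm = end_ppm, width = width,
         drop_terminal = isTRUE(drop_terminal), n_buckets = as.integer(n),
         centers = start_ppm + (seq_len(n) - 0.5) * width),
    class = "bucket_grid")
}

#' @export
print.bucket_grid <- function(x, ...) {
  cat(sprintf("<bucket_grid> %d buckets of %.4g ppm over [%.4g, %.4g)%s\n",
              x$n_buckets, x$width, x$start_ppm, x$end_ppm,
              if (x$drop_terminal) ", terminal interval dropped" else ""))
  invisible(x)
}

#' Bucket identity labels (center ppm, 4 decimals)
#' @param grid A [bucket_grid()].
#' @return Character vector of bucket labels.
#' @export
bucket_labels <- function(grid) sprintf("%.4f", grid$centers)

# Reconstruct a grid from a vector of bucket centers (e.g. a CSV header).
# Spacing must be uniform within `tol` ppm.
grid_from_centers <- function(centers, tol = 1e-6) {
  if (length(centers) < 1L || anyNA(centers))
    stop("bucket centers must be numeric and non-missing", call. = FALSE)
  if (length(centers) == 1L)
    stop("cannot infer a bucket width from a single bucket center",
         call. = FALSE)
  d <- diff(centers)
  if (any(d <= 0))
    stop("bucket centers must be strictly increasing", call. = FALSE)
  width <- stats::median(d)
  if (max(abs(d - width)) > tol)
    stop(sprintf(
      "bucket centers are not uniformly spaced: spacing deviates by %.3g ppm (> %g)",
      max(abs(d - width)), tol), call. = FALSE)
  bucket_grid(start_ppm = centers[1L] - width / 2,
              end_ppm = centers[length(centers)] + width / 2,
              width = width, drop_terminal = FALSE)
}

# Same bucket centers within tol ppm?
grids_compatible <- function(g1, g2, tol = 1e-6) {
  g1$n_buckets == g2$n_buckets && max(abs(g1$centers - g2$centers)) <= tol
}

#' Full-resolution 1D spectrum
#'
#' A processed (Fourier-transformed, phased, baseline-corrected) spectrum as
#' paired chemical shift / intensity vectors.  The ppm axis must be strictly
#' monotone; descending axes (the NMR display convention) are stored
#' ascending.
#'
#' @param sample_id Sample identifier (single string).
#' @param ppm Numeric vector of chemical shifts, strictly monotone.
#' @param intensity Numeric vector of intensities, same length as `ppm`.
#' @return An object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(sample_id, ppm, intensity) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  ppm <- as.numeric(ppm); intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity))
    stop("ppm and intensity must have the same length", call. = FALSE)
  if (length(ppm) < 2L)
    stop("a spectrum needs at least two points", call. = FALSE)
  if (!all(is.finite(intensity)) || !all(is.finite(ppm)))
    stop("ppm and intensity must be finite", call. = FALSE)
  d <- diff(ppm)
  if (all(d < 0)) { ppm <- rev(ppm); intensity <- rev(intensity); d <- -rev(d) }
  if (any(d <= 0))
    stop("ppm axis must be strictly monotone", call. = FALSE)
  structure(list(sample_id = sample_id, ppm = ppm, intensity = intensity),
            class = "raw_spectrum")
}

#' Sample-by-bucket spectral matrix
#'
#' The central container: a samples x buckets intensity matrix on a
#' [bucket_grid()], with unique sample identifiers and a flag recording
#' whether probabilistic quotient normalization has been applied.  Rows are
#' samples; columns are buckets ordered by ascending ppm.
#'
#' @param mat Numeric matrix, samples in rows, buckets in columns.
#' @param grid A [bucket_grid()] whose `n_buckets` matches `ncol(mat)`.
#' @param sample_ids Character vector of unique sample IDs; defaults to
#'   `rownames(mat)`.
#' @param normalized Either `"raw"` or `"pqn"`.
#' @return An object of class `bucket_set` with fields `matrix`,
#'   `sample_ids`, `grid` and `normalized`.
#' @export
bucket_set <- function(mat, grid, sample_ids = rownames(mat),
                       normalized = c("raw", "pqn")) {
  normalized <- match.arg(normalized)
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  if (is.null(sample_ids))
    sample_ids <- sprintf("sample_%03d", seq_len(nrow(mat)))
  sample_ids <- as.character(sample_ids)
  if (!inherits(grid, "bucket_grid")) stop("grid must be a bucket_grid",
                                           call. = FALSE)
  if (ncol(mat) != grid$n_buckets)
    stop(sprintf("matrix has %d columns but the grid defines %d buckets",
                 ncol(mat), grid$n_buckets), call. = FALSE)
  if (nrow(mat) != length(sample_ids))
    stop("number of sample_ids must equal the number of rows", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(mat)))
    stop("bucket matrix contains non-finite values", call. = FALSE)
  dimnames(mat) <- list(sample_ids, bucket_labels(grid))
  structure(list(matrix = mat, sample_ids = sample_ids, grid = grid,
                 normalized = normalized),
            class = "bucket_set")
}

#' @export
print.bucket_set <- function(x, ...) {
  cat(sprintf("<bucket_set> %d samples x %d buckets (%s), %s\n",
              nrow(x$matrix), ncol(x$matrix),
              format(x$grid$width), x$normalized))
  invisible(x)
}

#' @export
dim.bucket_set <- function(x) dim(x$matrix)

#' Library of pure component spectra
#'
#' The frozen pure-spectra matrix produced by MCR-ALS peak separation: one
#' unit-Euclidean-norm, non-negative spectrum per component on a shared
#' bucket grid.  This is the matrix that later decomposes large
#' conventional-NMR datasets into per-sample macromolecule intensities.
#'
#' @param spectra Numeric k x buckets matrix, non-negative, each row with
#'   Euclidean norm 1 (tolerance 1e-9).
#' @param grid A [bucket_grid()] matching `ncol(spectra)`.
#' @param labels Character vector of k component labels; defaults to
#'   `"Macro 1"`, `"Macro 2"`, ...
#' @return An object of class `component_library`.
#' @export
component_library <- function(spectra, grid,
                              labels = sprintf("Macro %d", seq_len(nrow(spectra)))) {
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  if (nrow(spectra) < 1L) stop("library needs at least one component",
                               call. = FALSE)
  if (!inherits(grid, "bucket_grid")) stop("grid must be a bucket_grid",
                                           call. = FALSE)
  if (ncol(spectra) != grid$n_buckets)
    stop("spectra column count does not match the grid", call. = FALSE)
  if (length(labels) != nrow(spectra))
    stop("one label per component is required", call. = FALSE)
  if (!all(is.finite(spectra)) || any(spectra < 0))
    stop("component spectra must be finite and non-negative", call. = FALSE)
  norms <- sqrt(rowSums(spectra^2))
  if (any(abs(norms - 1) > 1e-9))
    stop(sprintf("component rows must have unit Euclidean norm (worst deviation %.3g)",
                 max(abs(norms - 1))), call. = FALSE)
  dimnames(spectra) <- list(as.character(labels), bucket_labels(grid))
  structure(list(spectra = spectra, labels = as.character(labels), grid = grid),
            class = "component_library")
}

#' @export
print.component_library <- function(x, ...) {
  cat(sprintf("<component_library> %d components x %d buckets: %s\n",
              nrow(x$spectra), ncol(x$spectra),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

# Coerce a bucket_set or matrix argument to a plain matrix.
as_bucket_matrix <- function(x) {
  if (inherits(x, "bucket_set")) x$matrix
  else { m <- as.matrix(x); storage.mode(m) <- "double"; m }
}
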