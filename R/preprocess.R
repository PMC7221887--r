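#' Reduce a full-resolution spectrum to a bucket grid
#'
#' Each bucket value is the integral of the intensity over the half-open
#' interval `[lo, lo + width)`, computed by the trapezoidal rule on the raw
#' points falling inside the interval with the interval endpoints linearly
#' interpolated.  The integral (rather than the mean) is used so that total
#' signal area is conserved under rebinning; bucketing is consequently linear
#' in the spectrum and conserves the integral over the covered range.
#'
#' @param raw A [raw_spectrum()] whose ppm range covers the grid.
#' @param grid A [bucket_grid()].
#' @return Numeric vector of length `grid$n_buckets`, named by bucket center.
#' @examples
#' g <- bucket_grid(0, 1, 0.25, drop_terminal = FALSE)
#' s <- raw_spectrum("a", seq(-0.1, 1.1, by = 0.001),
#'                   rep(2, length(seq(-0.1, 1.1, by = 0.001))))
#' bucket_spectrum(s, g)  # each bucket = 2 * 0.25
#' @export
bucket_spectrum <- function(raw, grid) {
  stopifnot(inherits(raw, "raw_spectrum"), inherits(grid, "bucket_grid"))
  edges <- grid$start_ppm + (0:grid$n_buckets) * grid$width
  lo <- min(raw$ppm); hi <- max(raw$ppm)
  if (lo > edges[1L] || hi < edges[length(edges)])
    stop(sprintf(
      "spectrum [%.4f, %.4f] ppm does not cover the grid: interval [%.4f, %.4f] is uncovered",
      lo, hi,
      if (lo > edges[1L]) edges[1L] else hi,
      if (lo > edges[1L]) min(lo, edges[length(edges)]) else edges[length(edges)]),
      call. = FALSE)
  # cumulative trapezoid on the union of raw points and bucket edges; a
  # bucket integral is then a difference of the cumulative at its edges
  xs <- sort(unique(c(raw$ppm, edges)))
  ys <- stats::approx(raw$ppm, raw$intensity, xout = xs, rule = 1)$y
  ct <- c(0, cumsum(diff(xs) * (ys[-1L] + ys[-length(ys)]) / 2))
  at_edges <- ct[match(edges, xs)]
  out <- diff(at_edges)
  names(out) <- bucket_labels(grid)
  out
}

#' Bucket a set of full-resolution spectra
#'
#' @param spectra List of [raw_spectrum()] objects.
#' @inheritParams bucket_spectrum
#' @return A [bucket_set()] (state `"raw"`).
#' @export
bucket_spectra <- function(spectra, grid) {
  stopifnot(is.list(spectra), length(spectra) >= 1L)
  mat <- t(vapply(spectra, bucket_spectrum, numeric(grid$n_buckets),
                  grid = grid))
  ids <- vapply(spectra, function(s) s$sample_id, character(1L))
  bucket_set(mat, grid, sample_ids = ids, normalized = "raw")
}

#' Probabilistic quotient normalization
#'
#' Removes per-sample dilution by dividing each spectrum by its most probable
#' dilution factor: the median, over buckets where the reference is
#' non-negligible, of the bucket-wise quotients between the sample and a
#' reference spectrum.  The default reference is the element-wise median
#' spectrum of the dataset itself; an external reference (for example the
#' training-set reference applied to a test set) may be supplied instead.
#' No total-area normalization is applied beforehand: the quotient step alone
#' removes global scale and, unlike integral normalization, is not biased by
#' a few strongly changing signals.
#'
#' Buckets where the reference is at or below `eps = 1e-12 * max(reference)`
#' are excluded from the quotient median, so empty baseline regions do not
#' drive the factor.
#'
#' @param x A [bucket_set()].
#' @param reference_mode `"median_spectrum"` (default) or `"external"`.
#' @param external_reference Numeric vector of length `n_buckets`; required
#'   when `reference_mode = "external"`.
#' @return An object of class `pqn_result`: `normalized` (a [bucket_set()]
#'   with state `"pqn"`), `dilution_factors` (named, one per sample),
#'   `reference` and `reference_mode`.
#' @export
pqn_normalize <- function(x, reference_mode = c("median_spectrum", "external"),
                          external_reference = NULL) {
  stopifnot(inherits(x, "bucket_set"))
  reference_mode <- match.arg(reference_mode)
  mat <- x$matrix
  if (nrow(mat) < 1L) stop("need at least one sample", call. = FALSE)
  reference <- switch(reference_mode,
    median_spectrum = apply(mat, 2L, stats::median),
    external = {
      if (is.null(external_reference))
        stop("external reference_mode requires external_reference",
             call. = FALSE)
      if (length(external_reference) != ncol(mat))
        stop("external_reference length does not match the bucket grid",
             call. = FALSE)
      as.numeric(external_reference)
    })
  eps <- 1e-12 * max(reference)
  support <- which(reference > eps)
  if (!length(support) || max(reference) <= 0)
    stop("reference spectrum has no support (all values negligible)",
         call. = FALSE)
  factors <- apply(mat, 1L, function(row)
    stats::median(row[support] / reference[support]))
  bad <- which(!is.finite(factors) | factors <= 0)
  if (length(bad))
    stop("non-positive or non-finite dilution factor for sample(s): ",
         paste(x$sample_ids[bad], collapse = ", "), call. = FALSE)
  names(factors) <- x$sample_ids
  out <- bucket_set(mat / factors, x$grid, sample_ids = x$sample_ids,
                    normalized = "pqn")
  structure(list(normalized = out, dilution_factors = factors,
                 reference = reference, reference_mode = reference_mode),
            class = "pqn_result")
}

#' @export
print.pqn_result <- function(x, ...) {
  cat(sprintf("<pqn_result> %d samples, %s reference; dilution factors in [%.3g, %.3g]\n",
              length(x$dilution_factors), x$reference_mode,
              min(x$dilution_factors), max(x$dilution_factors)))
  invisible(x)
}
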