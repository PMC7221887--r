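# CSV/JSON readers and writers.  All tables are plain RFC 4180 CSV (TSV
# accepted on read), numbers written with "%.17g" so that doubles round-trip
# bit-identically; reports are JSON.  Readers never reorder samples or
# buckets: rows and columns come back in file order.

fmt_num <- function(x) sprintf("%.17g", x)

infer_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("file is empty: ", path, call. = FALSE)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

check_rectangular <- function(path, sep) {
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(nf) < 2L)
    stop("expected a header row and at least one data row in ", path,
         call. = FALSE)
  bad <- which(nf != nf[1L])
  if (length(bad))
    stop(sprintf("ragged table in %s: line %d has %d fields, header has %d",
                 path, bad[1L], nf[bad[1L]], nf[1L]), call. = FALSE)
}

parse_numeric_cells <- function(df, path, what = "value") {
  m <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(df)))
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric %s in %s at data row %d, column %d ('%s')",
                 what, path, idx[1L], idx[2L],
                 as.character(df[idx[1L], idx[2L]])), call. = FALSE)
  }
  m
}

#' Read a sample-by-bucket table
#'
#' Expects a CSV or TSV whose header row holds the bucket-center ppm values
#' (first field is the sample-ID column name) and whose first column holds
#' sample IDs.  The grid is inferred from the header: the width is the median
#' spacing between centers, which must be uniform within 1e-6 ppm.
#'
#' @param path Path to a CSV/TSV file.
#' @param normalized Normalization state to record on the returned set
#'   (`"raw"` by default; the file itself carries no such flag).
#' @return A [bucket_set()].
#' @seealso [write_bucket_table()]
#' @export
read_bucket_table <- function(path, normalized = c("raw", "pqn")) {
  normalized <- match.arg(normalized)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- infer_sep(path)
  check_rectangular(path, sep)
  df <- utils::read.table(path, sep = sep, header = FALSE, skip = 1L,
                          colClasses = "character", quote = "\"",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  centers <- suppressWarnings(as.numeric(header[-1L]))
  if (anyNA(centers))
    stop("header must contain numeric bucket-center ppm values in ", path,
         call. = FALSE)
  grid <- grid_from_centers(centers)
  ids <- df[[1L]]
  mat <- parse_numeric_cells(df[-1L], path, what = "cell")
  bucket_set(mat, grid, sample_ids = ids, normalized = normalized)
}

#' Write a sample-by-bucket table
#'
#' @param x A [bucket_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bucket_table <- function(x, path) {
  stopifnot(inherits(x, "bucket_set"))
  header <- paste(c("sample_id", bucket_labels(x$grid)), collapse = ",")
  rows <- vapply(seq_len(nrow(x$matrix)), function(i)
    paste(c(x$sample_ids[i], fmt_num(x$matrix[i, ])), collapse = ","),
    character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write / read a component library
#'
#' Libraries are CSV with a `label` column followed by one column per bucket
#' center.  On read, every row is validated against the library invariants
#' (non-negative, unit Euclidean norm within 1e-9).
#'
#' @param lib A [component_library()].
#' @param path CSV path.
#' @return `write_component_library()` returns `path` invisibly;
#'   `read_component_library()` returns a [component_library()].
#' @export
write_component_library <- function(lib, path) {
  stopifnot(inherits(lib, "component_library"))
  header <- paste(c("label", bucket_labels(lib$grid)), collapse = ",")
  rows <- vapply(seq_len(nrow(lib$spectra)), function(i)
    paste(c(lib$labels[i], fmt_num(lib$spectra[i, ])), collapse = ","),
    character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_component_library
#' @export
read_component_library <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- infer_sep(path)
  check_rectangular(path, sep)
  df <- utils::read.table(path, sep = sep, header = FALSE, skip = 1L,
                          colClasses = "character", quote = "\"",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  centers <- suppressWarnings(as.numeric(header[-1L]))
  if (anyNA(centers))
    stop("header must contain numeric bucket-center ppm values in ", path,
         call. = FALSE)
  grid <- grid_from_centers(centers)
  spectra <- parse_numeric_cells(df[-1L], path, what = "cell")
  component_library(spectra, grid, labels = df[[1L]])
}

#' Write / read a model-order selection report
#'
#' Reports are JSON holding the scanned component counts, relative RSS/ESS
#' per count, the per-sample Durbin-Watson matrix (degenerate residuals as
#' null), the chosen component count and the RSS threshold.  Fitted models
#' are not serialized.
#'
#' @param report A `selection_report` from [scan_components()].
#' @param path JSON path.
#' @return `write_selection_report()` returns `path` invisibly;
#'   `read_selection_report()` returns a `selection_report` (without models).
#' @export
write_selection_report <- function(report, path) {
  stopifnot(inherits(report, "selection_report"))
  payload <- list(
    k_values = report$k_values,
    rss_by_k = report$rss_by_k,
    ess_by_k = report$ess_by_k,
    dw_matrix = report$dw_matrix,
    dw_flagged = report$dw_flagged,
    sample_ids = report$sample_ids,
    chosen_k = report$chosen_k,
    rss_threshold = report$rss_threshold,
    dw_turning_k = report$dw_turning_k,
    opts = report$opts)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_selection_report
#' @export
read_selection_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  dw <- as.matrix(p$dw_matrix)
  flg <- as.matrix(p$dw_flagged)
  dimnames(dw) <- dimnames(flg) <- list(p$sample_ids, paste0("k", p$k_values))
  structure(list(k_values = as.integer(p$k_values),
                 rss_by_k = as.numeric(p$rss_by_k),
                 ess_by_k = as.numeric(p$ess_by_k),
                 dw_matrix = dw, dw_flagged = flg,
                 sample_ids = p$sample_ids,
                 chosen_k = if (is.null(p$chosen_k)) NA_integer_
                            else as.integer(p$chosen_k),
                 rss_threshold = as.numeric(p$rss_threshold),
                 dw_turning_k = if (is.null(p$dw_turning_k)) NA_integer_
                                else as.integer(p$dw_turning_k),
                 opts = p$opts, models = NULL),
            class = "selection_report")
}

#' Write / read a macromolecule distribution matrix
#'
#' Matrix D as CSV: sample IDs, one column per component, and the per-sample
#' relative residual norm (percent; empty for flagged all-zero samples).
#'
#' @param dm A `distribution_matrix` from [decompose_spectra()].
#' @param path CSV path.
#' @param grid Optional [bucket_grid()] the decomposition was performed on
#'   (the CSV does not carry it; `NULL` if unknown).
#' @return `write_distribution_matrix()` returns `path` invisibly;
#'   `read_distribution_matrix()` returns a `distribution_matrix`.
#' @export
write_distribution_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "distribution_matrix"))
  header <- paste(c("sample_id", dm$component_labels, "residual_norm"),
                  collapse = ",")
  res <- ifelse(is.na(dm$residual_norm), "", fmt_num(dm$residual_norm))
  rows <- vapply(seq_len(nrow(dm$values)), function(i)
    paste(c(dm$sample_ids[i], fmt_num(dm$values[i, ]), res[i]), collapse = ","),
    character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_distribution_matrix
#' @export
read_distribution_matrix <- function(path, grid = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- infer_sep(path)
  check_rectangular(path, sep)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  labels <- names(df)[-c(1L, ncol(df))]
  vals <- parse_numeric_cells(df[-c(1L, ncol(df))], path, what = "cell")
  res <- suppressWarnings(as.numeric(df[[ncol(df)]]))
  new_distribution_matrix(vals, sample_ids = df[[1L]],
                          component_labels = labels,
                          residual_norm = res, grid = grid)
}
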