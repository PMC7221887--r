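# Model-order selection: RSS/ESS over a scan of component counts plus a
# per-sample Durbin-Watson diagnostic on the residual rows.

#' Durbin-Watson statistic of an ordered vector
#'
#' `DW = sum((e_t - e_{t-1})^2) / sum(e_t^2)` over an ordered vector, a
#' classical noise diagnostic in chemometrics: it tends to 0 for a smooth
#' (strongly autocorrelated) signal and to 2 when the vector is pure white
#' noise, with 4 the upper bound reached by perfectly alternating sign.
#' Here it is applied to per-sample residual rows ordered by ascending ppm:
#' residuals that still contain smooth structure (DW well below 2) indicate
#' an underfitted model, residuals of pure noise (DW near 2) an adequate one.
#'
#' @param e Numeric vector, length >= 2, finite, not all zero.
#' @return The DW statistic, in `[0, 4]`.
#' @examples
#' durbin_watson(c(1, -1, 1, -1))  # 3
#' @export
durbin_watson <- function(e) {
  e <- as.numeric(e)
  if (length(e) < 2L)
    stop("Durbin-Watson needs at least two ordered values", call. = FALSE)
  if (!all(is.finite(e))) stop("vector must be finite", call. = FALSE)
  denom <- sum(e^2)
  if (denom == 0)
    stop("Durbin-Watson is undefined for an all-zero vector (0/0)",
         call. = FALSE)
  sum(diff(e)^2) / denom
}

# DW of each residual row; rows whose relative residual is below the ALS
# convergence floor (a numerically perfect fit) are flagged NA rather than
# given a meaningless statistic of rounding errors.  Any data-driven
# residual (noise >= 0.5% of signal) sits orders of magnitude above 1e-6.
dw_rows <- function(E, X, floor_rel = 1e-6) {
  res <- sqrt(rowSums(E^2)); tot <- sqrt(rowSums(X^2))
  flagged <- res <= floor_rel * pmax(tot, .Machine$double.xmin)
  dw <- rep(NA_real_, nrow(E))
  for (i in which(!flagged)) dw[i] <- durbin_watson(E[i, ])
  list(dw = dw, flagged = flagged)
}

#' Scan component counts and report RSS/ESS and Durbin-Watson diagnostics
#'
#' Fits the best-restart MCR-ALS model for each component count
#' `k = 1..k_max` and records the relative RSS/ESS and the Durbin-Watson
#' statistic of every sample's residual row.  `k = 0` is included as the
#' no-model reference: RSS 100% and DW computed on the data rows themselves.
#' Solution nesting is enforced: the best spectra at `k` (padded with one
#' extra row) are always among the candidate starts at `k + 1`, which
#' guarantees that `rss_by_k` is non-increasing.
#'
#' Samples whose residual is at the numerical floor (perfect fit) get a
#' flagged missing DW value (`dw_flagged`) instead of a statistic.
#'
#' @param X A [bucket_set()] or numeric matrix.
#' @param k_max Largest component count to scan (`<= min(dim(X))`).
#' @param rss_threshold Relative-RSS threshold (percent) recorded in the
#'   report and used by [select_k()].
#' @param keep_models If `TRUE` (default) the fitted `mcr_model` objects are
#'   kept in the report (element `models`, indexed by k).
#' @inheritParams mcr_als_fit
#' @return An object of class `selection_report`: `k_values` (0..k_max),
#'   `rss_by_k`, `ess_by_k` (percent), `dw_matrix` and `dw_flagged`
#'   (samples x length(k_values)), `dw_turning_k`, `chosen_k` (NA until
#'   [select_k()]), `rss_threshold`, `opts` and optionally `models`.
#' @export
scan_components <- function(X, k_max = 20L, max_iter = 500L, tol = 1e-8,
                            n_restarts = 10L, seed = 0L,
                            nonneg = c("A", "BT"), rss_threshold = 2,
                            keep_models = TRUE) {
  M <- as_bucket_matrix(X)
  if (k_max < 1L || k_max > min(dim(M)))
    stop(sprintf("k_max must be in [1, %d]", min(dim(M))), call. = FALSE)
  n <- nrow(M)
  k_values <- 0:k_max
  rss <- numeric(k_max + 1L)
  dw <- matrix(NA_real_, n, k_max + 1L)
  flg <- matrix(FALSE, n, k_max + 1L)
  rss[1L] <- 100
  d0 <- dw_rows(M, M)  # k = 0: the residual is the data itself
  dw[, 1L] <- d0$dw; flg[, 1L] <- d0$flagged
  models <- vector("list", k_max)
  prev_BT <- NULL
  for (k in seq_len(k_max)) {
    extra <- NULL
    if (!is.null(prev_BT)) {
      pad <- with_seed(seed + 17L * k,
                       matrix(stats::runif(ncol(M)), nrow = 1L))
      extra <- list(rbind(prev_BT, pad / sqrt(sum(pad^2))))
    }
    fit <- tryCatch(
      mcr_als_fit(M, k, max_iter = max_iter, tol = tol,
                  n_restarts = n_restarts, seed = seed, nonneg = nonneg,
                  extra_inits = extra),
      error = function(e)
        stop(sprintf("component scan failed at k = %d: %s", k,
                     conditionMessage(e)), call. = FALSE))
    rss[k + 1L] <- fit$rss_relative
    d <- dw_rows(fit$E, M)
    dw[, k + 1L] <- d$dw; flg[, k + 1L] <- d$flagged
    models[[k]] <- fit
    prev_BT <- fit$BT
  }
  ids <- if (!is.null(rownames(M))) rownames(M)
         else sprintf("sample_%03d", seq_len(n))
  dimnames(dw) <- dimnames(flg) <- list(ids, paste0("k", k_values))
  med <- apply(dw, 2L, stats::median, na.rm = TRUE)
  turning <- which(med[-1L] > 2 - 0.2)  # per-sample median DW first near 2
  structure(list(k_values = k_values, rss_by_k = rss, ess_by_k = 100 - rss,
                 dw_matrix = dw, dw_flagged = flg, sample_ids = ids,
                 chosen_k = NA_integer_, rss_threshold = rss_threshold,
                 dw_turning_k = if (length(turning)) as.integer(turning[1L])
                                else NA_integer_,
                 opts = list(k_max = as.integer(k_max), max_iter = max_iter,
                             tol = tol, n_restarts = n_restarts,
                             seed = as.integer(seed), nonneg = nonneg),
                 models = if (keep_models) models else NULL),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> k scanned 0..%d\n",
              max(x$k_values)))
  tab <- data.frame(k = x$k_values, rss = round(x$rss_by_k, 4),
                    ess = round(x$ess_by_k, 4),
                    median_dw = round(apply(x$dw_matrix, 2L, stats::median,
                                            na.rm = TRUE), 3))
  print(tab, row.names = FALSE)
  if (!is.na(x$chosen_k))
    cat(sprintf("chosen k = %d (RSS threshold %.3g%%)\n", x$chosen_k,
                x$rss_threshold))
  if (!is.na(x$dw_turning_k))
    cat(sprintf("median residual DW first exceeds %.2g at k = %d\n",
                1.8, x$dw_turning_k))
  invisible(x)
}

#' Choose the component count from a scan report
#'
#' Returns the smallest `k >= 1` whose relative RSS is at or below
#' `rss_threshold` (percent).  The Durbin-Watson matrix is a reported
#' diagnostic for human inspection -- the k at which the per-sample median
#' residual DW first exceeds `2 - 0.2` is available as
#' `report$dw_turning_k` -- but it does not override the RSS rule.
#'
#' @param report A `selection_report` from [scan_components()].
#' @param rss_threshold Relative-RSS threshold in percent (default 2).
#' @return The chosen component count (integer).
#' @export
select_k <- function(report, rss_threshold = 2) {
  stopifnot(inherits(report, "selection_report"))
  ks <- report$k_values
  ok <- which(ks >= 1L & report$rss_by_k <= rss_threshold)
  if (!length(ok))
    stop(sprintf(
      "no scanned k reaches relative RSS <= %.3g%% (minimum %.3g%% at k = %d); rerun the scan with a larger k_max",
      rss_threshold, min(report$rss_by_k[ks >= 1L]), max(ks)), call. = FALSE)
  as.integer(ks[ok[1L]])
}
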