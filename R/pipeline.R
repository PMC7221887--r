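# End-to-end orchestration of the two-stage design: resolve the small
# diffusion-edited training matrix into a frozen pure-spectra library, then
# decompose the large conventional matrix onto it.

#' Default pipeline configuration
#'
#' Every option of [run_pipeline()] with its default; values passed through
#' `...` override the defaults.  The full configuration (defaults included)
#' is echoed into the run report so that no silently defaulted value is lost.
#'
#' @param ... Named overrides, e.g. `k_max = 5`, `seed = 1`.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    reference_mode = "median_spectrum",  # PQN reference for both datasets
    k = NA_integer_,        # fixed component count; NA = choose by scan
    k_max = 20L,            # scan range upper bound
    rss_threshold = 2,      # percent, for select_k
    max_iter = 500L, tol = 1e-8, n_restarts = 10L, seed = 0L,
    nonneg = c("A", "BT"),
    constraint = "nonneg",  # decomposition constraint
    group_test = "wilcoxon_rank_sum")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

load_input <- function(x, what) {
  if (inherits(x, "bucket_set")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x))
      stop(sprintf("%s input file not found: %s", what, x), call. = FALSE)
    return(read_bucket_table(x))
  }
  stop(sprintf("%s must be a bucket_set or a file path", what), call. = FALSE)
}

#' Run the full macromolecule-extraction pipeline
#'
#' Executes, in order: PQN of the training set; component-count scan with
#' RSS/Durbin-Watson diagnostics; component-count choice (threshold rule, or
#' the fixed `k` from the configuration); freezing of the pure-spectra
#' library; PQN of the test set (against its own median reference by
#' default); decomposition of the test set onto the library; and, if sample
#' groups are supplied, per-group summaries with a two-group test.  Every
#' intermediate is written to `out_dir` (if given) along with a MANIFEST of
#' stage completion; a failing stage aborts with its name, leaving the
#' partial outputs and MANIFEST behind.  The run is bit-deterministic given
#' the configuration seed.
#'
#' @param train Training [bucket_set()] (diffusion-edited) or CSV path.
#' @param test Optional test [bucket_set()] (conventional) or CSV path.
#' @param groups Optional named character vector, two-column data frame or
#'   CSV path mapping sample IDs of the test set to group labels.
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `run_report`: `config` (fully echoed), `stages`
#'   (completed stage names), `pqn_train`, `selection`, `chosen_k`, `model`,
#'   `library`, `pqn_test`, `distribution`, `group_summary`.
#' @export
run_pipeline <- function(train, test = NULL, groups = NULL,
                         config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stages <- character(0)
  report <- list(config = unclass(config))
  manifest <- function(status, failed = NULL) {
    if (!is.null(out_dir))
      jsonlite::write_json(
        list(status = status, completed = stages, failed = failed,
             config = unclass(config)),
        file.path(out_dir, "MANIFEST.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
  }
  step <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      manifest("failed", failed = name)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    stages <<- c(stages, name)
    res
  }

  train <- step("load_train", load_input(train, "training"))
  report$pqn_train <- step("pqn_train", pqn_normalize(train, config$reference_mode))
  if (!is.null(out_dir)) {
    write_bucket_table(report$pqn_train$normalized,
                       file.path(out_dir, "train_pqn.csv"))
    jsonlite::write_json(as.list(report$pqn_train$dilution_factors),
                         file.path(out_dir, "train_dilution_factors.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  fixed_k <- !is.na(config$k)
  k_max <- if (fixed_k) config$k else config$k_max
  report$selection <- step("scan_components",
    scan_components(report$pqn_train$normalized, k_max = k_max,
                    max_iter = config$max_iter, tol = config$tol,
                    n_restarts = config$n_restarts, seed = config$seed,
                    nonneg = config$nonneg,
                    rss_threshold = config$rss_threshold))
  report$chosen_k <- step("select_k",
    if (fixed_k) as.integer(config$k)
    else select_k(report$selection, config$rss_threshold))
  report$selection$chosen_k <- report$chosen_k
  report$model <- report$selection$models[[report$chosen_k]]
  report$library <- step("freeze_library",
    freeze_library(report$model, train$grid))
  if (!is.null(out_dir)) {
    write_selection_report(report$selection,
                           file.path(out_dir, "selection_report.json"))
    write_component_library(report$library, file.path(out_dir, "library.csv"))
    jsonlite::write_json(
      list(k = report$model$k, rss_relative = report$model$rss_relative,
           ess_relative = report$model$ess_relative,
           n_iter = report$model$n_iter, converged = report$model$converged,
           seed = report$model$seed, restarts = report$model$restarts,
           init = report$model$init),
      file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }

  if (!is.null(test)) {
    test <- step("load_test", load_input(test, "test"))
    report$pqn_test <- step("pqn_test",
                            pqn_normalize(test, config$reference_mode))
    report$distribution <- step("decompose",
      decompose_spectra(report$pqn_test$normalized, report$library,
                        constraint = config$constraint))
    if (!is.null(out_dir)) {
      write_bucket_table(report$pqn_test$normalized,
                         file.path(out_dir, "test_pqn.csv"))
      write_distribution_matrix(report$distribution,
                                file.path(out_dir, "distribution.csv"))
    }
    if (!is.null(groups)) {
      if (is.character(groups) && length(groups) == 1L) {
        if (!file.exists(groups))
          stop("groups input file not found: ", groups, call. = FALSE)
        groups <- utils::read.csv(groups, stringsAsFactors = FALSE)
      }
      report$group_summary <- step("group_compare",
        group_compare(report$distribution, groups, test = config$group_test))
      if (!is.null(out_dir))
        jsonlite::write_json(
          list(test = report$group_summary$test,
               summary = report$group_summary$summary,
               tests = report$group_summary$tests),
          file.path(out_dir, "group_summary.json"), auto_unbox = TRUE,
          digits = NA, pretty = TRUE, dataframe = "rows")
    }
  }
  report$stages <- stages
  manifest("complete")
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> stages: %s\n", paste(x$stages, collapse = " -> ")))
  cat(sprintf("chosen k = %d; model RSS %.4g%%\n", x$chosen_k,
              x$model$rss_relative))
  if (!is.null(x$distribution)) print(x$distribution)
  invisible(x)
}

#' Write a generated paired dataset to a directory
#'
#' Writes `train.csv`, `test.csv`, the true spectra (`truth_spectra.csv`,
#' component-library format), the true mixing-weight matrices
#' (`truth_A.csv`, `truth_D.csv`) and the remaining ground-truth metadata
#' (`truth.json`).
#'
#' @param ds A list from [generate_paired_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_paired_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_bucket_table(ds$train, file.path(dir, "train.csv"))
  write_bucket_table(ds$test, file.path(dir, "test.csv"))
  grid <- ds$train$grid
  write_component_library(
    component_library(ds$truth$true_spectra, grid,
                      labels = rownames(ds$truth$true_spectra)),
    file.path(dir, "truth_spectra.csv"))
  wt <- function(W, ids, path) {
    dm <- new_distribution_matrix(W, ids, colnames(W, do.NULL = FALSE,
                                                   prefix = "Macro "),
                                  rep(NA_real_, nrow(W)), grid)
    write_distribution_matrix(dm, path)
  }
  wt(ds$truth$true_A, ds$train$sample_ids, file.path(dir, "truth_A.csv"))
  wt(ds$truth$true_D, ds$test$sample_ids, file.path(dir, "truth_D.csv"))
  jsonlite::write_json(
    list(component_kinds = ds$truth$component_kinds,
         noise_sigma = ds$truth$noise_sigma, seed = ds$truth$seed,
         dilution_train = ds$truth$dilution_train,
         dilution_test = ds$truth$dilution_test,
         small_molecule_params = ds$truth$small_molecule_params),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
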