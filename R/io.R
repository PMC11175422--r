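#' Write an experiment result to disk
#'
#' Emits a tidy CSV of the per-seed metrics (one row per seed x condition),
#' a CSV of the test table, and a JSON summary carrying the experiment id,
#' the configuration snapshot and the tests. File contents are
#' deterministic for a deterministic result.
#'
#' @param result an `experiment_result`
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
write_experiment_result <- function(result, dir) {
  stopifnot(inherits(result, "experiment_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, result$experiment)
  paths <- c(metrics = paste0(base, "_metrics.csv"),
             tests = paste0(base, "_tests.csv"),
             summary = paste0(base, "_summary.json"))
  utils::write.csv(result$metrics, paths["metrics"], row.names = FALSE)
  utils::write.csv(result$tests, paths["tests"], row.names = FALSE)
  jsonlite::write_json(
    list(experiment = result$experiment, config = result$config,
         tests = result$tests),
    paths["summary"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read an experiment result written by [write_experiment_result()]
#'
#' @param dir directory holding the files
#' @param experiment experiment id (file prefix)
#' @return an `experiment_result` (config restored from the JSON summary)
#' @export
read_experiment_result <- function(dir, experiment) {
  base <- file.path(dir, experiment)
  metrics <- utils::read.csv(paste0(base, "_metrics.csv"),
                             stringsAsFactors = FALSE)
  tests <- utils::read.csv(paste0(base, "_tests.csv"),
                           stringsAsFactors = FALSE)
  summ <- jsonlite::read_json(paste0(base, "_summary.json"),
                              simplifyVector = TRUE)
  .experiment_result(summ$experiment, metrics, tests, config = summ$config)
}

#' Summarize all experiment results found in a directory
#'
#' Reads every `*_summary.json` written by [write_experiment_result()]
#' under `dir` and prints, per experiment, its configuration id and test
#' table.
#'
#' @param dir directory holding experiment output files
#' @return invisibly, a named list of the test tables
#' @export
report_results <- function(dir) {
  files <- list.files(dir, pattern = "_summary\\.json$", full.names = TRUE)
  if (!length(files)) stop("no experiment summaries found in ", dir)
  out <- list()
  for (f in files) {
    summ <- jsonlite::read_json(f, simplifyVector = TRUE)
    cat("==", summ$experiment, "==\n")
    tests <- as.data.frame(summ$tests)
    cols <- intersect(c("label", "statistic", "p_value", "adjusted_p"),
                      names(tests))
    print(tests[, cols], row.names = FALSE, digits = 3)
    cat("\n")
    out[[summ$experiment]] <- tests
  }
  invisible(out)
}

#' Run an experiment from a configuration file or list
#'
#' Dispatches on the `experiment` field (`dropout`, `lesion`,
#' `curriculum`, `congruence`) and forwards the remaining fields as
#' arguments to the corresponding experiment function. Accepts a YAML file
#' path or an already-parsed list. Unknown fields raise a validation error
#' naming the offending field.
#'
#' @param config path to a YAML file or a named list
#' @param output_dir optional directory; when given, results are written
#'   with [write_experiment_result()]
#' @return the `experiment_result`
#' @export
run_experiment <- function(config, output_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$experiment)) {
    stop("config must contain an 'experiment' field")
  }
  fn <- switch(config$experiment,
               dropout = dropout_experiment,
               lesion = lesion_experiment,
               curriculum = curriculum_experiment,
               congruence = congruence_experiment,
               stop("unknown experiment: ", config$experiment))
  args <- config[setdiff(names(config), "experiment")]
  bad <- setdiff(names(args), names(formals(fn)))
  if (length(bad)) {
    stop("invalid config field(s) for '", config$experiment, "': ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(args$seeds)) args$seeds <- as.integer(unlist(args$seeds))
  result <- do.call(fn, args)
  if (!is.null(output_dir)) write_experiment_result(result, output_dir)
  result
}
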