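#' Read a scoring problem from CSV and a config file
#'
#' The data file is a headered CSV (UTF-8, `.` decimal); the label
#' column is named. The optional config is a flat key/value YAML file
#' declaring `var_types`, `var_names`, `groups` (list of 1- or 2-element
#' 1-based column indices, label column excluded), `method`, and any
#' option understood by [ics_options()] (`max_bins`, `preselect`,
#' `auto`, `cutoff`, `weight_grid`, `cv_folds`, `seed`, ...).
#'
#' @param data_file CSV path.
#' @param label_col name of the label column.
#' @param config_file optional YAML path.
#' @param test_file optional CSV with the same schema for a held-out
#'   split.
#' @return An [ics_problem()], unvalidated.
#' @export
read_ics_problem <- function(data_file, label_col, config_file = NULL,
                             test_file = NULL) {
  df <- utils::read.csv(data_file, stringsAsFactors = FALSE)
  if (!label_col %in% names(df))
    stop(sprintf("label column '%s' not found in %s", label_col, data_file),
         call. = FALSE)
  cfg <- if (!is.null(config_file)) yaml::read_yaml(config_file) else list()

  y <- df[[label_col]]
  x <- df[names(df) != label_col]
  x_test <- NULL; y_test <- NULL
  if (!is.null(test_file)) {
    dt <- utils::read.csv(test_file, stringsAsFactors = FALSE)
    if (!label_col %in% names(dt))
      stop(sprintf("label column '%s' not found in %s", label_col, test_file),
           call. = FALSE)
    y_test <- dt[[label_col]]
    x_test <- dt[names(dt) != label_col]
  }

  opt_names <- names(formals(ics_options))
  opts <- do.call(ics_options, cfg[intersect(names(cfg), opt_names)])
  groups <- if (!is.null(cfg$groups)) lapply(cfg$groups, as.integer) else NULL
  ics_problem(x, y, x_test = x_test, y_test = y_test,
              var_types = cfg$var_types,
              var_names = cfg$var_names %||% names(x),
              groups = groups,
              method = cfg$method %||% "lp",
              options = opts)
}

#' Write an assessment report as JSON
#'
#' @param report an `ics_assessment` from [assess_model()].
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_ics_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
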