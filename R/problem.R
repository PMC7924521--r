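#' Describe an interval coded scoring problem
#'
#' Bundles the training data, labels, optional held-out test split, the
#' declared variable types, the effects to consider (main effects and
#' two-way interactions) and the fitting method into a single object, the
#' analogue of a model formula plus data for interval coded scoring.
#'
#' @param x_train data frame or matrix, `N x N_d`, raw variable values.
#' @param y_train vector of length `N` with exactly two distinct values;
#'   the numerically larger value is taken as the target (+1) class.
#' @param x_test,y_test optional held-out split with the same column schema.
#' @param var_types character vector, one of `"binary"`, `"categorical"`,
#'   `"ordinal"`, `"continuous"` per column. If `NULL`, columns with two
#'   distinct values are tagged binary, character/factor columns
#'   categorical, and the rest continuous.
#' @param var_names column labels; defaults to the column names of
#'   `x_train`.
#' @param groups list of effects: a length-1 integer vector is a main
#'   effect, a length-2 vector a two-way interaction (1-based column
#'   indices). Default: all main effects, no interactions.
#' @param method `"lp"` (total-variation penalized linear program) or
#'   `"en"` (constrained elastic net on the cumulative encoding; main
#'   effects only).
#' @param options an [ics_options()] list.
#'
#' @return An object of class `ics_problem` (unvalidated; see
#'   [validate_problem()]).
#' @seealso [run_ics()]
#' @export
ics_problem <- function(x_train, y_train, x_test = NULL, y_test = NULL,
                        var_types = NULL, var_names = NULL, groups = NULL,
                        method = c("lp", "en"), options = ics_options()) {
  method <- match.arg(method)
  prob <- structure(list(
    x_train = x_train, y_train = y_train,
    x_test = x_test, y_test = y_test,
    var_types = var_types, var_names = var_names,
    groups = groups, method = method, options = options,
    validated = FALSE
  ), class = "ics_problem")
  prob
}

#' Options for interval coded scoring
#'
#' @param max_bins maximum number of intervals per continuous or ordinal
#'   variable (the cap on the percentile split).
#' @param preselect run the effect-preselection screen before the main fit.
#' @param auto if `TRUE`, the reweighting value is chosen automatically by
#'   the cutoff rule on the cross-validated tuning curve; if `FALSE`, the
#'   curve is printed and `choose_weight` (or an interactive prompt) picks.
#' @param cutoff length-2 numeric in (0, 1]: fraction of the maximum
#'   cross-validated AUC that a candidate must retain, for (preselection,
#'   reweighting) respectively.
#' @param weight_grid candidate reweighting values `a`; the sentinel `-1`
#'   (no reweighting) must be present.
#' @param gamma_grid slack/penalty trade-off grid for the LP formulation.
#' @param t_grid L1-budget grid for the elastic-net formulation; `NULL`
#'   means 20 log-spaced values up to the unconstrained L1 norm,
#'   determined from the data.
#' @param cv_folds number of stratified cross-validation folds.
#' @param seed integer seed governing fold draws and any other randomness.
#' @param show print tuning and assessment summaries while fitting.
#' @param choose_weight reweighting value to use when `auto = FALSE`.
#'
#' @return A list of class `ics_options`.
#' @export
ics_options <- function(max_bins = 10, preselect = FALSE, auto = TRUE,
                        cutoff = c(0.75, 0.80),
                        weight_grid = c(-1, 0, 0.5, 1, 2, 4),
                        gamma_grid = c(0.1, 1, 10, 100),
                        t_grid = NULL, cv_folds = 10, seed = 1,
                        show = FALSE, choose_weight = NULL) {
  opts <- list(max_bins = max_bins, preselect = preselect, auto = auto,
               cutoff = cutoff, weight_grid = weight_grid,
               gamma_grid = gamma_grid, t_grid = t_grid,
               cv_folds = cv_folds, seed = seed, show = show,
               choose_weight = choose_weight)
  class(opts) <- "ics_options"
  opts
}

check_options <- function(opts) {
  stopifnot(is.numeric(opts$max_bins), opts$max_bins >= 1)
  if (length(opts$cutoff) != 2 || any(opts$cutoff <= 0) || any(opts$cutoff > 1))
    stop("`cutoff` must be two fractions in (0, 1]", call. = FALSE)
  if (length(opts$weight_grid) == 0)
    stop("`weight_grid` must be non-empty", call. = FALSE)
  if (!(-1 %in% opts$weight_grid))
    stop("`weight_grid` must contain the sentinel -1 (no reweighting)",
         call. = FALSE)
  if (length(opts$gamma_grid) == 0)
    stop("`gamma_grid` must be non-empty", call. = FALSE)
  stopifnot(opts$cv_folds >= 2)
  opts$weight_grid <- sort(unique(opts$weight_grid))
  opts
}

infer_var_types <- function(x) {
  vapply(seq_len(ncol(x)), function(j) {
    col <- x[[j]]
    if (is.character(col) || is.factor(col)) return("categorical")
    nu <- length(unique(col))
    if (nu <= 2) "binary" else "continuous"
  }, character(1))
}

#' Validate and normalise a scoring problem
#'
#' Checks dimensions and field invariants, fills defaults (variable types,
#' names, groups), catalogues categorical levels and maps the two label
#' values to \{-1, +1\} with the numerically larger original value becoming
#' +1 (the target class). Validation is idempotent.
#'
#' @param prob an [ics_problem()].
#' @return The normalised problem, with `validated = TRUE`, labels in
#'   \{-1, +1\} and a `label_map` recording the original coding.
#' @export
validate_problem <- function(prob) {
  stopifnot(inherits(prob, "ics_problem"))
  if (isTRUE(prob$validated)) return(prob)

  x <- prob$x_train
  if (is.matrix(x)) x <- as.data.frame(x)
  if (!is.data.frame(x)) stop("x_train must be a matrix or data frame", call. = FALSE)
  n <- nrow(x); nd <- ncol(x)
  if (n == 0 || nd == 0) stop("x_train is empty", call. = FALSE)

  y <- prob$y_train
  if (length(y) != n)
    stop(sprintf("dimension mismatch: x_train has %d rows but y_train has length %d",
                 n, length(y)), call. = FALSE)
  lv <- sort(unique(y))
  if (length(lv) != 2)
    stop(sprintf("y_train must contain exactly 2 distinct values, found %d",
                 length(lv)), call. = FALSE)
  label_map <- list(negative = lv[1], positive = lv[2])
  y_pm <- ifelse(y == lv[2], 1, -1)

  var_names <- prob$var_names %||% colnames(x) %||% paste0("x", seq_len(nd))
  if (length(var_names) != nd)
    stop("var_names length does not match the number of columns", call. = FALSE)
  colnames(x) <- var_names

  var_types <- prob$var_types %||% infer_var_types(x)
  if (length(var_types) != nd)
    stop("var_types length does not match the number of columns", call. = FALSE)
  bad <- setdiff(var_types, c("binary", "categorical", "ordinal", "continuous"))
  if (length(bad))
    stop("unknown var_types: ", paste(bad, collapse = ", "), call. = FALSE)

  groups <- prob$groups %||% as.list(seq_len(nd))
  groups <- lapply(groups, function(g) as.integer(g))
  for (g in groups) {
    if (!length(g) %in% c(1, 2))
      stop("each group must have 1 (main effect) or 2 (interaction) indices",
           call. = FALSE)
    if (any(g < 1 | g > nd))
      stop(sprintf("group index out of range [1..%d]: %s", nd,
                   paste(g, collapse = ",")), call. = FALSE)
    if (length(g) == 2 && g[1] == g[2])
      stop("interaction group must use two distinct variables", call. = FALSE)
  }
  if (prob$method == "en" && any(lengths(groups) == 2))
    stop("enICS only supports main effects; remove interaction groups or use method = \"lp\"",
         call. = FALSE)

  xt <- prob$x_test
  yt <- prob$y_test
  if (!is.null(xt)) {
    if (is.matrix(xt)) xt <- as.data.frame(xt)
    if (ncol(xt) != nd)
      stop("x_test schema does not match x_train (different column count)",
           call. = FALSE)
    colnames(xt) <- var_names
    if (is.null(yt) || length(yt) != nrow(xt))
      stop("dimension mismatch: y_test does not match x_test rows", call. = FALSE)
    extra <- setdiff(unique(yt), lv)
    if (length(extra))
      stop("y_test contains label values absent from y_train: ",
           paste(extra, collapse = ", "), call. = FALSE)
    yt <- ifelse(yt == lv[2], 1, -1)
  }

  prob$x_train <- x
  prob$y_train <- y_pm
  prob$x_test <- xt
  prob$y_test <- yt
  prob$var_types <- var_types
  prob$var_names <- var_names
  prob$groups <- groups
  prob$options <- check_options(prob$options)
  prob$label_map <- label_map
  prob$validated <- TRUE
  prob
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
#' @method print ics_problem
print.ics_problem <- function(x, ...) {
  cat("Interval coded scoring problem\n")
  cat(sprintf("  observations : %d train%s\n", NROW(x$x_train),
              if (!is.null(x$x_test)) sprintf(" / %d test", NROW(x$x_test)) else ""))
  cat(sprintf("  variables    : %d\n", NCOL(x$x_train)))
  cat(sprintf("  effects      : %d (%d interactions)\n",
              length(x$groups %||% list()),
              sum(lengths(x$groups %||% list()) == 2)))
  cat(sprintf("  method       : %sICS\n", x$method))
  invisible(x)
}
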