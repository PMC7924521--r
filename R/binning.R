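#' Interval thresholds for a single variable
#'
#' Continuous variables are split into (up to) `max_bins` equal-count
#' intervals at empirical quantiles of the training sample, under the
#' occupancy rule that every interval must hold at least five training
#' points: the interval count is decremented until the rule holds (or a
#' single interval remains). Ordinal thresholds are additionally rounded
#' to integers; duplicated thresholds (heavy ties) are collapsed. Binary
#' and categorical variables carry no thresholds: their intervals are the
#' catalogued levels.
#'
#' @param x training values of one variable.
#' @param var_type one of `"binary"`, `"categorical"`, `"ordinal"`,
#'   `"continuous"`.
#' @param max_bins cap on the interval count for continuous/ordinal
#'   variables.
#' @return A list with `thresholds` (strictly increasing, possibly empty),
#'   `n_intervals`, `levels` (binary/categorical only) and `var_type`.
#' @export
compute_thresholds <- function(x, var_type, max_bins = 10) {
  if (length(x) == 0) stop("cannot bin an empty variable", call. = FALSE)
  stopifnot(max_bins >= 1)

  if (var_type %in% c("binary", "categorical")) {
    lev <- if (var_type == "binary") sort(unique(x)) else unique(x)
    if (var_type == "binary" && length(lev) > 2)
      stop("binary variable has more than two levels", call. = FALSE)
    if (length(lev) == 1)
      warning("constant variable: single interval, effect cannot discriminate",
              call. = FALSE)
    return(list(thresholds = numeric(0), n_intervals = length(lev),
                levels = lev, var_type = var_type))
  }

  x <- as.numeric(x)
  if (length(unique(x)) == 1) {
    warning("constant variable: single interval, effect cannot discriminate",
            call. = FALSE)
    return(list(thresholds = numeric(0), n_intervals = 1L,
                levels = NULL, var_type = var_type))
  }

  np <- min(max_bins, max(1L, floor(length(x) / 5)))
  thr <- numeric(0)
  while (np >= 2) {
    thr <- unname(stats::quantile(x, probs = seq_len(np - 1) / np, type = 7))
    if (var_type == "ordinal") thr <- round(thr)
    thr <- sort(unique(thr))
    if (length(thr) == 0) { np <- 1L; break }
    occ <- tabulate(findInterval(x, thr) + 1L, nbins = length(thr) + 1L)
    if (min(occ) >= 5) break
    np <- np - 1L
  }
  if (np <= 1) thr <- numeric(0)
  list(thresholds = thr, n_intervals = length(thr) + 1L,
       levels = NULL, var_type = var_type)
}

#' Build the binning scheme for a problem
#'
#' Computes thresholds/levels for every variable referenced by at least
#' one effect group. Interaction grids reuse the marginal thresholds of
#' the two variables involved.
#'
#' @param prob a validated [ics_problem()].
#' @return An object of class `ics_scheme`: per variable the
#'   [compute_thresholds()] result, plus the effect `groups` and derived
#'   per-effect interval counts.
#' @export
build_scheme <- function(prob) {
  stopifnot(isTRUE(prob$validated))
  used <- sort(unique(unlist(prob$groups)))
  vars <- stats::setNames(vector("list", ncol(prob$x_train)), prob$var_names)
  for (j in used) {
    vars[[j]] <- compute_thresholds(prob$x_train[[j]], prob$var_types[j],
                                    prob$options$max_bins)
  }
  structure(list(vars = vars, groups = prob$groups,
                 var_names = prob$var_names),
            class = "ics_scheme")
}

## number of Z columns contributed by one effect
effect_size <- function(scheme, g) {
  if (length(g) == 1) scheme$vars[[g]]$n_intervals
  else scheme$vars[[g[1]]]$n_intervals * scheme$vars[[g[2]]]$n_intervals
}

effect_label <- function(scheme, g) {
  paste(scheme$var_names[g], collapse = ":")
}

## 1-based interval index of each value of one variable; NA for an
## unseen categorical level
interval_index <- function(x, var) {
  if (var$var_type %in% c("binary", "categorical")) {
    idx <- match(x, var$levels)
  } else {
    idx <- findInterval(as.numeric(x), var$thresholds) + 1L
  }
  idx
}
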