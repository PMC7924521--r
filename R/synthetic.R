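#' Generative truth for synthetic interval-score data
#'
#' Describes a population in which the log-odds of the positive class is
#' an additive piecewise-constant function of the variables — exactly
#' the model family a score system can represent — so that every stage
#' of the pipeline can be tested against a known answer and the Bayes
#' AUC ceiling is computable.
#'
#' The default truth is the package's recovery benchmark: two
#' informative step-function variables (a single true threshold each,
#' log-odds steps of 2.4 and 2.0) plus three pure-noise variables, all
#' uniform on (0, 1) so percentile thresholds are analytically
#' predictable.
#'
#' @param variables list of per-variable descriptions; each a list with
#'   `name`, `type` (`"continuous"`, `"binary"` or `"categorical"`),
#'   and for continuous: `range`, `thresholds`, `contrib` (per-interval
#'   log-odds, length `length(thresholds) + 1`); for binary/categorical:
#'   `levels`, `probs`, `contrib` (per level).
#' @param intercept population log-odds offset.
#' @param seed integer seed; datasets drawn from the same truth are
#'   reproducible.
#' @return A list of class `ics_truth`.
#' @export
ics_truth <- function(variables = NULL, intercept = 0, seed = 7) {
  if (is.null(variables)) {
    variables <- list(
      list(name = "step1", type = "continuous", range = c(0, 1),
           thresholds = 0.4, contrib = c(-1.2, 1.2)),
      list(name = "step2", type = "continuous", range = c(0, 1),
           thresholds = 0.6, contrib = c(-1.0, 1.0)),
      list(name = "noise1", type = "continuous", range = c(0, 1),
           thresholds = numeric(0), contrib = 0),
      list(name = "noise2", type = "continuous", range = c(0, 1),
           thresholds = numeric(0), contrib = 0),
      list(name = "noise3", type = "continuous", range = c(0, 1),
           thresholds = numeric(0), contrib = 0)
    )
  }
  for (v in variables) {
    if (v$type == "continuous") {
      stopifnot(length(v$contrib) == length(v$thresholds) + 1)
    } else {
      stopifnot(length(v$contrib) == length(v$levels),
                length(v$probs) == length(v$levels))
      if (any(v$probs < 0) || abs(sum(v$probs) - 1) > 1e-8)
        stop("level probabilities must be non-negative and sum to 1",
             call. = FALSE)
    }
  }
  structure(list(variables = variables, intercept = intercept, seed = seed),
            class = "ics_truth")
}

#' True log-odds score of observations under a generative truth
#'
#' @param truth an [ics_truth()].
#' @param x data frame with the truth's variables.
#' @return Numeric vector of total true log-odds (including intercept).
#' @export
true_score <- function(truth, x) {
  total <- rep(truth$intercept, nrow(x))
  for (j in seq_along(truth$variables)) {
    v <- truth$variables[[j]]
    xi <- x[[j]]
    if (v$type == "continuous") {
      total <- total + v$contrib[findInterval(as.numeric(xi), v$thresholds) + 1L]
    } else {
      total <- total + v$contrib[match(xi, v$levels)]
    }
  }
  total
}

#' Draw a synthetic dataset with known interval-score structure
#'
#' Continuous variables are uniform over their stated range, categorical
#' and binary variables follow their stated level probabilities; labels
#' are Bernoulli draws through the logistic link of the total true
#' log-odds, mapped to \{-1, +1\}. Given the truth's seed the draw is
#' reproducible; `seed_offset` yields independent replicates of the same
#' population.
#'
#' @param truth an [ics_truth()].
#' @param n number of observations.
#' @param seed_offset added to the truth's seed for replicate draws.
#' @return A list with data frame `x`, labels `y` in \{-1, +1\}, and the
#'   `truth`.
#' @export
make_piecewise_dataset <- function(truth, n, seed_offset = 0) {
  stopifnot(inherits(truth, "ics_truth"), n >= 1)
  with_seed(truth$seed + seed_offset, {
    cols <- lapply(truth$variables, function(v) {
      if (v$type == "continuous") {
        stats::runif(n, v$range[1], v$range[2])
      } else {
        sample(v$levels, n, replace = TRUE, prob = v$probs)
      }
    })
    names(cols) <- vapply(truth$variables, `[[`, "", "name")
    x <- as.data.frame(cols)
    eta <- true_score(truth, x)
    y <- ifelse(stats::runif(n) < stats::plogis(eta), 1, -1)
    list(x = x, y = y, truth = truth)
  })
}

#' Bayes reference AUC of a generative truth
#'
#' Monte-Carlo estimate of the AUC attained by the true log-odds score
#' itself — the ceiling no classifier on the same variables can beat in
#' expectation — used as the recovery target for fitted models.
#'
#' @param truth an [ics_truth()].
#' @param n_mc Monte-Carlo sample size.
#' @return AUC estimate in \[0, 1\].
#' @export
bayes_reference <- function(truth, n_mc = 2e5) {
  d <- make_piecewise_dataset(truth, n_mc, seed_offset = 990)
  roc_auc(true_score(truth, d$x), d$y)$auc
}

## evaluate expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Type declarations matching a generative truth
#'
#' @param truth an [ics_truth()].
#' @return Character vector of variable types in problem declaration
#'   form.
#' @export
truth_var_types <- function(truth) {
  vapply(truth$variables, function(v) {
    if (v$type == "categorical" && length(v$levels) == 2) "binary" else v$type
  }, character(1))
}
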