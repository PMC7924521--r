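#' Fit an interval coded scoring model
#'
#' Runs the full training flow: interval construction, binary expansion,
#' an initial fit, selection of the reweighting value on a
#' cross-validated tuning curve, iterative reweighting, pruning of
#' effects whose interval weights carry no information, a
#' refit-and-prune loop until the effect set is stable, scaling and
#' rounding of the interval weights to integer points (merging adjacent
#' equal-point intervals), and a final logistic recalibration mapping
#' total scores to risks.
#'
#' An effect is pruned when all its interval weights are equal within
#' tolerance: under the total-variation penalty a constant block is pure
#' offset, so its common value is absorbed into the intercept and the
#' effect removed — zero blocks are the special case with common value
#' zero.
#'
#' @param problem an [ics_problem()]; validated on entry.
#' @return An object of class `ics_model`; see [predict.ics_model()],
#'   [assess_model()], [render_scorecard()], [write_ics_model()].
#' @export
run_ics <- function(problem) {
  prob <- validate_problem(problem)
  opts <- prob$options
  x <- prob$x_train; y <- prob$y_train

  groups <- prob$groups
  if (isTRUE(opts$preselect)) {
    sel <- preselect(prob)
    if (length(sel$selected) == 0) {
      warning("preselection discarded every effect; keeping all", call. = FALSE)
    } else groups <- prob$groups[sel$selected]
  }

  scheme <- build_scheme(prob)
  hyper <- select_hyper(x, y, prob, groups)
  if (isTRUE(opts$show))
    message(sprintf("selected %s = %.4g by cross-validation",
                    if (prob$method == "lp") "gamma" else "t", hyper))

  a_log <- numeric(0)
  curve <- NULL
  repeat {
    tuned <- tune_weight(x, y, prob, groups, hyper, opts$weight_grid,
                         opts$cutoff[2])
    curve <- tuned
    a <- if (isTRUE(opts$auto)) {
      tuned$grid$a[tuned$chosen]
    } else if (!is.null(opts$choose_weight)) {
      if (!opts$choose_weight %in% tuned$grid$a)
        stop("choose_weight must be one of the weight grid values", call. = FALSE)
      opts$choose_weight
    } else {
      if (isTRUE(opts$show)) print(tuned)
      message(sprintf("auto = FALSE without choose_weight: using the cutoff-rule suggestion a = %g",
                      tuned$grid$a[tuned$chosen]))
      tuned$grid$a[tuned$chosen]
    }
    a_log <- c(a_log, a)

    eng <- engine_fit(x, y, scheme, groups, prob$method, hyper, a)
    keep <- active_effects(eng$w_blocks)
    if (length(keep) == 0) {
      warning("all effects pruned: returning an intercept-only model",
              call. = FALSE)
      groups <- list(); eng$w_blocks <- list()
      break
    }
    if (length(keep) == length(groups)) break
    groups <- groups[keep]
  }

  sr <- scale_and_round(eng$w_blocks, scheme, groups, x, y)
  scores <- score_rows(sr, x)
  cal <- calibrate_risk(scores, y)

  model <- structure(list(
    format_version = 1L,
    method = prob$method,
    effects = sr$effects,
    multiplier = sr$m,
    offset_policy = "per-effect minimum absorbed; offset re-estimated by the logistic recalibration",
    logistic = list(b0 = cal$b0, b1 = cal$b1),
    risk_table = risk_table(sr, cal),
    label_map = prob$label_map,
    provenance = list(
      a = if (length(a_log)) a_log[length(a_log)] else NA_real_,
      a_history = a_log,
      hyper = hyper,
      hyper_name = if (prob$method == "lp") "gamma" else "t",
      seed = opts$seed,
      n_train = nrow(x),
      tuning = if (!is.null(curve)) curve$grid else NULL,
      linear_offset = sr$b_linear
    )
  ), class = "ics_model")

  if (isTRUE(opts$show)) print(assess_model(model, x, y, split = "train"))
  model
}

## -------------------------------------------------------------------
## engine dispatch: fit + reweight, returning per-effect blocks of
## interval-domain weights

engine_fit <- function(x, y, scheme, groups, method, hyper, a) {
  if (method == "lp") {
    ze <- lp_encode(x, scheme, groups)
    ds <- build_difference_structure(scheme, groups)
    fit0 <- fit_lp(ze, y, hyper, ds)
    fit <- reweight_lp(ze, y, hyper, ds, reweight_config(a, max_iter = 10), fit0)
    w_int <- fit$w
  } else {
    ze <- en_encode(x, scheme, groups)
    ds <- build_difference_structure(scheme, groups)
    fit0 <- fit_en(ze, y, hyper)
    fit <- reweight_en(ze, y, hyper, reweight_config(a, max_iter = 25), fit0)
    w_int <- as.numeric(ds$r %*% fit$w_hat)
  }
  w_blocks <- split(w_int, ze$column_map$effect)
  names(w_blocks) <- NULL
  list(w_blocks = w_blocks, b = fit$b, fit = fit, column_map = ze$column_map)
}

## effects whose interval weights are not all equal (within tolerance);
## constant blocks are offset in disguise and carry no information
active_effects <- function(w_blocks, tol = NULL) {
  if (length(w_blocks) == 0) return(integer(0))
  scale <- max(1, max(abs(unlist(w_blocks))))
  tol <- tol %||% 1e-5 * scale
  which(vapply(w_blocks, function(w) diff(range(w)) > tol, logical(1)))
}

## -------------------------------------------------------------------
## hyperparameter selection (gamma for lp, t for en) by CV AUC at a = -1

select_hyper <- function(x, y, prob, groups) {
  opts <- prob$options
  grid <- if (prob$method == "lp") {
    opts$gamma_grid
  } else {
    opts$t_grid %||% {
      sc <- scheme_from_data(x, groups, prob)
      ze <- en_encode(x, sc, groups)
      t_max <- sum(abs(fit_en(ze, y, Inf)$w_hat))
      exp(seq(log(0.01), log(max(t_max, 0.02)), length.out = 20))
    }
  }
  if (length(grid) == 1) return(grid)
  grid <- sort(grid)  # ascending = simpler models first
  folds <- stratified_folds(y, opts$cv_folds, opts$seed)
  fold_auc <- vapply(grid, function(hy) {
    cv_auc_one(x, y, prob, groups, hy, -1, folds)
  }, numeric(length(folds)))
  m <- colMeans(fold_auc, na.rm = TRUE)
  best <- which.max(m)
  ## one-standard-error rule: the simplest setting whose mean CV AUC is
  ## within one SE of the best
  se <- stats::sd(fold_auc[, best], na.rm = TRUE) / sqrt(nrow(fold_auc))
  grid[which(m >= m[best] - se)[1]]
}

## per-fold out-of-fold AUC for one (hyper, a) setting
cv_auc_one <- function(x, y, prob, groups, hyper, a, folds) {
  vapply(seq_along(folds), function(k) {
    tr <- setdiff(seq_along(y), folds[[k]]); va <- folds[[k]]
    if (length(unique(y[va])) < 2) return(NA_real_)
    sc_tr <- scheme_from_data(x[tr, , drop = FALSE], groups, prob)
    eng <- engine_fit(x[tr, , drop = FALSE], y[tr], sc_tr, groups,
                      prob$method, hyper, a)
    zv <- lp_encode(x[va, , drop = FALSE], sc_tr, groups)
    sv <- as.numeric(zv$z %*% unlist(eng$w_blocks))
    roc_auc(sv, y[va])$auc
  }, numeric(1))
}

## rebuild a binning scheme from a data subset (per-fold thresholds)
scheme_from_data <- function(x, groups, prob) {
  used <- sort(unique(unlist(groups)))
  vars <- stats::setNames(vector("list", ncol(x)), prob$var_names)
  for (j in used)
    vars[[j]] <- suppressWarnings(
      compute_thresholds(x[[j]], prob$var_types[j], prob$options$max_bins))
  structure(list(vars = vars, groups = groups, var_names = prob$var_names),
            class = "ics_scheme")
}

## -------------------------------------------------------------------
## tuning curve over the reweighting grid

#' Cross-validated tuning curve for the reweighting value
#'
#' For every candidate reweighting value `a` (including the sentinel
#' `-1`, no reweighting) computes stratified-CV performance (AUC,
#' calibration slope and bias of the out-of-fold risk predictions) and
#' the complexity (variables and intervals after pruning, rounding and
#' merging) of the full-data model at that `a`. The automatic choice is
#' the grid point with the fewest intervals among those whose CV AUC
#' reaches `cutoff` times the maximum CV AUC; ties prefer larger `a`,
#' then the calibration slope closest to 1.
#'
#' @param x,y training data and \{-1, +1\} labels.
#' @param prob the validated problem (carries types, options, seed).
#' @param groups the active effect list.
#' @param hyper the selected gamma (lp) or t (en).
#' @param grid reweighting candidates, must include -1.
#' @param cutoff fraction in (0, 1].
#' @return A list of class `ics_tuning`: `grid` data frame with columns
#'   `a`, `cv_auc`, `cv_slope`, `cv_bias`, `n_variables`, `n_intervals`;
#'   `chosen` row index; `cutoff`.
#' @export
tune_weight <- function(x, y, prob, groups, hyper, grid, cutoff) {
  stopifnot(-1 %in% grid)
  grid <- sort(unique(grid))
  folds <- stratified_folds(y, prob$options$cv_folds, prob$options$seed)
  attr(folds, "prob") <- prob
  scheme <- scheme_from_data(x, groups, prob)

  rows <- lapply(grid, function(a) {
    stats_f <- matrix(NA_real_, length(folds), 3)
    for (k in seq_along(folds)) {
      tr <- setdiff(seq_along(y), folds[[k]]); va <- folds[[k]]
      sc_tr <- scheme_from_data(x[tr, , drop = FALSE], groups, prob)
      eng <- engine_fit(x[tr, , drop = FALSE], y[tr], sc_tr, groups,
                        prob$method, hyper, a)
      zt <- lp_encode(x[tr, , drop = FALSE], sc_tr, groups)
      zv <- lp_encode(x[va, , drop = FALSE], sc_tr, groups)
      w <- unlist(eng$w_blocks)
      s_tr <- as.numeric(zt$z %*% w); s_va <- as.numeric(zv$z %*% w)
      if (length(unique(y[va])) < 2) next
      stats_f[k, 1] <- roc_auc(s_va, y[va])$auc
      cal_tr <- suppressWarnings(calibrate_risk(s_tr, y[tr]))
      risk_va <- stats::plogis(cal_tr$b0 + cal_tr$b1 * s_va)
      cc <- tryCatch(calibration_curve(risk_va, y[va]), error = function(e) NULL)
      if (!is.null(cc)) { stats_f[k, 2] <- cc$a_cal; stats_f[k, 3] <- cc$b_cal }
    }
    eng_full <- engine_fit(x, y, scheme, groups, prob$method, hyper, a)
    keep <- active_effects(eng_full$w_blocks)
    if (length(keep)) {
      sr <- scale_and_round(eng_full$w_blocks[keep], scheme, groups[keep], x, y)
      nv <- length(unique(unlist(lapply(sr$effects, `[[`, "vars"))))
      ni <- sum(vapply(sr$effects, function(e) length(e$points), 0L))
    } else { nv <- 0L; ni <- 0L }
    c(cv_auc = mean(stats_f[, 1], na.rm = TRUE),
      cv_slope = mean(stats_f[, 2], na.rm = TRUE),
      cv_bias = mean(stats_f[, 3], na.rm = TRUE),
      n_variables = nv, n_intervals = ni)
  })
  tab <- cbind(data.frame(a = grid), as.data.frame(do.call(rbind, rows)))

  eligible <- which(tab$cv_auc >= cutoff * max(tab$cv_auc, na.rm = TRUE))
  cand <- eligible[tab$n_intervals[eligible] == min(tab$n_intervals[eligible])]
  cand <- cand[tab$a[cand] == max(tab$a[cand])]
  chosen <- cand[which.min(abs(tab$cv_slope[cand] - 1))]
  if (!length(chosen) || is.na(chosen)) chosen <- which.max(tab$cv_auc)
  structure(list(grid = tab, chosen = chosen, cutoff = cutoff),
            class = "ics_tuning")
}

#' @export
#' @method print ics_tuning
print.ics_tuning <- function(x, ...) {
  cat(sprintf("reweighting tuning curve (cutoff %.2f; * = suggested)\n", x$cutoff))
  tab <- x$grid
  tab$mark <- ifelse(seq_len(nrow(tab)) == x$chosen, "*", "")
  print(format(tab, digits = 3), row.names = FALSE)
  invisible(x)
}

## stratified k-fold assignment; redraws (new seed) if a fold loses a
## class, errors after 5 attempts
stratified_folds <- function(y, k, seed) {
  k <- min(k, max(2, min(table(y))))
  for (attempt in 0:4) {
    folds <- with_seed(seed + attempt, {
      idx <- seq_along(y)
      f <- integer(length(y))
      for (cls in unique(y)) {
        ic <- sample(idx[y == cls])
        f[ic] <- rep_len(seq_len(k), length(ic))
      }
      lapply(unname(split(idx, f)), unname)
    })
    ok <- all(vapply(folds, function(va) {
      length(unique(y[va])) == 2 && length(unique(y[-va])) == 2
    }, logical(1)))
    if (ok) return(folds)
  }
  stop("could not draw stratified folds with both classes in every fold",
       call. = FALSE)
}

## -------------------------------------------------------------------
## scaling, rounding, merging

#' Convert interval weights to integer points
#'
#' Centers each effect's interval weights so its minimum is zero (the
#' minima are offset and get absorbed by the later logistic
#' recalibration), then searches a multiplier grid for the smallest
#' multiplier whose rounded integer points keep at least 90% of the
#' unrounded training AUC with maximum point magnitude at most 10
#' (falling back to the AUC-maximising multiplier), rounds, merges
#' adjacent equal-point intervals of continuous and ordinal effects
#' (removing the thresholds between them) and drops effects whose every
#' interval rounds to zero.
#'
#' @param w_blocks list of per-effect interval-domain weight vectors.
#' @param scheme the binning scheme the weights refer to.
#' @param groups the effect list matching `w_blocks`.
#' @param x,y training data for the rounding-fidelity search.
#' @return A list: `effects` (per retained effect: name, kind, vars,
#'   type, thresholds/levels/grid dims, integer `points`), multiplier
#'   `m`, `b_linear`, and the achievable `score_range`.
#' @export
scale_and_round <- function(w_blocks, scheme, groups, x, y) {
  stopifnot(length(w_blocks) == length(groups))
  mins <- vapply(w_blocks, min, 0)
  wc <- lapply(w_blocks, function(w) w - min(w))
  flat <- unlist(wc)
  maxabs <- if (length(flat)) max(abs(flat)) else 0

  if (maxabs < 1e-9) {
    return(list(effects = list(), m = NA_real_, b_linear = sum(mins),
                unrounded_auc = NA_real_, rounded_auc = NA_real_))
  }

  ze <- lp_encode(x, scheme, groups)
  auc_un <- roc_auc(as.numeric(ze$z %*% flat), y)$auc
  m_grid <- exp(seq(log(0.5 / maxabs), log(10 / maxabs), length.out = 50))
  auc_m <- vapply(m_grid, function(m) {
    s <- round(m * flat)
    if (all(s == 0) || length(unique(as.numeric(ze$z %*% s))) < 2) return(NA_real_)
    roc_auc(as.numeric(ze$z %*% s), y)$auc
  }, numeric(1))
  ## structure preservation: rounding may not flatten an effect the
  ## optimiser kept non-constant
  keeps_structure <- vapply(m_grid, function(m) {
    all(vapply(wc, function(w) {
      diff(range(w)) == 0 || diff(range(round(m * w))) > 0
    }, logical(1)))
  }, logical(1))
  ok <- !is.na(auc_m) & auc_m >= 0.9 * auc_un & keeps_structure &
    vapply(m_grid, function(m) max(abs(round(m * flat))) <= 10, logical(1))
  m <- if (any(ok)) m_grid[which(ok)[1]] else m_grid[which.max(auc_m)]

  s_blocks <- lapply(wc, function(w) as.integer(round(m * w)))

  effects <- list()
  for (e in seq_along(groups)) {
    g <- groups[[e]]
    s <- s_blocks[[e]]
    if (all(s == 0)) next
    if (length(g) == 1) {
      var <- scheme$vars[[g]]
      eff <- list(name = scheme$var_names[g], kind = "main",
                  vars = scheme$var_names[g], type = var$var_type,
                  points = s)
      if (var$var_type %in% c("binary", "categorical")) {
        eff$levels <- var$levels
      } else {
        mg <- merge_intervals(s, var$thresholds)
        eff$points <- mg$points
        eff$thresholds <- mg$thresholds
      }
      effects[[length(effects) + 1]] <- eff
    } else {
      v1 <- scheme$vars[[g[1]]]; v2 <- scheme$vars[[g[2]]]
      effects[[length(effects) + 1]] <- list(
        name = paste(scheme$var_names[g], collapse = ":"),
        kind = "interaction", vars = scheme$var_names[g],
        type = c(v1$var_type, v2$var_type),
        dims = c(v1$n_intervals, v2$n_intervals),
        thresholds1 = v1$thresholds, thresholds2 = v2$thresholds,
        levels1 = v1$levels, levels2 = v2$levels,
        points = s)  # column-major over the grid
    }
  }
  sc_round <- if (length(effects)) {
    roc_auc(as.numeric(ze$z %*% unlist(s_blocks)), y)$auc
  } else NA_real_
  list(effects = effects, m = m, b_linear = sum(mins),
       unrounded_auc = auc_un, rounded_auc = sc_round)
}

## collapse adjacent equal-point intervals, removing their thresholds
merge_intervals <- function(points, thresholds) {
  stopifnot(length(points) == length(thresholds) + 1)
  keep_thr <- which(diff(points) != 0)
  list(points = points[c(1L, keep_thr + 1L)],
       thresholds = thresholds[keep_thr])
}

## total integer score of each row of x under rounded effects
score_rows <- function(sr, x) {
  total <- rep(0L, nrow(x))
  warned <- FALSE
  for (eff in sr$effects) {
    if (eff$kind == "main") {
      idx <- if (eff$type %in% c("binary", "categorical")) {
        match(x[[eff$vars]], eff$levels)
      } else {
        findInterval(as.numeric(x[[eff$vars]]), eff$thresholds) + 1L
      }
      pts <- ifelse(is.na(idx), 0L, eff$points[pmax(idx, 1L)])
      if (anyNA(idx)) { pts[is.na(idx)] <- 0L; warned <- TRUE }
    } else {
      i1 <- effect_axis_index(x[[eff$vars[1]]], eff$type[1], eff$thresholds1, eff$levels1)
      i2 <- effect_axis_index(x[[eff$vars[2]]], eff$type[2], eff$thresholds2, eff$levels2)
      cellidx <- (i2 - 1L) * eff$dims[1] + i1
      pts <- ifelse(is.na(cellidx), 0L, eff$points[pmax(cellidx, 1L)])
      if (anyNA(cellidx)) { pts[is.na(cellidx)] <- 0L; warned <- TRUE }
    }
    total <- total + pts
  }
  if (warned)
    warning("unseen level(s): zero points contributed", call. = FALSE)
  total
}

effect_axis_index <- function(xv, type, thresholds, levels) {
  if (type %in% c("binary", "categorical")) match(xv, levels)
  else findInterval(as.numeric(xv), thresholds) + 1L
}

## every achievable total score (sum over effects of any per-effect value)
achievable_scores <- function(effects) {
  if (!length(effects)) return(0L)
  sets <- lapply(effects, function(e) sort(unique(e$points)))
  Reduce(function(acc, s) sort(unique(as.vector(outer(acc, s, `+`)))), sets,
         accumulate = FALSE)
}

risk_table <- function(sr, cal) {
  sc <- achievable_scores(sr$effects)
  data.frame(score = sc, risk = stats::plogis(cal$b0 + cal$b1 * sc))
}

## -------------------------------------------------------------------
## logistic recalibration

#' Logistic risk profile from total scores
#'
#' Fits a two-parameter logistic regression of the class on the total
#' integer score by Newton iteration, with a small ridge penalty on the
#' slope (1/2000) so the fit stays finite under complete separation;
#' the intercept is unpenalized. With a single distinct score the slope
#' is undefined and an intercept-only profile at the observed
#' prevalence is returned with a warning.
#'
#' @param scores integer total scores.
#' @param y labels in \{-1, +1\}.
#' @param slope_ridge ridge weight on the slope.
#' @return A list with `b0`, `b1` and the risk at each input score.
#' @export
calibrate_risk <- function(scores, y, slope_ridge = 1 / 2000) {
  stopifnot(length(scores) == length(y), all(y %in% c(-1, 1)))
  y01 <- (y + 1) / 2
  if (length(unique(scores)) < 2) {
    warning("single distinct score: intercept-only risk profile (prevalence)",
            call. = FALSE)
    prev <- mean(y01)
    prev <- min(max(prev, 1e-12), 1 - 1e-12)
    return(list(b0 = stats::qlogis(prev), b1 = 0,
                risk = rep(prev, length(scores))))
  }
  beta <- c(0, 0)
  for (it in seq_len(100)) {
    eta <- beta[1] + beta[2] * scores
    p <- stats::plogis(eta)
    grad <- c(sum(p - y01), sum((p - y01) * scores) + 2 * slope_ridge * beta[2])
    wgt <- pmax(p * (1 - p), 1e-12)
    hess <- matrix(c(sum(wgt), sum(wgt * scores),
                     sum(wgt * scores), sum(wgt * scores^2) + 2 * slope_ridge),
                   2, 2)
    step <- solve(hess, grad)
    beta <- beta - step
    if (max(abs(step)) < 1e-12) break
  }
  list(b0 = beta[1], b1 = beta[2],
       risk = stats::plogis(beta[1] + beta[2] * scores))
}

## score where the calibrated risk crosses 0.5
risk_threshold_score <- function(model) {
  if (model$logistic$b1 == 0) return(Inf)
  -model$logistic$b0 / model$logistic$b1
}

model_n_intervals <- function(model) {
  sum(vapply(model$effects, function(e) length(e$points), 0L))
}

model_n_variables <- function(model) {
  length(unique(unlist(lapply(model$effects, `[[`, "vars"))))
}

#' Predict scores, risks and classes with a score model
#'
#' Applies the binning, sums the integer points of each effect (unseen
#' categorical levels contribute zero points, with a warning), converts
#' the total score to a risk through the fitted logistic profile and
#' assigns the class by the risk-0.5 rule, reported in the original
#' label coding.
#'
#' @param object an `ics_model`.
#' @param newdata data frame with the training schema.
#' @param ... unused.
#' @return A data frame with `score`, `risk`, `predicted_class`.
#' @export
predict.ics_model <- function(object, newdata, ...) {
  if (is.matrix(newdata)) newdata <- as.data.frame(newdata)
  score <- score_rows(object, newdata)
  risk <- stats::plogis(object$logistic$b0 + object$logistic$b1 * score)
  cls <- ifelse(risk >= 0.5, object$label_map$positive, object$label_map$negative)
  data.frame(score = score, risk = risk, predicted_class = cls)
}

#' @export
#' @method print ics_model
print.ics_model <- function(x, ...) {
  cat(sprintf("interval coded scoring model (%sICS)\n", x$method))
  if (!length(x$effects)) {
    cat("  intercept-only model\n")
  } else {
    for (eff in x$effects) {
      if (eff$kind == "main") {
        cat(sprintf("  %s (%s): points %s\n", eff$name, eff$type,
                    paste(eff$points, collapse = "/")))
      } else {
        cat(sprintf("  %s (interaction %dx%d)\n", eff$name,
                    eff$dims[1], eff$dims[2]))
      }
    }
  }
  cat(sprintf("  risk profile: logit(risk) = %.3f + %.3f * score\n",
              x$logistic$b0, x$logistic$b1))
  invisible(x)
}
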