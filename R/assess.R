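#' ROC curve and area under the curve
#'
#' AUC follows the Mann-Whitney probability-of-concordance convention:
#' the probability that a random positive scores above a random
#' negative, with half credit for ties. The ROC curve is a threshold
#' sweep over the distinct scores, starting at (0, 0) and ending at
#' (1, 1); its trapezoidal area equals the concordance AUC.
#'
#' @param scores numeric predictions, larger = more positive.
#' @param y labels in \{-1, +1\}.
#' @return A list with `auc` and `roc` (data frame of `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, y) {
  stopifnot(length(scores) == length(y), all(y %in% c(-1, 1)))
  npos <- as.numeric(sum(y == 1)); nneg <- as.numeric(sum(y == -1))
  if (npos == 0 || nneg == 0)
    stop("AUC needs at least one positive and one negative", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)

  ## threshold sweep from high to low over distinct scores
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys == 1); fp <- cumsum(ys == -1)
  last <- !duplicated(ss, fromLast = TRUE)  # last row of each tie block
  roc <- data.frame(fpr = c(0, fp[last] / nneg, 1),
                    tpr = c(0, tp[last] / npos, 1))
  roc <- roc[!duplicated(roc), , drop = FALSE]
  list(auc = auc, roc = roc)
}

#' Classification accuracy at a score threshold
#'
#' Fraction of observations whose sign prediction (`+1` iff
#' `score >= threshold`) matches the label.
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold on the score scale; the natural
#'   default for a calibrated score model is the score where the
#'   estimated risk crosses 0.5.
#' @return A fraction in \[0, 1\].
#' @export
ics_accuracy <- function(scores, y, threshold = 0) {
  stopifnot(length(scores) == length(y), all(y %in% c(-1, 1)))
  mean(ifelse(scores >= threshold, 1, -1) == y)
}

#' Calibration curve slope and bias
#'
#' Groups observations by distinct predicted risk (for a score model the
#' predicted risk is constant within a total score, so this is grouping
#' by score), computes each group's empirical risk as its positive
#' fraction, and fits the weighted least-squares line
#' `empirical = a_cal * predicted + b_cal` with group sizes as weights.
#' An ideally calibrated model has unit slope and zero bias.
#'
#' @param pred_risk predicted probabilities of the positive class.
#' @param y labels in \{-1, +1\}.
#' @return A list with `a_cal` (slope), `b_cal` (bias) and the `groups`
#'   data frame (`predicted`, `empirical`, `n`).
#' @export
calibration_curve <- function(pred_risk, y) {
  stopifnot(length(pred_risk) == length(y), all(y %in% c(-1, 1)))
  grp <- stats::aggregate(data.frame(empirical = (y + 1) / 2, n = 1),
                          by = list(predicted = pred_risk),
                          FUN = function(v) sum(v))
  grp$empirical <- grp$empirical / grp$n
  if (nrow(grp) < 2)
    stop("calibration slope undefined: fewer than 2 distinct predicted risks",
         call. = FALSE)
  fit <- stats::lm(empirical ~ predicted, data = grp, weights = grp$n)
  list(a_cal = unname(stats::coef(fit)[2]),
       b_cal = unname(stats::coef(fit)[1]),
       groups = grp)
}

#' Calibration error
#'
#' The L1 distance between the fitted calibration line and the ideal
#' identity line over the unit risk range,
#' `e = integral_0^1 |(a_cal - 1) p + b_cal| dp`, evaluated in closed
#' form: when the integrand does not change sign the integral is
#' `|(a_cal - 1)/2 + b_cal|`; otherwise it splits at the root into two
#' triangles.
#'
#' @param a_cal calibration slope.
#' @param b_cal calibration bias.
#' @return Non-negative error `e`.
#' @export
calibration_error <- function(a_cal, b_cal) {
  d <- a_cal - 1
  if (d == 0) return(abs(b_cal))
  root <- -b_cal / d
  if (root <= 0 || root >= 1) return(abs(d / 2 + b_cal))
  f0 <- abs(b_cal)            # |f(0)|
  f1 <- abs(d + b_cal)        # |f(1)|
  f0 * root / 2 + f1 * (1 - root) / 2
}

#' Assess a score model on a data split
#'
#' Computes the evaluation surface of a fitted score model on given
#' data: AUC, accuracy at the risk-0.5 threshold, the ROC curve, the
#' calibration slope/bias and error, and the model complexity counts.
#'
#' @param model an `ics_model` from [run_ics()].
#' @param x data with the training schema.
#' @param y labels (original coding or \{-1, +1\}).
#' @param split label for the report (`"train"`, `"test"`, `"new"`).
#' @return A list of class `ics_assessment`.
#' @export
assess_model <- function(model, x, y, split = "new") {
  pred <- predict(model, x)
  y <- normalize_labels(y, model$label_map)
  ra <- roc_auc(pred$score, y)
  thr <- risk_threshold_score(model)
  cal <- tryCatch(calibration_curve(pred$risk, y), error = function(e) NULL)
  e_cal <- if (!is.null(cal)) calibration_error(cal$a_cal, cal$b_cal) else NA_real_
  structure(list(
    split = split,
    auc = ra$auc,
    accuracy = ics_accuracy(pred$score, y, thr),
    roc = ra$roc,
    threshold = thr,
    a_cal = if (!is.null(cal)) cal$a_cal else NA_real_,
    b_cal = if (!is.null(cal)) cal$b_cal else NA_real_,
    calibration_error = e_cal,
    calibration_groups = if (!is.null(cal)) cal$groups else NULL,
    n_intervals = model_n_intervals(model),
    n_variables = model_n_variables(model),
    n = length(y),
    risk_profile = model$risk_table
  ), class = "ics_assessment")
}

#' @export
#' @method print ics_assessment
print.ics_assessment <- function(x, ...) {
  cat(format_assessment(x), sep = "\n")
  invisible(x)
}

format_assessment <- function(a) {
  out <- sprintf("assessment (%s split, n = %d)", a$split, a$n)
  if (!is.null(a$risk_profile) && nrow(a$risk_profile)) {
    out <- c(out, "  risk profile:",
             sprintf("    score %+d -> %.1f%%",
                     a$risk_profile$score, 100 * a$risk_profile$risk))
  }
  if (!is.null(a$calibration_groups)) {
    out <- c(out, "  calibration curve (predicted -> empirical, n):",
             sprintf("    %.3f -> %.3f  (%d)", a$calibration_groups$predicted,
                     a$calibration_groups$empirical, a$calibration_groups$n))
  }
  c(out,
    sprintf("  ROC: %d points; threshold at score %.2f (risk 0.5)",
            nrow(a$roc), a$threshold),
    sprintf("  AUC        : %.3f", a$auc),
    sprintf("  accuracy   : %.3f", a$accuracy),
    sprintf("  cal. slope : %s", fmt_or_na(a$a_cal)),
    sprintf("  cal. bias  : %s", fmt_or_na(a$b_cal)),
    sprintf("  cal. error : %s", fmt_or_na(a$calibration_error)),
    sprintf("  complexity : %d intervals over %d variables",
            a$n_intervals, a$n_variables))
}

fmt_or_na <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)

## map arbitrary two-valued labels onto {-1, +1} using a stored map
normalize_labels <- function(y, label_map) {
  if (all(y %in% c(-1, 1)) &&
      !all(c(label_map$negative, label_map$positive) %in% c(-1, 1)))
    return(y)
  out <- ifelse(y == label_map$positive, 1,
                ifelse(y == label_map$negative, -1, NA))
  if (anyNA(out)) stop("labels outside the trained coding", call. = FALSE)
  out
}
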