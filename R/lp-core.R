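#' Fit the total-variation penalized LP classifier
#'
#' Solves the soft-margin linear program at the core of the LP
#' formulation:
#' \deqn{\min_{w,b,\varepsilon} \|\chi D w\|_1 + \gamma 1^T\varepsilon
#'   \quad s.t. \quad Y(Zw + b) \ge 1 - \varepsilon,\ \varepsilon \ge 0,}
#' where `D` holds adjacent-interval differences, so the L1 penalty is a
#' total-variation penalty favouring piecewise-constant interval weight
#' profiles. The standard linearisation introduces one auxiliary variable
#' per difference row (`u >= (chi D w)_i`, `u >= -(chi D w)_i`); the
#' resulting LP is solved by the package's sparse interior-point engine.
#' The offset `b` is unpenalized.
#'
#' @param zexp an [lp_encode()] expansion.
#' @param y labels in \{-1, +1\}.
#' @param gamma positive slack trade-off.
#' @param dstruct an [build_difference_structure()] for the same scheme
#'   and groups.
#' @param row_weights optional positive difference-row weights (the
#'   reweighting diagonal); default all ones.
#' @return A list of class `ics_lp_fit`: interval weights `w`, offset
#'   `b`, hinge slacks `slack`, the penalized `objective`
#'   (`sum(|chi D w|) + gamma * sum(slack)`), `gamma`, and the solver
#'   status.
#' @export
fit_lp <- function(zexp, y, gamma, dstruct, row_weights = NULL) {
  stopifnot(inherits(zexp, "ics_expanded"), zexp$encoding == "lp")
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop("gamma must be a positive scalar", call. = FALSE)
  Z <- zexp$z
  n <- nrow(Z); ns <- ncol(Z); nds <- dstruct$n_ds
  stopifnot(length(y) == n, all(y %in% c(-1, 1)), dstruct$n_s == ns)
  chi <- row_weights %||% rep(1, nds)
  stopifnot(length(chi) == nds, all(chi > 0))
  ## the argmin is invariant to a positive rescaling of the whole
  ## objective; normalising the row weights keeps the reweighted LPs
  ## well conditioned (chi spans several orders of magnitude)
  cs <- if (nds > 0) max(chi) else 1
  chi_int <- chi / cs
  gamma_int <- gamma / cs
  ## keep the largest cost coefficient at 1 (large-gamma runs otherwise
  ## push the interior point method into badly scaled territory)
  obj_scale <- max(1, gamma_int)
  Dw <- dstruct$d * chi_int  # chi D, row-scaled

  ## variables v = (w [ns], b, u [nds], eps [n])
  nv <- ns + 1 + nds + n
  f <- c(rep(0, ns + 1), rep(1, nds), rep(gamma_int, n)) / obj_scale
  Zs <- methods::as(Matrix::Matrix(Z, sparse = TRUE), "CsparseMatrix")
  YZ <- Zs * y
  Iu <- Matrix::Diagonal(nds)
  Ie <- Matrix::Diagonal(n)
  zero_ne <- Matrix::Matrix(0, n, nds, sparse = TRUE)
  zero_dn <- Matrix::Matrix(0, nds, n, sparse = TRUE)
  zero_d1 <- Matrix::Matrix(0, nds, 1, sparse = TRUE)
  zero_n1 <- Matrix::Matrix(0, n, ns + 1 + nds, sparse = TRUE)
  G <- rbind(
    cbind(YZ, Matrix::Matrix(y, n, 1, sparse = TRUE), zero_ne, Ie),  # Y(Zw+b)+eps >= 1
    cbind(-Dw, zero_d1, Iu, zero_dn),                                # u - chiDw >= 0
    cbind(Dw, zero_d1, Iu, zero_dn),                                 # u + chiDw >= 0
    cbind(zero_n1, Ie)                                               # eps >= 0
  )
  h <- c(rep(1, n), rep(0, 2 * nds + n))
  sol <- ipm_lp(f, G, h)

  w <- sol$v[seq_len(ns)]
  b <- sol$v[ns + 1]
  slack <- pmax(0, 1 - y * (as.numeric(Z %*% w) + b))
  obj <- sum(chi * abs(as.numeric(dstruct$d %*% w))) + gamma * sum(slack)
  structure(list(w = w, b = b, slack = slack, objective = obj,
                 gamma = gamma, status = sol$status,
                 lp_objective = sol$objective, iterations = sol$iterations),
            class = "ics_lp_fit")
}

#' Reweighting configuration
#'
#' @param a reweighting value; `-1` is the sentinel for no reweighting.
#' @param eps1 additive floor in the LP reweighting diagonal, guarding
#'   against division by zero (default 5e-4).
#' @param eps2 convergence tolerance on the mean absolute coefficient
#'   change (default 1e-8).
#' @param max_iter iteration cap: 10 for the LP route, 25 for the
#'   elastic-net route.
#' @return A list of class `ics_reweight_config`.
#' @export
reweight_config <- function(a, eps1 = 5e-4, eps2 = 1e-8, max_iter = 10) {
  stopifnot(eps1 > 0, eps2 > 0, a >= 0 || a == -1)
  structure(list(a = a, eps1 = eps1, eps2 = eps2, max_iter = max_iter),
            class = "ics_reweight_config")
}

#' Iterative reweighting of the LP fit
#'
#' Repeatedly re-solves the LP with the difference-row weights
#' `chi_i = 1 / (eps1 + a |(D w)_i|)` computed from the current solution,
#' until the mean absolute change of the interval weights drops below
#' `eps2` or 10 iterations have run. Larger `a` drives more adjacent
#' differences to exact zero, simplifying the interval profile. The
#' sentinel `a = -1` returns the initial fit untouched.
#'
#' @inheritParams fit_lp
#' @param cfg a [reweight_config()].
#' @param fit0 the initial [fit_lp()] solution.
#' @return An `ics_lp_fit` with an added `reweight_iterations` count.
#' @export
reweight_lp <- function(zexp, y, gamma, dstruct, cfg, fit0) {
  stopifnot(inherits(cfg, "ics_reweight_config"))
  if (cfg$a == -1) {
    fit0$reweight_iterations <- 0L
    return(fit0)
  }
  w <- fit0$w
  fit <- fit0
  for (it in seq_len(cfg$max_iter)) {
    chi <- 1 / (cfg$eps1 + cfg$a * abs(as.numeric(dstruct$d %*% w)))
    fit <- fit_lp(zexp, y, gamma, dstruct, row_weights = chi)
    if (mean(abs(fit$w - w)) < cfg$eps2) { w <- fit$w; break }
    w <- fit$w
  }
  fit$reweight_iterations <- it
  fit
}
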