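#' Fit the constrained elastic net on the cumulative encoding
#'
#' Solves the budget-form elastic net at the core of the elastic-net
#' formulation:
#' \deqn{\min_{\hat w, b} \|\hat Z \hat w + b - y\|_2^2 +
#'   \epsilon \|\hat w\|_2^2 \quad s.t. \quad \|\hat w\|_1 \le t,}
#' a regression on the \{-1, +1\} labels with unpenalized offset and a
#' small fixed ridge (`ridge_eps = 0.05`) for stability. The coefficients
#' live in the difference domain of the cumulative encoding, so the L1
#' budget is implicitly a total-variation budget on the interval weights.
#'
#' The solver works on the penalized form
#' `RSS + ridge_eps ||w||^2 + lambda ||w||_1` (cyclic coordinate descent
#' with exact soft-thresholding, offset absorbed by centering) and
#' bisects `lambda` until the L1 norm meets the budget; `lambda = 0`
#' (the pure ridge solution) is returned when the constraint is
#' inactive.
#'
#' @param zexp an [en_encode()] expansion (or any numeric design; the
#'   raw matrix is also accepted for internal reuse).
#' @param y labels in \{-1, +1\} (any numeric response is accepted).
#' @param t non-negative L1 budget.
#' @param ridge_eps fixed ridge parameter (default 0.05).
#' @return A list of class `ics_en_fit`: difference-domain weights
#'   `w_hat`, offset `b`, budget `t`, the constrained `objective`
#'   (`RSS + ridge_eps ||w||^2`), the active `lambda`, and the iteration
#'   count of the bisection.
#' @export
fit_en <- function(zexp, y, t, ridge_eps = 0.05) {
  if (t < 0) stop("the L1 budget t must be non-negative", call. = FALSE)
  Z <- if (inherits(zexp, "ics_expanded")) {
    stopifnot(zexp$encoding == "en")
    zexp$z
  } else as.matrix(zexp)
  n <- nrow(Z); p <- ncol(Z)
  stopifnot(length(y) == n)

  ## absorb the unpenalized offset: b = mean(y) - colMeans(Z) w
  zm <- colMeans(Z); ym <- mean(y)
  Zc <- sweep(Z, 2, zm)
  yc <- y - ym
  xtx <- colSums(Zc^2)

  solve_pen <- function(lambda, w0) {
    as.numeric(en_cd(Zc, yc, xtx, lambda, ridge_eps, w0))
  }

  if (t == 0) {
    w <- numeric(p)
    lambda <- Inf
    iters <- 0L
  } else {
    w_ridge <- solve_pen(0, numeric(p))
    if (sum(abs(w_ridge)) <= t) {
      w <- w_ridge
      lambda <- 0
      iters <- 0L
    } else {
      ## ||w(lambda)||_1 is continuous and non-increasing in lambda;
      ## lambda_hi makes w = 0
      lo <- 0; hi <- 2 * max(abs(crossprod(Zc, yc))) + ridge_eps
      w <- w_ridge
      for (iters in seq_len(100)) {
        mid <- (lo + hi) / 2
        w <- solve_pen(mid, w)
        l1 <- sum(abs(w))
        if (abs(l1 - t) < 1e-10 * max(1, t)) break
        if (l1 > t) lo <- mid else hi <- mid
      }
      lambda <- (lo + hi) / 2
      w <- solve_pen(lambda, w)
      ## project the tiny residual budget violation, if any
      if (sum(abs(w)) > t && sum(abs(w)) > 0) w <- w * (t / sum(abs(w)))
    }
  }
  b <- ym - sum(zm * w)
  resid <- y - as.numeric(Z %*% w) - b
  structure(list(w_hat = w, b = b, t = t, ridge_eps = ridge_eps,
                 objective = sum(resid^2) + ridge_eps * sum(w^2),
                 lambda = lambda, bisect_iterations = iters),
            class = "ics_en_fit")
}

#' Iterative reweighting of the elastic-net fit
#'
#' Re-solves the constrained elastic net on the column-rescaled design
#' `Zhat %*% diag(chi)` with `chi_i = a |w_i|` computed from the current
#' solution, mapping each rescaled solution `v` back to the data domain
#' as `w = chi * v`, until the mean absolute change of `w` drops below
#' `eps2` or 25 iterations have run. Columns whose current weight is
#' zero are scaled to zero and remain excluded (the zero-trap of the
#' multiplicative reweighting). The sentinel `a = -1` returns the
#' initial fit untouched.
#'
#' @inheritParams fit_en
#' @param cfg a [reweight_config()] with `max_iter = 25`.
#' @param fit0 the initial [fit_en()] solution.
#' @return An `ics_en_fit` (data-domain `w_hat`) with an added
#'   `reweight_iterations` count.
#' @export
reweight_en <- function(zexp, y, t, cfg, fit0, ridge_eps = 0.05) {
  stopifnot(inherits(cfg, "ics_reweight_config"))
  if (cfg$a == -1) {
    fit0$reweight_iterations <- 0L
    return(fit0)
  }
  Z <- if (inherits(zexp, "ics_expanded")) zexp$z else as.matrix(zexp)
  w <- fit0$w_hat
  fit <- fit0
  for (it in seq_len(cfg$max_iter)) {
    chi <- cfg$a * abs(w)
    fit <- fit_en(Z %*% diag(chi, length(chi)), y, t, ridge_eps)
    w_new <- chi * fit$w_hat
    converged <- mean(abs(w_new - w)) < cfg$eps2
    w <- w_new
    if (converged) break
  }
  fit$w_hat <- w
  fit$b <- mean(y) - sum(colMeans(Z) * w)
  resid <- y - as.numeric(Z %*% w) - fit$b
  fit$objective <- sum(resid^2) + ridge_eps * sum(w^2)
  fit$reweight_iterations <- it
  fit
}
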