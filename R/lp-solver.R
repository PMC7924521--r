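## Sparse primal-dual interior-point solver for linear programs in
## inequality form,
##
##    min  f'v   s.t.  G v >= h,        (v free)
##
## via Mehrotra's predictor-corrector on the perturbed KKT system
##    G'z = f,  Gv - s = h,  s o z = mu,  s, z >= 0.
## Each iteration factorises the normal matrix G' diag(z/s) G with a
## sparse Cholesky; a small diagonal regularisation guards against rank
## deficiency from degenerate optimal faces. On such faces the dual
## iterate can keep jittering after the complementarity product has
## underflowed, so the solver also stops on (near-zero mu, feasible
## primal) and always returns the best iterate seen by the merit
## max(relative gap, primal residual, dual residual).

ipm_lp <- function(f, G, h, tol = 1e-9, max_iter = 150) {
  G <- methods::as(G, "CsparseMatrix")
  m <- nrow(G); n <- ncol(G)
  stopifnot(length(f) == n, length(h) == m)

  v <- numeric(n)
  s <- pmax(1, abs(h))
  z <- rep(1, m)
  Gt <- Matrix::t(G)
  norm_h <- 1 + sqrt(sum(h^2))
  norm_f <- 1 + sqrt(sum(f^2))
  step <- 0.99995
  status <- "max_iter"
  best <- list(merit = Inf, v = v, z = z, s = s)
  stall <- 0L

  for (it in seq_len(max_iter)) {
    rd <- as.numeric(Gt %*% z) - f          # dual residual
    rp <- as.numeric(G %*% v) - s - h       # primal residual
    mu <- sum(s * z) / m
    pobj <- sum(f * v); dobj <- sum(h * z)
    gap <- abs(pobj - dobj) / (1 + abs(pobj))
    rp_rel <- sqrt(sum(rp^2)) / norm_h
    rd_rel <- sqrt(sum(rd^2)) / norm_f
    merit <- max(gap, rp_rel, rd_rel)
    if (is.finite(merit) && merit < best$merit) {
      best <- list(merit = merit, v = v, z = z, s = s)
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (merit < tol) { status <- "optimal"; break }
    if (mu / (1 + abs(pobj)) < 1e-12 && rp_rel < tol && best$merit < 1e-7) {
      status <- "optimal"; break
    }
    if (!is.finite(merit) || mu <= 0) { status <- "numerical"; break }
    if (stall >= 25) { status <- "stalled"; break }

    w <- z / s
    H <- Matrix::crossprod(G * sqrt(w))
    dmax <- max(Matrix::diag(H), 1)
    ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(H) +
                                      Matrix::Diagonal(n, 1e-13 * dmax),
                                    LDL = FALSE),
                   error = function(e) NULL)
    if (is.null(ch)) {
      ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(H) +
                                        Matrix::Diagonal(n, 1e-7 * dmax),
                                      LDL = FALSE),
                     error = function(e) NULL)
      if (is.null(ch)) { status <- "numerical"; break }
    }
    newton <- function(rc) {
      rhs <- rd - as.numeric(Gt %*% (w * rp)) - as.numeric(Gt %*% (rc / s))
      dv <- as.numeric(Matrix::solve(ch, rhs))
      ## one step of iterative refinement against the unregularised
      ## normal matrix; the diagonal shift plus wide z/s ratios can cost
      ## several digits otherwise
      res <- rhs - as.numeric(Gt %*% (w * as.numeric(G %*% dv)))
      dv <- dv + as.numeric(Matrix::solve(ch, res))
      ds <- as.numeric(G %*% dv) + rp
      dz <- -(rc + z * ds) / s
      list(dv = dv, ds = ds, dz = dz)
    }
    max_step <- function(x, dx) {
      neg <- which(dx < 0)
      if (!length(neg)) return(1)
      min(1, min(-x[neg] / dx[neg]))
    }

    ## predictor (affine) step
    aff <- newton(s * z)
    if (!all(is.finite(aff$dv))) { status <- "numerical"; break }
    ap <- max_step(s, aff$ds); ad <- max_step(z, aff$dz)
    mu_aff <- sum((s + ap * aff$ds) * (z + ad * aff$dz)) / m
    sigma <- min(1, max(0, mu_aff / mu))^3

    ## corrector step
    cor <- newton(s * z + aff$ds * aff$dz - sigma * mu)
    if (!all(is.finite(cor$dv))) { status <- "numerical"; break }
    ap <- step * max_step(s, cor$ds)
    ad <- step * max_step(z, cor$dz)
    v <- v + ap * cor$dv
    s <- s + ap * cor$ds
    z <- z + ad * cor$dz
  }
  if (status %in% c("max_iter", "stalled", "numerical") ||
      !all(is.finite(v))) {
    v <- best$v; z <- best$z; s <- best$s
    if (best$merit < 1e-6) status <- "optimal"
  }
  list(v = v, z = z, s = s, objective = sum(f * v),
       dual_objective = sum(h * z), status = status, iterations = it,
       merit = best$merit)
}
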