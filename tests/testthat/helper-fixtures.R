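## Shared fixtures and independent oracles. All fixtures are generated
## in code under fixed seeds.

## small two-variable continuous problem with a one-step signal
small_step_problem <- function(n = 60, seed = 42, max_bins = 4,
                               method = "lp") {
  set.seed(seed)
  x <- data.frame(a = runif(n), b = runif(n))
  y <- ifelse(runif(n) < plogis(3 * (x$a > 0.5) - 1.5), 1, -1)
  if (length(unique(y)) < 2) y[1:2] <- c(-1, 1)
  validate_problem(ics_problem(
    x, y, var_types = c("continuous", "continuous"), method = method,
    options = ics_options(max_bins = max_bins, cv_folds = 3, seed = seed)))
}

## encoded pieces for a problem
encoded_parts <- function(prob, encoding = "lp") {
  scheme <- build_scheme(prob)
  ze <- if (encoding == "lp") lp_encode(prob$x_train, scheme)
        else en_encode(prob$x_train, scheme)
  ds <- build_difference_structure(scheme)
  list(scheme = scheme, ze = ze, ds = ds)
}

## step-function fixture with known structure for reweighting/rounding
## checks: 2 informative + 1 noise variable, moderate n
step_fixture <- function(n = 150, seed = 7) {
  truth <- ics_truth(variables = list(
    list(name = "s1", type = "continuous", range = c(0, 1),
         thresholds = 0.5, contrib = c(-1.5, 1.5)),
    list(name = "s2", type = "continuous", range = c(0, 1),
         thresholds = 0.5, contrib = c(-1.2, 1.2)),
    list(name = "nz", type = "continuous", range = c(0, 1),
         thresholds = numeric(0), contrib = 0)
  ), seed = seed)
  make_piecewise_dataset(truth, n)
}

## independent LP oracle: scipy.optimize.linprog (HiGHS) through python
scipy_lp_objective <- function(Z, D, y, gamma) {
  td <- tempfile("lporacle")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  utils::write.csv(as.matrix(Z), file.path(td, "Z.csv"), row.names = FALSE)
  utils::write.csv(as.matrix(D), file.path(td, "D.csv"), row.names = FALSE)
  utils::write.csv(data.frame(y = y), file.path(td, "y.csv"), row.names = FALSE)
  out <- system2("python",
                 c(testthat::test_path("lp_oracle.py"), td, format(gamma, digits = 17)),
                 stdout = TRUE, stderr = TRUE)
  val <- suppressWarnings(as.numeric(out[length(out)]))
  if (is.na(val)) stop("LP oracle failed: ", paste(out, collapse = "\n"))
  val
}

## exact oracle for the penalized elastic net via the KKT system: given
## an active set and sign pattern, the optimum solves ridge-regularised
## normal equations; the inactive coordinates must satisfy the
## subgradient bound. Returns NULL if the certificate fails.
en_kkt_oracle <- function(X, y, lambda1, w_active, ridge = 0.05) {
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  act <- which(abs(w_active) > 1e-10)
  if (!length(act)) {
    r <- yc
    if (any(abs(crossprod(Xc, r)) > lambda1 / 2 + 1e-7)) return(NULL)
    return(list(w = numeric(ncol(X)), objective = sum(r^2)))
  }
  sA <- sign(w_active[act])
  XA <- Xc[, act, drop = FALSE]
  wA <- solve(crossprod(XA) + ridge * diag(length(act)),
              crossprod(XA, yc) - (lambda1 / 2) * sA)
  if (any(sign(wA) != sA)) return(NULL)
  r <- yc - XA %*% wA
  inact <- setdiff(which(colSums(Xc^2) > 1e-12), act)
  if (any(abs(crossprod(Xc[, inact, drop = FALSE], r)) > lambda1 / 2 + 1e-7))
    return(NULL)
  w <- numeric(ncol(X)); w[act] <- wA
  list(w = w, objective = sum(r^2) + ridge * sum(wA^2))
}

## glmnet oracle for the penalized elastic net
##   min ||y - b - X w||^2 + ridge ||w||^2 + lambda1 ||w||_1
## mapped onto glmnet's 1/(2n) RSS + lam (al |w|_1 + (1-al)/2 |w|_2^2)
glmnet_en_oracle <- function(X, y, lambda1, ridge = 0.05) {
  n <- nrow(X)
  lam <- lambda1 / (2 * n) + ridge / n
  al <- (lambda1 / (2 * n)) / lam
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = al,
                        lambda = lam * c(8, 4, 2, 1), standardize = FALSE,
                        thresh = 1e-15, maxit = 1e7)
  w <- as.numeric(fit$beta[, ncol(fit$beta)])
  b <- fit$a0[length(fit$a0)]
  list(w = w, b = unname(b),
       objective = sum((y - as.numeric(X %*% w) - b)^2) + ridge * sum(w^2))
}
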