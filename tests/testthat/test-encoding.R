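test_that("lp encoding is one-hot per effect for every row", {
  for (s in 1:5) {
    set.seed(200 + s)
    n <- 40
    x <- data.frame(a = runif(n), b = sample(c("p", "q", "r"), n, TRUE),
                    c = rbinom(n, 1, 0.4), d = sample(1:6, n, TRUE))
    y <- rep(c(-1, 1), n / 2)
    prob <- validate_problem(ics_problem(
      x, y, var_types = c("continuous", "categorical", "binary", "ordinal"),
      options = ics_options(max_bins = 4)))
    scheme <- suppressWarnings(build_scheme(prob))
    ze <- lp_encode(prob$x_train, scheme)
    expect_true(all(ze$z %in% c(0, 1)))
    expect_equal(unname(rowSums(ze$z)), rep(length(prob$groups), n))
    for (e in seq_along(prob$groups)) {
      blk <- ze$z[, ze$column_map$effect == e, drop = FALSE]
      expect_equal(unname(rowSums(blk)), rep(1, n))
    }
  }
})

test_that("binary and first-interval indicators match the convention", {
  x <- data.frame(v = c(0, 1, 0))
  prob <- validate_problem(ics_problem(x, c(-1, 1, 1), var_types = "binary"))
  ze <- lp_encode(prob$x_train, build_scheme(prob))
  expect_equal(ze$z[1, ], c(1, 0))
  expect_equal(ze$z[2, ], c(0, 1))

  set.seed(5)
  x <- data.frame(v = runif(30))
  prob <- validate_problem(ics_problem(x, rep(c(-1, 1), 15),
                                       options = ics_options(max_bins = 4)))
  scheme <- build_scheme(prob)
  ze <- lp_encode(data.frame(v = min(scheme$vars[[1]]$thresholds) - 1), scheme)
  expect_equal(as.numeric(ze$z), c(1, rep(0, scheme$vars[[1]]$n_intervals - 1)))
})

test_that("en encoding is a prefix of ones and ties to the lp encoding", {
  set.seed(6)
  n <- 50
  x <- data.frame(a = runif(n), b = runif(n))
  prob <- validate_problem(ics_problem(x, rep(c(-1, 1), 25), method = "en",
                                       options = ics_options(max_bins = 5)))
  scheme <- build_scheme(prob)
  zl <- lp_encode(prob$x_train, scheme)
  zh <- en_encode(prob$x_train, scheme)
  for (e in seq_along(prob$groups)) {
    blk <- zh$z[, zh$column_map$effect == e, drop = FALSE]
    expect_true(all(blk[, 1] == 1))                   # leading all-ones
    expect_true(all(apply(blk, 1, diff) <= 0))        # monotone prefix
    ## lp block is the first difference of the en block (trailing zero)
    lp_blk <- zl$z[, zl$column_map$effect == e, drop = FALSE]
    expect_equal(lp_blk, t(apply(cbind(blk, 0), 1, function(r) -diff(r))),
                 ignore_attr = TRUE)
  }
  ## value at or above the last threshold activates the whole block
  v1 <- scheme$vars[[1]]
  zh_top <- en_encode(data.frame(a = max(v1$thresholds) + 1, b = 0.5), scheme)
  expect_equal(as.numeric(zh_top$z[, zh_top$column_map$effect == 1]),
               rep(1, v1$n_intervals))
})

test_that("interaction blocks hold a single 1 at the column-major cell", {
  set.seed(7)
  n <- 120
  x <- data.frame(a = runif(n), b = runif(n))
  prob <- validate_problem(ics_problem(x, rep(c(-1, 1), 60),
                                       groups = list(c(1L, 2L)),
                                       options = ics_options(max_bins = 4)))
  scheme <- build_scheme(prob)
  ze <- lp_encode(prob$x_train, scheme)
  n1 <- scheme$vars[[1]]$n_intervals; n2 <- scheme$vars[[2]]$n_intervals
  i1 <- findInterval(x$a, scheme$vars[[1]]$thresholds) + 1
  i2 <- findInterval(x$b, scheme$vars[[2]]$thresholds) + 1
  expect_equal(unname(rowSums(ze$z)), rep(1, n))
  hit <- apply(ze$z, 1, which.max)
  expect_equal(hit, (i2 - 1) * n1 + i1)  # column-major vectorisation
  expect_equal(ze$column_map$k, rep(seq_len(n1), times = n2))
  expect_equal(ze$column_map$l, rep(seq_len(n2), each = n1))
})

test_that("difference structure counts rows per effect correctly", {
  set.seed(8)
  n <- 200
  x <- data.frame(a = runif(n), b = runif(n))
  prob <- validate_problem(ics_problem(x, rep(c(-1, 1), 100),
                                       groups = list(1L, 2L, c(1L, 2L)),
                                       options = ics_options(max_bins = 4)))
  scheme <- build_scheme(prob)
  n1 <- scheme$vars[[1]]$n_intervals; n2 <- scheme$vars[[2]]$n_intervals
  expect_equal(c(n1, n2), c(4L, 4L))
  ds <- build_difference_structure(scheme)
  ## mains: (n1-1) + (n2-1); interaction grid k x l: k(l-1) + l(k-1)
  expect_equal(ds$n_ds, (n1 - 1) + (n2 - 1) + n1 * (n2 - 1) + n2 * (n1 - 1))
  ## every row: one +1 and one -1 inside a single effect block
  dmat <- as.matrix(ds$d)
  expect_true(all(apply(dmat, 1, function(r) sum(r == 1) == 1 && sum(r == -1) == 1)))
  ze <- lp_encode(prob$x_train, scheme)
  col_effect <- ze$column_map$effect
  for (r in seq_len(nrow(dmat))) {
    nz <- which(dmat[r, ] != 0)
    expect_length(unique(col_effect[nz]), 1)
    expect_equal(unique(col_effect[nz]), ds$row_map[r])
  }
})

test_that("a 3x4 interaction grid yields 17 difference rows", {
  set.seed(9)
  n <- 400
  x <- data.frame(a = runif(n), b = runif(n))
  prob <- validate_problem(ics_problem(x, rep(c(-1, 1), 200),
                                       groups = list(c(1L, 2L))))
  scheme <- build_scheme(prob)
  scheme$vars[[1]]$thresholds <- scheme$vars[[1]]$thresholds[1:2]
  scheme$vars[[1]]$n_intervals <- 3L
  scheme$vars[[2]]$thresholds <- scheme$vars[[2]]$thresholds[1:3]
  scheme$vars[[2]]$n_intervals <- 4L
  ds <- build_difference_structure(scheme)
  expect_equal(ds$n_ds, 3 * 3 + 4 * 2)  # 17
})

test_that("reconstruction inverts the per-variable difference operator", {
  prob <- small_step_problem(method = "en")
  parts <- encoded_parts(prob, "en")
  ds <- parts$ds
  expect_equal(as.matrix(ds$r %*% ds$d_full), diag(ds$n_s), ignore_attr = TRUE)
  ## R is block lower-triangular of ones
  expect_true(all(as.matrix(ds$r) %in% c(0, 1)))

  ## w_tilde' z_lp == w_hat' z_en whenever w_tilde = R w_hat
  zl <- lp_encode(prob$x_train, parts$scheme)
  set.seed(10)
  for (i in 1:5) {
    w_hat <- rnorm(ds$n_s)
    w_tilde <- as.numeric(ds$r %*% w_hat)
    expect_equal(as.numeric(zl$z %*% w_tilde),
                 as.numeric(parts$ze$z %*% w_hat), tolerance = 1e-12)
  }
})

test_that("unseen categorical levels produce an all-zero block and warning", {
  x <- data.frame(g = c("u", "v", "u", "v", "u", "v"))
  prob <- validate_problem(ics_problem(x, rep(c(-1, 1), 3),
                                       var_types = "categorical"))
  scheme <- build_scheme(prob)
  expect_warning(ze <- lp_encode(data.frame(g = c("u", "zz")), scheme),
                 "unseen")
  expect_equal(unname(ze$z[2, ]), c(0, 0))
  expect_equal(unname(ze$z[1, ]), c(1, 0))
})

test_that("categorical encoding is stable under level relabeling", {
  x <- data.frame(g = c("u", "v", "w", "u", "v", "w"))
  y <- rep(c(-1, 1), 3)
  p1 <- validate_problem(ics_problem(x, y, var_types = "categorical"))
  z1 <- lp_encode(p1$x_train, build_scheme(p1))
  relab <- c(u = "B", v = "C", w = "A")
  x2 <- data.frame(g = unname(relab[x$g]))
  p2 <- validate_problem(ics_problem(x2, y, var_types = "categorical"))
  z2 <- lp_encode(p2$x_train, build_scheme(p2))
  expect_equal(z1$z, z2$z)  # first-appearance catalogue order is shared
})
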