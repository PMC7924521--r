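test_that("AUC attains its analytic anchors", {
  y <- rep(c(1, -1), each = 10)
  s_perfect <- c(runif(10, 2, 3), runif(10, 0, 1))
  expect_equal(roc_auc(s_perfect, y)$auc, 1)
  expect_equal(roc_auc(rep(0.3, 20), y)$auc, 0.5)
  expect_error(roc_auc(runif(5), rep(1, 5)), "positive and")
})

test_that("AUC equals brute-force pairwise concordance", {
  brute_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == -1]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  for (seed in 1:8) {
    set.seed(500 + seed)
    n <- sample(10:40, 1)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(-1, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # ties likely
    expect_equal(roc_auc(s, y)$auc, brute_auc(s, y))
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(20)
  y <- sample(c(-1, 1), 50, replace = TRUE); y[1:2] <- c(-1, 1)
  s <- rnorm(50)
  a0 <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a0)
  expect_equal(roc_auc(3 * s - 10, y)$auc, a0)
  expect_equal(roc_auc(rank(s, ties.method = "average"), y)$auc, a0)
})

test_that("trapezoidal ROC area equals the concordance AUC", {
  for (seed in 1:5) {
    set.seed(520 + seed)
    y <- sample(c(-1, 1), 60, replace = TRUE); y[1:2] <- c(-1, 1)
    s <- sample(1:8, 60, replace = TRUE)
    ra <- roc_auc(s, y)
    trap <- sum(diff(ra$roc$fpr) * (head(ra$roc$tpr, -1) + tail(ra$roc$tpr, -1)) / 2)
    expect_equal(trap, ra$auc, tolerance = 1e-12)
    expect_equal(ra$roc$fpr[1], 0); expect_equal(ra$roc$tpr[1], 0)
    expect_equal(ra$roc$fpr[nrow(ra$roc)], 1)
    expect_equal(ra$roc$tpr[nrow(ra$roc)], 1)
    expect_true(all(diff(ra$roc$fpr) >= 0))
    expect_true(all(diff(ra$roc$tpr) >= 0))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  y <- sample(c(-1, 1), 80, replace = TRUE); y[1:2] <- c(-1, 1)
  s <- rnorm(80) + 0.8 * y
  ref <- as.numeric(pROC::auc(pROC::roc(response = factor(y, levels = c(-1, 1)),
                                        predictor = s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(s, y)$auc, ref, tolerance = 1e-12)
})

test_that("accuracy counts sign-correct predictions at a threshold", {
  y <- rep(c(-1, 1), each = 5)
  s <- c(1:5, 6:10)
  expect_equal(ics_accuracy(s, y, threshold = 5.5), 1)
  expect_equal(ics_accuracy(s, -y, threshold = 5.5), 0)
  set.seed(22)
  ss <- rnorm(30); yy <- sample(c(-1, 1), 30, replace = TRUE)
  thr <- 0.2
  expect_equal(ics_accuracy(ss, yy, thr),
               mean(ifelse(ss >= thr, 1, -1) == yy))
})

test_that("the calibration curve recovers exact affine relationships", {
  ## groups engineered so the empirical risk is exactly the predicted
  pred <- rep(c(0.2, 0.5, 0.8), each = 10)
  emp_counts <- c(2, 5, 8)  # positives per 10 in each group
  y <- unlist(lapply(emp_counts, function(k) c(rep(1, k), rep(-1, 10 - k))))
  cc <- calibration_curve(pred, y)
  expect_equal(cc$a_cal, 1, tolerance = 1e-12)
  expect_equal(cc$b_cal, 0, tolerance = 1e-12)

  ## empirical = predicted + 0.1 exactly
  pred2 <- rep(c(0.2, 0.4, 0.6), each = 10)
  y2 <- unlist(lapply(c(3, 5, 7), function(k) c(rep(1, k), rep(-1, 10 - k))))
  cc2 <- calibration_curve(pred2, y2)
  expect_equal(cc2$a_cal, 1, tolerance = 1e-12)
  expect_equal(cc2$b_cal, 0.1, tolerance = 1e-12)

  expect_error(calibration_curve(rep(0.5, 10), rep(c(-1, 1), 5)), "distinct")
})

test_that("the calibration fit matches weighted normal equations", {
  set.seed(23)
  pred <- rep(round(runif(6), 2), times = sample(2:8, 6, replace = TRUE))
  y <- ifelse(runif(length(pred)) < pmin(pmax(pred + 0.1, 0), 1), 1, -1)
  if (length(unique(y)) < 2) y[1:2] <- c(-1, 1)
  cc <- calibration_curve(pred, y)
  g <- cc$groups
  X <- cbind(1, g$predicted)
  beta <- solve(t(X) %*% (g$n * X), t(X) %*% (g$n * g$empirical))
  expect_equal(cc$b_cal, beta[1], tolerance = 1e-10)
  expect_equal(cc$a_cal, beta[2], tolerance = 1e-10)
})

test_that("the calibration error closed form matches quadrature", {
  expect_equal(calibration_error(1, 0), 0)
  expect_equal(calibration_error(1, 0.3), 0.3)
  expect_equal(calibration_error(1, -0.4), 0.4)

  quad <- function(a, b) {
    stats::integrate(function(p) abs((a - 1) * p + b), 0, 1,
                     subdivisions = 2000, rel.tol = 1e-13)$value
  }
  ## the published liver calibration pair (slope 0.44, bias 0.40)
  expect_equal(calibration_error(0.44, 0.40), quad(0.44, 0.40),
               tolerance = 1e-10)
  set.seed(24)
  for (i in 1:100) {
    a <- runif(1, -1, 3); b <- runif(1, -1, 1)
    expect_equal(calibration_error(a, b), quad(a, b), tolerance = 1e-10)
  }
})
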