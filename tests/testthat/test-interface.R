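make_cli_fixture <- function(td, n = 200, seed = 60) {
  truth <- ics_truth(seed = seed)
  d <- make_piecewise_dataset(truth, n)
  df <- cbind(d$x, outcome = ifelse(d$y > 0, 1, 0))
  utils::write.csv(df, file.path(td, "train.csv"), row.names = FALSE)
  writeLines(c("method: en", "cv_folds: 4", "seed: 3",
               "weight_grid: [-1, 1, 4]"),
             file.path(td, "cfg.yaml"))
  d
}

test_that("the fit subcommand trains and serializes a model", {
  td <- withr::local_tempdir()
  d <- make_cli_fixture(td)
  st <- suppressMessages(suppressWarnings(
    ics_main(c("fit", "--data", file.path(td, "train.csv"),
               "--label-col", "outcome", "--config", file.path(td, "cfg.yaml"),
               "--out", file.path(td, "model.json")))))
  expect_equal(st, 0L)
  expect_true(file.exists(file.path(td, "model.json")))
  m <- read_ics_model(file.path(td, "model.json"))
  expect_s3_class(m, "ics_model")
  expect_equal(m$method, "en")

  ## minimal invocation without config: all-main-effects defaults
  st2 <- suppressMessages(suppressWarnings(
    ics_main(c("fit", "--data", file.path(td, "train.csv"),
               "--label-col", "outcome",
               "--out", file.path(td, "model2.json")))))
  expect_equal(st2, 0L)
})

test_that("prediction round-trips and is header-driven", {
  td <- withr::local_tempdir()
  d <- make_cli_fixture(td)
  suppressMessages(suppressWarnings(
    ics_main(c("fit", "--data", file.path(td, "train.csv"),
               "--label-col", "outcome", "--config", file.path(td, "cfg.yaml"),
               "--out", file.path(td, "model.json")))))
  st <- suppressMessages(
    ics_main(c("predict", "--model", file.path(td, "model.json"),
               "--data", file.path(td, "train.csv"),
               "--out", file.path(td, "pred.csv"))))
  expect_equal(st, 0L)
  pred <- utils::read.csv(file.path(td, "pred.csv"))
  expect_named(pred, c("row_id", "score", "risk", "predicted_class"))

  m <- read_ics_model(file.path(td, "model.json"))
  direct <- predict(m, d$x)
  expect_equal(pred$score, direct$score)
  expect_equal(pred$risk, direct$risk, tolerance = 1e-12)

  ## permuted column order with named header gives identical output
  perm <- rev(seq_len(ncol(d$x)))
  p2 <- predict(m, d$x[, perm])
  expect_identical(p2$score, direct$score)

  ## single-row input works
  p1 <- predict(m, d$x[1, , drop = FALSE])
  expect_equal(nrow(p1), 1)
  expect_equal(p1$score, direct$score[1])
})

test_that("missing inputs surface as nonzero exit codes", {
  td <- withr::local_tempdir()
  make_cli_fixture(td)
  expect_equal(suppressMessages(
    ics_main(c("fit", "--data", file.path(td, "train.csv"),
               "--label-col", "nope", "--out", file.path(td, "m.json")))), 1L)
  expect_equal(suppressWarnings(suppressMessages(
    ics_main(c("fit", "--data", file.path(td, "missing.csv"),
               "--label-col", "outcome", "--out", file.path(td, "m.json"))))), 1L)
  expect_equal(suppressMessages(ics_main(c("frobnicate"))), 1L)
})

test_that("the assess subcommand writes a JSON report", {
  td <- withr::local_tempdir()
  make_cli_fixture(td)
  suppressMessages(suppressWarnings(
    ics_main(c("fit", "--data", file.path(td, "train.csv"),
               "--label-col", "outcome", "--config", file.path(td, "cfg.yaml"),
               "--out", file.path(td, "model.json")))))
  st <- suppressMessages(utils::capture.output(
    res <- ics_main(c("assess", "--model", file.path(td, "model.json"),
                      "--data", file.path(td, "train.csv"),
                      "--label-col", "outcome",
                      "--report", file.path(td, "rep.json")))))
  expect_equal(res, 0L)
  rep <- jsonlite::read_json(file.path(td, "rep.json"))
  expect_true(all(c("auc", "accuracy", "a_cal", "b_cal") %in% names(rep)))
  expect_true(rep$auc >= 0 && rep$auc <= 1)
})

test_that("text score cards list every threshold, point and risk", {
  d <- step_fixture(n = 150, seed = 61)
  m <- suppressWarnings(run_ics(ics_problem(
    d$x, d$y, options = ics_options(cv_folds = 3, seed = 2, max_bins = 5,
                                    weight_grid = c(-1, 1), gamma_grid = 10))))
  txt <- paste(render_scorecard(m, "txt"), collapse = "\n")
  for (eff in m$effects) {
    expect_true(grepl(eff$name, txt, fixed = TRUE))
    for (p in eff$points)
      expect_true(grepl(sprintf("%+d", p), txt, fixed = TRUE))
    for (thr in eff$thresholds)
      expect_true(grepl(format(thr, digits = 4), txt, fixed = TRUE))
  }
  for (r in m$risk_table$risk)
    expect_true(grepl(sprintf("%.1f%%", 100 * r), txt, fixed = TRUE))
})

test_that("intercept-only models render just the risk strip", {
  x <- data.frame(v = rep(1, 40))
  y <- rep(c(-1, 1), 20)
  m <- suppressWarnings(run_ics(ics_problem(
    x, y, options = ics_options(cv_folds = 3, seed = 1,
                                weight_grid = c(-1, 1), gamma_grid = 10))))
  txt <- render_scorecard(m, "txt")
  expect_false(any(grepl("^-- v --$", txt)))
  expect_true(any(grepl("risk profile", txt)))
  svg <- render_scorecard(m, "svg")
  expect_true(any(grepl("<svg", svg)))
})

test_that("svg cards colour equal points identically across effects", {
  d <- step_fixture(n = 200, seed = 62)
  m <- suppressWarnings(run_ics(ics_problem(
    d$x, d$y, method = "en",
    options = ics_options(cv_folds = 4, seed = 2, cutoff = c(0.75, 1)))))
  svg <- render_scorecard(m, "svg")
  fills <- regmatches(svg, regexpr('fill="[^"]*"', svg))
  expect_gt(length(fills), 0)
  ## collect (point value -> fill) pairs from effect strips
  pts <- unlist(lapply(m$effects, `[[`, "points"))
  if (length(unique(pts)) > 1 && length(m$effects) > 1) {
    rects <- grep("<rect", svg, value = TRUE)
    texts <- grep("<text", svg, value = TRUE)
    expect_gt(length(rects), length(unique(pts)) - 1)
  }
  ## grayscale variant emits grey fills (equal rgb channels)
  svg_g <- render_scorecard(m, "svg", grayscale = TRUE)
  g_fills <- regmatches(svg_g, regexpr('fill="#[0-9A-F]{6}"', svg_g))
  chan <- function(f) {
    h <- sub('fill="#', "", f); h <- sub('"', "", h)
    c(substr(h, 1, 2), substr(h, 3, 4), substr(h, 5, 6))
  }
  for (f in g_fills) expect_length(unique(chan(f)), 1)
})

test_that("equal point values map to equal colours", {
  pal <- icscore:::point_colour(c(0, 1, 1, -2, 0), c(-2, 0, 1), FALSE)
  expect_equal(pal[1], pal[5])
  expect_equal(pal[2], pal[3])
  expect_false(pal[1] == pal[4])
  ## grayscale maps magnitude: |1| == |-1|
  pg <- icscore:::point_colour(c(-1, 1), c(-1, 1), TRUE)
  expect_equal(pg[1], pg[2])
})
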