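test_that("the worked two-class example yields its textbook metrics", {
  gt <- c("A", "A", "B", "B")
  pred <- c("A", "B", "B", "B")
  m <- classwise_prf(gt, pred)
  pc <- m$per_class
  expect_equal(pc$precision[pc$class == "A"], 1)
  expect_equal(pc$recall[pc$class == "A"], 0.5)
  expect_equal(pc$f1[pc$class == "A"], 2 / 3)
  expect_equal(pc$precision[pc$class == "B"], 2 / 3)
  expect_equal(pc$recall[pc$class == "B"], 1)
  expect_equal(pc$f1[pc$class == "B"], 0.8)
  expect_equal(m$macro_pr, 5 / 6)
  expect_equal(m$macro_re, 0.75)
  expect_equal(m$macro_f1, (2 / 3 + 0.8) / 2)
  expect_equal(m$accuracy, 0.75)
  expect_equal(frame_accuracy(gt, pred), 0.75)
  expect_output(print(m), "macro PR")
})

test_that("metrics match a brute-force oracle on random label pairs", {
  set.seed(22)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    k <- sample(2:8, 1)
    gt <- sample(0:(k - 1), n, replace = TRUE)
    pred <- sample(0:(k - 1), n, replace = TRUE)
    m <- classwise_prf(gt, pred)
    o <- oracle_prf(gt, pred)
    expect_equal(m$macro_pr, o$macro_pr)
    expect_equal(m$macro_re, o$macro_re)
    expect_equal(m$macro_f1, o$macro_f1)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(frame_accuracy(gt, pred), o$accuracy)
  }
})

test_that("undefined metric cases resolve as documented", {
  # class 2 is never predicted but occurs in the ground truth: PR = 0, F1 = 0
  m <- classwise_prf(c(0, 2, 2), c(0, 0, 0), classes = 0:2)
  pc <- m$per_class
  expect_equal(pc$precision[pc$class == 2], 0)
  expect_equal(pc$recall[pc$class == 2], 0)
  expect_equal(pc$f1[pc$class == 2], 0)
  # class 1 appears in neither track: NA metrics, excluded from the macros
  expect_true(is.na(pc$precision[pc$class == 1]))
  expect_equal(m$macro_pr, mean(c(1 / 3, 0)))
  # frame accuracy is the micro-average: sum of per-class TP over frames
  gt <- c(0, 0, 1, 2, 2)
  pred <- c(0, 1, 1, 2, 0)
  m2 <- classwise_prf(gt, pred)
  tp_total <- sum(vapply(unique(gt), function(c0) sum(gt == c0 & pred == c0),
                         numeric(1)))
  expect_equal(m2$accuracy, tp_total / length(gt))
})

test_that("joint accuracy counts frames where both tasks are right", {
  gp <- c(0, 0, 1, 1)
  pp <- c(0, 0, 1, 0)
  gs <- c(0, 1, 2, 3)
  ps <- c(0, 0, 2, 3)
  expect_equal(joint_accuracy(gp, pp, gs, ps), 0.5)
  expect_lte(joint_accuracy(gp, pp, gs, ps),
             min(frame_accuracy(gp, pp), frame_accuracy(gs, ps)))
  set.seed(23)
  for (i in 1:20) {
    gp <- sample(0:2, 30, replace = TRUE); pp <- sample(0:2, 30, replace = TRUE)
    gs <- sample(0:5, 30, replace = TRUE); ps <- sample(0:5, 30, replace = TRUE)
    expect_lte(joint_accuracy(gp, pp, gs, ps),
               min(frame_accuracy(gp, pp), frame_accuracy(gs, ps)))
  }
  expect_error(joint_accuracy(0:1, 0:1, 0:1, 0L), "equal")
})

test_that("cross-validation folds partition the corpus", {
  ids <- paste0("video", 1:40)
  folds <- make_folds(ids, n_folds = 4, n_val = 6, seed = 2)
  expect_length(folds, 4L)
  test_sets <- lapply(folds, `[[`, "test")
  expect_setequal(unlist(test_sets), ids)
  expect_equal(anyDuplicated(unlist(test_sets)), 0L)
  for (f in folds) {
    expect_length(f$test, 10L)
    expect_length(f$val, 6L)
    expect_length(f$train, 24L)
    expect_setequal(c(f$test, f$val, f$train), ids)
  }
  expect_identical(folds, make_folds(ids, n_folds = 4, n_val = 6, seed = 2))
  expect_false(identical(folds, make_folds(ids, seed = 3)))
  expect_error(make_folds(ids[1:39], n_folds = 4), "equal test sets")
  expect_error(make_folds(ids[1:8], n_folds = 4, n_val = 6), "no training")
})

test_that("fold aggregation reports mean and sample sd", {
  a <- aggregate_folds(c(80, 90))
  expect_equal(a$mean, 85)
  expect_equal(a$sd, sd(c(80, 90)))
  expect_equal(a$sd, 7.0710678, tolerance = 1e-6)
  expect_equal(aggregate_folds(5)$sd, 0)
  expect_error(aggregate_folds(numeric(0)), "no fold values")
})

test_that("evaluate_predictions averages per video or pools frames", {
  tls <- list(timeline("a", c(0L, 0L), c(0L, 0L)),
              timeline("b", c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L)))
  preds <- list(list(phase = c(0L, 0L), step = c(0L, 0L)),
                list(phase = c(0L, 1L, 1L, 1L), step = c(0L, 1L, 1L, 1L)))
  pv <- evaluate_predictions(tls, preds)
  acc <- function(d, task) d$value[d$task == task & d$metric == "accuracy"]
  expect_equal(acc(pv, "phase"), (1 + 0.75) / 2)
  expect_equal(acc(pv, "joint"), (1 + 0.75) / 2)
  pooled <- evaluate_predictions(tls, preds, granularity = "pooled")
  expect_equal(acc(pooled, "phase"), 5 / 6)
  expect_setequal(unique(pv$task), c("phase", "step", "joint"))
  # single-task predictions evaluate only the available head
  sp <- lapply(preds, function(p) p["step"])
  ev <- evaluate_predictions(tls, sp)
  expect_setequal(unique(ev$task), "step")
})
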