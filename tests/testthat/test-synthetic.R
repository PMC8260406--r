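test_that("workflow_model validates its step parameter table", {
  h <- tiny_hierarchy(c(2L, 1L))
  sp <- data.frame(step_id = 0:2, incl_prob = 1, mean_dur = 10, size = 2,
                   min_dur = 1, max_dur = Inf)
  expect_s3_class(workflow_model(h, sp), "surgtcn_workflow_model")
  expect_error(workflow_model(h, sp[, -2]), "missing column")
  expect_error(workflow_model(h, sp[1:2, ]), "exactly the steps")
  bad <- sp; bad$incl_prob[1] <- 1.5
  expect_error(workflow_model(h, bad), "incl_prob")
  bad <- sp; bad$mean_dur[2] <- 0
  expect_error(workflow_model(h, bad), "mean durations")
  bad <- sp; bad$min_dur[1] <- 10; bad$max_dur[1] <- 5
  expect_error(workflow_model(h, bad), "min_dur")
  expect_error(workflow_model(h, sp, phase_skip_prob = 1), "skip")
})

test_that("sampled timelines are deterministic, ordered and consistent", {
  su <- recovery_setup()
  tl1 <- sample_workflow(su$wm, 42L, "v")
  tl2 <- sample_workflow(su$wm, 42L, "v")
  expect_identical(tl1$phase_labels, tl2$phase_labels)
  expect_identical(tl1$step_labels, tl2$step_labels)
  tl3 <- sample_workflow(su$wm, 43L, "v")
  expect_false(identical(tl1$step_labels, tl3$step_labels))
  # phases are visited in ontology order and the step program is ordered
  expect_true(all(diff(tl1$phase_labels) >= 0L))
  expect_true(all(diff(tl1$step_labels) >= 0L))
  expect_equal(nrow(validate_timeline(tl1, su$h)), 0L)
})

test_that("degenerate dwell bounds pin every segment to a fixed length", {
  h <- tiny_hierarchy(c(2L, 1L))
  sp <- data.frame(step_id = 0:2, incl_prob = 1, mean_dur = 5, size = 3,
                   min_dur = 5, max_dur = 5)
  m <- workflow_model(h, sp)
  tl <- sample_workflow(m, 1L)
  expect_equal(n_frames(tl), 15L)
  expect_equal(rle(tl$step_labels)$lengths, c(5L, 5L, 5L))
  # the implied expectation matches: 3 mandatory steps x 5 frames
  epd <- expected_phase_durations(m)
  expect_equal(epd$mean_frames, c(10, 5))
})

test_that("sampled phase durations match their expectation within 3 SE", {
  h <- tiny_hierarchy(c(2L, 2L, 2L))
  sp <- data.frame(step_id = 0:5,
                   incl_prob = c(1, 0.8, 1, 0.6, 1, 0.9),
                   mean_dur = c(10, 20, 30, 40, 15, 25),
                   size = 5, min_dur = 1, max_dur = Inf)
  m <- workflow_model(h, sp)
  n <- 200L
  per_video <- vapply(seq_len(n), function(i) {
    tl <- sample_workflow(m, surgtcn:::child_seed(9L, i))
    tabulate(tl$phase_labels + 1L, nbins = 3L)
  }, numeric(3))
  expected <- expected_phase_durations(m)$mean_frames
  for (p in 1:3) {
    se <- sd(per_video[p, ]) / sqrt(n)
    expect_lt(abs(mean(per_video[p, ]) - expected[p]), 3 * se + 1e-9)
  }
})

test_that("feature emission is a seeded Gaussian around the step means", {
  means <- rbind(c(1, 0, 0), c(0, 1, 0))
  em0 <- emission_model(2, dim = 3, step_means = means, noise_sd = 0)
  tl <- timeline("v", c(0L, 0L, 1L), c(0L, 0L, 1L))
  x <- emit_features(tl, em0, 1L)
  expect_equal(x, means[c(1, 1, 2), ], ignore_attr = TRUE)

  em <- emission_model(2, dim = 3, step_means = means, noise_sd = 0.5)
  x1 <- emit_features(tl, em, 5L)
  expect_identical(x1, emit_features(tl, em, 5L))
  expect_false(identical(x1, emit_features(tl, em, 6L)))
  expect_equal(dim(x1), c(3L, 3L))

  bad_tl <- timeline("v", 0L, 5L)
  expect_error(emit_features(bad_tl, em, 1L), "absent from the emission")
  expect_error(emission_model(2, dim = 3, noise_sd = -1), ">= 0")
})

test_that("drift adds a rank-one perturbation along a fixed direction", {
  means <- matrix(0, 2, 6)
  em <- emission_model(2, dim = 6, step_means = means, noise_sd = 0,
                       drift_sd = 1, seed = 3)
  tl <- timeline("v", rep(0L, 50L), rep(0L, 50L))
  x <- emit_features(tl, em, 11L)
  # every frame is a scalar multiple of the same unit direction
  expect_equal(abs(x %*% em$drift_dir), sqrt(rowSums(x^2)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("nearest-mean decoding recovers labels at low noise", {
  ns <- 12L
  means <- diag(1, ns)
  em <- emission_model(ns, dim = ns, step_means = means, noise_sd = 0.05)
  labels <- rep(seq_len(ns) - 1L, length.out = 10000L)
  tl <- timeline("v", parent_phase(tiny_hierarchy(rep(2L, 6L)), labels),
                 labels)
  x <- emit_features(tl, em, 21L)
  decoded <- max.col(x, ties.method = "first") - 1L
  expect_gt(mean(decoded == labels), 0.99)
})

test_that("the default corpus model matches its stated scale and long tail", {
  dm <- default_model(mean_video_minutes = 110, dim = 8)
  expected_total <- sum(expected_phase_durations(dm$workflow)$mean_frames *
                          (1 - dm$workflow$phase_skip_prob))
  expect_equal(expected_total, 110 * 60, tolerance = 0.02)
  dwell <- dm$workflow$step_params$mean_dur
  expect_gt(max(dwell) / min(dwell), 50) # long-tailed durations
  expect_equal(dm$emission$dim, 8L)
  tl <- sample_workflow(dm$workflow, 2L)
  expect_equal(nrow(validate_timeline(tl, default_hierarchy())), 0L)
})

test_that("corpus files round-trip through simulate_corpus / load_corpus", {
  dm <- default_model(mean_video_minutes = 1.5, dim = 5)
  dir <- file.path(tempdir(), "corpus_rt")
  manifest <- simulate_corpus(dir, 3L, dm, seed = 4L)
  expect_equal(nrow(manifest), 3L)
  corpus <- load_corpus(dir)
  expect_equal(names(corpus$timelines), manifest$video_id)
  for (i in 1:3) {
    vid <- manifest$video_id[i]
    tl <- sample_workflow(dm$workflow, surgtcn:::child_seed(4L, i, 1L), vid)
    x <- emit_features(tl, dm$emission, surgtcn:::child_seed(4L, i, 2L))
    expect_identical(corpus$timelines[[vid]]$step_labels, tl$step_labels)
    # float32 container: round-trip within single precision
    expect_equal(corpus$features[[vid]], x, tolerance = 1e-6)
  }
  expect_error(load_corpus(tempdir()), "manifest")
})
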