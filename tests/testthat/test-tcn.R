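test_that("causal dilated convolution matches hand-computed examples", {
  expect_equal(causal_dilated_conv(c(1, 1, 1, 1), c(1, 1, 1), dilation = 1),
               c(1, 2, 3, 3))
  # dilation 2 reads taps t, t-2, t-4
  expect_equal(causal_dilated_conv(c(1, 1, 1, 1, 1), c(1, 1, 1), dilation = 2),
               c(1, 1, 2, 2, 3))
  # a kernel with only the current-frame tap is the identity
  x <- rnorm(6)
  expect_equal(causal_dilated_conv(x, c(0, 0, 1), dilation = 4), x)
  # last tap is the current frame: weighting only the oldest tap delays
  expect_equal(causal_dilated_conv(1:5, c(1, 0, 0), dilation = 1),
               c(0, 0, 1, 2, 3))
  # multi-channel: C_out x C_in x k kernel
  xm <- rbind(1:4, c(0, 1, 0, 1))
  kern <- array(0, c(3, 2, 3))
  kern[1, 1, 3] <- 1 # out1 = in1 at t
  kern[2, 2, 2] <- 1 # out2 = in2 at t-1
  kern[3, 1, 1] <- 1 # out3 = in1 at t-2
  out <- causal_dilated_conv(xm, kern)
  expect_equal(out[1, ], c(1, 2, 3, 4))
  expect_equal(out[2, ], c(0, 0, 1, 0))
  expect_equal(out[3, ], c(0, 0, 1, 2))
  b <- causal_dilated_conv(xm, kern, bias = c(10, 20, 30))
  expect_equal(b[3, ], c(30, 30, 31, 32))
  expect_error(causal_dilated_conv(xm, kern, dilation = 0), "dilation")
  expect_error(causal_dilated_conv(rbind(x), kern), "input-channel")
})

test_that("the receptive field follows 1 + (k-1)(2^L - 1)", {
  expect_equal(receptive_field(10, 3), 2047)
  expect_equal(receptive_field(8, 3), 511)
  expect_equal(receptive_field(1, 3), 3)
  expect_equal(receptive_field(0, 3), 1)
  expect_equal(receptive_field(4, 5), 61)
  expect_error(receptive_field(-1), ">= 0")
})

test_that("parameter initialization is seeded and bounded by 1/sqrt(fan_in)", {
  cfg <- tcn_config(input_dim = 6, n_stages = 2, n_layers = 3,
                    n_channels = 8, seed = 4)
  p1 <- init_tcn_params(cfg)
  p2 <- init_tcn_params(cfg)
  expect_identical(p1, p2)
  cfg5 <- tcn_config(input_dim = 6, n_stages = 2, n_layers = 3,
                     n_channels = 8, seed = 5)
  expect_false(identical(p1, init_tcn_params(cfg5)))
  expect_true(all(abs(p1$s1_proj_w) <= 1 / sqrt(6)))
  expect_true(all(abs(p1$s1_l1_conv_w) <= 1 / sqrt(8 * 3)))
  expect_equal(p1$s1_proj_b, numeric(8))
  # stage 2 consumes the concatenated probability rows (width P + S)
  expect_equal(dim(p1$s2_proj_w), c(8L, 11L + 44L))
})

test_that("forward passes have normalized heads in every task mode", {
  x <- matrix(rnorm(30 * 5), 30, 5)
  for (tasks in c("both", "phase", "step")) {
    cfg <- tcn_config(input_dim = 5, n_phases = 4, n_steps = 9, n_stages = 2,
                      n_layers = 2, n_channels = 6, tasks = tasks, seed = 2)
    preds <- model_forward(x, init_tcn_params(cfg), cfg)
    expect_length(preds, 2L)
    for (s in 1:2) {
      if (tasks %in% c("both", "phase")) {
        expect_equal(dim(preds[[s]]$phase_scores), c(30L, 4L))
        expect_equal(rowSums(preds[[s]]$phase_scores), rep(1, 30))
      } else {
        expect_null(preds[[s]]$phase_scores)
      }
      if (tasks %in% c("both", "step")) {
        expect_equal(dim(preds[[s]]$step_scores), c(30L, 9L))
        expect_equal(rowSums(preds[[s]]$step_scores), rep(1, 30))
      } else {
        expect_null(preds[[s]]$step_scores)
      }
    }
  }
  cfg <- tcn_config(input_dim = 7)
  expect_error(model_forward(x, init_tcn_params(cfg), cfg),
               "does not match config")
})

test_that("the training loss decomposes over stages and tasks", {
  x <- matrix(rnorm(20 * 4), 20, 4)
  tl <- timeline("v", sample(0:10, 20, replace = TRUE),
                 sample(0:43, 20, replace = TRUE))
  for (S in 1:3) {
    cfg <- tcn_config(input_dim = 4, n_stages = S, n_layers = 2,
                      n_channels = 5, seed = 3)
    # all-zero parameters give uniform heads: total = S (ln 11 + ln 44)
    zero <- lapply(init_tcn_params(cfg), function(p) p * 0)
    l0 <- tcn_loss(model_forward(x, zero, cfg), tl)
    expect_equal(l0$total, S * (log(11) + log(44)))

    params <- init_tcn_params(cfg)
    l <- tcn_loss(model_forward(x, params, cfg), tl)
    expect_length(l$stages, S)
    for (s in seq_len(S)) {
      expect_equal(l$stages[[s]]$total,
                   l$stages[[s]]$phase_loss + l$stages[[s]]$step_loss,
                   tolerance = 1e-6)
    }
    expect_equal(l$total,
                 sum(vapply(l$stages, `[[`, numeric(1), "total")))
  }
  cfg1 <- tcn_config(input_dim = 4, n_stages = 1, n_layers = 2,
                     n_channels = 5)
  short <- timeline("v", 0L, 0L)
  expect_error(tcn_loss(model_forward(x, init_tcn_params(cfg1), cfg1), short),
               "does not match the timeline")
})

test_that("multi-stage multi-task backprop matches numerical gradients", {
  cfg <- tcn_config(input_dim = 3, n_phases = 3, n_steps = 4, n_stages = 2,
                    n_layers = 2, n_channels = 4, dropout = 0, seed = 6)
  params <- init_tcn_params(cfg)
  tt <- 12L
  x <- matrix(rnorm(tt * 3), tt, 3)
  tl <- timeline("v", sample(0:2, tt, replace = TRUE),
                 sample(0:3, tt, replace = TRUE))
  gb <- surgtcn:::tcn_grads_one(x, tl, params, cfg)
  loss_fn <- function(p) surgtcn:::tcn_grads_one(x, tl, p, cfg)$loss
  set.seed(7)
  for (nm in names(params)) {
    for (idx in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      num <- num_grad_entry(loss_fn, params, nm, idx)
      expect_equal(gb$grads[[nm]][idx], num, tolerance = 1e-5,
                   label = sprintf("analytic grad of %s[%d]", nm, idx))
    }
  }
})

test_that("fitting reduces the loss and is deterministic in its seed", {
  corpus <- recovery_corpus(3L, n_videos = 4L)
  cfg <- tcn_config(input_dim = 16, n_phases = 5, n_steps = 12, n_stages = 1,
                    n_layers = 4, n_channels = 8, seed = 3)
  fit1 <- mtms_tcn(corpus$features[1:3], corpus$timelines[1:3], cfg,
                   val = 3, epochs = 8, learning_rate = 3e-4, seed = 3)
  fit2 <- mtms_tcn(corpus$features[1:3], corpus$timelines[1:3], cfg,
                   val = 3, epochs = 8, learning_rate = 3e-4, seed = 3)
  expect_identical(fit1$log, fit2$log)
  expect_identical(fit1$params, fit2$params)
  expect_lt(tail(fit1$log$train_loss, 1), fit1$log$train_loss[1])
  expect_s3_class(fit1, "mtms_tcn")
  expect_error(mtms_tcn(corpus$features[1:2], corpus$timelines[1:3], cfg),
               "length")
  expect_error(mtms_tcn(corpus$features[1], corpus$timelines[2], cfg),
               "feature rows")
})

test_that("the fitted model honours the classic S3 modelling surface", {
  corpus <- recovery_corpus(5L, n_videos = 3L)
  cfg <- tcn_config(input_dim = 16, n_phases = 5, n_steps = 12, n_stages = 2,
                    n_layers = 3, n_channels = 8, seed = 5)
  fit <- mtms_tcn(corpus$features, corpus$timelines, cfg, val = 3,
                  epochs = 3, learning_rate = 3e-4, seed = 5)
  expect_output(print(fit), "MTMS-TCN")
  s <- summary(fit)
  expect_equal(s$n_parameters, sum(lengths(coef(fit))))
  expect_equal(s$receptive_field, receptive_field(3, 3))
  expect_output(print(s), "parameters")

  x <- corpus$features[[1]]
  cl <- predict(fit, x)
  expect_length(cl$phase, nrow(x))
  expect_true(all(cl$phase %in% 0:4) && all(cl$step %in% 0:11))
  pb <- predict(fit, x, type = "prob")
  expect_length(pb, 2L)
  expect_equal(max.col(pb[[2]]$step_scores, ties.method = "first") - 1L,
               cl$step)
  # per-stage class predictions are available
  s1 <- predict(fit, x, stage = 1)
  expect_equal(max.col(pb[[1]]$phase_scores, ties.method = "first") - 1L,
               s1$phase)
  # list input maps over videos
  many <- predict(fit, corpus$features)
  expect_length(many, 3L)
  expect_identical(many[[1]], cl)
  # plot renders without error
  png(tempfile(fileext = ".png"))
  expect_invisible(plot(fit))
  dev.off()
})
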