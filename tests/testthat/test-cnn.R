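test_that("rendered frames are deterministic, bounded and class-coded", {
  tl <- timeline("v", c(0L, 0L, 1L), c(0L, 1L, 2L))
  fr <- render_frames(tl, seed = 1, size = 32)
  expect_equal(dim(fr), c(3L, 32L, 32L, 3L))
  expect_true(all(fr >= 0 & fr <= 1))
  expect_identical(fr, render_frames(tl, seed = 1, size = 32))
  # different step ids give different images; same step id gives the same
  expect_false(isTRUE(all.equal(fr[1, , , ], fr[2, , , ])))
  tl2 <- timeline("w", c(0L, 0L), c(1L, 1L))
  fr2 <- render_frames(tl2, seed = 1, size = 32)
  expect_equal(fr2[1, , , ], fr[2, , , ])
})

test_that("augmentation transforms are seeded and optional", {
  img <- render_frames(timeline("v", 0L, 0L), seed = 2, size = 16)[1, , , ]
  a1 <- surgtcn:::with_seed(3L, augment_image(img))
  a2 <- surgtcn:::with_seed(3L, augment_image(img))
  expect_identical(a1, a2)
  expect_equal(dim(a1), dim(img))
  expect_true(all(a1 >= 0 & a1 <= 1))
  # empty augmentation settings are the identity
  expect_identical(augment_image(img, aug = list()), img)
})

test_that("extracted features have the contract shape and are deterministic", {
  h <- tiny_hierarchy(c(1L, 1L))
  tl <- timeline("v", c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L))
  fr <- render_frames(tl, seed = 1, size = 32)
  cfg <- backbone_config(input_shape = c(32, 32, 3), n_features = 7,
                         epochs = 1, learning_rate = 1e-3, batch_size = 2,
                         channels = c(2, 3), stem_pool = 2, seed = 1)
  bb <- train_backbone(fr, tl$phase_labels, tl$step_labels, h, cfg)
  x <- extract_features(fr, bb)
  expect_equal(dim(x), c(4L, 7L))
  expect_identical(x, extract_features(fr, bb))
  expect_error(extract_features(render_frames(tl, seed = 1, size = 16), bb),
               "expected 32x32x3")
  expect_error(train_backbone(fr, tl$phase_labels, tl$step_labels, h,
                              backbone_config(trunk = "resnet50-class")),
               "small-cnn")
})

test_that("backbone backprop matches numerical differentiation", {
  h <- tiny_hierarchy(c(1L, 2L))
  cfg <- backbone_config(input_shape = c(12, 12, 3), n_features = 4,
                         channels = c(2, 3), stem_pool = 2, seed = 5)
  geo <- surgtcn:::backbone_geometry(cfg)
  params <- surgtcn:::init_backbone_params(cfg, 2L, 3L)
  img <- render_frames(timeline("v", 0L, 0L), seed = 4, size = 12,
                       noise_sd = 0.1)[1, , , ]
  yp <- 2L # 1-based phase label
  ys <- 3L # 1-based step label
  loss_fn <- function(p) {
    fw <- surgtcn:::backbone_forward_one(img, p, cfg, geo)
    pp <- softmax_rows(matrix(fw$phase_logits, 1))
    ps <- softmax_rows(matrix(fw$step_logits, 1))
    -log(pp[yp]) - log(ps[ys])
  }
  fw <- surgtcn:::backbone_forward_one(img, params, cfg, geo,
                                       keep_cache = TRUE)
  pp <- drop(softmax_rows(matrix(fw$phase_logits, 1)))
  ps <- drop(softmax_rows(matrix(fw$step_logits, 1)))
  g <- surgtcn:::backbone_backward_one(pp - (seq_len(2) == yp),
                                       ps - (seq_len(3) == ys),
                                       fw, params, cfg, geo)
  set.seed(8)
  for (nm in names(params)) {
    for (idx in sample(length(params[[nm]]), min(4, length(params[[nm]])))) {
      num <- num_grad_entry(loss_fn, params, nm, idx)
      expect_equal(g[[nm]][idx], num, tolerance = 1e-4,
                   label = sprintf("analytic grad of %s[%d]", nm, idx))
    }
  }
})

test_that("the backbone learns a separable toy corpus to perfect validation", {
  h <- tiny_hierarchy(c(1L, 1L, 1L))
  tl_tr <- timeline("train", rep(0:2, each = 5), rep(0:2, each = 5))
  tl_va <- timeline("val", rep(0:2, 2), rep(0:2, 2))
  fr_tr <- render_frames(tl_tr, seed = 1, size = 64, noise_sd = 0.02)
  fr_va <- render_frames(tl_va, seed = 2, size = 64, noise_sd = 0.02)
  cfg <- backbone_config(input_shape = c(64, 64, 3), n_features = 16,
                         epochs = 40, learning_rate = 1e-2, batch_size = 5,
                         channels = c(4, 8), stem_pool = 4, seed = 1)
  bb <- train_backbone(fr_tr, tl_tr$phase_labels, tl_tr$step_labels, h, cfg,
                       val_frames = fr_va, val_phase = tl_va$phase_labels,
                       val_step = tl_va$step_labels)
  expect_equal(max(bb$log$val_score), 1)
  pr <- predict_backbone(fr_va, bb)
  expect_equal(pr$phase, tl_va$phase_labels)
  expect_equal(pr$step, tl_va$step_labels)
  # training loss decreased
  expect_lt(tail(bb$log$train_loss, 1), bb$log$train_loss[1])
  expect_output(print(bb), "small-cnn")
})

test_that("backbone training is deterministic in its seed and warns on absent classes", {
  h <- tiny_hierarchy(c(1L, 1L))
  tl <- timeline("v", c(0L, 0L, 1L), c(0L, 0L, 1L))
  fr <- render_frames(tl, seed = 3, size = 16)
  cfg <- backbone_config(input_shape = c(16, 16, 3), n_features = 3,
                         epochs = 2, learning_rate = 1e-3, batch_size = 2,
                         channels = c(2), stem_pool = 2, seed = 9)
  b1 <- train_backbone(fr, tl$phase_labels, tl$step_labels, h, cfg)
  b2 <- train_backbone(fr, tl$phase_labels, tl$step_labels, h, cfg)
  expect_identical(b1$log, b2$log)
  expect_identical(b1$params, b2$params)
  # a class with no training frames gets weight 0 with a warning
  h3 <- tiny_hierarchy(c(1L, 1L, 1L))
  expect_warning(
    b3 <- train_backbone(fr, tl$phase_labels, tl$step_labels, h3, cfg),
    "absent")
  expect_equal(b3$class_weights$phase[3], 0)
})
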