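# Small multi-task CNN trunk. A compact, CPU-trainable stand-in satisfying
# the backbone contract: 224x224x3 images in, one N_f-dimensional feature
# vector per frame out, with a phase head and a step head sharing the trunk.
# Architecture: stem average-pool (factor `stem_pool`) -> three blocks of
# [3x3 conv, ReLU, 2x2 average-pool] -> global average pool -> fully
# connected layer to N_f with ReLU (the extracted feature) -> two linear
# heads. All convolutions use zero padding 1 so blocks only downsample via
# pooling. Forward and backward passes are written directly in matrix form
# (im2col); the optimizer is Adam with an additive L2 penalty gradient.

# --- low-level spatial ops ---------------------------------------------------

# mean-pool an H x W x C array by integer factor f (crops any remainder)
pool_mean <- function(x, f) {
  d <- dim(x)
  ho <- d[1] %/% f
  wo <- d[2] %/% f
  out <- array(0, c(ho, wo, d[3]))
  gr <- rep(seq_len(ho), each = f)
  gc <- rep(seq_len(wo), each = f)
  for (c in seq_len(d[3])) {
    m <- x[seq_len(ho * f), seq_len(wo * f), c]
    out[, , c] <- t(rowsum(t(rowsum(m, gr)), gc)) / (f * f)
  }
  out
}

# backward of pool_mean onto the cropped input region
pool_mean_backward <- function(dout, f, in_dim) {
  d <- dim(dout)
  dx <- array(0, in_dim)
  for (c in seq_len(in_dim[3])) {
    up <- dout[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), c]
    dx[seq_len(d[1] * f), seq_len(d[2] * f), c] <- up / (f * f)
  }
  dx
}

# precompute im2col gather indices for 3x3 / pad 1 convolution on H x W x C
im2col_indices <- function(h, w, cin) {
  hp <- h + 2L
  oh <- rep(seq_len(h), times = w)
  ow <- rep(seq_len(w), each = h)
  cols <- vector("list", 9L * cin)
  j <- 0L
  for (c in seq_len(cin)) {
    base <- (c - 1L) * hp * (w + 2L)
    for (dw in 0:2) {
      for (dh in 0:2) {
        j <- j + 1L
        cols[[j]] <- base + (oh + dh) + (ow + dw - 1L) * hp
      }
    }
  }
  matrix(unlist(cols), nrow = h * w, ncol = 9L * cin)
}

conv3_forward <- function(x, kernel, bias, idx) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3]))
  xp[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- x
  xcol <- matrix(xp[idx], nrow = nrow(idx), ncol = ncol(idx))
  y <- xcol %*% kernel
  y <- sweep(y, 2, bias, `+`)
  list(out = array(y, c(d[1], d[2], ncol(kernel))), xcol = xcol)
}

conv3_backward <- function(dout, xcol, kernel, idx, in_dim) {
  d_mat <- matrix(dout, nrow = nrow(xcol), ncol = dim(dout)[3])
  dk <- crossprod(xcol, d_mat)
  db <- colSums(d_mat)
  dxcol <- tcrossprod(d_mat, kernel)
  hp <- in_dim[1] + 2L
  wp <- in_dim[2] + 2L
  dxp <- numeric(hp * wp * in_dim[3])
  for (j in seq_len(ncol(idx))) {
    ii <- idx[, j]
    dxp[ii] <- dxp[ii] + dxcol[, j]
  }
  dxp <- array(dxp, c(hp, wp, in_dim[3]))
  list(dx = dxp[2:(in_dim[1] + 1L), 2:(in_dim[2] + 1L), , drop = FALSE],
       dk = dk, db = db)
}

# --- trunk construction ------------------------------------------------------

backbone_geometry <- function(cfg) {
  h <- cfg$input_shape[1] %/% cfg$stem_pool
  w <- cfg$input_shape[2] %/% cfg$stem_pool
  dims <- list()
  cin <- cfg$input_shape[3]
  for (i in seq_along(cfg$channels)) {
    dims[[i]] <- list(h = h, w = w, cin = cin, cout = cfg$channels[i],
                      idx = im2col_indices(h, w, cin))
    h <- h %/% 2L
    w <- w %/% 2L
    cin <- cfg$channels[i]
    if (h < 1L || w < 1L) stop("input too small for the block stack",
                               call. = FALSE)
  }
  list(blocks = dims, gap_c = cin)
}

init_backbone_params <- function(cfg, n_phases, n_steps) {
  geo <- backbone_geometry(cfg)
  with_seed(child_seed(cfg$seed, 11L), {
    params <- list()
    for (i in seq_along(geo$blocks)) {
      b <- geo$blocks[[i]]
      params[[paste0("conv", i, "_k")]] <- he_init(c(9L * b$cin, b$cout),
                                                   9L * b$cin)
      params[[paste0("conv", i, "_b")]] <- numeric(b$cout)
    }
    params$fc_w <- he_init(c(geo$gap_c, cfg$n_features), geo$gap_c)
    params$fc_b <- numeric(cfg$n_features)
    params$head_phase_w <- he_init(c(cfg$n_features, n_phases),
                                   cfg$n_features)
    params$head_phase_b <- numeric(n_phases)
    params$head_step_w <- he_init(c(cfg$n_features, n_steps), cfg$n_features)
    params$head_step_b <- numeric(n_steps)
    params
  })
}

# forward one image; returns feature vector, head logits and caches
backbone_forward_one <- function(img, params, cfg, geo, keep_cache = FALSE) {
  x <- pool_mean(img, cfg$stem_pool)
  caches <- list(stem = dim(img))
  for (i in seq_along(geo$blocks)) {
    b <- geo$blocks[[i]]
    cv <- conv3_forward(x, params[[paste0("conv", i, "_k")]],
                        params[[paste0("conv", i, "_b")]], b$idx)
    a <- relu(cv$out)
    p <- pool_mean(a, 2L)
    if (keep_cache) {
      caches[[paste0("blk", i)]] <- list(xcol = cv$xcol, pre = cv$out,
                                         act_dim = dim(a))
    }
    x <- p
  }
  gap <- apply(x, 3, mean)
  pre_feat <- drop(gap %*% params$fc_w) + params$fc_b
  feat <- relu(pre_feat)
  phase_logits <- drop(feat %*% params$head_phase_w) + params$head_phase_b
  step_logits <- drop(feat %*% params$head_step_w) + params$head_step_b
  list(feature = feat, phase_logits = phase_logits,
       step_logits = step_logits,
       cache = if (keep_cache) c(caches, list(gap = gap, gap_dim = dim(x),
                                              pre_feat = pre_feat,
                                              feat = feat)) else NULL)
}

# backward one image given dLoss/dlogits for both heads; returns grads list
backbone_backward_one <- function(dphase, dstep, fw, params, cfg, geo) {
  g <- list()
  cache <- fw$cache
  feat <- cache$feat
  g$head_phase_w <- outer(feat, dphase)
  g$head_phase_b <- dphase
  g$head_step_w <- outer(feat, dstep)
  g$head_step_b <- dstep
  dfeat <- drop(params$head_phase_w %*% dphase) +
    drop(params$head_step_w %*% dstep)
  dpre <- dfeat * (cache$pre_feat > 0)
  g$fc_w <- outer(cache$gap, dpre)
  g$fc_b <- dpre
  dgap <- drop(params$fc_w %*% dpre)
  gd <- cache$gap_dim
  dx <- array(rep(dgap / (gd[1] * gd[2]), each = gd[1] * gd[2]), gd)
  for (i in rev(seq_along(geo$blocks))) {
    b <- geo$blocks[[i]]
    blk <- cache[[paste0("blk", i)]]
    da <- pool_mean_backward(dx, 2L, blk$act_dim)
    dpre_conv <- da * (blk$pre > 0)
    cb <- conv3_backward(dpre_conv, blk$xcol, params[[paste0("conv", i, "_k")]],
                         b$idx, c(b$h, b$w, b$cin))
    g[[paste0("conv", i, "_k")]] <- cb$dk
    g[[paste0("conv", i, "_b")]] <- cb$db
    dx <- cb$dx
  }
  g
}

# --- augmentation ------------------------------------------------------------

#' Augment one image (horizontal flip, saturation, rotation)
#'
#' The training-time augmentation of the backbone: horizontal flip with the
#' configured probability, a global saturation rescale with factor drawn
#' uniformly from the configured range, and a nearest-neighbour rotation by
#' an angle drawn uniformly from the configured degree range (out-of-frame
#' pixels are zero). Randomness is taken from the current RNG state, so
#' callers seed once per epoch.
#'
#' @param img `H x W x 3` array with values in `[0, 1]`.
#' @param aug Augmentation settings (see [backbone_config()]).
#' @return Augmented image of the same shape.
#' @export
augment_image <- function(img, aug = list(hflip = 0.5,
                                          saturation = c(0.75, 1.25),
                                          rotation = c(-10, 10))) {
  d <- dim(img)
  if (!is.null(aug$hflip) && stats::runif(1) < aug$hflip) {
    img <- img[, rev(seq_len(d[2])), , drop = FALSE]
  }
  if (!is.null(aug$saturation)) {
    f <- stats::runif(1, aug$saturation[1], aug$saturation[2])
    gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    for (c in 1:3) img[, , c] <- pmin(pmax(gray + f * (img[, , c] - gray), 0), 1)
  }
  if (!is.null(aug$rotation)) {
    ang <- stats::runif(1, aug$rotation[1], aug$rotation[2]) * pi / 180
    if (abs(ang) > 1e-9) {
      cy <- (d[1] + 1) / 2
      cx <- (d[2] + 1) / 2
      oh <- rep(seq_len(d[1]), times = d[2])
      ow <- rep(seq_len(d[2]), each = d[1])
      sh <- round(cy + cos(ang) * (oh - cy) + sin(ang) * (ow - cx))
      sw <- round(cx - sin(ang) * (oh - cy) + cos(ang) * (ow - cx))
      ok <- sh >= 1 & sh <= d[1] & sw >= 1 & sw <= d[2]
      out <- array(0, d)
      for (c in 1:3) {
        plane <- img[, , c]
        dst <- numeric(d[1] * d[2])
        dst[ok] <- plane[cbind(sh[ok], sw[ok])]
        out[, , c] <- dst
      }
      img <- out
    }
  }
  img
}

# --- training & inference ----------------------------------------------------

as_image_list <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 4L) {
    lapply(seq_len(dim(frames)[1]), function(i) frames[i, , , ])
  } else if (is.list(frames)) {
    frames
  } else {
    stop("frames must be a list of HxWx3 arrays or a TxHxWx3 array",
         call. = FALSE)
  }
}

#' Train the multi-task frame-level backbone
#'
#' Trains trunk and both heads jointly on individual frames (no temporal
#' context) with median-frequency-balanced class-weighted cross-entropy per
#' task and total loss `L_phase + L_step` plus an L2 weight penalty. The
#' checkpoint kept is the epoch with the best validation score, defined as
#' the mean of validation phase accuracy and step accuracy. Classes absent
#' from the training set get weight 0 (with a warning).
#'
#' @param frames Training images: list of `H x W x 3` arrays (or a 4-D
#'   array, first dimension = frame).
#' @param phase_labels,step_labels 0-based integer labels per frame.
#' @param h A `surgtcn_hierarchy` giving the head sizes.
#' @param cfg A [backbone_config()].
#' @param val_frames,val_phase,val_step Optional validation split; without
#'   one the final epoch is kept.
#' @param verbose Print per-epoch progress.
#' @return Object of class `surgtcn_backbone` with the selected parameters,
#'   the per-epoch `log` (`data.frame`), and the class weights used.
#' @export
train_backbone <- function(frames, phase_labels, step_labels, h, cfg,
                           val_frames = NULL, val_phase = NULL,
                           val_step = NULL, verbose = FALSE) {
  stopifnot(inherits(h, "surgtcn_hierarchy"),
            inherits(cfg, "surgtcn_backbone_config"))
  if (cfg$trunk != "small-cnn") {
    stop("only the 'small-cnn' trunk ships with the package; ",
         "'resnet50-class' trunks plug in through the same contract ",
         "(extract_features / feature containers) with external weights",
         call. = FALSE)
  }
  frames <- as_image_list(frames)
  nimg <- length(frames)
  if (nimg == 0L) stop("empty training corpus", call. = FALSE)
  phase_labels <- as.integer(phase_labels)
  step_labels <- as.integer(step_labels)
  np <- n_phases(h)
  ns <- n_steps(h)
  counts_p <- tabulate(phase_labels + 1L, nbins = np)
  counts_s <- tabulate(step_labels + 1L, nbins = ns)
  if (any(counts_p == 0L) || any(counts_s == 0L)) {
    warning("some classes are absent from the training set; their weight is 0")
  }
  w_phase <- median_frequency_weights(counts_p)
  w_step <- median_frequency_weights(counts_s)

  geo <- backbone_geometry(cfg)
  params <- init_backbone_params(cfg, np, ns)
  opt <- adam_init(params)
  log <- data.frame()
  best <- list(score = -Inf, params = params)
  has_val <- !is.null(val_frames)
  if (has_val) val_frames <- as_image_list(val_frames)

  for (epoch in seq_len(cfg$epochs)) {
    epoch_loss <- with_seed(child_seed(cfg$seed, 20L, epoch), {
      ord <- sample.int(nimg)
      total <- 0
      nb <- 0L
      for (start in seq(1L, nimg, by = cfg$batch_size)) {
        batch <- ord[start:min(start + cfg$batch_size - 1L, nimg)]
        grads <- NULL
        bl <- 0
        for (i in batch) {
          img <- augment_image(frames[[i]], cfg$augmentation)
          fw <- backbone_forward_one(img, params, cfg, geo, keep_cache = TRUE)
          pp <- softmax_rows(matrix(fw$phase_logits, nrow = 1))
          ps <- softmax_rows(matrix(fw$step_logits, nrow = 1))
          yp <- phase_labels[i] + 1L
          ys <- step_labels[i] + 1L
          bl <- bl + w_phase[yp] * -log(max(pp[yp], 1e-300)) +
            w_step[ys] * -log(max(ps[ys], 1e-300))
          dphase <- w_phase[yp] * (drop(pp) - (seq_len(np) == yp))
          dstep <- w_step[ys] * (drop(ps) - (seq_len(ns) == ys))
          g <- backbone_backward_one(dphase, dstep, fw, params, cfg, geo)
          if (is.null(grads)) {
            grads <- g
          } else {
            for (nm in names(g)) grads[[nm]] <- grads[[nm]] + g[[nm]]
          }
        }
        nb <- nb + 1L
        nbatch <- length(batch)
        for (nm in names(grads)) {
          grads[[nm]] <- grads[[nm]] / nbatch + cfg$weight_decay * params[[nm]]
        }
        st <- adam_step(params, grads, opt, cfg$learning_rate)
        params <- st$params
        opt <- st$state
        total <- total + bl / nbatch
      }
      total / nb
    })
    row <- data.frame(epoch = epoch, train_loss = epoch_loss,
                      val_phase_acc = NA_real_, val_step_acc = NA_real_,
                      val_score = NA_real_)
    if (has_val) {
      pred <- predict_backbone_internal(val_frames, params, cfg, geo)
      row$val_phase_acc <- mean(pred$phase == val_phase)
      row$val_step_acc <- mean(pred$step == val_step)
      row$val_score <- (row$val_phase_acc + row$val_step_acc) / 2
      if (row$val_score > best$score) {
        best <- list(score = row$val_score, params = params)
      }
    }
    log <- rbind(log, row)
    if (verbose) {
      message(sprintf("backbone epoch %d: loss %.4f val %.3f", epoch,
                      epoch_loss, row$val_score))
    }
  }
  if (!has_val) best <- list(score = NA_real_, params = params)
  structure(list(params = best$params, config = cfg, log = log,
                 n_phases = np, n_steps = ns,
                 class_weights = list(phase = w_phase, step = w_step)),
            class = "surgtcn_backbone")
}

predict_backbone_internal <- function(frames, params, cfg, geo) {
  np <- length(params$head_phase_b)
  ns <- length(params$head_step_b)
  n <- length(frames)
  phase <- integer(n)
  step <- integer(n)
  for (i in seq_len(n)) {
    fw <- backbone_forward_one(frames[[i]], params, cfg, geo)
    phase[i] <- which.max(fw$phase_logits) - 1L
    step[i] <- which.max(fw$step_logits) - 1L
  }
  list(phase = phase, step = step)
}

#' Frame-wise class predictions from a trained backbone
#'
#' @param frames Images (list or 4-D array).
#' @param backbone A trained `surgtcn_backbone`.
#' @return List with 0-based `phase` and `step` id vectors.
#' @export
predict_backbone <- function(frames, backbone) {
  frames <- as_image_list(frames)
  geo <- backbone_geometry(backbone$config)
  predict_backbone_internal(frames, backbone$params, backbone$config, geo)
}

#' Extract per-frame feature vectors with a trained backbone
#'
#' Inference is deterministic: the same frame always yields the same
#' feature vector.
#'
#' @param frames Images (list of `H x W x 3` arrays or 4-D array).
#' @param backbone A trained `surgtcn_backbone`.
#' @return `T x N_f` feature matrix.
#' @export
extract_features <- function(frames, backbone) {
  stopifnot(inherits(backbone, "surgtcn_backbone"))
  frames <- as_image_list(frames)
  cfg <- backbone$config
  expected <- cfg$input_shape
  geo <- backbone_geometry(cfg)
  out <- matrix(0, length(frames), cfg$n_features)
  for (i in seq_along(frames)) {
    d <- dim(frames[[i]])
    if (length(d) != 3L || any(d != expected)) {
      stop(sprintf("frame %d has shape %s; expected %s", i,
                   paste(d, collapse = "x"),
                   paste(expected, collapse = "x")), call. = FALSE)
    }
    fw <- backbone_forward_one(frames[[i]], backbone$params, cfg, geo)
    out[i, ] <- fw$feature
  }
  out
}

#' @export
print.surgtcn_backbone <- function(x, ...) {
  cat(sprintf("<surgtcn_backbone> trunk '%s', N_f = %d, %d epochs trained; best val score %.3f\n",
              x$config$trunk, x$config$n_features, nrow(x$log),
              if (is.na(x$log$val_score[1])) NA else max(x$log$val_score)))
  invisible(x)
}
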