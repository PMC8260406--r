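# MTMS-TCN: the multi-task multi-stage causal temporal model.
#
# Stage 1 consumes the per-frame feature sequence; every later stage
# consumes the previous stage's per-frame class probabilities (phase and
# step heads concatenated) and re-predicts, refining over-segmented output.
# All stages are supervised; the training loss is the sum over stages and
# tasks of unweighted frame-mean cross-entropy (deliberately unweighted so
# the temporal model learns class durations and occurrence implicitly). The
# final stage's heads are the model output.

#' Temporal model configuration
#'
#' @param input_dim Feature dimension N_f of the stage-1 input.
#' @param n_phases,n_steps Head sizes (default: the 11/44 ontology).
#' @param n_stages Number of refinement stages S (>= 1).
#' @param n_layers Dilated residual layers per stage L; layer `l` uses
#'   dilation `2^(l-1)`, so the receptive field is
#'   `1 + (kernel_size - 1)(2^L - 1)` frames.
#' @param n_channels Channel width C inside a stage.
#' @param kernel_size Odd convolution kernel size k.
#' @param dropout Dropout probability inside residual layers (training only).
#' @param tasks `"both"` (multi-task), `"phase"` or `"step"` (single-task
#'   ablations).
#' @param seed Seed for parameter initialization.
#' @return An object of class `surgtcn_tcn_config`.
#' @export
tcn_config <- function(input_dim, n_phases = 11, n_steps = 44, n_stages = 2,
                       n_layers = 10, n_channels = 64, kernel_size = 3,
                       dropout = 0.5, tasks = c("both", "phase", "step"),
                       seed = 1) {
  tasks <- match.arg(tasks)
  stopifnot(input_dim >= 1, n_stages >= 1, n_layers >= 1, n_channels >= 1,
            kernel_size >= 1, kernel_size %% 2 == 1,
            dropout >= 0, dropout < 1, n_phases >= 1, n_steps >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 n_phases = as.integer(n_phases),
                 n_steps = as.integer(n_steps),
                 n_stages = as.integer(n_stages),
                 n_layers = as.integer(n_layers),
                 n_channels = as.integer(n_channels),
                 kernel_size = as.integer(kernel_size),
                 dropout = dropout, tasks = tasks, seed = as.integer(seed)),
            class = "surgtcn_tcn_config")
}

stage_input_dim <- function(cfg, stage) {
  if (stage == 1L) {
    cfg$input_dim
  } else {
    switch(cfg$tasks,
           both = cfg$n_phases + cfg$n_steps,
           phase = cfg$n_phases,
           step = cfg$n_steps)
  }
}

#' Initialize MTMS-TCN parameters
#'
#' Uniform `+-1/sqrt(fan_in)` initialization (the convention of this model
#' family; it keeps activations bounded through deep residual stacks),
#' deterministic in `cfg$seed`.
#'
#' @param cfg A [tcn_config()].
#' @return Named list of parameter arrays.
#' @export
init_tcn_params <- function(cfg) {
  with_seed(child_seed(cfg$seed, 31L), {
    p <- list()
    cc <- cfg$n_channels
    k <- cfg$kernel_size
    for (s in seq_len(cfg$n_stages)) {
      pre <- paste0("s", s)
      din <- stage_input_dim(cfg, s)
      p[[paste0(pre, "_proj_w")]] <- unif_init(c(cc, din), din)
      p[[paste0(pre, "_proj_b")]] <- numeric(cc)
      for (l in seq_len(cfg$n_layers)) {
        p[[paste0(pre, "_l", l, "_conv_w")]] <- unif_init(c(cc, cc, k), cc * k)
        p[[paste0(pre, "_l", l, "_conv_b")]] <- numeric(cc)
        p[[paste0(pre, "_l", l, "_pw_w")]] <- unif_init(c(cc, cc), cc)
        p[[paste0(pre, "_l", l, "_pw_b")]] <- numeric(cc)
      }
      if (cfg$tasks %in% c("both", "phase")) {
        p[[paste0(pre, "_head_phase_w")]] <- unif_init(c(cfg$n_phases, cc), cc)
        p[[paste0(pre, "_head_phase_b")]] <- numeric(cfg$n_phases)
      }
      if (cfg$tasks %in% c("both", "step")) {
        p[[paste0(pre, "_head_step_w")]] <- unif_init(c(cfg$n_steps, cc), cc)
        p[[paste0(pre, "_head_step_b")]] <- numeric(cfg$n_steps)
      }
    }
    p
  })
}

#' Full forward pass of the MTMS-TCN
#'
#' @param x `T x N_f` feature matrix (one row per frame).
#' @param params Parameter list from [init_tcn_params()] or a fitted model.
#' @param cfg The matching [tcn_config()].
#' @param training Keep caches and apply dropout (internal use).
#' @return List of S stage predictions; each has `phase_scores`
#'   (`T x n_phases`) and/or `step_scores` (`T x n_steps`), rows summing
#'   to 1. The final element is the model output.
#' @export
model_forward <- function(x, params, cfg, training = FALSE) {
  x <- t(as.matrix(x)) # internal layout: channels x time
  if (nrow(x) != cfg$input_dim) {
    stop(sprintf("input feature dimension %d does not match config (%d)",
                 nrow(x), cfg$input_dim), call. = FALSE)
  }
  out <- vector("list", cfg$n_stages)
  inp <- x
  for (s in seq_len(cfg$n_stages)) {
    fw <- stage_forward_internal(inp, params, paste0("s", s), cfg, training)
    pred <- list()
    if (!is.null(fw$phase_probs)) pred$phase_scores <- t(fw$phase_probs)
    if (!is.null(fw$step_probs)) pred$step_scores <- t(fw$step_probs)
    if (training) pred$.fw <- fw
    out[[s]] <- pred
    inp <- switch(cfg$tasks,
                  both = rbind(fw$phase_probs, fw$step_probs),
                  phase = fw$phase_probs,
                  step = fw$step_probs)
  }
  out
}

#' Multi-stage multi-task training loss
#'
#' Sum over stages of the unweighted frame-mean cross-entropy of each head
#' against the timeline labels.
#'
#' @param predictions List of stage predictions from [model_forward()].
#' @param tl A `surgtcn_timeline` with matching length.
#' @return List with `stages` (a `surgtcn_loss` per stage) and `total`.
#' @export
tcn_loss <- function(predictions, tl) {
  stopifnot(inherits(tl, "surgtcn_timeline"))
  ce_from_probs <- function(p, labels) {
    if (nrow(p) != length(labels)) {
      stop("prediction length does not match the timeline", call. = FALSE)
    }
    idx <- cbind(seq_along(labels), labels + 1L)
    mean(-log(pmax(p[idx], 1e-300)))
  }
  stages <- lapply(predictions, function(pred) {
    lp <- if (!is.null(pred$phase_scores)) {
      ce_from_probs(pred$phase_scores, tl$phase_labels)
    } else 0
    ls <- if (!is.null(pred$step_scores)) {
      ce_from_probs(pred$step_scores, tl$step_labels)
    } else 0
    multitask_loss(lp, ls)
  })
  list(stages = stages, total = sum(vapply(stages, `[[`, numeric(1), "total")))
}

# forward + backward for one video; returns loss and parameter gradients
tcn_grads_one <- function(x, tl, params, cfg) {
  preds <- model_forward(x, params, cfg, training = TRUE)
  loss <- tcn_loss(preds, tl)
  grads <- list()
  dp_next <- NULL # gradient wrt the probability input of stage s+1
  for (s in rev(seq_len(cfg$n_stages))) {
    fw <- preds[[s]]$.fw
    dlp <- NULL
    dls <- NULL
    if (!is.null(fw$phase_probs)) {
      dlp <- ce_grad_probs(fw$phase_probs, tl$phase_labels)
      if (!is.null(dp_next)) {
        npp <- cfg$n_phases
        dlp <- dlp + softmax_cols_backward(fw$phase_probs,
                                           dp_next[seq_len(npp), , drop = FALSE])
      }
    }
    if (!is.null(fw$step_probs)) {
      dls <- ce_grad_probs(fw$step_probs, tl$step_labels)
      if (!is.null(dp_next)) {
        off <- if (cfg$tasks == "both") cfg$n_phases else 0L
        dls <- dls + softmax_cols_backward(
          fw$step_probs, dp_next[off + seq_len(cfg$n_steps), , drop = FALSE])
      }
    }
    g <- stage_backward_internal(dlp, dls, fw, params, paste0("s", s), cfg,
                                 want_dx = (s > 1L))
    dp_next <- g$dx
    g$dx <- NULL
    grads <- c(grads, g)
  }
  list(loss = loss$total, grads = grads,
       stage_losses = loss$stages)
}

#' Fit the multi-task multi-stage temporal convolutional network
#'
#' The main fitting function of the package. Whole per-video sequences (no
#' temporal chunking) are consumed one per optimization step with Adam; the
#' kept checkpoint is the epoch with the best validation score (mean of
#' phase and step frame accuracy on the final stage; the single available
#' accuracy in single-task mode). Without a validation split the final
#' epoch is kept.
#'
#' @param features List of `T x N_f` feature matrices, one per video.
#' @param timelines Parallel list of `surgtcn_timeline` objects.
#' @param config A [tcn_config()]; its `input_dim` must match the features.
#' @param val Optional integer/character indices into `features` used for
#'   validation (excluded from training).
#' @param epochs Training epochs (reference recipe: 200).
#' @param learning_rate Adam learning rate (reference recipe: 3e-4).
#' @param seed Seed for shuffling and dropout.
#' @param verbose Print per-epoch progress.
#' @return An object of class `mtms_tcn` with elements `params` (selected
#'   checkpoint), `final_params`, `config`, `log` (per-epoch
#'   `data.frame`), and the fitted `call`.
#' @export
mtms_tcn <- function(features, timelines, config, val = NULL, epochs = 200,
                     learning_rate = 3e-4, seed = 1, verbose = FALSE) {
  stopifnot(inherits(config, "surgtcn_tcn_config"),
            length(features) == length(timelines), length(features) >= 1)
  for (i in seq_along(features)) {
    if (nrow(features[[i]]) != n_frames(timelines[[i]])) {
      stop(sprintf("video %d: %d feature rows but %d labelled frames", i,
                   nrow(features[[i]]), n_frames(timelines[[i]])),
           call. = FALSE)
    }
  }
  idx_all <- seq_along(features)
  val_idx <- if (is.character(val)) match(val, names(features)) else val
  train_idx <- setdiff(idx_all, val_idx)
  if (!length(train_idx)) stop("no training videos left", call. = FALSE)

  params <- init_tcn_params(config)
  opt <- adam_init(params)
  log <- data.frame()
  best <- list(score = -Inf, params = params)

  for (epoch in seq_len(epochs)) {
    epoch_loss <- with_seed(child_seed(seed, 40L, epoch), {
      ord <- train_idx[sample.int(length(train_idx))]
      total <- 0
      for (i in ord) {
        gb <- tcn_grads_one(features[[i]], timelines[[i]], params, config)
        st <- adam_step(params, gb$grads, opt, learning_rate)
        params <- st$params
        opt <- st$state
        total <- total + gb$loss
      }
      total / length(ord)
    })
    row <- data.frame(epoch = epoch, train_loss = epoch_loss,
                      val_phase_acc = NA_real_, val_step_acc = NA_real_,
                      val_score = NA_real_)
    if (length(val_idx)) {
      accs <- vapply(val_idx, function(i) {
        pred <- predict_tcn_labels(features[[i]], params, config)
        c(if (!is.null(pred$phase)) {
          mean(pred$phase == timelines[[i]]$phase_labels)
        } else NA_real_,
        if (!is.null(pred$step)) {
          mean(pred$step == timelines[[i]]$step_labels)
        } else NA_real_)
      }, numeric(2))
      row$val_phase_acc <- mean(accs[1, ])
      row$val_step_acc <- mean(accs[2, ])
      row$val_score <- mean(c(row$val_phase_acc, row$val_step_acc),
                            na.rm = TRUE)
      if (row$val_score > best$score) {
        best <- list(score = row$val_score, params = params)
      }
    }
    log <- rbind(log, row)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val %.3f", epoch, epoch_loss,
                      row$val_score))
    }
  }
  if (!length(val_idx)) best <- list(score = NA_real_, params = params)
  structure(list(params = best$params, final_params = params,
                 config = config, log = log, n_train = length(train_idx),
                 call = match.call()),
            class = "mtms_tcn")
}

# argmax labels (0-based, ties to the lowest id via which.max) on the final
# stage
predict_tcn_labels <- function(x, params, cfg) {
  preds <- model_forward(x, params, cfg)
  last <- preds[[length(preds)]]
  out <- list()
  if (!is.null(last$phase_scores)) {
    out$phase <- max.col(last$phase_scores, ties.method = "first") - 1L
  }
  if (!is.null(last$step_scores)) {
    out$step <- max.col(last$step_scores, ties.method = "first") - 1L
  }
  out
}

#' @export
print.mtms_tcn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("MTMS-TCN: %d stage(s) x %d layers, %d channels, kernel %d (receptive field %d frames)\n",
              cfg$n_stages, cfg$n_layers, cfg$n_channels, cfg$kernel_size,
              receptive_field(cfg$n_layers, cfg$kernel_size)))
  cat(sprintf("tasks: %s; input N_f = %d; trained %d epochs on %d videos\n",
              cfg$tasks, cfg$input_dim, nrow(x$log), x$n_train))
  if (!all(is.na(x$log$val_score))) {
    b <- which.max(x$log$val_score)
    cat(sprintf("best validation epoch %d: phase acc %.3f, step acc %.3f\n",
                b, x$log$val_phase_acc[b], x$log$val_step_acc[b]))
  }
  invisible(x)
}

#' @export
summary.mtms_tcn <- function(object, ...) {
  npar <- sum(vapply(object$params, length, integer(1)))
  structure(list(config = object$config, n_parameters = npar,
                 log = object$log,
                 receptive_field = receptive_field(object$config$n_layers,
                                                   object$config$kernel_size)),
            class = "summary.mtms_tcn")
}

#' @export
print.summary.mtms_tcn <- function(x, ...) {
  cat(sprintf("MTMS-TCN with %d parameters; receptive field %d frames\n",
              x$n_parameters, x$receptive_field))
  cat("training log (last 5 epochs):\n")
  print(utils::tail(x$log, 5), row.names = FALSE)
  invisible(x)
}

#' @export
coef.mtms_tcn <- function(object, ...) object$params

#' Predict phase/step labels for new feature sequences
#'
#' @param object A fitted `mtms_tcn`.
#' @param newdata One `T x N_f` matrix or a list of them.
#' @param type `"class"` for 0-based argmax label tracks (ties broken
#'   toward the lowest class id), `"prob"` for the per-stage score
#'   matrices.
#' @param stage Which stage to report for `type = "class"`: `"final"`
#'   (default) or a stage number.
#' @param ... Unused.
#' @return For one matrix: a list with `phase` and/or `step` (and
#'   score matrices when `type = "prob"`); for a list input, a list of such
#'   results.
#' @export
predict.mtms_tcn <- function(object, newdata, type = c("class", "prob"),
                             stage = "final", ...) {
  type <- match.arg(type)
  one <- function(x) {
    preds <- model_forward(x, object$params, object$config)
    if (type == "prob") return(preds)
    s <- if (identical(stage, "final")) length(preds) else as.integer(stage)
    pr <- preds[[s]]
    out <- list()
    if (!is.null(pr$phase_scores)) {
      out$phase <- max.col(pr$phase_scores, ties.method = "first") - 1L
    }
    if (!is.null(pr$step_scores)) {
      out$step <- max.col(pr$step_scores, ties.method = "first") - 1L
    }
    out
  }
  if (is.list(newdata) && !is.matrix(newdata)) lapply(newdata, one) else one(newdata)
}

#' Plot the training log of a fitted model
#'
#' Training loss per epoch and, when a validation split was used, the
#' validation frame accuracies.
#'
#' @param x A fitted `mtms_tcn`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mtms_tcn <- function(x, ...) {
  log <- x$log
  op <- graphics::par(mfrow = c(1, if (all(is.na(log$val_score))) 1 else 2),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(log$epoch, log$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "MTMS-TCN training", ...)
  if (!all(is.na(log$val_score))) {
    graphics::plot(log$epoch, log$val_phase_acc, type = "l", col = "steelblue",
                   ylim = range(c(log$val_phase_acc, log$val_step_acc),
                                na.rm = TRUE),
                   xlab = "epoch", ylab = "validation accuracy")
    graphics::lines(log$epoch, log$val_step_acc, col = "firebrick")
    graphics::legend("bottomright", c("phase", "step"), lty = 1,
                     col = c("steelblue", "firebrick"), bty = "n")
  }
  invisible(x)
}
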