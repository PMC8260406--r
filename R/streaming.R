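# Online (streaming) inference. A stream holds, per stage and per dilated
# layer, a fixed-size ring buffer of that layer's input columns covering its
# conv taps ((k-1) * dilation frames), so memory is bounded by the receptive
# field regardless of stream length. Because every operation in the model is
# causal, the emitted prediction at frame t equals row t of the batch
# forward pass, and already-emitted predictions never change when more
# frames arrive.

#' Open a streaming predictor over a fitted model
#'
#' @param object A fitted [mtms_tcn()] model, or a list with `params` and
#'   `config`.
#' @return An object of class `surgtcn_stream`; feed frames with
#'   [stream_step()].
#' @export
tcn_stream <- function(object) {
  cfg <- object$config
  params <- object$params
  st <- new.env(parent = emptyenv())
  st$cfg <- cfg
  st$params <- params
  st$t <- 0L
  st$buffers <- lapply(seq_len(cfg$n_stages), function(s) {
    lapply(seq_len(cfg$n_layers), function(l) {
      m <- (cfg$kernel_size - 1L) * 2L^(l - 1L)
      matrix(0, cfg$n_channels, max(m, 1L))
    })
  })
  class(st) <- "surgtcn_stream"
  st
}

#' Feed one frame to a stream and get its prediction
#'
#' @param stream A `surgtcn_stream` from [tcn_stream()].
#' @param x_t Numeric feature vector of length `input_dim` (frame t).
#' @return List with `phase`, `step` (0-based argmax ids) and
#'   `phase_scores`, `step_scores` (probability vectors), as the model's
#'   heads admit. The stream advances by one frame as a side effect.
#' @export
stream_step <- function(stream, x_t) {
  stopifnot(inherits(stream, "surgtcn_stream"))
  cfg <- stream$cfg
  params <- stream$params
  if (length(x_t) != cfg$input_dim) {
    stop("frame has wrong feature dimension", call. = FALSE)
  }
  t <- stream$t + 1L
  k <- cfg$kernel_size
  inp <- as.numeric(x_t)
  out <- list()
  for (s in seq_len(cfg$n_stages)) {
    pre <- paste0("s", s)
    h <- drop(params[[paste0(pre, "_proj_w")]] %*% inp) +
      params[[paste0(pre, "_proj_b")]]
    for (l in seq_len(cfg$n_layers)) {
      d <- 2L^(l - 1L)
      buf <- stream$buffers[[s]][[l]]
      m <- ncol(buf)
      kw <- params[[paste0(pre, "_l", l, "_conv_w")]]
      z <- drop(matrix(kw[, , k], cfg$n_channels, cfg$n_channels) %*% h) +
        params[[paste0(pre, "_l", l, "_conv_b")]]
      for (j in seq_len(k - 1L)) {
        tp <- t - j * d
        if (tp >= 1L) {
          col <- buf[, ((tp - 1L) %% m) + 1L]
          z <- z + drop(matrix(kw[, , k - j], cfg$n_channels,
                               cfg$n_channels) %*% col)
        }
      }
      # record this layer's input at time t, then advance
      buf[, ((t - 1L) %% m) + 1L] <- h
      stream$buffers[[s]][[l]] <- buf
      a <- relu(z)
      u <- drop(params[[paste0(pre, "_l", l, "_pw_w")]] %*% a) +
        params[[paste0(pre, "_l", l, "_pw_b")]]
      h <- h + u
    }
    probs <- c()
    if (cfg$tasks %in% c("both", "phase")) {
      lg <- drop(params[[paste0(pre, "_head_phase_w")]] %*% h) +
        params[[paste0(pre, "_head_phase_b")]]
      pp <- exp(lg - max(lg))
      pp <- pp / sum(pp)
      out$phase_scores <- pp
      out$phase <- which.max(pp) - 1L
      probs <- c(probs, pp)
    }
    if (cfg$tasks %in% c("both", "step")) {
      lg <- drop(params[[paste0(pre, "_head_step_w")]] %*% h) +
        params[[paste0(pre, "_head_step_b")]]
      ps <- exp(lg - max(lg))
      ps <- ps / sum(ps)
      out$step_scores <- ps
      out$step <- which.max(ps) - 1L
      probs <- c(probs, ps)
    }
    inp <- probs
  }
  stream$t <- t
  out
}

#' Streaming prediction over a whole sequence
#'
#' Convenience wrapper: feeds the frames of `x` one by one through
#' [stream_step()] and collects per-frame predictions in the same layout as
#' the batch path, for checking streaming/batch equivalence or for
#' simulating online deployment.
#'
#' @param x `T x N_f` feature matrix.
#' @param object A fitted `mtms_tcn` (or list with `params` and `config`).
#' @return List with `phase`, `step` label vectors and `phase_scores`,
#'   `step_scores` matrices (`T x C`), as the model's heads admit.
#' @export
online_predict <- function(x, object) {
  x <- as.matrix(x)
  cfg <- object$config
  stream <- tcn_stream(object)
  tt <- nrow(x)
  res <- list()
  if (cfg$tasks %in% c("both", "phase")) {
    res$phase <- integer(tt)
    res$phase_scores <- matrix(0, tt, cfg$n_phases)
  }
  if (cfg$tasks %in% c("both", "step")) {
    res$step <- integer(tt)
    res$step_scores <- matrix(0, tt, cfg$n_steps)
  }
  for (t in seq_len(tt)) {
    p <- stream_step(stream, x[t, ])
    if (!is.null(p$phase)) {
      res$phase[t] <- p$phase
      res$phase_scores[t, ] <- p$phase_scores
    }
    if (!is.null(p$step)) {
      res$step[t] <- p$step
      res$step_scores[t, ] <- p$step_scores
    }
  }
  res
}
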