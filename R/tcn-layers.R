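# Causal dilated temporal convolution primitives and one refinement stage.
#
# Internally a sequence is a C x T matrix (channels by time). A causal
# convolution with kernel size k and dilation d reads taps at offsets
# {(k-1)d, ..., d, 0} into the past, with zero padding on the left, so the
# output at frame t never depends on any frame > t. A stage is a 1x1 input
# projection, L dilated residual layers with dilation 2^(l-1) at layer l,
# and one 1x1 softmax head per task.

# shift a C x T matrix right by m frames (zero-fill on the left)
shift_right <- function(x, m) {
  tt <- ncol(x)
  if (m == 0L) return(x)
  if (m >= tt) return(matrix(0, nrow(x), tt))
  cbind(matrix(0, nrow(x), m), x[, seq_len(tt - m), drop = FALSE])
}

# shift left by m frames (zero-fill on the right); adjoint of shift_right
shift_left <- function(x, m) {
  tt <- ncol(x)
  if (m == 0L) return(x)
  if (m >= tt) return(matrix(0, nrow(x), tt))
  cbind(x[, (m + 1L):tt, drop = FALSE], matrix(0, nrow(x), m))
}

#' Causal dilated convolution over a sequence
#'
#' Output frame `t` is a weighted sum of input frames
#' `t, t - d, ..., t - (k-1)d` (missing past frames count as zero), so no
#' output depends on any future frame. The last kernel tap is the
#' current-frame tap.
#'
#' @param x Input sequence: a numeric vector of length `T` (single channel)
#'   or a `C_in x T` matrix.
#' @param kernel Numeric vector of length `k` (single-channel case) or a
#'   `C_out x C_in x k` array.
#' @param dilation Positive integer dilation `d`.
#' @param bias Optional per-output-channel bias.
#' @return A vector (if `x` was a vector) or `C_out x T` matrix.
#' @examples
#' causal_dilated_conv(c(1, 1, 1, 1), kernel = c(1, 1, 1), dilation = 1)
#' # 1 2 3 3
#' @export
causal_dilated_conv <- function(x, kernel, dilation = 1, bias = NULL) {
  if (dilation < 1) stop("dilation must be >= 1", call. = FALSE)
  was_vector <- is.null(dim(x))
  if (was_vector) x <- matrix(x, nrow = 1)
  if (is.null(dim(kernel))) kernel <- array(kernel, c(1, 1, length(kernel)))
  k <- dim(kernel)[3]
  if (dim(kernel)[2] != nrow(x)) {
    stop("kernel input-channel dimension does not match the sequence",
         call. = FALSE)
  }
  out <- matrix(0, dim(kernel)[1], ncol(x))
  for (j in seq_len(k)) {
    off <- (k - j) * dilation
    out <- out + matrix(kernel[, , j], dim(kernel)[1], nrow(x)) %*%
      shift_right(x, off)
  }
  if (!is.null(bias)) out <- out + bias
  if (was_vector && nrow(out) == 1L) drop(out) else out
}

#' Receptive field of a stack of dilation-doubling causal layers
#'
#' With kernel size `k` and dilations `1, 2, ..., 2^(L-1)`, the number of
#' past-inclusive frames that can influence one output frame is
#' `1 + (k - 1) (2^L - 1)`.
#'
#' @param n_layers Number of dilated layers `L` (>= 0).
#' @param kernel_size Kernel size `k`.
#' @return Receptive field in frames.
#' @examples
#' receptive_field(10, 3) # 2047 frames (~34 min at 1 fps)
#' @export
receptive_field <- function(n_layers, kernel_size = 3) {
  if (n_layers < 0) stop("n_layers must be >= 0", call. = FALSE)
  1 + (kernel_size - 1) * (2^n_layers - 1)
}

# column-wise softmax of a C x T score matrix
softmax_cols <- function(x) {
  z <- exp(sweep(x, 2, apply(x, 2, max), `-`))
  sweep(z, 2, colSums(z), `/`)
}

# backward through column-wise softmax: dP -> dlogits
softmax_cols_backward <- function(p, dp) {
  p * sweep(dp, 2, colSums(p * dp), `-`)
}

# conv as used internally during training: kernel array (C_out, C_in, k)
conv_forward_mat <- function(x, kernel, bias, dilation) {
  k <- dim(kernel)[3]
  out <- matrix(0, dim(kernel)[1], ncol(x))
  for (j in seq_len(k)) {
    out <- out + matrix(kernel[, , j], dim(kernel)[1], dim(kernel)[2]) %*%
      shift_right(x, (k - j) * dilation)
  }
  out + bias
}

conv_backward_mat <- function(dout, x, kernel, dilation) {
  k <- dim(kernel)[3]
  dk <- array(0, dim(kernel))
  dx <- matrix(0, nrow(x), ncol(x))
  for (j in seq_len(k)) {
    off <- (k - j) * dilation
    xs <- shift_right(x, off)
    dk[, , j] <- tcrossprod(dout, xs)
    dx <- dx + shift_left(crossprod(matrix(kernel[, , j], dim(kernel)[1],
                                           dim(kernel)[2]), dout), off)
  }
  list(dk = dk, db = rowSums(dout), dx = dx)
}

# --- one refinement stage ----------------------------------------------------

# forward; x is D_in x T. Returns features (C x T), per-task probability
# matrices, and caches for the backward pass when training.
stage_forward_internal <- function(x, params, prefix, cfg, training = FALSE) {
  keep <- 1 - cfg$dropout
  x0 <- params[[paste0(prefix, "_proj_w")]] %*% x +
    params[[paste0(prefix, "_proj_b")]]
  h <- x0
  layer_cache <- if (training) vector("list", cfg$n_layers) else NULL
  for (l in seq_len(cfg$n_layers)) {
    d <- 2L^(l - 1L)
    kw <- params[[paste0(prefix, "_l", l, "_conv_w")]]
    kb <- params[[paste0(prefix, "_l", l, "_conv_b")]]
    pw <- params[[paste0(prefix, "_l", l, "_pw_w")]]
    pb <- params[[paste0(prefix, "_l", l, "_pw_b")]]
    z <- conv_forward_mat(h, kw, kb, d)
    a <- relu(z)
    u <- pw %*% a + pb
    if (training && cfg$dropout > 0) {
      mask <- (matrix(stats::runif(length(u)), nrow(u), ncol(u)) < keep) / keep
      du <- u * mask
    } else {
      mask <- NULL
      du <- u
    }
    out <- h + du
    if (training) layer_cache[[l]] <- list(h = h, z = z, a = a, mask = mask)
    h <- out
  }
  res <- list(features = h)
  if (cfg$tasks %in% c("both", "phase")) {
    lg <- params[[paste0(prefix, "_head_phase_w")]] %*% h +
      params[[paste0(prefix, "_head_phase_b")]]
    res$phase_probs <- softmax_cols(lg)
  }
  if (cfg$tasks %in% c("both", "step")) {
    lg <- params[[paste0(prefix, "_head_step_w")]] %*% h +
      params[[paste0(prefix, "_head_step_b")]]
    res$step_probs <- softmax_cols(lg)
  }
  if (training) {
    res$cache <- list(x = x, x0 = x0, layers = layer_cache)
  }
  res
}

# backward; dlogits_* are gradients wrt the head logits (already combining
# the cross-entropy term and any gradient arriving from the next stage).
# Returns parameter gradients (named like params) and dx, the gradient wrt
# the stage input.
stage_backward_internal <- function(dlogits_phase, dlogits_step, fw, params,
                                    prefix, cfg, want_dx = TRUE) {
  g <- list()
  feat <- fw$features
  dh <- matrix(0, nrow(feat), ncol(feat))
  if (!is.null(dlogits_phase)) {
    w <- params[[paste0(prefix, "_head_phase_w")]]
    g[[paste0(prefix, "_head_phase_w")]] <- tcrossprod(dlogits_phase, feat)
    g[[paste0(prefix, "_head_phase_b")]] <- rowSums(dlogits_phase)
    dh <- dh + crossprod(w, dlogits_phase)
  }
  if (!is.null(dlogits_step)) {
    w <- params[[paste0(prefix, "_head_step_w")]]
    g[[paste0(prefix, "_head_step_w")]] <- tcrossprod(dlogits_step, feat)
    g[[paste0(prefix, "_head_step_b")]] <- rowSums(dlogits_step)
    dh <- dh + crossprod(w, dlogits_step)
  }
  cache <- fw$cache
  for (l in rev(seq_len(cfg$n_layers))) {
    lc <- cache$layers[[l]]
    d <- 2L^(l - 1L)
    pw <- params[[paste0(prefix, "_l", l, "_pw_w")]]
    du <- if (is.null(lc$mask)) dh else dh * lc$mask
    g[[paste0(prefix, "_l", l, "_pw_w")]] <- tcrossprod(du, lc$a)
    g[[paste0(prefix, "_l", l, "_pw_b")]] <- rowSums(du)
    da <- crossprod(pw, du)
    dz <- da * (lc$z > 0)
    cb <- conv_backward_mat(dz, lc$h, params[[paste0(prefix, "_l", l, "_conv_w")]], d)
    g[[paste0(prefix, "_l", l, "_conv_w")]] <- cb$dk
    g[[paste0(prefix, "_l", l, "_conv_b")]] <- cb$db
    dh <- dh + cb$dx # residual path + conv path
  }
  g[[paste0(prefix, "_proj_w")]] <- tcrossprod(dh, cache$x)
  g[[paste0(prefix, "_proj_b")]] <- rowSums(dh)
  if (want_dx) {
    g$dx <- crossprod(params[[paste0(prefix, "_proj_w")]], dh)
  }
  g
}
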