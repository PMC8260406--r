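# Frame-level multi-task backbone contract: class weighting, losses, and
# configuration. The trunk itself (a small CNN trained from scratch) lives
# in cnn.R; everything here is architecture-independent.

#' Median-frequency class-balancing weights
#'
#' For each class with a positive frame count, the weight is
#' `median(freq over present classes) / freq_c`, where
#' `freq_c = count_c / sum(counts)`. Frequencies are per frame over the
#' training split. Classes with zero count are excluded from the median and
#' receive weight 0: they cannot be learned and must not produce infinite
#' weights.
#'
#' @param class_counts Non-negative integer vector of per-class frame counts.
#' @return Numeric weight vector, same length as `class_counts`.
#' @examples
#' median_frequency_weights(c(50, 30, 20)) # 0.6, 1.0, 1.5
#' @export
median_frequency_weights <- function(class_counts) {
  if (length(class_counts) < 1L || any(class_counts < 0)) {
    stop("class_counts must be a non-negative vector", call. = FALSE)
  }
  total <- sum(class_counts)
  if (total == 0) stop("all class counts are zero", call. = FALSE)
  freq <- class_counts / total
  present <- class_counts > 0
  med <- stats::median(freq[present])
  w <- numeric(length(class_counts))
  w[present] <- med / freq[present]
  w
}

#' Numerically stable row-wise softmax
#'
#' @param logits `T x C` matrix of unnormalized scores.
#' @return `T x C` matrix of probabilities; each row sums to 1.
#' @export
softmax_rows <- function(logits) {
  logits <- as.matrix(logits)
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Class-weighted cross-entropy over frames
#'
#' Mean over frames of `w[label] * (-log softmax(logits)[label])`. With unit
#' weights this is the ordinary multinomial cross-entropy.
#'
#' @param logits `T x C` matrix of class scores (pre-softmax).
#' @param labels Integer vector of 0-based class ids, length `T`.
#' @param weights Per-class weight vector (default: all 1).
#' @return Non-negative scalar loss.
#' @export
weighted_cross_entropy <- function(logits, labels,
                                   weights = rep(1, ncol(logits))) {
  logits <- as.matrix(logits)
  labels <- as.integer(labels)
  if (length(labels) != nrow(logits)) {
    stop("one label per frame required", call. = FALSE)
  }
  if (any(labels < 0L) || any(labels >= ncol(logits))) {
    stop("label outside class range [0, C)", call. = FALSE)
  }
  p <- softmax_rows(logits)
  idx <- cbind(seq_along(labels), labels + 1L)
  nll <- -log(pmax(p[idx], 1e-300))
  mean(weights[labels + 1L] * nll)
}

#' Combine per-task losses into the multi-task total
#'
#' The total training loss is the equally weighted sum of the phase-head and
#' step-head losses.
#'
#' @param phase_loss,step_loss Non-negative scalar loss terms.
#' @return An object of class `surgtcn_loss` with fields `phase_loss`,
#'   `step_loss`, `total`.
#' @export
multitask_loss <- function(phase_loss, step_loss) {
  structure(list(phase_loss = phase_loss, step_loss = step_loss,
                 total = phase_loss + step_loss),
            class = "surgtcn_loss")
}

#' @export
print.surgtcn_loss <- function(x, ...) {
  cat(sprintf("loss: phase %.4f + step %.4f = %.4f\n",
              x$phase_loss, x$step_loss, x$total))
  invisible(x)
}

#' Backbone training configuration
#'
#' Defaults follow the reference training recipe: 30 epochs, learning rate
#' 1e-5, L2 weight penalty 5e-5, batch size 32, with horizontal-flip /
#' saturation / rotation augmentation. The trunk is pluggable: `"small-cnn"`
#' (a compact 3-block CNN trainable on a CPU) or a ResNet-50-class trunk
#' supplied by the user through the same contract. `n_features` is the
#' output feature dimension N_f (2048 in the reference setup; smaller values
#' are sensible for the small trunk).
#'
#' @param trunk `"small-cnn"` or `"resnet50-class"`.
#' @param input_shape Image shape, default `c(224, 224, 3)`.
#' @param n_features Feature dimension N_f.
#' @param epochs,learning_rate,weight_decay,batch_size Optimization settings.
#' @param channels Per-block channel widths of the small trunk.
#' @param stem_pool Average-pooling factor applied to the input before the
#'   conv blocks (224 / 8 = 28 keeps the trunk CPU-sized).
#' @param augmentation List with `hflip` (probability), `saturation`
#'   (range of the saturation factor), `rotation` (degree range).
#' @param seed Integer seed for initialization, shuffling, augmentation.
#' @return An object of class `surgtcn_backbone_config`.
#' @export
backbone_config <- function(trunk = c("small-cnn", "resnet50-class"),
                            input_shape = c(224, 224, 3),
                            n_features = 2048,
                            epochs = 30, learning_rate = 1e-5,
                            weight_decay = 5e-5, batch_size = 32,
                            channels = c(8, 16, 32), stem_pool = 8,
                            augmentation = list(hflip = 0.5,
                                                saturation = c(0.75, 1.25),
                                                rotation = c(-10, 10)),
                            seed = 1) {
  trunk <- match.arg(trunk)
  stopifnot(length(input_shape) == 3, all(input_shape > 0),
            n_features >= 1, epochs >= 1, learning_rate > 0,
            weight_decay >= 0, batch_size >= 1, all(channels >= 1),
            stem_pool >= 1)
  structure(list(trunk = trunk, input_shape = input_shape,
                 n_features = as.integer(n_features),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 channels = as.integer(channels),
                 stem_pool = as.integer(stem_pool),
                 augmentation = augmentation,
                 seed = as.integer(seed)),
            class = "surgtcn_backbone_config")
}
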