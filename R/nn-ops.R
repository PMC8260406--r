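# Shared neural-network primitives: parameter initialization and the Adam
# optimizer over named lists of numeric arrays. Used by both the CNN trunk
# and the temporal model.

relu <- function(x) pmax(x, 0)

# He-style Gaussian init for a weight array with given fan-in
he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

# uniform +-1/sqrt(fan_in) init (the convention of the TCN family; keeps
# activations bounded through deep residual stacks)
unif_init <- function(dims, fan_in) {
  b <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -b, b), dim = dims)
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0) # preserves shape and class
  list(m = zeros, v = zeros, t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One Adam step; params and grads are parallel named lists of arrays.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# gradient of mean cross-entropy wrt logits, given probabilities p (C x T or
# T x C as `byrow`), 0-based labels, and optional per-class weights
ce_grad_probs <- function(p, labels, weights = NULL) {
  # p: C x T (class by frame); returns dlogits of same shape for loss
  # mean_t w[y_t] * (-log p[y_t, t])
  tt <- ncol(p)
  g <- p
  idx <- cbind(labels + 1L, seq_len(tt))
  if (is.null(weights)) {
    g[idx] <- g[idx] - 1
    g / tt
  } else {
    wt <- weights[labels + 1L]
    g <- sweep(g, 2, wt, `*`)
    g[idx] <- g[idx] - wt
    g / tt
  }
}
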