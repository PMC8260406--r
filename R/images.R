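# Synthetic RGB frame rendering. Frames are a deterministic function of the
# step id (base colour plus an oriented sinusoidal texture whose frequency
# and direction are id-dependent) with optional additive pixel noise; enough
# visual class structure for desk-scale backbone experiments, with no
# pretension of photorealism.

step_base_color <- function(step_id) {
  # golden-angle hue walk gives well-separated colours for any class count
  hue <- (step_id * 0.61803398875) %% 1
  grDevices::col2rgb(grDevices::hsv(hue, s = 0.75, v = 0.85)) / 255
}

#' Render synthetic frames for a timeline
#'
#' One `size x size x 3` image per frame; appearance depends only on the
#' frame's step id plus seeded Gaussian pixel noise, so two frames of the
#' same step with `noise_sd = 0` are pixel-identical.
#'
#' @param tl A `surgtcn_timeline`.
#' @param seed Integer seed for the pixel noise.
#' @param size Image side length (default 224).
#' @param noise_sd Pixel noise standard deviation (0 disables noise).
#' @return `T x size x size x 3` array with values in `[0, 1]`.
#' @export
render_frames <- function(tl, seed = 1, size = 224, noise_sd = 0) {
  stopifnot(inherits(tl, "surgtcn_timeline"))
  tt <- n_frames(tl)
  out <- array(0, c(tt, size, size, 3))
  gx <- matrix(rep(seq_len(size), each = size), size, size)
  gy <- matrix(rep(seq_len(size), times = size), size, size)
  patterns <- new.env()
  for (t in seq_len(tt)) {
    s <- tl$step_labels[t]
    key <- as.character(s)
    if (is.null(patterns[[key]])) {
      base <- step_base_color(s)
      freq <- 2 * pi * (1 + s %% 5) / size
      ang <- (s %% 8) * pi / 8
      tex <- 0.15 * sin(freq * (cos(ang) * gx + sin(ang) * gy))
      img <- array(0, c(size, size, 3))
      for (c in 1:3) img[, , c] <- pmin(pmax(base[c] + tex, 0), 1)
      patterns[[key]] <- img
    }
    out[t, , , ] <- patterns[[key]]
  }
  if (noise_sd > 0) {
    with_seed(seed, {
      out <- out + array(stats::rnorm(length(out), sd = noise_sd), dim(out))
    })
    out <- pmin(pmax(out, 0), 1)
  }
  out
}
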