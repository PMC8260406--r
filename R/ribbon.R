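# Ribbon plots: horizontal colour bands showing label timelines (ground
# truth above model predictions) for whole-video qualitative assessment.
# Steps reuse a 20-colour categorical map (id modulo 20), since 44 fully
# distinct colours are not distinguishable in print.

#' Categorical colours for phase / step ids
#'
#' Phases get one distinct colour each; step ids are folded onto a
#' `n_colors`-category map by `id %% n_colors` (default 20).
#'
#' @param ids Integer label ids (0-based).
#' @param n_colors Size of the categorical map; `Inf` for one colour per id.
#' @return Character vector of colours, one per id.
#' @export
label_colors <- function(ids, n_colors = 20) {
  fold <- if (is.finite(n_colors)) ids %% n_colors else ids
  # golden-angle hue walk with alternating value for neighbour contrast
  hue <- (fold * 0.61803398875) %% 1
  val <- ifelse(fold %% 2 == 0, 0.9, 0.65)
  grDevices::hsv(hue, s = 0.85, v = val)
}

#' Ribbon plot of label timelines
#'
#' Renders one horizontal band per named label sequence (e.g. ground truth
#' and each model's prediction track) with a shared colormap, and writes it
#' to an image file. Band length is proportional to the sequence length.
#'
#' @param tracks Named list of equal-meaning label sequences (integer ids,
#'   0-based). They may differ in length; each band is drawn over its own
#'   frame axis.
#' @param path Output file; the extension selects the device (`.png` or
#'   `.svg`).
#' @param n_colors Categorical map size: use `Inf` (one colour per phase id)
#'   for phases, 20 for the 44-step label space.
#' @param title Plot title.
#' @param width,height Device size in pixels (png) or inches (svg).
#' @return `path`, invisibly.
#' @export
ribbon_plot <- function(tracks, path, n_colors = 20, title = NULL,
                        width = 900, height = 60 + 60 * length(tracks)) {
  if (!length(tracks) || is.null(names(tracks)) || any(names(tracks) == "")) {
    stop("tracks must be a non-empty named list", call. = FALSE)
  }
  if (any(vapply(tracks, length, integer(1)) < 1L)) {
    stop("every track must contain at least one frame", call. = FALSE)
  }
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "svg") {
    grDevices::svg(path, width = width / 100, height = height / 100)
  } else {
    grDevices::png(path, width = width, height = height)
  }
  on.exit(grDevices::dev.off())
  n <- length(tracks)
  graphics::par(mar = c(2.5, 6, if (is.null(title)) 0.5 else 2, 0.5))
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, n), xlab = "", ylab = "",
                 axes = FALSE, main = title)
  for (i in seq_len(n)) {
    lab <- as.integer(tracks[[i]])
    tt <- length(lab)
    runs <- rle(lab)
    ends <- cumsum(runs$lengths) / tt
    starts <- c(0, ends[-length(ends)])
    graphics::rect(starts, n - i + 0.2, ends, n - i + 0.8,
                   col = label_colors(runs$values, n_colors), border = NA)
    graphics::mtext(names(tracks)[i], side = 2, at = n - i + 0.5, las = 1,
                    line = 0.5, cex = 0.9)
  }
  graphics::axis(1, at = c(0, 0.5, 1), labels = c("start", "", "end"))
  invisible(path)
}
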