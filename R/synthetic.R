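# Synthetic hierarchical-workflow generator.
#
# Surgical activities are dwell-time processes: a procedure visits phases in
# a mostly linear order, each phase executes an ordered program of steps
# (not all of which occur in every procedure), and each executed step dwells
# for a random number of frames. The generator is therefore an explicit-
# duration (semi-Markov) model rather than a frame-level Markov chain, with
# per-step negative-binomial dwell times truncated to [min, max]. Per-frame
# features are emitted from a class-conditional Gaussian around a per-step
# mean vector, optionally with a slow rank-one drift across the video.

#' Build a semi-Markov workflow model over a hierarchy
#'
#' @param h A `surgtcn_hierarchy`.
#' @param step_params `data.frame` with one row per step of `h`, columns:
#'   `step_id`, `incl_prob` (probability the step occurs when its phase is
#'   visited; steps with `incl_prob >= 1` are mandatory), `mean_dur`
#'   (negative-binomial mean dwell in frames), `size` (NB dispersion),
#'   `min_dur`, `max_dur` (truncation bounds, frames).
#' @param phase_skip_prob Per-phase probability of skipping the phase
#'   entirely (scalar or one per phase).
#' @param fps Frame rate of generated timelines.
#' @return An object of class `surgtcn_workflow_model`.
#' @export
workflow_model <- function(h, step_params, phase_skip_prob = 0, fps = 1) {
  stopifnot(inherits(h, "surgtcn_hierarchy"))
  need <- c("step_id", "incl_prob", "mean_dur", "size", "min_dur", "max_dur")
  miss <- setdiff(need, names(step_params))
  if (length(miss)) {
    stop("step_params missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(step_params$step_id, h$steps$step_id)) {
    stop("step_params must cover exactly the steps of the hierarchy",
         call. = FALSE)
  }
  step_params <- step_params[match(h$steps$step_id, step_params$step_id), ]
  rownames(step_params) <- NULL
  if (any(step_params$mean_dur < 1)) {
    stop("all mean durations must be >= 1 frame", call. = FALSE)
  }
  if (any(step_params$min_dur > step_params$max_dur)) {
    stop("min_dur must be <= max_dur", call. = FALSE)
  }
  if (any(step_params$incl_prob < 0 | step_params$incl_prob > 1)) {
    stop("incl_prob must lie in [0, 1]", call. = FALSE)
  }
  skip <- rep_len(phase_skip_prob, n_phases(h))
  if (any(skip < 0 | skip >= 1)) {
    stop("phase_skip_prob must lie in [0, 1)", call. = FALSE)
  }
  if (all(step_params$incl_prob == 0)) {
    stop("model can emit no frames: every step has inclusion probability 0",
         call. = FALSE)
  }
  structure(list(hierarchy = h, step_params = step_params,
                 phase_skip_prob = skip, fps = fps),
            class = "surgtcn_workflow_model")
}

#' @export
print.surgtcn_workflow_model <- function(x, ...) {
  cat(sprintf(
    "<surgtcn_workflow_model> %d phases / %d steps; mean dwell %.1f-%.1f frames; expected video %.0f frames\n",
    n_phases(x$hierarchy), n_steps(x$hierarchy),
    min(x$step_params$mean_dur), max(x$step_params$mean_dur),
    sum(expected_phase_durations(x)$mean_frames)))
  invisible(x)
}

# mean of a NB(mu, size) truncated to [min, max] (max may be Inf)
truncated_nb_mean <- function(mu, size, min_dur, max_dur) {
  upper <- if (is.finite(max_dur)) max_dur else {
    max(stats::qnbinom(1 - 1e-12, mu = mu, size = size), min_dur) + 1
  }
  ks <- seq(from = min_dur, to = upper)
  p <- stats::dnbinom(ks, mu = mu, size = size)
  if (sum(p) <= 0) return(min_dur)
  sum(ks * p) / sum(p)
}

#' Expected phase durations implied by a workflow model
#'
#' The mean number of frames a visited phase contributes: the sum over its
#' step program of inclusion probability times the truncated-NB mean dwell.
#'
#' @param m A `surgtcn_workflow_model`.
#' @return `data.frame` with `phase_id` and `mean_frames`.
#' @export
expected_phase_durations <- function(m) {
  sp <- m$step_params
  e_step <- vapply(seq_len(nrow(sp)), function(i) {
    truncated_nb_mean(sp$mean_dur[i], sp$size[i], sp$min_dur[i], sp$max_dur[i])
  }, numeric(1))
  parent <- parent_phase(m$hierarchy, sp$step_id)
  contrib <- sp$incl_prob * e_step
  agg <- tapply(contrib, factor(parent, levels = m$hierarchy$phases$phase_id),
                sum, default = 0)
  data.frame(phase_id = m$hierarchy$phases$phase_id,
             mean_frames = as.numeric(agg))
}

sample_trunc_nb <- function(n, mu, size, min_dur, max_dur) {
  out <- integer(n)
  todo <- seq_len(n)
  for (tries in 1:200) {
    draw <- stats::rnbinom(length(todo), mu = mu, size = size)
    ok <- draw >= min_dur & draw <= max_dur
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
    if (!length(todo)) break
  }
  if (length(todo)) out[todo] <- pmin(pmax(round(mu), min_dur), max_dur)
  out
}

#' Sample one timeline from a workflow model
#'
#' Phases are visited in ontology order; each may be skipped with its skip
#' probability; within a visited phase each step of the program occurs with
#' its inclusion probability and dwells for a truncated-NB number of frames.
#' If a draw produces an empty video, the mandatory program of the first
#' phase is emitted so the timeline invariant `T >= 1` always holds.
#'
#' @param m A `surgtcn_workflow_model`.
#' @param seed Integer seed; identical `(m, seed)` gives identical output.
#' @param video_id Identifier for the generated video.
#' @return A hierarchy-consistent `surgtcn_timeline`.
#' @export
sample_workflow <- function(m, seed, video_id = "synthetic") {
  stopifnot(inherits(m, "surgtcn_workflow_model"))
  h <- m$hierarchy
  sp <- m$step_params
  with_seed(seed, {
    phase_seq <- integer(0)
    step_seq <- integer(0)
    emit_phase <- function(p, force = FALSE) {
      rows <- which(parent_phase(h, sp$step_id) == p)
      for (i in rows) {
        prob <- if (force) max(sp$incl_prob[i], 1) else sp$incl_prob[i]
        if (stats::runif(1) <= prob) {
          dur <- sample_trunc_nb(1, sp$mean_dur[i], sp$size[i],
                                 sp$min_dur[i], sp$max_dur[i])
          if (dur > 0) {
            phase_seq <<- c(phase_seq, rep.int(p, dur))
            step_seq <<- c(step_seq, rep.int(sp$step_id[i], dur))
          }
        }
      }
    }
    for (p in h$phases$phase_id) {
      if (stats::runif(1) < m$phase_skip_prob[p + 1L]) next
      emit_phase(p)
    }
    if (!length(phase_seq)) emit_phase(h$phases$phase_id[1], force = TRUE)
    if (!length(phase_seq)) {
      stop("workflow model emitted no frames", call. = FALSE)
    }
    timeline(video_id, phase_seq, step_seq, fps = m$fps)
  })
}

# ---------------------------------------------------------------------------
# Feature emission.

#' Build a class-conditional Gaussian emission model
#'
#' Frame `t` of a timeline emits `step_means[step_t, ] + noise`, with
#' isotropic Gaussian noise of standard deviation `noise_sd` and an optional
#' slow rank-one drift: a Gaussian random-walk scalar (per-frame increment sd
#' `drift_sd`) times a fixed random unit direction, modelling gradual
#' within-video appearance change (lighting, smoke, lens soiling).
#'
#' @param n_steps Number of step classes.
#' @param dim Feature dimension `N_f` (default 2048, the backbone contract).
#' @param step_means `n_steps x dim` matrix of class means; default: random
#'   unit vectors drawn from `seed`.
#' @param noise_sd Per-coordinate noise standard deviation (>= 0).
#' @param drift_sd Per-frame sd of the drift random walk (0 disables drift).
#' @param seed Seed for the default means/drift direction.
#' @return An object of class `surgtcn_emission_model`.
#' @export
emission_model <- function(n_steps, dim = 2048, step_means = NULL,
                           noise_sd = 0.5, drift_sd = 0, seed = 1) {
  if (noise_sd < 0 || drift_sd < 0) {
    stop("noise_sd and drift_sd must be >= 0", call. = FALSE)
  }
  if (is.null(step_means)) {
    step_means <- with_seed(child_seed(seed, 101L), {
      mm <- matrix(stats::rnorm(n_steps * dim), n_steps, dim)
      mm / sqrt(rowSums(mm^2))
    })
  }
  step_means <- as.matrix(step_means)
  if (nrow(step_means) != n_steps) {
    stop("step_means must have one row per step", call. = FALSE)
  }
  drift_dir <- with_seed(child_seed(seed, 102L), {
    v <- stats::rnorm(ncol(step_means))
    v / sqrt(sum(v^2))
  })
  structure(list(dim = ncol(step_means), n_steps = n_steps,
                 step_means = step_means, noise_sd = noise_sd,
                 drift_sd = drift_sd, drift_dir = drift_dir),
            class = "surgtcn_emission_model")
}

#' Emit per-frame features for a timeline
#'
#' @param tl A `surgtcn_timeline`.
#' @param e A `surgtcn_emission_model`.
#' @param seed Integer seed.
#' @return `T x dim` numeric matrix, one feature vector per frame.
#' @export
emit_features <- function(tl, e, seed) {
  stopifnot(inherits(tl, "surgtcn_timeline"),
            inherits(e, "surgtcn_emission_model"))
  if (any(tl$step_labels < 0L | tl$step_labels >= e$n_steps)) {
    stop("timeline contains step ids absent from the emission model",
         call. = FALSE)
  }
  tt <- n_frames(tl)
  x <- e$step_means[tl$step_labels + 1L, , drop = FALSE]
  with_seed(seed, {
    if (e$noise_sd > 0) {
      x <- x + matrix(stats::rnorm(tt * e$dim, sd = e$noise_sd), tt, e$dim)
    }
    if (e$drift_sd > 0) {
      walk <- cumsum(stats::rnorm(tt, sd = e$drift_sd))
      x <- x + outer(walk, e$drift_dir)
    }
  })
  dimnames(x) <- NULL
  x
}

# ---------------------------------------------------------------------------
# Defaults emulating the study conditions.

#' Default workflow + emission model pair
#'
#' Emulates the structure of a 40-video gastric-bypass annotation campaign:
#' videos averaging ~110 minutes at 1 fps, strongly long-tailed step dwell
#' times (the longest mean dwell is two orders of magnitude above the
#' shortest, so class-balancing code paths are exercised), a mostly linear
#' phase order with rare phase skips, and optional steps (the first step of
#' each phase is mandatory, the rest occur with probability 0.9).
#'
#' @param h Hierarchy to model (default: the bundled 11/44 ontology).
#' @param seed Seed controlling the (deterministic) assignment of dwell
#'   means to steps and the emission means.
#' @param mean_video_minutes Target expected video duration (minutes).
#' @param fps Frame rate (default 1).
#' @param dim Feature dimension (default 2048).
#' @param noise_sd Emission noise sd (default 0.5).
#' @return List with elements `workflow` and `emission`.
#' @export
default_model <- function(h = default_hierarchy(), seed = 1,
                          mean_video_minutes = 110, fps = 1, dim = 2048,
                          noise_sd = 0.5) {
  ns <- n_steps(h)
  first_in_phase <- !duplicated(h$steps$parent_phase_id)
  incl <- ifelse(first_in_phase, 1, 0.9)
  # long-tailed dwell means: log-spaced over two decades, shuffled so long
  # and short steps are interleaved across phases
  raw <- exp(seq(log(8), log(800), length.out = ns))
  ord <- with_seed(child_seed(seed, 7L), sample.int(ns))
  raw <- raw[ord]
  sp <- data.frame(step_id = h$steps$step_id, incl_prob = incl,
                   mean_dur = raw, size = 4, min_dur = 1L, max_dur = Inf)
  m <- workflow_model(h, sp, phase_skip_prob = 0.05, fps = fps)
  # scale dwell means so the expected total matches the target video length
  target <- mean_video_minutes * 60 * fps
  expected <- sum(expected_phase_durations(m)$mean_frames *
                    (1 - m$phase_skip_prob))
  sp$mean_dur <- pmax(sp$mean_dur * target / expected, 1)
  m <- workflow_model(h, sp, phase_skip_prob = 0.05, fps = fps)
  e <- emission_model(ns, dim = dim, noise_sd = noise_sd, seed = seed)
  list(workflow = m, emission = e)
}

# ---------------------------------------------------------------------------
# Corpus generation on disk.

#' Generate a corpus of synthetic videos on disk
#'
#' Writes one timeline CSV and one feature container per video plus a
#' manifest CSV (`video_id,n_frames,timeline,features`). All paths in the
#' manifest are relative to `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_videos Number of videos.
#' @param model List with `workflow` and `emission` (see [default_model()]).
#' @param seed Integer seed; video `i` uses an independent derived stream.
#' @param format Feature container format, `"bin"` or `"csv"`.
#' @return The manifest as a `data.frame`, invisibly.
#' @export
simulate_corpus <- function(out_dir, n_videos, model, seed, format = "bin") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(video_id = character(0), n_frames = integer(0),
                         timeline = character(0), features = character(0))
  for (i in seq_len(n_videos)) {
    vid <- sprintf("video%03d", i)
    tl <- sample_workflow(model$workflow, child_seed(seed, i, 1L), vid)
    x <- emit_features(tl, model$emission, child_seed(seed, i, 2L))
    tl_path <- file.path(out_dir, paste0(vid, "_timeline.csv"))
    ft_path <- file.path(out_dir, paste0(vid, "_features",
                                         if (format == "bin") ".bin" else ".csv"))
    write_timeline(tl, tl_path)
    write_features(x, ft_path, format = format, video_id = vid)
    manifest <- rbind(manifest, data.frame(
      video_id = vid, n_frames = n_frames(tl),
      timeline = basename(tl_path), features = basename(ft_path)))
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Load a corpus generated by [simulate_corpus()]
#'
#' @param dir Corpus directory containing `manifest.csv`.
#' @return List with `manifest`, `timelines` (list of `surgtcn_timeline`),
#'   and `features` (list of `T x N_f` matrices), indexed by video id.
#' @export
load_corpus <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir, call. = FALSE)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  tls <- lapply(seq_len(nrow(manifest)), function(i) {
    read_timeline(file.path(dir, manifest$timeline[i]),
                  video_id = manifest$video_id[i])
  })
  fts <- lapply(seq_len(nrow(manifest)), function(i) {
    read_features(file.path(dir, manifest$features[i]))
  })
  names(tls) <- manifest$video_id
  names(fts) <- manifest$video_id
  list(manifest = manifest, timelines = tls, features = fts)
}
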