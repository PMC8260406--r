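# Two-level phase/step label space: construction, validation, file I/O.
#
# A hierarchy binds a set of coarse phases and fine-grained steps, each step
# belonging to exactly one parent phase. Ids are 0-based and contiguous, the
# convention used in annotation files.

#' Construct a phase/step hierarchy
#'
#' @param phases `data.frame` with columns `phase_id` (integer, 0-based
#'   contiguous) and `name` (character).
#' @param steps `data.frame` with columns `step_id` (integer, 0-based
#'   contiguous), `name`, `parent_phase_id` (must exist in `phases`), and
#'   optionally `critical` (logical, defaults to `FALSE`).
#' @return An object of class `surgtcn_hierarchy`.
#' @examples
#' h <- hierarchy(
#'   phases = data.frame(phase_id = 0:1, name = c("P0", "P1")),
#'   steps  = data.frame(step_id = 0:2, name = c("S0", "S1", "S2"),
#'                       parent_phase_id = c(0L, 0L, 1L))
#' )
#' n_steps(h)
#' @export
hierarchy <- function(phases, steps) {
  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s is missing column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  req(phases, c("phase_id", "name"), "`phases`")
  req(steps, c("step_id", "name", "parent_phase_id"), "`steps`")
  phases$phase_id <- as.integer(phases$phase_id)
  steps$step_id <- as.integer(steps$step_id)
  steps$parent_phase_id <- as.integer(steps$parent_phase_id)
  if (!"critical" %in% names(steps)) steps$critical <- FALSE
  steps$critical <- as.logical(steps$critical)

  check_ids <- function(ids, what) {
    if (anyNA(ids)) stop(sprintf("NA %s id", what), call. = FALSE)
    dup <- ids[duplicated(ids)]
    if (length(dup)) {
      stop(sprintf("duplicate %s id(s): %s", what,
                   paste(unique(dup), collapse = ", ")), call. = FALSE)
    }
    if (!identical(sort(ids), seq(0L, length(ids) - 1L))) {
      stop(sprintf("%s ids must be contiguous from 0; got {%s}", what,
                   paste(sort(ids), collapse = ",")), call. = FALSE)
    }
  }
  check_ids(phases$phase_id, "phase")
  check_ids(steps$step_id, "step")
  dangling <- setdiff(steps$parent_phase_id, phases$phase_id)
  if (length(dangling)) {
    bad <- steps$step_id[steps$parent_phase_id %in% dangling]
    stop(sprintf("step(s) %s parented to missing phase(s) %s",
                 paste(bad, collapse = ","),
                 paste(dangling, collapse = ",")), call. = FALSE)
  }
  phases <- phases[order(phases$phase_id), c("phase_id", "name"), drop = FALSE]
  steps <- steps[order(steps$step_id),
                 c("step_id", "name", "parent_phase_id", "critical"),
                 drop = FALSE]
  rownames(phases) <- NULL
  rownames(steps) <- NULL
  structure(list(phases = phases, steps = steps), class = "surgtcn_hierarchy")
}

#' Number of phases / steps in a hierarchy
#' @param h A `surgtcn_hierarchy`.
#' @return Integer count.
#' @export
n_phases <- function(h) nrow(h$phases)

#' @rdname n_phases
#' @export
n_steps <- function(h) nrow(h$steps)

#' Parent phase of a step
#'
#' @param h A `surgtcn_hierarchy`.
#' @param step_id Integer step id(s).
#' @return The parent `phase_id` for each step queried.
#' @export
parent_phase <- function(h, step_id) {
  step_id <- as.integer(step_id)
  idx <- match(step_id, h$steps$step_id)
  if (anyNA(idx)) {
    stop(sprintf("unknown step id(s): %s",
                 paste(step_id[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  h$steps$parent_phase_id[idx]
}

#' Load a hierarchy from an ontology file
#'
#' The ontology file is a CSV with header
#' `kind,id,name,parent_phase_id,critical`; one row per phase
#' (`kind = "phase"`, `parent_phase_id` empty) and one per step
#' (`kind = "step"`). The packaged default (11 phases, 44 steps with
#' placeholder names) is returned by [default_hierarchy()].
#'
#' @param path Path to an ontology CSV.
#' @return A validated `surgtcn_hierarchy`.
#' @export
load_hierarchy <- function(path) {
  if (!file.exists(path)) stop("ontology file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(kind = "character", name = "character"))
  req <- c("kind", "id", "name", "parent_phase_id", "critical")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("malformed ontology file, missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad_kind <- setdiff(unique(df$kind), c("phase", "step"))
  if (length(bad_kind)) {
    stop("malformed ontology record kind: ",
         paste(bad_kind, collapse = ", "), call. = FALSE)
  }
  ph <- df[df$kind == "phase", , drop = FALSE]
  st <- df[df$kind == "step", , drop = FALSE]
  crit <- as.logical(st$critical)
  crit[is.na(crit)] <- FALSE
  hierarchy(
    phases = data.frame(phase_id = ph$id, name = ph$name,
                        stringsAsFactors = FALSE),
    steps = data.frame(step_id = st$id, name = st$name,
                       parent_phase_id = st$parent_phase_id,
                       critical = crit, stringsAsFactors = FALSE)
  )
}

#' Write a hierarchy to an ontology CSV
#' @param h A `surgtcn_hierarchy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(h, path) {
  df <- rbind(
    data.frame(kind = "phase", id = h$phases$phase_id, name = h$phases$name,
               parent_phase_id = NA_integer_, critical = NA,
               stringsAsFactors = FALSE),
    data.frame(kind = "step", id = h$steps$step_id, name = h$steps$name,
               parent_phase_id = h$steps$parent_phase_id,
               critical = h$steps$critical, stringsAsFactors = FALSE)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' The packaged default 11-phase / 44-step ontology
#'
#' Placeholder names (`P0..P10`, `S0..S43`); four steps nested under each
#' phase. The clinically critical steps carried by the default annotation
#' scheme are flagged, but the flag set is data, not code: supply your own
#' ontology file for real annotation campaigns.
#'
#' @return A `surgtcn_hierarchy` with 11 phases and 44 steps.
#' @export
default_hierarchy <- function() {
  path <- system.file("extdata", "ontology_default.csv", package = "surgtcn")
  if (!nzchar(path)) stop("bundled ontology not found", call. = FALSE)
  load_hierarchy(path)
}

#' @export
print.surgtcn_hierarchy <- function(x, ...) {
  cat(sprintf("<surgtcn_hierarchy> %d phases, %d steps (%d critical)\n",
              n_phases(x), n_steps(x), sum(x$steps$critical)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Timelines: per-frame (phase, step) ground-truth label pairs.

#' Construct a per-frame label timeline
#'
#' @param video_id Character video identifier.
#' @param phase_labels Integer vector of phase ids, one per frame.
#' @param step_labels Integer vector of step ids, same length.
#' @param fps Frame rate of the label track (default 1 frame/s).
#' @return An object of class `surgtcn_timeline`.
#' @export
timeline <- function(video_id, phase_labels, step_labels, fps = 1) {
  phase_labels <- as.integer(phase_labels)
  step_labels <- as.integer(step_labels)
  if (length(phase_labels) != length(step_labels)) {
    stop("phase and step label tracks differ in length", call. = FALSE)
  }
  if (length(phase_labels) < 1L) {
    stop("a timeline must contain at least one frame", call. = FALSE)
  }
  if (anyNA(phase_labels) || anyNA(step_labels)) {
    stop("labels must not contain NA", call. = FALSE)
  }
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive", call. = FALSE)
  structure(list(video_id = as.character(video_id), fps = fps,
                 phase_labels = phase_labels, step_labels = step_labels),
            class = "surgtcn_timeline")
}

#' Number of frames in a timeline
#' @param tl A `surgtcn_timeline`.
#' @return Integer frame count.
#' @export
n_frames <- function(tl) length(tl$phase_labels)

#' @export
print.surgtcn_timeline <- function(x, ...) {
  cat(sprintf("<surgtcn_timeline> video '%s': %d frames @ %g fps, %d phase segment(s)\n",
              x$video_id, n_frames(x), x$fps,
              1L + sum(diff(x$phase_labels) != 0L)))
  invisible(x)
}

#' Check a timeline against a hierarchy
#'
#' A frame is a violation when the parent phase of its step label differs
#' from its phase label. Labels outside the ontology are an error, not a
#' violation: they indicate the wrong ontology was bound, not a bad frame.
#'
#' @param tl A `surgtcn_timeline`.
#' @param h A `surgtcn_hierarchy`.
#' @return A `data.frame` with columns `frame` (0-based), `phase_id`,
#'   `step_id`; zero rows iff the timeline is hierarchy-consistent.
#' @export
validate_timeline <- function(tl, h) {
  stopifnot(inherits(tl, "surgtcn_timeline"), inherits(h, "surgtcn_hierarchy"))
  bad_phase <- setdiff(unique(tl$phase_labels), h$phases$phase_id)
  bad_step <- setdiff(unique(tl$step_labels), h$steps$step_id)
  if (length(bad_phase) || length(bad_step)) {
    stop(sprintf("timeline labels outside the ontology (phases: %s; steps: %s)",
                 paste(bad_phase, collapse = ","),
                 paste(bad_step, collapse = ",")), call. = FALSE)
  }
  expected <- parent_phase(h, tl$step_labels)
  bad <- which(expected != tl$phase_labels)
  data.frame(frame = bad - 1L,
             phase_id = tl$phase_labels[bad],
             step_id = tl$step_labels[bad])
}

#' Read / write timeline CSV files
#'
#' The on-disk dialect is a CSV with header `frame,phase_id,step_id` and one
#' row per frame; frame indices are 0-based and must be contiguous.
#'
#' @param path File path.
#' @param video_id Video id to attach on read (default: file stem).
#' @param fps Frame rate to attach on read.
#' @return `read_timeline` returns a `surgtcn_timeline`; `write_timeline`
#'   returns `path` invisibly.
#' @export
read_timeline <- function(path, video_id = NULL, fps = 1) {
  if (!file.exists(path)) stop("timeline file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  miss <- setdiff(c("frame", "phase_id", "step_id"), names(df))
  if (length(miss)) {
    stop("timeline CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) < 1L) stop("timeline CSV has no frames", call. = FALSE)
  if (!identical(as.integer(df$frame), seq(0L, nrow(df) - 1L))) {
    stop("timeline frame index must be 0-based and contiguous", call. = FALSE)
  }
  if (is.null(video_id)) video_id <- sub("\\.[^.]*$", "", basename(path))
  timeline(video_id, df$phase_id, df$step_id, fps = fps)
}

#' @rdname read_timeline
#' @param tl A `surgtcn_timeline` to write.
#' @export
write_timeline <- function(tl, path) {
  stopifnot(inherits(tl, "surgtcn_timeline"))
  df <- data.frame(frame = seq_len(n_frames(tl)) - 1L,
                   phase_id = tl$phase_labels, step_id = tl$step_labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
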