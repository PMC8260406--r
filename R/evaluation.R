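# Frame-wise evaluation: accuracy, class-wise precision/recall/F1 with
# macro averaging, joint phase-step accuracy, video-level cross-validation
# folds, and fold aggregation.
#
# Per class c: PR = |{t: pred_t = c & gt_t = c}| / |{t: pred_t = c}|,
# RE with the ground-truth count in the denominator, F1 the harmonic mean.
# Undefined cases (the annotation protocol is silent on them) are resolved
# as: a class never predicted gets PR = 0 (never-predicting a rare class is
# not rewarded); a class absent from both ground truth and predictions is
# excluded from the macro averages (impossible classes are not penalized);
# F1 at PR = RE = 0 is 0 (harmonic-mean limit).

#' Frame-wise accuracy
#'
#' @param gt,pred Equal-length label vectors.
#' @return Fraction of frames with `gt == pred`.
#' @export
frame_accuracy <- function(gt, pred) {
  if (length(gt) != length(pred) || length(gt) < 1L) {
    stop("gt and pred must be equal-length, non-empty", call. = FALSE)
  }
  mean(gt == pred)
}

#' Class-wise precision / recall / F1 with macro averages
#'
#' @param gt,pred Equal-length label vectors.
#' @param classes The class set to evaluate over (default: all classes seen
#'   in either vector). Classes present in neither `gt` nor `pred` are
#'   reported with `NA` metrics and excluded from the macro averages.
#' @return Object of class `surgtcn_metrics`: a list with `accuracy`,
#'   `per_class` (`data.frame` of class, precision, recall, f1, support),
#'   and `macro_pr`, `macro_re`, `macro_f1`.
#' @export
classwise_prf <- function(gt, pred, classes = sort(unique(c(gt, pred)))) {
  if (length(gt) != length(pred) || length(gt) < 1L) {
    stop("gt and pred must be equal-length, non-empty", call. = FALSE)
  }
  n <- length(classes)
  prec <- rec <- f1 <- rep(NA_real_, n)
  support <- integer(n)
  for (i in seq_len(n)) {
    c0 <- classes[i]
    tp <- sum(gt == c0 & pred == c0)
    n_pred <- sum(pred == c0)
    n_gt <- sum(gt == c0)
    support[i] <- n_gt
    if (n_gt == 0L && n_pred == 0L) next # absent from both: excluded
    prec[i] <- if (n_pred > 0L) tp / n_pred else 0
    rec[i] <- if (n_gt > 0L) tp / n_gt else 0
    f1[i] <- if (prec[i] + rec[i] > 0) {
      2 * prec[i] * rec[i] / (prec[i] + rec[i])
    } else 0
  }
  included <- !is.na(prec)
  structure(list(
    accuracy = mean(gt == pred),
    per_class = data.frame(class = classes, precision = prec, recall = rec,
                           f1 = f1, support = support),
    macro_pr = mean(prec[included]),
    macro_re = mean(rec[included]),
    macro_f1 = mean(f1[included])
  ), class = "surgtcn_metrics")
}

#' @export
print.surgtcn_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro PR %.4f RE %.4f F1 %.4f (%d classes)\n",
              x$accuracy, x$macro_pr, x$macro_re, x$macro_f1,
              sum(!is.na(x$per_class$precision))))
  invisible(x)
}

#' Joint phase-step accuracy
#'
#' Fraction of frames at which both the phase and the step are correctly
#' recognized; never exceeds the smaller of the two per-task accuracies.
#'
#' @param gt_phase,pred_phase,gt_step,pred_step Equal-length label vectors.
#' @return Fraction in `[0, 1]`.
#' @export
joint_accuracy <- function(gt_phase, pred_phase, gt_step, pred_step) {
  n <- length(gt_phase)
  if (any(c(length(pred_phase), length(gt_step), length(pred_step)) != n) ||
      n < 1L) {
    stop("all four label tracks must have equal, positive length",
         call. = FALSE)
  }
  mean(gt_phase == pred_phase & gt_step == pred_step)
}

#' Video-level cross-validation folds
#'
#' Shuffles the video ids with the given seed and splits them into
#' `n_folds` equal test sets; for each fold the remaining videos are split
#' into `n_val` validation and the rest training. Every video appears in
#' exactly one test set. The reference protocol is 40 videos in 4 folds of
#' test = 10 with train/val = 24/6.
#'
#' @param video_ids Character or integer vector of ids; length must be a
#'   multiple of `n_folds`.
#' @param n_folds Number of folds (default 4).
#' @param n_val Validation videos per fold (default 6).
#' @param seed Shuffle seed.
#' @return List of `n_folds` splits, each a list with `fold_id`, `test`,
#'   `val`, `train`.
#' @export
make_folds <- function(video_ids, n_folds = 4, n_val = 6, seed = 1) {
  n <- length(video_ids)
  if (n %% n_folds != 0L) {
    stop(sprintf("%d videos cannot be split into %d equal test sets", n,
                 n_folds), call. = FALSE)
  }
  per <- n %/% n_folds
  if (n_val >= n - per) {
    stop("n_val leaves no training videos", call. = FALSE)
  }
  shuffled <- with_seed(child_seed(seed, 51L), sample(video_ids))
  lapply(seq_len(n_folds), function(f) {
    test <- shuffled[((f - 1L) * per + 1L):(f * per)]
    rest <- setdiff(shuffled, test)
    val <- rest[seq_len(n_val)]
    train <- setdiff(rest, val)
    list(fold_id = f, test = test, val = val, train = train)
  })
}

#' Aggregate a per-fold metric into mean and standard deviation
#'
#' @param values Numeric vector, one value per fold.
#' @return List with `mean` and `sd` (sample sd; 0 for a single fold).
#' @examples
#' aggregate_folds(c(80, 90)) # mean 85, sd ~7.071
#' @export
aggregate_folds <- function(values) {
  if (length(values) < 1L) stop("no fold values to aggregate", call. = FALSE)
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else 0)
}

#' Evaluate model predictions over a set of test videos
#'
#' Computes per-task accuracy, macro PR/RE/F1 and joint accuracy. By
#' default each metric is computed per video and then averaged over videos
#' (`granularity = "per-video"`); `"pooled"` concatenates all frames before
#' computing metrics.
#'
#' @param timelines List of ground-truth `surgtcn_timeline`s.
#' @param predictions Parallel list of prediction lists with 0-based
#'   `phase` and/or `step` elements (as returned by [predict.mtms_tcn()]
#'   or [online_predict()]).
#' @param granularity `"per-video"` or `"pooled"`.
#' @return `data.frame` with one row per metric (`task`, `metric`,
#'   `value`).
#' @export
evaluate_predictions <- function(timelines, predictions,
                                 granularity = c("per-video", "pooled")) {
  granularity <- match.arg(granularity)
  stopifnot(length(timelines) == length(predictions))
  tasks <- intersect(c("phase", "step"), names(predictions[[1]]))
  gt_of <- function(tl, task) {
    if (task == "phase") tl$phase_labels else tl$step_labels
  }
  one_video <- function(i) {
    out <- list()
    for (task in tasks) {
      m <- classwise_prf(gt_of(timelines[[i]], task), predictions[[i]][[task]])
      out[[task]] <- c(accuracy = m$accuracy, precision = m$macro_pr,
                       recall = m$macro_re, f1 = m$macro_f1)
    }
    if (length(tasks) == 2L) {
      out$joint <- c(accuracy = joint_accuracy(
        timelines[[i]]$phase_labels, predictions[[i]]$phase,
        timelines[[i]]$step_labels, predictions[[i]]$step))
    }
    out
  }
  if (granularity == "per-video") {
    per <- lapply(seq_along(timelines), one_video)
    rows <- do.call(rbind, lapply(names(per[[1]]), function(task) {
      vals <- do.call(rbind, lapply(per, `[[`, task))
      data.frame(task = task, metric = colnames(vals),
                 value = colMeans(vals), row.names = NULL)
    }))
  } else {
    pooled_tl <- timeline("pooled",
                          unlist(lapply(timelines, `[[`, "phase_labels")),
                          unlist(lapply(timelines, `[[`, "step_labels")))
    pooled_pred <- list()
    for (task in tasks) {
      pooled_pred[[task]] <- unlist(lapply(predictions, `[[`, task))
    }
    rows <- do.call(rbind, lapply(tasks, function(task) {
      m <- classwise_prf(gt_of(pooled_tl, task), pooled_pred[[task]])
      data.frame(task = task,
                 metric = c("accuracy", "precision", "recall", "f1"),
                 value = c(m$accuracy, m$macro_pr, m$macro_re, m$macro_f1))
    }))
    if (length(tasks) == 2L) {
      rows <- rbind(rows, data.frame(
        task = "joint", metric = "accuracy",
        value = joint_accuracy(pooled_tl$phase_labels, pooled_pred$phase,
                               pooled_tl$step_labels, pooled_pred$step)))
    }
  }
  rownames(rows) <- NULL
  rows
}
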