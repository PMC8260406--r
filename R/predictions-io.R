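# Prediction file I/O: CSV with header `frame,pred_phase_id,pred_step_id`
# (either prediction column may be absent in single-task runs).

#' Write / read per-frame predictions
#'
#' @param pred List with 0-based `phase` and/or `step` label vectors.
#' @param path CSV path.
#' @return `write_predictions` returns `path` invisibly; `read_predictions`
#'   returns a list with `phase` and/or `step`.
#' @export
write_predictions <- function(pred, path) {
  n <- length(pred$phase %||% pred$step)
  df <- data.frame(frame = seq_len(n) - 1L)
  if (!is.null(pred$phase)) df$pred_phase_id <- pred$phase
  if (!is.null(pred$step)) df$pred_step_id <- pred$step
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path)
  out <- list()
  if ("pred_phase_id" %in% names(df)) out$phase <- as.integer(df$pred_phase_id)
  if ("pred_step_id" %in% names(df)) out$step <- as.integer(df$pred_step_id)
  out
}
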