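# Per-video feature containers. The native format is a raw binary array of
# little-endian 32-bit floats, row-major (frame-contiguous), with a JSON
# sidecar `<path>.json` holding {video_id, n_frames, n_features, dtype,
# order}. A plain-CSV fallback (header f1..fN, one row per frame) is
# provided for interoperability; it is lossier only in file size.

#' Write a per-frame feature matrix to a container file
#'
#' @param x `T x N_f` numeric matrix (one row per frame).
#' @param path Output path. For `format = "bin"` a `<path>.json` sidecar is
#'   written alongside.
#' @param format `"bin"` (float32 little-endian, row-major) or `"csv"`.
#' @param video_id Video identifier recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_features <- function(x, path, format = c("bin", "csv"),
                           video_id = "unknown") {
  format <- match.arg(format)
  x <- as.matrix(x)
  if (format == "bin") {
    con <- file(path, "wb")
    on.exit(close(con))
    # row-major: frames contiguous on disk
    writeBin(as.vector(t(x)), con, size = 4L, endian = "little")
    meta <- list(video_id = video_id, n_frames = nrow(x),
                 n_features = ncol(x), dtype = "float32", order = "row-major")
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  } else {
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a feature container written by [write_features()]
#'
#' The format is inferred: a `<path>.json` sidecar marks the binary format,
#' otherwise the file is parsed as CSV.
#'
#' @param path Container path.
#' @return `T x N_f` numeric matrix.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path, call. = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    n <- meta$n_frames * meta$n_features
    con <- file(path, "rb")
    on.exit(close(con))
    v <- readBin(con, what = "numeric", n = n, size = 4L, endian = "little")
    if (length(v) != n) stop("feature file truncated: ", path, call. = FALSE)
    matrix(v, nrow = meta$n_frames, ncol = meta$n_features, byrow = TRUE)
  } else {
    m <- as.matrix(utils::read.csv(path))
    dimnames(m) <- NULL
    m
  }
}
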