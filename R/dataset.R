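#' Construct a labeled sonomyography frame dataset
#'
#' The in-memory container for one data-collection dataset: a stack of
#' grayscale frames plus one row of labels per frame. All frames must share
#' the same dimensions and intensities must be finite.
#'
#' @param frames numeric array `H x W x N` of grayscale intensities, or a
#'   list of `H x W` matrices (converted).
#' @param info data frame with one row per frame and columns `subject`,
#'   `session`, `phase`, `motion`, `repetition`, `role`, `frame_index`.
#'   `role` must be one of `"move"`, `"hold"`, `"return"`, `"rest"`;
#'   `phase` one of `"baseline"`, `"feedback"`, `"none"`.
#' @return an object of class `smg_dataset`: a list with elements `frames`
#'   (array) and `info` (data frame).
#' @export
smg_dataset <- function(frames, info) {
  if (is.list(frames) && !is.array(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) {
      stop("all frames must share the same height and width", call. = FALSE)
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1L]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("'frames' must be an H x W x N array", call. = FALSE)
  }
  if (!all(is.finite(frames))) {
    stop("frame intensities must be finite", call. = FALSE)
  }
  required <- c("subject", "session", "phase", "motion", "repetition",
                "role", "frame_index")
  missing_cols <- setdiff(required, names(info))
  if (length(missing_cols) > 0L) {
    stop("'info' is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(info) != dim(frames)[3L]) {
    stop("'info' must have one row per frame", call. = FALSE)
  }
  bad_role <- setdiff(unique(info$role), c("move", "hold", "return", "rest"))
  if (length(bad_role) > 0L) {
    stop("invalid role label(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  bad_phase <- setdiff(unique(info$phase), c("baseline", "feedback", "none"))
  if (length(bad_phase) > 0L) {
    stop("invalid phase label(s): ", paste(bad_phase, collapse = ", "),
         call. = FALSE)
  }
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  rownames(info) <- NULL
  structure(list(frames = frames, info = info), class = "smg_dataset")
}

#' @export
print.smg_dataset <- function(x, ...) {
  d <- dim(x$frames)
  motions <- setdiff(unique(x$info$motion), "rest")
  cat(sprintf("SMG dataset: %d frames of %d x %d px\n", d[3L], d[1L], d[2L]))
  cat(sprintf("  motions (%d): %s\n", length(motions),
              paste(motions, collapse = ", ")))
  cat(sprintf("  repetitions: %d   roles: %s\n",
              length(unique(x$info$repetition)),
              paste(sort(unique(x$info$role)), collapse = "/")))
  cat(sprintf("  subject %s, session %s, phase %s\n",
              x$info$subject[1L], x$info$session[1L], x$info$phase[1L]))
  invisible(x)
}

#' Number of frames in a dataset
#' @param x an `smg_dataset`.
#' @return integer frame count.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "smg_dataset"))
  dim(x$frames)[3L]
}

#' Subset a dataset by frame index
#'
#' @param dataset an `smg_dataset`.
#' @param idx integer or logical index over frames.
#' @return an `smg_dataset` containing the selected frames.
#' @export
subset_frames <- function(dataset, idx) {
  stopifnot(inherits(dataset, "smg_dataset"))
  smg_dataset(dataset$frames[, , idx, drop = FALSE],
              dataset$info[idx, , drop = FALSE])
}

#' Flatten frames to a pixel-vector matrix
#'
#' Each frame becomes one row of length `H * W` (column-major pixel order).
#'
#' @param dataset an `smg_dataset`.
#' @return numeric matrix `N x (H*W)`.
#' @export
frame_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "smg_dataset"))
  d <- dim(dataset$frames)
  t(matrix(dataset$frames, nrow = d[1L] * d[2L], ncol = d[3L]))
}

# Select the frames that enter classification / feature analysis:
# hold-role frames, excluding rest unless asked for.
analysis_frames <- function(dataset, include_rest = FALSE) {
  keep <- dataset$info$role == "hold" & dataset$info$motion != "rest"
  if (include_rest) {
    keep <- keep | (dataset$info$role == "rest")
  }
  subset_frames(dataset, keep)
}
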