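# Readers/writers, downscaling and cue-aligned frame extraction.

# Area-overlap resampling matrix mapping n_src pixels onto n_dst (<= n_src):
# row t holds the fraction of each source pixel covered by destination
# pixel t, normalized so rows sum to 1 (exact area average).
area_weights <- function(n_src, n_dst) {
  scale <- n_src / n_dst
  W <- matrix(0, n_dst, n_src)
  for (t in seq_len(n_dst)) {
    lo <- (t - 1) * scale
    hi <- t * scale
    src <- seq(floor(lo) + 1L, ceiling(hi))
    overlap <- pmin(src, hi) - pmax(src - 1, lo)
    W[t, src] <- overlap / scale
  }
  W
}

#' Downscale a grayscale frame by area averaging
#'
#' Resamples a frame to smaller target dimensions using exact area-weighted
#' averaging (each output pixel is the mean of the source area it covers).
#' Deterministic; a constant image stays constant and equal target
#' dimensions return the input unchanged.
#'
#' @param pixels numeric matrix of grayscale intensities.
#' @param target_h,target_w target dimensions; must not exceed the source
#'   dimensions (upscaling is an error).
#' @return `target_h x target_w` numeric matrix.
#' @examples
#' downscale_frame(matrix(0.4, 200, 280), 100, 140)[1, 1]
#' @export
downscale_frame <- function(pixels, target_h, target_w) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (target_h > nrow(pixels) || target_w > ncol(pixels)) {
    stop("target dimensions must not exceed source dimensions (no upscaling)",
         call. = FALSE)
  }
  if (target_h < 1L || target_w < 1L) {
    stop("target dimensions must be >= 1", call. = FALSE)
  }
  if (target_h == nrow(pixels) && target_w == ncol(pixels)) {
    return(pixels)
  }
  Wh <- area_weights(nrow(pixels), target_h)
  Ww <- area_weights(ncol(pixels), target_w)
  Wh %*% pixels %*% t(Ww)
}

#' Assign cue-cycle roles and extract end-state and rest frames
#'
#' Labels an ordered frame sequence by its position inside the repeated cue
#' cycle (default one second each of move, hold, return, rest) and returns
#' the hold ("end state") and rest frames, tagged with the repetition
#' number. Time windows are half-open `[start, end)` in frame indices, so
#' every frame receives exactly one role. A final cycle cut short by the
#' end of the sequence is labeled as far as it goes, with a warning.
#'
#' @param sequence either an `H x W x N` frame array or an integer frame
#'   count `N` (labels only).
#' @param frame_rate frames per second.
#' @param cycle numeric length-4 vector of segment durations in seconds,
#'   ordered move/hold/return/rest; default `c(1, 1, 1, 1)`.
#' @return a data frame with columns `index` (1-based position in the
#'   sequence), `role` (`"hold"` or `"rest"`) and `repetition`; if
#'   `sequence` was an array, the matching frames are attached as the
#'   `"frames"` attribute (`H x W x n` array).
#' @examples
#' lab <- extract_task_frames(40, frame_rate = 10)
#' range(lab$index[lab$role == "hold"]) # frames 11..20 (0-based 10..19)
#' @export
extract_task_frames <- function(sequence, frame_rate,
                                cycle = c(1, 1, 1, 1)) {
  stopifnot(length(cycle) == 4L, all(cycle > 0), frame_rate >= 1)
  if (is.array(sequence) && length(dim(sequence)) == 3L) {
    n <- dim(sequence)[3L]
    frames <- sequence
  } else if (is.numeric(sequence) && length(sequence) == 1L) {
    n <- as.integer(sequence)
    frames <- NULL
  } else {
    stop("'sequence' must be an H x W x N array or a frame count",
         call. = FALSE)
  }
  seg_frames <- round(cycle * frame_rate)
  cyc_frames <- sum(seg_frames)
  if (n < cyc_frames) {
    if (n < seg_frames[1L] + 1L) {
      stop("sequence shorter than the first hold window; nothing to extract",
           call. = FALSE)
    }
    warning("sequence does not cover a full cue cycle; labeling partial cycle",
            call. = FALSE)
  } else if (n %% cyc_frames != 0L) {
    warning("final cue cycle is truncated; its frames are labeled partially",
            call. = FALSE)
  }
  roles <- rep(c("move", "hold", "return", "rest"), times = seg_frames)
  pos0 <- seq_len(n) - 1L # 0-based time index
  repetition <- pos0 %/% cyc_frames + 1L
  role <- roles[pos0 %% cyc_frames + 1L]
  keep <- role %in% c("hold", "rest")
  out <- data.frame(index = which(keep), role = role[keep],
                    repetition = repetition[keep],
                    stringsAsFactors = FALSE)
  if (!is.null(frames)) {
    attr(out, "frames") <- frames[, , out$index, drop = FALSE]
  }
  out
}

manifest_columns <- c("subject", "session", "phase", "motion", "repetition",
                      "role", "frame_index", "path")

#' Save a dataset to disk
#'
#' Two dialects: a directory of 8-bit grayscale PNG frames plus a
#' `manifest.csv` (one row per frame with all labels and the relative PNG
#' path), or a single `.rds` container holding frames and labels exactly.
#' PNG intensities are scaled to 8 bits on write, so the PNG dialect round
#' trips pixel values to within 1/255 (labels exactly); the RDS container
#' round trips bit-for-bit.
#'
#' @param dataset an [smg_dataset()].
#' @param path target path: an existing/creatable directory for the PNG
#'   dialect, or a file name ending in `.rds` for the container dialect.
#' @return `path`, invisibly.
#' @seealso [load_dataset()]
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "smg_dataset"))
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(list(frames = dataset$frames, info = dataset$info), path)
    return(invisible(path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  n <- n_frames(dataset)
  rel <- sprintf("frame_%05d.png", seq_len(n))
  for (i in seq_len(n)) {
    img <- pmin(pmax(dataset$frames[, , i], 0), 1)
    png::writePNG(img, file.path(path, rel[i]))
  }
  manifest <- cbind(dataset$info, path = rel)
  utils::write.csv(manifest, file.path(path, "manifest.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Load a dataset from disk
#'
#' Reads either dialect written by [save_dataset()]. For the PNG dialect
#' the `manifest.csv` must contain every label column; a missing column or
#' frames of inconsistent dimensions are format errors.
#'
#' @param path dataset directory (PNG dialect) or `.rds` container file.
#' @return an [smg_dataset()].
#' @export
load_dataset <- function(path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    obj <- readRDS(path)
    return(smg_dataset(obj$frames, obj$info))
  }
  manifest_path <- file.path(path, "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop("no manifest.csv found in ", path, call. = FALSE)
  }
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(manifest_columns, names(manifest))
  if (length(missing_cols) > 0L) {
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  imgs <- lapply(file.path(path, manifest$path), function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 3L) img <- img[, , 1L] # tolerate gray-alpha
    img
  })
  dims <- unique(lapply(imgs, dim))
  if (length(dims) != 1L) {
    stop("frames have inconsistent dimensions", call. = FALSE)
  }
  info <- manifest[, setdiff(names(manifest), "path"), drop = FALSE]
  smg_dataset(imgs, info)
}
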