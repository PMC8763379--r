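# Real-time style biofeedback trace: inverted correlation against rest.

#' Inverted-correlation biofeedback trace of a frame sequence
#'
#' For every frame the Pearson correlation against the sequence's first
#' frame (taken at rest) is computed and inverted, `v_t = 1 - r_t`, so the
#' display reads approximately 0 at rest and rises towards 1 (or up to 2
#' for anti-correlated frames) as the muscle deformation departs from the
#' rest configuration. Values are appended in frame order and earlier
#' values are retained, mimicking a persistent real-time display trace.
#' An alternative inversion `v_t = -r_t` is available.
#'
#' @param sequence `H x W x N` frame array (or [smg_dataset()], whose
#'   frames are used in stored order).
#' @param mapping `"one_minus_r"` (default) or `"neg_r"`.
#' @return an object of class `smg_feedback`: data frame with columns
#'   `frame` (1-based index) and `v` (display value).
#' @export
correlation_trace <- function(sequence, mapping = c("one_minus_r",
                                                    "neg_r")) {
  mapping <- match.arg(mapping)
  if (inherits(sequence, "smg_dataset")) sequence <- sequence$frames
  if (!is.array(sequence) || length(dim(sequence)) != 3L) {
    stop("'sequence' must be an H x W x N array", call. = FALSE)
  }
  n <- dim(sequence)[3L]
  if (n < 2L) stop("need at least 2 frames", call. = FALSE)
  d <- dim(sequence)
  X <- t(matrix(sequence, d[1L] * d[2L], n))
  r <- row_correlations(X, X[1L, , drop = FALSE])[, 1L]
  v <- switch(mapping, one_minus_r = 1 - r, neg_r = -r)
  structure(data.frame(frame = seq_len(n), v = v),
            class = c("smg_feedback", "data.frame"))
}

#' Plateau-consistency score of a hold window
#'
#' The population standard deviation of the display value over a hold
#' window. A flat plateau -- successive end-state frames that deform the
#' image the same way -- scores 0; frame-to-frame variation raises the
#' score.
#'
#' @param trace an [correlation_trace()] result.
#' @param hold_window integer vector of frame indices within the trace.
#' @return non-negative scalar.
#' @export
plateau_score <- function(trace, hold_window) {
  stopifnot(inherits(trace, "smg_feedback"))
  if (length(hold_window) == 0L) {
    stop("hold window is empty", call. = FALSE)
  }
  if (any(hold_window < 1L) || any(hold_window > nrow(trace))) {
    stop("hold window outside the trace", call. = FALSE)
  }
  v <- trace$v[hold_window]
  sqrt(mean((v - mean(v))^2))
}

#' @export
plot.smg_feedback <- function(x, ...) {
  graphics::plot(x$frame, x$v, type = "l", col = "red", lwd = 2,
                 xlab = "frame", ylab = "1 - correlation with rest", ...)
  graphics::abline(h = 0, col = "grey70", lty = 2)
  invisible(x)
}
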