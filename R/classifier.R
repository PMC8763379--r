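# Nearest-class correlation classifier with leave-one-out cross-validation.
#
# The classifier is a modified 1-nearest-neighbor: the Pearson correlation
# between the query frame's pixel vector and every training frame is
# averaged within each class, and the class with the highest mean
# correlation wins (instead of the single most similar image).

#' Pearson similarity between two grayscale frames
#'
#' Sample Pearson correlation of the two flattened pixel vectors. Invariant
#' under positive affine intensity transforms of either frame. A frame with
#' zero intensity variance has no defined correlation; its similarity is
#' reported as 0 with a warning so that degenerate frames do not abort a
#' whole cross-validation run.
#'
#' @param a,b numeric matrices of identical dimensions.
#' @return correlation in `[-1, 1]`.
#' @examples
#' m <- matrix(runif(20), 4, 5)
#' pearson_similarity(m, 2 * m + 3) # exactly 1
#' @export
pearson_similarity <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("frames must have identical dimensions", call. = FALSE)
  }
  va <- as.vector(a); vb <- as.vector(b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("zero-variance frame; similarity defined as 0", call. = FALSE)
    return(0)
  }
  stats::cor(va, vb)
}

# Correlations of each row of `X` (frames as pixel-vector rows) against
# each row of `Y`; zero-variance rows yield 0 (with one warning).
row_correlations <- function(X, Y) {
  zx <- row_standardize(X)
  zy <- row_standardize(Y)
  warn <- attr(zx, "zero_variance") || attr(zy, "zero_variance")
  if (warn) {
    warning("zero-variance frame(s); their similarities defined as 0",
            call. = FALSE)
  }
  tcrossprod(zx, zy) / (ncol(X) - 1L)
}

row_standardize <- function(X) {
  mu <- rowMeans(X)
  Xc <- X - mu
  s <- sqrt(rowSums(Xc^2) / (ncol(X) - 1L))
  zero <- s == 0
  s[zero] <- Inf # zero-variance rows become all-zero -> correlation 0
  out <- Xc / s
  attr(out, "zero_variance") <- any(zero)
  out
}

#' Classify a frame by class-averaged correlation
#'
#' Computes the Pearson correlation between the query and every training
#' frame, averages the similarities within each class, and returns the
#' class with the highest mean. Ties are broken deterministically in favor
#' of the class that sorts first (lowest class index).
#'
#' @param query numeric matrix (one frame).
#' @param train `H x W x N` array, list of matrices, or `N x P` matrix of
#'   flattened training frames.
#' @param labels character or factor vector of training class labels.
#' @return list with `class` (predicted label) and `class_means` (named
#'   vector of per-class mean similarities, in sorted class order).
#' @export
classify_frame <- function(query, train, labels) {
  if (is.array(train) && length(dim(train)) == 3L) {
    d <- dim(train)
    train <- t(matrix(train, d[1L] * d[2L], d[3L]))
  } else if (is.list(train) && !is.matrix(train)) {
    train <- t(vapply(train, as.vector, numeric(length(train[[1L]]))))
  }
  labels <- as.character(labels)
  if (nrow(train) != length(labels)) {
    stop("one label per training frame required", call. = FALSE)
  }
  classes <- sort(unique(labels))
  counts <- table(factor(labels, levels = classes))
  if (any(counts == 0L)) {
    stop("every class needs at least one training frame", call. = FALSE)
  }
  sims <- row_correlations(matrix(as.vector(query), nrow = 1L), train)[1L, ]
  class_means <- vapply(classes, function(cl) mean(sims[labels == cl]),
                        numeric(1L))
  list(class = classes[which.max(class_means)], class_means = class_means)
}

#' Leave-one-out cross-validation of the nearest-class classifier
#'
#' Every analysis frame is classified with itself withheld from its own
#' class's training pool (`holdout = "frame"`), or with its entire
#' repetition withheld (`holdout = "repetition"`, a stricter protocol for
#' robustness studies). Accumulates a confusion matrix and the
#' cross-validation accuracy `CA = 100 * P_correct / P_total`.
#'
#' By default only hold-role frames of the motion classes enter the
#' analysis; `include_rest = TRUE` adds the rest frames as an additional
#' `"rest"` class.
#'
#' @param dataset an [smg_dataset()].
#' @param include_rest logical; treat rest as a class of its own.
#' @param holdout `"frame"` (default) or `"repetition"`.
#' @return an object of class `smg_cv`: list with `predicted` (per-frame
#'   data frame of true/predicted labels), `confusion` (true x predicted
#'   count matrix), `P_correct`, `P_total`, `CA` (percent) and `per_class`
#'   accuracies.
#' @examples
#' cfg <- image_gen_config(n_classes = 3, n_repetitions = 3,
#'                         frame_height = 24, frame_width = 32,
#'                         frame_rate = 4, class_separation = 2,
#'                         frame_noise = 0.01, seed = 5)
#' cv <- loo_cross_validate(generate_dataset(cfg))
#' cv$CA
#' @export
loo_cross_validate <- function(dataset, include_rest = FALSE,
                               holdout = c("frame", "repetition")) {
  stopifnot(inherits(dataset, "smg_dataset"))
  holdout <- match.arg(holdout)
  af <- analysis_frames(dataset, include_rest)
  X <- frame_matrix(af)
  labels <- as.character(af$info$motion)
  reps <- af$info$repetition
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("classification requires at least 2 classes", call. = FALSE)
  }
  counts <- table(factor(labels, levels = classes))
  if (holdout == "frame" && any(counts < 2L)) {
    stop("class(es) with fewer than 2 frames: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  if (holdout == "repetition") {
    nrep <- tapply(reps, labels, function(r) length(unique(r)))
    if (any(nrep < 2L)) {
      stop("class(es) with fewer than 2 repetitions: ",
           paste(names(nrep)[nrep < 2L], collapse = ", "), call. = FALSE)
    }
  }
  n <- nrow(X)
  C <- row_correlations(X, X)
  # per-class similarity sums for every query frame
  cls_f <- factor(labels, levels = classes)
  sums <- C %*% stats::model.matrix(~ cls_f - 1) # n x n_classes
  cnt <- matrix(as.numeric(counts), n, length(classes), byrow = TRUE)
  self_cls <- match(labels, classes)
  if (holdout == "frame") {
    # remove the held-out frame itself from its own class pool
    idx <- cbind(seq_len(n), self_cls)
    sums[idx] <- sums[idx] - diag(C)
    cnt[idx] <- cnt[idx] - 1L
  } else {
    # remove the whole repetition of the held-out frame from its class pool
    for (i in seq_len(n)) {
      mates <- labels == labels[i] & reps == reps[i]
      sums[i, self_cls[i]] <- sums[i, self_cls[i]] - sum(C[i, mates])
      cnt[i, self_cls[i]] <- cnt[i, self_cls[i]] - sum(mates)
    }
  }
  means <- sums / cnt
  pred_idx <- max.col(means, ties.method = "first")
  predicted <- classes[pred_idx]
  confusion <- table(true = factor(labels, levels = classes),
                     predicted = factor(predicted, levels = classes))
  P_correct <- sum(predicted == labels)
  P_total <- n
  per_class <- diag(confusion) / rowSums(confusion) * 100
  structure(list(
    predicted = data.frame(true = labels, predicted = predicted,
                           repetition = reps,
                           stringsAsFactors = FALSE),
    confusion = unclass(confusion),
    P_correct = P_correct, P_total = P_total,
    CA = 100 * P_correct / P_total,
    per_class = per_class,
    holdout = holdout, include_rest = include_rest
  ), class = "smg_cv")
}

#' @export
print.smg_cv <- function(x, ...) {
  cat(sprintf("Leave-one-%s-out cross-validation (nearest-class correlation)\n",
              x$holdout))
  cat(sprintf("  CA = %.1f%%  (%d / %d frames correct)\n",
              x$CA, x$P_correct, x$P_total))
  invisible(x)
}

#' @export
summary.smg_cv <- function(object, ...) {
  print(object)
  cat("\nPer-class accuracy (%):\n")
  print(round(object$per_class, 1))
  cat("\nConfusion matrix (true x predicted):\n")
  print(object$confusion)
  invisible(object)
}
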