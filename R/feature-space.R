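# PCA feature space and cluster consistency/separability metrics.
#
# Frames are flattened to pixel vectors (points in an H*W-dimensional
# space, 14,000-D at the default 100 x 140 frame size) and projected onto
# the top principal components (5 by default). Each motion class forms a
# labeled point cluster in that space; the metrics below summarize how
# consistent the repetitions of one motion are (WD), how separable
# different motions are (IDNN, IDAN, MSD), and how variable a motion
# cluster is (MSA).

#' Construct a labeled feature cloud
#'
#' Low-level constructor used both by [fit_project_pca()] and directly in
#' analyses of pre-computed feature points.
#'
#' @param points numeric `N x k` matrix of feature coordinates.
#' @param motion character/factor vector of class labels (length `N`).
#' @param repetition integer vector of repetition labels (length `N`).
#' @param projection optional list describing the projection used
#'   (`center`, `rotation`, `sdev`).
#' @return an object of class `smg_features`.
#' @export
feature_cloud <- function(points, motion, repetition,
                          projection = NULL) {
  points <- as.matrix(points)
  if (nrow(points) != length(motion) || nrow(points) != length(repetition)) {
    stop("every point needs a motion and repetition label", call. = FALSE)
  }
  structure(list(points = points, motion = as.character(motion),
                 repetition = as.integer(repetition),
                 projection = projection),
            class = "smg_features")
}

#' @export
print.smg_features <- function(x, ...) {
  cat(sprintf("SMG feature cloud: %d points in %d-D\n",
              nrow(x$points), ncol(x$points)))
  cat(sprintf("  classes: %s\n",
              paste(sort(unique(x$motion)), collapse = ", ")))
  if (!is.null(x$projection)) {
    ve <- x$projection$sdev[seq_len(ncol(x$points))]^2 /
      sum(x$projection$sdev^2)
    cat(sprintf("  PCA variance explained: %s\n",
                paste(sprintf("%.1f%%", 100 * ve), collapse = " ")))
  }
  invisible(x)
}

#' Project a dataset's frames into a low-dimensional PCA feature space
#'
#' Flattens every analysis frame to its pixel vector, fits a mean-centered
#' PCA on all of them jointly, and keeps the scores on the top
#' `n_components` variance-ordered axes.
#'
#' @param dataset an [smg_dataset()].
#' @param n_components dimensionality of the feature space (default 5).
#' @param include_rest logical; include rest frames (labeled `"rest"`) in
#'   the projection and cloud. Off by default: the motion classes define
#'   the feature space.
#' @return an [feature_cloud()] whose `projection` holds the PCA center,
#'   rotation and all singular standard deviations.
#' @export
fit_project_pca <- function(dataset, n_components = 5L,
                            include_rest = FALSE) {
  stopifnot(inherits(dataset, "smg_dataset"))
  af <- analysis_frames(dataset, include_rest)
  X <- frame_matrix(af)
  if (nrow(X) < n_components) {
    stop(sprintf("need at least %d frames for %d components",
                 n_components, n_components), call. = FALSE)
  }
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE,
                     rank. = n_components)
  feature_cloud(p$x[, seq_len(n_components), drop = FALSE],
                af$info$motion, af$info$repetition,
                projection = list(center = p$center,
                                  rotation = p$rotation,
                                  sdev = p$sdev))
}

#' Mean, covariance and semi-principal axes of a point cluster
#'
#' @param points numeric `n x k` matrix (cluster points).
#' @return an object of class `smg_cluster_stats`: list with `mu` (mean
#'   vector), `S` (sample covariance), `axes` (square roots of the
#'   covariance eigenvalues, i.e. standard deviations along the principal
#'   axes of the 1-sigma hyperellipsoid, sorted descending) and `n_points`.
#' @export
cluster_stats <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) {
    stop("need at least 2 points for a covariance", call. = FALSE)
  }
  S <- stats::cov(points)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  structure(list(mu = colMeans(points), S = S,
                 axes = sqrt(pmax(ev, 0)), n_points = nrow(points)),
            class = "smg_cluster_stats")
}

# Ridge regularization keeping the covariance invertible for small or
# degenerate clusters: S + lambda * tr(S)/k * I.
regularize_cov <- function(S, lambda) {
  if (lambda <= 0) return(S)
  S + diag(lambda * sum(diag(S)) / ncol(S), ncol(S))
}

#' Half Mahalanobis distance between two cluster means
#'
#' The directed distance `(1/2) * sqrt((mu_from - mu_to)' S_from^{-1}
#' (mu_from - mu_to))`, using the covariance of the cluster the distance is
#' measured *from*. The covariance can be ridge-regularized (see
#' [feature_metrics()]) to keep small clusters invertible.
#'
#' @param mu_from,mu_to mean vectors of equal length.
#' @param S_from covariance matrix of the "from" cluster (symmetric).
#' @param regularize logical; apply the ridge before inverting.
#' @param lambda ridge strength relative to the mean diagonal.
#' @return non-negative scalar.
#' @examples
#' half_mahalanobis(c(2, 0, 0, 0, 0), rep(0, 5), diag(5)) # 1
#' @export
half_mahalanobis <- function(mu_from, mu_to, S_from,
                             regularize = TRUE, lambda = 1e-6) {
  if (length(mu_from) != length(mu_to) ||
      !all(dim(S_from) == length(mu_from))) {
    stop("dimensions of means and covariance must agree", call. = FALSE)
  }
  if (!isSymmetric(unname(S_from), tol = 1e-8)) {
    stop("covariance matrix must be symmetric", call. = FALSE)
  }
  if (regularize) S_from <- regularize_cov(S_from, lambda)
  d <- mu_from - mu_to
  0.5 * sqrt(drop(crossprod(d, solve(S_from, d))))
}

#' Symmetric pooling of two directed distances
#'
#' Combines the two directed half-Mahalanobis distances between a pair of
#' clusters into one symmetric value, `d_ab * d_ba / (d_ab + d_ba)` (half
#' the harmonic mean). When both inputs are zero the 0/0 form is defined
#' as 0 (coincident clusters are at distance zero).
#'
#' @param d_ab,d_ba non-negative directed distances (vectorized).
#' @return non-negative scalar (or vector).
#' @examples
#' combined_distance(1, 1)  # 0.5
#' combined_distance(2, 3)  # 1.2
#' @export
combined_distance <- function(d_ab, d_ba) {
  if (any(d_ab < 0) || any(d_ba < 0)) {
    stop("distances must be non-negative", call. = FALSE)
  }
  out <- ifelse(d_ab + d_ba == 0, 0, d_ab * d_ba / (d_ab + d_ba))
  as.numeric(out)
}

# Combined distance between two clusters given their stats.
pair_distance <- function(a, b, regularize, lambda) {
  combined_distance(
    half_mahalanobis(a$mu, b$mu, a$S, regularize, lambda),
    half_mahalanobis(b$mu, a$mu, b$S, regularize, lambda)
  )
}

# Split a cloud's points by class (sorted class order), or by repetition
# within one class.
split_by_class <- function(cloud) {
  classes <- sort(unique(cloud$motion))
  lapply(stats::setNames(classes, classes),
         function(cl) cloud$points[cloud$motion == cl, , drop = FALSE])
}

split_by_repetition <- function(cloud, class_j) {
  sel <- cloud$motion == class_j
  if (!any(sel)) {
    stop(sprintf("no points with class '%s'", class_j), call. = FALSE)
  }
  reps <- sort(unique(cloud$repetition[sel]))
  lapply(stats::setNames(reps, reps), function(r) {
    cloud$points[sel & cloud$repetition == r, , drop = FALSE]
  })
}

#' Within-class distance of one motion (repetition consistency)
#'
#' Sums, over all ordered pairs of repetitions of the motion, the combined
#' half-Mahalanobis distance between the repetition sub-clusters (each
#' directed distance uses its own repetition's covariance). Self-pairs are
#' 0/0 forms and contribute 0. Smaller values mean the repetitions landed
#' closer together in feature space, i.e. more consistent performance.
#'
#' @param cloud an [feature_cloud()].
#' @param class_j class label to evaluate.
#' @param regularize,lambda covariance ridge, see [feature_metrics()].
#' @return non-negative scalar `WD_j`.
#' @export
within_class_distance <- function(cloud, class_j, regularize = TRUE,
                                  lambda = 1e-6) {
  reps <- split_by_repetition(cloud, class_j)
  if (length(reps) < 2L) {
    stop(sprintf("class '%s' has fewer than 2 repetitions", class_j),
         call. = FALSE)
  }
  st <- lapply(reps, cluster_stats)
  total <- 0
  for (r in seq_along(st)) {
    for (k in seq_along(st)) {
      if (r == k) next # 0/0 self-term, defined as 0
      d_rk <- half_mahalanobis(st[[r]]$mu, st[[k]]$mu, st[[r]]$S,
                               regularize, lambda)
      d_kr <- half_mahalanobis(st[[k]]$mu, st[[r]]$mu, st[[k]]$S,
                               regularize, lambda)
      total <- total + combined_distance(d_rk, d_kr)
    }
  }
  total
}

# Class-level cluster stats and the matrix of pairwise combined distances.
class_distance_matrix <- function(cloud, regularize, lambda) {
  by_class <- split_by_class(cloud)
  if (length(by_class) < 2L) {
    stop("separability metrics require at least 2 classes", call. = FALSE)
  }
  st <- lapply(by_class, cluster_stats)
  n <- length(st)
  D <- matrix(0, n, n, dimnames = list(names(st), names(st)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      D[i, j] <- D[j, i] <- pair_distance(st[[i]], st[[j]],
                                          regularize, lambda)
    }
  }
  list(stats = st, D = D)
}

#' Inter-class distance to the nearest neighboring motion
#'
#' For each motion class, the combined half-Mahalanobis distance (computed
#' from the class-level means and covariances) to its nearest other class;
#' the total is the mean over classes. Larger values mean better
#' separability.
#'
#' @inheritParams within_class_distance
#' @return list with `per_class` (named vector `IDNN_j`) and `total`.
#' @export
inter_class_nn <- function(cloud, regularize = TRUE, lambda = 1e-6) {
  cd <- class_distance_matrix(cloud, regularize, lambda)
  D <- cd$D
  diag(D) <- Inf
  per <- apply(D, 1L, min)
  list(per_class = per, total = mean(per))
}

#' Inter-class distance summed over all neighboring motions
#'
#' Like [inter_class_nn()] but summing the combined distances to every
#' other class instead of taking the nearest one.
#'
#' @inheritParams within_class_distance
#' @return list with `per_class` (named vector `IDAN_j`) and `total`.
#' @export
inter_class_all <- function(cloud, regularize = TRUE, lambda = 1e-6) {
  cd <- class_distance_matrix(cloud, regularize, lambda)
  per <- rowSums(cd$D)
  list(per_class = per, total = mean(per))
}

#' Separability in the single most separable feature dimension
#'
#' For every pair of classes the combined distance is evaluated dimension
#' by dimension (1-D half-Mahalanobis, `|delta mu_d| / (2 sqrt(S_dd))` per
#' direction) and the best dimension is kept; each class then takes the
#' minimum over the other classes, and the total is the mean.
#'
#' @inheritParams within_class_distance
#' @return list with `per_class` (named vector `MSD_j`) and `total`.
#' @export
most_separable_dimension <- function(cloud, regularize = TRUE,
                                     lambda = 1e-6) {
  by_class <- split_by_class(cloud)
  if (length(by_class) < 2L) {
    stop("separability metrics require at least 2 classes", call. = FALSE)
  }
  st <- lapply(by_class, cluster_stats)
  if (regularize) {
    st <- lapply(st, function(s) {
      s$S <- regularize_cov(s$S, lambda)
      s
    })
  }
  n <- length(st)
  k <- length(st[[1L]]$mu)
  Dmax <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      dmu <- abs(st[[i]]$mu - st[[j]]$mu)
      d_ij <- 0.5 * dmu / sqrt(diag(st[[i]]$S))
      d_ji <- 0.5 * dmu / sqrt(diag(st[[j]]$S))
      Dmax[i, j] <- Dmax[j, i] <- max(combined_distance(d_ij, d_ji))
    }
  }
  diag(Dmax) <- Inf
  per <- apply(Dmax, 1L, min)
  names(per) <- names(st)
  list(per_class = per, total = mean(per))
}

#' Mean semi-principal axis of each motion cluster
#'
#' The geometric mean of the semi-principal axes of a class's 1-sigma
#' hyperellipsoid, i.e. of the square roots of its covariance eigenvalues.
#' Larger values mean a more variable (more spread out) cluster. The axis
#' scale (1-sigma by default) can be changed with `axis_scale`.
#'
#' @inheritParams within_class_distance
#' @param axis_scale multiplier applied to every semi-axis (e.g. a
#'   confidence-ellipsoid radius); default 1.
#' @return list with `per_class` (named vector `MSA_j`) and `total`.
#' @export
mean_semi_principal_axis <- function(cloud, regularize = TRUE,
                                     lambda = 1e-6, axis_scale = 1) {
  by_class <- split_by_class(cloud)
  st <- lapply(by_class, cluster_stats)
  k <- ncol(cloud$points)
  per <- vapply(st, function(s) {
    S <- if (regularize) regularize_cov(s$S, lambda) else s$S
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 1e-12 * max(ev, 0))) {
      warning("rank-deficient class covariance; semi-axes include ~0",
              call. = FALSE)
    }
    axes <- axis_scale * sqrt(pmax(ev, 0))
    prod(axes)^(1 / k)
  }, numeric(1L))
  list(per_class = per, total = mean(per))
}

#' All five feature-space metrics of a labeled cloud
#'
#' Computes the per-class and total within-class distance (WD), inter-class
#' nearest-/all-neighbor distances (IDNN, IDAN), most separable dimension
#' (MSD) and mean semi-principal axis (MSA). Totals are arithmetic means of
#' the per-class values over the motion classes; the `"rest"` label, if
#' present in the cloud, is excluded by default.
#'
#' Per-repetition and per-class covariances of small clusters can be
#' singular; a ridge `S + lambda * tr(S)/k * I` keeps them invertible.
#' Disable it (`regularize = FALSE`) when exact affine invariance of
#' WD/IDNN/IDAN matters and clusters are well-conditioned.
#'
#' @param cloud an [feature_cloud()].
#' @param regularize logical; ridge-regularize covariances (default TRUE).
#' @param lambda ridge strength relative to the mean diagonal.
#' @param exclude_rest drop points labeled `"rest"` before computing.
#' @param axis_scale semi-axis multiplier for MSA.
#' @return an object of class `smg_metrics`: list with `per_class` (data
#'   frame, one row per class) and `totals` (named numeric vector).
#' @export
feature_metrics <- function(cloud, regularize = TRUE, lambda = 1e-6,
                            exclude_rest = TRUE, axis_scale = 1) {
  stopifnot(inherits(cloud, "smg_features"))
  if (exclude_rest && any(cloud$motion == "rest")) {
    keep <- cloud$motion != "rest"
    cloud <- feature_cloud(cloud$points[keep, , drop = FALSE],
                           cloud$motion[keep], cloud$repetition[keep],
                           cloud$projection)
  }
  classes <- sort(unique(cloud$motion))
  wd <- vapply(classes, function(cl) {
    within_class_distance(cloud, cl, regularize, lambda)
  }, numeric(1L))
  idnn <- inter_class_nn(cloud, regularize, lambda)
  idan <- inter_class_all(cloud, regularize, lambda)
  msd <- most_separable_dimension(cloud, regularize, lambda)
  msa <- mean_semi_principal_axis(cloud, regularize, lambda, axis_scale)
  per_class <- data.frame(
    motion = classes,
    WD = unname(wd),
    IDNN = unname(idnn$per_class[classes]),
    IDAN = unname(idan$per_class[classes]),
    MSD = unname(msd$per_class[classes]),
    MSA = unname(msa$per_class[classes]),
    stringsAsFactors = FALSE
  )
  totals <- c(WD = mean(per_class$WD), IDNN = idnn$total,
              IDAN = idan$total, MSD = msd$total, MSA = msa$total)
  structure(list(per_class = per_class, totals = totals),
            class = "smg_metrics")
}

#' @export
print.smg_metrics <- function(x, digits = 4, ...) {
  cat("SMG feature-space metrics\n")
  df <- x$per_class
  df[-1L] <- lapply(df[-1L], round, digits)
  print(df, row.names = FALSE)
  cat("totals:\n")
  print(round(x$totals, digits))
  invisible(x)
}
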