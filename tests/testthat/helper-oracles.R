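# Independent brute-force oracles and fixture builders, written as plain
# loops so they share no code path with the package implementation.

# Naive nearest-class classifier: one cor() call per training frame,
# explicit per-class averaging, lowest-sorted-class tie-break.
naive_classify <- function(query_vec, train_mat, labels) {
  classes <- sort(unique(labels))
  best_class <- NA_character_
  best_mean <- -Inf
  for (cl in classes) {
    sims <- c()
    for (i in which(labels == cl)) {
      sims <- c(sims, stats::cor(query_vec, train_mat[i, ]))
    }
    m <- mean(sims)
    if (m > best_mean) {
      best_mean <- m
      best_class <- cl
    }
  }
  best_class
}

# Directed half-Mahalanobis via base mahalanobis() (squared form).
naive_half_dist <- function(mu_from, mu_to, S_from) {
  0.5 * sqrt(stats::mahalanobis(mu_from, mu_to, S_from))
}

naive_combined <- function(a, b) {
  if (a + b == 0) 0 else a * b / (a + b)
}

# All five cluster metrics evaluated with explicit loops, no
# regularization.
naive_metrics <- function(points, motion, repetition) {
  classes <- sort(unique(motion))
  n <- length(classes)
  k <- ncol(points)
  mus <- list(); Ss <- list()
  for (cl in classes) {
    P <- points[motion == cl, , drop = FALSE]
    mus[[cl]] <- colMeans(P)
    Ss[[cl]] <- stats::cov(P)
  }
  WD <- IDNN <- IDAN <- MSD <- MSA <- stats::setNames(numeric(n), classes)
  for (cl in classes) {
    reps <- sort(unique(repetition[motion == cl]))
    tot <- 0
    for (r in reps) {
      for (kk in reps) {
        if (r == kk) next
        Pr <- points[motion == cl & repetition == r, , drop = FALSE]
        Pk <- points[motion == cl & repetition == kk, , drop = FALSE]
        d1 <- naive_half_dist(colMeans(Pr), colMeans(Pk), stats::cov(Pr))
        d2 <- naive_half_dist(colMeans(Pk), colMeans(Pr), stats::cov(Pk))
        tot <- tot + naive_combined(d1, d2)
      }
    }
    WD[cl] <- tot
  }
  for (j in classes) {
    dists <- c(); dmaxes <- c()
    for (i in classes) {
      if (i == j) next
      d_ji <- naive_half_dist(mus[[j]], mus[[i]], Ss[[j]])
      d_ij <- naive_half_dist(mus[[i]], mus[[j]], Ss[[i]])
      dists <- c(dists, naive_combined(d_ji, d_ij))
      per_dim <- c()
      for (d in seq_len(k)) {
        a <- 0.5 * abs(mus[[j]][d] - mus[[i]][d]) / sqrt(Ss[[j]][d, d])
        b <- 0.5 * abs(mus[[i]][d] - mus[[j]][d]) / sqrt(Ss[[i]][d, d])
        per_dim <- c(per_dim, naive_combined(a, b))
      }
      dmaxes <- c(dmaxes, max(per_dim))
    }
    IDNN[j] <- min(dists)
    IDAN[j] <- sum(dists)
    MSD[j] <- min(dmaxes)
    ax <- sqrt(eigen(Ss[[j]], symmetric = TRUE)$values)
    MSA[j] <- prod(ax)^(1 / k)
  }
  list(WD = WD, IDNN = IDNN, IDAN = IDAN, MSD = MSD, MSA = MSA,
       totals = c(WD = mean(WD), IDNN = mean(IDNN), IDAN = mean(IDAN),
                  MSD = mean(MSD), MSA = mean(MSA)))
}

# Random labeled cloud: k classes x n_rep repetitions x pts points, 5-D.
random_cloud <- function(n_classes = 3, n_rep = 2, pts = 8, dim = 5,
                         spread = 3) {
  points <- NULL; motion <- c(); repetition <- c()
  for (j in seq_len(n_classes)) {
    center_j <- stats::rnorm(dim, 0, spread)
    for (r in seq_len(n_rep)) {
      center_r <- center_j + stats::rnorm(dim, 0, 0.5)
      P <- matrix(stats::rnorm(pts * dim), pts, dim) +
        rep(center_r, each = pts)
      points <- rbind(points, P)
      motion <- c(motion, rep(sprintf("c%d", j), pts))
      repetition <- c(repetition, rep(r, pts))
    }
  }
  feature_cloud(points, motion, repetition)
}

# Points with exact sample mean `mu` and exact sample covariance `Sigma`.
exact_moment_points <- function(n, mu, Sigma) {
  k <- length(mu)
  Z <- matrix(stats::rnorm(n * k), n, k)
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  Z0 <- Zc %*% solve(chol(stats::cov(Zc)))
  Z0 %*% chol(Sigma) + rep(mu, each = n)
}

# Cloud of classes with prescribed exact means, identity covariances.
cloud_with_means <- function(means, pts = 12) {
  k <- ncol(means)
  points <- NULL; motion <- c(); repetition <- c()
  for (j in seq_len(nrow(means))) {
    points <- rbind(points, exact_moment_points(pts, means[j, ], diag(k)))
    motion <- c(motion, rep(sprintf("c%d", j), pts))
    repetition <- c(repetition, rep(1L, pts))
  }
  feature_cloud(points, motion, repetition)
}

# Small image-generator configuration used across tests (kept tiny so the
# suite stays fast).
tiny_image_config <- function(...) {
  defaults <- list(n_classes = 3L, n_repetitions = 3L, frame_height = 20L,
                   frame_width = 28L, frame_rate = 5L,
                   class_separation = 1.5, rep_jitter = 0.05,
                   frame_noise = 0.02, speckle_smoothness = 2, seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(image_gen_config, args)
}
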