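test_that("PCA projection preserves geometry of low-rank data", {
  set.seed(2)
  # frames lying exactly in a 5-D affine subspace of pixel space
  n <- 30; p <- 80
  basis <- qr.Q(qr(matrix(rnorm(p * 5), p, 5)))
  scores <- matrix(rnorm(n * 5, sd = rep(5:1, each = n)), n, 5)
  X <- scores %*% t(basis) + rep(rnorm(p), each = n)
  frames <- lapply(seq_len(n), function(i) matrix(X[i, ], 8, 10))
  d <- smg_dataset(frames,
                   data.frame(subject = "s", session = 1, phase = "none",
                              motion = rep(c("a", "b"), n / 2),
                              repetition = 1, role = "hold",
                              frame_index = seq_len(n)))
  cloud <- fit_project_pca(d, 5)
  expect_equal(dim(cloud$points), c(n, 5))
  expect_equal(as.vector(dist(cloud$points)), as.vector(dist(X)),
               tolerance = 1e-8)
  # explained variance non-increasing
  expect_true(all(diff(cloud$projection$sdev) <= 1e-12))
})

test_that("PCA scores match an eigendecomposition oracle up to sign", {
  set.seed(6)
  n <- 20
  frames <- replicate(n, matrix(rnorm(24), 4, 6), simplify = FALSE)
  d <- smg_dataset(frames,
                   data.frame(subject = "s", session = 1, phase = "none",
                              motion = "a", repetition = 1, role = "hold",
                              frame_index = 1:n))
  cloud <- fit_project_pca(d, 5)
  X <- frame_matrix(d)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eg <- eigen(crossprod(Xc) / (n - 1), symmetric = TRUE)
  oracle <- Xc %*% eg$vectors[, 1:5]
  for (k in 1:5) {
    expect_equal(abs(cloud$points[, k]), abs(oracle[, k]),
                 tolerance = 1e-6)
  }
  expect_error(fit_project_pca(subset_frames(d, 1:3), 5), "at least 5")
})

test_that("half-Mahalanobis and combined distance closed forms hold", {
  d1 <- c(2, 0, 0, 0, 0)
  expect_equal(half_mahalanobis(d1, rep(0, 5), diag(5),
                                regularize = FALSE), 1.0)
  expect_equal(half_mahalanobis(d1, rep(0, 5), diag(c(4, 1, 1, 1, 1)),
                                regularize = FALSE), 0.5)
  expect_equal(half_mahalanobis(rep(1, 5), rep(1, 5), diag(5)), 0)
  M <- diag(5); M[1, 2] <- 0.5 # asymmetric
  expect_error(half_mahalanobis(d1, rep(0, 5), M), "symmetric")

  expect_equal(combined_distance(1, 1), 0.5)
  expect_equal(combined_distance(0, 3), 0)
  expect_equal(combined_distance(0, 0), 0)
  expect_equal(combined_distance(2, 3), 1.2)
  expect_error(combined_distance(-1, 1), "non-negative")
})

test_that("within-class distance evaluates the repetition-pair sum", {
  set.seed(8)
  # two repetitions with exact means (0,...) and (1,0,...) and identity
  # covariances: each directed half distance 0.5, combined 0.25, two
  # ordered pairs -> 0.5
  P1 <- exact_moment_points(10, rep(0, 5), diag(5))
  P2 <- exact_moment_points(10, c(1, 0, 0, 0, 0), diag(5))
  cloud <- feature_cloud(rbind(P1, P2), rep("a", 20), rep(1:2, each = 10))
  expect_equal(within_class_distance(cloud, "a", regularize = FALSE), 0.5)

  # coincident repetition means: zero
  P3 <- exact_moment_points(10, rep(0, 5), diag(5))
  cloud0 <- feature_cloud(rbind(P1, P3), rep("a", 20), rep(1:2, each = 10))
  expect_equal(within_class_distance(cloud0, "a", regularize = FALSE), 0)

  expect_error(within_class_distance(cloud, "zz"), "zz")
  cloud1 <- feature_cloud(P1, rep("a", 10), rep(1, 10))
  expect_error(within_class_distance(cloud1, "a"), "repetitions")
})

test_that("inter-class distances reproduce the hand-computed example", {
  set.seed(10)
  means <- rbind(rep(0, 5),
                 c(2, 0, 0, 0, 0),
                 c(6, 0, 0, 0, 0))
  cloud <- cloud_with_means(means)
  idnn <- inter_class_nn(cloud, regularize = FALSE)
  idan <- inter_class_all(cloud, regularize = FALSE)
  expect_equal(unname(idnn$per_class), c(0.5, 0.5, 1.0))
  expect_equal(idnn$total, 2 / 3)
  expect_equal(unname(idan$per_class), c(2.0, 1.5, 2.5))
  expect_equal(idan$total, 2.0)
  # nearest-neighbor term never exceeds the all-neighbor sum
  expect_true(all(idnn$per_class <= idan$per_class + 1e-12))

  # coincident classes sit at distance zero
  cloud_co <- cloud_with_means(rbind(rep(0, 5), rep(0, 5)))
  expect_equal(unname(inter_class_nn(cloud_co,
                                     regularize = FALSE)$per_class),
               c(0, 0))
  one <- feature_cloud(cloud$points[1:12, ], rep("a", 12), rep(1, 12))
  expect_error(inter_class_nn(one), "2 classes")
})

test_that("most separable dimension reduces to IDNN for axis-aligned means", {
  set.seed(12)
  means <- rbind(rep(0, 5),
                 c(2, 0, 0, 0, 0),
                 c(6, 0, 0, 0, 0))
  cloud <- cloud_with_means(means)
  msd <- most_separable_dimension(cloud, regularize = FALSE)
  idnn <- inter_class_nn(cloud, regularize = FALSE)
  expect_equal(msd$total, idnn$total)

  # invariant under permutation of the feature axes
  perm <- c(3, 1, 5, 2, 4)
  cloud_p <- feature_cloud(cloud$points[, perm], cloud$motion,
                           cloud$repetition)
  msd_p <- most_separable_dimension(cloud_p, regularize = FALSE)
  expect_equal(msd_p$per_class, msd$per_class)

  cloud_co <- cloud_with_means(rbind(rep(0, 5), rep(0, 5)))
  expect_equal(unname(most_separable_dimension(
    cloud_co, regularize = FALSE)$per_class), c(0, 0))
})

test_that("mean semi-principal axis is the geometric mean of the axes", {
  set.seed(14)
  P <- exact_moment_points(30, rep(0, 5), 4 * diag(5))
  cloud <- feature_cloud(P, rep("a", 30), rep(1, 30))
  msa <- mean_semi_principal_axis(cloud, regularize = FALSE)
  expect_equal(unname(msa$per_class), 2.0)

  P2 <- exact_moment_points(30, rep(0, 5), diag(c(1, 4, 9, 16, 25)))
  cloud2 <- feature_cloud(P2, rep("a", 30), rep(1, 30))
  msa2 <- mean_semi_principal_axis(cloud2, regularize = FALSE)
  expect_equal(unname(msa2$per_class), 120^(1 / 5))

  # homogeneity: scaling all points by c scales MSA by |c|
  cloud3 <- feature_cloud(2.5 * P2, rep("a", 30), rep(1, 30))
  msa3 <- mean_semi_principal_axis(cloud3, regularize = FALSE)
  expect_equal(msa3$per_class, 2.5 * msa2$per_class)

  # rank-deficient cluster warns
  Pflat <- cbind(P2[, 1:4], 0)
  cloudf <- feature_cloud(Pflat, rep("a", 30), rep(1, 30))
  expect_warning(mean_semi_principal_axis(cloudf, regularize = FALSE),
                 "rank-deficient")
})

test_that("metric set aggregates per-class values into exact means", {
  set.seed(16)
  cloud <- random_cloud(n_classes = 3, n_rep = 2, pts = 10)
  met <- feature_metrics(cloud, regularize = FALSE)
  expect_equal(met$totals[["WD"]], mean(met$per_class$WD))
  expect_equal(met$totals[["IDNN"]], mean(met$per_class$IDNN))
  expect_equal(met$totals[["IDAN"]], mean(met$per_class$IDAN))
  expect_equal(met$totals[["MSD"]], mean(met$per_class$MSD))
  expect_equal(met$totals[["MSA"]], mean(met$per_class$MSA))
  expect_true(all(unlist(met$per_class[-1]) >= 0))
})

test_that("metrics match the brute-force oracle on random clouds", {
  set.seed(18)
  for (i in 1:20) {
    cloud <- random_cloud()
    met <- feature_metrics(cloud, regularize = FALSE)
    oracle <- naive_metrics(cloud$points, cloud$motion, cloud$repetition)
    expect_equal(met$per_class$WD, unname(oracle$WD), tolerance = 1e-10)
    expect_equal(met$per_class$IDNN, unname(oracle$IDNN), tolerance = 1e-10)
    expect_equal(met$per_class$IDAN, unname(oracle$IDAN), tolerance = 1e-10)
    expect_equal(met$per_class$MSD, unname(oracle$MSD), tolerance = 1e-10)
    expect_equal(met$per_class$MSA, unname(oracle$MSA), tolerance = 1e-10)
  }
})

test_that("WD, IDNN and IDAN are invariant under invertible affine maps", {
  set.seed(22)
  cloud <- random_cloud(pts = 12)
  met <- feature_metrics(cloud, regularize = FALSE)
  for (i in 1:5) {
    A <- matrix(rnorm(25), 5, 5)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(25), 5, 5)
    b <- rnorm(5)
    cloud_t <- feature_cloud(cloud$points %*% t(A) + rep(b, each = nrow(cloud$points)),
                             cloud$motion, cloud$repetition)
    met_t <- feature_metrics(cloud_t, regularize = FALSE)
    expect_equal(met_t$per_class$WD, met$per_class$WD, tolerance = 1e-6)
    expect_equal(met_t$per_class$IDNN, met$per_class$IDNN, tolerance = 1e-6)
    expect_equal(met_t$per_class$IDAN, met$per_class$IDAN, tolerance = 1e-6)
  }
})
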