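test_that("pearson similarity has the expected closed-form behavior", {
  set.seed(1)
  a <- matrix(runif(60), 6, 10)
  expect_equal(pearson_similarity(a, a), 1)
  expect_equal(pearson_similarity(a, 2 * a + 3), 1) # affine invariance
  expect_equal(pearson_similarity(a, -(a - mean(a))), -1)
  expect_warning(z <- pearson_similarity(a, matrix(0.5, 6, 10)),
                 "zero-variance")
  expect_equal(z, 0)
  expect_error(pearson_similarity(a, matrix(0, 3, 3)), "dimensions")
})

test_that("classify_frame matches the naive double-loop oracle", {
  set.seed(20)
  for (rep in 1:30) {
    k <- sample(2:4, 1)
    per <- sample(2:4, 1)
    p <- 30
    train <- matrix(rnorm(k * per * p), k * per, p)
    labels <- rep(sprintf("c%d", 1:k), each = per)
    query <- rnorm(p)
    got <- classify_frame(matrix(query, 5, 6), train, labels)
    expect_identical(got$class, naive_classify(query, train, labels))
  }
})

test_that("ties break to the lowest-sorted class", {
  p <- 24
  proto <- rnorm(p)
  train <- rbind(proto, proto, proto, proto) # two identical classes
  labels <- c("b", "b", "a", "a")
  got <- classify_frame(matrix(proto, 4, 6), train, labels)
  expect_identical(got$class, "a")
  expect_equal(unname(got$class_means["a"]), unname(got$class_means["b"]))
})

test_that("query matching one class's frame wins over noise classes", {
  set.seed(7)
  p <- 50
  target <- rnorm(p)
  train <- rbind(target, matrix(rnorm(4 * p), 4, p))
  labels <- c("hit", "n1", "n1", "n2", "n2")
  got <- classify_frame(matrix(target, 5, 10), train, labels)
  expect_identical(got$class, "hit")
})

test_that("leave-one-out cross-validation separates distinct classes", {
  # classes of identical copies, mutually distinct: every LOO fold keeps
  # perfect matches in the pool
  set.seed(3)
  h <- 6; w <- 8; per <- 4
  frames <- list(); motion <- c()
  for (j in 1:3) {
    proto <- matrix(rnorm(h * w), h, w)
    for (r in 1:per) {
      frames <- c(frames, list(proto))
      motion <- c(motion, sprintf("m%d", j))
    }
  }
  d <- smg_dataset(frames,
                   data.frame(subject = "s", session = 1, phase = "none",
                              motion = motion,
                              repetition = rep(1:per, 3), role = "hold",
                              frame_index = seq_along(motion)))
  cv <- loo_cross_validate(d)
  expect_equal(cv$CA, 100)
  expect_equal(cv$P_correct, cv$P_total)
  expect_equal(sum(cv$confusion), cv$P_total)
})

test_that("CA follows the accuracy formula on an imperfect run", {
  # 5 classes x 5 frames; one frame of class m1 is an exact copy of the
  # m2 prototype, so exactly that frame is misclassified: 24/25 -> 96.0
  set.seed(4)
  h <- 6; w <- 8
  protos <- lapply(1:5, function(j) matrix(rnorm(h * w), h, w))
  frames <- list(); motion <- c()
  for (j in 1:5) {
    for (r in 1:5) {
      f <- protos[[j]]
      if (j == 1 && r == 5) f <- protos[[2]]
      frames <- c(frames, list(f))
      motion <- c(motion, sprintf("m%d", j))
    }
  }
  d <- smg_dataset(frames,
                   data.frame(subject = "s", session = 1, phase = "none",
                              motion = motion, repetition = rep(1:5, 5),
                              role = "hold",
                              frame_index = seq_along(motion)))
  cv <- loo_cross_validate(d)
  expect_equal(cv$P_total, 25)
  expect_equal(cv$P_correct, 24)
  expect_equal(cv$CA, 96.0)
  expect_equal(cv$CA, 100 * cv$P_correct / cv$P_total)
  expect_equal(unname(cv$confusion["m1", "m2"]), 1)
})

test_that("predictions are invariant to positive affine intensity maps", {
  cfg <- tiny_image_config(seed = 13, frame_noise = 0.05,
                           class_separation = 0.8)
  d <- generate_dataset(cfg)
  cv1 <- loo_cross_validate(d)
  d_aff <- d
  # rescale a single frame and the whole stack
  d_aff$frames <- 0.3 * d_aff$frames + 0.2
  i <- 5L
  d_aff$frames[, , i] <- 2 * d_aff$frames[, , i] + 1
  cv2 <- loo_cross_validate(d_aff)
  expect_identical(cv1$predicted$predicted, cv2$predicted$predicted)
  expect_equal(cv1$CA, cv2$CA)
})

test_that("LOO hygiene: cross-class duplication can flip a prediction", {
  set.seed(9)
  p <- 40
  u <- rnorm(p); v <- rnorm(p)
  # held-out frame u sits alone-ish in class A; planting copies of u in
  # class B's pool pulls the prediction over
  make_ds <- function(extra_b) {
    frames <- c(list(matrix(u, 5, 8), matrix(u + rnorm(p, 0, 2), 5, 8)),
                replicate(2 + extra_b, matrix(v, 5, 8), simplify = FALSE))
    if (extra_b > 0) {
      for (i in seq_len(extra_b)) {
        frames[[2 + 2 + i]] <- matrix(u, 5, 8)
      }
    }
    motion <- c("A", "A", rep("B", 2 + extra_b))
    smg_dataset(frames,
                data.frame(subject = "s", session = 1, phase = "none",
                           motion = motion,
                           repetition = seq_along(motion), role = "hold",
                           frame_index = seq_along(motion)))
  }
  cv_clean <- loo_cross_validate(make_ds(0))
  cv_dup <- loo_cross_validate(make_ds(3))
  expect_identical(cv_clean$predicted$predicted[1], "A")
  expect_identical(cv_dup$predicted$predicted[1], "B")
})

test_that("repetition holdout is stricter than frame holdout", {
  cfg <- tiny_image_config(seed = 21, rep_jitter = 0.15,
                           frame_noise = 0.05, class_separation = 0.6)
  d <- generate_dataset(cfg)
  cv_f <- loo_cross_validate(d, holdout = "frame")
  cv_r <- loo_cross_validate(d, holdout = "repetition")
  expect_lte(cv_r$CA, cv_f$CA + 1e-9)
})

test_that("degenerate classes raise argument errors", {
  frames <- list(matrix(rnorm(12), 3, 4), matrix(rnorm(12), 3, 4),
                 matrix(rnorm(12), 3, 4))
  d <- smg_dataset(frames,
                   data.frame(subject = "s", session = 1, phase = "none",
                              motion = c("A", "A", "B"),
                              repetition = c(1, 2, 1), role = "hold",
                              frame_index = 1:3))
  expect_error(loo_cross_validate(d), "B")
  # one frame per class is fine for plain classification
  expect_no_error(classify_frame(matrix(rnorm(12), 3, 4), frames[1:2],
                                 c("A", "B")))
})
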