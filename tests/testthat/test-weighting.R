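test_that("two-cluster k-means recovers hand-checked optima", {
  r <- kmeans2(c(0, 10), seed = 1)
  expect_equal(sort(as.numeric(r$centers)), c(0, 10))
  expect_identical(sort(unique(r$assignments)), c(1L, 2L))

  r2 <- kmeans2(c(0, 1, 10, 11), seed = 1)
  expect_equal(sort(as.numeric(r2$centers)), c(0.5, 10.5))

  pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  r3 <- kmeans2(pts, seed = 1)
  want <- brute_kmeans_parts(pts)
  expect_equal(r3$tot_withinss, want$sse, tolerance = 1e-12)
  expect_equal(sort(r3$centers[, 1]), c(0, 10))
  expect_equal(unname(r3$centers[, 2]), c(0.5, 0.5))

  expect_error(kmeans2(rep(3, 5)), "degenerate")
  expect_error(kmeans2(matrix(1)), "at least 2")
})

test_that("k-means matches the exhaustive minimum-SSE bipartition on 1-D instances", {
  set.seed(123)
  for (trial in 1:10) {
    n <- sample(3:12, 1)
    x <- round(rnorm(n, sd = 5), 2)
    if (max(x) == min(x)) next
    want <- brute_kmeans_1d(x)
    got <- kmeans2(x, seed = trial, nstart = 10)
    expect_equal(got$tot_withinss, want$sse, tolerance = 1e-8)
    expect_equal(sort(as.numeric(got$centers)), want$centers, tolerance = 1e-8)
  }
})

test_that("per-class centers average the two within-class cluster centers", {
  expect_equal(unname(class_center(c(0, 1, 10, 11), seed = 1)), 5.5)
  expect_warning(z <- class_center(c(5, 5, 5, 5)), "degenerate")
  expect_equal(unname(z), 5)
  # symmetric data about m gives z = m
  expect_equal(unname(class_center(c(1, 2, 4, 5), seed = 1)), 3)
})

two_class_table <- function(x1, x2) {
  X <- matrix(c(x1, x2), ncol = 1, dimnames = list(NULL, "f1"))
  feature_table(X, rep(1:2, c(length(x1), length(x2))), set = "toy")
}

test_that("KMCC weights are mean-to-center ratios with identity on symmetric classes", {
  tab <- two_class_table(c(0, 1, 10, 11), c(20, 21, 30, 31))
  cw <- kmcc_weights(tab, seed = 1)
  # class symmetric -> z equals the class mean -> weight 1
  expect_equal(unname(cw$w[, 1]), c(1, 1), tolerance = 1e-10)
  expect_equal(unname(cw$z[, 1]), c(5.5, 25.5), tolerance = 1e-10)
  # identity weighting leaves the table unchanged
  expect_equal(apply_weights(tab, cw, "faithful")$X, tab$X, tolerance = 1e-10)
})

test_that("KMCCD weights are mean-distance-to-center ratios", {
  tab <- two_class_table(c(0, 1, 10, 11), c(0, 1, 10, 11) + 100)
  cw <- kmccd_weights(tab, seed = 1)
  # distances {5.5, 4.5, 4.5, 5.5}, mean 5, center 5.5
  expect_equal(unname(cw$w[1, 1]), 5 / 5.5, tolerance = 1e-10)
  expect_equal(unname(cw$mu[1, 1]), 5, tolerance = 1e-10)

  # not translation invariant: brute-force recomputation after a shift
  t_shift <- 100
  shifted <- two_class_table(c(0, 1, 10, 11) + t_shift,
                             c(0, 1, 10, 11) + 200)
  cw2 <- kmccd_weights(shifted, seed = 1)
  expect_equal(unname(cw2$w[1, 1]), 5 / 105.5, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(cw$w[1, 1], cw2$w[1, 1])))
})

test_that("all-constant class features get the method's null weight", {
  tab <- two_class_table(rep(4, 4), rep(8, 4))
  suppressWarnings({
    cwc <- kmccd_weights(tab, seed = 1)
  })
  expect_equal(unname(cwc$w), matrix(0, 2, 1), tolerance = 1e-12)
  wtd <- apply_weights(tab, cwc, "faithful")
  expect_true(all(wtd$X == 0))
})

test_that("weights are scale-equivariant", {
  set.seed(5)
  # each class holds two well-separated subclusters along f2, so the
  # within-class partition is stable when f1 alone is rescaled
  X <- cbind(f1 = rnorm(20, 10, 1),
             f2 = c(rep(c(0, 50), each = 5), rep(c(100, 150), each = 5)) +
               rnorm(20, 0, 0.5))
  tab <- feature_table(X, rep(1:2, each = 10), set = "toy")
  for (fn in list(kmcc_weights, kmccd_weights)) {
    cw <- fn(tab, seed = 3)
    # whole-table scaling
    tab_a <- feature_table(3.7 * X, tab$y, set = "toy")
    expect_equal(fn(tab_a, seed = 3)$w, cw$w, tolerance = 1e-8)
    # single well-separated feature scaled
    Xb <- X; Xb[, 1] <- 2 * Xb[, 1]
    cwb <- fn(feature_table(Xb, tab$y, set = "toy"), seed = 3)
    expect_equal(cwb$w[, 1], cw$w[, 1], tolerance = 1e-6)
  }
})

test_that("per-feature clustering matches full-matrix clustering in one dimension", {
  tab <- two_class_table(c(0, 1, 10, 11), c(20, 21, 30, 31))
  for (fn in list(kmcc_weights, kmccd_weights)) {
    full <- fn(tab, seed = 2)
    per <- fn(tab, seed = 2, per_feature = TRUE)
    expect_equal(per$z, full$z, tolerance = 1e-10)
    expect_equal(per$w, full$w, tolerance = 1e-10)
  }
  # in 2-D the per-feature centers are the columnwise 1-D centers
  X <- cbind(f1 = c(0, 1, 10, 11, 0, 1, 10, 11),
             f2 = c(2, 3, 2, 3, 40, 41, 40, 41))
  tab2 <- feature_table(X, rep(1:2, each = 4), set = "toy")
  per2 <- kmcc_weights(tab2, seed = 2, per_feature = TRUE)
  expect_equal(unname(per2$z[1, 1]),
               unname(class_center(X[1:4, 1], seed = 3)), tolerance = 1e-10)
  expect_equal(unname(per2$z[1, 2]),
               unname(class_center(X[1:4, 2], seed = 3)), tolerance = 1e-10)
})

test_that("weight application follows the faithful and global semantics", {
  tab <- feature_table(matrix(c(5, 5), ncol = 1,
                              dimnames = list(NULL, "f1")),
                       c(1L, 2L), set = "toy")
  cw <- structure(list(w = matrix(c(2, 3), 2, 1), z = matrix(1, 2, 1),
                       mu = matrix(1, 2, 1), method = "kmcc"),
                  class = "class_weights")
  expect_equal(as.numeric(apply_weights(tab, cw, "faithful")$X), c(10, 15))
  expect_equal(as.numeric(apply_weights(tab, cw, "global")$X), c(12.5, 12.5))

  tab_na <- tab; tab_na$y <- c(1L, NA)
  expect_error(apply_weights(tab_na, cw, "faithful"), "label")
  expect_error(kmcc_weights(subset_table(tab, 1)), "class")
})
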