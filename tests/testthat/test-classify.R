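test_that("stratified folds preserve sizes, class balance and determinism", {
  y <- rep(c(1L, 2L), each = 870)
  f <- stratified_kfold(y, k = 10, seed = 4)
  expect_true(all(table(f) == 174))
  expect_true(all(table(f[y == 1L]) == 87))
  expect_identical(f, stratified_kfold(y, k = 10, seed = 4))
  expect_false(identical(f, stratified_kfold(y, k = 10, seed = 5)))

  # uneven classes: global fold sizes still within floor/ceiling of n/k
  y2 <- rep(c(1L, 2L), c(11, 12))
  f2 <- stratified_kfold(y2, k = 10, seed = 1)
  expect_true(all(table(factor(f2, levels = 1:10)) %in% c(2, 3)))

  expect_error(stratified_kfold(rep(1:2, c(5, 50)), k = 10), "fewer than")
})

test_that("1-NN returns exact-match labels and breaks ties by row order", {
  train <- feature_table(matrix(c(0, 2, 5), ncol = 1), c(1L, 2L, 1L), "toy")
  # identical point
  expect_identical(fit_predict("knn1", train,
                               feature_table(matrix(5), 1L, "toy")), 1L)
  # equidistant between rows 1 and 2: lower index wins
  expect_identical(fit_predict("knn1", train,
                               feature_table(matrix(1), 2L, "toy")), 1L)
})

test_that("LDA separates well-spaced 1-D Gaussians at the Bayes level", {
  set.seed(10)
  x <- c(rnorm(100, -5), rnorm(100, 5))
  tab <- feature_table(matrix(x, ncol = 1), rep(1:2, each = 100), "toy")
  pred <- fit_predict("lda", tab, tab)
  expect_gte(mean(pred == tab$y), 0.99)
})

test_that("pooled-covariance LDA agrees with the reference implementation", {
  set.seed(11)
  X <- rbind(MASS::mvrnorm(80, c(0, 0), diag(2)),
             MASS::mvrnorm(80, c(3, 1), diag(2)))
  y <- rep(1:2, each = 80)
  tab <- feature_table(X, y, "toy")
  Xt <- rbind(MASS::mvrnorm(50, c(0, 0), diag(2)),
              MASS::mvrnorm(50, c(3, 1), diag(2)))
  tt <- feature_table(Xt, rep(1:2, each = 50), "toy")
  ours <- fit_predict("lda", tab, tt)
  ref <- as.integer(predict(MASS::lda(X, grouping = y), Xt)$class)
  expect_gte(mean(ours == ref), 0.98)
})

test_that("linear SVM is perfect on a separable toy problem", {
  X <- rbind(c(-2, 1), c(-2, -1), c(-3, 1), c(-3, -1),
             c(2, 1), c(2, -1), c(3, 1), c(3, -1))
  tab <- feature_table(X, rep(1:2, each = 4), "toy")
  expect_identical(fit_predict("svm_linear", tab, tab), tab$y)
})

test_that("single-class training folds are rejected", {
  tab <- feature_table(matrix(1:4, ncol = 1), rep(1L, 4), "toy")
  expect_error(fit_predict("knn1", tab, tab), "both classes")
})

test_that("confusion counts match hand counts with class 1 positive", {
  cc <- confusion(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_identical(unclass(cc)[c("TP", "TN", "FP", "FN")],
                   list(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  cc2 <- confusion(c(1, 2), c(2, 1))
  expect_identical(c(cc2$TP, cc2$TN, cc2$FP, cc2$FN), c(0L, 0L, 1L, 1L))
  cc3 <- confusion(c(1, 1, 1, 2), c(1, 2, 1, 1))
  expect_identical(c(cc3$TP, cc3$FN, cc3$FP, cc3$TN), c(2L, 1L, 1L, 0L))
  expect_error(confusion(c(1, 2), c(1)), "length")
})

counts <- function(TP, TN, FP, FN)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN),
            class = "confusion_counts")

test_that("metric formulas reproduce hand-worked cells", {
  perfect <- confusion_metrics(counts(5, 5, 0, 0))
  expect_equal(perfect$acc, 100)
  expect_equal(perfect$sens, 1)
  expect_equal(perfect$fpr, 0)
  expect_equal(perfect$prc, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$error, 0)
  expect_equal(perfect$ci, 0)

  chance <- confusion_metrics(counts(25, 25, 25, 25))
  expect_equal(chance$acc, 50)
  expect_equal(chance$kappa, 0)

  m <- confusion_metrics(counts(870 - 87, 870 - 87, 87, 87), n = 1740)
  expect_equal(m$error, 0.1)
  expect_equal(m$ci, 1.96 * sqrt(0.1 * 0.9 / 1740), tolerance = 1e-4)
  expect_equal(m$ci, 0.0141, tolerance = 5e-4)
})

test_that("metric identities hold", {
  set.seed(12)
  for (i in 1:20) {
    v <- sample(0:50, 4, replace = TRUE)
    if (sum(v) == 0) next
    m <- confusion_metrics(counts(v[1], v[2], v[3], v[4]))
    expect_equal(m$acc / 100 + m$error, 1, tolerance = 1e-12)
    if (!is.na(m$sens))
      expect_equal(m$sens * (v[1] + v[4]), v[1], tolerance = 1e-9)
    if (!is.na(m$kappa)) {
      if (v[3] == 0 && v[4] == 0 && v[1] > 0 && v[2] > 0)
        expect_equal(m$kappa, 1)
      if (identical(m$kappa, 1)) expect_true(v[3] == 0 && v[4] == 0)
    }
  }
})

test_that("kappa is near zero for label-permuted predictions", {
  set.seed(13)
  truth <- rep(c(1L, 2L), each = 500)
  kap <- replicate(20, {
    confusion_metrics(confusion(truth, sample(truth)))$kappa
  })
  expect_lt(abs(mean(kap)), 0.05)
})

test_that("undefined metric denominators yield NA markers, not zeros", {
  m <- confusion_metrics(counts(0, 5, 0, 5))   # nothing predicted positive
  expect_true(is.na(m$prc))
  expect_equal(m$sens, 0)
  m2 <- confusion_metrics(counts(0, 0, 3, 3))  # every prediction wrong
  expect_equal(m2$fpr, 1)
  expect_true(is.na(confusion_metrics(counts(0, 3, 0, 0))$sens))
})

test_that("printed-formula compatibility variants are available behind the flag", {
  cc <- counts(40, 30, 20, 10)
  std <- confusion_metrics(cc)
  lit <- confusion_metrics(cc, printed_formulas = TRUE)
  expect_equal(std$acc, 100 * 70 / 100)
  expect_equal(lit$acc, 100 * 60 / 100)    # (TP+FP)/total variant
  expect_equal(std$fpr, 20 / 50)           # FP/(FP+TN)
  expect_equal(lit$fpr, 20 / 70)           # FP/(TP+TN) variant
})
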