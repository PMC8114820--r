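test_that("hand-checked feature values are reproduced", {
  f <- channel_features(c(1, 2, 3), fs = 1)
  expect_equal(unname(f[c("mean", "max", "var", "median", "skew")]),
               c(2, 3, 1, 2, 0))

  # exact ramp: slope 1 amplitude/s at 1 Hz
  expect_equal(unname(channel_features(c(1, 2, 3, 4), fs = 1)["slope"]), 1)
  # same samples at 10 Hz: ten times steeper per second
  expect_equal(unname(channel_features(c(1, 2, 3, 4), fs = 10)["slope"]), 10)

  # fourth standardized moment of [0,0,0,12] under population sigma,
  # against direct evaluation: m4/m2^2 = 1701/729 = 7/3
  x <- c(0, 0, 0, 12)
  expect_equal(unname(channel_features(x)["kurt"]),
               unname(brute_features(x)["kurt"]))
  expect_equal(unname(channel_features(x)["kurt"]), 7 / 3)
})

test_that("all seven features agree with the brute-force oracle", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(3:200, 1)
    fs <- sample(c(1, 10, 200), 1)
    x <- rnorm(n) * 10^runif(1, -3, 3)
    got <- channel_features(x, fs)
    want <- brute_features(x, fs)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("features transform predictably under affine maps", {
  set.seed(7)
  x <- rnorm(100)
  a <- 3.7; b <- 2.1
  f0 <- channel_features(x, 10)
  f1 <- channel_features(a * x, 10)
  f2 <- channel_features(a * x + b, 10)
  expect_equal(f1[c("mean", "max", "slope", "median")],
               a * f0[c("mean", "max", "slope", "median")], tolerance = 1e-10)
  expect_equal(unname(f1["var"]), a^2 * unname(f0["var"]), tolerance = 1e-10)
  expect_equal(f2[c("skew", "kurt")], f0[c("skew", "kurt")], tolerance = 1e-10)
})

test_that("the windowed slope variant averages per-window regression slopes", {
  # a pure ramp has the same slope under both definitions
  x <- 0.5 * (0:99) / 10
  expect_equal(unname(channel_features(x, 10)["slope"]), 0.5)
  expect_equal(unname(channel_features(x, 10, slope_window = 2)["slope"]), 0.5)

  # piecewise signal: windowed slope is the mean of the per-window fits
  set.seed(9)
  y <- rnorm(100)
  nw <- 20  # 2 s at 10 Hz
  manual <- mean(vapply(seq(1, 81, by = nw), function(s) {
    xs <- y[s:(s + nw - 1)]
    t <- (seq_len(nw) - 1) / 10
    unname(stats::coef(stats::lm(xs ~ t))[2])
  }, numeric(1)))
  expect_equal(unname(channel_features(y, 10, slope_window = 2)["slope"]),
               manual, tolerance = 1e-10)

  expect_error(channel_features(y, 10, slope_window = 0.05), "at least 2")
})

test_that("degenerate epochs follow the documented conventions", {
  expect_warning(f <- channel_features(rep(5, 10)), "constant")
  expect_equal(unname(f[c("skew", "kurt")]), c(0, 0))
  expect_error(channel_features(c(1, 2)), "at least 3")
})

random_epochs <- function(n_tr, n_ch, n_samp = 20, fs = 10, seed = 1) {
  set.seed(seed)
  bci_epochs(array(rnorm(n_tr * n_ch * n_samp), c(n_tr, n_ch, n_samp)),
             fs, 0, rep(c(1L, 2L), length.out = n_tr),
             paste0("ch", seq_len(n_ch)), "test")
}

test_that("feature tables have the protocol column counts", {
  t36 <- build_table(random_epochs(4, 36))
  expect_identical(ncol(t36$X), 252L)   # 36 channels x 7 features
  t32 <- build_table(random_epochs(4, 32))
  expect_identical(ncol(t32$X), 224L)   # 32 channels x 7

  expect_identical(ncol(combine_tables(t32, t36)$X), 476L)
  expect_identical(ncol(combine_tables(t36, t36)$X), 504L)

  t1 <- build_table(random_epochs(1, 1))
  expect_identical(dim(t1$X), c(1L, 7L))  # + label vector = 8 values per trial

  # serialized with the label column appended last
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(t36, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_length(header, 253)
  expect_identical(gsub('"', "", header[253]), "label")
})

test_that("table columns are channel-major with all 7 features per channel", {
  ep <- random_epochs(3, 2)
  tab <- build_table(ep)
  expect_identical(colnames(tab$X)[1:7],
                   paste0("ch1_", c("mean", "max", "slope", "var", "skew",
                                    "kurt", "median")))
  expect_identical(colnames(tab$X)[8:14],
                   paste0("ch2_", c("mean", "max", "slope", "var", "skew",
                                    "kurt", "median")))
  # row k holds channel c's features of trial k
  expect_equal(unname(tab$X[2, 1:7]),
               unname(channel_features(ep$data[2, 1, ], ep$fs)))
})

test_that("combining with an empty table is the identity on features", {
  a <- build_table(random_epochs(5, 3))
  empty <- feature_table(matrix(numeric(0), 5, 0), a$y, set = "empty")
  expect_identical(combine_tables(a, empty)$X, a$X)
})

test_that("label mismatches are detected as trial-ordering bugs", {
  a <- build_table(random_epochs(6, 2, seed = 1))
  b <- build_table(random_epochs(6, 2, seed = 2))
  b$y <- rev(b$y)
  expect_error(combine_tables(a, b), "ordering")
})
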