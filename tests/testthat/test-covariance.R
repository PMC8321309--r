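test_that("class clips column-stack in column-major order", {
  sc <- multiband_scene(list(matrix(c(1, 3, 2, 4), 2, 2)), band_ids = "B3")
  m <- class_map(matrix(1L, 2, 2), "a")
  v <- extract_class_vector(sc, m, "a", "B3")
  expect_equal(v$values, c(1, 3, 2, 4))
  expect_length(v, 4)

  row_sc <- multiband_scene(list(matrix(5:9, 1, 5)), band_ids = "B3")
  row_m <- class_map(matrix(1L, 1, 5), "a")
  expect_equal(extract_class_vector(row_sc, row_m, "a", "B3")$values, 5:9)

  expect_error(extract_class_vector(sc, m, "missing", "B3"), "missing")
})

test_that("non-class pixels inside the clip are filled with the class mean", {
  z <- matrix(c(10, 10, 10, 99), 2, 2)
  sc <- multiband_scene(list(z), band_ids = "B3")
  lab <- matrix(c(1L, 1L, 1L, 2L), 2, 2)
  v <- extract_class_vector(sc, class_map(lab, c("a", "b")), "a", "B3")
  expect_equal(v$values, c(10, 10, 10, 10))   # the 99 is masked to the mean
  d <- detrend(v)
  expect_equal(d$values[4], 0)
})

test_that("detrending removes the arithmetic mean and stores it", {
  d <- detrend(pixel_vector(c(1, 2, 3)))
  expect_equal(d$values, c(-1, 0, 1))
  expect_equal(d$mean, 2)
  expect_true(d$detrended)
  expect_equal(detrend(pixel_vector(rep(7, 5)))$values, rep(0, 5))
  dd <- detrend(d)
  expect_equal(dd$values, d$values)  # idempotent on a centred vector
})

test_that("the covariance estimator matches the direct summation", {
  v <- detrend(pixel_vector(c(1, 2, 3, 4)))
  s <- covariance_series(v, kmax = 2)
  expect_equal(s$K[1], 1.25)            # population variance at lag 0
  expect_equal(s$K[2], 1.25 / 3)
  expect_equal(s$counts, c(4L, 3L, 2L))
  set.seed(5)
  x <- detrend(pixel_vector(rnorm(40)))
  expect_equal(covariance_series(x)$K[1], mean(x$values^2))
})

test_that("covariance estimation enforces its preconditions", {
  raw <- pixel_vector(c(1, 2, 3, 4))
  expect_error(covariance_series(raw), "detrend")
  v <- detrend(raw)
  expect_error(covariance_series(v, kmax = 3), "n/2")
  expect_error(normalize_series(covariance_series(detrend(pixel_vector(rep(1, 10)))),
                                detrend(pixel_vector(rep(1, 10)))),
               "zero-variance")
})

test_that("vectorized estimator equals the brute-force double-loop oracle", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    x <- rnorm(n); x <- x - mean(x)
    y <- rnorm(n); y <- y - mean(y)
    kmax <- n %/% 2L
    sa <- covariance_series(pixel_vector(x, detrended = TRUE), kmax = kmax)
    expect_equal(sa$K, brute_force_cov(x, x, kmax), tolerance = 1e-12)
    sc <- covariance_series(pixel_vector(x, detrended = TRUE),
                            pixel_vector(y, detrended = TRUE), kmax = kmax)
    expect_equal(sc$K, brute_force_cov(x, y, kmax), tolerance = 1e-12)
    # cross-covariance symmetry: swapping the vectors swaps the lead role
    scs <- covariance_series(pixel_vector(y, detrended = TRUE),
                             pixel_vector(x, detrended = TRUE), kmax = kmax)
    expect_equal(scs$K, brute_force_cov(y, x, kmax), tolerance = 1e-12)
  }
})

test_that("a shifted copy produces a cross-covariance peak at the shift lag", {
  set.seed(8)
  base <- rnorm(400)
  shift <- 7L
  x <- detrend(pixel_vector(base[1:350]))
  y <- detrend(pixel_vector(base[(1 + shift):(350 + shift)]))
  s <- normalize_series(covariance_series(y, x, kmax = 30), y, x)
  expect_equal(which.max(s$r) - 1L, shift)
  expect_gt(max(s$r), 0.9)
})

test_that("normalization yields r(0) = 1 for auto-series and -1 for a sign flip", {
  set.seed(2)
  for (i in 1:5) {
    v <- detrend(pixel_vector(rnorm(100)))
    s <- normalize_series(covariance_series(v, kmax = 20), v)
    expect_identical(s$r[1], 1)
    neg <- pixel_vector(-v$values, detrended = TRUE)
    sx <- normalize_series(covariance_series(v, neg, kmax = 20), v, neg)
    expect_equal(sx$r[1], -1)
    # explicit v2 = v1 reduces to the auto normalization
    s2 <- normalize_series(covariance_series(v, v, kmax = 20), v, v)
    expect_equal(s2$r, s$r)
  }
})

test_that("correlation standard error follows (1 - r^2)/sqrt(m)", {
  expect_equal(stderr_r(1, 50), 0)
  expect_equal(stderr_r(0, 100), 0.1)
  expect_equal(stderr_r(0.5, 25), 0.75 / 5)
  expect_error(stderr_r(0, 1), "m >= 2")
  expect_error(stderr_r(1.5, 100), "exceed")
  v <- detrend(pixel_vector(rnorm(50)))
  s <- normalize_series(covariance_series(v, kmax = 10), v)
  expect_equal(s$sigma_r[1], 0)                      # r = 1 at lag 0
  expect_equal(s$sigma_r[3],
               (1 - min(1, abs(s$r[3]))^2) / sqrt(48))
  slag <- normalize_series(covariance_series(v, kmax = 10), v,
                           se_denom = "lag")
  expect_true(is.na(slag$sigma_r[1]))
  expect_equal(slag$sigma_r[6], (1 - min(1, abs(slag$r[6]))^2) / sqrt(5))
})

test_that("the segment correlation grid is symmetric with a unit diagonal", {
  set.seed(13)
  v <- rnorm(120)
  g <- correlation_matrix(list(a = v, b = v), segment_count = 3)
  expect_equal(dim(g$values), c(6L, 6L))
  expect_true(all(abs(diag(g$values) - 1) < 1e-12))
  # identical vectors: the cross-class block diagonal is also exactly 1
  expect_equal(diag(g$values[1:3, 4:6]), rep(1, 3), tolerance = 1e-12)
  expect_equal(g$values, t(g$values))
})

test_that("independent vectors give near-zero off-diagonal correlations", {
  set.seed(19)
  n <- 4000; segs <- 4
  g <- correlation_matrix(list(a = rnorm(n), b = rnorm(n), c = rnorm(n)), segs)
  off <- g$values[row(g$values) != col(g$values)]
  expect_lt(abs(mean(off)), 3 / sqrt(n / segs))
  # three classes: three unit ridges on the main diagonal
  expect_equal(unname(diag(g$values)), rep(1, 3 * segs))
  expect_error(correlation_matrix(list(a = 1:3, b = 1:3), segment_count = 2),
               "shorter than 2")
})

test_that("cov_series methods expose the series as a data frame and summary", {
  v <- detrend(pixel_vector(rnorm(200)))
  s <- normalize_series(covariance_series(v, kmax = 40), v)
  df <- as.data.frame(s)
  expect_named(df, c("k", "K", "r", "count", "sigma_r"))
  expect_equal(nrow(df), 41)
  expect_equal(df$count, 200 - df$k)
  sm <- summary(s)
  expect_equal(sm$kind, "auto")
  expect_output(print(s), "auto-covariance")
})
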