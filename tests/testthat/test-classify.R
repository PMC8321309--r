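sig2 <- function() list(
  spectral_signature("a", c("B2", "B3", "B4"), c(100, 100, 100)),
  spectral_signature("b", c("B2", "B3", "B4"), c(200, 200, 200)))

test_that("minimum-distance classification assigns the nearest signature", {
  sigs <- table1_signatures()
  px <- multiband_scene(list(matrix(473, 1, 1), matrix(1090, 1, 1),
                             matrix(822, 1, 1)),
                        band_ids = c("B2", "B3", "B4"))
  m <- min_distance_classify(px, sigs)
  expect_equal(m$legend[m$labels[1, 1]], "H. sosnowskyi")

  # a pixel equidistant from two signatures goes to the first-listed class
  mid <- multiband_scene(list(matrix(150, 1, 1), matrix(150, 1, 1),
                              matrix(150, 1, 1)),
                         band_ids = c("B2", "B3", "B4"))
  expect_equal(min_distance_classify(mid, sig2())$labels[1, 1], 1L)

  # rejection threshold leaves far pixels unclassified
  far <- multiband_scene(list(matrix(100, 1, 1), matrix(100, 1, 1),
                              matrix(110, 1, 1)),
                         band_ids = c("B2", "B3", "B4"))
  expect_equal(min_distance_classify(far, sig2(), max_distance = 5)$labels[1, 1], 0L)
  expect_equal(min_distance_classify(far, sig2(), max_distance = 15)$labels[1, 1], 1L)

  expect_error(min_distance_classify(px, list()), "signature")
})

test_that("one signature and no threshold classifies every valid pixel", {
  sc <- make_test_scene(15, 15, 3, nodata = 6)
  one <- list(spectral_signature("only", c("B2", "B3", "B4"), c(0, 0, 0)))
  m <- min_distance_classify(sc, one)
  nod <- Reduce(`|`, lapply(sc$bands, function(b) b == 6))
  expect_true(all(m$labels[!nod] == 1L))
  expect_true(all(m$labels[nod] == 0L))
})

test_that("confusion matrices count (reference, prediction) pairs", {
  leg <- c("a", "b")
  ref <- class_map(matrix(c(1L, 1L, 2L, 2L), 2, 2), leg)
  pred_same <- ref
  cm <- confusion(pred_same, ref)
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  pred_a <- class_map(matrix(1L, 2, 2), leg)
  cm2 <- confusion(pred_a, ref)
  expect_equal(cm2["b", "a"], 2L)
  expect_equal(cm2["a", "a"], 2L)

  empty_ref <- class_map(matrix(0L, 2, 2), leg)
  expect_error(confusion(pred_a, empty_ref), "no classified")
  small <- class_map(matrix(1L, 1, 1), leg)
  expect_error(confusion(small, ref), "dimensions")
})

test_that("overall accuracy is the diagonal fraction", {
  d <- matrix(c(10L, 0L, 0L, 10L), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(overall_accuracy(d), 1.0)
  m <- matrix(c(45L, 5L, 5L, 45L), 2, byrow = TRUE)
  expect_equal(overall_accuracy(m), 0.90)
  expect_equal(overall_accuracy(matrix(c(0L, 10L, 10L, 0L), 2)), 0)
})

test_that("kappa corrects agreement for chance", {
  m <- matrix(c(45L, 5L, 5L, 45L), 2, byrow = TRUE)
  expect_equal(kappa_coefficient(m), (0.90 - 0.50) / (1 - 0.50))
  perfect <- matrix(c(30L, 0L, 0L, 30L), 2)
  expect_equal(kappa_coefficient(perfect), 1.0)
  # independent labels give kappa near zero
  set.seed(3)
  leg <- c("a", "b", "c")
  ref <- class_map(matrix(sample(1:3, 10000, TRUE), 100, 100), leg)
  prd <- class_map(matrix(sample(1:3, 10000, TRUE), 100, 100), leg)
  expect_lt(abs(kappa_coefficient(confusion(prd, ref))), 0.05)
  degen <- matrix(c(7L, 0L, 0L, 0L), 2)
  expect_error(kappa_coefficient(degen), "degenerate")
})

test_that("kappa agrees with the e1071 implementation and is bounded by
           overall accuracy above chance", {
  skip_if_not_installed("e1071")
  set.seed(9)
  for (i in 1:10) {
    cm <- matrix(rpois(9, 30) + diag(3) * rpois(3, 60), 3)
    expect_equal(kappa_coefficient(cm),
                 e1071::classAgreement(cm)$kappa, tolerance = 1e-12)
    expect_lte(kappa_coefficient(cm), overall_accuracy(cm) + 1e-12)
  }
})

test_that("threshold segmentation windows the mean band score", {
  flat <- multiband_scene(list(matrix(1090, 8, 8), matrix(822, 8, 8)),
                          band_ids = c("B3", "B4"))  # score 956 everywhere
  m <- threshold_segment(flat, low = 800, high = 1000, min_area = 5)
  expect_true(all(m$labels == 1L))
  expect_equal(m$legend, c("target", "other"))
  out <- threshold_segment(flat, low = 1000, high = 1200, min_area = 5)
  expect_true(all(out$labels == 2L))
  expect_error(threshold_segment(flat, low = 10, high = 5, min_area = 1), "low")
  expect_error(threshold_segment(flat, bands = character(0), low = 1, high = 2),
               "band")
})

test_that("components below the minimum mapping unit are removed", {
  z <- matrix(0, 20, 20)
  z[2:3, 2:3] <- 950          # 4-pixel blob: below the 5-pixel unit
  z[10:14, 10] <- 950         # 5-pixel line: retained
  sc <- multiband_scene(list(z, z), band_ids = c("B3", "B4"))
  m <- threshold_segment(sc, low = 900, high = 1000, min_area = 5)
  expect_true(all(m$labels[2:3, 2:3] == 2L))
  expect_true(all(m$labels[10:14, 10] == 1L))
})

test_that("segmentation components are 8-connected", {
  z <- matrix(0, 12, 12)
  for (i in 1:5) z[i + 1, i + 1] <- 950   # diagonal chain of 5 pixels
  sc <- multiband_scene(list(z, z), band_ids = c("B3", "B4"))
  m <- threshold_segment(sc, low = 900, high = 1000, min_area = 5)
  expect_equal(sum(m$labels == 1L), 5)    # kept as one component
  m4 <- threshold_segment(sc, low = 900, high = 1000, min_area = 6)
  expect_equal(sum(m4$labels == 1L), 0)
})

test_that("no retained target component is ever smaller than min_area", {
  set.seed(21)
  for (i in 1:5) {
    z <- matrix(sample(c(0, 950), 900, TRUE, prob = c(0.7, 0.3)), 30, 30)
    sc <- multiband_scene(list(z, z), band_ids = c("B3", "B4"))
    m <- threshold_segment(sc, low = 900, high = 1000, min_area = 5)
    if (any(m$labels == 1L)) {
      lb <- pixelcov:::.label_components8(m$labels == 1L)
      expect_gte(min(tabulate(lb[lb > 0])), 5)
    }
  }
})

test_that("majority smoothing absorbs speckle and keeps ties at the centre", {
  leg <- c("a", "b")
  const <- class_map(matrix(1L, 9, 9), leg)
  expect_identical(smooth_map(const)$labels, const$labels)

  spk <- matrix(1L, 9, 9); spk[5, 5] <- 2L
  expect_true(all(smooth_map(class_map(spk, leg))$labels == 1L))

  chk <- matrix(rep_len(c(1L, 2L), 9), 3, 3)  # checkerboard centre: 5 vs 4
  sm <- smooth_map(class_map(chk, leg))
  expect_equal(sm$labels[2, 2], chk[2, 2])

  # genuine tie (4 a, 4 b around a single c): the centre label survives
  tie <- matrix(c(1L, 2L, 2L, 1L, 3L, 1L, 1L, 2L, 2L), 3, 3)
  expect_equal(smooth_map(class_map(tie, c("a", "b", "c")))$labels[2, 2], 3L)

  expect_error(smooth_map(const, window = 4), "odd")
})

test_that("class maps round-trip through TIFF + legend sidecar", {
  m <- class_map(matrix(sample(0:2, 30, TRUE), 5, 6), c("x", "y"))
  p <- file.path(tempdir(), "cm.tif")
  write_class_map(m, p)
  back <- read_class_map(p)
  expect_identical(back$labels, m$labels)
  expect_identical(back$legend, m$legend)
})
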