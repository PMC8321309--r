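# Shared fixtures: all built in code, nothing on disk.

# Spring-scene visible-band class signatures (blue, green, red DN means)
# used across classification and signature tests.
table1_signatures <- function() {
  list(
    spectral_signature("H. sosnowskyi", c("B2", "B3", "B4"), c(473, 1090, 822)),
    spectral_signature("forest", c("B2", "B3", "B4"), c(356, 870, 816)),
    spectral_signature("pathway", c("B2", "B3", "B4"), c(694, 1130, 1264)))
}

table1_scene_spec <- function(rows = 200, cols = 200, noise_std = 30,
                              seed = 42L, corr_length = 0) {
  scene_spec(rows, cols, classes = list(
    list(class_label = "H. sosnowskyi", mean = c(B2 = 473, B3 = 1090, B4 = 822),
         noise_std = noise_std, corr_length = corr_length),
    list(class_label = "other plants", mean = c(B2 = 356, B3 = 870, B4 = 816),
         noise_std = noise_std, corr_length = corr_length),
    list(class_label = "agricultural land",
         mean = c(B2 = 694, B3 = 1130, B4 = 1264),
         noise_std = noise_std, corr_length = corr_length)),
    layout = "stripes", seed = seed)
}

# small integer scene with deterministic values
make_test_scene <- function(rows = 10, cols = 10, nbands = 3, nodata = NULL) {
  bands <- lapply(seq_len(nbands), function(b)
    matrix(((seq_len(rows * cols) * 7 + b * 13) %% 1000), rows, cols))
  multiband_scene(bands, band_ids = paste0("B", 1 + seq_len(nbands)),
                  nodata = nodata)
}

# independent double-loop estimator of the lagged covariance (the oracle
# the vectorized implementation is checked against)
brute_force_cov <- function(x, y = x, kmax) {
  n <- min(length(x), length(y))
  vapply(0:kmax, function(k) {
    s <- 0
    for (i in seq_len(n - k)) s <- s + x[i] * y[i + k]
    s / (n - k)
  }, 0)
}
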