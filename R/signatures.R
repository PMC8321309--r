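#' Spectral signature of a land-cover class
#'
#' Per-band mean and population standard deviation of the pixel
#' intensities inside a class's region of interest, together with the
#' pixel count. The mean vector is what the minimum-distance classifier
#' and the signature similarity metrics operate on.
#'
#' @param class_label non-empty class name.
#' @param band_ids ordered band labels.
#' @param mean,std numeric vectors aligned with `band_ids`; `std >= 0`.
#' @param n_pixels number of contributing pixels (>= 1).
#' @return An object of class `spectral_signature`.
#' @export
spectral_signature <- function(class_label, band_ids, mean, std = rep(0, length(mean)),
                               n_pixels = 1L) {
  if (!nzchar(class_label)) stop("class_label must be non-empty")
  if (length(mean) != length(band_ids) || length(std) != length(band_ids))
    stop("mean, std and band_ids must have equal length")
  if (n_pixels < 1L) stop("n_pixels must be >= 1")
  if (any(std < 0)) stop("std must be non-negative")
  structure(list(class_label = class_label, band_ids = band_ids,
                 mean = stats::setNames(as.numeric(mean), band_ids),
                 std = stats::setNames(as.numeric(std), band_ids),
                 n_pixels = as.integer(n_pixels)),
            class = "spectral_signature")
}

#' @export
print.spectral_signature <- function(x, ...) {
  cat(sprintf("<spectral_signature> '%s' (%d px)\n", x$class_label, x$n_pixels))
  print(round(rbind(mean = x$mean, std = x$std), 2))
  invisible(x)
}

#' Compute a class spectral signature from scene pixels
#'
#' Arithmetic mean and population standard deviation of each band over the
#' given pixel set. Pixels equal to the scene's nodata value in any band
#' are excluded; a pixel set consisting only of nodata is an error.
#'
#' @param scene a [multiband_scene()].
#' @param pixels `n x 2` matrix of 0-based `(row, col)` indices (as
#'   produced by [rasterize_rois()]).
#' @param class_label class name for the signature.
#' @return A [spectral_signature()].
#' @export
compute_signature <- function(scene, pixels, class_label) {
  stopifnot(inherits(scene, "mb_scene"))
  pixels <- matrix(as.integer(pixels), ncol = 2)
  if (nrow(pixels) == 0L) stop("empty pixel set")
  d <- dim(scene$bands[[1]])
  if (any(pixels[, 1] < 0 | pixels[, 1] >= d[1] |
          pixels[, 2] < 0 | pixels[, 2] >= d[2]))
    stop("pixel indices outside scene bounds")
  idx <- cbind(pixels[, 1] + 1L, pixels[, 2] + 1L)
  vals <- vapply(scene$bands, function(b) b[idx], numeric(nrow(idx)))
  vals <- matrix(vals, nrow = nrow(idx))
  if (!is.null(scene$nodata)) {
    keep <- rowSums(vals == scene$nodata) == 0L
    if (!any(keep)) stop(sprintf("class '%s': all ROI pixels are nodata", class_label))
    vals <- vals[keep, , drop = FALSE]
  }
  mu <- colMeans(vals)
  sdev <- sqrt(colMeans(sweep(vals, 2, mu)^2))  # population std
  spectral_signature(class_label, scene$band_ids, mu, sdev, nrow(vals))
}

#' Signatures for every ROI class of a scene
#'
#' Convenience wrapper: rasterizes the ROIs and computes one signature per
#' class, in ROI order.
#'
#' @param scene a [multiband_scene()].
#' @param rois an [roi_set()].
#' @return Named list of [spectral_signature()] objects.
#' @export
signatures_from_rois <- function(scene, rois) {
  px <- rasterize_rois(rois, scene)
  stats::setNames(lapply(names(px), function(lab)
    compute_signature(scene, px[[lab]], lab)), names(px))
}

#' Mean spectral signature over the green and red bands
#'
#' The average of the B3 (green) and B4 (red) signature means — the scalar
#' statistic used to threshold-segment vegetation whose visible
#' reflectance is raised by dense chlorophyll. With the default bands this
#' is `(mean_B3 + mean_B4) / 2`.
#'
#' @param sig a [spectral_signature()] containing both bands.
#' @param bands the two band ids averaged (default `c("B3", "B4")`).
#' @return Scalar mean signature in the signature's intensity units.
#' @export
mean_signature_b3b4 <- function(sig, bands = c("B3", "B4")) {
  stopifnot(inherits(sig, "spectral_signature"), length(bands) == 2L)
  if (!all(bands %in% sig$band_ids))
    stop(sprintf("signature '%s' lacks band(s): %s", sig$class_label,
                 paste(setdiff(bands, sig$band_ids), collapse = ", ")))
  unname((sig$mean[bands[1]] + sig$mean[bands[2]]) / 2)
}

.aligned_means <- function(a, b) {
  stopifnot(inherits(a, "spectral_signature"), inherits(b, "spectral_signature"))
  if (!identical(a$band_ids, b$band_ids))
    stop("signatures have mismatched bands")
  list(a = unname(a$mean), b = unname(b$mean))
}

#' Euclidean distance between two signatures
#'
#' \eqn{\sqrt{\sum_i (a_i - b_i)^2}} over the band means; in the scene's
#' intensity units. Sensitive to overall brightness, unlike
#' [spectral_angle()].
#'
#' @param a,b [spectral_signature()] objects over identical bands.
#' @return Non-negative scalar distance.
#' @export
euclidean_distance <- function(a, b) {
  m <- .aligned_means(a, b)
  sqrt(sum((m$a - m$b)^2))
}

#' Spectral angle between two signatures
#'
#' The angle \eqn{\arccos(a \cdot b / (\|a\|\|b\\|))} between the mean
#' vectors, in degrees in \eqn{[0, 180]}; invariant to positive rescaling
#' of either signature.
#'
#' @inheritParams euclidean_distance
#' @return Angle in degrees.
#' @export
spectral_angle <- function(a, b) {
  m <- .aligned_means(a, b)
  na <- sqrt(sum(m$a^2)); nb <- sqrt(sum(m$b^2))
  if (na == 0 || nb == 0) stop("spectral angle undefined for a zero signature")
  acos(min(1, max(-1, sum(m$a * m$b) / (na * nb)))) * 180 / pi
}

#' Bray-Curtis similarity between two signatures
#'
#' \eqn{100 (1 - \sum_i |a_i - b_i| / \sum_i (a_i + b_i))} percent over the
#' band means, in \eqn{[0, 100]}; requires non-negative means.
#'
#' @inheritParams euclidean_distance
#' @return Similarity in percent.
#' @export
bray_curtis_similarity <- function(a, b) {
  m <- .aligned_means(a, b)
  if (any(m$a < 0) || any(m$b < 0))
    stop("Bray-Curtis similarity requires non-negative band means")
  denom <- sum(m$a + m$b)
  if (denom == 0) stop("Bray-Curtis similarity undefined for two zero signatures")
  100 * (1 - sum(abs(m$a - m$b)) / denom)
}

#' Write signatures to CSV
#'
#' Long format: one row per (class, band) with columns `class_label`,
#' `band_id`, `mean`, `std`, `n_pixels`.
#'
#' @param sigs list of [spectral_signature()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(sigs, path) {
  rows <- do.call(rbind, lapply(sigs, function(s)
    data.frame(class_label = s$class_label, band_id = s$band_ids,
               mean = unname(s$mean), std = unname(s$std),
               n_pixels = s$n_pixels)))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read signatures written by [write_signatures()]
#'
#' @param path CSV path.
#' @return Named list of [spectral_signature()] objects, in file order.
#' @export
read_signatures <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  labs <- unique(df$class_label)
  stats::setNames(lapply(labs, function(lab) {
    s <- df[df$class_label == lab, ]
    spectral_signature(lab, s$band_id, s$mean, s$std, s$n_pixels[1])
  }), labs)
}
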