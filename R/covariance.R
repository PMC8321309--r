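#' Pixel intensity vector of one class
#'
#' The 1-D sequence obtained by column-stacking the rectangular clip of a
#' class's pixels (see [extract_class_vector()]), or any 1-D intensity
#' series to be analysed with [covariance_series()]. The `mean` field
#' stores the trend \eqn{\bar\varphi} removed by [detrend()]; covariance
#' estimation requires a detrended vector.
#'
#' @param values numeric intensity sequence.
#' @param class_label class name (informational).
#' @param detrended has the mean trend been removed?
#' @param trend_mean the removed mean \eqn{\bar\varphi} (NA before
#'   detrending).
#' @return An object of class `pixel_vector`.
#' @export
pixel_vector <- function(values, class_label = "", detrended = FALSE,
                         trend_mean = NA_real_) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("empty pixel vector")
  structure(list(values = values, class_label = class_label,
                 mean = trend_mean, detrended = isTRUE(detrended)),
            class = "pixel_vector")
}

#' @export
print.pixel_vector <- function(x, ...) {
  cat(sprintf("<pixel_vector> '%s', n = %d, %s\n", x$class_label,
              length(x$values),
              if (x$detrended) sprintf("detrended (trend %.4g)", x$mean)
              else "raw"))
  invisible(x)
}

#' @export
length.pixel_vector <- function(x) length(x$values)

.as_pixel_vector <- function(v) {
  if (inherits(v, "pixel_vector")) v else pixel_vector(v)
}

#' Column-stack the clip of one class into a pixel vector
#'
#' Takes the bounding box of the class's pixels in the map, fills pixels of
#' other classes inside that box with the mean intensity of the class
#' pixels (so they contribute approximately zero after detrending), and
#' stacks the clip column-by-column (column-major order) into a single
#' vector of length `rows x cols` of the clip.
#'
#' @param scene a [multiband_scene()].
#' @param map a [class_map()] aligned with the scene.
#' @param class_label class to extract (must occur in the map).
#' @param band a band id, or several band ids whose per-pixel mean forms a
#'   composite intensity.
#' @return A raw (not yet detrended) [pixel_vector()].
#' @export
extract_class_vector <- function(scene, map, class_label, band) {
  stopifnot(inherits(scene, "mb_scene"), inherits(map, "class_map"))
  if (!identical(dim(scene$bands[[1]]), dim(map$labels)))
    stop("scene and class map differ in dimensions")
  code <- match(class_label, map$legend)
  if (is.na(code)) stop(sprintf("class '%s' not in map legend", class_label))
  sel <- map$labels == code
  if (!any(sel)) stop(sprintf("class '%s' has no pixels in the map", class_label))
  if (!all(band %in% scene$band_ids))
    stop(sprintf("scene lacks band(s): %s",
                 paste(setdiff(band, scene$band_ids), collapse = ", ")))
  grid <- Reduce(`+`, scene$bands[band]) / length(band)
  rr <- range(which(rowSums(sel) > 0)); cc <- range(which(colSums(sel) > 0))
  clip <- grid[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  inclip <- sel[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  fill <- mean(clip[inclip])
  clip[!inclip] <- fill
  pixel_vector(as.vector(clip), class_label = class_label)
}

#' Remove the mean trend from a pixel vector
#'
#' Subtracts the arithmetic mean \eqn{\bar\varphi} so that the centred
#' vector \eqn{\delta\varphi = \varphi - \bar\varphi} carries no
#' systematic offset into the covariance estimate. The removed mean is
#' stored in the result's `mean` field. Detrending an already centred
#' vector changes nothing (up to floating-point round-off).
#'
#' @param v a [pixel_vector()] or numeric vector.
#' @return A detrended [pixel_vector()].
#' @export
detrend <- function(v) {
  v <- .as_pixel_vector(v)
  m <- mean(v$values)
  pixel_vector(v$values - m, class_label = v$class_label,
               detrended = TRUE, trend_mean = m)
}

#' Auto- or cross-covariance series over quantisation intervals
#'
#' Estimates the covariance function of one detrended pixel vector with
#' itself (auto-covariance) or of two detrended vectors (cross-covariance)
#' at integer lags — quantisation intervals — `k = 0, ..., kmax`:
#' \deqn{K(k) = \frac{1}{n-k} \sum_{i=1}^{n-k}
#'   \delta\varphi_1(u_i)\,\delta\varphi_2(u_{i+k})}
#' with the biased `1/(n-k)` denominator. At `k = 0` the auto-series
#' equals the population variance. For a cross-series the vectors are
#' truncated to their common length `n = min(n1, n2)` (with a message).
#' Lags run at the pixel-position unit, and `kmax` may not exceed `n/2`.
#'
#' The returned `cov_series` object carries the raw covariances `K`, the
#' pair counts `n - k`, and — after [normalize_series()] — the correlation
#' coefficients `r` and their standard errors `sigma_r`. Methods:
#' `print`, `summary`, `plot`, `as.data.frame`.
#'
#' @param v1,v2 detrended [pixel_vector()]s ([detrend()]); omit `v2` (or
#'   pass the same vector) for an auto-series.
#' @param kmax largest lag; defaults to `floor(n/2)`.
#' @return An object of class `cov_series` with fields `lags`, `K`, `r`
#'   (NULL until normalized), `counts`, `sigma_r`, `auto`, `n`,
#'   `class_labels`.
#' @examples
#' v <- detrend(pixel_vector(c(1, 2, 3, 4)))
#' covariance_series(v, kmax = 1)$K  # 1.25, 0.41667
#' @export
covariance_series <- function(v1, v2 = v1, kmax = NULL) {
  auto <- missing(v2)
  v1 <- .as_pixel_vector(v1); v2 <- .as_pixel_vector(v2)
  if (!auto) auto <- identical(v1$values, v2$values)
  if (!v1$detrended || !v2$detrended)
    stop("vectors must be detrended first (see detrend())")
  n <- min(length(v1$values), length(v2$values))
  if (n < 2L) stop("covariance requires vectors of length >= 2")
  if (!auto && length(v1$values) != length(v2$values))
    message(sprintf("cross-covariance: vectors truncated to common length %d", n))
  x <- v1$values[seq_len(n)]; y <- v2$values[seq_len(n)]
  if (is.null(kmax)) kmax <- n %/% 2L
  kmax <- as.integer(kmax)
  if (kmax < 0L || kmax > n / 2)
    stop(sprintf("kmax must lie in [0, n/2] = [0, %d]", n %/% 2L))
  K <- vapply(0:kmax, function(k)
    sum(x[seq_len(n - k)] * y[(k + 1):n]) / (n - k), 0)
  structure(list(lags = 0:kmax, K = K, r = NULL, counts = n - (0:kmax),
                 sigma_r = NULL, auto = auto, n = n,
                 class_labels = c(v1$class_label, v2$class_label)),
            class = "cov_series")
}

#' Normalize a covariance series to correlation coefficients
#'
#' Divides the covariance estimates by the product of the vectors'
#' standard deviations \eqn{\sigma_i = \sqrt{K_{auto,i}(0)}} (population
#' standard deviations of the detrended vectors). For an auto-series this
#' reduces to `K(k)/K(0)`, so `r(0) = 1` exactly. Because the estimator
#' uses the biased `1/(n-k)` denominator, `|r(k)|` can marginally exceed
#' 1 at large lags; stored values are never clipped.
#'
#' Standard errors \eqn{\sigma_r = (1 - r^2)/\sqrt{m}} are attached per
#' lag with `m` the pair count `n - k` (set `se_denom = "lag"` for the
#' variant that divides by \eqn{\sqrt{k}} instead; its lag-0 entry is NA).
#'
#' @param s a `cov_series` from [covariance_series()].
#' @param v1,v2 the same detrended vectors the series was computed from.
#' @param se_denom `"pairs"` (default) or `"lag"`.
#' @return The series with `r` and `sigma_r` filled in.
#' @export
normalize_series <- function(s, v1, v2 = v1, se_denom = c("pairs", "lag")) {
  stopifnot(inherits(s, "cov_series"))
  se_denom <- match.arg(se_denom)
  v1 <- .as_pixel_vector(v1); v2 <- .as_pixel_vector(v2)
  n <- s$n
  if (s$auto) {
    if (s$K[1] == 0) stop("constant (zero-variance) vector cannot be normalized")
    r <- s$K / s$K[1]
  } else {
    var1 <- mean(v1$values[seq_len(n)]^2)
    var2 <- mean(v2$values[seq_len(n)]^2)
    if (var1 == 0 || var2 == 0)
      stop("constant (zero-variance) vector cannot be normalized")
    r <- s$K / sqrt(var1 * var2)
  }
  rc <- pmin(1, pmax(-1, r))  # clamp only inside the error formula
  m <- if (se_denom == "pairs") s$counts else s$lags
  sig <- rep(NA_real_, length(r))
  ok <- m >= if (se_denom == "pairs") 2 else 1
  sig[ok] <- (1 - rc[ok]^2) / sqrt(m[ok])
  s$r <- r
  s$sigma_r <- sig
  s
}

#' Standard error of a correlation coefficient
#'
#' \eqn{\sigma_r = (1 - r^2)/\sqrt{m}} for a coefficient estimated from
#' `m` pairs; zero at `|r| = 1`.
#'
#' @param r correlation coefficient(s), `|r| <= 1`.
#' @param m pair count(s), `>= 2`.
#' @return Standard error(s), recycled over `r` and `m`.
#' @export
stderr_r <- function(r, m) {
  if (any(m < 2)) stop("standard error requires m >= 2 pairs")
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must not exceed 1")
  (1 - pmin(1, abs(r))^2) / sqrt(m)
}

#' @export
print.cov_series <- function(x, ...) {
  kind <- if (x$auto) "auto" else "cross"
  labs <- unique(x$class_labels[nzchar(x$class_labels)])
  cat(sprintf("<cov_series> %s-covariance%s, n = %d, lags 0..%d\n", kind,
              if (length(labs)) paste0(" of ", paste(labs, collapse = " x "))
              else "", x$n, max(x$lags)))
  if (!is.null(x$r))
    cat("  r:", paste(format(head(x$r, 6), digits = 4), collapse = " "),
        if (length(x$r) > 6) "...", "\n")
  else cat("  (not normalized; see normalize_series())\n")
  invisible(x)
}

#' @export
summary.cov_series <- function(object, ...) {
  df <- as.data.frame(object)
  pos <- df[df$k >= 1, ]
  out <- list(
    kind = if (object$auto) "auto" else "cross",
    n = object$n, kmax = max(df$k),
    K0 = df$K[1],
    r_peak = if (!is.null(object$r)) pos$k[which.max(abs(pos$r))] else NA,
    r_peak_value = if (!is.null(object$r)) pos$r[which.max(abs(pos$r))] else NA,
    mean_abs_r = if (!is.null(object$r)) mean(abs(pos$r)) else NA)
  structure(out, class = "summary.cov_series")
}

#' @export
print.summary.cov_series <- function(x, ...) {
  cat(sprintf("%s-covariance series: n = %d, kmax = %d, K(0) = %.6g\n",
              x$kind, x$n, x$kmax, x$K0))
  if (!is.na(x$r_peak))
    cat(sprintf("  peak |r| beyond lag 0: %.4f at k = %d; mean |r| = %.4f\n",
                x$r_peak_value, x$r_peak, x$mean_abs_r))
  invisible(x)
}

#' @export
as.data.frame.cov_series <- function(x, ...) {
  data.frame(k = x$lags, K = x$K,
             r = if (is.null(x$r)) NA_real_ else x$r,
             count = x$counts,
             sigma_r = if (is.null(x$sigma_r)) NA_real_ else x$sigma_r)
}

#' @param x a `cov_series`.
#' @param what `"r"` (correlation; requires [normalize_series()]) or
#'   `"K"` (raw covariance).
#' @param ... passed to [plot()].
#' @rdname covariance_series
#' @export
plot.cov_series <- function(x, what = c("r", "K"), ...) {
  what <- match.arg(what)
  y <- if (what == "r") x$r else x$K
  if (is.null(y)) stop("series is not normalized; plot what = \"K\" or normalize first")
  yl <- if (what == "r") "correlation coefficient r" else "covariance K"
  yy <- if (what == "r") pmin(1, pmax(-1, y)) else y  # clip for display only
  plot(x$lags, yy, type = "l", xlab = "quantisation interval k", ylab = yl, ...)
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Pairwise segment correlation matrix of class pixel vectors
#'
#' Splits every class vector into `segment_count` equal segments
#' (truncating any remainder, with a message) and computes the full grid
#' of Pearson correlations between all segment pairs across classes. For
#' well-separated classes the within-class diagonal blocks ride on a
#' ridge of 1s while between-class blocks stay near zero, so a c-class
#' grid shows c "pyramids" when drawn as a surface.
#'
#' @param vectors named list (>= 2 classes) of [pixel_vector()]s or
#'   numeric vectors.
#' @param segment_count number of segments per vector; each segment must
#'   hold at least 2 values.
#' @return An object of class `cor_matrix_grid`: fields `values` (the
#'   correlation matrix with `class:segment` dimnames), `classes`,
#'   `segment_count`, `segment_length`.
#' @export
correlation_matrix <- function(vectors, segment_count) {
  if (length(vectors) < 2L) stop("at least two classes are required")
  if (is.null(names(vectors)) || any(!nzchar(names(vectors))))
    stop("'vectors' must be a named list")
  segment_count <- as.integer(segment_count)
  if (segment_count < 1L) stop("segment_count must be >= 1")
  cols <- list()
  seglen <- NULL
  for (lab in names(vectors)) {
    v <- .as_pixel_vector(vectors[[lab]])$values
    L <- length(v) %/% segment_count
    if (L < 2L) stop(sprintf("class '%s': segments shorter than 2", lab))
    if (length(v) %% segment_count != 0L)
      message(sprintf("class '%s': %d trailing value(s) dropped", lab,
                      length(v) %% segment_count))
    seglen <- if (is.null(seglen)) L else min(seglen, L)
    for (s in seq_len(segment_count))
      cols[[paste0(lab, ":", s)]] <- v[((s - 1) * L + 1):(s * L)]
  }
  M <- vapply(cols, function(v) v[seq_len(seglen)], numeric(seglen))
  G <- stats::cor(M)
  structure(list(values = G, classes = names(vectors),
                 segment_count = segment_count, segment_length = seglen),
            class = "cor_matrix_grid")
}

#' @export
print.cor_matrix_grid <- function(x, ...) {
  cat(sprintf("<cor_matrix_grid> %d class(es) x %d segment(s) (segment length %d)\n",
              length(x$classes), x$segment_count, x$segment_length))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' @param x a `cor_matrix_grid`.
#' @param type `"image"` for a heat map, `"surface"` for a perspective
#'   surface (the "pyramids" view).
#' @param ... passed to [graphics::image()] or [graphics::persp()].
#' @rdname correlation_matrix
#' @export
plot.cor_matrix_grid <- function(x, type = c("image", "surface"), ...) {
  type <- match.arg(type)
  z <- pmin(1, pmax(-1, x$values))
  if (type == "image") {
    image(seq_len(nrow(z)), seq_len(ncol(z)), z, zlim = c(-1, 1),
          col = hcl.colors(64, "Blue-Red 3"), xlab = "segment index",
          ylab = "segment index", ...)
  } else {
    graphics::persp(seq_len(nrow(z)), seq_len(ncol(z)), z,
                    zlim = c(-1, 1), xlab = "segment", ylab = "segment",
                    zlab = "r", theta = 35, phi = 30, ...)
  }
  invisible(x)
}
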