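#' Specification of a synthetic multiband scene
#'
#' Describes a three-class (or n-class) agricultural test scene: per-class
#' per-band mean digital numbers, Gaussian noise level, spatial
#' correlation length, and a spatial layout. The defaults elsewhere in the
#' package pair this with digital-number magnitudes typical of
#' spring-season visible-band vegetation signatures (several hundred to
#' ~1300 DN).
#'
#' @param rows,cols scene dimensions in pixels.
#' @param classes list; each element a list with `class_label`, `mean`
#'   (numeric, one value per band, optionally named by band id),
#'   `noise_std` (Gaussian noise standard deviation in DN, >= 0) and
#'   `corr_length` (Gaussian correlation length in pixels, >= 0; 0 means
#'   white noise).
#' @param layout `"stripes"` (horizontal stripes, one per class),
#'   `"halves"` (left/right split, exactly 2 classes) or `"blobs"`
#'   (first class is background, later classes are disc-shaped patches).
#' @param band_ids band labels (default blue/green/red `B2`, `B3`, `B4`).
#' @param seed integer seed; identical (spec, seed) pairs generate
#'   identical scenes.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(rows, cols, classes,
                       layout = c("stripes", "blobs", "halves"),
                       band_ids = c("B2", "B3", "B4"), seed = 1L) {
  layout <- match.arg(layout)
  if (length(classes) < 1L) stop("at least one class is required")
  for (cl in classes) {
    if (is.null(cl$class_label) || !nzchar(cl$class_label))
      stop("every class needs a class_label")
    if (length(cl$mean) != length(band_ids))
      stop(sprintf("class '%s': one mean per band required", cl$class_label))
    if (is.null(cl$noise_std) || cl$noise_std < 0)
      stop(sprintf("class '%s': noise_std must be >= 0", cl$class_label))
    if (is.null(cl$corr_length) || cl$corr_length < 0)
      stop(sprintf("class '%s': corr_length must be >= 0", cl$class_label))
  }
  if (layout == "halves" && length(classes) != 2L)
    stop("layout 'halves' requires exactly 2 classes")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 classes = classes, layout = layout, band_ids = band_ids,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

.layout_mask <- function(spec) {
  nr <- spec$rows; nc <- spec$cols; ncl <- length(spec$classes)
  lab <- matrix(1L, nr, nc)
  if (spec$layout == "stripes") {
    if (nr < ncl) stop("degenerate layout: fewer rows than classes")
    bounds <- floor(seq(0, nr, length.out = ncl + 1))
    for (i in seq_len(ncl)) lab[(bounds[i] + 1):bounds[i + 1], ] <- i
  } else if (spec$layout == "halves") {
    if (nc < 2) stop("degenerate layout: too few columns")
    lab[, (nc %/% 2 + 1):nc] <- 2L
  } else {  # blobs: class 1 background, others as discs (drawn with the RNG)
    rad <- max(3, round(min(nr, nc) / 8))
    rowg <- row(lab); colg <- col(lab)
    for (i in seq_len(ncl)[-1]) {
      for (b in 1:3) {
        cr <- runif(1, rad + 1, nr - rad); cc <- runif(1, rad + 1, nc - rad)
        lab[(rowg - cr)^2 + (colg - cc)^2 <= rad^2] <- i
      }
    }
  }
  present <- tabulate(lab, ncl)
  if (any(present == 0L))
    stop(sprintf("degenerate layout: class '%s' has zero area",
                 spec$classes[[which(present == 0L)[1]]]$class_label))
  lab
}

# white noise convolved with a gaussian kernel (circular), rescaled to unit sd
.correlated_field <- function(nr, nc, corr_length) {
  f <- matrix(rnorm(nr * nc), nr, nc)
  if (corr_length > 0) {
    half <- max(1L, ceiling(3 * corr_length))
    g <- exp(-(seq(-half, half))^2 / (2 * corr_length^2))
    kern <- outer(g, g)
    kern <- kern / sum(kern)
    f <- EBImage::filter2(f, kern)
    f <- matrix(as.numeric(f), nr, nc)
  }
  (f - mean(f)) / sd(f)
}

#' Generate a synthetic scene with ground truth and ROIs
#'
#' Builds the layout mask, then draws, class by class and band by band (in
#' listed order), a noise field — white Gaussian noise convolved with a
#' Gaussian kernel of the class's correlation length and rescaled to its
#' noise standard deviation — added to the class's band mean. Digital
#' numbers are rounded to integers and floored at zero. Finally, for each
#' class, up to 200 interior pixels (all 4-neighbours in the same class)
#' are sampled as that class's ROI.
#'
#' All randomness comes from one generator seeded with `spec$seed`, in the
#' draw order above, so identical specs reproduce identical output.
#'
#' @param spec a [scene_spec()].
#' @return List with elements `scene` (a [multiband_scene()], units DN),
#'   `truth` (the exact [class_map()]) and `rois` (an [roi_set()] of
#'   interior pixel samples).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  lab <- .layout_mask(spec)
  nr <- spec$rows; nc <- spec$cols
  nb <- length(spec$band_ids)
  bands <- rep(list(matrix(0, nr, nc)), nb)
  for (ci in seq_along(spec$classes)) {
    cl <- spec$classes[[ci]]
    sel <- lab == ci
    for (bi in seq_len(nb)) {
      field <- if (cl$noise_std > 0)
        .correlated_field(nr, nc, cl$corr_length) * cl$noise_std
      else matrix(0, nr, nc)
      mu <- if (!is.null(names(cl$mean))) unname(cl$mean[[spec$band_ids[bi]]])
            else unname(cl$mean[[bi]])
      bands[[bi]][sel] <- mu + field[sel]
    }
  }
  bands <- lapply(bands, function(b) pmax(round(b), 0))
  legend <- vapply(spec$classes, `[[`, "", "class_label")
  truth <- class_map(lab, legend)
  interior <- lab
  interior[] <- 0L
  core <- lab[2:(nr - 1), 2:(nc - 1)]
  ok <- core == lab[1:(nr - 2), 2:(nc - 1)] & core == lab[3:nr, 2:(nc - 1)] &
        core == lab[2:(nr - 1), 1:(nc - 2)] & core == lab[2:(nr - 1), 3:nc]
  interior[2:(nr - 1), 2:(nc - 1)][ok] <- core[ok]
  entries <- lapply(seq_along(legend), function(ci) {
    cand <- which(interior == ci, arr.ind = TRUE)
    if (nrow(cand) == 0L)
      stop(sprintf("class '%s' has no interior pixels for an ROI", legend[ci]))
    take <- sample(nrow(cand), min(200L, nrow(cand)))
    list(class_label = legend[ci],
         pixels = unname(cand[take, , drop = FALSE]) - 1L)
  })
  list(scene = multiband_scene(bands, band_ids = spec$band_ids, units = "DN"),
       truth = truth, rois = roi_set(entries))
}

#' Generate a stationary AR(1) pixel vector
#'
#' First-order autoregressive sequence
#' \eqn{x_t = \rho x_{t-1} + \epsilon_t}, \eqn{\epsilon_t \sim N(0,
#' \sigma^2)}, started from its stationary distribution, so the
#' theoretical autocorrelation at lag `k` is exactly \eqn{\rho^k}. Used as
#' the closed-form oracle for covariance-series recovery.
#'
#' @param n length (>= 2).
#' @param rho AR coefficient, `|rho| < 1`.
#' @param sigma innovation standard deviation.
#' @param seed integer seed.
#' @return A raw [pixel_vector()] (class label `"ar1"`).
#' @export
generate_ar1_vector <- function(n, rho, sigma = 1, seed = 1L) {
  if (abs(rho) >= 1) stop("|rho| must be < 1 for a stationary AR(1)")
  if (n < 2L) stop("n must be >= 2")
  set.seed(seed)
  x0 <- rnorm(1, 0, sigma / sqrt(1 - rho^2))
  innov <- rnorm(n - 1, 0, sigma)
  x <- as.numeric(stats::filter(c(x0, innov), rho, method = "recursive"))
  pixel_vector(x, class_label = "ar1")
}
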