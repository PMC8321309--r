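#' Class-label map
#'
#' A `class_map` is a 2-D grid of integer class codes with a legend. Code
#' `0` is reserved for unclassified pixels and never appears in the
#' legend; code `i >= 1` means `legend[i]`.
#'
#' @param labels integer matrix of class codes (0 = unclassified).
#' @param legend character vector; `legend[i]` names code `i`.
#' @return An object of class `class_map`.
#' @export
class_map <- function(labels, legend) {
  if (!is.matrix(labels)) stop("'labels' must be a matrix")
  storage.mode(labels) <- "integer"
  legend <- as.character(legend)
  if (anyDuplicated(legend)) stop("legend labels must be unique")
  u <- unique(as.vector(labels))
  if (any(u < 0L) || any(u > length(legend)))
    stop("labels contain codes outside the legend")
  structure(list(labels = labels, legend = legend), class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, nbins = length(x$legend) + 1L)
  d <- dim(x$labels)
  cat(sprintf("<class_map> %d x %d pixels\n", d[1], d[2]))
  df <- data.frame(code = c(0L, seq_along(x$legend)),
                   class = c("(unclassified)", x$legend), pixels = tab)
  print(df[df$pixels > 0 | df$code > 0, ], row.names = FALSE)
  invisible(x)
}

#' @param x a `class_map`.
#' @param col colours, one per legend entry (unclassified is drawn white).
#' @param ... passed to [graphics::image()].
#' @rdname class_map
#' @export
plot.class_map <- function(x, col = hcl.colors(length(x$legend), "Dark 3"), ...) {
  z <- t(x$labels)[, nrow(x$labels):1, drop = FALSE]
  image(z, col = c("white", col), zlim = c(0, length(x$legend)),
        axes = FALSE, asp = nrow(x$labels) / ncol(x$labels), ...)
  legend("topright", fill = col, legend = x$legend, bty = "n", cex = 0.8)
  invisible(x)
}

#' Minimum-distance supervised classification
#'
#' Assigns each valid pixel the class whose signature mean vector is
#' nearest in Euclidean band space. Ties go to the first-listed signature.
#' Pixels whose minimal distance exceeds `max_distance` (when given) and
#' nodata pixels are left unclassified (code 0).
#'
#' @param scene a [multiband_scene()].
#' @param sigs non-empty list of [spectral_signature()] objects sharing one
#'   band set, each band present in the scene.
#' @param max_distance optional rejection threshold in intensity units.
#' @return A [class_map()] whose legend follows signature order.
#' @export
min_distance_classify <- function(scene, sigs, max_distance = NULL) {
  stopifnot(inherits(scene, "mb_scene"))
  if (length(sigs) == 0L) stop("at least one signature is required")
  bands <- sigs[[1]]$band_ids
  for (s in sigs) if (!identical(s$band_ids, bands))
    stop("all signatures must share one band set")
  if (!all(bands %in% scene$band_ids))
    stop("signature bands must be a subset of scene bands")
  d <- dim(scene$bands[[1]])
  X <- vapply(bands, function(id) as.vector(scene$bands[[id]]),
              numeric(prod(d)))
  X <- matrix(X, ncol = length(bands))
  D2 <- vapply(sigs, function(s) {
    mu <- unname(s$mean)
    rowSums((X - matrix(mu, nrow(X), length(mu), byrow = TRUE))^2)
  }, numeric(nrow(X)))
  D2 <- matrix(D2, ncol = length(sigs))
  idx <- max.col(-D2, ties.method = "first")
  if (!is.null(max_distance))
    idx[D2[cbind(seq_along(idx), idx)] > max_distance^2] <- 0L
  if (!is.null(scene$nodata)) {
    nd <- rowSums(X == scene$nodata) > 0L
    idx[nd] <- 0L
  }
  class_map(matrix(as.integer(idx), d[1], d[2]),
            vapply(sigs, `[[`, "", "class_label"))
}

#' Confusion matrix of a classification against reference labels
#'
#' Counts pixels by (reference class, predicted class) over pixels where
#' the reference is classified; reference-unclassified pixels are
#' excluded. The matrix is square over the union of both legends (plus an
#' `"(unclassified)"` prediction column when the prediction rejects pixels
#' the reference labels).
#'
#' @param pred,ref [class_map()]s of identical dimensions.
#' @return An object of class `confusion_matrix`: the integer count matrix
#'   with reference classes in rows, predicted in columns.
#' @export
confusion <- function(pred, ref) {
  stopifnot(inherits(pred, "class_map"), inherits(ref, "class_map"))
  if (!identical(dim(pred$labels), dim(ref$labels)))
    stop("prediction and reference maps differ in dimensions")
  keep <- ref$labels != 0L
  if (!any(keep)) stop("reference map has no classified pixels")
  rl <- ref$legend[ref$labels[keep]]
  pcode <- pred$labels[keep]
  pl <- ifelse(pcode == 0L, "(unclassified)", pred$legend[pmax(pcode, 1L)])
  classes <- union(ref$legend, pred$legend)
  if (any(pcode == 0L)) classes <- c(classes, "(unclassified)")
  cm <- table(factor(rl, levels = classes), factor(pl, levels = classes))
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(reference = classes, predicted = classes))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Overall accuracy of a confusion matrix
#'
#' Fraction of pixels on the diagonal (agreement), in `[0, 1]`.
#'
#' @param cm a matrix from [confusion()].
#' @return Scalar fraction.
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  sum(diag(as.matrix(cm))) / total
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement \eqn{(p_o - p_e)/(1 - p_e)} with the
#' expected agreement \eqn{p_e} computed from the row and column
#' marginals. Ranges over \eqn{[-1, 1]}; values near 1 indicate a highly
#' accurate classification.
#'
#' @param cm a matrix from [confusion()].
#' @return Scalar kappa coefficient.
#' @export
kappa_coefficient <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (pe >= 1) stop("degenerate marginals: expected agreement is 1")
  (po - pe) / (1 - pe)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged through their adjacency graph.
.label_components8 <- function(mask) {
  lb <- EBImage::bwlabel(mask)
  nmax <- max(lb)
  if (nmax <= 1L) return(lb)
  d <- dim(lb)
  pairs <- rbind(
    cbind(as.vector(lb[-d[1], -d[2]]), as.vector(lb[-1, -1])),   # down-right
    cbind(as.vector(lb[-1, -d[2]]), as.vector(lb[-d[1], -1])))   # up-right
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) == 0L) return(lb)
  g <- igraph::graph_from_edgelist(matrix(as.character(pairs), ncol = 2),
                                   directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(1:nmax),
                                    igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  remap <- integer(nmax)
  remap[as.integer(names(comp))] <- comp
  out <- lb
  out[lb > 0] <- remap[lb[lb > 0]]
  out
}

#' Unsupervised threshold segmentation with a minimum mapping unit
#'
#' Scores each pixel by the mean of the named bands (by default the green
#' and red bands whose average is the mean spectral signature), keeps
#' pixels with `low <= score <= high` as the target mask, and removes
#' 8-connected target components smaller than `min_area` pixels (the
#' minimum mapping unit). The result is a binary map with classes
#' `target` and `other`.
#'
#' @param scene a [multiband_scene()].
#' @param bands band ids averaged into the pixel score (default
#'   `c("B3", "B4")`).
#' @param low,high inclusive score window, `low <= high`.
#' @param min_area smallest retained component, in pixels (>= 1).
#' @return A [class_map()] with legend `c("target", "other")`.
#' @export
threshold_segment <- function(scene, bands = c("B3", "B4"), low, high,
                              min_area = 5L) {
  stopifnot(inherits(scene, "mb_scene"))
  if (length(bands) == 0L) stop("at least one band must be selected")
  if (!all(bands %in% scene$band_ids))
    stop(sprintf("scene lacks band(s): %s",
                 paste(setdiff(bands, scene$band_ids), collapse = ", ")))
  if (low > high) stop("'low' must not exceed 'high'")
  if (min_area < 1L) stop("'min_area' must be >= 1")
  score <- Reduce(`+`, scene$bands[bands]) / length(bands)
  mask <- score >= low & score <= high
  if (!is.null(scene$nodata))
    for (id in bands) mask[scene$bands[[id]] == scene$nodata] <- FALSE
  if (any(mask) && min_area > 1L) {
    lb <- .label_components8(mask)
    sizes <- tabulate(lb[lb > 0])
    mask[lb > 0 & sizes[pmax(lb, 1L)] < min_area] <- FALSE
  }
  class_map(matrix(ifelse(mask, 1L, 2L), nrow(score), ncol(score)),
            c("target", "other"))
}

#' Majority smoothing of a class map
#'
#' Replaces each pixel's label by the most frequent label in the
#' surrounding `window x window` neighbourhood (partial windows at the
#' edges). Ties keep the centre pixel's label, which makes the filter
#' idempotent on constant maps.
#'
#' @param map a [class_map()].
#' @param window odd window size >= 3.
#' @return The smoothed [class_map()] (same legend).
#' @export
smooth_map <- function(map, window = 3L) {
  stopifnot(inherits(map, "class_map"))
  if (window %% 2L != 1L || window < 3L) stop("'window' must be odd and >= 3")
  lab <- map$labels
  d <- dim(lab)
  h <- (window - 1L) %/% 2L
  codes <- sort(unique(as.vector(lab)))
  counts <- array(0L, c(d[1], d[2], length(codes)))
  for (ci in seq_along(codes)) {
    ind <- (lab == codes[ci]) * 1L
    acc <- matrix(0L, d[1], d[2])
    for (dr in -h:h) for (dc in -h:h) {
      rs <- max(1, 1 + dr):min(d[1], d[1] + dr)
      rd <- max(1, 1 - dr):min(d[1], d[1] - dr)
      cs <- max(1, 1 + dc):min(d[2], d[2] + dc)
      cd <- max(1, 1 - dc):min(d[2], d[2] - dc)
      acc[rd, cd] <- acc[rd, cd] + ind[rs, cs]
    }
    counts[, , ci] <- acc
  }
  best <- apply(counts, c(1, 2), which.max)
  nmax <- apply(counts, c(1, 2), function(v) sum(v == max(v)))
  out <- matrix(codes[best], d[1], d[2])
  tie <- nmax > 1L  # a unique winner stands; the centre keeps its label on ties
  out[tie] <- lab[tie]
  class_map(out, map$legend)
}

#' Write a class map as a TIFF with a JSON legend sidecar
#'
#' @param map a [class_map()].
#' @param path output TIFF path; the legend goes to
#'   `<path minus extension>.json`.
#' @return `path`, invisibly.
#' @export
write_class_map <- function(map, path) {
  stopifnot(inherits(map, "class_map"))
  tiff::writeTIFF(map$labels / 65535, path, bits.per.sample = 16L)
  jsonlite::write_json(list(legend = map$legend), .sidecar_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a class map written by [write_class_map()]
#'
#' @param path TIFF path with its JSON legend sidecar.
#' @return A [class_map()].
#' @export
read_class_map <- function(path) {
  lab <- suppressWarnings(tiff::readTIFF(path, as.is = TRUE))
  meta <- jsonlite::fromJSON(.sidecar_path(path))
  class_map(lab, meta$legend)
}
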