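#' Region-of-interest sets
#'
#' An `roi_set` is an ordered list of class-labelled regions used to train
#' spectral signatures and to hold out reference pixels. Each entry carries
#' either a polygon in pixel coordinates (x = column, y = row; the centre
#' of 0-based pixel `(i, j)` is at `(j + 0.5, i + 0.5)`) or an explicit
#' 0-based `(row, col)` pixel list.
#'
#' @param entries list; each element a list with `class_label` (non-empty
#'   string) and either `polygon` (n x 2 matrix of x, y vertices) or
#'   `pixels` (n x 2 matrix of 0-based row, col indices).
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(entries) {
  if (!is.list(entries) || length(entries) == 0L)
    stop("'entries' must be a non-empty list")
  for (e in entries) {
    if (is.null(e$class_label) || !nzchar(e$class_label))
      stop("every ROI entry needs a non-empty class_label")
    if (is.null(e$polygon) && is.null(e$pixels))
      stop("every ROI entry needs a 'polygon' or a 'pixels' matrix")
  }
  structure(list(entries = entries), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d region(s): %s\n", length(x$entries),
              paste(vapply(x$entries, `[[`, "", "class_label"), collapse = ", ")))
  invisible(x)
}

#' Read ROIs from a GeoJSON FeatureCollection
#'
#' Features must carry a `class_label` property. `Polygon` geometries are
#' taken as pixel-coordinate polygons (outer ring only); `MultiPoint`
#' geometries are taken as explicit pixel lists with coordinates
#' `[col, row]` (0-based).
#'
#' @param path path to a GeoJSON file.
#' @return An [roi_set()].
#' @export
read_rois <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  entries <- lapply(gj$features, function(f) {
    lab <- f$properties$class_label
    if (is.null(lab)) stop("feature lacks a 'class_label' property")
    geom <- f$geometry
    if (identical(geom$type, "Polygon")) {
      ring <- geom$coordinates[[1]]
      xy <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      list(class_label = lab, polygon = xy)
    } else if (identical(geom$type, "MultiPoint")) {
      cr <- do.call(rbind, lapply(geom$coordinates, function(p) c(p[[2]], p[[1]])))
      list(class_label = lab, pixels = cr)
    } else stop(sprintf("unsupported geometry type '%s'", geom$type))
  })
  roi_set(entries)
}

#' Write ROIs as a GeoJSON FeatureCollection
#'
#' Inverse of [read_rois()]: polygons become `Polygon` features, pixel
#' lists become `MultiPoint` features with `[col, row]` coordinates.
#'
#' @param rois an [roi_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  feats <- lapply(rois$entries, function(e) {
    geom <- if (!is.null(e$polygon)) {
      ring <- lapply(seq_len(nrow(e$polygon)),
                     function(i) as.numeric(e$polygon[i, ]))
      list(type = "Polygon", coordinates = list(ring))
    } else {
      pts <- lapply(seq_len(nrow(e$pixels)),
                    function(i) as.numeric(e$pixels[i, c(2, 1)]))
      list(type = "MultiPoint", coordinates = pts)
    }
    list(type = "Feature", properties = list(class_label = e$class_label),
         geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize ROIs onto a scene's pixel grid
#'
#' Polygons are rasterized with the pixel-centre-inside-polygon rule;
#' explicit pixel lists are bounds-checked and passed through. A pixel can
#' belong to at most one class: overlaps are assigned to the first-listed
#' class and a warning names the classes involved. Entries sharing a
#' class_label are merged.
#'
#' @param rois an [roi_set()].
#' @param scene a [multiband_scene()] defining the pixel grid.
#' @return Named list mapping class_label to an `n x 2` integer matrix of
#'   0-based `(row, col)` pixel indices.
#' @export
rasterize_rois <- function(rois, scene) {
  stopifnot(inherits(rois, "roi_set"), inherits(scene, "mb_scene"))
  d <- dim(scene$bands[[1]])
  seen <- matrix(FALSE, d[1], d[2])
  out <- list()
  for (e in rois$entries) {
    if (!is.null(e$pixels)) {
      px <- matrix(as.integer(round(e$pixels)), ncol = 2)
      if (any(px[, 1] < 0 | px[, 1] >= d[1] | px[, 2] < 0 | px[, 2] >= d[2]))
        stop(sprintf("ROI '%s' has pixels outside scene bounds", e$class_label))
    } else {
      xp <- e$polygon[, 1]; yp <- e$polygon[, 2]
      c0 <- max(0L, floor(min(xp))); c1 <- min(d[2] - 1L, ceiling(max(xp)))
      r0 <- max(0L, floor(min(yp))); r1 <- min(d[1] - 1L, ceiling(max(yp)))
      if (c0 > c1 || r0 > r1)
        stop(sprintf("ROI '%s' rasterizes to zero pixels", e$class_label))
      grid <- expand.grid(row = r0:r1, col = c0:c1)
      inside <- pracma::inpolygon(grid$col + 0.5, grid$row + 0.5, xp, yp,
                                  boundary = FALSE)
      px <- as.matrix(grid[inside, , drop = FALSE])
      dimnames(px) <- NULL
    }
    if (nrow(px) == 0L)
      stop(sprintf("ROI '%s' rasterizes to zero pixels", e$class_label))
    taken <- seen[cbind(px[, 1] + 1L, px[, 2] + 1L)]
    if (any(taken)) {
      warning(sprintf("%d pixel(s) of ROI '%s' overlap an earlier class; kept with the first-listed class",
                      sum(taken), e$class_label))
      px <- px[!taken, , drop = FALSE]
    }
    if (nrow(px) > 0L) seen[cbind(px[, 1] + 1L, px[, 2] + 1L)] <- TRUE
    lab <- e$class_label
    out[[lab]] <- if (is.null(out[[lab]])) px else rbind(out[[lab]], px)
  }
  empty <- names(out)[vapply(out, nrow, 0L) == 0L]
  if (length(empty))
    stop(sprintf("ROI '%s' rasterizes to zero pixels after overlap resolution",
                 empty[1]))
  out
}
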