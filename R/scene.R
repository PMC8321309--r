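#' Multiband scene container
#'
#' A `mb_scene` holds an ordered set of co-registered 2-D intensity grids
#' (one per spectral band) together with band labels and minimal raster
#' metadata. All bands must share the same dimensions. Pixel indexing
#' throughout the package is 0-based `(row, col)` and windows are half-open,
#' so a 100x100 scene spans rows `[0, 100)` and cols `[0, 100)`.
#'
#' @param bands list of numeric matrices (identical dimensions), or a 3-D
#'   array `rows x cols x bands`.
#' @param band_ids character labels, one per band (default `"B1"`, `"B2"`,
#'   ...). Must be unique.
#' @param nodata optional sentinel intensity marking invalid pixels; must
#'   not coincide with any valid intensity.
#' @param pixel_size ground pixel size in metres (informational only).
#' @param units `"DN"` for raw digital numbers or `"reflectance"`.
#' @param geo opaque geographic metadata (carried through read/clip/write,
#'   never interpreted).
#' @return An object of class `mb_scene` with fields `bands`, `band_ids`,
#'   `nodata`, `pixel_size`, `units`, `geo`.
#' @seealso [read_scene()], [clip_scene()]
#' @export
multiband_scene <- function(bands, band_ids = NULL, nodata = NULL,
                            pixel_size = NA_real_,
                            units = c("DN", "reflectance"), geo = NULL) {
  if (is.array(bands) && length(dim(bands)) == 3L)
    bands <- lapply(seq_len(dim(bands)[3]), function(i) bands[, , i])
  if (is.matrix(bands)) bands <- list(bands)
  if (!is.list(bands) || length(bands) == 0L)
    stop("'bands' must be a non-empty list of matrices")
  bands <- lapply(bands, function(b) {
    if (!is.matrix(b) || !is.numeric(b)) stop("each band must be a numeric matrix")
    b
  })
  dims <- vapply(bands, dim, integer(2))
  if (length(bands) > 1L && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]))
    stop("all bands must share identical dimensions (format error)")
  if (is.null(band_ids)) band_ids <- paste0("B", seq_along(bands))
  if (length(band_ids) != length(bands)) stop("one band_id per band required")
  if (anyDuplicated(band_ids)) stop("band_ids must be unique")
  names(bands) <- band_ids
  units <- match.arg(units)
  structure(list(bands = bands, band_ids = band_ids, nodata = nodata,
                 pixel_size = pixel_size, units = units, geo = geo),
            class = "mb_scene")
}

#' @export
print.mb_scene <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("<mb_scene> %d x %d pixels, %d band(s): %s\n",
              d[1], d[2], length(x$bands), paste(x$band_ids, collapse = ", ")))
  cat(sprintf("  units: %s; nodata: %s; pixel size: %s m\n", x$units,
              if (is.null(x$nodata)) "none" else format(x$nodata),
              format(x$pixel_size)))
  invisible(x)
}

#' @export
dim.mb_scene <- function(x) dim(x$bands[[1]])

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a multiband scene from a TIFF file
#'
#' Bands are read in file order (one TIFF directory per band as written by
#' [write_scene()]; a single-directory file yields a single-band scene).
#' If a JSON sidecar written by [write_scene()] sits next to the file, band
#' ids, units, nodata and geographic metadata are restored from it;
#' otherwise units default to `"DN"`.
#'
#' @param path path to a readable TIFF file.
#' @param band_ids,nodata optional overrides for the sidecar/default values.
#' @return A [multiband_scene()] object.
#' @export
read_scene <- function(path, band_ids = NULL, nodata = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read scene: '%s' not found", path))
  meta <- NULL
  sp <- .sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::fromJSON(sp)
  pages <- tryCatch(
    suppressWarnings(tiff::readTIFF(path, all = TRUE, info = TRUE)),
    error = function(e) stop(sprintf("cannot read scene '%s': %s", path,
                                     conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  bands <- lapply(pages, function(p) {
    bps <- attr(p, "bits.per.sample")
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] != 1L) stop("multi-sample TIFF directories are not supported (format error)")
      p <- p[, , 1]
    }
    if (is.null(bps)) bps <- 16L
    if (bps < 32L) {  # unsigned integer samples, normalized by readTIFF
      p <- round(p * (2^bps - 1))
      storage.mode(p) <- "double"
    }
    attributes(p) <- list(dim = dim(p))
    p
  })
  scale <- if (!is.null(meta$float_scale)) meta$float_scale else NULL
  offset <- if (!is.null(meta$float_offset)) meta$float_offset else 0
  if (!is.null(scale)) bands <- lapply(bands, function(b) b * scale + offset)
  if (is.null(band_ids) && !is.null(meta$band_ids) &&
      length(meta$band_ids) == length(bands)) band_ids <- meta$band_ids
  if (is.null(nodata) && !is.null(meta$nodata)) nodata <- meta$nodata
  if (!is.null(nodata) && !is.null(scale)) {
    # float storage is approximate; snap near-nodata values back to the sentinel
    tol <- max(abs(nodata), scale) * 1e-5
    bands <- lapply(bands, function(b) { b[abs(b - nodata) < tol] <- nodata; b })
  }
  multiband_scene(bands, band_ids = band_ids, nodata = nodata,
                  pixel_size = if (!is.null(meta$pixel_size)) meta$pixel_size else NA_real_,
                  units = if (!is.null(meta$units)) meta$units else "DN",
                  geo = meta$geo)
}

#' Write a multiband scene to a TIFF file
#'
#' Integer-valued digital-number scenes are stored losslessly as 16-bit
#' unsigned samples (one TIFF directory per band); reflectance or other
#' floating-point scenes are stored as 32-bit floats after an affine
#' rescale into `[0, 1]`. Band ids, units, nodata, pixel size, geographic
#' metadata and the float rescale are recorded in a JSON sidecar
#' (`<path minus extension>.json`) that [read_scene()] restores from.
#'
#' @param scene a [multiband_scene()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "mb_scene"))
  vals <- unlist(scene$bands, use.names = FALSE)
  integer_like <- all(vals == round(vals)) && min(vals) >= 0 && max(vals) <= 65535
  meta <- list(band_ids = scene$band_ids, units = scene$units,
               nodata = scene$nodata, pixel_size = scene$pixel_size,
               geo = scene$geo)
  if (integer_like) {
    tiff::writeTIFF(lapply(scene$bands, function(b) round(b) / 65535),
                    path, bits.per.sample = 16L)
  } else {
    off <- min(vals, 0)
    sc <- max(vals - off, 1e-12)
    meta$float_offset <- off
    meta$float_scale <- sc
    tiff::writeTIFF(lapply(scene$bands, function(b) (b - off) / sc),
                    path, bits.per.sample = 32L)
  }
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Clip a working window out of a scene
#'
#' Windows are half-open 0-based pixel rectangles: `rows = c(r0, r1)` keeps
#' rows `r0 <= r < r1`. The window is intersected with the scene bounds; an
#' empty intersection is an error. Band order and all metadata are
#' preserved, so clipping a clip equals clipping with the composed window.
#'
#' @param scene a [multiband_scene()].
#' @param rows,cols integer length-2 vectors `c(from, to)`, half-open.
#' @return The clipped [multiband_scene()].
#' @export
clip_scene <- function(scene, rows, cols) {
  stopifnot(inherits(scene, "mb_scene"), length(rows) == 2L, length(cols) == 2L)
  d <- dim(scene$bands[[1]])
  r0 <- max(rows[1], 0); r1 <- min(rows[2], d[1])
  c0 <- max(cols[1], 0); c1 <- min(cols[2], d[2])
  if (r0 >= r1 || c0 >= c1)
    stop("clip window does not intersect scene bounds")
  bands <- lapply(scene$bands, function(b) b[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE])
  multiband_scene(bands, band_ids = scene$band_ids, nodata = scene$nodata,
                  pixel_size = scene$pixel_size, units = scene$units,
                  geo = scene$geo)
}
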