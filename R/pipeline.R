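#' Run the full classification + covariance pipeline
#'
#' Drives the four-stage workflow from one configuration: (1) load or
#' simulate the scene and turn it into band matrices (optionally converted
#' to TOA reflectance), (2) derive signatures and class maps, (3)
#' column-stack each class into a pixel vector and estimate the auto- and
#' cross-covariance series, (4) normalize to correlation coefficients and
#' visualise. For a c-class run, stage 3 emits c auto-series named
#' `kfr1..kfrc` and all pairwise cross-series `kfrij` (i < j) as CSV
#' files with columns `k, K, r, count, sigma_r`.
#'
#' The configuration is a list (or a YAML/JSON file path) with:
#' \describe{
#'   \item{seed}{integer; seeds all randomness, making reruns
#'     byte-identical.}
#'   \item{out_dir}{output directory (created if missing).}
#'   \item{input}{either `scene`/`rois` file paths, or `simulate`: the
#'     fields of [scene_spec()].}
#'   \item{stages}{logical toggles `toa`, `classify`, `segment`,
#'     `covariance` (all but `toa` default on).}
#'   \item{toa}{TOA parameters as in [apply_toa()].}
#'   \item{classify}{`max_distance` (optional).}
#'   \item{segment}{`bands`, `low`, `high`, `min_area`, `smooth_window`
#'     (defaults B3/B4, 800, 1000, 5, none).}
#'   \item{covariance}{`band` (default first green-like band present, else
#'     first band), `kmax` (default n/2), `segment_count` (default 0 =
#'     skip the correlation matrix), `plots` (default FALSE).}
#' }
#'
#' A machine-readable report (`report.json`) records per-stage parameters
#' and MD5 hashes of every artifact. If a stage fails, files it already
#' wrote are renamed with a `.partial` suffix and the error names the
#' stage.
#'
#' @param config list or path to a YAML/JSON configuration.
#' @return The report, invisibly (also written to
#'   `out_dir/report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$out_dir)) stop("config needs an 'out_dir'")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- modifyList(list(toa = FALSE, classify = TRUE, segment = TRUE,
                            covariance = TRUE),
                       if (is.null(config$stages)) list() else config$stages)
  report <- list(seed = seed, stages = list(), artifacts = list())
  written <- character()
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      for (f in written[file.exists(written)])
        file.rename(f, paste0(f, ".partial"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  emit <- function(path) { written[length(written) + 1L] <<- path; path }

  # stage 1: image -> matrices
  truth <- NULL; rois <- NULL; scene <- NULL
  run_stage("input", function() {
    if (!is.null(config$input$simulate)) {
      sim <- config$input$simulate
      sim$seed <- if (is.null(sim$seed)) seed else sim$seed
      sim$classes <- lapply(sim$classes, function(cl) {
        cl$mean <- unlist(cl$mean); cl
      })
      spec <- do.call(scene_spec, sim)
      g <- generate_scene(spec)
      scene <<- g$scene; truth <<- g$truth; rois <<- g$rois
      report$stages$input <<- list(kind = "simulate", rows = spec$rows,
                                   cols = spec$cols, layout = spec$layout,
                                   seed = spec$seed)
    } else {
      if (is.null(config$input$scene)) stop("no input scene configured")
      scene <<- read_scene(config$input$scene)
      if (!is.null(config$input$rois)) rois <<- read_rois(config$input$rois)
      report$stages$input <<- list(kind = "files", scene = config$input$scene)
    }
  })
  if (isTRUE(stages$toa)) run_stage("toa", function() {
    scene <<- apply_toa(scene, config$toa)
    report$stages$toa <<- list(d = config$toa$d,
                               sun_elevation = config$toa$sun_elevation)
  }) else report$stages$toa <- list(skipped = TRUE)

  # stage 2: signatures + class maps
  sigs <- NULL; cmap <- NULL
  if (isTRUE(stages$classify)) run_stage("classify", function() {
    if (is.null(rois)) stop("classification requires ROIs")
    sigs <<- signatures_from_rois(scene, rois)
    write_signatures(sigs, emit(file.path(out_dir, "signatures.csv")))
    md <- config$classify$max_distance
    cmap <<- min_distance_classify(scene, sigs, max_distance = md)
    write_class_map(cmap, emit(file.path(out_dir, "classmap.tif")))
    emit(file.path(out_dir, "classmap.json"))
    st <- list(classes = names(sigs), max_distance = md)
    if (!is.null(truth)) {
      cm <- confusion(cmap, truth)
      st$overall_accuracy <- overall_accuracy(cm)
      st$kappa <- kappa_coefficient(cm)
    }
    report$stages$classify <<- st
  }) else report$stages$classify <- list(skipped = TRUE)

  if (isTRUE(stages$segment)) run_stage("segment", function() {
    sg <- modifyList(list(bands = c("B3", "B4"), low = 800, high = 1000,
                          min_area = 5L, smooth_window = NULL),
                     if (is.null(config$segment)) list() else config$segment)
    smap <- threshold_segment(scene, bands = unlist(sg$bands), low = sg$low,
                              high = sg$high, min_area = sg$min_area)
    if (!is.null(sg$smooth_window)) smap <- smooth_map(smap, sg$smooth_window)
    write_class_map(smap, emit(file.path(out_dir, "segmentmap.tif")))
    emit(file.path(out_dir, "segmentmap.json"))
    report$stages$segment <<- sg[c("bands", "low", "high", "min_area")]
  }) else report$stages$segment <- list(skipped = TRUE)

  # stages 3-4: pixel vectors -> covariance -> correlation + visualisation
  if (isTRUE(stages$covariance)) run_stage("covariance", function() {
    vmap <- if (!is.null(truth)) truth else cmap
    if (is.null(vmap)) stop("covariance stage requires a class map")
    cv <- modifyList(list(band = NULL, kmax = NULL, segment_count = 0L,
                          plots = FALSE),
                     if (is.null(config$covariance)) list() else config$covariance)
    if (is.null(cv$band))
      cv$band <- if ("B3" %in% scene$band_ids) "B3" else scene$band_ids[1]
    labs <- vmap$legend
    vecs <- lapply(labs, function(lab)
      detrend(extract_class_vector(scene, vmap, lab, band = unlist(cv$band))))
    names(vecs) <- labs
    series_files <- character()
    save_series <- function(s, name) {
      f <- emit(file.path(out_dir, paste0(name, ".csv")))
      write.csv(format(as.data.frame(s), digits = 15, trim = TRUE,
                       scientific = FALSE), f, row.names = FALSE, quote = FALSE)
      if (isTRUE(cv$plots)) {
        pf <- emit(file.path(out_dir, paste0(name, ".png")))
        grDevices::png(pf, width = 700, height = 450)
        plot(s, main = name)
        grDevices::dev.off()
      }
      series_files[length(series_files) + 1L] <<- basename(f)
    }
    for (i in seq_along(vecs)) {
      km <- if (is.null(cv$kmax)) NULL
            else min(cv$kmax, length(vecs[[i]]) %/% 2L)
      s <- normalize_series(covariance_series(vecs[[i]], kmax = km), vecs[[i]])
      save_series(s, paste0("kfr", i))
    }
    if (length(vecs) > 1L) {
      for (i in seq_len(length(vecs) - 1L)) for (j in (i + 1):length(vecs)) {
        n <- min(length(vecs[[i]]), length(vecs[[j]]))
        km <- min(if (is.null(cv$kmax)) n %/% 2L else cv$kmax, n %/% 2L)
        s <- suppressMessages(
          covariance_series(vecs[[i]], vecs[[j]], kmax = km))
        s <- normalize_series(s, vecs[[i]], vecs[[j]])
        save_series(s, paste0("kfr", i, j))
      }
    }
    if (cv$segment_count >= 1L && length(vecs) > 1L) {
      g <- suppressMessages(correlation_matrix(vecs, cv$segment_count))
      gf <- emit(file.path(out_dir, "correlation_matrix.csv"))
      write.csv(format(as.data.frame(g$values), digits = 15), gf, quote = FALSE)
      if (isTRUE(cv$plots)) {
        pf <- emit(file.path(out_dir, "correlation_matrix.png"))
        grDevices::png(pf, width = 600, height = 600)
        plot(g)
        grDevices::dev.off()
      }
    }
    report$stages$covariance <<- list(band = cv$band, kmax = cv$kmax,
                                      segment_count = cv$segment_count,
                                      series = series_files)
  }) else report$stages$covariance <- list(skipped = TRUE)

  arts <- written[file.exists(written)]
  report$artifacts <- lapply(stats::setNames(as.list(arts), basename(arts)),
                             function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(report)
}

#' Read a pipeline configuration file
#'
#' @param path YAML or JSON configuration (see [run_pipeline()]).
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = FALSE)
  else stop("run config must be YAML or JSON")
}
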