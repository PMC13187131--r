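#' Read and write Esri ASCII grid rasters
#'
#' Annual label maps, DEMs and zone rasters travel as Esri ASCII grid
#' (`.asc`), a plain-text raster format with a six-line header. Round-trips
#' preserve the grid, values and nodata.
#'
#' @param map Numeric/integer matrix (row 1 = northernmost row).
#' @param path File path.
#' @param nodata Nodata value written to the header.
#' @param cellsize Cell size (m).
#' @return `read_ascii_grid` returns the matrix (with `NA` for nodata);
#'   `write_ascii_grid` returns `path` invisibly.
#' @export
write_ascii_grid <- function(map, path, nodata = -9999, cellsize = 30) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(map)), paste("nrows", nrow(map)),
               "xllcorner 0", "yllcorner 0",
               paste("cellsize", cellsize),
               paste("NODATA_value", nodata)), con)
  m <- map
  m[is.na(m)] <- nodata
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  if (nrow(m) != vals[["nrows"]] || ncol(m) != vals[["ncols"]])
    stopf("grid dimensions do not match the header")
  m[m == vals[["nodata_value"]]] <- NA
  m
}

# year x pixel matrix (row-major pixels) -> per-year label matrices on the grid
maps_to_grids <- function(maps, nr, nc) {
  lapply(seq_len(nrow(maps)), function(yi) {
    matrix(maps[yi, ], nr, nc, byrow = TRUE)
  })
}

grid_to_row <- function(grid) as.integer(t(grid))

#' Read a pipeline run configuration
#'
#' Plain-text YAML holding the scene description (grid, cadence, events),
#' break-detection parameters, classifier settings, post-processing tables,
#' trend settings and estimation settings. Required top-level fields are
#' checked by name. The configuration round-trips losslessly through
#' [yaml::as.yaml()].
#'
#' @param path YAML file path.
#' @return A `run_config` list with `scene` (a [scene_config()]),
#'   `breaks` (a [break_params()]), `classifier`, `postprocess`, `trend`,
#'   `estimation` settings, and `seed`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build_run_config(raw)
}

build_run_config <- function(raw) {
  need <- c("scene", "breaks", "classifier", "trend", "estimation")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stopf("config missing field(s): %s", paste(miss, collapse = ", "))
  sc <- raw$scene
  events <- lapply(sc$events %||% list(), function(e) {
    event_spec(kind = e$kind, driver = e$driver, onset = e$onset,
               target = e$target, rows = unlist(e$rows), cols = unlist(e$cols),
               recovery = e$recovery, duration = e$duration,
               only_from = e$only_from)
  })
  tide <- if (!is.null(sc[["tide"]])) {
    cs <- do.call(rbind, lapply(sc[["tide"]]$constituents, as.data.frame))
    tide_model(sc[["tide"]]$mean_level %||% 0, cs)
  } else default_tide_model()
  scene_args <- sc[setdiff(names(sc), c("events", "tide"))]
  scene <- do.call(scene_config,
                   c(scene_args, list(events = events, tide = tide)))
  breaks <- do.call(break_params, raw$breaks %||% list())
  list(scene = scene, breaks = breaks,
       classifier = raw$classifier %||% list(),
       postprocess = raw$postprocess %||% list(),
       trend = raw$trend %||% list(),
       estimation = raw$estimation %||% list(),
       seed = raw$seed %||% 1L)
}
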