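#' Write a five-band reflectance scene as a TIFF
#'
#' Bands are stored as separate TIFF pages in the fixed order blue, green,
#' red, red-edge, NIR; a JSON sidecar (`<path>.json`) records the band
#' order and storage format. `format = "float32"` stores reflectance
#' directly; `format = "uint16"` stores `round(reflectance * 32768)` as
#' 16-bit integers, the convention of radiometrically calibrated
#' orthomosaic exports, and is rescaled to [0, 1] on read.
#'
#' @param scene an `ms_scene`.
#' @param path output TIFF path.
#' @param format `"float32"` (default) or `"uint16"`.
#' @return `path`, invisibly.
#' @export
write_scene_tiff <- function(scene, path, format = c("float32", "uint16")) {
  format <- match.arg(format)
  stopifnot(inherits(scene, "ms_scene"))
  refl <- scene$reflectance
  pages <- lapply(seq_len(dim(refl)[3]), function(b) refl[, , b])
  if (format == "float32") {
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    # writeTIFF maps [0,1] to 0..65535; pre-divide so stored int = round(r * 32768)
    pages <- lapply(pages, function(m) round(m * 32768) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  meta <- list(band_names = scene$band_names, format = format,
               scale = if (format == "uint16") 32768 else 1,
               year = scene$year)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a five-band reflectance scene written by [write_scene_tiff()]
#'
#' Restores reflectance in [0, 1]; 16-bit rasters are divided by their
#' recorded scale factor (32,768). Without a sidecar, `band_names` must be
#' supplied and the raster is assumed float reflectance.
#'
#' @param path TIFF path.
#' @param band_names override for the band order when no sidecar exists.
#' @return an `ms_scene`.
#' @export
read_scene_tiff <- function(path, band_names = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 5)
    stopf("expected a 5-band raster, got %d band(s)", length(pages))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else NULL
  if (is.null(meta) && is.null(band_names))
    stopf("no band-order sidecar (%s); pass band_names to override", side)
  bn <- band_names %||% meta$band_names
  if (!identical(as.character(bn), BAND_NAMES))
    stopf("band order must be %s", paste(BAND_NAMES, collapse = "/"))
  refl <- array(0, dim = c(dim(pages[[1]]), 5L),
                dimnames = list(NULL, NULL, BAND_NAMES))
  uint16 <- !is.null(meta) && identical(meta$format, "uint16")
  for (b in 1:5) {
    m <- pages[[b]]
    refl[, , b] <- if (uint16) round(m * 65535) / meta$scale else m
  }
  structure(list(reflectance = refl, band_names = BAND_NAMES,
                 year = meta$year %||% NA), class = "ms_scene")
}

#' Write / read a class-label raster as a single-band TIFF
#'
#' Integer codes (0 = unclassified, 1 = soil, 2 = stems_leaves, 3 = lint)
#' stored in an 8-bit page.
#'
#' @param labels integer matrix of class codes, or a `class_map`.
#' @param path TIFF path.
#' @return `path` (write) / integer matrix (read).
#' @export
write_labels_tiff <- function(labels, path) {
  if (inherits(labels, "class_map")) labels <- labels$labels
  tiff::writeTIFF(labels / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_labels_tiff
#' @export
read_labels_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Write polygons (plots, sampling points or ROIs) as GeoJSON
#'
#' Coordinates are in the raster's pixel coordinate system (x = column,
#' y = row, origin at the top-left corner). All non-geometry columns become
#' feature properties.
#'
#' @param polygons polygon data frame with a `coords` list-column, or an
#'   `roi_set` (converted to square polygons).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(polygons, path) {
  if (inherits(polygons, "roi_set")) {
    coords <- lapply(seq_len(nrow(polygons)), function(i)
      rect_coords(polygons$row[i], polygons$row[i] + polygons$size[i] - 1L,
                  polygons$col[i], polygons$col[i] + polygons$size[i] - 1L))
    polygons <- as.data.frame(polygons)
    polygons$coords <- coords
  }
  keep <- setdiff(names(polygons), "coords")
  features <- lapply(seq_len(nrow(polygons)), function(i) {
    cc <- polygons$coords[[i]]
    if (!all(cc[1, ] == cc[nrow(cc), ])) cc <- rbind(cc, cc[1, ])
    list(type = "Feature",
         properties = as.list(polygons[i, keep, drop = FALSE]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(cc)),
                                                   function(k) unname(cc[k, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons written by [write_polygons_geojson()]
#'
#' @param path GeoJSON path.
#' @return polygon data frame with property columns and a `coords`
#'   list-column.
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) stopf("not a GeoJSON FeatureCollection")
  rows <- lapply(gj$features, function(f) {
    props <- as.data.frame(f$properties, stringsAsFactors = FALSE)
    ring <- f$geometry$coordinates[[1]]
    props$coords <- list(do.call(rbind, lapply(ring, function(pt)
      c(x = pt[[1]], y = pt[[2]]))))
    props
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write / read the per-sampling-point SBW table as CSV
#'
#' Columns: `sample_id`, `plot_id`, `density`, `variety`, `year`, `sbw_g`.
#' An empty table reads back as zero records without error.
#'
#' @param sbw data frame with at least those columns.
#' @param path CSV path.
#' @return `path` (write) / data frame (read).
#' @export
write_sbw_csv <- function(sbw, path) {
  cols <- intersect(c("sample_id", "plot_id", "density", "variety", "year", "sbw_g"),
                    names(sbw))
  utils::write.csv(sbw[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sbw_csv
#' @export
read_sbw_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "sbw_g")
  if (nrow(df) && !all(need %in% names(df)))
    stopf("SBW table must contain columns %s", paste(need, collapse = ", "))
  df
}

#' Write a complete synthetic fixture bundle to a directory
#'
#' Writes the scene raster (+ JSON sidecar), label raster, ROI / plot /
#' sampling-point GeoJSON files and the SBW CSV, so the whole pipeline can
#' be re-run from files through the package readers.
#'
#' @param scene,truth,rois outputs of [generate_scene()] and
#'   [generate_rois()].
#' @param out_dir output directory (created if needed).
#' @param format scene storage format, see [write_scene_tiff()].
#' @return named vector of written paths.
#' @export
write_fixture_bundle <- function(scene, truth, rois, out_dir,
                                 format = c("float32", "uint16")) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory '%s'", out_dir)
  paths <- c(
    scene = file.path(out_dir, "scene.tif"),
    labels = file.path(out_dir, "labels.tif"),
    rois = file.path(out_dir, "rois.geojson"),
    plots = file.path(out_dir, "plots.geojson"),
    sampling_points = file.path(out_dir, "sampling_points.geojson"),
    sbw = file.path(out_dir, "sbw.csv")
  )
  write_scene_tiff(scene, paths[["scene"]], format = format)
  write_labels_tiff(truth$label_raster, paths[["labels"]])
  write_polygons_geojson(rois, paths[["rois"]])
  write_polygons_geojson(truth$plots, paths[["plots"]])
  write_polygons_geojson(truth$sampling_points, paths[["sampling_points"]])
  write_sbw_csv(truth$sbw, paths[["sbw"]])
  paths
}
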