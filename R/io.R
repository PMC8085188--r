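# File formats: GeoJSON region polygons, PNG images/masks/label rasters,
# CSV morphometry tables, JSON reports.

#' Write tessellation regions as GeoJSON
#'
#' One Polygon feature per region in pixel coordinates, with `region_id`,
#' `site` and `scale_um_per_px` in the properties; the image rectangle goes
#' in the top-level `bbox`.
#'
#' @param t A tessellation.
#' @param path Output `.geojson` path.
#' @export
write_regions_geojson <- function(t, path) {
  feats <- lapply(t$regions, function(r) {
    ring <- rbind(r$vertices, r$vertices[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(region_id = r$region_id,
                           site = as.numeric(r$site),
                           scale_um_per_px = t$scale),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) as.numeric(ring[i, ])))))
  })
  gj <- list(type = "FeatureCollection",
             bbox = c(0, 0, t$bbox[1], t$bbox[2]),
             features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read tessellation regions from GeoJSON
#'
#' @param path A file written by [write_regions_geojson()].
#' @return A tessellation.
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  bbox <- as.numeric(unlist(gj$bbox))[3:4]
  regions <- lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) as.numeric(unlist(p))))
    ring <- ring[-nrow(ring), , drop = FALSE]
    list(region_id = as.integer(f$properties$region_id),
         site = as.numeric(unlist(f$properties$site)),
         vertices = ring)
  })
  scale <- as.numeric(gj$features[[1]]$properties$scale_um_per_px)
  ord <- order(vapply(regions, function(r) r$region_id, 0L))
  regions <- regions[ord]
  sites <- tibble::tibble(
    region_id = vapply(regions, function(r) r$region_id, 0L),
    x = vapply(regions, function(r) r$site[1], 0),
    y = vapply(regions, function(r) r$site[2], 0))
  new_tessellation(bbox, sites, regions, scale)
}

#' Read a grayscale image (PNG/TIFF)
#'
#' RGB images are converted by luminance (0.2126 R + 0.7152 G + 0.0722 B).
#'
#' @param path `.png` or `.tif`/`.tiff` file.
#' @return Numeric matrix on the 0-255 scale.
#' @export
read_image <- function(path) {
  x <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' is required for TIFF input")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(x)) == 3) {
    x <- 0.2126 * x[, , 1] + 0.7152 * x[, , 2] + 0.0722 * x[, , 3]
  }
  x * 255
}

#' Write a grayscale image or binary mask as 8-bit PNG
#'
#' @param x Numeric matrix (0-255), logical matrix, or `binary_mask`
#'   (written as 0/255).
#' @param path Output path.
#' @export
write_image_png <- function(x, path) {
  g <- if (inherits(x, "binary_mask")) x$grid else x
  g <- if (is.logical(g)) g * 255 else g
  png::writePNG(pmin(pmax(g / 255, 0), 1), path)
  invisible(path)
}

#' Write an integer label raster as PNG
#'
#' Labels are split across the red (high byte) and green (low byte)
#' channels, giving a lossless 16-bit round trip through standard 8-bit RGB
#' PNG.
#'
#' @param labels Integer matrix (0-65535).
#' @param path Output path.
#' @export
write_labels_png <- function(labels, path) {
  stopifnot(max(labels) < 65536)
  arr <- array(0, c(nrow(labels), ncol(labels), 3))
  arr[, , 1] <- (labels %/% 256) / 255
  arr[, , 2] <- (labels %% 256) / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' Read an integer label raster written by [write_labels_png()]
#' @param path PNG path.
#' @return Integer matrix.
#' @export
read_labels_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2) return(matrix(as.integer(round(x * 255)), nrow(x), ncol(x)))
  matrix(as.integer(round(x[, , 1] * 255)) * 256L +
           as.integer(round(x[, , 2] * 255)), dim(x)[1], dim(x)[2])
}

#' Write a zone raster as 8-bit PNG
#'
#' Zone labels 0/1/2/3 map to intensities 0/85/170/255.
#'
#' @param zone_raster Integer matrix with values in 0..3 (or a `zonation`).
#' @param path Output path.
#' @export
write_zones_png <- function(zone_raster, path) {
  zr <- if (inherits(zone_raster, "zonation")) zone_raster$zone_raster else zone_raster
  png::writePNG(zr * 85 / 255, path)
  invisible(path)
}

#' Write a morphometry table as CSV
#'
#' Header: `region_id,side_count,area_mm2,circumcircle_diameter_mm,centroid_x,centroid_y`.
#'
#' @param x A `morphometry_report` or its `table`.
#' @param path Output CSV path.
#' @export
write_morphometry_csv <- function(x, path) {
  tab <- if (inherits(x, "morphometry_report")) x$table else x
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

report_as_list <- function(report, digits = 1) {
  if (inherits(report, "accuracy_report")) {
    list(
      type = "accuracy_report",
      pct_pt_zone1 = na_null(report$pct_pt_zone1),
      pct_gs_zone3 = na_null(report$pct_gs_zone3),
      total_accuracy = na_null(report$total_accuracy),
      pct_pt_zone1_display = na_null(round_or_null(report$pct_pt_zone1, digits)),
      pct_gs_zone3_display = na_null(round_or_null(report$pct_gs_zone3, digits)),
      total_accuracy_display = na_null(round_or_null(report$total_accuracy, digits)),
      n_portal_tracts = report$n_portal_tracts,
      n_lobules = na_null(report$n_lobules),
      warnings = if (is.na(report$pct_pt_zone1)) list("pct_pt_zone1 undefined: no portal tracts") else list()
    )
  } else if (inherits(report, "overlap_report")) {
    list(
      type = "overlap_report",
      overlap_def = report$overlap_def,
      mean_overlap = report$mean_overlap,
      mean_overlap_display = round(report$mean_overlap, digits),
      n_lobules = nrow(report$per_lobule),
      per_lobule = lapply(seq_len(nrow(report$per_lobule)), function(i)
        as.list(report$per_lobule[i, ]))
    )
  } else if (inherits(report, "morphometry_report")) {
    s <- report$summary
    list(
      type = "morphometry_report",
      n_regions = s$n_regions,
      mean_area_mm2 = na_null(s$mean_area_mm2),
      sd_area_mm2 = na_null(s$sd_area_mm2),
      mean_circumcircle_diameter_mm = na_null(s$mean_circumcircle_diameter_mm),
      median_circumcircle_diameter_mm = na_null(s$median_circumcircle_diameter_mm),
      histogram = lapply(seq_len(nrow(report$histogram)), function(i)
        as.list(report$histogram[i, ]))
    )
  } else {
    stop("unsupported report type")
  }
}

na_null <- function(x) if (is.null(x) || length(x) == 0 || is.na(x)) NULL else x
round_or_null <- function(x, digits) if (is.null(x) || is.na(x)) NULL else round(x, digits)

#' Write a report as JSON (stable key order, full precision)
#'
#' Emits raw floats alongside display-rounded companion fields; missing
#' percentages become `null` with a warnings entry.
#'
#' @param report An `accuracy_report`, `overlap_report` or
#'   `morphometry_report`.
#' @param path Output JSON path.
#' @param digits Display rounding.
#' @export
write_report_json <- function(report, path, digits = 1) {
  jsonlite::write_json(report_as_list(report, digits), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
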