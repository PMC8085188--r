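# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a tessellation into a vertex table
#'
#' @param x A tessellation.
#' @param ... Unused.
#' @return Tibble with one row per polygon vertex: `region_id`, `vertex`,
#'   `x`, `y`, `site_x`, `site_y`.
#' @export
tidy.tessellation <- function(x, ...) {
  purrr::map_dfr(x$regions, function(r) {
    tibble::tibble(region_id = r$region_id,
                   vertex = seq_len(nrow(r$vertices)),
                   x = r$vertices[, 1], y = r$vertices[, 2],
                   site_x = r$site[1], site_y = r$site[2])
  })
}

#' One-row summary of a tessellation
#'
#' @param x A tessellation.
#' @param ... Unused.
#' @return Tibble: `n_regions`, `bbox_width`, `bbox_height`,
#'   `scale_um_per_px`, `total_area_mm2`.
#' @export
glance.tessellation <- function(x, ...) {
  tibble::tibble(
    n_regions = length(x$regions),
    bbox_width = x$bbox[1], bbox_height = x$bbox[2],
    scale_um_per_px = x$scale,
    total_area_mm2 = sum(vapply(x$regions,
                                function(r) polygon_area(r$vertices, x$scale), 0)))
}

#' Tidy a zonation result
#' @param x A `zonation`.
#' @param ... Unused.
#' @return The per-region diagnostics tibble (`region_id`, `s`, `J`, zone
#'   areas in mm^2).
#' @export
tidy.zonation <- function(x, ...) x$regions

#' One-row summary of a zonation result
#' @param x A `zonation`.
#' @param ... Unused.
#' @export
glance.zonation <- function(x, ...) {
  tibble::tibble(
    n_regions = nrow(x$regions),
    zone1_mm2 = sum(x$regions$zone1_mm2),
    zone2_mm2 = sum(x$regions$zone2_mm2),
    zone3_mm2 = sum(x$regions$zone3_mm2),
    mean_s = mean(x$regions$s))
}

#' Tidy an overlap report
#' @param x An `overlap_report`.
#' @param ... Unused.
#' @export
tidy.overlap_report <- function(x, ...) x$per_lobule

#' @export
glance.overlap_report <- function(x, ...) {
  tibble::tibble(mean_overlap = x$mean_overlap,
                 n_lobules = nrow(x$per_lobule),
                 overlap_def = x$overlap_def)
}

#' @export
glance.accuracy_report <- function(x, ...) {
  tibble::tibble(pct_pt_zone1 = x$pct_pt_zone1,
                 pct_gs_zone3 = x$pct_gs_zone3,
                 total_accuracy = x$total_accuracy,
                 n_portal_tracts = x$n_portal_tracts)
}

#' Tidy a morphometry report (per-region records)
#' @param x A `morphometry_report`.
#' @param ... Unused.
#' @export
tidy.morphometry_report <- function(x, ...) x$table

#' @export
glance.morphometry_report <- function(x, ...) {
  tibble::as_tibble(x$summary)
}

#' Plot a tessellation
#'
#' @param object A tessellation.
#' @param ... Unused.
#' @return A ggplot: region polygons with their generating sites.
#' @export
autoplot.tessellation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$region_id)) +
    ggplot2::geom_polygon(fill = NA, colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(x = .data$site_x, y = .data$site_y),
                        colour = "red", size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Plot the side-count histogram of a morphometry report
#'
#' @param object A `morphometry_report`.
#' @param ... Unused.
#' @export
autoplot.morphometry_report <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = factor(.data$side_count), y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "polygon sides", y = "% of lobules") +
    ggplot2::theme_minimal()
}

#' Plot a zonation raster
#'
#' @param object A `zonation`.
#' @param max_px Downsampling cap on the longer image side (default 512).
#' @param ... Unused.
#' @export
autoplot.zonation <- function(object, max_px = 512, ...) {
  zr <- object$zone_raster
  step <- max(1L, ceiling(max(dim(zr)) / max_px))
  zr <- zr[seq(1, nrow(zr), by = step), seq(1, ncol(zr), by = step)]
  df <- tibble::tibble(
    x = rep(seq_len(ncol(zr)) - 1L, each = nrow(zr)),
    y = rep(seq_len(nrow(zr)) - 1L, times = ncol(zr)),
    zone = factor(as.vector(zr), levels = 0:3,
                  labels = c("outside", "zone 1", "zone 2", "zone 3")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$zone)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c("white", "#1b9e77", "#d95f02", "#7570b3")) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
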