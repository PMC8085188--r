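# Accuracy scoring against ground truth (septal overlap in pig-like tissue,
# zonal landmark accuracy in human-like tissue) and lobular morphometrics.

partition_labels <- function(x) {
  if (inherits(x, "tessellation")) return(rasterize_tessellation(x))
  if (inherits(x, "label_partition")) return(x$labels)
  if (is.matrix(x)) return(x)
  stop("expected a tessellation, label_partition or label matrix")
}

#' Per-lobule surface overlap against true lobule labels
#'
#' Each true lobule is matched greedily (largest intersection first, each
#' predicted region used at most once, ties to the lower ids) to a predicted
#' region; per-lobule overlap is either intersection-over-union (default) or
#' intersection-over-truth, in percent. The mean is unweighted across
#' lobules.
#'
#' @param pred A tessellation, `label_partition`, or integer label matrix.
#' @param truth Integer matrix of true lobule labels (0 = unscored).
#' @param overlap_def `"iou"` or `"intersection-over-truth"`.
#' @return List of class `overlap_report`: `per_lobule` tibble (`truth_id`,
#'   `pred_id`, `overlap_pct`), `mean_overlap` (percent).
#' @export
lobule_overlap <- function(pred, truth,
                           overlap_def = c("iou", "intersection-over-truth")) {
  overlap_def <- match.arg(overlap_def)
  p <- partition_labels(pred)
  stopifnot(all(dim(p) == dim(truth)))
  t_ids <- sort(unique(as.integer(truth[truth > 0])))
  if (length(t_ids) == 0) stop("truth labels are empty")
  p_ids <- sort(unique(as.integer(p[p > 0])))
  ti <- match(as.integer(truth), t_ids)
  pi <- match(as.integer(p), p_ids)
  ok <- !is.na(ti) & !is.na(pi)
  tab <- table(factor(ti[ok], levels = seq_along(t_ids)),
               factor(pi[ok], levels = seq_along(p_ids)))
  t_size <- tabulate(ti[!is.na(ti)], length(t_ids))
  p_size <- tabulate(pi[!is.na(pi)], length(p_ids))
  # greedy matching: biggest intersections first, deterministic ties
  inter <- as.data.frame(as.table(tab), stringsAsFactors = FALSE)
  names(inter) <- c("t", "p", "n")
  inter$t <- as.integer(inter$t); inter$p <- as.integer(inter$p)
  inter <- inter[inter$n > 0, , drop = FALSE]
  inter <- inter[order(-inter$n, inter$t, inter$p), , drop = FALSE]
  t_used <- logical(length(t_ids)); p_used <- logical(length(p_ids))
  match_p <- rep(NA_integer_, length(t_ids))
  match_n <- rep(0, length(t_ids))
  for (k in seq_len(nrow(inter))) {
    tt <- inter$t[k]; pp <- inter$p[k]
    if (t_used[tt] || p_used[pp]) next
    t_used[tt] <- TRUE; p_used[pp] <- TRUE
    match_p[tt] <- pp; match_n[tt] <- inter$n[k]
  }
  denom <- if (overlap_def == "iou") {
    t_size + ifelse(is.na(match_p), 0, p_size[ifelse(is.na(match_p), 1, match_p)]) - match_n
  } else {
    t_size
  }
  pct <- 100 * match_n / denom
  rep_tbl <- tibble::tibble(truth_id = t_ids,
                            pred_id = ifelse(is.na(match_p), NA_integer_,
                                             p_ids[ifelse(is.na(match_p), 1, match_p)]),
                            overlap_pct = pct)
  structure(list(per_lobule = rep_tbl, mean_overlap = mean(pct),
                 overlap_def = overlap_def),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> %d lobule(s), mean overlap %.1f%% (%s)\n",
              nrow(x$per_lobule), x$mean_overlap, x$overlap_def))
  invisible(x)
}

#' Zonal accuracy against portal-tract and GS landmarks
#'
#' Portal tracts should fall in zone 1 and GS-positive signal in zone 3:
#' `pct_pt_zone1` is the percentage of portal-tract points whose pixel is
#' labelled zone 1, `pct_gs_zone3` the percentage of GS-positive pixels
#' labelled zone 3 (both over the zone-covered area), and `total_accuracy`
#' their unweighted mean. With no portal tracts `pct_pt_zone1` is reported
#' missing and the total falls back to `pct_gs_zone3` with a warning.
#'
#' @param zonation A [zonate_tessellation()] result (or a 0/1/2/3 zone-label
#'   matrix).
#' @param ann An `annotation_set` with portal tracts.
#' @param gs_mask `binary_mask` of GS-positive signal.
#' @param regions Optional vector of region ids restricting the scored area
#'   (e.g. complete lobules only, excluding regions clipped by the field of
#'   view); requires a `zonation` object.
#' @return List of class `accuracy_report`: `pct_pt_zone1`, `pct_gs_zone3`,
#'   `total_accuracy`, `n_portal_tracts`, `n_lobules`.
#' @export
zonal_accuracy <- function(zonation, ann, gs_mask, regions = NULL) {
  zr <- if (inherits(zonation, "zonation")) zonation$zone_raster else zonation
  n_lob <- if (inherits(zonation, "zonation")) nrow(zonation$regions) else NA_integer_
  g <- mask_grid(gs_mask)
  stopifnot(all(dim(g) == dim(zr)))
  covered <- zr > 0L
  if (!is.null(regions)) {
    if (!inherits(zonation, "zonation"))
      stop("region restriction requires a zonation object")
    covered <- covered & (zonation$region_raster %in% regions)
    zr[!covered] <- 0L
    n_lob <- length(regions)
  }
  pt <- ann$portal_tracts
  if (nrow(pt) > 0) {
    rr <- pmin(pmax(round(pt$y), 0), nrow(zr) - 1) + 1L
    cc <- pmin(pmax(round(pt$x), 0), ncol(zr) - 1) + 1L
    lab <- zr[cbind(rr, cc)]
    in_cov <- lab > 0L
    pct_pt <- if (any(in_cov)) 100 * mean(lab[in_cov] == 1L) else NA_real_
    n_pt <- sum(in_cov)
  } else {
    pct_pt <- NA_real_
    n_pt <- 0L
  }
  gs_cov <- g & covered
  pct_gs <- if (any(gs_cov)) 100 * sum(zr == 3L & g) / sum(gs_cov) else NA_real_
  if (is.na(pct_pt)) {
    warning("no portal tracts in the covered area: total accuracy falls back to pct_gs_zone3")
    total <- pct_gs
  } else {
    total <- mean(c(pct_pt, pct_gs))
  }
  structure(list(pct_pt_zone1 = pct_pt, pct_gs_zone3 = pct_gs,
                 total_accuracy = total, n_portal_tracts = n_pt,
                 n_lobules = n_lob),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> PT in zone 1: %s%%; GS in zone 3: %s%%; total: %s%%\n",
              fmt_or_na(x$pct_pt_zone1), fmt_or_na(x$pct_gs_zone3),
              fmt_or_na(x$total_accuracy)))
  invisible(x)
}

fmt_or_na <- function(x) if (is.null(x) || is.na(x)) "NA" else sprintf("%.1f", x)

#' Shape histogram from per-region side counts
#'
#' @param side_counts Integer vector of polygon side counts.
#' @param digits Display rounding for the percentage column (default 1).
#' @return Tibble `side_count`, `n`, `pct` (raw), `pct_display` (rounded).
#' @export
shape_histogram <- function(side_counts, digits = 1) {
  tb <- table(side_counts)
  tibble::tibble(
    side_count = as.integer(names(tb)),
    n = as.integer(tb),
    pct = 100 * as.integer(tb) / length(side_counts),
    pct_display = round(100 * as.integer(tb) / length(side_counts), digits)
  )
}

#' Morphometry report for a tessellation
#'
#' Per-region side counts, areas and minimum-enclosing-circle diameters,
#' with the side-count histogram and summary statistics.
#'
#' @param t A tessellation.
#' @param angle_tol,merge_dist Passed to [side_count()].
#' @param digits Display rounding for histogram percentages.
#' @return List of class `morphometry_report`: `table` (per-region tibble),
#'   `histogram`, `summary` (n, mean/sd area mm^2, mean/median circumcircle
#'   diameter mm).
#' @export
morphometry_report <- function(t, angle_tol = 10, merge_dist = 2, digits = 1) {
  tab <- morphometry(t, angle_tol, merge_dist)
  structure(list(
    table = tab,
    histogram = shape_histogram(tab$side_count, digits),
    summary = list(
      n_regions = nrow(tab),
      mean_area_mm2 = mean(tab$area_mm2),
      sd_area_mm2 = stats::sd(tab$area_mm2),
      mean_circumcircle_diameter_mm = mean(tab$circumcircle_diameter_mm),
      median_circumcircle_diameter_mm = stats::median(tab$circumcircle_diameter_mm)
    )
  ), class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<morphometry_report> %d region(s); mean area %.3f mm^2 (SD %.3f); mean circumcircle diameter %.2f mm\n",
              s$n_regions, s$mean_area_mm2, s$sd_area_mm2,
              s$mean_circumcircle_diameter_mm))
  invisible(x)
}

#' Flag compound and small lobule regions
#'
#' Compound regions hold two or more GS component centroids (before any
#' splitting); small regions fall below the `small_quantile` area quantile
#' or have no matched GS component (tangential cuts or lobule tips).
#'
#' @param t A tessellation, or an integer label matrix of lobule regions
#'   (e.g. ground-truth labels, possibly with merged compound lobules).
#' @param gs A `component_set` of GS-positive areas.
#' @param small_quantile Area quantile below which a region is "small"
#'   (default 0.05).
#' @return List of class `special_lobules`: `compound_ids`, `small_ids`,
#'   `compound_fraction`, `small_fraction` (fractions of all regions).
#' @export
flag_special_lobules <- function(t, gs, small_quantile = 0.05) {
  cent <- cbind(gs$components$centroid_x, gs$components$centroid_y)
  if (is.matrix(t)) {
    ids <- sort(unique(as.integer(t[t > 0])))
    rr <- pmin(pmax(round(cent[, 2]), 0), nrow(t) - 1) + 1L
    cc <- pmin(pmax(round(cent[, 1]), 0), ncol(t) - 1) + 1L
    owner <- t[cbind(rr, cc)]
    areas <- vapply(ids, function(i) sum(t == i), 0L)
  } else {
    owner <- rep(NA_integer_, nrow(cent))
    for (r in t$regions) {
      un <- which(is.na(owner))
      if (!length(un)) break
      inside <- points_in_polygon(cent[un, 1], cent[un, 2], r$vertices)
      owner[un[inside]] <- r$region_id
    }
    ids <- vapply(t$regions, function(r) r$region_id, 0L)
    areas <- vapply(t$regions, function(r) abs(shoelace_signed(r$vertices)), 0)
  }
  n_per_region <- vapply(ids, function(i) sum(owner == i, na.rm = TRUE), 0L)
  thr <- stats::quantile(areas, small_quantile, names = FALSE)
  compound <- ids[n_per_region >= 2]
  small <- ids[areas < thr | n_per_region == 0]
  structure(list(compound_ids = compound, small_ids = small,
                 compound_fraction = length(compound) / length(ids),
                 small_fraction = length(small) / length(ids)),
            class = "special_lobules")
}

#' @export
print.special_lobules <- function(x, ...) {
  cat(sprintf("<special_lobules> compound: %d (%.1f%%); small: %d (%.1f%%)\n",
              length(x$compound_ids), 100 * x$compound_fraction,
              length(x$small_ids), 100 * x$small_fraction))
  invisible(x)
}
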