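# The five lobule-tessellation procedures: seeded (file-supplied sites),
# centroid, object-edge, modified object-edge, and the composed algorithm
# (centroid + compound splitting + landmark refinement under a bounded
# per-lobule mismatch).

#' Seeded tessellation from explicit central-vein sites
#'
#' The file-based, reproducible stand-in for interactive site placement:
#' the user supplies (and may iteratively edit) a site list; the diagram is
#' the bounded Voronoi partition of those sites.
#'
#' @inheritParams voronoi_partition
#' @return A tessellation.
#' @export
seeded_method <- function(sites, bbox, scale = 0.5) {
  voronoi_partition(sites, bbox, scale)
}

#' Centroid tessellation from a marker mask
#'
#' Labels the GS-positive mask (8-connectivity), discards components below
#' `min_area_px`, and takes the bounded Voronoi partition of the component
#' centroids. `region_id` equals the generating component label.
#'
#' @param gs_mask A `binary_mask` of marker-positive signal.
#' @param min_area_px Minimum component area in pixels.
#' @return A tessellation with attribute `components` (the generating
#'   `component_set`).
#' @export
centroid_method <- function(gs_mask, min_area_px = 50) {
  cs <- connected_components(gs_mask, min_area_px)
  tessellation_from_components(cs, dim_bbox(gs_mask), mask_scale(gs_mask))
}

dim_bbox <- function(mask) {
  g <- mask_grid(mask)
  c(ncol(g), nrow(g))
}

mask_scale <- function(mask) if (inherits(mask, "binary_mask")) mask$scale else 0.5

tessellation_from_components <- function(cs, bbox, scale) {
  if (nrow(cs$components) == 0) stop("no generating sites: mask has no components")
  t <- voronoi_partition(
    data.frame(x = cs$components$centroid_x, y = cs$components$centroid_y),
    bbox, scale)
  attr(t, "components") <- cs
  t
}

#' Generalized (object-edge) Voronoi-like partition
#'
#' Assigns every pixel to the connected object whose *boundary* (pixel set)
#' is nearest in Euclidean distance, via one exact distance transform per
#' object; ties go to the lowest object label and object pixels keep their
#' own label. With single-pixel objects this reduces to the ordinary
#' nearest-site Voronoi labelling.
#'
#' @param object_mask A `binary_mask` of the generating objects.
#' @param min_area_px Minimum object size in pixels (default 1: use the mask
#'   as given).
#' @return Object of class `label_partition`: `labels` (integer matrix),
#'   `generators` (`component_set`), `scale`.
#' @export
object_edge_method <- function(object_mask, min_area_px = 1) {
  cs <- connected_components(object_mask, min_area_px)
  k <- nrow(cs$components)
  if (k == 0) stop("no generating objects: mask is empty")
  h <- nrow(cs$labels); w <- ncol(cs$labels)
  best_d <- matrix(Inf, h, w)
  best_l <- matrix(0L, h, w)
  for (i in seq_len(k)) {
    obj <- cs$labels == i
    dm <- EBImage::imageData(EBImage::distmap(1 - obj))
    take <- dm < best_d
    best_d[take] <- dm[take]
    best_l[take] <- i
  }
  structure(list(labels = best_l, generators = cs, scale = mask_scale(object_mask)),
            class = "label_partition")
}

#' @export
print.label_partition <- function(x, ...) {
  cat(sprintf("<label_partition> %d x %d px, %d generator(s)\n",
              nrow(x$labels), ncol(x$labels), nrow(x$generators$components)))
  invisible(x)
}

#' Object-edge partition from a curated annotation mask
#'
#' Identical computation to [object_edge_method()]; the input is a manually
#' curated mask (GS-positive areas and central veins annotated as objects)
#' rather than raw threshold output, which removes noise-driven generators.
#'
#' @inheritParams object_edge_method
#' @param annotated_mask Curated `binary_mask`.
#' @return A `label_partition`.
#' @export
modified_object_edge_method <- function(annotated_mask, min_area_px = 1) {
  object_edge_method(annotated_mask, min_area_px)
}

# --- landmark refinement -----------------------------------------------------

tri_area <- function(a, b, c) {
  abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
}

# Proper intersection point of open segments, or NULL.
seg_intersection_point <- function(p1, p2, p3, p4) {
  d1 <- p2 - p1; d2 <- p4 - p3
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-14) return(NULL)
  t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
  u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
  eps <- 1e-12
  if (t <= eps || t >= 1 - eps || u <= eps || u >= 1 - eps) return(NULL)
  p1 + t * d1
}

# Exact symmetric-difference area between a simple polygon and the same
# polygon with one vertex moved: the even-odd interior of the closed curve
# prev -> old -> next -> new.
vertex_move_delta_area <- function(vp, vold, vn, vnew) {
  x1 <- seg_intersection_point(vp, vold, vn, vnew)
  if (!is.null(x1)) return(tri_area(x1, vold, vn) + tri_area(x1, vnew, vp))
  x2 <- seg_intersection_point(vold, vn, vnew, vp)
  if (!is.null(x2)) return(tri_area(vp, vold, x2) + tri_area(x2, vn, vnew))
  abs(shoelace_signed(rbind(vp, vold, vn, vnew)))
}

# Weld coincident region vertices into shared vertex ids.
weld_vertices <- function(t, tol = 1e-6) {
  keys <- character(0); coords <- matrix(numeric(0), 0, 2)
  region_vids <- vector("list", length(t$regions))
  for (i in seq_along(t$regions)) {
    v <- t$regions[[i]]$vertices
    ids <- integer(nrow(v))
    for (k in seq_len(nrow(v))) {
      key <- paste(round(v[k, 1] / tol) * tol, round(v[k, 2] / tol) * tol)
      m <- match(key, keys)
      if (is.na(m)) {
        keys <- c(keys, key)
        coords <- rbind(coords, v[k, ])
        m <- length(keys)
      }
      ids[k] <- m
    }
    region_vids[[i]] <- ids
  }
  list(coords = coords, region_vids = region_vids)
}

#' Refine a tessellation toward landmark points
#'
#' Deterministic depth-first refinement: vertices are visited in (y, x)
#' order; each vertex considers the unclaimed landmarks within `snap_radius`
#' (nearest first) and snaps to the first one that keeps, for every incident
#' region, the accumulated symmetric-difference area against the *original*
#' region below `max_mismatch` of the original area (and keeps the polygon
#' simple). Rejected candidates are backtracked; each landmark can be
#' claimed once.
#'
#' The accumulated bound sums exact per-move symmetric differences, which by
#' the triangle inequality is an upper bound on the true original-vs-final
#' mismatch, so the reported `per_region_mismatch` can never understate a
#' violation.
#'
#' @param t A tessellation.
#' @param landmarks Data frame with columns `x`, `y` (pixels): septal nodes
#'   or portal tracts.
#' @param max_mismatch Maximum allowed non-overlapping area fraction per
#'   region, in (0, 1] (default 0.05).
#' @param snap_radius_um Landmark capture radius in micrometres (default 150).
#' @return Object of class `refinement_result`: `tessellation` (adjusted),
#'   `per_region_mismatch` (fractions, original-area relative upper bounds),
#'   `moves_applied` (tibble `vertex_id`, `from_x`, `from_y`, `to_x`,
#'   `to_y`).
#' @export
refine_to_landmarks <- function(t, landmarks, max_mismatch = 0.05,
                                snap_radius_um = 150) {
  if (!(max_mismatch > 0 && max_mismatch <= 1))
    stop("max_mismatch must be in (0, 1]")
  lm <- if (is.null(landmarks) || nrow(as.data.frame(landmarks)) == 0) {
    matrix(numeric(0), 0, 2)
  } else as_site_matrix(landmarks)
  snap_px <- snap_radius_um / t$scale
  weld <- weld_vertices(t)
  coords <- weld$coords
  rv <- weld$region_vids
  orig_polys <- lapply(t$regions, function(r) r$vertices)
  orig_area <- vapply(orig_polys, function(v) abs(shoelace_signed(v)), 0)
  acc <- numeric(length(t$regions))
  # incident regions per vertex id
  incident <- vector("list", nrow(coords))
  for (i in seq_along(rv)) for (k in seq_along(rv[[i]])) {
    vid <- rv[[i]][k]
    incident[[vid]] <- rbind(incident[[vid]], c(i, k))
  }
  claimed <- rep(FALSE, nrow(lm))
  order_v <- order(coords[, 2], coords[, 1])
  moves <- list()
  cur_polys <- orig_polys
  for (vid in order_v) {
    if (nrow(lm) == 0) break
    p <- coords[vid, ]
    d <- sqrt((lm[, 1] - p[1])^2 + (lm[, 2] - p[2])^2)
    cand <- which(!claimed & d <= snap_px)
    if (!length(cand)) next
    cand <- cand[order(d[cand])]
    for (ci in cand) {
      target <- lm[ci, ]
      inc <- incident[[vid]]
      ok <- TRUE
      deltas <- numeric(nrow(inc))
      for (r in seq_len(nrow(inc))) {
        reg <- inc[r, 1]; pos <- inc[r, 2]
        poly <- cur_polys[[reg]]
        n <- nrow(poly)
        vp <- poly[if (pos == 1) n else pos - 1, ]
        vn <- poly[if (pos == n) 1L else pos + 1, ]
        deltas[r] <- vertex_move_delta_area(vp, poly[pos, ], vn, target)
        newpoly <- poly; newpoly[pos, ] <- target
        if (acc[reg] + deltas[r] > max_mismatch * orig_area[reg] ||
            !is_simple_polygon(newpoly)) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        for (r in seq_len(nrow(inc))) {
          reg <- inc[r, 1]; pos <- inc[r, 2]
          cur_polys[[reg]][pos, ] <- target
          acc[reg] <- acc[reg] + deltas[r]
        }
        moves[[length(moves) + 1]] <- c(vid, p, target)
        coords[vid, ] <- target
        claimed[ci] <- TRUE
        break
      }
    }
  }
  regions <- t$regions
  for (i in seq_along(regions)) regions[[i]]$vertices <- cur_polys[[i]]
  adj <- new_tessellation(t$bbox, t$sites, regions, t$scale)
  attr(adj, "refined") <- TRUE
  mv <- if (length(moves)) {
    m <- do.call(rbind, moves)
    tibble::tibble(vertex_id = as.integer(m[, 1]), from_x = m[, 2],
                   from_y = m[, 3], to_x = m[, 4], to_y = m[, 5])
  } else {
    tibble::tibble(vertex_id = integer(), from_x = numeric(),
                   from_y = numeric(), to_x = numeric(), to_y = numeric())
  }
  structure(list(tessellation = adj,
                 per_region_mismatch = acc / orig_area,
                 moves_applied = mv),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("<refinement_result> %d move(s), max per-region mismatch %.4f\n",
              nrow(x$moves_applied), max(c(0, x$per_region_mismatch))))
  invisible(x)
}

#' Split compound-lobule regions around separated marker centroids
#'
#' A region containing two or more GS component centroids that fall into
#' distinct single-linkage clusters at `min_separation_um` is replaced by the
#' Voronoi sub-partition of the region polygon generated by the cluster mean
#' centroids (clipped to the region, so sub-areas sum to the parent area).
#' Regions whose centroids are closer than the separation threshold - or
#' that hold at most one centroid - are untouched.
#'
#' @param t A tessellation.
#' @param gs A `component_set` of GS-positive areas.
#' @param min_separation_um Minimum centroid separation in micrometres
#'   (default 200).
#' @return A tessellation with regions renumbered 1..n in place.
#' @export
split_compound_regions <- function(t, gs, min_separation_um = 200) {
  cent <- cbind(gs$components$centroid_x, gs$components$centroid_y)
  # assign each centroid to the first (lowest-id) region containing it
  owner <- rep(NA_integer_, nrow(cent))
  for (r in t$regions) {
    un <- which(is.na(owner))
    if (!length(un)) break
    inside <- points_in_polygon(cent[un, 1], cent[un, 2], r$vertices)
    owner[un[inside]] <- r$region_id
  }
  sep_px <- min_separation_um / t$scale
  new_regions <- list()
  for (r in t$regions) {
    mine <- which(owner == r$region_id)
    split_sites <- NULL
    if (length(mine) >= 2) {
      cl <- stats::cutree(stats::hclust(stats::dist(cent[mine, , drop = FALSE]),
                                        method = "single"), h = sep_px)
      if (max(cl) >= 2) {
        split_sites <- t(vapply(seq_len(max(cl)), function(g)
          colMeans(cent[mine[cl == g], , drop = FALSE]), numeric(2)))
      }
    }
    if (is.null(split_sites)) {
      new_regions[[length(new_regions) + 1]] <- r
    } else {
      for (i in seq_len(nrow(split_sites))) {
        v <- r$vertices
        for (j in seq_len(nrow(split_sites))) {
          if (j == i) next
          a <- split_sites[j, ] - split_sites[i, ]
          b <- (sum(split_sites[j, ]^2) - sum(split_sites[i, ]^2)) / 2
          v <- clip_halfplane(v, a, b)
        }
        if (nrow(v) < 3) next
        new_regions[[length(new_regions) + 1]] <-
          list(region_id = NA_integer_, site = split_sites[i, ],
               vertices = ensure_ccw(v))
      }
    }
  }
  for (i in seq_along(new_regions)) new_regions[[i]]$region_id <- i
  sites <- tibble::tibble(
    region_id = seq_along(new_regions),
    x = vapply(new_regions, function(r) r$site[1], 0),
    y = vapply(new_regions, function(r) r$site[2], 0))
  out <- new_tessellation(t$bbox, sites, new_regions, t$scale)
  attr(out, "components") <- gs
  out
}

#' Full algorithmic tessellation: centroids, splitting, refinement
#'
#' Composes [centroid_method()] (Voronoi of GS component centroids),
#' [split_compound_regions()] and [refine_to_landmarks()] against septal or
#' portal-tract landmarks.
#'
#' @param gs_mask `binary_mask` of GS-positive signal.
#' @param landmarks Data frame with `x`, `y`, or `NULL` for no refinement.
#' @param min_area_px Component size floor for centroid extraction.
#' @param max_mismatch,snap_radius_um Passed to [refine_to_landmarks()].
#' @param min_separation_um Passed to [split_compound_regions()].
#' @return A `refinement_result`.
#' @export
algorithm_method <- function(gs_mask, landmarks = NULL, min_area_px = 50,
                             max_mismatch = 0.05, snap_radius_um = 150,
                             min_separation_um = 200) {
  cs <- connected_components(gs_mask, min_area_px)
  t <- tessellation_from_components(cs, dim_bbox(gs_mask), mask_scale(gs_mask))
  t <- split_compound_regions(t, cs, min_separation_um)
  refine_to_landmarks(t, landmarks, max_mismatch, snap_radius_um)
}
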