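# Exact 2D computational geometry: bounded Voronoi diagrams, Delaunay duals,
# and polygon morphometrics. All coordinates are 0-based pixel coordinates,
# x rightward, y downward, pixel centers at integers; a physical scale in
# micrometres per pixel is carried explicitly wherever areas or lengths are
# reported in physical units.

#' Construct a tessellation object
#'
#' A tessellation pairs a list of generating sites with one convex (or, after
#' refinement, simple) polygonal region per site, clipped to a bounding
#' rectangle `[0, width] x [0, height]` in pixel coordinates.
#'
#' @param bbox Numeric length-2, `c(width, height)` in pixels.
#' @param sites Tibble with columns `region_id`, `x`, `y`.
#' @param regions List of regions, each a list with elements `region_id`,
#'   `site` (length-2 numeric) and `vertices` (n x 2 matrix, counter-clockwise
#'   by signed shoelace in the x-right/y-down frame).
#' @param scale Physical scale in micrometres per pixel.
#' @return An object of class `tessellation`.
#' @export
new_tessellation <- function(bbox, sites, regions, scale = 0.5) {
  stopifnot(length(bbox) == 2, all(bbox > 0), is.data.frame(sites))
  structure(
    list(bbox = as.numeric(bbox), sites = tibble::as_tibble(sites),
         regions = regions, scale = as.numeric(scale)),
    class = "tessellation"
  )
}

#' @export
print.tessellation <- function(x, ...) {
  cat(sprintf("<tessellation> %d region(s), bbox %g x %g px, scale %g um/px\n",
              length(x$regions), x$bbox[1], x$bbox[2], x$scale))
  invisible(x)
}

# Signed shoelace area (positive for counter-clockwise order in the
# y-down frame used throughout).
shoelace_signed <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

ensure_ccw <- function(v) {
  if (shoelace_signed(v) < 0) v[rev(seq_len(nrow(v))), , drop = FALSE] else v
}

# Remove consecutive duplicate vertices (closure included).
dedup_vertices <- function(v, tol = 1e-9) {
  n <- nrow(v)
  if (n < 2) return(v)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (keep[i] && sqrt(sum((v[i, ] - v[j, ])^2)) < tol) keep[j] <- FALSE
  }
  v[keep, , drop = FALSE]
}

# Sutherland-Hodgman clip of polygon `v` against half-plane a . x <= b.
clip_halfplane <- function(v, a, b, tol = 1e-12) {
  n <- nrow(v)
  if (n == 0) return(v)
  d <- as.numeric(v %*% a) - b
  inside <- d <= tol
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) {
      out <- rbind(out, v[i, ])
      if (!inside[j]) {
        t <- d[i] / (d[i] - d[j])
        out <- rbind(out, v[i, ] + t * (v[j, ] - v[i, ]))
      }
    } else if (inside[j]) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, v[i, ] + t * (v[j, ] - v[i, ]))
    }
  }
  dedup_vertices(out)
}

bbox_polygon <- function(bbox) {
  w <- bbox[1]; h <- bbox[2]
  # counter-clockwise under positive shoelace in the y-down frame
  m <- matrix(c(0, 0, w, 0, w, h, 0, h), ncol = 2, byrow = TRUE)
  ensure_ccw(m)
}

as_site_matrix <- function(sites) {
  if (is.matrix(sites)) return(sites)
  if (is.data.frame(sites)) return(cbind(sites$x, sites$y))
  stop("sites must be a matrix or a data frame with columns x, y")
}

#' Bounded Voronoi partition of a rectangle
#'
#' Computes the Voronoi diagram of `sites` clipped to the rectangle
#' `[0, width] x [0, height]` by half-plane intersection: each region starts
#' as the full rectangle and is cut by the perpendicular bisector of its site
#' and every other site. Regions are convex, contain their site, and tile the
#' rectangle.
#'
#' @param sites Data frame with columns `x`, `y` (pixels) or an n x 2 matrix.
#' @param bbox `c(width, height)` in pixels.
#' @param scale Micrometres per pixel.
#' @return A [new_tessellation()] object with one region per site;
#'   `region_id` follows the input row order.
#' @examples
#' t <- voronoi_partition(data.frame(x = c(2, 8), y = c(5, 5)), c(10, 10))
#' sapply(t$regions, function(r) abs(shoelace_signed(r$vertices)))
#' @export
voronoi_partition <- function(sites, bbox, scale = 0.5) {
  s <- as_site_matrix(sites)
  n <- nrow(s)
  if (n < 1) stop("at least one site is required")
  if (any(!is.finite(s))) stop("sites must be finite")
  w <- bbox[1]; h <- bbox[2]
  out_of_box <- s[, 1] < 0 | s[, 1] > w | s[, 2] < 0 | s[, 2] > h
  if (any(out_of_box)) {
    stop(sprintf("site %d at (%g, %g) lies outside the bounding box",
                 which(out_of_box)[1], s[which(out_of_box)[1], 1],
                 s[which(out_of_box)[1], 2]))
  }
  if (n > 1) {
    dd <- as.matrix(stats::dist(s))
    diag(dd) <- Inf
    if (min(dd) < 1e-9) {
      p <- which(dd == min(dd), arr.ind = TRUE)[1, ]
      stop(sprintf("duplicate sites: %d and %d coincide", min(p), max(p)))
    }
  }
  box <- bbox_polygon(bbox)
  regions <- vector("list", n)
  for (i in seq_len(n)) {
    v <- box
    for (j in seq_len(n)) {
      if (j == i) next
      a <- s[j, ] - s[i, ]
      b <- (sum(s[j, ]^2) - sum(s[i, ]^2)) / 2
      v <- clip_halfplane(v, a, b)
      if (nrow(v) < 3) break
    }
    if (nrow(v) < 3) stop(sprintf("region %d degenerated during clipping", i))
    regions[[i]] <- list(region_id = i, site = s[i, ], vertices = ensure_ccw(v))
  }
  new_tessellation(bbox, tibble::tibble(region_id = seq_len(n),
                                        x = s[, 1], y = s[, 2]),
                   regions, scale)
}

#' Delaunay dual of a tessellation
#'
#' Returns the site-index pairs whose Voronoi regions share a boundary
#' segment of positive length within the bounding box - the (bounded)
#' Delaunay adjacency graph. Each region edge not on the box boundary is
#' equidistant from its own site and exactly one neighbour; adjacency is read
#' off the edge midpoints.
#'
#' @param t A [new_tessellation()] object with at least two sites.
#' @param tol Relative distance tolerance for equidistance testing.
#' @return Two-column integer matrix of site-index pairs (i < j).
#' @export
delaunay_dual <- function(t, tol = 1e-7) {
  n <- length(t$regions)
  if (n < 2) stop("at least two sites are required")
  s <- cbind(t$sites$x, t$sites$y)
  pairs <- matrix(integer(0), 0, 2)
  for (i in seq_len(n)) {
    v <- t$regions[[i]]$vertices
    m <- nrow(v)
    for (e in seq_len(m)) {
      p1 <- v[e, ]; p2 <- v[if (e == m) 1L else e + 1L, ]
      len <- sqrt(sum((p2 - p1)^2))
      if (len < 1e-9) next
      mid <- (p1 + p2) / 2
      di <- sqrt(sum((mid - s[i, ])^2))
      d_all <- sqrt(rowSums((s - matrix(mid, n, 2, byrow = TRUE))^2))
      cand <- which(abs(d_all - di) <= tol * max(di, 1) & seq_len(n) != i)
      if (length(cand)) {
        j <- cand[which.min(d_all[cand])]
        if (j > i) pairs <- rbind(pairs, c(i, j))
      }
    }
  }
  unique(pairs)
}

# Segment-pair proper/improper intersection test used by the simplicity check.
segments_intersect <- function(p1, p2, p3, p4, tol = 1e-12) {
  d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
  d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
  d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
  d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
  ((d1 > tol & d2 < -tol) | (d1 < -tol & d2 > tol)) &&
    ((d3 > tol & d4 < -tol) | (d3 < -tol & d4 > tol))
}

#' Test whether a polygon is simple (non-self-intersecting)
#'
#' @param v n x 2 vertex matrix.
#' @return Logical scalar.
#' @export
is_simple_polygon <- function(v) {
  v <- dedup_vertices(v)
  n <- nrow(v)
  if (n < 3) return(FALSE)
  nxt <- c(2:n, 1)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip edges sharing a vertex
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (segments_intersect(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ]))
        return(FALSE)
    }
  }
  TRUE
}

#' Polygon area in square millimetres
#'
#' Shoelace area of a simple polygon given in pixel coordinates, converted by
#' the physical scale: `area_px2 * (scale/1000)^2`.
#'
#' @param vertices n x 2 vertex matrix (pixels), or a region list with a
#'   `vertices` element.
#' @param scale Micrometres per pixel.
#' @return Area in mm^2.
#' @export
polygon_area <- function(vertices, scale = 0.5) {
  v <- if (is.list(vertices) && !is.null(vertices$vertices)) vertices$vertices else vertices
  v <- dedup_vertices(as.matrix(v))
  if (nrow(v) < 3) stop("polygon must have at least 3 distinct vertices")
  if (!is_simple_polygon(v)) stop("polygon is self-intersecting")
  abs(shoelace_signed(v)) * (scale / 1000)^2
}

#' Count the sides of a polygon after artifact suppression
#'
#' Collapses vertices closer than `merge_dist` pixels, then merges consecutive
#' edges whose turning angle is below `angle_tol` degrees (near-collinear
#' joints left behind by clipping or rasterization). Used for the shape
#' histograms of lobule polygons (triangles through octagons).
#'
#' @param vertices n x 2 vertex matrix (pixels) or a region list.
#' @param angle_tol Turning-angle threshold in degrees (default 10).
#' @param merge_dist Vertex-merge distance in pixels (default 2).
#' @return Integer side count (>= 3).
#' @export
side_count <- function(vertices, angle_tol = 10, merge_dist = 2) {
  v <- if (is.list(vertices) && !is.null(vertices$vertices)) vertices$vertices else vertices
  v <- as.matrix(v)
  # collapse runs of near-coincident vertices
  keep <- rep(TRUE, nrow(v))
  last <- 1L
  for (i in seq_len(nrow(v))[-1]) {
    if (sqrt(sum((v[i, ] - v[last, ])^2)) < merge_dist) keep[i] <- FALSE else last <- i
  }
  v <- v[keep, , drop = FALSE]
  if (nrow(v) >= 2 && sqrt(sum((v[1, ] - v[nrow(v), ])^2)) < merge_dist)
    v <- v[-nrow(v), , drop = FALSE]
  n <- nrow(v)
  if (n < 3 || abs(shoelace_signed(v)) < 1e-12) stop("degenerate polygon")
  turn <- numeric(n)
  for (i in seq_len(n)) {
    p0 <- v[if (i == 1) n else i - 1, ]
    p1 <- v[i, ]
    p2 <- v[if (i == n) 1L else i + 1, ]
    u <- p1 - p0; w <- p2 - p1
    ang <- acos(pmin(1, pmax(-1, sum(u * w) / (sqrt(sum(u^2)) * sqrt(sum(w^2))))))
    turn[i] <- ang * 180 / pi
  }
  sides <- sum(turn >= angle_tol)
  max(sides, 3L)
}

# Circle through three points; NULL if (near-)collinear.
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
}

# Welzl-style minimum enclosing circle, deterministic order (no shuffle);
# returns c(cx, cy, r) in the input units.
min_enclosing_circle <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n == 1) return(c(pts[1, ], 0))
  circle_from2 <- function(p, q) c((p + q) / 2, sqrt(sum((p - q)^2)) / 2)
  in_circle <- function(cir, p) sqrt(sum((p - cir[1:2])^2)) <= cir[3] * (1 + 1e-9) + 1e-12
  cir <- circle_from2(pts[1, ], pts[2, ])
  for (i in seq_len(n)) {
    if (in_circle(cir, pts[i, ])) next
    # i is on the boundary of the MEC of pts[1..i]
    cir <- circle_from2(pts[1, ], pts[i, ])
    for (j in seq_len(max(i - 1, 1))) {
      if (j >= i || in_circle(cir, pts[j, ])) next
      cir <- circle_from2(pts[i, ], pts[j, ])
      for (k in seq_len(max(j - 1, 1))) {
        if (k >= j || in_circle(cir, pts[k, ])) next
        cc <- circumcircle(pts[i, ], pts[j, ], pts[k, ])
        if (!is.null(cc)) cir <- cc
      }
    }
  }
  cir
}

#' Minimum enclosing circle diameter of a polygon, in millimetres
#'
#' The "circumcircle diameter" of a lobule polygon, operationalized as the
#' diameter of the smallest circle containing all vertices; for regular
#' polygons it equals the classical circumcircle diameter.
#'
#' @param vertices n x 2 vertex matrix (pixels) or a region list.
#' @param scale Micrometres per pixel.
#' @return Diameter in mm.
#' @export
min_enclosing_circle_diameter <- function(vertices, scale = 0.5) {
  v <- if (is.list(vertices) && !is.null(vertices$vertices)) vertices$vertices else vertices
  v <- as.matrix(v)
  if (nrow(v) < 3) stop("polygon must have at least 3 vertices")
  2 * min_enclosing_circle(v)[3] * scale / 1000
}

#' Area of a regular polygon from its circumcircle radius
#'
#' `(n/2) R^2 sin(2*pi/n)`, in mm^2 for `R` in mm. Used for the
#' regular-heptagon consistency check relating reported lobule radii
#' (0.49-0.65 mm) to expected lobule cross-sectional areas.
#'
#' @param n Number of sides (>= 3).
#' @param R Circumcircle radius in mm.
#' @return Area in mm^2.
#' @examples
#' regular_polygon_area(7, 0.57) # ~0.89 mm^2, a prototypical human lobule
#' @export
regular_polygon_area <- function(n, R) {
  if (n < 3) stop("a polygon needs at least 3 sides")
  if (any(R <= 0)) stop("R must be positive")
  (n / 2) * R^2 * sin(2 * pi / n)
}

#' Polygon centroid (area-weighted), pixel coordinates
#' @param vertices n x 2 vertex matrix.
#' @return Length-2 numeric `c(x, y)`.
#' @export
polygon_centroid <- function(vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  j <- c(2:n, 1)
  cr <- v[, 1] * v[j, 2] - v[j, 1] * v[, 2]
  a <- sum(cr) / 2
  c(sum((v[, 1] + v[j, 1]) * cr), sum((v[, 2] + v[j, 2]) * cr)) / (6 * a)
}

# Minimum distance from points (m x 2) to a polygon boundary.
dist_to_polygon_boundary <- function(pts, v) {
  v <- as.matrix(v)
  n <- nrow(v)
  best <- rep(Inf, nrow(pts))
  for (e in seq_len(n)) {
    p1 <- v[e, ]; p2 <- v[if (e == n) 1L else e + 1L, ]
    d <- p2 - p1
    len2 <- sum(d^2)
    if (len2 < 1e-18) next
    t <- ((pts[, 1] - p1[1]) * d[1] + (pts[, 2] - p1[2]) * d[2]) / len2
    t <- pmin(1, pmax(0, t))
    dx <- pts[, 1] - (p1[1] + t * d[1])
    dy <- pts[, 2] - (p1[2] + t * d[2])
    best <- pmin(best, sqrt(dx^2 + dy^2))
  }
  best
}

#' Region ids of complete (interior) lobules
#'
#' Regions with no vertex on the bounding rectangle, i.e. lobules not
#' clipped by the field of view.
#'
#' @param t A tessellation.
#' @param tol Distance to the rectangle treated as touching (pixels).
#' @return Integer vector of region ids.
#' @export
interior_regions <- function(t, tol = 1e-6) {
  which(vapply(t$regions, function(r) {
    v <- r$vertices
    all(v[, 1] > tol & v[, 1] < t$bbox[1] - tol &
          v[, 2] > tol & v[, 2] < t$bbox[2] - tol)
  }, TRUE))
}

#' Per-region morphometry of a tessellation
#'
#' @param t A tessellation.
#' @param angle_tol,merge_dist Passed to [side_count()].
#' @return Tibble with columns `region_id`, `side_count`, `area_mm2`,
#'   `circumcircle_diameter_mm`, `centroid_x`, `centroid_y`.
#' @export
morphometry <- function(t, angle_tol = 10, merge_dist = 2) {
  purrr::map_dfr(t$regions, function(r) {
    ctr <- polygon_centroid(r$vertices)
    tibble::tibble(
      region_id = r$region_id,
      side_count = side_count(r$vertices, angle_tol, merge_dist),
      area_mm2 = polygon_area(r$vertices, t$scale),
      circumcircle_diameter_mm = min_enclosing_circle_diameter(r$vertices, t$scale),
      centroid_x = ctr[1], centroid_y = ctr[2]
    )
  })
}
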