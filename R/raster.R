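# Rasterization of tessellations and polygons onto the image pixel grid.
# Pixel (row r, col c) of an H x W matrix has center (x = c-1, y = r-1).

#' Binary mask container
#'
#' @param grid Logical matrix (rows = y, cols = x), `TRUE` = marker-positive.
#' @param scale Micrometres per pixel.
#' @return Object of class `binary_mask`.
#' @export
new_binary_mask <- function(grid, scale = 0.5) {
  stopifnot(is.matrix(grid))
  structure(list(grid = matrix(as.logical(grid), nrow(grid), ncol(grid)),
                 scale = as.numeric(scale)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground, scale %g um/px\n",
              nrow(x$grid), ncol(x$grid), sum(x$grid), x$scale))
  invisible(x)
}

mask_grid <- function(m) if (inherits(m, "binary_mask")) m$grid else m

#' Points-in-polygon test (boundary inclusive)
#'
#' @param px,py Point coordinates.
#' @param v n x 2 polygon vertex matrix.
#' @return Logical vector.
#' @export
points_in_polygon <- function(px, py, v) {
  pracma::inpolygon(px, py, v[, 1], v[, 2], boundary = TRUE)
}

#' Rasterize a polygon to a logical pixel mask
#'
#' @param v n x 2 vertex matrix in pixel coordinates.
#' @param bbox `c(width, height)`; the mask is `height x width`.
#' @return Logical matrix; `TRUE` where the pixel center lies in the closed
#'   polygon.
#' @export
rasterize_polygon <- function(v, bbox) {
  w <- as.integer(bbox[1]); h <- as.integer(bbox[2])
  out <- matrix(FALSE, h, w)
  x0 <- max(0L, floor(min(v[, 1]))); x1 <- min(w - 1L, ceiling(max(v[, 1])))
  y0 <- max(0L, floor(min(v[, 2]))); y1 <- min(h - 1L, ceiling(max(v[, 2])))
  if (x1 < x0 || y1 < y0) return(out)
  xs <- x0:x1; ys <- y0:y1
  gx <- rep(xs, each = length(ys)); gy <- rep(ys, times = length(xs))
  inside <- points_in_polygon(gx, gy, v)
  out[cbind(gy[inside] + 1L, gx[inside] + 1L)] <- TRUE
  out
}

#' Region-label raster of a tessellation
#'
#' Assigns every pixel center to a region: regions are tested in increasing
#' `region_id` order with boundary-inclusive membership, so pixels on shared
#' boundaries deterministically take the lowest id. Pixel centers claimed by
#' no polygon (numerical boundary misses) fall back to the nearest site,
#' again with lowest-id ties.
#'
#' @param t A tessellation.
#' @return Integer matrix `height x width` of region ids (no zeros).
#' @export
rasterize_tessellation <- function(t) {
  w <- as.integer(t$bbox[1]); h <- as.integer(t$bbox[2])
  lab <- matrix(0L, h, w)
  for (r in t$regions) {
    v <- r$vertices
    x0 <- max(0L, floor(min(v[, 1]))); x1 <- min(w - 1L, ceiling(max(v[, 1])))
    y0 <- max(0L, floor(min(v[, 2]))); y1 <- min(h - 1L, ceiling(max(v[, 2])))
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1; ys <- y0:y1
    gx <- rep(xs, each = length(ys)); gy <- rep(ys, times = length(xs))
    idx <- cbind(gy + 1L, gx + 1L)
    open <- lab[idx] == 0L
    if (!any(open)) next
    inside <- points_in_polygon(gx[open], gy[open], v)
    sel <- idx[open, , drop = FALSE][inside, , drop = FALSE]
    lab[sel] <- r$region_id
  }
  if (any(lab == 0L)) {
    miss <- which(lab == 0L, arr.ind = TRUE)
    px <- miss[, 2] - 1; py <- miss[, 1] - 1
    s <- cbind(t$sites$x, t$sites$y)
    ids <- t$sites$region_id
    best_d <- rep(Inf, nrow(miss)); best_i <- rep(ids[1], nrow(miss))
    for (k in order(ids)) {
      d <- (px - s[k, 1])^2 + (py - s[k, 2])^2
      take <- d < best_d
      best_d[take] <- d[take]; best_i[take] <- ids[k]
    }
    lab[miss] <- best_i
  }
  lab
}

#' Nearest-site label raster (brute force definition)
#'
#' Labels each pixel center with the index of the nearest site, ties broken
#' by lowest site index. This is the defining property of a Voronoi
#' partition evaluated directly on the grid.
#'
#' @param sites Data frame/matrix of sites.
#' @param bbox `c(width, height)`.
#' @return Integer matrix `height x width`.
#' @export
nearest_site_labels <- function(sites, bbox) {
  s <- as_site_matrix(sites)
  w <- as.integer(bbox[1]); h <- as.integer(bbox[2])
  xs <- 0:(w - 1); ys <- 0:(h - 1)
  gx <- rep(xs, each = h); gy <- rep(ys, times = w)
  best_d <- rep(Inf, w * h); best_i <- rep(1L, w * h)
  for (k in seq_len(nrow(s))) {
    d <- (gx - s[k, 1])^2 + (gy - s[k, 2])^2
    take <- d < best_d
    best_d[take] <- d[take]; best_i[take] <- k
  }
  matrix(best_i, h, w)
}
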