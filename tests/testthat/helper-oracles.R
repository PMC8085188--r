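# Independent brute-force oracles and small fixture builders.

# Nearest-site labels by direct per-pixel loop over sites (ties -> lowest
# index); independent of both the polygon rasterizer and the vectorized
# streaming version in the package.
oracle_nearest_site <- function(sites, bbox) {
  s <- as.matrix(sites)
  w <- bbox[1]; h <- bbox[2]
  lab <- matrix(0L, h, w)
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      d2 <- (s[, 1] - (cc - 1))^2 + (s[, 2] - (r - 1))^2
      lab[r, cc] <- which.min(d2)  # which.min takes the first (lowest) index
    }
  }
  lab
}

# Per-pixel minimum distance to each object's pixel set (ties -> lowest
# label), looping objects and computing full distance fields directly.
oracle_object_edge <- function(comp_labels) {
  h <- nrow(comp_labels); w <- ncol(comp_labels)
  k <- max(comp_labels)
  gx <- rep(0:(w - 1), each = h); gy <- rep(0:(h - 1), times = w)
  best_d <- rep(Inf, h * w); best_l <- rep(0L, h * w)
  for (i in seq_len(k)) {
    idx <- which(comp_labels == i, arr.ind = TRUE)
    ox <- idx[, 2] - 1; oy <- idx[, 1] - 1
    d <- rep(Inf, h * w)
    for (j in seq_along(ox)) {
      d <- pmin(d, (gx - ox[j])^2 + (gy - oy[j])^2)
    }
    take <- d < best_d
    best_d[take] <- d[take]; best_l[take] <- i
  }
  matrix(best_l, h, w)
}

# Delaunay edges by the empty-circumcircle test over all site triples, plus
# the 2-site hull edge case.
oracle_delaunay_edges <- function(s) {
  n <- nrow(s)
  edges <- matrix(integer(0), 0, 2)
  if (n == 2) return(matrix(c(1L, 2L), 1))
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    cc <- lobulizer:::circumcircle(s[i, ], s[j, ], s[k, ])
    if (is.null(cc)) next
    d <- sqrt((s[, 1] - cc[1])^2 + (s[, 2] - cc[2])^2)
    others <- setdiff(seq_len(n), c(i, j, k))
    if (all(d[others] > cc[3] * (1 + 1e-9))) {
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
    }
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

# Smallest enclosing circle by exhaustive 2/3-point candidate search.
oracle_mec <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  best <- NULL
  contains_all <- function(c0, r) all(sqrt((pts[, 1] - c0[1])^2 + (pts[, 2] - c0[2])^2) <= r * (1 + 1e-9))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    c0 <- (pts[i, ] + pts[j, ]) / 2
    r <- sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2
    if (contains_all(c0, r) && (is.null(best) || r < best)) best <- r
  }
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      cc <- lobulizer:::circumcircle(pts[i, ], pts[j, ], pts[k, ])
      if (is.null(cc)) next
      if (contains_all(cc[1:2], cc[3]) && (is.null(best) || cc[3] < best)) best <- cc[3]
    }
  }
  best
}

# Monte-Carlo polygon area in pixel^2.
oracle_mc_area <- function(v, n = 2e5, seed = 99) {
  withr::with_seed(seed, {
    x0 <- min(v[, 1]); x1 <- max(v[, 1]); y0 <- min(v[, 2]); y1 <- max(v[, 2])
    px <- runif(n, x0, x1); py <- runif(n, y0, y1)
    mean(points_in_polygon(px, py, v)) * (x1 - x0) * (y1 - y0)
  })
}

# Clean synthetic field: the exact-model limit (no jitter, dropout, noise or
# blob irregularity), used for parameter-recovery checks.
clean_config <- function(size = 512, seed = 7, ...) {
  synthetic_config(image_size = c(size, size), scale = 8,
                   site_jitter_um = 0, gs_centroid_jitter_um = 0,
                   pt_vertex_jitter_um = 0, pt_dropout = 0,
                   compound_event = 0, noise_sigma = 0,
                   blob_irregularity = 0, rng_seed = seed, ...)
}

# A small disc-blob mask for segmentation-oriented tests.
disc_mask <- function(w, h, centers, radius) {
  g <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(centers))) {
    for (r in seq_len(h)) {
      dy2 <- (r - 1 - centers[i, 2])^2
      cols <- which((0:(w - 1) - centers[i, 1])^2 + dy2 <= radius^2)
      g[r, cols] <- TRUE
    }
  }
  g
}
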