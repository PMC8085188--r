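# Synthetic liver-tissue generator: Voronoi lobules from a (jittered)
# hexagonal lattice or Poisson point process, GS-positive blobs around
# central-vein sites, portal tracts at lobule vertices, interlobular septa
# (pig mode), compound-lobule merges and tangential small cuts, with full
# ground-truth layers for every pipeline stage.

#' Synthetic tissue configuration
#'
#' Defaults describe a field of roughly hexagonal lobules of mean
#' circumcircle diameter 1.2 mm, GS cuffs of 80-140 um mean radius around the
#' central veins, portal tracts near lobule vertices, and a compound-lobule
#' rate of 10 percent. The simulator grid is deliberately coarser
#' (8 um/px) than slide scans so whole-tissue fields stay small; zonal
#' geometry is scale-free.
#'
#' @param mode `"human"` (no septa) or `"pig"` (dark interlobular septa).
#' @param image_size Pixels, `c(width, height)`.
#' @param scale Micrometres per pixel.
#' @param lattice `"hex"` (jittered honeycomb) or `"poisson"`.
#' @param mean_lobule_diameter_um Mean lobule circumcircle diameter.
#' @param site_jitter_um Gaussian jitter SD of lattice sites.
#' @param gs_blob_radius_um Range (min, max) of GS blob mean radius.
#' @param gs_centroid_jitter_um Gaussian jitter SD of blob centers away from
#'   their site.
#' @param pt_vertex_jitter_um Gaussian jitter SD of portal tracts around
#'   lobule vertices.
#' @param pt_dropout Probability that a vertex has no portal tract.
#' @param septa_width_um Septal band width (pig mode).
#' @param compound_event Probability that a lobule merges with a neighbour
#'   into a compound lobule in the truth labels.
#' @param noise_sigma Gaussian intensity noise SD (8-bit scale).
#' @param background_level,gs_level,septa_level 8-bit intensities.
#' @param blob_irregularity Relative amplitude of the star-convex radial
#'   perturbation of GS blobs.
#' @param rng_seed Integer seed; identical config + seed reproduce the run.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(mode = c("human", "pig"),
                             image_size = c(1024, 1024),
                             scale = 8,
                             lattice = c("hex", "poisson"),
                             mean_lobule_diameter_um = 1200,
                             site_jitter_um = 100,
                             gs_blob_radius_um = c(80, 140),
                             gs_centroid_jitter_um = 0,
                             pt_vertex_jitter_um = 20,
                             pt_dropout = 0.05,
                             septa_width_um = 30,
                             compound_event = 0.1,
                             noise_sigma = 10,
                             background_level = 40,
                             gs_level = 200,
                             septa_level = 15,
                             blob_irregularity = 0.1,
                             rng_seed = 1) {
  mode <- match.arg(mode)
  lattice <- match.arg(lattice)
  stopifnot(pt_dropout >= 0, pt_dropout <= 1,
            compound_event >= 0, compound_event <= 1,
            scale > 0, mean_lobule_diameter_um > 0,
            all(gs_blob_radius_um > 0), noise_sigma >= 0)
  if (max(gs_blob_radius_um) >= mean_lobule_diameter_um / 2)
    stop("infeasible geometry: GS blob radius must be smaller than the lobule radius")
  structure(as.list(environment()), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> %s, %d x %d px at %g um/px, %s lattice, seed %d\n",
              x$mode, x$image_size[1], x$image_size[2], x$scale, x$lattice,
              x$rng_seed))
  invisible(x)
}

# Radial distance from an interior point to a convex polygon boundary along
# each angle.
polygon_radius_at_angles <- function(poly, center, theta) {
  n <- nrow(poly)
  ux <- cos(theta); uy <- sin(theta)
  best <- rep(Inf, length(theta))
  for (e in seq_len(n)) {
    p1 <- poly[e, ]; p2 <- poly[if (e == n) 1L else e + 1L, ]
    d <- p2 - p1
    den <- ux * (-d[2]) - uy * (-d[1])
    q <- p1 - center
    t <- (q[1] * (-d[2]) - q[2] * (-d[1])) / den
    s <- (ux * q[2] - uy * q[1]) / den
    ok <- is.finite(t) & t > 0 & s >= -1e-9 & s <= 1 + 1e-9
    best[ok] <- pmin(best[ok], t[ok])
  }
  best
}

# Star-convex GS blob: a shrunken copy of the lobule profile around the
# central-vein site (the perivenular core of the model), with a low-order
# radial Fourier perturbation; 48 vertices.
star_blob <- function(region_poly, center, r_px, irregularity, n_pts = 48) {
  theta <- seq(0, 2 * pi, length.out = n_pts + 1)[-(n_pts + 1)]
  R <- polygon_radius_at_angles(region_poly, center, theta)
  s <- r_px / mean(R[is.finite(R)])
  pert <- 1 + irregularity * (
    stats::runif(1, -1, 1) * cos(2 * theta + stats::runif(1, 0, 2 * pi)) +
    stats::runif(1, -1, 1) * cos(3 * theta + stats::runif(1, 0, 2 * pi)))
  r <- pmin(s * pert, 0.95) * R
  cbind(center[1] + r * cos(theta), center[2] + r * sin(theta))
}

hex_lattice_sites <- function(bbox, pitch_px) {
  dy <- pitch_px * sqrt(3) / 2
  rows <- seq(dy / 2, bbox[2] - 1, by = dy)
  out <- list()
  for (i in seq_along(rows)) {
    off <- if (i %% 2 == 0) pitch_px / 2 else 0
    xs <- seq(pitch_px / 2 + off, bbox[1] - 1, by = pitch_px)
    out[[i]] <- cbind(xs, rows[i])
  }
  do.call(rbind, out)
}

#' Generate a synthetic tissue field with ground truth
#'
#' Sites are a jittered hexagonal lattice (or Poisson process) at the
#' density implied by the configured lobule diameter; the true lobules are
#' their bounded Voronoi regions. GS blobs are star-convex shapes at
#' (optionally jittered) sites; portal tracts sit at interior lobule
#' vertices with dropout; pig mode paints septal bands along region edges;
#' compound events merge a lobule with a random neighbour in the truth
#' labels while keeping both GS blobs.
#'
#' @param config A [synthetic_config()].
#' @return List of class `ground_truth`: `image` (8-bit numeric matrix),
#'   `gs_truth_mask` (`binary_mask`), `true_sites` (tibble),
#'   `true_tessellation`, `true_lobule_labels` (integer matrix, after
#'   compound merges), `annotations` (`annotation_set`), `septa_mask` (pig
#'   mode), `compound_pairs` (tibble), `interior_ids`, `blob_polys`,
#'   `blob_dirs`, `config`.
#' @export
generate_tissue <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$rng_seed)
  bbox <- config$image_size
  sc <- config$scale
  pitch_px <- config$mean_lobule_diameter_um * sqrt(3) / 2 / sc
  if (config$lattice == "hex") {
    s <- hex_lattice_sites(bbox, pitch_px)
    if (config$site_jitter_um > 0) {
      s <- s + matrix(stats::rnorm(length(s), 0, config$site_jitter_um / sc),
                      ncol = 2)
    }
  } else {
    cell_area <- sqrt(3) / 2 * pitch_px^2
    n <- max(1, stats::rpois(1, prod(bbox) / cell_area))
    s <- cbind(stats::runif(n, 0, bbox[1]), stats::runif(n, 0, bbox[2]))
  }
  keep <- s[, 1] > 0 & s[, 1] < bbox[1] & s[, 2] > 0 & s[, 2] < bbox[2]
  s <- s[keep, , drop = FALSE]
  t <- voronoi_partition(s, bbox, sc)
  labels <- rasterize_tessellation(t)
  n <- nrow(s)

  # complete lobules: regions not clipped by the field of view
  interior_ids <- interior_regions(t)

  # GS blobs: one per site, center jittered along a stored unit direction so
  # corruption levels can be applied coherently later
  ang <- stats::runif(n, 0, 2 * pi)
  blob_dirs <- cbind(cos(ang), sin(ang))
  jit_mag <- if (config$gs_centroid_jitter_um > 0)
    abs(stats::rnorm(n, 0, config$gs_centroid_jitter_um / sc)) else numeric(n)
  r_px <- stats::runif(n, config$gs_blob_radius_um[1],
                       config$gs_blob_radius_um[2]) / sc
  blob_polys <- lapply(seq_len(n), function(i) {
    star_blob(t$regions[[i]]$vertices, s[i, ] + blob_dirs[i, ] * jit_mag[i],
              r_px[i], config$blob_irregularity)
  })
  gs <- raster_blobs(blob_polys, bbox)

  # compound events: merge region with a random unused Delaunay neighbour
  adj <- if (n >= 2) delaunay_dual(t) else matrix(integer(0), 0, 2)
  merged_into <- seq_len(n)
  used <- logical(n)
  compound <- list()
  if (config$compound_event > 0 && nrow(adj) > 0) {
    # each merge removes one lobule from the final count, so the internal
    # draw rate is deflated to keep the expected *final* compound fraction
    # at the configured value
    q <- config$compound_event / (1 + config$compound_event / 2)
    for (i in seq_len(n)) {
      if (used[i]) next
      if (stats::runif(1) >= q) next
      nbr <- c(adj[adj[, 1] == i, 2], adj[adj[, 2] == i, 1])
      nbr <- nbr[!used[nbr] & nbr != i]
      if (!length(nbr)) next
      j <- nbr[sample.int(length(nbr), 1)]
      used[i] <- used[j] <- TRUE
      merged_into[j] <- i
      compound[[length(compound) + 1]] <- c(i, j)
    }
  }
  true_labels <- matrix(merged_into[labels], nrow(labels), ncol(labels))

  # portal tracts at welded interior vertices, jittered, with dropout
  weld <- weld_vertices(t)
  vb <- weld$coords
  inner <- vb[, 1] > 1e-6 & vb[, 1] < bbox[1] - 1e-6 &
    vb[, 2] > 1e-6 & vb[, 2] < bbox[2] - 1e-6
  pts <- vb[inner, , drop = FALSE]
  if (nrow(pts) > 0) {
    keep_pt <- stats::runif(nrow(pts)) >= config$pt_dropout
    pts <- pts[keep_pt, , drop = FALSE]
    if (config$pt_vertex_jitter_um > 0 && nrow(pts) > 0) {
      pts <- pts + matrix(stats::rnorm(length(pts), 0,
                                       config$pt_vertex_jitter_um / sc), ncol = 2)
      pts[, 1] <- pmin(pmax(pts[, 1], 0), bbox[1] - 1)
      pts[, 2] <- pmin(pmax(pts[, 2], 0), bbox[2] - 1)
    }
  }

  septa <- NULL
  if (config$mode == "pig") {
    septa <- septa_band(labels, config$septa_width_um / sc)
  }

  img <- matrix(config$background_level, bbox[2], bbox[1])
  img[gs] <- config$gs_level
  if (!is.null(septa)) img[septa & !gs] <- config$septa_level
  if (config$noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, config$noise_sigma),
                        nrow(img), ncol(img))
  }
  img <- pmin(pmax(img, 0), 255)

  ann <- new_annotation_set(
    portal_tracts = tibble::tibble(x = pts[, 1], y = pts[, 2]),
    central_veins = tibble::tibble(x = s[, 1], y = s[, 2]),
    septa_mask = if (!is.null(septa)) new_binary_mask(septa, sc) else NULL,
    true_lobule_labels = true_labels)

  structure(list(
    image = img,
    gs_truth_mask = new_binary_mask(gs, sc),
    true_sites = t$sites,
    true_tessellation = t,
    true_lobule_labels = true_labels,
    annotations = ann,
    septa_mask = if (!is.null(septa)) new_binary_mask(septa, sc) else NULL,
    compound_pairs = if (length(compound)) {
      m <- do.call(rbind, compound)
      tibble::tibble(keep_id = m[, 1], merged_id = m[, 2])
    } else tibble::tibble(keep_id = integer(), merged_id = integer()),
    interior_ids = interior_ids,
    blob_polys = blob_polys,
    blob_dirs = blob_dirs,
    config = config
  ), class = "ground_truth")
}

raster_blobs <- function(blob_polys, bbox) {
  gs <- matrix(FALSE, bbox[2], bbox[1])
  for (bp in blob_polys) gs <- gs | rasterize_polygon(bp, bbox)
  gs
}

# Band of pixels within width_px/2 of a label boundary.
septa_band <- function(labels, width_px) {
  h <- nrow(labels); w <- ncol(labels)
  edge <- matrix(FALSE, h, w)
  edge[, -w] <- edge[, -w] | (labels[, -w] != labels[, -1])
  edge[, -1] <- edge[, -1] | (labels[, -w] != labels[, -1])
  edge[-h, ] <- edge[-h, ] | (labels[-h, ] != labels[-1, ])
  edge[-1, ] <- edge[-1, ] | (labels[-h, ] != labels[-1, ])
  if (width_px <= 1) return(edge)
  dm <- EBImage::imageData(EBImage::distmap(1 - edge))
  dm <= width_px / 2
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d lobule site(s), %d portal tract(s), %d compound pair(s)\n",
              nrow(x$true_sites), nrow(x$annotations$portal_tracts),
              nrow(x$compound_pairs)))
  invisible(x)
}

#' Apply graded corruption to a synthetic field
#'
#' Shifts every GS blob along its pre-drawn unit direction by
#' `gs_jitter_um`, applies extra portal-tract dropout and extra intensity
#' noise, and re-renders the image and GS mask. Truth layers are unchanged
#' except for the dropped portal tracts, and jitter levels are coupled (the
#' same directions at every level), so degradation curves are monotone in
#' the level by construction.
#'
#' @param gt A [generate_tissue()] result.
#' @param gs_jitter_um Blob displacement in micrometres.
#' @param pt_dropout Extra dropout probability in `[0, 1]`.
#' @param noise_sigma Extra Gaussian intensity noise SD.
#' @param seed Seed for the dropout/noise draws (default: the generating
#'   seed + 1).
#' @return A `ground_truth` with updated `image`, `gs_truth_mask`,
#'   `annotations`, `blob_polys`.
#' @export
corrupt <- function(gt, gs_jitter_um = 0, pt_dropout = 0, noise_sigma = 0,
                    seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  if (gs_jitter_um == 0 && pt_dropout == 0 && noise_sigma == 0) return(gt)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(if (is.null(seed)) gt$config$rng_seed + 1L else seed)
  sc <- gt$config$scale
  bbox <- gt$config$image_size
  shift_px <- gs_jitter_um / sc
  polys <- lapply(seq_along(gt$blob_polys), function(i) {
    sweep(gt$blob_polys[[i]], 2, gt$blob_dirs[i, ] * shift_px, `+`)
  })
  gs <- raster_blobs(polys, bbox)
  img <- matrix(gt$config$background_level, bbox[2], bbox[1])
  img[gs] <- gt$config$gs_level
  if (!is.null(gt$septa_mask)) img[gt$septa_mask$grid & !gs] <- gt$config$septa_level
  sigma <- sqrt(gt$config$noise_sigma^2 + noise_sigma^2)
  if (sigma > 0) img <- img + matrix(stats::rnorm(length(img), 0, sigma),
                                     nrow(img), ncol(img))
  img <- pmin(pmax(img, 0), 255)
  pt <- gt$annotations$portal_tracts
  if (pt_dropout > 0 && nrow(pt) > 0) {
    pt <- pt[stats::runif(nrow(pt)) >= pt_dropout, , drop = FALSE]
  }
  out <- gt
  out$image <- img
  out$gs_truth_mask <- new_binary_mask(gs, sc)
  out$blob_polys <- polys
  out$annotations <- new_annotation_set(
    portal_tracts = pt, central_veins = gt$annotations$central_veins,
    septa_mask = gt$annotations$septa_mask,
    true_lobule_labels = gt$annotations$true_lobule_labels)
  out
}
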