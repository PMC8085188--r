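# Raster preprocessing mirroring a standard immunostain workflow:
# 8-bit conversion, isodata (iterative intermeans) thresholding, 3x3 median
# despeckling, 8-connected component labelling with centroid extraction.

#' Threshold a grayscale marker image
#'
#' The image is rescaled to 8-bit (min -> 0, max -> 255), a threshold is
#' computed by the iterative intermeans (isodata-variant) rule on the 256-bin
#' histogram, and the marker-positive side becomes the mask foreground.
#' Because of the initial rescaling the mask is invariant to affine intensity
#' transforms of the input.
#'
#' @param image Numeric matrix (any range).
#' @param polarity `"bright"` if the marker is brighter than background
#'   (synthetic images), `"dark"` for brightfield DAB-like stains.
#' @param scale Micrometres per pixel, carried into the mask.
#' @return A [new_binary_mask()].
#' @export
threshold_marker <- function(image, polarity = c("bright", "dark"), scale = 0.5) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(image))
  rng <- range(image)
  if (diff(rng) == 0) stop("no threshold exists: image is constant")
  v8 <- round((image - rng[1]) / diff(rng) * 255)
  counts <- tabulate(as.integer(v8) + 1L, nbins = 256L)
  levels <- 0:255
  t <- isodata_threshold(counts, levels)
  fg <- if (polarity == "bright") v8 > t else v8 <= t
  new_binary_mask(fg, scale)
}

# Iterative intermeans: threshold t; means of the two classes are averaged
# and the process repeated to a fixed point.
isodata_threshold <- function(counts, levels) {
  t <- sum(counts * levels) / sum(counts)  # start at the global mean
  repeat {
    lo <- levels <= t
    if (!any(counts[lo]) || !any(counts[!lo])) {
      # all mass on one side: fall back to midpoint of occupied range
      occ <- range(levels[counts > 0])
      return(mean(occ))
    }
    m_lo <- sum(counts[lo] * levels[lo]) / sum(counts[lo])
    m_hi <- sum(counts[!lo] * levels[!lo]) / sum(counts[!lo])
    t_new <- (m_lo + m_hi) / 2
    if (abs(t_new - t) < 0.5) return(t_new)
    t <- t_new
  }
}

#' Despeckle a binary mask (3x3 median filter)
#'
#' One pass of a 3x3 median, which for a binary image is a 5-of-9 majority
#' vote; edges are handled by replication. Removes isolated noise pixels
#' while leaving solid blobs intact.
#'
#' @param mask A [new_binary_mask()] or logical matrix.
#' @return A `binary_mask` of the same shape.
#' @export
despeckle <- function(mask) {
  g <- mask_grid(mask)
  h <- nrow(g); w <- ncol(g)
  acc <- matrix(0L, h, w)
  ri <- function(i) pmin(pmax(i, 1L), h)
  ci <- function(j) pmin(pmax(j, 1L), w)
  for (dr in -1:1) for (dc in -1:1) {
    acc <- acc + g[ri(seq_len(h) + dr), ci(seq_len(w) + dc)]
  }
  out <- acc >= 5L
  new_binary_mask(out, if (inherits(mask, "binary_mask")) mask$scale else 0.5)
}

#' 8-connected components with centroids
#'
#' Labels foreground with 8-connectivity, discards components smaller than
#' `min_area_px`, and reports each component's pixel count and centroid
#' (mean of member pixel centers, 0-based x/y). Labels are renumbered
#' 1..k in order of first (column-major) foreground pixel.
#'
#' @param mask A `binary_mask` or logical matrix.
#' @param min_area_px Minimum component size in pixels (default 50).
#' @return List of class `component_set`: `labels` (integer matrix, 0 =
#'   background) and `components` (tibble `label`, `pixel_count`,
#'   `centroid_x`, `centroid_y`).
#' @export
connected_components <- function(mask, min_area_px = 50) {
  g <- mask_grid(mask)
  h <- nrow(g); w <- ncol(g)
  fg <- which(g)
  labels <- matrix(0L, h, w)
  if (length(fg) == 0) {
    return(structure(list(labels = labels,
                          components = tibble::tibble(label = integer(),
                                                      pixel_count = integer(),
                                                      centroid_x = numeric(),
                                                      centroid_y = numeric())),
                     class = "component_set"))
  }
  pos <- match(fg, fg)  # identity; fg index -> vertex id
  r <- ((fg - 1L) %% h) + 1L
  c_ <- ((fg - 1L) %/% h) + 1L
  # edges to 4 of the 8 neighbours (the other 4 are symmetric)
  edges <- list()
  nb <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  inside <- function(rr, cc) rr >= 1L & rr <= h & cc >= 1L & cc <= w
  for (k in seq_len(nrow(nb))) {
    rr <- r + nb[k, 1]; cc <- c_ + nb[k, 2]
    ok <- inside(rr, cc)
    nidx <- (cc - 1L) * h + rr
    ok[ok] <- g[nidx[ok]]
    m <- match(nidx[ok], fg)
    edges[[k]] <- cbind(which(ok), m)
  }
  em <- do.call(rbind, edges)
  if (is.null(em) || nrow(em) == 0) {
    comp <- seq_along(fg)
  } else {
    gr <- igraph::graph_from_edgelist(em, directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0, length(fg) - igraph::vcount(gr)))
    comp <- igraph::components(gr)$membership[seq_along(fg)]
  }
  # renumber by first occurrence in column-major order
  comp <- match(comp, unique(comp))
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_area_px)
  newlab <- integer(length(sizes))
  newlab[keep] <- seq_along(keep)
  lab_px <- newlab[comp]
  sel <- lab_px > 0L
  labels[fg[sel]] <- lab_px[sel]
  comps <- tibble::tibble(
    label = seq_along(keep),
    pixel_count = sizes[keep],
    centroid_x = as.numeric(tapply((c_ - 1L)[sel], lab_px[sel], mean)),
    centroid_y = as.numeric(tapply((r - 1L)[sel], lab_px[sel], mean))
  )
  structure(list(labels = labels, components = comps), class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d component(s), %d labelled pixel(s)\n",
              nrow(x$components), sum(x$labels > 0)))
  invisible(x)
}

#' Load point annotations from CSV or GeoJSON
#'
#' CSV dialect: comma-separated with header `kind,x,y`,
#' `kind` in `portal_tract`, `central_vein`. GeoJSON: a FeatureCollection of
#' Point features with a `kind` property.
#'
#' @param path File path (`.csv`, `.json` or `.geojson`).
#' @param bbox Optional `c(width, height)`; points outside are an error.
#' @param septa_mask Optional `binary_mask` of interlobular septa.
#' @return An `annotation_set`: tibble `points` (`kind`, `x`, `y`) plus the
#'   optional septa mask.
#' @export
load_annotations <- function(path, bbox = NULL, septa_mask = NULL) {
  if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path)
    feats <- gj$features %||% list()
    pts <- purrr::map_dfr(feats, function(f) {
      tibble::tibble(kind = f$properties$kind %||% NA_character_,
                     x = as.numeric(f$geometry$coordinates[[1]]),
                     y = as.numeric(f$geometry$coordinates[[2]]))
    })
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
    pts <- if (nrow(raw) == 0) {
      tibble::tibble(kind = character(), x = numeric(), y = numeric())
    } else {
      tibble::tibble(kind = as.character(raw$kind),
                     x = as.numeric(raw$x), y = as.numeric(raw$y))
    }
  }
  bad <- which(!pts$kind %in% c("portal_tract", "central_vein"))
  if (length(bad)) stop(sprintf("unknown annotation kind '%s' at row %d",
                                pts$kind[bad[1]], bad[1]))
  if (!is.null(bbox)) {
    out <- which(pts$x < 0 | pts$x > bbox[1] | pts$y < 0 | pts$y > bbox[2])
    if (length(out)) stop(sprintf("annotation point at row %d lies outside the image bounds",
                                  out[1]))
  }
  new_annotation_set(portal_tracts = pts[pts$kind == "portal_tract", c("x", "y")],
                     central_veins = pts[pts$kind == "central_vein", c("x", "y")],
                     septa_mask = septa_mask)
}

#' Write point annotations to CSV
#' @param ann An `annotation_set`.
#' @param path Output CSV path.
#' @export
write_annotations <- function(ann, path) {
  df <- rbind(
    data.frame(kind = rep("portal_tract", nrow(ann$portal_tracts)),
               x = ann$portal_tracts$x, y = ann$portal_tracts$y),
    data.frame(kind = rep("central_vein", nrow(ann$central_veins)),
               x = ann$central_veins$x, y = ann$central_veins$y)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an annotation set
#'
#' @param portal_tracts,central_veins Data frames with columns `x`, `y`.
#' @param septa_mask Optional `binary_mask`.
#' @param true_lobule_labels Optional integer matrix of ground-truth lobule
#'   labels.
#' @return Object of class `annotation_set`.
#' @export
new_annotation_set <- function(portal_tracts = NULL, central_veins = NULL,
                               septa_mask = NULL, true_lobule_labels = NULL) {
  empty <- tibble::tibble(x = numeric(), y = numeric())
  structure(list(
    portal_tracts = tibble::as_tibble(portal_tracts %||% empty),
    central_veins = tibble::as_tibble(central_veins %||% empty),
    septa_mask = septa_mask,
    true_lobule_labels = true_lobule_labels
  ), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d portal tract(s), %d central vein(s)%s\n",
              nrow(x$portal_tracts), nrow(x$central_veins),
              if (!is.null(x$septa_mask)) ", septa mask" else ""))
  invisible(x)
}
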