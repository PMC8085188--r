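test_that("lobule_overlap scores identity, disjoint and shifted-square cases", {
  lab <- matrix(0L, 40, 40); lab[6:25, 6:25] <- 1L
  expect_equal(lobule_overlap(lab, lab)$mean_overlap, 100)

  pred <- matrix(0L, 40, 40); pred[30:39, 30:39] <- 1L
  expect_equal(lobule_overlap(pred, lab)$mean_overlap, 0)

  # 10 x 10 mm square shifted by 2 mm: |intersection| 80, |union| 120
  truth <- matrix(0L, 30, 30); truth[2:11, 2:11] <- 1L
  shift <- matrix(0L, 30, 30); shift[4:13, 2:11] <- 1L
  ov <- lobule_overlap(shift, truth)
  expect_equal(ov$mean_overlap, 100 * 80 / 120, tolerance = 1e-9)
  ovt <- lobule_overlap(shift, truth, overlap_def = "intersection-over-truth")
  expect_equal(ovt$mean_overlap, 80)

  # IoU is symmetric in prediction/truth
  ov_sym <- lobule_overlap(truth, shift)
  expect_equal(ov_sym$mean_overlap, ov$mean_overlap)

  expect_error(lobule_overlap(shift, matrix(0L, 30, 30)), "empty")
})

test_that("zonal_accuracy computes the landmark percentages and their mean", {
  zr <- matrix(1L, 20, 20)
  zr[8:14, 8:14] <- 3L
  gs <- matrix(FALSE, 20, 20); gs[9:13, 9:13] <- TRUE
  ann <- new_annotation_set(portal_tracts = data.frame(x = c(1, 2, 18), y = c(1, 16, 3)))
  acc <- zonal_accuracy(zr, ann, new_binary_mask(gs, 1))
  expect_equal(acc$pct_pt_zone1, 100)
  expect_equal(acc$pct_gs_zone3, 100)
  expect_equal(acc$total_accuracy, 100)

  # half the portal tracts in zone 2
  zr2 <- zr; zr2[15:20, ] <- 2L
  ann2 <- new_annotation_set(portal_tracts = data.frame(x = c(1, 2, 1, 2), y = c(1, 1, 16, 17)))
  acc2 <- zonal_accuracy(zr2, ann2, new_binary_mask(gs, 1))
  expect_equal(acc2$pct_pt_zone1, 50)
  expect_equal(acc2$total_accuracy, 75)

  # no portal tracts: missing percentage, fallback with a warning
  ann0 <- new_annotation_set()
  expect_warning(acc0 <- zonal_accuracy(zr, ann0, new_binary_mask(gs, 1)),
                 "no portal tracts")
  expect_true(is.na(acc0$pct_pt_zone1))
  expect_equal(acc0$total_accuracy, acc0$pct_gs_zone3)
})

test_that("zonal accuracy is invariant to translation and 90-degree rotation", {
  gt <- generate_tissue(clean_config(256, seed = 9))
  tc <- centroid_method(gt$gs_truth_mask, min_area_px = 10)
  z <- zonate_tessellation(tc, gt$gs_truth_mask)
  acc <- zonal_accuracy(z, gt$annotations, gt$gs_truth_mask)
  # rotate all rasters and points by 90 degrees
  rot_m <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  h <- nrow(z$zone_raster)
  zr_rot <- rot_m(z$zone_raster)
  gs_rot <- rot_m(gt$gs_truth_mask$grid)
  pt <- gt$annotations$portal_tracts
  ann_rot <- new_annotation_set(portal_tracts = data.frame(x = h - 1 - pt$y, y = pt$x))
  acc_rot <- zonal_accuracy(zr_rot, ann_rot, new_binary_mask(gs_rot, 8))
  expect_equal(acc_rot$pct_pt_zone1, acc$pct_pt_zone1)
  expect_equal(acc_rot$pct_gs_zone3, acc$pct_gs_zone3)
})

test_that("shape histogram percentages reproduce report arithmetic and sum to 100", {
  counts <- c(rep(5L, 81), rep(6L, 66), rep(4L, 30), rep(7L, 20), rep(3L, 6))
  h <- shape_histogram(counts, digits = 1)
  expect_equal(sum(h$n), 203)
  expect_equal(round(h$pct[h$side_count == 5]), 40)
  expect_equal(h$pct_display[h$side_count == 6], 32.5)
  expect_equal(sum(h$pct), 100, tolerance = 1e-9)
})

test_that("flag_special_lobules identifies compound and small regions", {
  g <- disc_mask(200, 200, cbind(c(55, 100), c(50, 150)), 3)
  cs <- connected_components(g, 1)
  t <- voronoi_partition(data.frame(x = c(55, 100), y = c(50, 150)), c(200, 200),
                         scale = 10)
  fl <- flag_special_lobules(t, cs, small_quantile = 0)
  expect_length(fl$compound_ids, 0)
  expect_length(fl$small_ids, 0)

  # two GS components in region 1 -> compound; region lacking GS -> small
  g2 <- disc_mask(200, 200, cbind(c(40, 70), c(40, 60)), 3)
  cs2 <- connected_components(g2, 1)
  fl2 <- flag_special_lobules(t, cs2, small_quantile = 0)
  expect_equal(fl2$compound_ids, 1L)
  expect_equal(fl2$small_ids, 2L)
  expect_equal(fl2$compound_fraction, 0.5)
})

test_that("compound flagging recovers the simulated compound rate", {
  # three fields of ~140 lobules each with a 10% compound rate
  n_total <- 0; n_compound <- 0
  for (seed in c(41, 42, 43)) {
    cfg <- synthetic_config(image_size = c(1024, 1024), scale = 8,
                            mean_lobule_diameter_um = 800,
                            site_jitter_um = 50, gs_blob_radius_um = c(60, 90),
                            pt_dropout = 0, noise_sigma = 0,
                            compound_event = 0.1, rng_seed = seed)
    gt <- generate_tissue(cfg)
    cs <- connected_components(gt$gs_truth_mask, 10)
    fl <- flag_special_lobules(gt$true_lobule_labels, cs, small_quantile = 0)
    ids <- sort(unique(as.integer(gt$true_lobule_labels)))
    n_total <- n_total + length(ids)
    n_compound <- n_compound + length(fl$compound_ids)
  }
  p_hat <- n_compound / n_total
  # the fraction estimator has its merge count in both numerator and
  # denominator, inflating the binomial sd by (1 + p)
  ci <- 0.1 + c(-1, 1) * 1.96 * 1.1 * sqrt(0.1 * 0.9 / n_total)
  expect_gte(p_hat, ci[1])
  expect_lte(p_hat, ci[2])
})

test_that("morphometry_report summarizes simulated lobules near the lattice geometry", {
  gt <- generate_tissue(clean_config(512, seed = 7))
  mr <- morphometry_report(gt$true_tessellation)
  ids <- gt$interior_ids
  pitch_px <- gt$config$mean_lobule_diameter_um * sqrt(3) / 2 / gt$config$scale
  cell_mm2 <- sqrt(3) / 2 * (pitch_px * gt$config$scale / 1000)^2
  mean_int <- mean(mr$table$area_mm2[mr$table$region_id %in% ids])
  expect_equal(mean_int, cell_mm2, tolerance = 0.05)
  expect_true(all(mr$table$side_count[mr$table$region_id %in% ids] == 6))
  expect_equal(sum(mr$histogram$pct), 100, tolerance = 1e-9)
  # enclosing circle is never smaller than the equal-area circle
  d_equiv <- 2 * sqrt(mr$table$area_mm2 / pi)
  expect_true(all(mr$table$circumcircle_diameter_mm >= d_equiv - 1e-9))
})
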