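# lobulizer

Voronoi models of hepatic lobular architecture and zonation, in R.

The classic (Kiernan) liver lobule is a polygonal unit with a central vein
near its middle and portal tracts at its vertices. In pigs the lobule
boundary is visible as fibrous septa; in humans it is not demarcated at
all, which makes lobule delineation — and with it any quantitative
statement about zonal biology — surprisingly hard. lobulizer implements the
Voronoi view of this architecture: central veins are generating sites, and
each lobule is the region of tissue nearer to its own central vein than to
any other,

> V(sᵢ) = { p : ‖p − sᵢ‖ ≤ ‖p − sⱼ‖ ∀ j },

clipped to the image rectangle. On top of the tessellation it implements a
zonal algorithm in the spirit of the Rappaport acinus: **zone 3** is the
homothet of the lobule polygon (scale `s` about the glutamine-synthetase
anchor) maximizing `J(s) = GS_inside − nonGS_inside`; **zones 1 and 2**
split the remainder at the homothet of scale `(1+s)/2`, giving equal widths
along every ray.

It is intended for computational-pathology work on liver sections:
segmenting GS-immunostain-like images, building lobule maps by five methods
(explicit sites, GS-component centroids, object-edge / generalized Voronoi,
curated-annotation object-edge, and an algorithmic route with
compound-lobule splitting plus landmark refinement bounded at 5% per-lobule
mismatch), zonating every lobule, and scoring overlap, zonal landmark
accuracy and polygon morphometrics. A synthetic-tissue generator provides
labelled ground truth so the entire pipeline is testable without
whole-slide images.

## Worked example

```r
library(lobulizer)

cfg <- synthetic_config(image_size = c(768, 768), scale = 8, rng_seed = 1)
gt  <- generate_tissue(cfg)                       # image + full ground truth

gs  <- despeckle(threshold_marker(gt$image, "bright", scale = 8))
t   <- centroid_method(gs, min_area_px = 10)      # lobule map from GS blobs
ov  <- lobule_overlap(t, gt$true_lobule_labels)   # vs. simulated truth
z   <- zonate_tessellation(t, gs)                 # zones 1-3 per lobule
acc <- zonal_accuracy(z, gt$annotations, gs,
                      regions = interior_regions(t))

glance(t)
#> # A tibble: 1 x 5
#>   n_regions bbox_width bbox_height scale_um_per_px total_area_mm2
#> 1        39        768         768               8           37.7
ov
#> <overlap_report> 37 lobule(s), mean overlap 95.6% (iou)
glance(acc)
#> # A tibble: 1 x 4
#>   pct_pt_zone1 pct_gs_zone3 total_accuracy n_portal_tracts
#> 1          100         89.4           94.7              37
morphometry_report(t)
#> <morphometry_report> 39 region(s); mean area 0.968 mm^2 (SD 0.130); mean circumcircle diameter 1.38 mm
```

Reading: on a 6.1 mm synthetic field of 39 lobules, the centroid method
recovers the true lobule map at 95.6% mean per-lobule IoU; all 37 portal
tracts land in zone 1 and 89.4% of GS-positive area lands in zone 3 over
the complete (unclipped) lobules; lobule profiles average 0.97 mm². The
`tidy()`/`glance()` verbs return tibbles, and `autoplot()` draws
tessellations, zone rasters and shape histograms.

A command-line pipeline ships as `inst/cli/lobulizer` with subcommands
`simulate`, `segment`, `tessellate`, `zonate`, `score`, `morph`, exchanging
PNG rasters, GeoJSON region polygons, CSV annotations and JSON reports.

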