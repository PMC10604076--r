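test_that("preprocessing creates no spurious contrast and preserves edges", {
  cfg <- small_detection_config()
  const <- matrix(5, 64, 64)
  expect_equal(preprocess(const, cfg), matrix(0, 64, 64))
  expect_error(preprocess(matrix(c(NA, 1:63), 8, 8), cfg), "non-finite")

  # step edge stays put within 1 px
  step <- matrix(0, 80, 80); step[, 41:80] <- 1
  pp <- preprocess(step, cfg)
  grad_before <- rowMeans(abs(diff(t(step))))
  grad_after <- rowMeans(abs(diff(t(pp))))
  expect_lte(abs(which.max(grad_after) - which.max(grad_before)), 1)

  # low-contrast image: equalization restores at least half the full range
  low <- matrix(0.5, 96, 96)
  low[30:60, 30:60] <- 0.52
  low <- low + matrix(runif(96 * 96, 0, 0.005), 96)
  expect_gte(diff(range(preprocess(low, cfg))), 0.5)
})

test_that("a single plausible annulus becomes one filled region; blank images none", {
  cfg <- small_detection_config()
  blank <- matrix(0.2, 200, 200)
  expect_equal(nrow(detect_modality(blank, cfg)$regions), 0)

  ring <- matrix(0.1, 200, 200)
  rr <- sqrt(outer((1:200 - 100)^2, (1:200 - 120)^2, "+"))
  ring[rr >= 9 & rr <= 12] <- 0.9
  m <- detect_modality(ring, cfg)
  expect_equal(nrow(m$regions), 1)
  expect_lt(sqrt((m$regions$centroid_row - 100)^2 +
                 (m$regions$centroid_col - 120)^2), 2)
  # the ring interior was filled
  expect_gt(m$regions$area_px, pi * 9^2 * 0.8)
})

test_that("region filtering enforces area, shape, edge and overlap rules and is idempotent", {
  cfg <- small_detection_config(area_min_px = 100, area_max_px = 1000,
                                eccentricity_max = 0.9, edge_margin_px = 10,
                                convexity_min = 0.4)
  nr <- 300; nc <- 300
  lab <- matrix(0L, nr, nc)
  # region 1: fine disc (r = 10, area ~314)
  rr <- sqrt(outer((1:nr - 60)^2, (1:nc - 60)^2, "+")); lab[rr <= 10] <- 1L
  # region 2: too small (area_min - 1 pixels, a compact blob)
  blob <- which(sqrt(outer((1:nr - 150)^2, (1:nc - 60)^2, "+")) <= 6.5)
  lab[blob[seq_len(99)]] <- 2L
  # region 3: elongated bar, eccentricity ~0.99
  lab[230:232, 40:140] <- 3L
  # region 4: touches the edge margin
  rr4 <- sqrt(outer((1:nr - 60)^2, (1:nc - 290)^2, "+")); lab[rr4 <= 10] <- 4L
  # regions 5/6: concentric ring and disc whose equivalent discs overlap
  rr5 <- sqrt(outer((1:nr - 220)^2, (1:nc - 220)^2, "+"))
  lab[rr5 >= 12 & rr5 <= 16] <- 5L
  lab[rr5 <= 6] <- 6L
  mask <- detection_mask(lab, swarmreader:::region_features(lab, "bright_field"))
  filtered <- filter_regions(mask, cfg)
  expect_equal(nrow(filtered$regions), 1)
  expect_lt(abs(filtered$regions$centroid_row - 60), 1.5)
  expect_lt(abs(filtered$regions$centroid_col - 60), 1.5)
  # idempotence
  again <- filter_regions(filtered, cfg)
  expect_identical(again$label_image, filtered$label_image)
  expect_equal(again$regions, filtered$regions)
})

test_that("particles rendered touching the well edge are excluded", {
  cfg <- small_scene_config(seed = 13, n_particles = 6, edge_particles = 2,
                            noise_sd = 0, quantize = FALSE)
  sc <- rendered_scene(cfg)
  det <- small_detection_config()
  m <- filter_regions(detect_modality(sc$images$dark_field, det,
                                      "dark_field"), det)
  ev <- evaluate_detection(m, sc$truth)
  # the 6 interior particles are found; the 2 edge-touchers are not
  edge_idx <- 7:8
  expect_true(all(is.na(ev$matches[edge_idx])))
  expect_equal(sum(!is.na(ev$matches[1:6])), 6)
})

test_that("mask fusion ORs regions, keeps provenance and applies the convexity constraint", {
  cfg <- small_detection_config()
  nr <- 200; nc <- 200
  m1 <- disc_mask(rbind(c(50, 50)), 10, nr, nc, "bright_field")
  m2 <- disc_mask(rbind(c(50, 120)), 10, nr, nc, "dark_field")
  m3 <- disc_mask(rbind(c(140, 80)), 10, nr, nc, "fluorescence")

  # three identical masks: fused equals any input
  same <- fuse_masks(m1, m1, m1, cfg)
  expect_equal(same$label_image > 0, m1$label_image > 0)
  expect_equal(same$regions$modalities, "bright_field,dark_field,fluorescence")

  # disjoint single regions: three fused regions, one modality each
  fused <- fuse_masks(m1, m2, m3, cfg)
  expect_equal(nrow(fused$regions), 3)
  expect_setequal(fused$regions$modalities,
                  c("bright_field", "dark_field", "fluorescence"))

  # slightly offset discs of one particle fuse to a convex blob (kept);
  # two far-apart discs bridged into a dumbbell fail convexity (removed)
  off <- disc_mask(rbind(c(50, 53)), 10, nr, nc, "dark_field")
  kept <- suppressWarnings(fuse_masks(m1, off, NULL, cfg))
  expect_equal(nrow(kept$regions), 1)

  lab <- matrix(0L, nr, nc)
  rr1 <- sqrt(outer((1:nr - 100)^2, (1:nc - 60)^2, "+"))
  rr2 <- sqrt(outer((1:nr - 100)^2, (1:nc - 100)^2, "+"))
  lab[rr1 <= 12 | rr2 <= 12] <- 1L
  lab[99:101, 60:100] <- 1L   # thin bridge -> dumbbell
  dumb <- detection_mask(lab, swarmreader:::region_features(lab, "fluorescence"))
  gone <- suppressWarnings(fuse_masks(NULL, NULL, dumb, cfg))
  expect_equal(nrow(gone$regions), 0)
})

test_that("fusion warns about missing modalities but still runs", {
  cfg <- small_detection_config()
  m <- disc_mask(rbind(c(50, 50)), 10, 120, 120)
  expect_warning(f <- fuse_masks(NULL, m, m, cfg), "bright_field")
  expect_equal(nrow(f$regions), 1)
  expect_error(suppressWarnings(fuse_masks(NULL, NULL, NULL, cfg)), "no masks")
})

test_that("detection scoring matches truth label maps and handles empty masks", {
  cfg <- small_scene_config(seed = 17, n_particles = 5)
  tr <- sample_scene(cfg)
  mask <- detection_mask(tr$label_map,
                         swarmreader:::region_features(tr$label_map))
  ev <- evaluate_detection(mask, tr)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)

  empty <- detection_mask(matrix(0L, cfg$image_height_px,
                                 cfg$image_width_px),
                          swarmreader:::empty_regions())
  ev0 <- evaluate_detection(empty, tr)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$precision, 0)
  expect_false(ev0$precision_defined)
})

test_that("adding a region to a modality never decreases fused matches", {
  cfg <- small_scene_config(seed = 19, n_particles = 6, noise_sd = 0,
                            quantize = FALSE)
  sc <- rendered_scene(cfg)
  det <- small_detection_config(convexity_min = 0.01)  # isolate OR property
  m_df <- filter_regions(detect_modality(sc$images$dark_field, det,
                                         "dark_field"), det)
  # drop one detected region from the dark-field mask
  weaker <- swarmreader:::subset_mask(m_df, m_df$regions$label[-1])
  n_weaker <- evaluate_detection(suppressWarnings(
    fuse_masks(NULL, weaker, NULL, det)), sc$truth)$n_matched
  n_full <- evaluate_detection(suppressWarnings(
    fuse_masks(NULL, m_df, NULL, det)), sc$truth)$n_matched
  expect_gte(n_full, n_weaker)
})
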