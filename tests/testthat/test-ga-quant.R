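test_that("a flat band gives a constant evaluation band at centroid +/- margins", {
  mask <- flat_band_mask(depth0 = 30L, thick = 5L)  # centroid depth 32
  band <- fit_evaluation_band(mask, 10L, 10L)
  expect_true(all(band$upper == 22))
  expect_true(all(band$lower == 42))
  expect_true(all(band$source == "auto"))
  expect_error(fit_evaluation_band(mask_from_array(array(FALSE, c(8, 8, 2)))),
               "no depolarizing pixels")
})

test_that("manual override replaces the band for the listed B-scan only", {
  mask <- flat_band_mask()
  band <- fit_evaluation_band(mask, 10L, 10L, manual = list(`5` = c(10, 50)))
  expect_true(all(band$upper[, 5] == 10) && all(band$lower[, 5] == 50))
  expect_true(all(band$upper[, -5] == 22))
  expect_identical(band$source[5], "manual")
  expect_error(fit_evaluation_band(mask, manual = list(`99` = c(10, 50))),
               "outside the volume")
  expect_error(fit_evaluation_band(mask, manual = list(`5` = c(50, 10))),
               "upper < lower")
})

test_that("sub-band choroidal depolarizing speckle changes no thickness-map cell", {
  g <- tiny_geometry()
  base <- phantom_spec(geometry = g, rpe_depth_px = 30L, rpe_thickness_px = 5L,
                       noise_sd = 0)
  speck <- phantom_spec(geometry = g, rpe_depth_px = 30L, rpe_thickness_px = 5L,
                        noise_sd = 0, lesions = list(
                          lesion_ectopic_focus(1.5, 1.6, depth_offset_px = 25L,
                                               size_px = 3L)))
  tm <- lapply(list(base, speck), function(sp) {
    sim <- generate_phantom(sp, 4)
    d <- compute_dopu(sim$volume)
    m <- segment_rpe(d, sim$volume, 0.8)
    band <- fit_evaluation_band(m, 10L, 10L)
    depolarizing_thickness_map(m, band)
  })
  expect_identical(tm[[1]]$counts, tm[[2]]$counts)
})

test_that("thickness map counts band voxels per A-line and conserves the in-band total", {
  mask <- flat_band_mask(depth0 = 30L, thick = 5L)
  band <- fit_evaluation_band(mask, 10L, 10L)
  tmap <- depolarizing_thickness_map(mask, band)
  expect_true(all(tmap$counts == 5L))
  # planted circular gap: zero inside, nominal outside
  m2 <- mask$mask
  gap <- matrix(FALSE, 40, 8); gap[10:20, 3:6] <- TRUE
  for (a in 1:40) for (b in 1:8) if (gap[a, b]) m2[, a, b] <- FALSE
  mask2 <- mask_from_array(m2)
  t2 <- depolarizing_thickness_map(mask2, band)
  expect_true(all(t2$counts[gap] == 0L))
  expect_true(all(t2$counts[!gap] == 5L))
  # conservation: map total equals in-band mask cardinality
  expect_identical(sum(t2$counts), sum(m2))
  band_shift <- band; band_shift$upper[] <- 33; band_shift$lower[] <- 43
  t3 <- depolarizing_thickness_map(mask2, band_shift)
  expect_identical(sum(t3$counts), 2L * sum(gap == FALSE))
})

test_that("binarization and smoothing behave like the direct morphology oracle", {
  g <- scan_geometry(width_mm = 1, height_mm = 1, n_ascans = 7L, n_bscans = 7L,
                     n_depth = 8L, axial_step_um = 9)
  counts <- matrix(5L, 7, 7)
  amap <- binarize_and_smooth(tmap_from_matrix(counts, g), 0L, 1L)
  expect_false(any(amap$atrophic))             # all counts 5 -> all false
  counts[4, 4] <- 0L                           # single isolated atrophic pixel
  amap1 <- binarize_and_smooth(tmap_from_matrix(counts, g), 0L, 1L)
  expect_false(any(amap1$atrophic))            # removed by median/opening
  amap0 <- binarize_and_smooth(tmap_from_matrix(counts, g), 0L, 0L)
  expect_identical(sum(amap0$atrophic), 1L)    # radius 0 = no smoothing
  expect_identical(amap1$params$smooth_radius_px, 1L)
})

test_that("a planted disc gap much larger than the smoothing radius survives within a 1-px boundary", {
  g <- scan_geometry_test()
  truth <- phantom_ground_truth(phantom_spec(geometry = g, lesions = list(
    lesion_ga_patch(3.0, 3.3, radius_mm = 0.8))))
  fp <- truth$footprints[[1]]
  counts <- matrix(5L, g$n_ascans, g$n_bscans)
  counts[fp] <- 0L
  amap <- binarize_and_smooth(tmap_from_matrix(counts, g), 0L, 1L)
  diffpx <- which(amap$atrophic != fp)
  # any disagreeing pixel must touch the footprint boundary (1-px tolerance)
  boundary <- fp != (EBImage::erode(fp * 1, EBImage::makeBrush(3, "box")) > 0.5)
  ring <- (EBImage::dilate(boundary * 1, EBImage::makeBrush(3, "box")) > 0.5)
  expect_true(all(ring[diffpx]))
})

test_that("GA floor splits components at exactly 0.1 mm^2 and conserves area", {
  g <- scan_geometry_test()
  pa <- pixel_area_mm2(g)
  amap <- matrix(FALSE, g$n_ascans, g$n_bscans)
  n_big <- ceiling(0.28 / pa)        # ~0.28 mm^2 patch
  n_small <- floor(0.05 / pa)        # ~0.05 mm^2 patch
  amap[10:19, 4:9] <- FALSE
  amap[cbind(10 + (seq_len(n_big) - 1) %% 10, 4 + (seq_len(n_big) - 1) %/% 10)] <- TRUE
  amap[cbind(60 + (seq_len(n_small) - 1) %% 5, 40 + (seq_len(n_small) - 1) %/% 5)] <- TRUE
  ga <- detect_ga_lesions(amap_from_matrix(amap, g), g, 0.1)
  expect_identical(nrow(ga$lesions), 1L)
  expect_identical(nrow(ga$sub_threshold), 1L)
  expect_equal(ga$lesions$area_mm2, n_big * pa)
  expect_equal(ga$sub_threshold$area_mm2, n_small * pa)
  # conservation
  expect_equal(sum(ga$lesions$area_mm2) + sum(ga$sub_threshold$area_mm2),
               sum(amap) * pa)
  # empty map
  ga0 <- detect_ga_lesions(amap_from_matrix(amap & FALSE, g), g, 0.1)
  expect_identical(nrow(ga0$lesions), 0L)
  expect_identical(ga0$total_area_mm2, 0)
})

test_that("8-connected labelling equals the flood-fill oracle on random small grids", {
  set.seed(42)
  for (i in 1:25) {
    nr <- sample(3:32, 1); nc <- sample(3:32, 1)
    m <- matrix(runif(nr * nc) < 0.35, nr, nc)
    expect_true(same_partition(label_components(m, 8L), flood_fill_label(m, 8L)))
    expect_true(same_partition(label_components(m, 4L), flood_fill_label(m, 4L)))
  }
})

test_that("lesions are sorted by area descending with top-left tie-break", {
  g <- scan_geometry_test()
  amap <- matrix(FALSE, g$n_ascans, g$n_bscans)
  amap[40:49, 40:45] <- TRUE            # 60 px
  amap[5:9, 5:10] <- TRUE               # 30 px, earlier in scan order
  amap[90:94, 20:25] <- TRUE            # 30 px, later in scan order
  ga <- detect_ga_lesions(amap_from_matrix(amap, g), g, min_area_mm2 = 0)
  expect_identical(ga$lesions$n_pixels, c(60L, 30L, 30L))
  expect_lt(ga$lesions$centroid_y_mm[2], ga$lesions$centroid_y_mm[3])
})

test_that("measured area is monotone under patch growth and floor changes", {
  g <- scan_geometry_test()
  amap <- matrix(FALSE, g$n_ascans, g$n_bscans)
  amap[30:40, 30:35] <- TRUE
  a1 <- detect_ga_lesions(amap_from_matrix(amap, g), g, 0.1)
  amap2 <- amap; amap2[30:42, 30:37] <- TRUE   # grown patch
  a2 <- detect_ga_lesions(amap_from_matrix(amap2, g), g, 0.1)
  expect_gte(a2$total_area_mm2, a1$total_area_mm2)
  # lowering the floor never removes a detected lesion
  lo <- detect_ga_lesions(amap_from_matrix(amap2, g), g, 0.01)
  expect_gte(nrow(lo$lesions), nrow(a2$lesions))
})

test_that("planted GA discs are recovered end-to-end within the quantization bound", {
  g <- scan_geometry_test()
  radii <- c(0.25, 0.55, 0.9)
  for (i in seq_along(radii)) {
    r <- radii[i]
    sim <- generate_phantom(phantom_spec(geometry = g, lesions = list(
      lesion_ga_patch(3.0, 3.3, radius_mm = r))), seed = 20 + i)
    # low floor: this measures area recovery, not the clinical GA floor
    res <- analyze_eye_visit(sim$volume, pipeline_config(min_area_mm2 = 0.02))
    expect_identical(nrow(res$ga$lesions), 1L)
    bound <- 2 * pi * r * max(ascan_pitch_mm(g), bscan_pitch_mm(g))
    expect_lt(abs(res$ga$lesions$area_mm2[1] - pi * r^2), bound)
  }
})
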