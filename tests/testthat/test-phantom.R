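test_that("lesion-free phantom truth is a uniform band at the nominal depth", {
  g <- tiny_geometry()
  spec <- phantom_spec(geometry = g, rpe_depth_px = 40L, rpe_thickness_px = 5L,
                       noise_sd = 0)
  truth <- phantom_ground_truth(spec)
  expect_equal(dim(truth$label), c(g$n_depth, g$n_ascans, g$n_bscans))
  for (b in c(1L, g$n_bscans %/% 2L, g$n_bscans)) {
    sl <- truth$label[, , b]
    expect_true(all(sl[41:45, ] == 1L))
    expect_true(all(sl[-(41:45), ] == 0L))
  }
  expect_true(all(truth$band_thickness == 5L))
  expect_false(any(truth$expected_eye))
})

test_that("planted GA disc: analytic area matches rasterized footprint within the quantization bound", {
  g <- tiny_geometry()
  spec <- phantom_spec(geometry = g, lesions = list(
    lesion_ga_patch(1.5, 1.6, radius_mm = 0.3)))
  truth <- phantom_ground_truth(spec)
  analytic <- pi * 0.3^2
  expect_equal(truth$lesions$area_mm2, analytic, tolerance = 1e-12)
  raster <- truth$lesions$n_pixels * pixel_area_mm2(g)
  bound <- 2 * pi * 0.3 * max(ascan_pitch_mm(g), bscan_pitch_mm(g))
  expect_lt(abs(raster - analytic), bound)
})

test_that("rasterization bound holds across planted radii", {
  g <- scan_geometry_test()
  for (r in seq(0.2, 1.0, by = 0.2)) {
    truth <- phantom_ground_truth(phantom_spec(geometry = g, lesions = list(
      lesion_ga_patch(3.0, 3.3, radius_mm = r))))
    raster <- truth$lesions$n_pixels * pixel_area_mm2(g)
    bound <- 2 * pi * r * max(ascan_pitch_mm(g), bscan_pitch_mm(g))
    expect_lt(abs(raster - pi * r^2), bound)
  }
})

test_that("ground truth is invariant to seed and noise; volumes are deterministic in (spec, seed)", {
  g <- tiny_geometry()
  spec <- phantom_spec(geometry = g, lesions = list(
    lesion_ga_patch(1.5, 1.6, radius_mm = 0.3)))
  s7 <- generate_phantom(spec, 7)
  s8 <- generate_phantom(spec, 8)
  expect_identical(s7$truth$label, s8$truth$label)
  expect_identical(s7$truth$lesions, s8$truth$lesions)
  expect_false(identical(s7$volume$Q, s8$volume$Q))  # different noise
  spec0 <- phantom_spec(geometry = g, noise_sd = 0, lesions = spec$lesions)
  expect_identical(phantom_ground_truth(spec0)$label, s7$truth$label)
  s7b <- generate_phantom(spec, 7)
  expect_identical(s7$volume, s7b$volume)            # bitwise reproducible
})

test_that("every emitted voxel is physical", {
  g <- tiny_geometry()
  for (seed in 1:3) {
    spec <- phantom_spec(geometry = g, noise_sd = 0.1, depol_strength = 0.7,
                         lesions = list(lesion_ga_patch(1.5, 1.6, radius_mm = 0.25)))
    v <- generate_phantom(spec, seed)$volume
    expect_true(all(v$I >= 0))
    expect_true(all(sqrt(v$Q^2 + v$U^2 + v$V^2) <= v$I * (1 + 1e-9) + 1e-12))
  }
})

test_that("a lesion outside the scan area is rejected with the lesion identified", {
  g <- tiny_geometry()
  expect_error(
    phantom_spec(geometry = g, lesions = list(
      lesion_ga_patch(1.5, 1.6, radius_mm = 0.2),
      lesion_ga_patch(3.05, 1.6, radius_mm = 0.2))),
    "lesion 2 \\(ga_patch\\)")
})

test_that("cohort generation applies manifests cumulatively and deterministically", {
  g <- tiny_geometry()
  eyes <- list(
    list(eye_id = 1, crt_um = c(400, 380), bcva_letters = c(60, 62),
         lesions = list(list(kind = "ga_patch", center_x_mm = 1.5,
                             center_y_mm = 1.6, radius_mm = 0.3,
                             onset_month = 12))),
    list(eye_id = 2, crt_um = c(300, 290), bcva_letters = c(70, 71),
         lesions = list()))
  cs <- cohort_spec(eyes, visits_months = c(0, 12), geometry = g, seed = 5)
  recs <- generate_cohort(cs, with_volumes = FALSE)
  expect_length(recs, 4L)
  ga_truth <- vapply(recs, function(r) r$truth$expected_eye[["ga"]], TRUE)
  # lesion onsets at month 12: present only in eye 1's month-12 record
  who <- vapply(recs, function(r) paste(r$eye_id, r$visit_month), "")
  expect_identical(ga_truth[who == "1 12"], TRUE)
  expect_identical(sum(ga_truth), 1L)
  # all-negative for the lesion-free eye
  expect_false(any(unlist(lapply(recs[who %in% c("2 0", "2 12")],
                                 function(r) r$truth$expected_eye))))
  recs2 <- generate_cohort(cs, with_volumes = FALSE)
  expect_identical(recs, recs2)
})

test_that("empty visit schedule is rejected", {
  expect_error(cohort_spec(list(list(eye_id = 1)), visits_months = numeric(0)),
               "empty visit schedule")
})

test_that("month-24 fixture manifest matches its ground-truth GA count and area list", {
  cohort <- read_cohort_spec(month24_cohort_path())
  expect_length(cohort$eyes, 31L)
  recs <- generate_cohort(cohort, with_volumes = FALSE)
  ga_pos <- vapply(recs, function(r) r$truth$expected_eye[["ga"]], TRUE)
  areas <- scan(system.file("extdata", "ga_areas_month24.txt", package = "psoct"),
                quiet = TRUE)
  expect_identical(sum(ga_pos), length(areas))
  expect_identical(sum(ga_pos), 19L)
  # printed month-24 distribution encoded by the fixture list
  expect_equal(mean(areas), 1.10, tolerance = 0.005)
  expect_equal(sd(areas), 1.09, tolerance = 0.005)
  expect_equal(range(areas), c(0.14, 2.58))
})

test_that("eligibility filter keeps records with CRT strictly above threshold, in order", {
  recs <- data.frame(eye_id = 1:3, crt_um = c(450.9, 250, 251))
  kept <- eligibility_filter(recs, 250)
  expect_identical(kept$eye_id, c(1L, 3L))
  expect_identical(nrow(eligibility_filter(recs[0, ], 250)), 0L)
  allequal <- data.frame(eye_id = 1:3, crt_um = c(250, 250, 250))
  expect_identical(nrow(eligibility_filter(allequal, 250)), 0L)
  # missing CRT: flagged, excluded, logged
  miss <- data.frame(eye_id = 1:3, crt_um = c(400, NA, 300))
  expect_warning(kept <- eligibility_filter(miss, 250), "missing CRT")
  expect_identical(kept$eye_id, c(1L, 3L))
  expect_true(2L %in% attr(kept, "excluded"))
})
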