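test_that("normal band thickness is the median of non-zero counts and is robust", {
  g <- scan_geometry_test()
  counts <- matrix(5L, g$n_ascans, g$n_bscans)
  expect_identical(estimate_normal_thickness(tmap_from_matrix(counts, g))$value, 5)
  # 3% of cells thickened to 10 px: median unchanged
  thick <- counts
  thick[seq_len(round(0.03 * length(counts)))] <- 10L
  est <- estimate_normal_thickness(tmap_from_matrix(thick, g))
  direct <- median(thick[thick > 0])
  expect_identical(est$value, direct)
  expect_identical(est$value, 5)
  expect_error(estimate_normal_thickness(tmap_from_matrix(counts * 0L, g)),
               "no non-zero")
  excl <- matrix(TRUE, g$n_ascans, g$n_bscans)
  expect_error(estimate_normal_thickness(tmap_from_matrix(counts, g), excl),
               "fraction of cells")
})

test_that("porosity requires a series of gaps reaching 20% cumulative width", {
  n <- 512L
  # 4 gaps totalling 128 A-lines (25%) with interleaved residuals
  gr <- grade_bscan(row_with_gaps(n, c(32L, 32L, 32L, 32L)), 5)
  expect_true(gr$porosity)
  expect_identical(nrow(gr$evidence$gaps), 4L)
  expect_gte(nrow(gr$evidence$residuals), 2L)
  # same structure totalling 77 A-lines (15%)
  expect_false(grade_bscan(row_with_gaps(n, c(20L, 19L, 19L, 19L)), 5)$porosity)
  # a single wide gap (>= 20%) is not a series
  expect_false(grade_bscan(row_with_gaps(n, 120L), 5)$porosity)
  # intact row: nothing
  gr0 <- grade_bscan(rep(5L, n), 5)
  expect_false(any(unlist(gr0[c("porosity", "focal_atrophy", "thinning",
                                "accumulation_rpe_level")])))
  expect_error(grade_bscan(integer(0), 5), "zero-length")
})

test_that("porosity flips exactly at the 20% cumulative gap width", {
  n <- 512L  # 0.2 * 512 = 102.4 -> flips at 103 cumulative A-lines
  expect_false(grade_bscan(row_with_gaps(n, c(34L, 34L, 34L)), 5)$porosity)  # 102
  expect_true(grade_bscan(row_with_gaps(n, c(34L, 34L, 35L)), 5)$porosity)   # 103
  n2 <- 510L # 0.2 * 510 = 102 exactly: "at least 20%" includes equality
  expect_true(grade_bscan(row_with_gaps(n2, c(34L, 34L, 34L)), 5)$porosity)
  expect_false(grade_bscan(row_with_gaps(n2, c(34L, 34L, 33L)), 5)$porosity)
})

test_that("thinning requires counts strictly below half normal over at least 10% width", {
  n <- 512L
  mkrow <- function(width, value) {
    row <- rep(5L, n); row[100:(100 + width - 1L)] <- value; row
  }
  # 60 A-lines (11.7%) at count 2 < 2.5 with normal 5
  expect_true(grade_bscan(mkrow(60L, 2L), 5)$thinning)
  # width threshold: 0.1*512 = 51.2 -> flips at 52
  expect_false(grade_bscan(mkrow(51L, 2L), 5)$thinning)
  expect_true(grade_bscan(mkrow(52L, 2L), 5)$thinning)
  # half-thickness threshold is strict: 2 < 2.5 yes, 3 >= 2.5 no... 3 > 2.5
  expect_false(grade_bscan(mkrow(60L, 3L), 5)$thinning)
  # exactly half (normal 6, count 3) is not thinner than half
  expect_false(grade_bscan(mkrow(60L, 3L), 6)$thinning)
  expect_true(grade_bscan(mkrow(60L, 2L), 6)$thinning)
  # zero counts are gaps, not thinning
  expect_false(grade_bscan(mkrow(60L, 0L), 5)$thinning)
})

test_that("accumulation requires at least twice the normal thickness", {
  n <- 512L
  mkrow <- function(width, value) {
    row <- rep(5L, n); row[200:(200 + width - 1L)] <- value; row
  }
  expect_true(grade_bscan(mkrow(8L, 10L), 5)$accumulation_rpe_level)
  expect_false(grade_bscan(mkrow(8L, 9L), 5)$accumulation_rpe_level)   # factor 2 exact
  expect_false(grade_bscan(mkrow(4L, 10L), 5)$accumulation_rpe_level)  # below min run
})

test_that("rule monotonicity: extending gaps or raising thick runs never un-flags", {
  n <- 512L
  base <- row_with_gaps(n, c(34L, 34L, 35L))
  g0 <- grade_bscan(base, 5)
  expect_true(g0$porosity)
  ext <- base; ext[64:79] <- 0L   # extend the first gap backwards
  expect_true(grade_bscan(ext, 5)$porosity)
  thick <- rep(5L, n); thick[200:210] <- 10L
  expect_true(grade_bscan(thick, 5)$accumulation_rpe_level)
  thicker <- thick; thicker[200:210] <- 14L
  expect_true(grade_bscan(thicker, 5)$accumulation_rpe_level)
})

test_that("gaps are attributed to focal atrophy unless covered by a quantified GA lesion", {
  n <- 128L
  row <- rep(5L, n); row[40:47] <- 0L
  cols_none <- rep(FALSE, n)
  expect_true(grade_bscan(row, 5, ga_lesion_cols = cols_none)$focal_atrophy)
  cols_ga <- cols_none; cols_ga[35:50] <- TRUE
  expect_false(grade_bscan(row, 5, ga_lesion_cols = cols_ga)$focal_atrophy)
  # two gaps, one covered by GA: the uncovered one still counts as focal
  row2 <- row; row2[90:95] <- 0L
  expect_true(grade_bscan(row2, 5, ga_lesion_cols = cols_ga)$focal_atrophy)
})

test_that("ectopic foci require discontinuity and minimum separation from the band", {
  nd <- 64L; na <- 40L; nb <- 10L
  band_mask <- array(FALSE, c(nd, na, nb))
  band_mask[41:45, , ] <- TRUE
  mk_band <- function(m) fit_evaluation_band(mask_from_array(m), 10L, 10L)
  # planted 27-voxel focus 30 px above the band
  m1 <- band_mask
  m1[11:13, 20:22, 5:7] <- TRUE
  foci <- detect_ectopic_foci(mask_from_array(m1), mk_band(m1), rule_params())
  expect_identical(nrow(foci), 1L)
  expect_identical(foci$n_voxels, 27L)
  # a protrusion contiguous with the band is not a focus
  m2 <- band_mask
  m2[20:41, 20, 5] <- TRUE
  foci2 <- detect_ectopic_foci(mask_from_array(m2), mk_band(m2), rule_params())
  expect_identical(nrow(foci2), 0L)
  # empty space above the band
  foci3 <- detect_ectopic_foci(mask_from_array(band_mask), mk_band(band_mask),
                               rule_params())
  expect_identical(nrow(foci3), 0L)
  # too-small cluster is discarded
  m4 <- band_mask
  m4[12, 20:21, 5] <- TRUE
  foci4 <- detect_ectopic_foci(mask_from_array(m4), mk_band(m4), rule_params())
  expect_identical(nrow(foci4), 0L)
  # focus within min_sep of the band's upper bound does not qualify
  m5 <- band_mask
  m5[27:29, 20:22, 5:7] <- TRUE   # upper bound 32, min_sep 5 -> cut at 27 (0-based)
  foci5 <- detect_ectopic_foci(mask_from_array(m5), mk_band(m5), rule_params())
  expect_identical(nrow(foci5), 0L)
})

test_that("eye-visit scoring is any-B-scan and errors on missing grades", {
  g <- scan_geometry_test()
  amap <- amap_from_matrix(matrix(FALSE, g$n_ascans, g$n_bscans), g)
  ga0 <- detect_ga_lesions(amap, g, 0.1)
  rows <- replicate(10, grade_bscan(rep(5L, 64L), 5), simplify = FALSE)
  rows[[4]] <- grade_bscan(row_with_gaps(64L, c(5L, 5L, 5L), residual_width = 5L,
                                         lead = 5L), 5)
  expect_true(rows[[4]]$porosity)
  fb <- flat_band_mask()
  nofoci <- detect_ectopic_foci(fb, fit_evaluation_band(fb, 10L, 10L),
                                rule_params())
  sc <- score_eye_visit(ga0, rows, nofoci, eye_id = 9, visit_month = 24,
                        crt_um = 400)
  expect_identical(sc$porosity, 1L)
  expect_identical(sc$ga, 0L)
  expect_identical(sc$ga_area_mm2, 0)
  rows_all0 <- replicate(10, grade_bscan(rep(5L, 64L), 5), simplify = FALSE)
  sc0 <- score_eye_visit(ga0, rows_all0, nofoci)
  expect_identical(sum(sc0[, c("porosity", "focal_atrophy", "thinning",
                               "accumulation_rpe_level", "ectopic_material",
                               "ga")]), 0L)
  broken <- rows_all0
  broken[5] <- list(NULL)
  expect_error(score_eye_visit(ga0, broken, nofoci), "missing B-scan grades")
})

test_that("classifier agrees with ground truth on nearly all B-scan/type cells across seeded phantoms", {
  g <- scan_geometry_test()
  types <- c("porosity", "focal_atrophy", "thinning", "accumulation_rpe_level")
  total <- 0L; agree <- 0L
  layouts <- list(
    list(lesion_ga_patch(2.4, 2.8, radius_mm = 0.6),
         lesion_gap_series(1.0, 5.0)),
    list(lesion_thinning(2.46, 6.0, 0.92, 0.4, 0.2),
         lesion_thickening(4.08, 0.7, 1.16, 0.6, 3)),
    list(lesion_focal_atrophy(5.5, 1.2, 0.19),
         lesion_gap_series(1.5, 4.2, n_bscans_extent = 3L)))
  for (i in seq_along(layouts)) {
    sim <- generate_phantom(phantom_spec(geometry = g, lesions = layouts[[i]]),
                            seed = 100 + i)
    res <- analyze_eye_visit(sim$volume, pipeline_config())
    gd <- res$graded$default
    got <- vapply(gd$grades, function(x) unlist(x[types]), logical(4))
    want <- t(sim$truth$expected_bscan[, types])
    total <- total + length(want)
    agree <- agree + sum(got == want)
  }
  expect_gte(agree / total, 0.95)
})
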