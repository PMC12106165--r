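# Fiducial calibration, corneal centre, the eight parameters.

test_that("equivalent-circle calibration matches its closed form", {
  lab <- mask_labels()
  # a component of known pixel area A must give diameter 2*sqrt(A/pi)
  m <- matrix(lab["skin"], 80, 80)
  m[20:63, 20:63] <- lab["marker"]       # area 44^2
  sf <- calibrate(m, marker_diameter_mm = 10, refine = FALSE)
  expect_equal(sf$marker_px_diameter, 2 * sqrt(44^2 / pi), tolerance = 1e-12)
  expect_equal(sf$mm_per_px, 10 / sf$marker_px_diameter, tolerance = 1e-12)
  expect_identical(sf$method, "equivalent_circle")
})

test_that("calibration recovers the scale within 1% across the working range", {
  # physical sweep: the 10-mm marker at scales 0.083-0.5 mm/px spans pixel
  # radii ~10-60
  for (s in c(0.46, 0.31, 0.22, 0.17, 0.12, 0.086)) {
    r <- 5 / s
    m <- oracle_disc_mask(2 * ceiling(r) + 21, 2 * ceiling(r) + 21,
                          c(ceiling(r) + 10.3, ceiling(r) + 9.6), r,
                          label = mask_labels()["marker"],
                          background = mask_labels()["skin"])
    sf <- calibrate(m, marker_diameter_mm = 10)
    expect_lt(abs(sf$mm_per_px - s) / s, 0.01)
  }
})

test_that("a missing marker asks for an explicit scale; split markers warn", {
  m <- matrix(mask_labels()["skin"], 20, 20)
  expect_error(calibrate(m), "mm_per_px explicitly")
  m[2:5, 2:5] <- mask_labels()["marker"]
  m[12:18, 12:18] <- mask_labels()["marker"]
  sf <- calibrate(m, refine = FALSE)
  expect_match(sf$warnings, "largest")
  expect_equal(sf$marker_px_diameter, 2 * sqrt(49 / pi), tolerance = 1e-12)
})

test_that("corneal centre is recovered under partial lid occlusion", {
  for (s in 1:20) {
    cond <- c("normal", "blepharoptosis", "TAO")[1 + s %% 3]
    p <- params_for_condition(cond, seed = s)
    sc <- generate_scene(p)
    mask <- segment_image(sc$image)
    b <- detect_eyes(mask)[[1]]
    cc <- corneal_center(mask, b)
    expect_lt(sqrt(sum((cc$center - p$cornea_center)^2)), 2)
  }
  expect_error(corneal_center(matrix(mask_labels()["skin"], 5, 5)), "no cornea")
})

test_that("PF is identically MRD1 + MRD2 and the area partition is pixel-exact", {
  for (s in 1:10) {
    cond <- c("normal", "blepharoptosis", "lower eyelid retraction")[1 + s %% 3]
    sc <- scene_for(cond, seed = s)
    mask <- segment_image(sc$image)
    b <- detect_eyes(mask)[[1]]
    lmk <- locate_canthi(extract_contours(mask, b), b$laterality)
    sf <- calibrate(mask)
    r <- compute_morphometry(mask, lmk, sf, box = b)
    expect_equal(r$pf_mm, r$mrd1_mm + r$mrd2_mm, tolerance = 1e-9)
    # lateral + medial + visible cornea = total palpebral area, pixel-exact
    sub <- mask[(b$box[2] + 1):b$box[4], (b$box[1] + 1):b$box[3]]
    total <- sum(sub %in% mask_labels()[c("fissure", "cornea")]) * sf$mm_per_px^2
    expect_equal(r$lateral_area_mm2 + r$medial_area_mm2 + r$corneal_area_mm2,
                 total, tolerance = 1e-6 * total)
  }
})

test_that("doubling the scale doubles lengths and quadruples areas exactly", {
  sc <- scene_for("normal", seed = 9)
  mask <- segment_image(sc$image)
  b <- detect_eyes(mask)[[1]]
  lmk <- locate_canthi(extract_contours(mask, b), b$laterality)
  r1 <- compute_morphometry(mask, lmk, 0.2, box = b)
  r2 <- compute_morphometry(mask, lmk, 0.4, box = b)
  for (f in c("mrd1_mm", "mrd2_mm", "pf_mm", "upper_lid_length_mm",
              "lower_lid_length_mm", "icd_mm"))
    expect_equal(r2[[f]], 2 * r1[[f]], tolerance = 1e-12)
  for (f in c("corneal_area_mm2", "lateral_area_mm2", "medial_area_mm2"))
    expect_equal(r2[[f]], 4 * r1[[f]], tolerance = 1e-12)
})

test_that("a straight-chord lid measures its chord length", {
  lab <- mask_labels()
  m <- matrix(lab["skin"], 60, 120)
  m[30:40, 20:100] <- lab["fissure"]      # rectangular fissure: flat margins
  m[32:38, 55:65] <- lab["cornea"]
  b <- detect_eyes(m)[[1]]
  lmk <- locate_canthi(extract_contours(m, b), b$laterality)
  r <- compute_morphometry(m, lmk, 0.2, box = b)
  chord_px <- lmk$icd_px
  expect_equal(r$upper_lid_length_mm, chord_px * 0.2, tolerance = 1e-6)
  expect_equal(r$lower_lid_length_mm, chord_px * 0.2, tolerance = 1e-6)
})

test_that("a ptotic eye recovers its truth MRD1 within two pixels worth of mm", {
  for (s in 1:10) {
    p <- params_for_condition("blepharoptosis", seed = s)
    sc <- generate_scene(p)
    mask <- segment_image(sc$image)
    b <- detect_eyes(mask)[[1]]
    lmk <- locate_canthi(extract_contours(mask, b), b$laterality)
    r <- compute_morphometry(mask, lmk, calibrate(mask), box = b)
    expect_lt(abs(r$mrd1_mm - sc$truth_report$mrd1_mm), 2 * 0.2)
  }
})

test_that("visit-to-visit diffs report signed parameter deltas", {
  a <- scene_for("normal", seed = 1)$truth_report
  b <- scene_for("blepharoptosis", seed = 1)$truth_report
  d <- morphometry_diff(a, b)
  expect_equal(d$delta[d$parameter == "mrd1_mm"], b$mrd1_mm - a$mrd1_mm)
  expect_equal(nrow(d), 9)
})
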