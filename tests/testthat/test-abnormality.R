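# Parametric detectors, region classifiers, tumour segmentation.

fake_report <- function(mrd1 = 3.5, mrd2 = 2.5, icd = 29) {
  lidmorph:::new_morphometry_report(
    mrd1_mm = mrd1, mrd2_mm = mrd2, pf_mm = mrd1 + mrd2,
    corneal_area_mm2 = 60, lateral_area_mm2 = 25, medial_area_mm2 = 30,
    upper_lid_length_mm = 31, lower_lid_length_mm = 30,
    corneal_center_px = c(100, 100), axis_column = 100L,
    icd_mm = icd, mm_per_px = 0.2)
}

test_that("parametric findings obey strict thresholds with coherent scores", {
  th <- default_thresholds()
  f <- detect_parametric(fake_report(mrd1 = 1.0), th)
  expect_identical(f$change, "ptosis")
  expect_gt(f$score, 0.5)
  expect_identical(nrow(detect_parametric(fake_report(mrd1 = 2.0), th)), 0L)  # boundary
  f2 <- detect_parametric(fake_report(mrd1 = 6.0, mrd2 = 6.0), th)
  expect_setequal(f2$change, c("upper_retraction", "lower_retraction"))
  expect_identical(f2$region[f2$change == "upper_retraction"], "upper_eyelid")
  expect_identical(f2$region[f2$change == "lower_retraction"], "lower_eyelid")
})

test_that("threshold invariants are enforced", {
  expect_error(default_thresholds(ptosis_mrd1_max_mm = 6), "below")
  expect_error(default_thresholds(tumor_min_area_mm2 = -1), "positive")
})

patches_for <- function(cond, seed) {
  sc <- scene_for(cond, seed = seed)
  mask <- segment_image(sc$image)
  b <- detect_eyes(mask)[[1]]
  lmk <- locate_canthi(extract_contours(mask, b), b$laterality)
  list(rg = extract_regions(sc$image, mask, lmk), sc = sc, mask = mask, b = b)
}

test_that("the baseline inner-canthus classifier separates the fold types", {
  for (s in 1:5) {
    fi <- classify_inner_canthus(patches_for("epicanthus inversus", s)$rg$inner_canthus_patch)
    expect_identical(fi$change, "epicanthus_inversus")
    fo <- classify_inner_canthus(patches_for("other types of epicanthus", s)$rg$inner_canthus_patch)
    expect_identical(fo$change, "epicanthus_other")
    fn <- classify_inner_canthus(patches_for("normal", s)$rg$inner_canthus_patch)
    expect_identical(nrow(fn), 0L)
  }
})

test_that("any callable honouring the classifier contract slots in", {
  pt <- patches_for("normal", 2)
  stub <- function(patch) list(label = "epicanthus_other", prob = 0.77)
  f <- classify_inner_canthus(pt$rg$inner_canthus_patch, stub)
  expect_identical(f$change, "epicanthus_other")
  expect_equal(f$score, 0.77)
  tiny <- list(image = array(0.5, c(3, 3, 3)), mask = matrix(1L, 3, 3), box = c(0, 0, 3, 3))
  out <- classify_inner_canthus(tiny)
  expect_identical(nrow(out), 0L)
  expect_match(attr(out, "warnings"), "degenerate")
})

test_that("the baseline eyelid classifier detects margin textures per region", {
  for (s in 1:5) {
    pt <- patches_for("entropion and trichiasis", s)
    fu <- classify_eyelid(pt$rg$upper_eyelid_patch, "upper_eyelid")
    expect_true("entropion_trichiasis" %in% fu$change)
    pe <- patches_for("ectropion", s)
    fl <- classify_eyelid(pe$rg$lower_eyelid_patch, "lower_eyelid")
    expect_true("ectropion" %in% fl$change)
    pn <- patches_for("normal", s)
    expect_identical(nrow(classify_eyelid(pn$rg$upper_eyelid_patch, "upper_eyelid")), 0L)
    expect_identical(nrow(classify_eyelid(pn$rg$lower_eyelid_patch, "lower_eyelid")), 0L)
  }
})

test_that("lesions are segmented with a calibrated area and a thresholded finding", {
  p <- params_for_condition("eyelid tumor", seed = 4)
  p$tumor_radius_mm <- 2
  sc <- generate_scene(p)
  mask <- segment_image(sc$image)
  b <- detect_eyes(mask)[[1]]
  patch <- lidmorph:::region_patch(sc$image, mask, b$box)
  res <- segment_tumor(patch, calibrate(mask))
  expect_lt(abs(res$area_mm2 - 4 * pi) / (4 * pi), 0.1)
  expect_identical(res$finding$change, "tumor")
  # no tumour -> none
  pn <- patches_for("normal", 4)
  patch_n <- lidmorph:::region_patch(pn$sc$image, pn$mask, pn$b$box)
  res_n <- segment_tumor(patch_n, 0.2)
  expect_equal(res_n$area_mm2, 0)
  expect_identical(nrow(res_n$finding), 0L)
  # sub-threshold speck: mask returned, no finding (0.48 mm^2 at 0.2 mm/px)
  m <- matrix(mask_labels()["skin"], 30, 30)
  m[10:13, 10:12] <- mask_labels()["tumor"]
  speck <- list(image = array(0.5, c(30, 30, 3)), mask = m, box = c(0, 0, 30, 30))
  res_s <- segment_tumor(speck, 0.2)
  expect_equal(res_s$area_mm2, 12 * 0.04)
  expect_identical(nrow(res_s$finding), 0L)
  expect_true(any(res_s$lesion_mask))
})

test_that("no detector emits an inadmissible (region, change) pair", {
  expect_error(lidmorph:::finding("upper_eyelid", "ectropion", 0.9, "x"), "inadmissible")
  for (cond in c("blepharoptosis + ectropion", "BPES", "eyelid tumor")) {
    pt <- patches_for(cond, 6)
    rep_ <- run_pipeline(pt$sc, test_config())[[1]]
    adm <- admissibility_table()
    ok <- mapply(function(r, c) any(adm$region == r & adm$change == c),
                 rep_$findings$region, rep_$findings$change)
    expect_true(all(ok))
  }
})

test_that("classifier outputs are reproducible bit-for-bit given the seed", {
  a <- patches_for("epicanthus inversus", 8)
  b <- patches_for("epicanthus inversus", 8)
  expect_identical(classify_inner_canthus(a$rg$inner_canthus_patch),
                   classify_inner_canthus(b$rg$inner_canthus_patch))
})
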