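# Scene generator: analytic truth, determinism, validation, condition
# templates, cohorts.

test_that("rendered geometry carries its analytic truth (PF, marker size)", {
  # cornea on the vertical through the fissure centre, peak 4 + dip 1 mm
  p <- manual_params(peak_mm = 4, dip_mm = 1)
  sc <- generate_scene(p)
  expect_equal(sc$truth_report$pf_mm, 5, tolerance = 1e-12)
  expect_equal(sc$truth_report$mrd1_mm, 4, tolerance = 1e-12)
  expect_equal(sc$truth_report$mrd2_mm, 1, tolerance = 1e-12)
  # 10 mm marker at 0.2 mm/px rasterises to a ~50 px disc
  marker_px <- sum(sc$mask == mask_labels()["marker"])
  expect_equal(2 * sqrt(marker_px / pi), 50, tolerance = 0.03)
})

test_that("truth report equals closed-form geometry of the parameters", {
  for (s in 1:60) {
    cond <- c("normal", "blepharoptosis", "thyroid-associated ophthalmopathy")[1 + s %% 3]
    p <- params_for_condition(cond, seed = s)
    tr <- truth_morphometry(p)
    om <- oracle_margins(p)
    ax <- round(p$cornea_center[1])
    cy <- p$cornea_center[2]
    expect_equal(tr$mrd1_mm, (cy - om$yu(ax)) * p$mm_per_px, tolerance = 1e-9)
    expect_equal(tr$mrd2_mm, (om$yl(ax) - cy) * p$mm_per_px, tolerance = 1e-9)
    expect_equal(tr$pf_mm, tr$mrd1_mm + tr$mrd2_mm, tolerance = 1e-12)
    expect_equal(tr$icd_mm,
                 sqrt(sum((p$inner_canthus - p$outer_canthus)^2)) * p$mm_per_px,
                 tolerance = 1e-9)
  }
})

test_that("noise changes intensities only; identical params give identical scenes", {
  p1 <- manual_params(noise_sd = 0.05, seed = 1L)
  p2 <- manual_params(noise_sd = 0.05, seed = 2L)
  s1 <- generate_scene(p1); s1b <- generate_scene(p1); s2 <- generate_scene(p2)
  expect_identical(s1$mask, s2$mask)
  expect_false(identical(s1$image, s2$image))
  expect_identical(s1$image, s1b$image)
  expect_identical(s1$mask, s1b$mask)
})

test_that("mask pixels carry exactly one known label", {
  sc <- scene_for("blepharoptosis + trichiasis", seed = 5)
  expect_true(all(sc$mask %in% unname(mask_labels())))
  expect_true(is.matrix(sc$mask))
})

test_that("out-of-bounds geometry is rejected with the violated invariant named", {
  expect_error(manual_params(peak_mm = -1), "extrema")
  expect_error(eye_scene_params(inner_canthus = c(133, 140), outer_canthus = c(283, 140),
                                upper_curve_peak_mm = 3, lower_curve_dip_mm = 2,
                                cornea_center = c(208, 20)),   # above the lids
               "between the lid curves")
  expect_error(eye_scene_params(inner_canthus = c(133, 40), outer_canthus = c(283, 40),
                                upper_curve_peak_mm = 3, lower_curve_dip_mm = 2,
                                cornea_center = c(208, 40)),   # eye under the marker
               "marker")
  expect_error(manual_params(mm_per_px = -0.1), "mm_per_px")
  expect_error(eye_scene_params(inner_canthus = c(133, 140), outer_canthus = c(283, 200),
                                upper_curve_peak_mm = 3, lower_curve_dip_mm = 2,
                                cornea_center = c(208, 170)),
               "horizontal band")
})

test_that("condition templates satisfy their defining geometric predicates", {
  th <- default_thresholds()
  jm <- 0.3   # jitter margin: templates stay this far clear of the threshold
  for (s in 1:10) {
    expect_lt(truth_morphometry(params_for_condition("blepharoptosis", seed = s))$mrd1_mm,
              th$ptosis_mrd1_max_mm - jm)
    expect_gt(truth_morphometry(params_for_condition("TAO", seed = s))$mrd1_mm,
              th$upper_retraction_mrd1_min_mm + jm)
    expect_gt(truth_morphometry(params_for_condition("lower eyelid retraction", seed = s))$mrd2_mm,
              th$lower_retraction_mrd2_min_mm + jm)
    pb <- params_for_condition("BPES", seed = s)
    expect_lt(truth_morphometry(pb)$icd_mm, th$bpes_icd_max_mm - jm)
    expect_identical(pb$fold_type, "epicanthus_inversus")
    pn <- params_for_condition("normal", seed = s)
    expect_gt(truth_morphometry(pn)$mrd1_mm, th$ptosis_mrd1_max_mm + jm)
    expect_lt(truth_morphometry(pn)$mrd1_mm, th$upper_retraction_mrd1_min_mm - jm)
    expect_identical(pn$fold_type, "none")
    expect_null(pn$tumor_center)
  }
})

test_that("condition truth diagnoses match the requested label set", {
  expect_setequal(scene_for("blepharoptosis + trichiasis", seed = 2)$truth_diagnoses,
                  c("blepharoptosis", "entropion and trichiasis"))
  expect_setequal(scene_for("BPES", seed = 2)$truth_diagnoses, "BPES")
  expect_length(scene_for("normal", seed = 2)$truth_diagnoses, 0)
  p <- params_for_condition("blepharoptosis + trichiasis", seed = 2)
  expect_true(p$trichiasis_flag)
})

test_that("unknown condition labels are rejected with the supported list", {
  expect_error(params_for_condition("keratoconus"), "supported labels")
})

test_that("cohorts respect counts, are deterministic, and tag conditions", {
  mix <- c(normal = 3, "eyelid tumor" = 2)
  a <- generate_cohort(mix, seed = 7)
  b <- generate_cohort(mix, seed = 7)
  expect_length(a, 5)
  expect_identical(vapply(a, function(s) s$condition, ""),
                   c(rep("normal", 3), rep("eyelid tumor", 2)))
  n_tumor <- vapply(a, function(s) sum(s$mask == mask_labels()["tumor"]), 0L)
  expect_true(all(n_tumor[4:5] > 0) && all(n_tumor[1:3] == 0))
  expect_identical(a[[4]]$image, b[[4]]$image)
  expect_length(generate_cohort(list(), seed = 1), 0)
  expect_error(generate_cohort(c(normal = -1)), ">= 0")
})
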