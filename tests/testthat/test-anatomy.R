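# Contour extraction, canthus localisation, region decomposition.

test_that("upper chain never lies below the lower chain; chains track the parabola", {
  for (s in 1:8) {
    p <- params_for_condition("normal", seed = s)
    sc <- generate_scene(p)
    mask <- segment_image(sc$image)
    b <- detect_eyes(mask)[[1]]
    ct <- extract_contours(mask, b)
    shared <- intersect(ct$upper[, 1], ct$lower[, 1])
    iu <- match(shared, ct$upper[, 1]); il <- match(shared, ct$lower[, 1])
    expect_true(all(ct$upper[iu, 2] <= ct$lower[il, 2]))
    # rasterisation oracle: chains within 1 px of the analytic lid curves
    om <- oracle_margins(p)
    mid <- ct$upper[, 1] > quantile(ct$upper[, 1], 0.1) &
           ct$upper[, 1] < quantile(ct$upper[, 1], 0.9)
    expect_lt(max(abs(ct$upper[mid, 2] - om$yu(ct$upper[mid, 1]))), 1.01)
    expect_lt(max(abs(ct$lower[mid, 2] - om$yl(ct$lower[mid, 1]))), 1.01)
  }
})

test_that("a one-pixel-tall fissure yields coinciding chains", {
  lab <- mask_labels()
  m <- matrix(lab["skin"], 30, 40)
  m[15, 10:30] <- lab["fissure"]
  ct <- extract_contours(m, c(5, 5, 35, 25))
  expect_identical(ct$upper, ct$lower)
  empty_box <- c(0, 0, 5, 5)
  expect_error(extract_contours(m, empty_box), "no fissure")
})

test_that("canthi land within 2 px of generator truth", {
  for (s in 1:30) {
    cond <- c("normal", "blepharoptosis", "TAO", "BPES")[1 + s %% 4]
    p <- params_for_condition(cond, seed = s)
    sc <- generate_scene(p)
    mask <- segment_image(sc$image)
    b <- detect_eyes(mask)[[1]]
    lmk <- locate_canthi(extract_contours(mask, b), b$laterality)
    expect_lt(sqrt(sum((lmk$inner_canthus - p$inner_canthus)^2)), 2)
    expect_lt(sqrt(sum((lmk$outer_canthus - p$outer_canthus)^2)), 2)
  }
})

test_that("the nasal-side endpoint is the inner canthus under the laterality convention", {
  p <- params_for_condition("normal", seed = 21, laterality = "right")
  sc <- generate_scene(p)
  mask <- segment_image(sc$image)
  b <- detect_eyes(mask)[[1]]
  expect_identical(b$laterality, "right")
  lmk <- locate_canthi(extract_contours(mask, b), b$laterality)
  expect_gt(lmk$inner_canthus[1], lmk$outer_canthus[1])  # larger-x endpoint
  # margins run inner -> outer
  expect_equal(lmk$upper_margin[1, ], lmk$inner_canthus)
  expect_equal(lmk$upper_margin[nrow(lmk$upper_margin), ], lmk$outer_canthus)
})

test_that("mirroring a scene mirrors the landmarks exactly", {
  sc <- scene_for("normal", seed = 31)
  mask <- segment_image(sc$image)
  w <- ncol(mask)
  flipped <- mask[, w:1]
  b <- detect_eyes(mask)[[1]]
  bf <- detect_eyes(flipped)[[1]]
  expect_false(identical(b$laterality, bf$laterality))
  lmk <- locate_canthi(extract_contours(mask, b), b$laterality)
  lmkf <- locate_canthi(extract_contours(flipped, bf), bf$laterality)
  expect_equal(lmkf$inner_canthus[1], w - 1 - lmk$inner_canthus[1], tolerance = 1e-6)
  expect_equal(lmkf$inner_canthus[2], lmk$inner_canthus[2], tolerance = 1e-6)
  expect_equal(lmkf$outer_canthus[1], w - 1 - lmk$outer_canthus[1], tolerance = 1e-6)
  expect_equal(lmkf$icd_px, lmk$icd_px, tolerance = 1e-6)
})

test_that("canthus squares use side round(icd/3) with round-half-to-even", {
  fake_lm <- function(icd) {
    up <- cbind(seq(50, 50 + icd, length.out = 50), rep(100, 50))
    structure(list(inner_canthus = c(50, 100), outer_canthus = c(50 + icd, 100),
                   upper_margin = up, lower_margin = up + c(rep(0, 50), rep(10, 50)),
                   icd_px = icd, laterality = "left"),
              class = "eye_landmarks")
  }
  img <- array(0.5, dim = c(400, 500, 3))
  msk <- matrix(mask_labels()["skin"], 400, 500)
  expect_equal(extract_regions(img, msk, fake_lm(300))$side_px, 100)
  expect_equal(extract_regions(img, msk, fake_lm(301))$side_px, 100)  # 100.33 rounds down
  expect_equal(extract_regions(img, msk, fake_lm(304.5))$side_px, 102)  # 101.5 -> even
  expect_equal(extract_regions(img, msk, fake_lm(307.5))$side_px, 102)  # 102.5 -> even
})

test_that("eyelid patches are the minimum bounding rectangles of the margins", {
  sc <- scene_for("normal", seed = 41)
  mask <- segment_image(sc$image)
  b <- detect_eyes(mask)[[1]]
  lmk <- locate_canthi(extract_contours(mask, b), b$laterality)
  rg <- extract_regions(sc$image, mask, lmk)
  up <- lmk$upper_margin
  expect_equal(rg$upper_eyelid_patch$box,
               c(floor(min(up[, 1])), floor(min(up[, 2])),
                 floor(max(up[, 1])) + 1, floor(max(up[, 2])) + 1))
  # union of the four patch boxes covers every margin-polyline pixel
  boxes <- lapply(rg[c("inner_canthus_patch", "outer_canthus_patch",
                       "upper_eyelid_patch", "lower_eyelid_patch")], `[[`, "box")
  covered <- function(pt) any(vapply(boxes, function(bx)
    pt[1] >= bx[1] && pt[1] < bx[3] && pt[2] >= bx[2] && pt[2] < bx[4], TRUE))
  pts <- rbind(lmk$upper_margin, lmk$lower_margin)
  expect_true(all(apply(pts, 1, covered)))
})

test_that("patches clipped past half their area carry a warning flag", {
  img <- array(0.5, dim = c(60, 60, 3))
  msk <- matrix(mask_labels()["skin"], 60, 60)
  up <- cbind(seq(2, 50, length.out = 30), rep(5, 30))
  lmk <- structure(list(inner_canthus = c(2, 5), outer_canthus = c(50, 5),
                        upper_margin = up, lower_margin = up + 3,
                        icd_px = 48, laterality = "left"),
                   class = "eye_landmarks")
  rg <- extract_regions(img, msk, lmk)   # square side 16 centred near the border
  expect_true(rg$inner_canthus_patch$box[1] >= 0)
  expect_false(rg$upper_eyelid_patch$warning)
})
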