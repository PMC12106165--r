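#  Abnormality recognition: threshold-based parametric detectors on the
#  morphometry report, plus pluggable region classifiers and a tumour
#  segmentator with deterministic texture/blob baselines.
#
#  The classifier contract is a callable `patch -> list(label, prob)`; any
#  learned model honouring it slots in without touching downstream modules.

#' Screening thresholds
#'
#' Threshold set for the parametric detectors.  The defaults follow common
#' oculoplastic convention: ptosis when MRD1 < 2 mm, upper lid retraction
#' when MRD1 > 5 mm, lower lid retraction when MRD2 > 5.5 mm, a reportable
#' lesion from 1 mm^2, and a BPES-compatible horizontal fissure below 30 mm.
#' `score_slope_mm` sets the logistic slope converting a signed threshold
#' margin into a score in \[0,1\] (score 0.5 exactly at the threshold).
#'
#' @param ptosis_mrd1_max_mm,upper_retraction_mrd1_min_mm,lower_retraction_mrd2_min_mm
#'   MRD thresholds in mm.
#' @param tumor_min_area_mm2 minimum reportable lesion area.
#' @param bpes_icd_max_mm inter-canthal distance bound used by the BPES rule.
#' @param score_slope_mm logistic slope in mm.
#' @return object of class `thresholds`.
#' @export
default_thresholds <- function(ptosis_mrd1_max_mm = 2.0,
                               upper_retraction_mrd1_min_mm = 5.0,
                               lower_retraction_mrd2_min_mm = 5.5,
                               tumor_min_area_mm2 = 1.0,
                               bpes_icd_max_mm = 30.0,
                               score_slope_mm = 0.5) {
  th <- list(ptosis_mrd1_max_mm = ptosis_mrd1_max_mm,
             upper_retraction_mrd1_min_mm = upper_retraction_mrd1_min_mm,
             lower_retraction_mrd2_min_mm = lower_retraction_mrd2_min_mm,
             tumor_min_area_mm2 = tumor_min_area_mm2,
             bpes_icd_max_mm = bpes_icd_max_mm,
             score_slope_mm = score_slope_mm)
  if (any(unlist(th) <= 0)) abort("thresholds must all be positive")
  if (th$ptosis_mrd1_max_mm >= th$upper_retraction_mrd1_min_mm)
    abort("ptosis_mrd1_max_mm must be below upper_retraction_mrd1_min_mm")
  structure(th, class = "thresholds")
}

#' Parametric change detectors
#'
#' Screens the morphometry report against the thresholds with strict
#' inequalities: ptosis iff `mrd1 < ptosis_mrd1_max_mm` (upper eyelid),
#' upper retraction iff `mrd1 > upper_retraction_mrd1_min_mm`, lower
#' retraction iff `mrd2 > lower_retraction_mrd2_min_mm`.  Scores are the
#' logistic of the signed threshold margin, so a finding is emitted exactly
#' when its score exceeds 0.5.
#'
#' @param report a `morphometry_report`.
#' @param thresholds a [default_thresholds()] object.
#' @return findings data.frame (`region`, `change`, `score`, `evidence`).
#' @export
detect_parametric <- function(report, thresholds = default_thresholds()) {
  th <- thresholds; sl <- th$score_slope_mm
  f <- empty_findings()
  if (report$mrd1_mm < th$ptosis_mrd1_max_mm)
    f <- rbind(f, finding("upper_eyelid", "ptosis",
                          logistic_score(th$ptosis_mrd1_max_mm - report$mrd1_mm, sl),
                          sprintf("mrd1_mm=%.3f < %.2f", report$mrd1_mm, th$ptosis_mrd1_max_mm)))
  if (report$mrd1_mm > th$upper_retraction_mrd1_min_mm)
    f <- rbind(f, finding("upper_eyelid", "upper_retraction",
                          logistic_score(report$mrd1_mm - th$upper_retraction_mrd1_min_mm, sl),
                          sprintf("mrd1_mm=%.3f > %.2f", report$mrd1_mm, th$upper_retraction_mrd1_min_mm)))
  if (report$mrd2_mm > th$lower_retraction_mrd2_min_mm)
    f <- rbind(f, finding("lower_eyelid", "lower_retraction",
                          logistic_score(report$mrd2_mm - th$lower_retraction_mrd2_min_mm, sl),
                          sprintf("mrd2_mm=%.3f > %.2f", report$mrd2_mm, th$lower_retraction_mrd2_min_mm)))
  f
}

# Darkened-lid-tissue pixels: skin-labelled pixels whose intensity is a
# *uniform* attenuation of the skin palette colour (the rendered crease /
# lash textures sit at 0.70-0.72 of skin intensity on every channel).  The
# uniformity bound rejects hue shifts such as the red tarsal band, whose
# per-channel ratios are far apart.
textured_skin <- function(patch, lo = 0.60, hi = 0.82, max_spread = 0.15) {
  skin <- scene_palette()["skin", ]
  m <- patch$mask == mask_labels()["skin"]
  r1 <- patch$image[, , 1] / skin[1]
  r2 <- patch$image[, , 2] / skin[2]
  r3 <- patch$image[, , 3] / skin[3]
  ratio <- (r1 + r2 + r3) / 3
  spread <- pmax(r1, r2, r3) - pmin(r1, r2, r3)
  m & ratio >= lo & ratio <= hi & spread <= max_spread
}

patch_degenerate <- function(patch, min_side = 5L) {
  any(dim(patch$mask) < min_side)
}

#' Baseline inner-canthus classifier
#'
#' Geometric fold features on the canthus square: coverage of darkened
#' fold-crease pixels, and the sign of their mean vertical offset from the
#' patch centre (a fold arising from the lower lid — epicanthus inversus —
#' sits below the canthus; other folds above).
#'
#' @param patch canthus patch (`list(image, mask, box)`).
#' @return `list(label, prob)` with label in `none`, `epicanthus_inversus`,
#'   `epicanthus_other`.
#' @export
baseline_inner_canthus_classifier <- function(patch) {
  tx <- which(textured_skin(patch), arr.ind = TRUE)
  n <- nrow(tx)
  if (n < 15) return(list(label = "none", prob = 1 - logistic_score(n - 15, 8)))
  mid_row <- (nrow(patch$mask) + 1) / 2
  below <- mean(tx[, 1]) - mid_row
  list(label = if (below > 0) "epicanthus_inversus" else "epicanthus_other",
       prob = logistic_score(n - 15, 8))
}

#' Classify the inner canthus region
#'
#' @param patch inner-canthus patch from [extract_regions()].
#' @param classifier callable `patch -> list(label, prob)`; the default is
#'   [baseline_inner_canthus_classifier()].
#' @return a one-row findings data.frame, or an empty one for `"none"` /
#'   degenerate patches (degenerate patches also attach a warning attribute).
#' @export
classify_inner_canthus <- function(patch, classifier = baseline_inner_canthus_classifier) {
  if (patch_degenerate(patch)) {
    out <- empty_findings()
    attr(out, "warnings") <- "inner canthus patch degenerate (side <= 4 px)"
    return(out)
  }
  res <- classifier(patch)
  if (res$label == "none") return(empty_findings())
  finding("inner_canthus", res$label, res$prob,
          sprintf("inner canthus classifier margin %.2f", res$prob))
}

#' Baseline eyelid classifier
#'
#' Margin-texture features on an eyelid patch, evaluated on the central 70 %
#' of columns (the patch ends overlap the canthus squares): darkened
#' lash-stroke pixels signal the combined entropion/trichiasis change, and
#' red-dominant pixels (`R - G > 0.25`) an everted tarsal band (ectropion).
#'
#' @param patch eyelid patch.
#' @return list of `list(label, prob)` entries (multi-label).
#' @export
baseline_eyelid_classifier <- function(patch) {
  w <- ncol(patch$mask)
  keep_cols <- seq_len(w) >= 0.15 * w & seq_len(w) <= 0.85 * w
  dark <- textured_skin(patch)
  red <- (patch$image[, , 1] - patch$image[, , 2]) > 0.25
  n_dark <- sum(dark[, keep_cols])
  n_red <- sum(red[, keep_cols])
  out <- list()
  if (n_dark >= 15)
    out <- c(out, list(list(label = "entropion_trichiasis",
                            prob = logistic_score(n_dark - 15, 8))))
  if (n_red >= 15)
    out <- c(out, list(list(label = "ectropion",
                            prob = logistic_score(n_red - 15, 8))))
  out
}

#' Classify an eyelid region (multi-label)
#'
#' @param patch upper or lower eyelid patch from [extract_regions()].
#' @param region `"upper_eyelid"` or `"lower_eyelid"`; labels inadmissible
#'   for the region (ectropion on the upper lid) are dropped.
#' @param classifier callable `patch -> list of list(label, prob)`; default
#'   [baseline_eyelid_classifier()].
#' @return findings data.frame (possibly empty).
#' @export
classify_eyelid <- function(patch, region = c("upper_eyelid", "lower_eyelid"),
                            classifier = baseline_eyelid_classifier) {
  region <- match.arg(region)
  if (patch_degenerate(patch)) {
    out <- empty_findings()
    attr(out, "warnings") <- paste(region, "patch degenerate (side <= 4 px)")
    return(out)
  }
  adm <- admissibility_table()
  out <- empty_findings()
  for (res in classifier(patch)) {
    if (!any(adm$region == region & adm$change == res$label)) next
    out <- rbind(out, finding(region, res$label, res$prob,
                              sprintf("eyelid classifier margin %.2f", res$prob)))
  }
  out
}

#' Segment a lid lesion and report its area
#'
#' Baseline blob segmentation on the tumour label within the patch (the
#' output contract of a learned lesion segmentator): returns the lesion mask,
#' the calibrated area of the largest lesion, and a finding iff that area
#' reaches `tumor_min_area_mm2`.  The area is always reported because lesion
#' size feeds surgical planning.
#'
#' @param patch an eye-box patch (`list(image, mask, box)`).
#' @param scale a `scale_factor` or mm-per-px number.
#' @param thresholds a [default_thresholds()] object.
#' @param region anatomical region to attribute a finding to; `NULL` infers
#'   upper/lower eyelid from the lesion centroid relative to the patch centre.
#' @return list `lesion_mask` (logical matrix), `area_mm2`, `finding`
#'   (one-row findings data.frame or empty).
#' @export
segment_tumor <- function(patch, scale, thresholds = default_thresholds(),
                          region = NULL) {
  s <- if (inherits(scale, "scale_factor")) scale$mm_per_px else as.numeric(scale)
  bin <- patch$mask == mask_labels()["tumor"]
  if (!any(bin))
    return(list(lesion_mask = bin, area_mm2 = 0, finding = empty_findings()))
  cc <- EBImage::bwlabel(bin)
  sizes <- tabulate(cc[cc > 0])
  main <- cc == which.max(sizes)
  area <- max(sizes) * s^2
  if (is.null(region)) {
    cy <- mean(which(main, arr.ind = TRUE)[, 1])
    region <- if (cy > nrow(patch$mask) / 2) "lower_eyelid" else "upper_eyelid"
  }
  fnd <- if (area >= thresholds$tumor_min_area_mm2)
    finding(region, "tumor", logistic_score(area - thresholds$tumor_min_area_mm2, 0.5),
            sprintf("lesion area %.2f mm^2", area))
  else empty_findings()
  list(lesion_mask = main, area_mm2 = area, finding = fnd)
}
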