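#  Label codes, rendering palette, and the region/change admissibility table.
#  The palette is the documented contract between the scene renderer and the
#  baseline nearest-colour segmenter.

#' Segmentation label codes
#'
#' Integer codes used in every [SegMask][segment_image]: background 0, skin 1,
#' palpebral fissure 2, cornea 3, tumor 4, fiducial marker 5.  The code table
#' is exported in JSON report headers.
#'
#' @return named integer vector of label codes.
#' @export
#' @examples
#' mask_labels()
mask_labels <- function() {
  c(background = 0L, skin = 1L, fissure = 2L, cornea = 3L,
    tumor = 4L, marker = 5L)
}

#' Rendering palette of the synthetic scene generator
#'
#' RGB colours (rows, in \[0,1\]) used to render each mask class.  The baseline
#' segmenter inverts this palette by nearest-colour assignment, so the matrix
#' is part of the documented interface between `generate_scene()` and
#' `segment_image()`.
#'
#' @return 6 x 3 numeric matrix, rownames = label names.
#' @export
scene_palette <- function() {
  p <- rbind(
    background = c(0.08, 0.08, 0.10),
    skin       = c(0.87, 0.72, 0.60),
    fissure    = c(0.97, 0.97, 0.95),
    cornea     = c(0.22, 0.14, 0.10),
    tumor      = c(0.93, 0.82, 0.25),
    marker     = c(0.10, 0.55, 0.85))
  colnames(p) <- c("r", "g", "b")
  p
}

# Texture colours: intensity-level detail drawn on lid tissue.  All remain
# nearest to the skin palette colour so segmentation is unaffected.
texture_colors <- function() {
  skin <- scene_palette()["skin", ]
  list(
    lash   = skin * 0.70,            # entropion / trichiasis margin strokes
    crease = skin * 0.72,            # epicanthal fold crease
    tarsal = c(0.85, 0.45, 0.45))    # everted tarsal band (ectropion)
}

#' Admissible (region, change) pairs
#'
#' The eight pathological changes and the anatomical regions in which each may
#' be reported.  No detector ever emits a pair outside this table; the atlas
#' validates its rules against it.
#'
#' @return data.frame with columns `region`, `change`.
#' @export
admissibility_table <- function() {
  rbind(
    data.frame(region = "upper_eyelid",
               change = c("ptosis", "upper_retraction", "entropion_trichiasis", "tumor")),
    data.frame(region = "lower_eyelid",
               change = c("lower_retraction", "ectropion", "entropion_trichiasis", "tumor")),
    data.frame(region = "inner_canthus",
               change = c("epicanthus_inversus", "epicanthus_other", "tumor")),
    data.frame(region = "outer_canthus", change = "tumor"))
}

change_labels <- function() {
  c("entropion_trichiasis", "lower_retraction", "upper_retraction",
    "ectropion", "tumor", "ptosis", "epicanthus_inversus", "epicanthus_other")
}

region_labels <- function() {
  c("inner_canthus", "outer_canthus", "upper_eyelid", "lower_eyelid")
}

#' Disease labels recognised by the default atlas
#'
#' @return character vector of the eight disease/change outcome labels the
#'   shipped rules can emit (multimorbidity label sets are compositions of
#'   these).
#' @export
disease_labels <- function() {
  c("blepharoptosis", "thyroid-associated ophthalmopathy",
    "entropion and trichiasis", "ectropion", "eyelid tumor",
    "epicanthus inversus", "other types of epicanthus", "BPES")
}

# Construct one finding row (region-level pathological change).
finding <- function(region, change, score, evidence) {
  adm <- admissibility_table()
  if (!any(adm$region == region & adm$change == change))
    abort("inadmissible finding: change '", change, "' in region '", region, "'")
  stopifnot(score >= 0, score <= 1)
  data.frame(region = region, change = change, score = score,
             evidence = evidence, stringsAsFactors = FALSE)
}

empty_findings <- function() {
  data.frame(region = character(), change = character(),
             score = numeric(), evidence = character(), stringsAsFactors = FALSE)
}
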