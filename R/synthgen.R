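#  Seeded parametric generator of periocular scenes with exact analytic ground
#  truth.  Scenes emulate the standardised frontal photographic protocol:
#  primary gaze, one or two eyes, and a circular 10-mm fiducial marker on the
#  forehead that carries the only absolute scale information.
#
#  Lid margins are quadratic arcs (a parabola through both canthi with one
#  signed extremum relative to the canthus-to-canthus chord): the minimal
#  smooth curve family matching clinical lid shape, with arc length available
#  by quadrature for the analytic truth report.

default_canvas <- function() {
  list(image_size = c(220L, 320L), mm_per_px = 0.2, chord_y = 140,
       marker_center = c(160, 40), marker_diameter_mm = 10,
       cornea_radius_mm = 5.5, noise_sd = 0.02)
}

#' Construct eye-scene parameters
#'
#' The generative ground truth for one rendered eye plus the shared fiducial
#' marker.  All point coordinates are 0-based pixels (`c(x, y)`); lengths with
#' an `_mm` suffix are millimetres, converted with `mm_per_px`.
#'
#' @param image_size integer `c(height, width)` in px.
#' @param laterality `"left"` or `"right"` (the subject's side).
#' @param inner_canthus,outer_canthus canthus points in px.
#' @param upper_curve_peak_mm,lower_curve_dip_mm signed vertical extremum of
#'   the upper/lower lid margin relative to the inter-canthal chord (mm,
#'   positive = away from the chord, i.e. an open fissure).
#' @param cornea_center cornea centre point (px), at primary gaze between the
#'   lid curves.
#' @param cornea_radius_mm corneal radius (mm); the clinical default 5.5 mm.
#' @param fold_type `"none"`, `"epicanthus_inversus"` (fold arising from the
#'   lower lid) or `"epicanthus_other"`.
#' @param fold_extent_mm horizontal cover of the fold over the inner canthus (mm).
#' @param entropion_flag,trichiasis_flag,ectropion_flag render the
#'   corresponding deterministic margin texture (inward lash strokes for the
#'   combined entropion/trichiasis class, an everted tarsal band for
#'   ectropion).
#' @param tumor_center,tumor_radius_mm optional circular lid lesion (`NULL`
#'   for none).
#' @param marker_center,marker_diameter_mm fiducial spec (default 10 mm).
#' @param mm_per_px ground-truth scale (> 0).
#' @param noise_sd additive Gaussian intensity noise (image only, never the
#'   mask).
#' @param seed integer seed for the noise stream.
#' @return object of class `eye_scene_params`.
#' @export
eye_scene_params <- function(image_size = c(220L, 320L),
                             laterality = c("left", "right"),
                             inner_canthus, outer_canthus,
                             upper_curve_peak_mm, lower_curve_dip_mm,
                             cornea_center, cornea_radius_mm = 5.5,
                             fold_type = c("none", "epicanthus_inversus", "epicanthus_other"),
                             fold_extent_mm = 3,
                             entropion_flag = FALSE, trichiasis_flag = FALSE,
                             ectropion_flag = FALSE,
                             tumor_center = NULL, tumor_radius_mm = NULL,
                             marker_center = c(160, 40), marker_diameter_mm = 10,
                             mm_per_px = 0.2, noise_sd = 0.02, seed = 1L) {
  p <- list(image_size = as.integer(image_size),
            laterality = match.arg(laterality),
            inner_canthus = as.numeric(inner_canthus),
            outer_canthus = as.numeric(outer_canthus),
            upper_curve_peak_mm = upper_curve_peak_mm,
            lower_curve_dip_mm = lower_curve_dip_mm,
            cornea_center = as.numeric(cornea_center),
            cornea_radius_mm = cornea_radius_mm,
            fold_type = match.arg(fold_type),
            fold_extent_mm = fold_extent_mm,
            entropion_flag = isTRUE(entropion_flag),
            trichiasis_flag = isTRUE(trichiasis_flag),
            ectropion_flag = isTRUE(ectropion_flag),
            tumor_center = if (is.null(tumor_center)) NULL else as.numeric(tumor_center),
            tumor_radius_mm = tumor_radius_mm,
            marker_center = as.numeric(marker_center),
            marker_diameter_mm = marker_diameter_mm,
            mm_per_px = mm_per_px, noise_sd = noise_sd,
            seed = as.integer(seed))
  class(p) <- "eye_scene_params"
  validate_scene_params(p)
  p
}

#' @export
print.eye_scene_params <- function(x, ...) {
  cat(sprintf("<eye_scene_params> %s eye, ICD %.1f mm, MRD1* %.2f / MRD2* %.2f mm, fold %s%s%s\n",
              x$laterality, icd_px(x) * x$mm_per_px,
              truth_morphometry(x)$mrd1_mm, truth_morphometry(x)$mrd2_mm,
              x$fold_type,
              if (!is.null(x$tumor_center)) ", tumor" else "",
              if (x$entropion_flag || x$trichiasis_flag || x$ectropion_flag) ", textured margin" else ""))
  invisible(x)
}

icd_px <- function(params) {
  sqrt(sum((params$inner_canthus - params$outer_canthus)^2))
}

# Lid margin curves as continuous functions of the column coordinate x.
# Returns yu(x), yl(x) and their derivatives; chord runs canthus to canthus.
lid_curves <- function(params) {
  xi <- params$inner_canthus[1]; yi <- params$inner_canthus[2]
  xo <- params$outer_canthus[1]; yo <- params$outer_canthus[2]
  s <- params$mm_per_px
  peak <- params$upper_curve_peak_mm / s
  dip  <- params$lower_curve_dip_mm / s
  dx <- xo - xi
  chord  <- function(x) yi + (x - xi) / dx * (yo - yi)
  dchord <- (yo - yi) / dx
  tt  <- function(x) (x - xi) / dx
  bump  <- function(x) { t <- tt(x); 4 * t * (1 - t) }
  dbump <- function(x) 4 * (1 - 2 * tt(x)) / dx
  list(yu  = function(x) chord(x) - peak * bump(x),
       yl  = function(x) chord(x) + dip * bump(x),
       dyu = function(x) dchord - peak * dbump(x),
       dyl = function(x) dchord + dip * dbump(x),
       x_range = range(xi, xo))
}

validate_scene_params <- function(p) {
  h <- p$image_size[1]; w <- p$image_size[2]
  if (!is_point(p$inner_canthus) || !is_point(p$outer_canthus))
    abort("invalid params: canthus points must be finite 2-D points")
  if (p$mm_per_px <= 0) abort("invalid params: mm_per_px must be > 0")
  pts <- rbind(p$inner_canthus, p$outer_canthus, p$cornea_center)
  if (any(pts[, 1] < 0 | pts[, 1] >= w | pts[, 2] < 0 | pts[, 2] >= h))
    abort("invalid params: canthi and cornea centre must lie inside the image")
  d <- icd_px(p)
  if (d <= 0) abort("invalid params: canthi coincide")
  if (abs(p$inner_canthus[2] - p$outer_canthus[2]) > 0.25 * d)
    abort("invalid params: canthi must lie on the same horizontal band ",
          "(|dy| <= 0.25 * inter-canthal distance)")
  if (p$upper_curve_peak_mm <= 0 || p$lower_curve_dip_mm <= 0)
    abort("invalid params: lid extrema must be positive (open fissure at primary gaze)")
  crv <- lid_curves(p)
  cx <- p$cornea_center[1]; cy <- p$cornea_center[2]
  if (cx <= min(crv$x_range) || cx >= max(crv$x_range) ||
      cy <= crv$yu(cx) || cy >= crv$yl(cx))
    abort("invalid params: cornea_center must lie between the lid curves at primary gaze")
  # marker disjoint from the eye region (incl. texture/tumour skirt)
  mr <- p$marker_diameter_mm / 2 / p$mm_per_px
  mb <- c(p$marker_center[1] - mr, p$marker_center[2] - mr,
          p$marker_center[1] + mr, p$marker_center[2] + mr)
  pad <- p$fold_extent_mm / p$mm_per_px + 8
  ylow <- crv$yl(mean(crv$x_range)) + pad +
    if (!is.null(p$tumor_radius_mm)) 2 * p$tumor_radius_mm / p$mm_per_px else 0
  eb <- c(min(crv$x_range) - pad, crv$yu(mean(crv$x_range)) - pad,
          max(crv$x_range) + pad, ylow)
  if (mb[1] < eb[3] && eb[1] < mb[3] && mb[2] < eb[4] && eb[2] < mb[4])
    abort("invalid params: marker region overlaps the eye region")
  if (mb[1] < 0 || mb[2] < 0 || mb[3] >= w || mb[4] >= h)
    abort("invalid params: marker must lie inside the image")
  invisible(p)
}

#' Analytic truth morphometry of scene parameters
#'
#' Computes the eight morphological parameters in closed form (quadrature for
#' areas and arc lengths) from the generative parameters, with no pixel
#' measurement involved.  Definitions match [compute_morphometry()]: MRD1/MRD2
#' are the signed vertical distances from the corneal centre to the upper /
#' lower margin on the corneal axis column, the palpebral fissure is their
#' sum, areas are the visible cornea and the nasal (medial) / temporal
#' (lateral) portions of the fissure-minus-cornea region split at the axis
#' column, and lid lengths are margin arc lengths.
#'
#' @param params an [eye_scene_params()] object.
#' @return a `morphometry_report` (see [compute_morphometry()]).
#' @export
truth_morphometry <- function(params) {
  s <- params$mm_per_px
  crv <- lid_curves(params)
  cx <- params$cornea_center[1]; cy <- params$cornea_center[2]
  r <- params$cornea_radius_mm / s
  ax <- round(cx)
  xr <- crv$x_range
  gap <- function(x) pmax(0, crv$yl(x) - crv$yu(x))
  cor_vis <- function(x) {
    q2 <- r^2 - (x - cx)^2
    q <- sqrt(pmax(0, q2))
    v <- pmin(crv$yl(x), cy + q) - pmax(crv$yu(x), cy - q)
    ifelse(q2 > 0, pmax(0, v), 0)
  }
  # nasal side of the axis column = side of the inner canthus
  nasal_right <- params$inner_canthus[1] > params$outer_canthus[1]
  nas <- if (nasal_right) c(ax, xr[2]) else c(xr[1], ax)
  tem <- if (nasal_right) c(xr[1], ax) else c(ax, xr[2])
  fis_n <- simpson(gap, nas[1], nas[2]); fis_t <- simpson(gap, tem[1], tem[2])
  cor_n <- simpson(cor_vis, max(nas[1], cx - r), min(nas[2], cx + r))
  cor_t <- simpson(cor_vis, max(tem[1], cx - r), min(tem[2], cx + r))
  new_morphometry_report(
    mrd1_mm = (cy - crv$yu(ax)) * s,
    mrd2_mm = (crv$yl(ax) - cy) * s,
    pf_mm = (cy - crv$yu(ax)) * s + (crv$yl(ax) - cy) * s,
    corneal_area_mm2 = (cor_n + cor_t) * s^2,
    lateral_area_mm2 = (fis_t - cor_t) * s^2,
    medial_area_mm2 = (fis_n - cor_n) * s^2,
    upper_lid_length_mm = arc_length(crv$dyu, xr[1], xr[2]) * s,
    lower_lid_length_mm = arc_length(crv$dyl, xr[1], xr[2]) * s,
    corneal_center_px = c(cx, cy), axis_column = as.integer(ax),
    icd_mm = icd_px(params) * s, mm_per_px = s)
}

# Change-level findings implied by the generative parameters (truth labels
# for cohort evaluation); thresholds are the same defaults the detectors use.
truth_findings <- function(params, thresholds = default_thresholds()) {
  rep_ <- truth_morphometry(params)
  f <- detect_parametric(rep_, thresholds)
  if (params$entropion_flag || params$trichiasis_flag)
    f <- rbind(f, finding("upper_eyelid", "entropion_trichiasis", 0.9, "rendered margin texture"))
  if (params$ectropion_flag)
    f <- rbind(f, finding("lower_eyelid", "ectropion", 0.9, "rendered tarsal band"))
  if (!is.null(params$tumor_center) &&
      pi * params$tumor_radius_mm^2 >= thresholds$tumor_min_area_mm2)
    f <- rbind(f, finding("lower_eyelid", "tumor", 0.9,
                          sprintf("lesion area %.2f mm^2", pi * params$tumor_radius_mm^2)))
  if (params$fold_type == "epicanthus_inversus")
    f <- rbind(f, finding("inner_canthus", "epicanthus_inversus", 0.9, "rendered fold"))
  if (params$fold_type == "epicanthus_other")
    f <- rbind(f, finding("inner_canthus", "epicanthus_other", 0.9, "rendered fold"))
  f
}

#' Render a scene from parameters
#'
#' Deterministic rasterisation (pixel-centre rule, no anti-aliasing) of one or
#' two eyes plus the fiducial marker.  The returned scene carries the label
#' mask, the analytically computed truth report and the disease label set the
#' parameters imply under the default atlas.  Identical parameters (including
#' the seed) give a bit-identical scene; with `noise_sd > 0`, different seeds
#' change only the image intensities, never the mask.
#'
#' @param params an [eye_scene_params()] object, or a list of two such objects
#'   sharing canvas, scale and marker (a binocular scene).
#' @return object of class `eye_scene` with fields `image` (H x W x 3 array in
#'   \[0,1\]), `mask` (H x W integer matrix, see [mask_labels()]), `params`,
#'   `truth_report`, `truth_findings`, `truth_diagnoses`, `n_eyes`.
#' @export
#' @examples
#' p <- params_for_condition("normal", seed = 1)
#' sc <- generate_scene(p)
#' sc$truth_report$pf_mm
generate_scene <- function(params) {
  eyes <- if (inherits(params, "eye_scene_params")) list(params) else params
  stopifnot(length(eyes) >= 1, length(eyes) <= 2)
  for (e in eyes) validate_scene_params(e)
  p1 <- eyes[[1]]
  if (length(eyes) == 2) {
    p2 <- eyes[[2]]
    if (!identical(p1$image_size, p2$image_size) || p1$mm_per_px != p2$mm_per_px ||
        !identical(p1$marker_center, p2$marker_center))
      abort("binocular scene: eyes must share image size, scale and marker")
    span <- function(p) range(p$inner_canthus[1], p$outer_canthus[1]) +
      c(-1, 1) * (p$fold_extent_mm / p$mm_per_px + 2)
    s1 <- span(p1); s2 <- span(p2)
    if (s1[1] < s2[2] && s2[1] < s1[2])
      abort("binocular scene: eye regions overlap horizontally")
  }
  h <- p1$image_size[1]; w <- p1$image_size[2]
  lab <- mask_labels()
  mask <- matrix(lab["skin"], h, w)
  tex <- list()  # list of list(idx, color)

  # fiducial marker
  mr <- p1$marker_diameter_mm / 2 / p1$mm_per_px
  mask <- draw_disc(mask, p1$marker_center, mr, lab["marker"], over = lab["skin"])

  for (p in eyes) {
    crv <- lid_curves(p)
    s <- p$mm_per_px
    xr <- sort(crv$x_range)
    cols <- seq.int(floor(xr[1]) + 1L, ceiling(xr[2]) - 1L)
    cols <- cols[cols > xr[1] & cols < xr[2] & cols >= 0 & cols < w]
    cx <- p$cornea_center[1]; cy <- p$cornea_center[2]
    r <- p$cornea_radius_mm / s
    tcol <- texture_colors()
    stroke_cols <- band_cols <- integer()
    if (p$entropion_flag || p$trichiasis_flag) {
      tfrac <- (cols - min(cols)) / max(1, diff(range(cols)))
      stroke_cols <- cols[tfrac >= 0.2 & tfrac <= 0.8 & (cols - cols[1]) %% 3L == 0L]
    }
    if (p$ectropion_flag) {
      tfrac <- (cols - min(cols)) / max(1, diff(range(cols)))
      band_cols <- cols[tfrac >= 0.15 & tfrac <= 0.85]
    }
    for (x in cols) {
      yu <- crv$yu(x); yl <- crv$yl(x)
      r1 <- floor(yu) + 1L; r2 <- ceiling(yl) - 1L
      if (r2 < r1) next
      rows <- r1:r2
      rows <- rows[rows >= 0 & rows < h]
      if (!length(rows)) next
      mask[rows + 1L, x + 1L] <- lab["fissure"]
      q2 <- r^2 - (x - cx)^2
      if (q2 > 0) {
        q <- sqrt(q2)
        cr <- rows[rows >= cy - q & rows <= cy + q]
        if (length(cr)) mask[cr + 1L, x + 1L] <- lab["cornea"]
      }
      if (x %in% stroke_cols) {          # lash strokes: lid tissue into the fissure
        sr <- rows[rows <= r1 + 2L]
        if (length(sr)) {
          mask[sr + 1L, x + 1L] <- lab["skin"]
          tex[[length(tex) + 1L]] <- list(idx = cbind(sr + 1L, x + 1L), color = tcol$lash)
        }
      }
      if (x %in% band_cols) {            # everted tarsal band straddling the lower margin
        br <- rows[rows >= r2 - 2L]
        if (length(br)) {
          mask[br + 1L, x + 1L] <- lab["skin"]
          tex[[length(tex) + 1L]] <- list(idx = cbind(br + 1L, x + 1L), color = tcol$tarsal)
        }
        bs <- (r2 + 1L):(r2 + 3L); bs <- bs[bs >= 0 & bs < h]
        bs <- bs[mask[bs + 1L, x + 1L] == lab["skin"]]
        if (length(bs))
          tex[[length(tex) + 1L]] <- list(idx = cbind(bs + 1L, x + 1L), color = tcol$tarsal)
      }
    }
    if (!is.null(p$tumor_center))
      mask <- draw_disc(mask, p$tumor_center, p$tumor_radius_mm / s,
                        lab["tumor"], over = lab["skin"])
    if (p$fold_type != "none") {
      ic <- p$inner_canthus
      f <- p$fold_extent_mm / s
      nasal_sign <- sign(ic[1] - p$outer_canthus[1])
      x0 <- max(0L, floor(ic[1] - f - 2)); x1 <- min(w - 1L, ceiling(ic[1] + f + 2))
      y0 <- max(0L, floor(ic[2] - f - 2)); y1 <- min(h - 1L, ceiling(ic[2] + f + 2))
      gx <- x0:x1; gy <- y0:y1
      dxm <- outer(gy * 0, gx - ic[1], function(a, b) b)  # per-pixel x offset
      dym <- outer(gy - ic[2], gx * 0, function(a, b) a)
      d <- sqrt(dxm^2 + dym^2)
      half <- if (p$fold_type == "epicanthus_inversus") dym >= 0 else dym <= 0
      sel <- abs(d - f) <= 1.5 & dxm * nasal_sign >= -3 & half
      sub <- mask[gy + 1L, gx + 1L]
      sel <- sel & sub == lab["skin"]
      if (any(sel)) {
        idx <- which(sel, arr.ind = TRUE)
        tex[[length(tex) + 1L]] <-
          list(idx = cbind(idx[, 1] + y0, idx[, 2] + x0), color = tcol$crease)
      }
    }
  }

  pal <- scene_palette()
  img <- array(0, dim = c(h, w, 3))
  for (k in 1:3) img[, , k] <- matrix(pal[mask + 1L, k], h, w)
  for (t in tex) for (k in 1:3) img[, , k][t$idx] <- t$color[k]
  if (p1$noise_sd > 0)
    img <- with_seed(p1$seed, clamp(img + array(rnorm(h * w * 3, 0, p1$noise_sd),
                                                dim = c(h, w, 3)), 0, 1))
  one <- length(eyes) == 1L
  th <- default_thresholds()
  tf <- lapply(eyes, truth_findings, thresholds = th)
  tr <- lapply(eyes, truth_morphometry)
  td <- lapply(seq_along(eyes), function(i)
    apply_atlas(tf[[i]], tr[[i]], default_rules())$diseases)
  scene <- list(image = img, mask = mask,
                params = if (one) eyes[[1]] else eyes,
                truth_report = if (one) tr[[1]] else tr,
                truth_findings = if (one) tf[[1]] else tf,
                truth_diagnoses = if (one) td[[1]] else td,
                n_eyes = length(eyes))
  class(scene) <- "eye_scene"
  scene
}

#' @export
print.eye_scene <- function(x, ...) {
  dg <- if (x$n_eyes == 1) x$truth_diagnoses else unlist(x$truth_diagnoses)
  cat(sprintf("<eye_scene> %d x %d px, %d eye(s); truth diagnoses: %s\n",
              dim(x$mask)[1], dim(x$mask)[2], x$n_eyes,
              if (length(dg)) paste(dg, collapse = ", ") else "(normal)"))
  invisible(x)
}

# Rasterise a disc (pixel-centre rule) over pixels currently labelled `over`.
draw_disc <- function(mask, center, radius_px, label, over = NULL) {
  h <- nrow(mask); w <- ncol(mask)
  x0 <- max(0L, floor(center[1] - radius_px)); x1 <- min(w - 1L, ceiling(center[1] + radius_px))
  y0 <- max(0L, floor(center[2] - radius_px)); y1 <- min(h - 1L, ceiling(center[2] + radius_px))
  gx <- x0:x1; gy <- y0:y1
  d2 <- outer((gy - center[2])^2, (gx - center[1])^2, `+`)
  sel <- d2 <= radius_px^2
  if (!is.null(over)) sel <- sel & mask[gy + 1L, gx + 1L] %in% over
  sub <- mask[gy + 1L, gx + 1L]
  sub[sel] <- label
  mask[gy + 1L, gx + 1L] <- sub
  mask
}

condition_templates_path <- function() {
  system.file("extdata", "condition_templates.yaml", package = "lidmorph")
}

.template_cache <- new.env(parent = emptyenv())

#' Condition templates of the scene generator
#'
#' Parameter templates (jitter ranges, flags, fold types) for every supported
#' condition label, loaded from the packaged YAML so ranges are configuration,
#' not code.
#'
#' @param path optional path to an alternative template file.
#' @return list with `defaults`, `conditions`, `aliases`.
#' @export
condition_templates <- function(path = condition_templates_path()) {
  key <- path
  if (is.null(.template_cache[[key]]))
    .template_cache[[key]] <- yaml::read_yaml(path)
  .template_cache[[key]]
}

#' Supported condition labels
#'
#' @param include_aliases also list alias spellings (change-level names and
#'   abbreviations) that resolve to a canonical template.
#' @return character vector of labels accepted by [params_for_condition()].
#' @export
supported_conditions <- function(include_aliases = TRUE) {
  tpl <- condition_templates()
  out <- names(tpl$conditions)
  if (include_aliases) out <- c(out, names(tpl$aliases))
  out
}

resolve_condition <- function(condition) {
  tpl <- condition_templates()
  if (condition %in% names(tpl$aliases)) condition <- tpl$aliases[[condition]]
  if (!condition %in% names(tpl$conditions))
    abort("unknown condition '", condition, "'; supported labels: ",
          paste(supported_conditions(), collapse = ", "))
  condition
}

runif1 <- function(range) if (length(range) == 2) runif(1, range[1], range[2]) else range

#' Scene parameters for a named clinical condition
#'
#' Maps each supported single-disease / change / multimorbidity label (and
#' `"normal"`) to a jittered parameter template such that the rendered scene,
#' pushed through the full pipeline with default thresholds, carries the
#' condition's disease set as its truth diagnoses.  Jitter ranges live in the
#' packaged template YAML ([condition_templates()]).
#'
#' @param condition a label from [supported_conditions()].
#' @param seed integer seed controlling the jitter (and the scene noise).
#' @param laterality optional `"left"`/`"right"`; sampled if `NULL`.
#' @return an [eye_scene_params()] object.
#' @export
params_for_condition <- function(condition, seed = 1L, laterality = NULL) {
  condition <- resolve_condition(condition)
  tpl <- condition_templates()
  cfg <- modifyList(tpl$defaults, tpl$conditions[[condition]])
  with_seed(seed, {
    lat <- if (is.null(laterality)) sample(c("left", "right"), 1) else laterality
    h <- cfg$image_size[1]; w <- cfg$image_size[2]; s <- cfg$mm_per_px
    icd_mm <- runif1(cfg$icd_mm)
    mrd1 <- runif1(cfg$mrd1_mm); mrd2 <- runif1(cfg$mrd2_mm)
    chord_y <- cfg$chord_y_px + runif1(cfg$chord_jitter_mm) / s
    eye_cx <- if (lat == "right") 0.35 * w else 0.65 * w
    half <- icd_mm / 2 / s
    # subject-right eye sits in the left image half; its nasal side is +x
    inner_x <- if (lat == "right") eye_cx + half else eye_cx - half
    outer_x <- if (lat == "right") eye_cx - half else eye_cx + half
    cdx <- runif1(cfg$cornea_dx_mm) / s
    cdy_mm <- runif1(cfg$cornea_dy_mm)
    cx <- eye_cx + cdx; cy <- chord_y + cdy_mm / s
    tt <- (cx - inner_x) / (outer_x - inner_x)
    k <- 4 * tt * (1 - tt)          # chord-relative bump factor at the corneal axis
    peak_mm <- (mrd1 - cdy_mm) / k  # so truth MRD1/MRD2 hit the template targets
    dip_mm <- (mrd2 + cdy_mm) / k
    tumor_center <- NULL; tumor_radius_mm <- NULL
    if (!is.null(cfg$tumor_radius_mm)) {
      tumor_radius_mm <- runif1(cfg$tumor_radius_mm)
      tx <- eye_cx + runif(1, -20, 20)
      crv_dip <- chord_y + dip_mm / s   # lower margin depth at centre
      tumor_center <- c(tx, crv_dip + tumor_radius_mm / s + 4)
    }
    fold <- if (is.null(cfg$fold)) "none" else cfg$fold
    eye_scene_params(
      image_size = c(h, w), laterality = lat,
      inner_canthus = c(inner_x, chord_y), outer_canthus = c(outer_x, chord_y),
      upper_curve_peak_mm = peak_mm, lower_curve_dip_mm = dip_mm,
      cornea_center = c(cx, cy), cornea_radius_mm = cfg$cornea_radius_mm,
      fold_type = fold,
      fold_extent_mm = if (is.null(cfg$fold_extent_mm)) 3 else runif1(cfg$fold_extent_mm),
      entropion_flag = isTRUE(cfg$entropion), trichiasis_flag = isTRUE(cfg$trichiasis),
      ectropion_flag = isTRUE(cfg$ectropion),
      tumor_center = tumor_center, tumor_radius_mm = tumor_radius_mm,
      marker_center = cfg$marker_center_px, marker_diameter_mm = cfg$marker_diameter_mm,
      mm_per_px = s, noise_sd = cfg$noise_sd,
      seed = derive_seed(seed, 7919L))
  })
}

#' Generate a labelled cohort of scenes
#'
#' @param class_mix named integer vector or list, condition label -> count.
#' @param seed master seed; per-scene seeds are derived deterministically.
#' @return list of `eye_scene` objects, each with a `condition` field.
#' @export
#' @examples
#' cohort <- generate_cohort(c(normal = 2, "eyelid tumor" = 1), seed = 7)
#' length(cohort)
generate_cohort <- function(class_mix, seed = 1L) {
  counts <- unlist(class_mix)
  if (any(counts < 0)) abort("class counts must be >= 0")
  out <- list(); i <- 0L
  for (label in names(counts)) {
    for (j in seq_len(counts[[label]])) {
      i <- i + 1L
      sc <- generate_scene(params_for_condition(label, seed = derive_seed(seed, i)))
      sc$condition <- label
      out[[i]] <- sc
    }
  }
  out
}
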