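#  Fiducial scale calibration and the eight calibrated morphological
#  parameters.  All distances are measured along the true vertical (image
#  columns) at the corneal axis column, matching the standardised frontal
#  photographic protocol.

#' Calibrate millimetres per pixel from the fiducial marker
#'
#' The marker's pixel diameter is first taken as the equivalent-circle
#' diameter `2 * sqrt(area / pi)` of its largest connected component.  With
#' `refine = TRUE` (the default) that estimate seeds a rasterisation-matching
#' fit: the disc radius and centre minimising the row-extent mismatch with
#' the observed component, with the radius taken as the midpoint of the
#' minimising interval.  The refinement removes the lattice-count
#' fluctuations of the raw pixel area, which reach ~1.5 % of the diameter
#' for markers near 12 px radius; `mm_per_px = marker_diameter_mm /
#' marker_px_diameter` either way.
#'
#' @param mask integer label matrix containing marker pixels.
#' @param marker_diameter_mm physical marker diameter (default 10 mm).
#' @param refine refine the equivalent-circle diameter by rasterisation
#'   matching (default `TRUE`).
#' @return object of class `scale_factor`: `mm_per_px`,
#'   `marker_px_diameter`, `method` (`"equivalent_circle"` or
#'   `"raster_fit"`), `warnings`.
#' @export
calibrate <- function(mask, marker_diameter_mm = 10, refine = TRUE) {
  lab <- mask_labels()
  bin <- mask == lab["marker"]
  if (!any(bin))
    abort("calibrate: no marker pixels; pass mm_per_px explicitly to the pipeline config")
  cc <- EBImage::bwlabel(bin)
  sizes <- tabulate(cc[cc > 0])
  warn <- character()
  if (length(sizes) > 1)
    warn <- sprintf("calibrate: %d marker components; using the largest", length(sizes))
  comp <- cc == which.max(sizes)
  area <- max(sizes)
  d <- 2 * sqrt(area / pi)
  method <- "equivalent_circle"
  if (refine) {
    fit <- fit_raster_disc(comp)
    if (!is.null(fit)) { d <- 2 * fit$r; method <- "raster_fit" }
  }
  structure(list(mm_per_px = marker_diameter_mm / d, marker_px_diameter = d,
                 method = method, warnings = warn),
            class = "scale_factor")
}

# Row-extent representation of a connected component (0-based coordinates).
component_rows <- function(comp) {
  idx <- which(comp, arr.ind = TRUE)
  ys <- sort(unique(idx[, 1]))
  xl <- vapply(ys, function(r) min(idx[idx[, 1] == r, 2]), 0) - 1
  xr <- vapply(ys, function(r) max(idx[idx[, 1] == r, 2]), 0) - 1
  list(ys = ys - 1, xl = xl, xr = xr)
}

# Total row-extent mismatch between the observed component and the pixel-
# centre rasterisation of a disc (r, cx, cy); vectorised over rows.
raster_mismatch <- function(r, cx, cy, ob) {
  ally <- union(seq.int(floor(cy - r), ceiling(cy + r)), ob$ys)
  q2 <- r^2 - (ally - cy)^2
  a <- ifelse(q2 >= 0, ceiling(cx - sqrt(pmax(q2, 0))), 1)
  b <- ifelse(q2 >= 0, floor(cx + sqrt(pmax(q2, 0))), 0)
  i <- match(ally, ob$ys)
  obs <- !is.na(i)
  pred <- b >= a
  tot <- sum(abs(a[obs & pred] - ob$xl[i[obs & pred]]) +
             abs(b[obs & pred] - ob$xr[i[obs & pred]]))
  tot <- tot + sum(ob$xr[i[obs & !pred]] - ob$xl[i[obs & !pred]] + 1)
  tot + sum(b[!obs & pred] - a[!obs & pred] + 1)
}

# Coordinate-descent rasterisation fit of a disc to a component; returns the
# midpoint of the mismatch-minimising radius interval (NULL for components
# too small to fit).
fit_raster_disc <- function(comp, rounds = 3L, step = 0.02) {
  ob <- component_rows(comp)
  n <- sum(ob$xr - ob$xl + 1)
  if (n < 20 || length(ob$ys) < 5) return(NULL)
  r <- sqrt(n / pi)
  cx <- mean((ob$xl + ob$xr) / 2)
  cy <- sum(ob$ys * (ob$xr - ob$xl + 1)) / n
  for (k in seq_len(rounds)) {
    rs <- r + seq(-0.7, 0.7, by = step)
    ms <- vapply(rs, raster_mismatch, 0, cx = cx, cy = cy, ob = ob)
    r <- mean(range(rs[ms == min(ms)]))
    xs <- cx + seq(-0.5, 0.5, by = step)
    ms <- vapply(xs, function(v) raster_mismatch(r, v, cy, ob), 0)
    cx <- mean(range(xs[ms == min(ms)]))
    ys <- cy + seq(-0.5, 0.5, by = step)
    ms <- vapply(ys, function(v) raster_mismatch(r, cx, v, ob), 0)
    cy <- mean(range(ys[ms == min(ms)]))
  }
  list(r = r, center = c(cx, cy))
}

#' @export
print.scale_factor <- function(x, ...) {
  cat(sprintf("<scale_factor> %.4f mm/px (marker %.1f px, %s)\n",
              x$mm_per_px, x$marker_px_diameter, x$method))
  invisible(x)
}

#' Locate the corneal centre
#'
#' Estimates the centre of the (possibly lid-occluded) cornea from its
#' largest component.  Rows whose lateral cornea boundary touches the fissure
#' on both sides are full-width chords of the corneal circle: the horizontal
#' centre is the mean chord midpoint, and the vertical centre comes from the
#' linear relation `w(y)^2/4 + y^2 = r^2 - cy^2 + 2*cy*y` between chord width
#' and row.  With fewer than `min_rows` full rows the visible-area centroid
#' is used and flagged, since lid occlusion biases the centroid.
#'
#' @param mask integer label matrix.
#' @param box optional eye box restricting the search.
#' @param min_rows minimum full-width rows for the chord estimator.
#' @return list `center` (px), `radius_px`, `method`
#'   (`"chord_fit"`/`"centroid"`), `n_rows`.
#' @export
corneal_center <- function(mask, box = NULL, min_rows = 5L) {
  lab <- mask_labels()
  if (!is.null(box)) {
    if (inherits(box, "eye_box")) box <- box$box
    sub <- crop_box(mask, box); off <- c(box[1], box[2])
  } else { sub <- mask; off <- c(0, 0) }
  bin <- sub == lab["cornea"]
  if (!any(bin)) abort("corneal_center: no cornea pixels (fully occluded?)")
  cc <- EBImage::bwlabel(bin)
  sizes <- tabulate(cc[cc > 0])
  bin <- cc == which.max(sizes)
  fis <- sub == lab["fissure"]
  idx <- which(bin, arr.ind = TRUE)
  rows <- sort(unique(idx[, 1]))
  mids <- widths <- ys <- numeric()
  w <- ncol(sub)
  for (r in rows) {
    cs <- idx[idx[, 1] == r, 2]
    c0 <- min(cs); c1 <- max(cs)
    left_fis  <- c0 > 1 && fis[r, c0 - 1]
    right_fis <- c1 < w && fis[r, c1 + 1]
    if (left_fis && right_fis) {
      mids <- c(mids, (c0 + c1) / 2); widths <- c(widths, c1 - c0 + 1); ys <- c(ys, r)
    }
  }
  centroid <- c(mean(idx[, 2]) - 1 + off[1], mean(idx[, 1]) - 1 + off[2])
  if (length(ys) < min_rows)
    return(list(center = centroid, radius_px = sqrt(sum(bin) / pi),
                method = "centroid", n_rows = length(ys)))
  cx <- mean(mids) - 1 + off[1]
  # regress w^2/4 + y^2 on y: slope = 2*cy
  y0 <- ys - 1 + off[2]
  fit <- lm(z ~ y, data = data.frame(z = widths^2 / 4 + y0^2, y = y0))
  cy <- coef(fit)[[2]] / 2
  r2 <- coef(fit)[[1]] + cy^2
  list(center = c(cx, cy), radius_px = sqrt(max(r2, 0)),
       method = "chord_fit", n_rows = length(ys))
}

new_morphometry_report <- function(mrd1_mm, mrd2_mm, pf_mm, corneal_area_mm2,
                                   lateral_area_mm2, medial_area_mm2,
                                   upper_lid_length_mm, lower_lid_length_mm,
                                   corneal_center_px, axis_column, icd_mm,
                                   mm_per_px, warnings = character(),
                                   timestamp = NA_character_) {
  structure(list(mrd1_mm = mrd1_mm, mrd2_mm = mrd2_mm, pf_mm = pf_mm,
                 corneal_area_mm2 = corneal_area_mm2,
                 lateral_area_mm2 = lateral_area_mm2,
                 medial_area_mm2 = medial_area_mm2,
                 upper_lid_length_mm = upper_lid_length_mm,
                 lower_lid_length_mm = lower_lid_length_mm,
                 corneal_center_px = corneal_center_px,
                 axis_column = axis_column, icd_mm = icd_mm,
                 mm_per_px = mm_per_px, warnings = warnings,
                 timestamp = timestamp),
            class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, digits = 2, ...) {
  cat("<morphometry_report>\n")
  cat(sprintf("  MRD1 %.*f mm   MRD2 %.*f mm   PF %.*f mm   ICD %.*f mm\n",
              digits, x$mrd1_mm, digits, x$mrd2_mm, digits, x$pf_mm, digits, x$icd_mm))
  cat(sprintf("  areas (mm^2): cornea %.*f, lateral %.*f, medial %.*f\n",
              digits, x$corneal_area_mm2, digits, x$lateral_area_mm2, digits, x$medial_area_mm2))
  cat(sprintf("  lid lengths (mm): upper %.*f, lower %.*f\n",
              digits, x$upper_lid_length_mm, digits, x$lower_lid_length_mm))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.morphometry_report <- function(x, ...) {
  data.frame(mrd1_mm = x$mrd1_mm, mrd2_mm = x$mrd2_mm, pf_mm = x$pf_mm,
             corneal_area_mm2 = x$corneal_area_mm2,
             lateral_area_mm2 = x$lateral_area_mm2,
             medial_area_mm2 = x$medial_area_mm2,
             upper_lid_length_mm = x$upper_lid_length_mm,
             lower_lid_length_mm = x$lower_lid_length_mm,
             icd_mm = x$icd_mm, axis_column = x$axis_column,
             mm_per_px = x$mm_per_px,
             timestamp = x$timestamp)
}

# Margin row at the axis column: median over a 7-column window so single-
# column notches (rendered lash strokes) do not bias MRD; the quadratic
# margin's curvature bias over +/-3 columns is < 0.05 px.
margin_y_at <- function(poly, col, halfwin = 3L) {
  sel <- abs(poly[, 1] - col) <= halfwin
  if (!any(sel)) return(NA_real_)
  median(poly[sel, 2])
}

# Arc length of a margin polyline after smoothing-spline regularisation of
# y(x); raw pixel chains overestimate length by up to ~8 %.  The spline is
# fitted on the interior chain only and evaluated at every column including
# the canthus endpoints, so a degenerate (ambiguous-corner) margin still
# measures its chord.
polyline_length <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(sum(sqrt(rowSums(diff(poly)^2))))
  o <- order(poly[, 1])
  x <- poly[o, 1]; y <- poly[o, 2]
  int <- poly[2:(n - 1), , drop = FALSE]          # chain without the canthus rows
  int <- int[!duplicated(int[, 1]), , drop = FALSE]
  if (nrow(int) >= 10) {
    fit <- stats::smooth.spline(int[, 1], int[, 2], df = min(6, nrow(int) - 1))
    y <- stats::predict(fit, x)$y
  }
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Compute the eight morphological parameters
#'
#' On the corneal axis column (nearest column to the corneal centre): MRD1 is
#' the signed vertical distance from the corneal centre up to the upper
#' margin, MRD2 down to the lower margin (negative when a margin crosses the
#' centre), and the palpebral fissure PF = MRD1 + MRD2 by construction.
#' The corneal area is the visible cornea pixel count; lateral and medial
#' areas are the fissure-minus-cornea pixel counts on the temporal and nasal
#' sides of the axis column (the axis column itself counts as medial); lid
#' lengths are smoothed margin arc lengths.  All values are converted with
#' the calibrated scale.
#'
#' @param mask integer label matrix.
#' @param lm an `eye_landmarks` object.
#' @param scale a `scale_factor` (or a number, metres taken as mm/px).
#' @param box optional eye box; defaults to the margin extent plus 2 px.
#' @param timestamp optional visit timestamp string carried in the report for
#'   longitudinal monitoring (kept out by default so repeated runs are
#'   byte-identical).
#' @return a `morphometry_report`.
#' @export
compute_morphometry <- function(mask, lm, scale, box = NULL,
                                timestamp = NA_character_) {
  s <- if (inherits(scale, "scale_factor")) scale$mm_per_px else as.numeric(scale)
  stopifnot(s > 0)
  warn <- character()
  all_pts <- rbind(lm$upper_margin, lm$lower_margin)
  if (is.null(box)) {
    box <- c(floor(min(all_pts[, 1])) - 2, floor(min(all_pts[, 2])) - 2,
             ceiling(max(all_pts[, 1])) + 3, ceiling(max(all_pts[, 2])) + 3)
    box <- clamp_box(box, dim(mask))
  } else if (inherits(box, "eye_box")) box <- box$box
  cc <- corneal_center(mask, box)
  if (cc$method == "centroid")
    warn <- c(warn, "corneal centre from visible-area centroid (few full-width rows)")
  ax <- round(cc$center[1])
  uy <- margin_y_at(lm$upper_margin, ax)
  ly <- margin_y_at(lm$lower_margin, ax)
  if (is.na(uy) || is.na(ly))
    abort("compute_morphometry: axis column lies outside the fissure span")
  cy <- cc$center[2]
  mrd1 <- (cy - uy) * s
  mrd2 <- (ly - cy) * s
  lab <- mask_labels()
  sub <- crop_box(mask, box)
  idx_cor <- which(sub == lab["cornea"], arr.ind = TRUE)
  idx_fis <- which(sub == lab["fissure"], arr.ind = TRUE)
  xs_fis <- idx_fis[, 2] - 1 + box[1]
  nasal_is_right <- lm$laterality == "right"
  medial_sel <- if (nasal_is_right) xs_fis >= ax else xs_fis <= ax
  new_morphometry_report(
    mrd1_mm = mrd1, mrd2_mm = mrd2, pf_mm = mrd1 + mrd2,
    corneal_area_mm2 = nrow(idx_cor) * s^2,
    lateral_area_mm2 = sum(!medial_sel) * s^2,
    medial_area_mm2 = sum(medial_sel) * s^2,
    upper_lid_length_mm = polyline_length(lm$upper_margin) * s,
    lower_lid_length_mm = polyline_length(lm$lower_margin) * s,
    corneal_center_px = cc$center, axis_column = as.integer(ax),
    icd_mm = lm$icd_px * s, mm_per_px = s, warnings = warn,
    timestamp = timestamp)
}

#' Parameter deltas between two visits
#'
#' Longitudinal monitoring support: signed differences (visit B minus visit
#' A) of every scalar parameter.
#'
#' @param a,b `morphometry_report`s from two visits.
#' @return data.frame with columns `parameter`, `visit_a`, `visit_b`, `delta`.
#' @export
morphometry_diff <- function(a, b) {
  pars <- c("mrd1_mm", "mrd2_mm", "pf_mm", "corneal_area_mm2",
            "lateral_area_mm2", "medial_area_mm2",
            "upper_lid_length_mm", "lower_lid_length_mm", "icd_mm")
  data.frame(parameter = pars,
             visit_a = vapply(pars, function(p) a[[p]], 0),
             visit_b = vapply(pars, function(p) b[[p]], 0),
             delta = vapply(pars, function(p) b[[p]] - a[[p]], 0),
             row.names = NULL)
}
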