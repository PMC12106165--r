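#  Anatomical region identification: lid-margin contour extraction, canthus
#  localisation, and decomposition of the monocular patch into the four
#  regions (inner canthus, outer canthus, upper eyelid, lower eyelid).

#' Extract upper and lower lid-margin contours
#'
#' The palpebral region (fissure plus cornea labels) inside the eye box is
#' scanned column-wise; the boundary splits at the leftmost and rightmost
#' fissure columns into an upper chain (minimum row per column) and a lower
#' chain (maximum row per column).  Where the fissure is a single pixel tall
#' the chains coincide.
#'
#' @param mask integer label matrix.
#' @param box eye box (half-open `c(x0,y0,x1,y1)`) or an `eye_box`.
#' @return list with `upper`, `lower` (n x 2 matrices of `(x, y)` in global
#'   0-based px, ascending x).
#' @export
extract_contours <- function(mask, box) {
  if (inherits(box, "eye_box")) box <- box$box
  lab <- mask_labels()
  sub <- crop_box(mask, box)
  bin <- sub == lab["fissure"] | sub == lab["cornea"]
  if (!any(bin)) abort("extract_contours: no fissure pixels inside the box")
  cols <- which(colSums(bin) > 0)
  up <- lo <- matrix(NA_real_, length(cols), 2)
  for (i in seq_along(cols)) {
    rows <- which(bin[, cols[i]])
    up[i, ] <- c(box[1] + cols[i] - 1, box[2] + min(rows) - 1)
    lo[i, ] <- c(box[1] + cols[i] - 1, box[2] + max(rows) - 1)
  }
  list(upper = up, lower = lo)
}

# Quadratic fit of a margin chain y(x) with one outlier-trim pass (margin
# texture can notch single columns by a few px).  Returns coefficients
# (intercept, x, x^2) around x0, or NULL when the chain is too short.
fit_margin_quadratic <- function(poly, x0, trim_px = 1.5) {
  n <- nrow(poly)
  if (n < 8) return(NULL)
  keep <- seq(3, n - 2)                  # tips are sub-pixel thin; drop them
  d <- data.frame(x = poly[keep, 1] - x0, y = poly[keep, 2])
  fit <- lm(y ~ x + I(x^2), data = d)
  res <- abs(stats::residuals(fit))
  if (any(res > trim_px) && sum(res <= trim_px) >= 6)
    fit <- lm(y ~ x + I(x^2), data = d[res <= trim_px, ])
  coef(fit)
}

# Refine a fissure-corner estimate by intersecting the fitted upper and lower
# margin curves.  Rasterisation leaves the last columns of the fissure
# sub-pixel thin, so the extreme pixel alone sits 1-2 px inside the true
# canthus; extrapolating the curves to their intersection recovers the
# corner to sub-pixel accuracy.
refine_corner <- function(upper, lower, end = c("left", "right")) {
  end <- match.arg(end)
  n <- nrow(upper)
  ext_i <- if (end == "left") 1L else n
  # tie rule at the extreme column: prefer the smaller y
  extreme <- c(upper[ext_i, 1], min(upper[ext_i, 2], lower[ext_i, 2]))
  x0 <- extreme[1]
  cu <- fit_margin_quadratic(upper, x0)
  cl <- fit_margin_quadratic(lower, x0)
  if (is.null(cu) || is.null(cl)) return(extreme)
  dd <- cl - cu                          # lower-minus-upper gap polynomial
  roots <- if (abs(dd[3]) < 1e-9) {
    if (abs(dd[2]) < 1e-6) numeric() else -dd[1] / dd[2]
  } else {
    disc <- dd[2]^2 - 4 * dd[3] * dd[1]
    if (disc < 0) numeric()
    else (-dd[2] + c(-1, 1) * sqrt(disc)) / (2 * dd[3])
  }
  roots <- roots[is.finite(roots) & abs(roots) <= 4]
  if (!length(roots)) return(extreme)
  xr <- roots[which.min(abs(roots))]
  ys <- cu[1] + cu[2] * xr + cu[3] * xr^2
  if (abs(ys - extreme[2]) <= 4) c(x0 + xr, ys) else extreme
}

#' Locate the inner and outer canthus
#'
#' The contour endpoint on the nasal side is the inner canthus, the temporal
#' endpoint the outer canthus.  In a monocular patch the nose midline is not
#' visible; laterality substitutes for it (nasal = the side facing the image
#' centre, so for a subject-right eye the inner canthus is the larger-x
#' endpoint).  Endpoints are refined by intersecting local line fits of the
#' margin chains unless `refine = FALSE`.
#'
#' @param contours output of [extract_contours()].
#' @param laterality `"left"` or `"right"` (subject side).
#' @param refine sub-pixel corner refinement (default `TRUE`).
#' @return object of class `eye_landmarks`: `inner_canthus`, `outer_canthus`,
#'   `upper_margin`, `lower_margin` (polylines ordered inner -> outer),
#'   `icd_px`, `laterality`.
#' @export
locate_canthi <- function(contours, laterality = c("left", "right"), refine = TRUE) {
  laterality <- match.arg(laterality)
  up <- contours$upper; lo <- contours$lower
  if (is.null(up) || nrow(up) == 0) abort("locate_canthi: empty contours")
  # pixel centres sit half a pixel inside the skin/fissure boundary; shift
  # each chain to the boundary so margins, corners and arc lengths are
  # unbiased (the upper margin moves up, the lower margin down)
  up[, 2] <- up[, 2] - 0.5
  lo[, 2] <- lo[, 2] + 0.5
  left  <- if (refine) refine_corner(up, lo, "left")  else c(up[1, 1], min(up[1, 2], lo[1, 2]))
  right <- if (refine) refine_corner(up, lo, "right") else
    c(up[nrow(up), 1], min(up[nrow(up), 2], lo[nrow(lo), 2]))
  nasal_is_right <- laterality == "right"   # subject-right eye: nose on +x side
  inner <- if (nasal_is_right) right else left
  outer <- if (nasal_is_right) left else right
  # polylines ordered medial -> lateral, endpoints at the canthi
  ord <- if (nasal_is_right) rev(seq_len(nrow(up))) else seq_len(nrow(up))
  um <- rbind(inner, up[ord, , drop = FALSE], outer)
  lm_ <- rbind(inner, lo[ord, , drop = FALSE], outer)
  rownames(um) <- rownames(lm_) <- NULL
  icd <- sqrt(sum((inner - outer)^2))
  if (icd <= 0) abort("locate_canthi: degenerate contours (zero inter-canthal distance)")
  structure(list(inner_canthus = inner, outer_canthus = outer,
                 upper_margin = um, lower_margin = lm_,
                 icd_px = icd, laterality = laterality),
            class = "eye_landmarks")
}

#' @export
print.eye_landmarks <- function(x, ...) {
  cat(sprintf("<eye_landmarks> subject-%s eye; inner (%.1f, %.1f), outer (%.1f, %.1f), ICD %.1f px\n",
              x$laterality, x$inner_canthus[1], x$inner_canthus[2],
              x$outer_canthus[1], x$outer_canthus[2], x$icd_px))
  invisible(x)
}

region_patch <- function(image, mask, box, warning = FALSE) {
  dimhw <- dim(mask)
  raw_area <- box_area(box)
  cb <- clamp_box(box, dimhw)
  cb <- c(floor(cb[1]), floor(cb[2]), ceiling(cb[3]), ceiling(cb[4]))
  clipped <- box_area(cb) < 0.5 * raw_area
  list(box = cb, image = crop_box(image, cb), mask = crop_box(mask, cb),
       warning = warning || clipped)
}

#' Decompose an eye into the four anatomical region patches
#'
#' Canthus patches are squares centred on each canthus with side
#' `round(icd_px / 3)` (round-half-to-even), per the canthus-square
#' definition; eyelid patches are the minimum axis-aligned bounding rectangles
#' of the margin polylines.  All boxes are clamped to the image; a patch
#' losing more than half its area to clamping carries a warning flag.
#'
#' @param image scene image (H x W x 3 array).
#' @param mask label matrix.
#' @param lm an `eye_landmarks` object.
#' @return object of class `region_patches` with fields
#'   `inner_canthus_patch`, `outer_canthus_patch`, `upper_eyelid_patch`,
#'   `lower_eyelid_patch` (each `list(box, image, mask, warning)`) and
#'   `side_px`, the canthus-square side before clamping.
#' @export
extract_regions <- function(image, mask, lm) {
  side <- round_half_even(lm$icd_px / 3)
  square <- function(p) {
    x0 <- round(p[1]) - side %/% 2L
    y0 <- round(p[2]) - side %/% 2L
    c(x0, y0, x0 + side, y0 + side)
  }
  rect <- function(poly) {
    c(floor(min(poly[, 1])), floor(min(poly[, 2])),
      floor(max(poly[, 1])) + 1L, floor(max(poly[, 2])) + 1L)
  }
  structure(list(
    inner_canthus_patch = region_patch(image, mask, square(lm$inner_canthus)),
    outer_canthus_patch = region_patch(image, mask, square(lm$outer_canthus)),
    upper_eyelid_patch = region_patch(image, mask, rect(lm$upper_margin)),
    lower_eyelid_patch = region_patch(image, mask, rect(lm$lower_margin)),
    side_px = side), class = "region_patches")
}
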