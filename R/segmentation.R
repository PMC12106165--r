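#  Segmenter contract with a deterministic baseline, plus mask cleaning and
#  mask-driven eye detection.  The baseline inverts the generator's palette by
#  nearest-colour assignment; any callable with the same signature
#  (image -> SegMask) can replace it for real photographs.

#' Baseline palette segmenter
#'
#' Assigns each pixel the label of the nearest palette colour (Euclidean RGB
#' distance), then applies [clean_mask()].  This is the baseline
#' implementation of the segmenter contract (`image -> SegMask`); scenes from
#' [generate_scene()] with zero noise are inverted exactly.
#'
#' @param image H x W x 3 array in \[0,1\] (a matrix is treated as grayscale).
#' @param palette colour table, default [scene_palette()].
#' @param clean apply [clean_mask()] to the raw assignment (default `TRUE`).
#' @return integer label matrix (codes per [mask_labels()]), with attribute
#'   `warnings` when the input does not conform.
#' @export
segment_image <- function(image, palette = scene_palette(), clean = TRUE) {
  warn <- character()
  if (is.matrix(image)) image <- array(rep(image, 3), dim = c(dim(image), 3))
  if (length(dim(image)) != 3L || dim(image)[3] != 3L ||
      !all(is.finite(image)) || min(image) < -1e-9 || max(image) > 1 + 1e-9) {
    warn <- "segmentation: non-conforming image (expect H x W x 3 in [0,1]); returning all background"
    h <- dim(image)[1]; w <- dim(image)[2]
    mask <- matrix(mask_labels()["background"], if (is.na(h)) 1 else h, if (is.na(w)) 1 else w)
    attr(mask, "warnings") <- warn
    return(mask)
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]), as.vector(image[, , 3]))
  d2 <- sapply(seq_len(nrow(palette)), function(k)
    (px[, 1] - palette[k, 1])^2 + (px[, 2] - palette[k, 2])^2 + (px[, 3] - palette[k, 3])^2)
  mask <- matrix(max.col(-d2, ties.method = "first") - 1L, h, w)
  if (clean) mask <- clean_mask(mask)
  if (length(warn)) attr(mask, "warnings") <- warn
  mask
}

#' Clean a segmentation mask
#'
#' Per non-background class, keeps the `keep_k` largest connected components
#' (dropped pixels become background) and fills enclosed holes (hole pixels
#' still labelled background after the keep step are reassigned to the
#' enclosing class).  Idempotent.
#'
#' @param mask integer label matrix.
#' @param keep_k named integer vector of components to keep per class;
#'   defaults keep one marker, and two of each eye-level class so binocular
#'   scenes survive.
#' @return cleaned integer label matrix.
#' @export
clean_mask <- function(mask,
                       keep_k = c(cornea = 2L, tumor = 2L, marker = 1L,
                                  fissure = 2L, skin = 1L)) {
  lab <- mask_labels()
  out <- mask
  # fissure and cornea jointly form the palpebral region: a sliver of one
  # class separated from its own component by the other (diagonal contact at
  # the cornea rim) is not noise, so components touching the partner class
  # are kept alongside the K largest
  partner <- c(fissure = "cornea", cornea = "fissure")
  for (cls in c("cornea", "tumor", "marker", "fissure", "skin")) {
    code <- lab[[cls]]
    bin <- out == code
    if (!any(bin)) next
    cc <- EBImage::bwlabel(bin)
    sizes <- tabulate(cc[cc > 0])
    keep <- order(sizes, decreasing = TRUE)[seq_len(min(keep_k[[cls]], length(sizes)))]
    if (cls %in% names(partner)) {
      pb <- out == lab[[partner[[cls]]]]
      if (any(pb)) {
        adj <- unique(cc[dilate8(pb) & bin])
        keep <- union(keep, setdiff(adj, 0))
      }
    }
    kept <- bin & (cc %in% keep)
    out[bin & !kept] <- lab["background"]
    filled <- EBImage::fillHull(kept) > 0
    out[filled & out == lab["background"]] <- code
  }
  out
}

# 8-neighbourhood dilation of a logical matrix by one pixel.
dilate8 <- function(b) {
  h <- nrow(b); w <- ncol(b)
  out <- b
  sh <- function(m, dr, dc) {
    r <- matrix(FALSE, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    r[rs, cs] <- m[rs - dr, cs - dc]
    r
  }
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) out <- out | sh(b, dr, dc)
  out
}

#' Detect eyes from a segmentation mask
#'
#' One bounding box per connected palpebral-fissure blob (fissure plus
#' cornea), expanded by `margin_frac` of the blob diagonal and clamped to the
#' image.  Laterality follows the frontal-photo convention: a blob centroid in
#' the left image half is the subject's right eye.
#'
#' @param mask integer label matrix.
#' @param margin_frac box expansion as a fraction of the blob diagonal.
#' @param min_area_px ignore blobs smaller than this (rasterisation orphans).
#' @return list of `eye_box` objects (`box` = half-open `c(x0,y0,x1,y1)`,
#'   `laterality`), ordered left to right; empty list when no fissure pixels.
#' @export
detect_eyes <- function(mask, margin_frac = 0.25, min_area_px = 50) {
  lab <- mask_labels()
  bin <- mask == lab["fissure"] | mask == lab["cornea"]
  if (!any(bin)) return(list())
  cc <- EBImage::bwlabel(bin)
  ids <- seq_len(max(cc))
  sizes <- tabulate(cc[cc > 0], nbins = max(cc))
  ids <- ids[sizes[ids] >= min_area_px]
  if (!length(ids)) return(list())
  h <- nrow(mask); w <- ncol(mask)
  boxes <- lapply(ids, function(id) {
    idx <- which(cc == id, arr.ind = TRUE)
    x <- idx[, 2] - 1L; y <- idx[, 1] - 1L
    b <- c(min(x), min(y), max(x) + 1L, max(y) + 1L)
    diag_px <- sqrt((b[3] - b[1])^2 + (b[4] - b[2])^2)
    m <- margin_frac * diag_px
    b <- clamp_box(c(b[1] - m, b[2] - m, b[3] + m, b[4] + m), c(h, w))
    b <- c(floor(b[1]), floor(b[2]), ceiling(b[3]), ceiling(b[4]))
    structure(list(box = b,
                   laterality = if (mean(x) < w / 2) "right" else "left",
                   centroid = c(mean(x), mean(y))),
              class = "eye_box")
  })
  boxes[order(vapply(boxes, function(b) b$centroid[1], 0))]
}

#' @export
print.eye_box <- function(x, ...) {
  cat(sprintf("<eye_box> subject-%s eye, box [%d,%d) x [%d,%d)\n",
              x$laterality, x$box[1], x$box[3], x$box[2], x$box[4]))
  invisible(x)
}
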