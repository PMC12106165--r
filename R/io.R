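#  Serialisation: scene/mask PNGs with JSON sidecars, eye reports as JSON
#  (the canonical, machine-readable interpretability surface) with CSV
#  flatteners.

#' Write a scene image as PNG
#'
#' @param scene an `eye_scene` (or an H x W x 3 array).
#' @param path output PNG path.
#' @export
write_scene_png <- function(scene, path) {
  img <- if (inherits(scene, "eye_scene")) scene$image else scene
  png::writePNG(img, path)
  invisible(path)
}

#' Read a scene PNG
#'
#' @param path PNG path.
#' @return H x W x 3 array in \[0,1\].
#' @export
read_scene_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Write a label mask as a single-channel PNG
#'
#' Label codes (see [mask_labels()]) are stored as gray levels `code / 255`,
#' so the file is lossless for the six-code set.
#'
#' @param mask integer label matrix.
#' @param path output PNG path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read a label mask PNG written by [write_mask_png()]
#'
#' @param path PNG path.
#' @return integer label matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  m <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  bad <- setdiff(unique(as.vector(m)), unname(mask_labels()))
  if (length(bad)) abort("read_mask_png: unknown label codes: ", paste(bad, collapse = ", "))
  m
}

#' Serialise an eye report to JSON
#'
#' The JSON header carries the label-code table and the config digest; every
#' diagnosis lists its evidence chain (findings with region patch boxes and
#' parameter values).
#'
#' @param report an `eye_report` from [run_pipeline()].
#' @return JSON string.
#' @export
eye_report_json <- function(report) {
  d <- report$diagnosis
  obj <- list(
    header = list(label_codes = as.list(mask_labels()),
                  config_digest = report$config_digest),
    eye_id = report$eye_id,
    laterality = report$laterality,
    eye_box = report$box,
    scale = list(mm_per_px = report$scale$mm_per_px,
                 marker_px_diameter = report$scale$marker_px_diameter,
                 method = report$scale$method),
    morphometry = as.data.frame(report$report),
    region_boxes = report$region_boxes,
    findings = report$findings,
    lesion_area_mm2 = report$lesion_area_mm2,
    diagnosis = list(diseases = as.list(d$diseases),
                     support = d$support,
                     subsumed = as.list(d$subsumed)),
    warnings = as.list(report$warnings))
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 8, dataframe = "rows", pretty = TRUE)
}

#' Write eye reports to a JSON file
#'
#' @param reports list of `eye_report`s (one scene).
#' @param path output path.
#' @export
write_eye_reports <- function(reports, path) {
  writeLines(paste0("[", paste(vapply(reports, eye_report_json, ""), collapse = ",\n"), "]"),
             path)
  invisible(path)
}

#' Flatten eye reports to a CSV table
#'
#' One row per eye per visit: the eight parameters, scale, and the composed
#' diagnosis.
#'
#' @param reports list of `eye_report`s.
#' @param path optional CSV output path.
#' @return data.frame (invisibly written when `path` is given).
#' @export
reports_to_csv <- function(reports, path = NULL) {
  rows <- lapply(reports, function(r) {
    cbind(data.frame(eye_id = r$eye_id, laterality = r$laterality,
                     mm_per_px = r$scale$mm_per_px),
          as.data.frame(r$report)[, 1:9],
          data.frame(lesion_area_mm2 = r$lesion_area_mm2,
                     diagnoses = paste(r$diagnosis$diseases, collapse = " + ")))
  })
  df <- do.call(rbind, rows)
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}

#' Write an evaluation report as JSON and CSV
#'
#' @param ev an `evaluation_report`.
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @export
write_evaluation <- function(ev, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    obj <- list(n_eyes = ev$n_eyes, aacc = ev$aacc, macro_f1 = ev$macro_f1,
                per_class = ev$per_class,
                category_counts = as.list(ev$category_counts))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 8,
                                dataframe = "rows", pretty = TRUE), json_path)
  }
  if (!is.null(csv_path)) write.csv(ev$per_class, csv_path, row.names = FALSE)
  invisible(ev)
}

#' Write the JSON sidecar of a scene (params and analytic truth)
#'
#' @param scene an `eye_scene`.
#' @param path output JSON path.
#' @export
write_scene_sidecar <- function(scene, path) {
  one <- scene$n_eyes == 1
  obj <- list(
    n_eyes = scene$n_eyes,
    params = if (one) unclass(scene$params) else lapply(scene$params, unclass),
    truth_report = if (one) as.data.frame(scene$truth_report)
                   else lapply(scene$truth_report, as.data.frame),
    truth_diagnoses = if (one) as.list(scene$truth_diagnoses)
                      else lapply(scene$truth_diagnoses, as.list),
    condition = scene$condition)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 8, null = "null",
                              dataframe = "rows", pretty = TRUE), path)
  invisible(path)
}
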