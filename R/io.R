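# Reading and writing images, annotation JSON, and result files.

#' Read an 8-bit grayscale image
#'
#' PNG and (multi-page) TIFF are supported. Multi-channel images are
#' reduced to their first channel; intensities are rescaled to 0..255
#' integers.
#'
#' @param path file path; extension decides the reader.
#' @return an image matrix, or a list of matrices for a multi-page TIFF.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  to_mat <- function(x) {
    if (length(dim(x)) == 3) x <- x[, , 1]
    matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
  }
  if (ext == "png") return(to_mat(png::readPNG(path)))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) return(to_mat(pages))
    mats <- lapply(pages, to_mat)
    if (length(mats) == 1) return(mats[[1]])
    return(mats)
  }
  stop("unsupported image format: ", ext)
}

#' Write an 8-bit grayscale image as PNG
#'
#' @param image image matrix with values 0..255.
#' @param path output path.
#' @export
write_image <- function(image, path) {
  png::writePNG(clamp(image, 0, 255) / 255, path)
  invisible(path)
}

#' Read per-structure annotations from JSON
#'
#' Schema: `{"image": str, "detections": [{"structure": ..., "box":
#' [x_min, y_min, x_max, y_max], "confidence": float}]}` with 0-based
#' half-open boxes.
#'
#' @param path JSON file path.
#' @return list of [detection()] objects (raw; pass through
#'   [select_best_per_class()] to obtain a [detection_set()]).
#' @export
read_annotations <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(j$detections, function(d)
    detection(d$structure, unlist(d$box), d$confidence))
}

#' Write a detection set (or detection list) as annotation JSON
#'
#' @param detections a [detection_set()] or list of [detection()].
#' @param image_name image file name recorded in the annotation.
#' @param path output JSON path.
#' @export
write_annotations <- function(detections, image_name, path) {
  if (inherits(detections, "detection_set")) {
    ds <- detections
    detections <- list()
    for (s in STRUCTURES) {
      r <- ds_row(ds, s)
      if (r$present)
        detections <- c(detections,
                        list(detection(s, r$box, r$confidence)))
    }
  }
  out <- list(
    image = image_name,
    detections = lapply(detections, function(d)
      list(structure = d$structure, box = as.numeric(d$box),
           confidence = d$confidence))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a phantom frame (image, ground-truth sidecar) to disk
#'
#' The image goes to `frame_<index>.png` (zero-padded) and the exact
#' ground truth (boxes, landmarks, angles, tilt) to a JSON sidecar with
#' the same stem.
#'
#' @param frame a `phantom_frame`.
#' @param dir output directory (created if needed).
#' @param index frame number used in the file name.
#' @return the image path, invisibly.
#' @export
write_phantom_frame <- function(frame, dir, index = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, sprintf("frame_%04d", index))
  write_image(frame$image, paste0(stem, ".png"))
  write_annotations(frame$true_boxes, basename(paste0(stem, ".png")),
                    paste0(stem, ".json"))
  gt <- list(
    landmarks = frame$true_landmarks,
    alpha = frame$true_alpha, beta = frame$true_beta,
    tilt = frame$true_tilt
  )
  jsonlite::write_json(gt, paste0(stem, "_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paste0(stem, ".png"))
}

#' Write a phantom video as a numbered frame directory
#'
#' @param video a `phantom_video`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom_video <- function(video, dir) {
  for (i in seq_along(video$frames))
    write_phantom_frame(video$frames[[i]], dir, i - 1)
  invisible(dir)
}

#' Serialize an angle measurement result to JSON
#'
#' @param result an `angle_result`.
#' @param path output path.
#' @export
write_result_json <- function(result, path) {
  line_out <- function(l) list(point = as.numeric(l$point),
                               direction = as.numeric(l$direction))
  out <- list(
    alpha = result$alpha, beta = result$beta, graf_type = result$graf_type,
    landmarks = lapply(unclass(result$landmarks)[
      c("bony_roof_point", "bony_rim_point",
        "lower_limb_point", "labrum_center")], as.numeric),
    lines = lapply(result$lines, line_out),
    frame_index = result$frame_index
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Draw the measurement overlay onto an image
#'
#' Renders the three measurement lines (gray level 255) and the four
#' landmarks (3x3 blocks) into a copy of the image, for visual inspection
#' of a measurement.
#'
#' @param image 8-bit image matrix.
#' @param result an `angle_result`.
#' @return the annotated image matrix.
#' @export
draw_overlay <- function(image, result) {
  h <- nrow(image); w <- ncol(image)
  put <- function(img, x, y, val) {
    ok <- x >= 0 & x < w & y >= 0 & y < h
    img[cbind(round(y[ok]) + 1, round(x[ok]) + 1)] <- val
    img
  }
  for (l in result$lines) {
    tt <- seq(-max(h, w), max(h, w), by = 0.5)
    image <- put(image, l$point[1] + tt * l$direction[1],
                 l$point[2] + tt * l$direction[2], 255)
  }
  for (p in result$landmarks[c("bony_roof_point", "bony_rim_point",
                               "lower_limb_point", "labrum_center")]) {
    gx <- rep(p[1] + (-1:1), 3); gy <- rep(p[2] + (-1:1), each = 3)
    image <- put(image, gx, gy, 255)
  }
  image
}
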