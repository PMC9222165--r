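# Detector contract and detection post-processing.
#
# A detector is any function(image, frame_index) returning a list of
# `detection` objects (or a ready `detection_set`); the rest of the pipeline
# depends only on this schema, so an external neural detector can be plugged
# in wherever the bundled heuristic detector is used.

#' The four Graf anatomical structure classes
#'
#' The structures that must be localized on a coronal standard plane:
#' ilium, labrum, bony rim, and lower limb of the os ilium.
#' @export
STRUCTURES <- c("ilium", "labrum", "bony_rim", "lower_limb")

#' A single structure detection
#'
#' @param structure one of [STRUCTURES].
#' @param box numeric length-4 bounding box `c(x_min, y_min, x_max, y_max)`,
#'   0-based half-open pixel coordinates, with `x_max > x_min` and
#'   `y_max > y_min`.
#' @param confidence detector confidence. Values are clamped to `[0, 1]`;
#'   external detectors emitting logits must normalize before entry.
#' @return an object of class `detection`.
#' @export
detection <- function(structure, box, confidence) {
  structure <- match.arg(structure, STRUCTURES)
  box <- as.numeric(box)
  stopifnot(length(box) == 4)
  if (box[3] <= box[1] || box[4] <= box[2])
    stop("invalid box: x_max must exceed x_min and y_max must exceed y_min")
  confidence <- clamp(as.numeric(confidence), 0, 1)
  structure(list(structure = structure, box = box, confidence = confidence),
            class = "detection")
}

#' Assemble a detection set (at most one detection per structure)
#'
#' A `detection_set` is a four-row data frame, one row per structure class in
#' the fixed order of [STRUCTURES]. Absent structures carry confidence 0 and
#' `NA` box coordinates.
#'
#' @param detections list of [detection()] objects, at most one per class.
#' @return an object of class `detection_set` (also a `data.frame`).
#' @export
detection_set <- function(detections = list()) {
  ds <- data.frame(
    structure = STRUCTURES,
    present = FALSE,
    confidence = 0,
    x_min = NA_real_, y_min = NA_real_, x_max = NA_real_, y_max = NA_real_,
    stringsAsFactors = FALSE
  )
  seen <- character()
  for (d in detections) {
    stopifnot(inherits(d, "detection"))
    if (d$structure %in% seen)
      stop("duplicate structure in detection set: ", d$structure)
    seen <- c(seen, d$structure)
    i <- match(d$structure, STRUCTURES)
    ds$present[i] <- TRUE
    ds$confidence[i] <- d$confidence
    ds[i, c("x_min", "y_min", "x_max", "y_max")] <- as.list(d$box)
  }
  class(ds) <- c("detection_set", "data.frame")
  ds
}

ds_row <- function(ds, structure) {
  i <- match(structure, STRUCTURES)
  list(present = ds$present[i], confidence = ds$confidence[i],
       box = c(ds$x_min[i], ds$y_min[i], ds$x_max[i], ds$y_max[i]))
}

ds_center <- function(ds, structure) {
  r <- ds_row(ds, structure)
  c((r$box[1] + r$box[3]) / 2, (r$box[2] + r$box[4]) / 2)
}

#' Keep the best detection per structure class
#'
#' Raw detector output may contain several candidate boxes per class; only
#' the highest-confidence box of each class is retained. Equal-confidence
#' ties are broken by larger box area, then by first occurrence. Classes
#' with no candidate are marked absent with confidence 0.
#'
#' @param raw list of [detection()] objects (any classes, any multiplicity).
#' @return a [detection_set()].
#' @export
select_best_per_class <- function(raw) {
  if (inherits(raw, "detection_set")) return(raw)
  best <- list()
  for (d in raw) {
    stopifnot(inherits(d, "detection"))
    cur <- best[[d$structure]]
    if (is.null(cur)) {
      best[[d$structure]] <- d
      next
    }
    area_new <- (d$box[3] - d$box[1]) * (d$box[4] - d$box[2])
    area_cur <- (cur$box[3] - cur$box[1]) * (cur$box[4] - cur$box[2])
    if (d$confidence > cur$confidence ||
        (d$confidence == cur$confidence && area_new > area_cur))
      best[[d$structure]] <- d
  }
  detection_set(unname(best))
}

#' Check the clinical layout of a detection set
#'
#' Validates the relative positions of the detected structures against the
#' expected coronal standard-plane layout (near-vertical ilium; lower limb
#' deepest; bony rim at the caudal end of the ilium, superficial to the
#' lower limb; labrum superficial to the bony rim). Absent structures are
#' skipped, not failed. The rules, stated on box centers:
#'
#' * R1 - the lower-limb center is deeper (larger column) than the ilium
#'   center and caudal to the ilium box's vertical midpoint;
#' * R2 - the bony-rim center lies caudal to the ilium box's cranial edge
#'   and superficial to the lower-limb center;
#' * R3 - the labrum center is superficial (smaller column) to the bony-rim
#'   center;
#' * R4 - no box center lies outside the image (checked when `image_dim`
#'   is supplied).
#'
#' @param ds a [detection_set()].
#' @param image_dim optional `c(height, width)` in pixels for rule R4.
#' @return list with elements `valid` (logical) and `reasons` (character
#'   vector naming each violated rule); invalidity is a return state, not
#'   an error.
#' @export
check_relative_positions <- function(ds, image_dim = NULL) {
  stopifnot(inherits(ds, "detection_set"))
  reasons <- character()
  has <- function(s) ds_row(ds, s)$present
  if (has("ilium") && has("lower_limb")) {
    il <- ds_row(ds, "ilium"); ll <- ds_center(ds, "lower_limb")
    il_c <- ds_center(ds, "ilium")
    mid_y <- (il$box[2] + il$box[4]) / 2
    if (!(ll[1] > il_c[1] && ll[2] > mid_y))
      reasons <- c(reasons,
        "R1: lower limb center must be deeper than the ilium center and caudal to the ilium midline")
  }
  if (has("bony_rim")) {
    br <- ds_center(ds, "bony_rim")
    if (has("ilium")) {
      il <- ds_row(ds, "ilium")
      if (!(br[2] > il$box[2]))
        reasons <- c(reasons,
          "R2: bony rim center must lie caudal to the ilium's cranial edge")
    }
    if (has("lower_limb")) {
      ll <- ds_center(ds, "lower_limb")
      if (!(br[1] < ll[1]))
        reasons <- c(reasons,
          "R2: bony rim center must be superficial to the lower limb center")
    }
  }
  if (has("labrum") && has("bony_rim")) {
    la <- ds_center(ds, "labrum"); br <- ds_center(ds, "bony_rim")
    if (!(la[1] < br[1]))
      reasons <- c(reasons,
        "R3: labrum center must be superficial to the bony rim center")
  }
  if (!is.null(image_dim)) {
    for (s in STRUCTURES) {
      if (!has(s)) next
      ctr <- ds_center(ds, s)
      if (ctr[1] < 0 || ctr[2] < 0 ||
          ctr[1] >= image_dim[2] || ctr[2] >= image_dim[1])
        reasons <- c(reasons,
          sprintf("R4: %s box center lies outside the image", s))
    }
  }
  list(valid = length(reasons) == 0, reasons = reasons)
}

# Moment-based shape features of one labeled component.
component_features <- function(image, mask) {
  px <- mask_pixels(mask)
  n <- nrow(px)
  ctr <- colMeans(px)
  dx <- px[, 1] - ctr[1]; dy <- px[, 2] - ctr[2]
  a <- mean(dx^2); b <- mean(dx * dy); c2 <- mean(dy^2)
  ev <- eigen(matrix(c(a, b, b, c2), 2), symmetric = TRUE, only.values = TRUE)$values
  elong <- sqrt(max(ev[1], 1e-12) / max(ev[2], 1e-12))
  bb <- mask_bbox(mask)
  fill <- n / ((bb[3] - bb[1]) * (bb[4] - bb[2]))
  list(n = n, centroid = ctr, bbox = bb, fill = fill,
       mean_int = mean(image[mask]), elongation = elong,
       theta = tryCatch(orientation_theta(compute_moments(crop_box(image, bb) * crop_box(mask * 1, bb))),
                        error = function(e) NA_real_))
}

#' Heuristic structure detector for phantom-like images
#'
#' A deterministic stand-in for a trained detector, intended for
#' phantom-like images with bright structures on a dark background: the
#' image is thresholded at the maximum-entropy level, 8-connected bright
#' components are extracted, and components are assigned to structure
#' classes using the same layout rules enforced by
#' [check_relative_positions()]. The ilium is the most elongated
#' near-vertical component; components superficial to the fitted ilium edge
#' line become labrum candidates, and deep components are split into bony
#' rim (near the ilium's caudal tip) and lower limb (far from it).
#' Confidence is the component's mean intensity normalized to `[0, 1]`
#' multiplied by its bounding-box fill fraction; absent structures get
#' confidence 0.
#'
#' @param image integer matrix, 8-bit grayscale.
#' @param min_area smallest component (pixels) considered a structure.
#' @return a [detection_set()]; a blank (single-level) image yields an
#'   all-absent set.
#' @export
reference_detect <- function(image, min_area = 10) {
  stopifnot(is.matrix(image))
  empty <- detection_set()
  counts <- tabulate(as.integer(image) + 1L, nbins = 256)
  t <- tryCatch(max_entropy_threshold(counts), error = function(e) NULL)
  if (is.null(t)) return(empty)
  lab <- label_components(image > t)
  k <- max(lab)
  if (k == 0) return(empty)
  feats <- lapply(seq_len(k), function(i) {
    f <- component_features(image, lab == i)
    f$id <- i
    f
  })
  feats <- Filter(function(f) f$n >= min_area, feats)
  if (length(feats) == 0) return(empty)

  # ilium: most elongated near-vertical component, largest on ties
  is_il <- vapply(feats, function(f)
    f$elongation >= 2.5 && is.finite(f$theta) && abs(f$theta) <= 30, logical(1))
  if (!any(is_il)) return(empty)
  il_cands <- feats[is_il]
  il <- il_cands[[which.max(vapply(il_cands, function(f) f$n, numeric(1)))]]
  rest <- Filter(function(f) f$id != il$id, feats)

  # superficial edge line of the ilium component, for left/right assignment
  il_mask <- lab == il$id
  edge <- tryCatch(fit_baseline(il_mask), error = function(e) NULL)
  il_px <- mask_pixels(il_mask)
  tip <- il_px[which.max(il_px[, 2]), ]    # most caudal ilium pixel

  side_of_edge <- function(p) {
    if (is.null(edge)) return(p[1] - il$centroid[1])
    n <- c(edge$direction[2], -edge$direction[1])
    if (n[1] < 0) n <- -n                  # deep-pointing normal
    sum((p - edge$point) * n)
  }

  cand <- list(labrum = NULL, bony_rim = NULL, lower_limb = NULL)
  near <- 0.1 * ncol(image)
  for (f in rest) {
    cls <- if (side_of_edge(f$centroid) < 0) "labrum"
    else if (sqrt(sum((f$centroid - tip)^2)) <= near) "bony_rim"
    else "lower_limb"
    if (is.null(cand[[cls]]) || f$n > cand[[cls]]$n) cand[[cls]] <- f
  }

  dets <- list(detection("ilium", il$bbox,
                         clamp(il$mean_int / 255 * il$fill, 0, 1)))
  for (cls in names(cand)) {
    f <- cand[[cls]]
    if (!is.null(f))
      dets <- c(dets, list(detection(cls, f$bbox,
                                     clamp(f$mean_int / 255 * f$fill, 0, 1))))
  }
  detection_set(dets)
}
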