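# Standard-plane scoring.
#
# A frame's total score is a weighted sum of the per-structure detection
# confidences and a dedicated ilium shape score,
#
#   S = lambda1 * S_lower_limb + lambda2 * S_labrum
#     + lambda3 * S_bony_rim   + lambda4 * S_ilium,
#
# where the ilium term combines its confidence, the height-width ratio of
# its bounding box, and an angle score derived from the image-moment
# orientation of the expanded ilium region,
#
#   S_ilium = lambda5 * S_conf + lambda6 * S_hw + lambda7 * S_angle,
#   S_angle = 1 - |theta| / 10.
#
# The lower limb of the os ilium carries the largest frame-level weight
# because no Graf diagnosis may be made when it is not seen, and the angle
# score deliberately goes negative beyond 10 degrees of tilt to penalize
# oblique planes.

#' Scoring weights
#'
#' Frame-level weights `l1`-`l4` (lower limb, labrum, bony rim, ilium) and
#' ilium-level weights `l5`-`l7` (confidence, height-width ratio, angle
#' score). Defaults: `l1 = 3`, `l2 = l3 = 1`, `l4 = 1`, `l5 = 0.2`,
#' `l6 = 0.3`, `l7 = 0.5`. `l4` is the package's own choice, symmetric
#' with the labrum and bony-rim weights; the ilium's extra importance is
#' already encoded inside its composite score.
#'
#' @param l1,l2,l3,l4,l5,l6,l7 non-negative weights.
#' @return an object of class `graf_weights`.
#' @export
graf_weights <- function(l1 = 3, l2 = 1, l3 = 1, l4 = 1,
                         l5 = 0.2, l6 = 0.3, l7 = 0.5) {
  w <- list(l1 = l1, l2 = l2, l3 = l3, l4 = l4, l5 = l5, l6 = l6, l7 = l7)
  if (any(unlist(w) < 0)) stop("scoring weights must be non-negative")
  structure(w, class = "graf_weights")
}

#' Expand a bounding box by a per-side margin
#'
#' Each side is grown by `margin_fraction` of the corresponding box
#' dimension (floor on minima, ceiling on maxima) and clipped to the image
#' bounds, so that the expanded region contains the entire structure even
#' when the detector box is tight.
#'
#' @param box half-open box `c(x_min, y_min, x_max, y_max)`.
#' @param image_dim `c(height, width)` in pixels.
#' @param margin_fraction non-negative expansion fraction per side.
#' @return an expanded half-open box.
#' @export
expand_box <- function(box, image_dim, margin_fraction = 0.1) {
  stopifnot(margin_fraction >= 0, length(box) == 4)
  w <- box[3] - box[1]; h <- box[4] - box[2]
  if (w <= 0 || h <= 0) stop("degenerate box cannot be expanded")
  c(max(0, floor(box[1] - margin_fraction * w)),
    max(0, floor(box[2] - margin_fraction * h)),
    min(image_dim[2], ceiling(box[3] + margin_fraction * w)),
    min(image_dim[1], ceiling(box[4] + margin_fraction * h)))
}

#' Raw and central image moments of a pixel region
#'
#' For a region `V` with `I` columns and `J` rows, the raw moments are
#' `Mpq = sum_i sum_j i^p j^q V(i, j)` with `i` running over columns and
#' `j` over rows, both 0-based. The centroid is `(M10/M00, M01/M00)` and
#' the second-order central terms are `a = M20/M00 - xc^2`,
#' `b = M11/M00 - xc*yc`, `c = M02/M00 - yc^2`.
#'
#' @param V numeric matrix of pixel intensities (rows x cols).
#' @return an object of class `moment_set` with the raw moments up to
#'   order 2, the centroid `xc`, `yc`, and `a`, `b`, `c`.
#' @export
compute_moments <- function(V) {
  stopifnot(is.matrix(V), length(V) > 0)
  J <- nrow(V); I <- ncol(V)
  i <- 0:(I - 1); j <- 0:(J - 1)
  cs <- colSums(V)   # indexed by i
  rs <- rowSums(V)   # indexed by j
  m00 <- sum(cs)
  if (m00 <= 0) stop("region has zero total intensity; moments undefined")
  m10 <- sum(i * cs); m01 <- sum(j * rs)
  m20 <- sum(i^2 * cs); m02 <- sum(j^2 * rs)
  m11 <- sum((i %o% j) * t(V))
  xc <- m10 / m00; yc <- m01 / m00
  a <- max(0, m20 / m00 - xc^2)
  c_ <- max(0, m02 / m00 - yc^2)
  b <- m11 / m00 - xc * yc
  structure(list(I = I, J = J,
                 m00 = m00, m10 = m10, m01 = m01,
                 m11 = m11, m20 = m20, m02 = m02,
                 xc = xc, yc = yc, a = a, b = b, c = c_),
            class = "moment_set")
}

#' Principal-axis deviation of a region from the image vertical
#'
#' The principal axis of the intensity distribution is obtained from the
#' second-order central moments via the half-angle form
#' `theta_axis = atan2(2 b, a - c) / 2` (measured from the column axis),
#' and reported as the deviation of the major axis from the image
#' vertical, wrapped to `(-90, 90]`, positive when the top of the axis
#' leans toward larger column index (deeper). Isotropic regions return 0.
#'
#' @param m a [compute_moments()] result.
#' @return angle in degrees in `(-90, 90]`.
#' @export
orientation_theta <- function(m) {
  stopifnot(inherits(m, "moment_set"))
  if (abs(m$a - m$c) < 1e-12 && abs(m$b) < 1e-12) return(0)
  th <- 0.5 * atan2(2 * m$b, m$a - m$c)
  v <- c(cos(th), sin(th))             # major axis in (column, row)
  if (v[2] > 0) v <- -v                # cranial-pointing representative
  if (v[2] == 0) return(90)            # horizontal axis
  rad2deg(atan2(v[1], -v[2]))
}

#' Ilium angle score
#'
#' `S_angle = 1 - |theta| / 10`: maximal (1) for a perfectly vertical
#' ilium, zero at 10 degrees of tilt, and deliberately negative beyond --
#' the negativity penalizes oblique planes, so no clamping is applied.
#'
#' @param theta tilt from vertical, degrees.
#' @return dimensionless score (may be negative).
#' @export
angle_score <- function(theta) {
  stopifnot(is.finite(theta))
  1 - abs(theta) / 10
}

#' Height-width ratio of a bounding box
#'
#' A straight, vertical ilium occupies little width, so within one video a
#' larger height-width ratio of the ilium box indicates a frame closer to
#' the standard plane.
#'
#' @param box half-open box `c(x_min, y_min, x_max, y_max)`.
#' @return `(y_max - y_min) / (x_max - x_min)`.
#' @export
height_width_ratio <- function(box) {
  w <- box[3] - box[1]
  if (w <= 0) stop("box has non-positive width")
  (box[4] - box[2]) / w
}

#' Composite ilium shape score
#'
#' Expands the ilium box (default margin 0.1 per side), measures the
#' moment-based tilt `theta` of the expanded region, and combines
#' confidence, height-width ratio of the original box, and the angle score:
#' `S_ilium = l5 * S_conf + l6 * S_hw + l7 * S_angle`.
#'
#' @param conf ilium detection confidence in `(0, 1]`.
#' @param box ilium bounding box (half-open).
#' @param image 8-bit image matrix.
#' @param weights a [graf_weights()].
#' @param margin_fraction box expansion per side.
#' @return an object of class `ilium_shape_score` with fields `sconf`,
#'   `shw`, `sangle`, `theta`, `silium`.
#' @export
ilium_score <- function(conf, box, image, weights = graf_weights(),
                        margin_fraction = 0.1) {
  stopifnot(conf > 0)
  eb <- expand_box(box, dim(image), margin_fraction)
  m <- compute_moments(crop_box(image, eb))
  theta <- orientation_theta(m)
  sangle <- angle_score(theta)
  shw <- height_width_ratio(box)
  structure(list(
    sconf = conf, shw = shw, sangle = sangle, theta = theta,
    silium = weights$l5 * conf + weights$l6 * shw + weights$l7 * sangle
  ), class = "ilium_shape_score")
}

#' Score one frame against the Graf standard-plane criteria
#'
#' The lower-limb, labrum, and bony-rim terms are the detection
#' confidences (0 when absent); the ilium term is the composite
#' [ilium_score()] (0 when the ilium is absent). If the relative-position
#' check fails, the frame cannot be a clinically valid standard plane and
#' its total score is set to 0.
#'
#' @param image 8-bit image matrix.
#' @param ds a [detection_set()].
#' @param weights a [graf_weights()].
#' @param margin_fraction ilium box expansion per side.
#' @return an object of class `frame_score` with the total `s`, the
#'   sub-scores, the ilium shape score (or `NULL`), `position_valid`, and
#'   the violated-rule `reasons`.
#' @export
frame_score <- function(image, ds, weights = graf_weights(),
                        margin_fraction = 0.1) {
  stopifnot(inherits(ds, "detection_set"))
  pos <- check_relative_positions(ds, dim(image))
  il <- ds_row(ds, "ilium")
  s_il <- NULL
  silium <- 0
  if (il$present && il$confidence > 0) {
    s_il <- ilium_score(il$confidence, il$box, image, weights,
                        margin_fraction)
    silium <- s_il$silium
  }
  sll <- ds_row(ds, "lower_limb")$confidence
  slab <- ds_row(ds, "labrum")$confidence
  srim <- ds_row(ds, "bony_rim")$confidence
  s <- if (pos$valid)
    weights$l1 * sll + weights$l2 * slab + weights$l3 * srim +
      weights$l4 * silium
  else 0
  structure(list(s = s, s_lower_limb = sll, s_labrum = slab,
                 s_bony_rim = srim, s_ilium = s_il, silium = silium,
                 position_valid = pos$valid, reasons = pos$reasons),
            class = "frame_score")
}

#' Select the standard plane of a frame sequence
#'
#' Scores every frame and returns the index of the highest-scoring one
#' (earliest on exact ties). `method = "confidence_sum"` is the ablation
#' baseline that scores a frame by the plain sum of the four detection
#' confidences, with no shape term and no position check.
#'
#' @param frames list of 8-bit image matrices, or a `phantom_video`.
#' @param detector `function(image, frame_index)` returning a list of
#'   [detection()] or a [detection_set()]; see also [oracle_detector()]
#'   and [reference_detect()].
#' @param weights a [graf_weights()].
#' @param method `"spsm"` (full scoring) or `"confidence_sum"` (ablation).
#' @return list with `index` (1-based selected frame), `scores` (numeric
#'   per-frame totals), `frame_scores` (list of `frame_score`, `"spsm"`
#'   only), `detections` (per-frame [detection_set()]), and `summary`
#'   (data frame: one row per frame).
#' @export
select_standard_frame <- function(frames, detector,
                                  weights = graf_weights(),
                                  method = c("spsm", "confidence_sum")) {
  method <- match.arg(method)
  if (inherits(frames, "phantom_video"))
    frames <- lapply(frames$frames, `[[`, "image")
  n <- length(frames)
  if (n < 1) stop("need at least one frame")
  fs <- vector("list", n)
  dss <- vector("list", n)
  s <- numeric(n)
  for (i in seq_len(n)) {
    raw <- detector(frames[[i]], i)
    ds <- if (inherits(raw, "detection_set")) raw else select_best_per_class(raw)
    dss[[i]] <- ds
    if (method == "spsm") {
      fs[[i]] <- frame_score(frames[[i]], ds, weights)
      s[i] <- fs[[i]]$s
    } else {
      s[i] <- sum(ds$confidence)
    }
  }
  if (all(s == 0))
    stop("no usable plane: every frame scored 0")
  idx <- which.max(s)
  summary <- data.frame(
    frame_index = seq_len(n), s = s,
    s_lower_limb = vapply(dss, function(d) ds_row(d, "lower_limb")$confidence, 0),
    s_labrum = vapply(dss, function(d) ds_row(d, "labrum")$confidence, 0),
    s_bony_rim = vapply(dss, function(d) ds_row(d, "bony_rim")$confidence, 0),
    silium = if (method == "spsm")
      vapply(fs, function(f) f$silium, 0) else NA_real_,
    theta = if (method == "spsm")
      vapply(fs, function(f) if (is.null(f$s_ilium)) NA_real_ else f$s_ilium$theta, 0)
    else NA_real_,
    position_valid = if (method == "spsm")
      vapply(fs, function(f) f$position_valid, TRUE) else NA
  )
  list(index = idx, scores = s, frame_scores = fs, detections = dss,
       summary = summary)
}
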