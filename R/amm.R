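# Angle measurement.
#
# Inside each validated bounding box the structure is segmented by
# maximum-entropy (Kapur) thresholding, the four Graf landmarks are
# localized from the segmented masks, the three measurement lines are
# constructed (baseline = tangent of the uppermost ilium; bony roof line
# through the lower limb point and the lateral tangent point on the bony
# roof; cartilage roof line through the bony rim point and the labrum
# center), and alpha and beta are the acute angles these lines make with
# the baseline. Type I/II classification uses the 60-degree alpha boundary.

#' Maximum-entropy (Kapur) threshold of a 256-bin histogram
#'
#' Returns the gray level `t` maximizing the sum of Shannon entropies of
#' the normalized background (levels `<= t`) and foreground (levels `> t`)
#' distributions, searched exhaustively over all thresholds for which both
#' classes are non-empty; the smallest `t` wins ties. The foreground mask
#' of an image thresholded at `t` is `image > t`.
#'
#' @param histogram integer vector of 256 counts for levels 0..255.
#' @return the threshold gray level (0-based).
#' @export
max_entropy_threshold <- function(histogram) {
  stopifnot(length(histogram) == 256, all(histogram >= 0))
  total <- sum(histogram)
  if (total <= 0) stop("histogram is empty")
  if (sum(histogram > 0) < 2)
    stop("histogram has a single gray level; threshold undefined")
  p <- histogram / total
  plogp <- ifelse(p > 0, p * log(p), 0)
  cw <- cumsum(p)
  cpl <- cumsum(plogp)
  tot_pl <- cpl[256]
  psi <- rep(-Inf, 255)                      # candidate t = 0..254
  for (t in 0:254) {
    w0 <- cw[t + 1]; w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    psi[t + 1] <- log(w0) - cpl[t + 1] / w0 +
      log(w1) - (tot_pl - cpl[t + 1]) / w1
  }
  which.max(psi) - 1L                        # earliest maximum on ties
}

#' Segment the structure inside a bounding box
#'
#' Thresholds the box-local histogram at the maximum-entropy level and
#' keeps the largest 8-connected foreground component, suppressing speckle
#' islands.
#'
#' @param image 8-bit image matrix.
#' @param box half-open box within the image.
#' @return a logical box-local mask (same shape as the cropped region).
#' @export
segment_structure <- function(image, box) {
  sub <- crop_box(image, box)
  counts <- tabulate(as.integer(sub) + 1L, nbins = 256)
  t <- max_entropy_threshold(counts)
  mask <- sub > t
  if (!any(mask)) stop("segmentation produced an empty mask")
  largest_component(mask)
}

#' Fit the baseline as the tangent of the uppermost (superficial) ilium edge
#'
#' For each row spanned by the ilium mask the superficial edge pixel
#' (minimum column) is taken; a total-least-squares line is fitted to
#' these edge points and then translated perpendicular toward the
#' superficial side until every edge point lies on or deep to it, which
#' makes the returned line a tangent of the superficial ilium surface.
#'
#' @param mask logical ilium mask (box-local or full image), spanning at
#'   least 5 rows.
#' @param box optional half-open box locating the mask inside the image;
#'   when given, the returned line is in image coordinates.
#' @return a [graf_line()].
#' @export
fit_baseline <- function(mask, box = NULL) {
  stopifnot(is.matrix(mask))
  rows <- which(rowSums(mask) > 0)
  if (length(rows) < 5) stop("ilium mask spans fewer than 5 rows")
  edge <- t(vapply(rows, function(r)
    c(which(mask[r, ])[1] - 1, r - 1), numeric(2)))
  colnames(edge) <- c("x", "y")
  if (!is.null(box)) edge <- sweep(edge, 2, round(box[1:2]), `+`)
  ctr <- colMeans(edge)
  cc <- stats::cov(edge)
  ev <- eigen(cc, symmetric = TRUE)
  dir <- ev$vectors[, 1]
  ln <- graf_line(ctr, dir)
  n <- c(ln$direction[2], -ln$direction[1])
  if (n[1] < 0 || (n[1] == 0 && n[2] < 0)) n <- -n   # deep-pointing normal
  off <- as.matrix(sweep(edge, 2, ln$point)) %*% n
  graf_line(ln$point + min(off) * n, ln$direction)
}

#' Lateral tangent point from a pivot to a contour
#'
#' Returns the contour point `p` such that every contour point lies on the
#' deep (larger-column) side of the line from `pivot` through `p`;
#' collinear ties are broken by the point farthest from the pivot. This is
#' the construction of the bony roof line: a tangent placed from the lower
#' limb point just touching the bony roof.
#'
#' @param pivot numeric `(column, row)` point, not on the contour.
#' @param contour n x 2 matrix of `(column, row)` points.
#' @return the touching contour point, numeric length 2.
#' @export
tangent_point_from <- function(pivot, contour) {
  contour <- matrix(as.numeric(contour), ncol = 2)
  n <- nrow(contour)
  if (n == 0) stop("contour is empty")
  if (n == 1) return(contour[1, ])
  v <- sweep(contour, 2, pivot)
  eps <- 1e-9
  best <- 1L
  for (k in 2:n) {
    cr <- v[best, 1] * v[k, 2] - v[best, 2] * v[k, 1]
    if (cr < -eps) {
      best <- k
    } else if (abs(cr) <= eps &&
               sum(v[k, ]^2) > sum(v[best, ]^2)) {
      best <- k
    }
  }
  contour[best, ]
}

#' Localize the four Graf landmarks
#'
#' Operationalization of the clinical landmark definitions on segmented
#' masks:
#' * lower limb point -- centroid of the lower-limb mask;
#' * labrum center -- centroid of the labrum mask;
#' * bony rim point -- most superficial (minimum-column) pixel of the
#'   bony-rim mask, most cranial on ties;
#' * bony roof point -- [tangent_point_from()] the lower limb point to the
#'   contour formed by the caudal half of the ilium mask together with the
#'   bony-rim mask.
#'
#' Boxes are expanded by `margin_fraction` per side before segmentation so
#' that the box-local histogram always contains background context (a
#' perfectly tight box can otherwise be single-level).
#'
#' @param image 8-bit image matrix.
#' @param ds a [detection_set()] with all four structures present.
#' @param margin_fraction box expansion per side before segmentation.
#' @return a list with the four landmark `(column, row)` points; the
#'   box-local segmentation masks and the expanded boxes are attached as
#'   attributes `masks` and `boxes`.
#' @export
locate_landmarks <- function(image, ds, margin_fraction = 0.1) {
  stopifnot(inherits(ds, "detection_set"))
  missing <- STRUCTURES[!ds$present]
  if (length(missing))
    stop("cannot locate landmarks; missing structure(s): ",
         paste(missing, collapse = ", "))
  masks <- list()
  boxes <- list()
  px <- list()
  for (s in STRUCTURES) {
    b <- expand_box(ds_row(ds, s)$box, dim(image), margin_fraction)
    boxes[[s]] <- b
    masks[[s]] <- segment_structure(image, b)
    p <- mask_pixels(masks[[s]])
    p[, 1] <- p[, 1] + round(b[1]); p[, 2] <- p[, 2] + round(b[2])
    px[[s]] <- p
  }
  lower_limb_point <- colMeans(px$lower_limb)
  labrum_center <- colMeans(px$labrum)
  rp <- px$bony_rim
  rim_min <- rp[rp[, 1] == min(rp[, 1]), , drop = FALSE]
  bony_rim_point <- rim_min[which.min(rim_min[, 2]), ]
  ip <- px$ilium
  mid <- (min(ip[, 2]) + max(ip[, 2])) / 2
  contour <- rbind(ip[ip[, 2] >= mid, , drop = FALSE], rp)
  bony_roof_point <- tangent_point_from(lower_limb_point, contour)
  structure(list(bony_roof_point = as.numeric(bony_roof_point),
                 bony_rim_point = as.numeric(bony_rim_point),
                 lower_limb_point = as.numeric(lower_limb_point),
                 labrum_center = as.numeric(labrum_center)),
            masks = masks, boxes = boxes)
}

#' Acute angle between two undirected lines
#'
#' @param l1,l2 [graf_line()] objects.
#' @return `acos(|d1 . d2|)` in degrees, in `[0, 90]`.
#' @export
angle_between <- function(l1, l2) {
  d <- abs(sum(l1$direction * l2$direction))
  rad2deg(acos(clamp(d, 0, 1)))
}

#' Graf type from the alpha angle
#'
#' Type I (mature) if and only if `alpha >= boundary` (60 degrees by
#' default, boundary inclusive to type I); type II otherwise. Only the
#' binary type I / type II distinction is supported.
#'
#' @param alpha bony roof angle, degrees, in `[0, 90]`.
#' @param boundary classification boundary, degrees.
#' @return `"I"` or `"II"`.
#' @export
classify_graf <- function(alpha, boundary = 60) {
  stopifnot(is.finite(alpha), alpha >= 0, alpha <= 90)
  if (alpha >= boundary) "I" else "II"
}

#' Measure the Graf alpha and beta angles of one frame
#'
#' Composes segmentation, baseline fitting, and landmark localization: the
#' bony roof line runs through the lower limb point and the bony roof
#' point, the cartilage roof line through the bony rim point and the
#' labrum center, and alpha/beta are their acute angles with the baseline.
#'
#' @param image 8-bit image matrix.
#' @param ds a position-valid [detection_set()] with all four structures.
#' @param boundary type I/II classification boundary, degrees.
#' @return an object of class `angle_result`: `alpha`, `beta`,
#'   `graf_type`, `landmarks`, `lines` (baseline, bony roof, cartilage
#'   roof as [graf_line()]), `frame_index` (`NULL` unless set by the
#'   caller).
#' @export
measure <- function(image, ds, boundary = 60) {
  lm <- locate_landmarks(image, ds)
  baseline <- fit_baseline(attr(lm, "masks")$ilium, attr(lm, "boxes")$ilium)
  roof <- graf_line(lm$lower_limb_point,
                    lm$bony_roof_point - lm$lower_limb_point)
  cart <- graf_line(lm$bony_rim_point,
                    lm$labrum_center - lm$bony_rim_point)
  alpha <- angle_between(baseline, roof)
  beta <- angle_between(baseline, cart)
  structure(list(
    alpha = alpha, beta = beta,
    graf_type = classify_graf(alpha, boundary),
    landmarks = lm,
    lines = list(baseline = baseline, bony_roof_line = roof,
                 cartilage_roof_line = cart),
    frame_index = NULL
  ), class = "angle_result")
}

#' @export
print.angle_result <- function(x, ...) {
  cat(sprintf("Graf measurement: alpha = %.2f deg, beta = %.2f deg, type %s\n",
              x$alpha, x$beta, x$graf_type))
  invisible(x)
}
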