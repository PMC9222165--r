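# Shared geometry and raster helpers.
#
# Conventions used throughout the package:
#  * an image is an integer matrix (rows x cols) with gray levels 0..255,
#    origin at the top-left pixel;
#  * pixel coordinates are 0-based (column, row) pairs: the column index
#    increases with depth (rightward, toward the far field) and the row
#    index increases caudally (downward);
#  * bounding boxes are 0-based half-open: c(x_min, y_min, x_max, y_max).

DEG <- 180 / pi

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * DEG

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Construct a measurement line
#'
#' A line is stored as a point on the line plus a unit direction, both in
#' pixel coordinates (column, row). The direction is normalized and oriented
#' so that its row component is non-negative (caudal-pointing); purely
#' cranial/caudal ambiguity does not matter for the acute line-line angles
#' used by the measurement module.
#'
#' @param point numeric length-2, a point (column, row) on the line.
#' @param direction numeric length-2 direction vector; need not be unit.
#' @return an object of class `graf_line` with elements `point` and
#'   `direction` (unit norm).
#' @export
graf_line <- function(point, direction) {
  stopifnot(length(point) == 2, length(direction) == 2,
            all(is.finite(point)), all(is.finite(direction)))
  n <- sqrt(sum(direction^2))
  if (n == 0) stop("line direction must be non-zero")
  d <- direction / n
  if (d[2] < 0 || (d[2] == 0 && d[1] < 0)) d <- -d
  structure(list(point = as.numeric(point), direction = as.numeric(d)),
            class = "graf_line")
}

#' @export
print.graf_line <- function(x, ...) {
  cat(sprintf("<line through (%.2f, %.2f) direction (%.4f, %.4f)>\n",
              x$point[1], x$point[2], x$direction[1], x$direction[2]))
  invisible(x)
}

# Intersection-over-union of two half-open boxes.
iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) return(0)
  inter / ua
}

# 8-connected labeling of a logical mask. Returns an integer matrix of the
# same shape: 0 for background, 1..k for the components in the order their
# first (raster-order) pixel is met. Iterative flood fill over foreground
# indices only, so cost scales with the number of lit pixels.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  fg <- which(mask)               # column-major linear indices
  if (length(fg) == 0) return(lab)
  # raster order (row-major) so that component 1 starts at the topmost,
  # then leftmost, lit pixel
  rr <- (fg - 1L) %% h
  cc <- (fg - 1L) %/% h
  fg <- fg[order(rr, cc)]
  nxt <- 1L
  stack <- integer(length(fg))
  for (s in fg) {
    if (lab[s] != 0L) next
    lab[s] <- nxt
    top <- 1L
    stack[1L] <- s
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      r <- (cur - 1L) %% h + 1L
      c <- (cur - 1L) %/% h + 1L
      for (dc in -1:1) {
        nc <- c + dc
        if (nc < 1L || nc > w) next
        base <- (nc - 1L) * h
        for (dr in -1:1) {
          nr <- r + dr
          if (nr < 1L || nr > h) next
          ni <- base + nr
          if (mask[ni] && lab[ni] == 0L) {
            lab[ni] <- nxt
            top <- top + 1L
            if (top > length(stack)) stack <- c(stack, integer(length(stack)))
            stack[top] <- ni
          }
        }
      }
    }
    nxt <- nxt + 1L
  }
  lab
}

# Keep the largest 8-connected component of a mask (ties: the component
# whose first raster-order pixel comes first). Returns a logical matrix.
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# 0-based (column, row) coordinates of lit pixels, as an n x 2 matrix.
mask_pixels <- function(mask) {
  ij <- which(mask, arr.ind = TRUE)
  cbind(x = ij[, 2] - 1, y = ij[, 1] - 1)
}

# Tight half-open bounding box of a mask, in 0-based pixel coordinates.
mask_bbox <- function(mask) {
  px <- mask_pixels(mask)
  if (nrow(px) == 0) stop("empty mask has no bounding box")
  c(min(px[, 1]), min(px[, 2]), max(px[, 1]) + 1, max(px[, 2]) + 1)
}

# Extract the image region of a half-open box as a matrix (rows x cols).
crop_box <- function(image, box) {
  stopifnot(is.matrix(image))
  b <- round(box)
  if (b[3] <= b[1] || b[4] <= b[2]) stop("degenerate box")
  if (b[1] < 0 || b[2] < 0 || b[3] > ncol(image) || b[4] > nrow(image))
    stop("box extends outside the image")
  image[(b[2] + 1):b[4], (b[1] + 1):b[3], drop = FALSE]
}

# Evaluate a function with a temporary RNG seed, restoring the caller's
# generator state afterwards so rendering never disturbs user simulations.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
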