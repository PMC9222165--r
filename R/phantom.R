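# Synthetic hip-phantom generator.
#
# Renders coronal-standard-plane-like images with exact, analytically known
# ground truth: the ilium as a bright near-vertical band, the bony rim as a
# small diamond at the caudal end of the band, the lower limb of the os
# ilium as a disc placed along the true bony roof line, and the labrum as a
# disc placed along the true cartilage roof line. The construction
# guarantees that the four Graf landmarks derived from the rendered
# structures reproduce the requested alpha and beta angles, so every
# downstream stage (detection, scoring, measurement) can be tested without
# clinical data.
#
# Geometry (all in continuous pixel coordinates, column = depth, row =
# caudal): Q is the caudal tip of the ilium's superficial edge and the apex
# where the baseline meets the bony roof line. The baseline runs through Q
# tilted by `ilium_tilt` from the image vertical (positive tilt leans the
# cranial end deep). The bony roof line leaves Q at `alpha_true` degrees
# from the baseline toward the deep-caudal quadrant and carries the lower
# limb point K. The rim diamond sits just deep of the roof line near Q so
# that the lateral tangent from K touches the ilium tip exactly along the
# true roof line; its superficial vertex is the true bony rim point, from
# which the cartilage roof line leaves at `beta_true` degrees from the
# baseline toward the superficial-caudal quadrant and carries the labrum
# center.

PHANTOM_BG <- 20          # background gray level
PHANTOM_BAND_W <- 8       # ilium band width, px
PHANTOM_RIM_R <- 5.5      # rim diamond half-diagonal, px
PHANTOM_RIM_CLEAR <- 7    # rim center clearance from the roof line, px
PHANTOM_RIM_ALONG <- 0.051   # rim offset along the roof line, fraction of width
PHANTOM_DISC_R <- 6       # lower-limb / labrum disc radius, px
PHANTOM_ILIUM_H <- 0.33   # ilium band length, fraction of image height
PHANTOM_ROOF_L <- 0.215   # Q-to-lower-limb distance, fraction of width
PHANTOM_CART_L <- 0.16    # rim-to-labrum distance, fraction of width
PHANTOM_BOW_PX <- 10      # deep bow of the band at unit curvature, px

#' Specify a synthetic hip phantom
#'
#' @param image_height,image_width image size in pixels (at least 128).
#' @param ilium_tilt signed tilt of the ilium from the image vertical,
#'   degrees; positive leans the cranial end deep. Must lie in `[-20, 20]`.
#' @param ilium_curvature dimensionless bow factor; 0 renders a straight
#'   band, 1 bows the superficial edge about 10 px deep at mid-length.
#' @param alpha_true,beta_true the bony-roof and cartilage-roof angles the
#'   rendered geometry realizes, degrees; `alpha_true` in `[40, 80]`,
#'   `beta_true` in `[30, 90]`.
#' @param visibility named numeric vector over [STRUCTURES] with values in
#'   `[0, 1]`; 0 omits the structure entirely, intermediate values dim it.
#' @param noise_sigma standard deviation of additive Gaussian noise, gray
#'   levels.
#' @param contrast structure brightness above background, gray levels.
#' @param seed integer seed controlling the noise field.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_height = 256, image_width = 256,
                         ilium_tilt = 0, ilium_curvature = 0,
                         alpha_true = 60, beta_true = 55,
                         visibility = c(ilium = 1, labrum = 1,
                                        bony_rim = 1, lower_limb = 1),
                         noise_sigma = 3, contrast = 200, seed = 1) {
  vis <- c(ilium = 1, labrum = 1, bony_rim = 1, lower_limb = 1)
  if (length(visibility)) {
    stopifnot(!is.null(names(visibility)),
              all(names(visibility) %in% STRUCTURES))
    vis[names(visibility)] <- visibility
  }
  spec <- structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    ilium_tilt = as.numeric(ilium_tilt),
    ilium_curvature = as.numeric(ilium_curvature),
    alpha_true = as.numeric(alpha_true), beta_true = as.numeric(beta_true),
    visibility = vis, noise_sigma = as.numeric(noise_sigma),
    contrast = as.numeric(contrast), seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (image_height < 128 || image_width < 128)
      stop("image dimensions must be at least 128 px")
    if (alpha_true < 40 || alpha_true > 80)
      stop("alpha_true must lie in [40, 80] degrees")
    if (beta_true < 30 || beta_true > 90)
      stop("beta_true must lie in [30, 90] degrees")
    if (abs(ilium_tilt) > 20)
      stop("ilium_tilt must lie in [-20, 20] degrees")
    if (any(visibility < 0 | visibility > 1))
      stop("visibility values must lie in [0, 1]")
    if (noise_sigma < 0) stop("noise_sigma must be non-negative")
    if (contrast <= 0) stop("contrast must be positive")
  })
  invisible(spec)
}

# Continuous-coordinate scene layout for a spec. All directions are unit
# (column, row) vectors; angles measured from the image vertical.
phantom_geometry <- function(spec) {
  w <- spec$image_width; h <- spec$image_height
  t <- deg2rad(spec$ilium_tilt)
  psi <- deg2rad(spec$alpha_true - spec$ilium_tilt)     # roof from vertical
  phi <- deg2rad(-spec$ilium_tilt - spec$beta_true)     # cartilage from vertical
  q <- c(0.43 * w, 0.51 * h)
  d_base <- c(-sin(t), cos(t))        # baseline, caudal-pointing
  u_base <- -d_base                   # cranial-pointing
  n_base <- c(cos(t), sin(t))         # deep normal of the baseline
  d_roof <- c(sin(psi), cos(psi))
  n_roof <- c(cos(psi), -sin(psi))    # deep normal of the roof line
  d_cart <- c(sin(phi), cos(phi))
  k <- q + PHANTOM_ROOF_L * w * d_roof
  rim_c <- q + PHANTOM_RIM_ALONG * w * d_roof + PHANTOM_RIM_CLEAR * n_roof
  p_rim <- rim_c - c(PHANTOM_RIM_R, 0)
  labrum <- p_rim + PHANTOM_CART_L * w * d_cart
  list(q = q, k = k, rim_c = rim_c, p_rim = p_rim, labrum = labrum,
       d_base = d_base, u_base = u_base, n_base = n_base,
       d_roof = d_roof, d_cart = d_cart,
       band_len = PHANTOM_ILIUM_H * h)
}

#' Render a single phantom frame
#'
#' Deterministic for a fixed spec: the geometry is analytic and the noise
#' field is seeded. Structures with visibility 0 are omitted and their true
#' box is marked absent.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_frame`: `image` (8-bit matrix),
#'   `true_boxes` ([detection_set()] with confidence = visibility),
#'   `true_landmarks`, `true_baseline` (a [graf_line()]), `true_alpha`,
#'   `true_beta`, `true_tilt`, and the `spec`.
#' @export
render_frame <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  g <- phantom_geometry(spec)
  w <- spec$image_width; h <- spec$image_height

  margin <- 2
  pts <- rbind(g$q, g$q + g$band_len * g$u_base,
               g$k, g$rim_c, g$p_rim, g$labrum)
  reach <- c(PHANTOM_BAND_W + 1, PHANTOM_BAND_W + 1, PHANTOM_DISC_R,
             PHANTOM_RIM_R, 0, PHANTOM_DISC_R)
  if (any(pts[, 1] - reach < margin) || any(pts[, 1] + reach > w - margin) ||
      any(pts[, 2] - reach < margin) || any(pts[, 2] + reach > h - margin))
    stop("phantom geometry places a landmark or structure outside the image")

  X <- matrix(rep(0:(w - 1), each = h), h, w)   # column coordinate per pixel
  Y <- matrix(rep(0:(h - 1), times = w), h, w)  # row coordinate per pixel
  img <- matrix(PHANTOM_BG, h, w)

  masks <- list()
  vis <- spec$visibility

  if (vis[["ilium"]] > 0) {
    ux <- X - g$q[1]; uy <- Y - g$q[2]
    s <- ux * g$u_base[1] + uy * g$u_base[2]
    p <- ux * g$n_base[1] + uy * g$n_base[2]
    sh <- pmin(pmax(s / g$band_len, 0), 1)
    bow <- spec$ilium_curvature * PHANTOM_BOW_PX * 4 * sh * (1 - sh)
    masks$ilium <- s >= 0 & s <= g$band_len & p >= bow & p <= bow + PHANTOM_BAND_W
  }
  if (vis[["bony_rim"]] > 0)
    masks$bony_rim <- abs(X - g$rim_c[1]) + abs(Y - g$rim_c[2]) <= PHANTOM_RIM_R
  if (vis[["lower_limb"]] > 0)
    masks$lower_limb <- (X - g$k[1])^2 + (Y - g$k[2])^2 <= PHANTOM_DISC_R^2
  if (vis[["labrum"]] > 0)
    masks$labrum <- (X - g$labrum[1])^2 + (Y - g$labrum[2])^2 <= PHANTOM_DISC_R^2

  dets <- list()
  for (s in names(masks)) {
    lvl <- PHANTOM_BG + vis[[s]] * spec$contrast
    img[masks[[s]]] <- pmin(255, lvl)
    dets <- c(dets, list(detection(s, mask_bbox(masks[[s]]), vis[[s]])))
  }
  img <- round(img)
  storage.mode(img) <- "integer"
  if (spec$noise_sigma > 0)
    img <- add_noise(img, spec$noise_sigma, spec$seed)

  landmarks <- list(
    bony_roof_point = g$q,
    bony_rim_point = g$p_rim,
    lower_limb_point = g$k,
    labrum_center = g$labrum
  )
  structure(list(
    image = img,
    true_boxes = detection_set(dets),
    true_landmarks = landmarks,
    true_baseline = graf_line(g$q, g$d_base),
    true_alpha = spec$alpha_true,
    true_beta = spec$beta_true,
    true_tilt = spec$ilium_tilt,
    spec = spec
  ), class = "phantom_frame")
}

#' Add seeded Gaussian noise to an image
#'
#' Additive zero-mean Gaussian noise, rounded and clipped to `[0, 255]`.
#' Deterministic per seed; the caller's RNG state is left untouched.
#'
#' @param image 8-bit image matrix.
#' @param noise_sigma noise standard deviation in gray levels (`>= 0`).
#' @param seed integer seed.
#' @return an image matrix of the same shape.
#' @export
add_noise <- function(image, noise_sigma, seed = 1) {
  stopifnot(noise_sigma >= 0)
  if (noise_sigma == 0) return(image)
  noise <- with_seed(seed, matrix(stats::rnorm(length(image), 0, noise_sigma),
                                  nrow(image), ncol(image)))
  out <- clamp(round(image + noise), 0, 255)
  storage.mode(out) <- "integer"
  out
}

#' Render a probe-sweep phantom video
#'
#' One frame per tilt-trajectory entry, emulating a sweep across the
#' standard plane. Off-plane obliquity distorts the apparent joint
#' geometry: the angles rendered in a frame are the base spec's angles
#' shifted by `obliquity_gain` degrees per degree of tilt (clipped to the
#' renderable range), so only near-zero-tilt frames measure the hip's true
#' angles -- this is what makes standard-plane selection matter. Per-frame
#' `true_alpha`/`true_beta` record the rendered (apparent) angles; the
#' video-level `alpha_ref`/`beta_ref` record the hip's reference angles.
#'
#' @param base_spec a [phantom_spec()]; its tilt is overridden per frame.
#' @param tilt_trajectory numeric vector of per-frame tilts, degrees.
#' @param dropout_schedule optional list (one element per frame) of named
#'   visibility overrides, e.g. `list(NULL, c(lower_limb = 0), NULL)`.
#' @param obliquity_gain apparent-angle distortion, degrees per degree of
#'   tilt.
#' @return an object of class `phantom_video`: `frames` (list of
#'   `phantom_frame`), `best_frame_index` (1-based index of the frame
#'   minimizing `|tilt|` among frames with all four structures visible,
#'   earliest on ties), `alpha_ref`, `beta_ref`, `tilts`.
#' @export
render_video <- function(base_spec, tilt_trajectory, dropout_schedule = NULL,
                         obliquity_gain = 0.4) {
  stopifnot(inherits(base_spec, "phantom_spec"))
  n <- length(tilt_trajectory)
  if (n < 1) stop("tilt trajectory must be non-empty")
  if (!is.null(dropout_schedule) && length(dropout_schedule) != n)
    stop("dropout_schedule must have one entry per frame")
  frames <- vector("list", n)
  all_visible <- logical(n)
  for (i in seq_len(n)) {
    sp <- base_spec
    sp$ilium_tilt <- tilt_trajectory[i]
    sp$alpha_true <- clamp(base_spec$alpha_true +
                             obliquity_gain * tilt_trajectory[i], 40, 80)
    sp$beta_true <- clamp(base_spec$beta_true +
                            obliquity_gain * tilt_trajectory[i], 30, 90)
    if (!is.null(dropout_schedule) && !is.null(dropout_schedule[[i]])) {
      ov <- dropout_schedule[[i]]
      stopifnot(all(names(ov) %in% STRUCTURES))
      sp$visibility[names(ov)] <- ov
    }
    sp$seed <- base_spec$seed + i - 1L
    frames[[i]] <- render_frame(sp)
    all_visible[i] <- all(sp$visibility > 0)
  }
  if (!any(all_visible))
    stop("no frame shows all four structures; cannot define a best frame")
  cand <- which(all_visible)
  best <- cand[which.min(abs(tilt_trajectory[cand]))]
  structure(list(frames = frames, best_frame_index = best,
                 alpha_ref = base_spec$alpha_true,
                 beta_ref = base_spec$beta_true,
                 tilts = as.numeric(tilt_trajectory)),
            class = "phantom_video")
}

#' Ground-truth detector for phantom frames
#'
#' Returns a detector closure suitable for [select_standard_frame()] and
#' [run_dynamic()] that reads the exact ground-truth boxes of a
#' [render_video()] phantom (confidence = structure visibility). This is
#' the "oracle" detector used to test downstream modules in isolation from
#' detection quality.
#'
#' @param video a `phantom_video`.
#' @return `function(image, frame_index)` returning a [detection_set()].
#' @export
oracle_detector <- function(video) {
  stopifnot(inherits(video, "phantom_video"))
  function(image, frame_index) video$frames[[frame_index]]$true_boxes
}

#' Recompute alpha and beta from a landmark set and a baseline
#'
#' The analytic counterpart of [measure()]: the bony roof line is taken
#' through the lower limb and bony roof points, the cartilage roof line
#' through the bony rim point and labrum center, and both are intersected
#' with the given baseline as acute line-line angles.
#'
#' @param landmarks a landmark list with `bony_roof_point`,
#'   `bony_rim_point`, `lower_limb_point`, `labrum_center`.
#' @param baseline a [graf_line()].
#' @return named numeric `c(alpha, beta)` in degrees.
#' @export
angles_from_landmarks <- function(landmarks, baseline) {
  roof <- graf_line(landmarks$lower_limb_point,
                    landmarks$bony_roof_point - landmarks$lower_limb_point)
  cart <- graf_line(landmarks$bony_rim_point,
                    landmarks$labrum_center - landmarks$bony_rim_point)
  c(alpha = angle_between(baseline, roof),
    beta = angle_between(baseline, cart))
}
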