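test_that("expand_box grows each side by a fraction of its dimension", {
  expect_equal(expand_box(c(10, 10, 20, 30), c(100, 100), 0),
               c(10, 10, 20, 30))
  # width 10 -> +/-1, height 20 -> +/-2
  expect_equal(expand_box(c(10, 10, 20, 30), c(100, 100), 0.1),
               c(9, 8, 21, 32))
  # corner box clips at 0 and at the image edge
  expect_equal(expand_box(c(0, 0, 10, 10), c(12, 12), 0.5),
               c(0, 0, 12, 12))
  expect_error(expand_box(c(5, 5, 5, 10), c(100, 100), 0.1), "degenerate")
})

test_that("moments match hand sums on simple regions", {
  m <- compute_moments(matrix(1, 3, 3))
  expect_equal(m$m00, 9)
  expect_equal(c(m$xc, m$yc), c(1, 1))
  expect_equal(m$a, 2 / 3)
  expect_equal(m$c, 2 / 3)
  expect_equal(m$b, 0)

  v <- matrix(0, 8, 8); v[6, 3] <- 5   # single pixel at (i, j) = (2, 5)
  m2 <- compute_moments(v)
  expect_equal(c(m2$xc, m2$yc), c(2, 5))
  expect_equal(c(m2$a, m2$b, m2$c), c(0, 0, 0))

  expect_error(compute_moments(matrix(0, 4, 4)), "zero total intensity")
})

test_that("moments agree with a naive double-loop oracle on random regions", {
  with_test_seed(101, {
    for (rep in 1:100) {
      V <- matrix(stats::runif(64, 0, 255), 8, 8)
      m <- compute_moments(V)
      for (pq in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(2, 0), c(0, 2))) {
        expected <- naive_moment(V, pq[1], pq[2])
        got <- m[[paste0("m", pq[1], pq[2])]]
        expect_lt(abs(got - expected) / max(1, abs(expected)), 1e-9)
      }
    }
  })
})

test_that("orientation recovers bar tilts and respects the sign convention", {
  # vertical one-pixel-wide bar
  v <- matrix(0, 64, 64); v[10:50, 30] <- 1
  expect_equal(orientation_theta(compute_moments(v)), 0)
  # horizontal bar
  h <- matrix(0, 64, 64); h[30, 10:50] <- 1
  expect_equal(orientation_theta(compute_moments(h)), 90)
  # isotropic region
  expect_equal(orientation_theta(compute_moments(matrix(1, 9, 9))), 0)

  render_bar <- function(tilt, n = 256) {
    img <- matrix(0, n, n)
    for (y in 0:(n - 1)) {
      x0 <- n / 2 + (n / 2 - y) * tan(tilt * pi / 180)  # top leans deep for +tilt
      xs <- round(x0 + 0:3)
      xs <- xs[xs >= 0 & xs < n]
      img[y + 1, xs + 1] <- 200
    }
    img
  }
  for (tilt in c(-30, -15, -7, 0, 7, 15, 30)) {
    th <- orientation_theta(compute_moments(render_bar(tilt)))
    expect_lt(abs(th - tilt), 1)
  }
})

test_that("angle score is 1 at vertical and goes negative past 10 degrees", {
  expect_equal(angle_score(0), 1)
  expect_equal(angle_score(10), 0)
  expect_equal(angle_score(5), 0.5)
  expect_equal(angle_score(-5), 0.5)
  expect_equal(angle_score(15), -0.5)   # no clamping below zero
})

test_that("height-width ratio and ilium score compose per the formula", {
  expect_equal(height_width_ratio(c(10, 10, 20, 40)), 3)
  expect_equal(height_width_ratio(c(0, 0, 7, 7)), 1)
  expect_error(height_width_ratio(c(5, 0, 5, 7)), "width")

  # synthetic check of the weighted sum with a vertical band image
  img <- matrix(0, 100, 100); img[20:80, 48:52] <- 220
  box <- c(47, 19, 53, 81)
  sc <- ilium_score(1, box, img)
  expect_equal(sc$theta, 0, tolerance = 1e-8)
  expect_equal(sc$silium,
               0.2 * sc$sconf + 0.3 * sc$shw + 0.5 * sc$sangle)
  expect_equal(sc$sangle, 1 - abs(sc$theta) / 10)
  # weight substitution: Sconf 1, Shw 2, theta 0 -> 1.3
  expect_equal(0.2 * 1 + 0.3 * 2 + 0.5 * angle_score(0), 1.3)
  expect_equal(0.2 * 0.5 + 0.3 * 1 + 0.5 * angle_score(10), 0.4)
})

test_that("ilium score is strictly larger on the untilted plane", {
  s0 <- with(clean_frame(tilt = 0), frame_score(image, true_boxes))$silium
  s8 <- with(clean_frame(tilt = 8), frame_score(image, true_boxes))$silium
  expect_gt(s0, s8)
})

test_that("frame score follows the weighted-sum equation and its zeroing rules", {
  f <- clean_frame()
  w <- graf_weights()
  fs <- frame_score(f$image, f$true_boxes, w)
  expect_true(fs$position_valid)
  expect_equal(fs$s,
               w$l1 * fs$s_lower_limb + w$l2 * fs$s_labrum +
                 w$l3 * fs$s_bony_rim + w$l4 * fs$silium,
               tolerance = 1e-9)
  expect_equal(fs$s_ilium$silium,
               w$l5 * fs$s_ilium$sconf + w$l6 * fs$s_ilium$shw +
                 w$l7 * fs$s_ilium$sangle,
               tolerance = 1e-9)

  # absent lower limb zeroes the heaviest term
  f2 <- render_frame(phantom_spec(visibility = c(lower_limb = 0),
                                  noise_sigma = 0))
  fs2 <- frame_score(f2$image, f2$true_boxes, w)
  expect_equal(fs2$s_lower_limb, 0)
  expect_equal(fs2$s, fs$s - w$l1 * fs$s_lower_limb, tolerance = 0.2)

  # layout violation zeroes the whole frame
  ds <- f$true_boxes
  i <- match("labrum", STRUCTURES)
  ds$x_min[i] <- ds$x_min[i] + 120; ds$x_max[i] <- ds$x_max[i] + 120
  fs3 <- frame_score(f$image, ds, w)
  expect_false(fs3$position_valid)
  expect_equal(fs3$s, 0)
})

test_that("frame score increases in each confidence, holding the rest fixed", {
  f <- clean_frame()
  base <- f$true_boxes
  s_of <- function(ds) frame_score(f$image, ds)$s
  for (s in c("lower_limb", "labrum", "bony_rim", "ilium")) {
    lo <- base; i <- match(s, STRUCTURES)
    lo$confidence[i] <- 0.5
    expect_lt(s_of(lo), s_of(base))
  }
})

test_that("standard-frame selection takes the earliest argmax and finds the true plane", {
  # earliest-tie rule on hand-made scores via a stub detector
  imgs <- rep(list(matrix(0, 128, 128)), 4)
  confs <- list(0.3, 0.85, 0.85, 0.5)
  det <- function(image, i)
    detection_set(list(detection("ilium", c(60, 20, 68, 100), confs[[i]])))
  sel <- select_standard_frame(imgs, det, method = "confidence_sum")
  expect_equal(sel$index, 2)

  vid <- render_video(phantom_spec(noise_sigma = 0), c(-10, -5, 0, 5, 10))
  sel2 <- select_standard_frame(vid, oracle_detector(vid))
  expect_equal(sel2$index, vid$best_frame_index)

  single <- clean_frame()
  sel3 <- select_standard_frame(list(single$image),
                                function(im, i) single$true_boxes)
  expect_equal(sel3$index, 1)

  blank <- rep(list(matrix(0, 128, 128)), 3)
  expect_error(select_standard_frame(blank, function(im, i) reference_detect(im)),
               "no usable plane")
})

test_that("selection recovers the best frame across seeded sweep videos", {
  hits <- 0; n <- 20
  for (seed in seq_len(n)) {
    vid <- sweep_video(seed)
    sel <- select_standard_frame(vid, oracle_detector(vid))
    hits <- hits + (sel$index == vid$best_frame_index)
  }
  expect_gte(hits / n, 0.95)
})
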