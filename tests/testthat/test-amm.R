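test_that("maximum-entropy threshold matches its analytic cases", {
  # uniform histogram: psi(t) = log(t+1) + log(255-t), maximal at 127
  expect_equal(max_entropy_threshold(rep(1, 256)), 127)
  # two equal spikes: every split between them ties at 0; smallest t wins
  h <- rep(0, 256); h[11] <- 7; h[241] <- 7
  expect_equal(max_entropy_threshold(h), 10)
  # single-level histogram is degenerate
  h1 <- rep(0, 256); h1[100] <- 50
  expect_error(max_entropy_threshold(h1), "single gray level")
})

test_that("maximum-entropy threshold equals exhaustive search on random histograms", {
  with_test_seed(202, {
    for (rep in 1:100) {
      counts <- stats::rpois(256, lambda = stats::runif(1, 0.2, 6))
      if (sum(counts > 0) < 2) counts[c(3, 200)] <- counts[c(3, 200)] + 1
      expect_equal(max_entropy_threshold(counts), naive_kapur(counts))
    }
  })
})

test_that("segmentation recovers the phantom ilium and keeps the largest blob", {
  f <- clean_frame()
  box <- expand_box(true_box_of(f, "ilium"), dim(f$image), 0.1)
  mask <- segment_structure(f$image, box)
  sub <- grafhip:::crop_box(f$image, box)
  truth <- sub > 128
  expect_gte(sum(mask & truth) / sum(truth), 0.8)
  expect_equal(sum(mask & !truth), 0)

  expect_error(segment_structure(matrix(77, 64, 64), c(0, 0, 32, 32)),
               "single gray level")

  # two bright blobs in one box: only the larger survives
  img <- matrix(10, 64, 64)
  img[10:30, 10:20] <- 200   # 21 x 11
  img[45:50, 40:44] <- 200   # 6 x 5
  m <- segment_structure(img, c(0, 0, 64, 64))
  expect_true(all(which(m, arr.ind = TRUE)[, 1] <= 30))
  expect_equal(sum(m), 21 * 11)
})

test_that("baseline is the superficial tangent of the ilium edge", {
  # perfectly straight strip: baseline is the vertical line through col 10
  mask <- matrix(FALSE, 60, 30); mask[1:51, 11:13] <- TRUE
  bl <- fit_baseline(mask)
  expect_equal(abs(bl$direction), c(0, 1))
  expect_equal(bl$point[1], 10)

  expect_error(fit_baseline(matrix(FALSE, 10, 10)), "5 rows")
  thin <- matrix(FALSE, 10, 10); thin[3:5, 4] <- TRUE
  expect_error(fit_baseline(thin), "5 rows")

  # tilted phantom band: direction within 1 degree of the rendered band
  f <- clean_frame(tilt = 4)
  box <- expand_box(true_box_of(f, "ilium"), dim(f$image), 0.1)
  mask4 <- segment_structure(f$image, box)
  bl4 <- fit_baseline(mask4, box)
  ang <- angle_between(bl4, f$true_baseline)
  expect_lt(ang, 1)

  # tangent condition: all edge points on or deep to the line, one touching
  rows <- which(rowSums(mask4) > 0)
  edge <- t(vapply(rows, function(r) c(which(mask4[r, ])[1] - 1 + box[1],
                                       r - 1 + box[2]), numeric(2)))
  n <- c(bl4$direction[2], -bl4$direction[1]); if (n[1] < 0) n <- -n
  off <- as.matrix(sweep(edge, 2, bl4$point)) %*% n
  expect_gte(min(off), -1e-9)
  expect_lt(min(off), 0.5)
})

test_that("tangent point satisfies the one-sided property (brute-force check)", {
  # axis-aligned example: pivot at origin, three stacked points
  contour <- rbind(c(5, 1), c(5, 2), c(5, 3))
  expect_equal(tangent_point_from(c(0, 0), contour), c(5, 1))
  expect_true(tangent_one_sided(c(0, 0), contour, c(5, 1)))
  # single-point contour returns that point
  expect_equal(tangent_point_from(c(0, 0), rbind(c(3, 4))), c(3, 4))
  # collinear tie goes to the farthest point
  col3 <- rbind(c(2, 2), c(4, 4), c(6, 6))
  expect_equal(tangent_point_from(c(0, 0), col3), c(6, 6))

  with_test_seed(303, {
    for (rep in 1:50) {
      n <- sample(5:40, 1)
      ang <- sort(stats::runif(n, 0, 2 * pi))
      rad <- stats::runif(n, 2, 6)           # non-convex star-shaped contour
      ctr <- c(stats::runif(1, 15, 25), stats::runif(1, 15, 25))
      contour <- cbind(ctr[1] + rad * cos(ang), ctr[2] + rad * sin(ang))
      pivot <- ctr + c(30, stats::runif(1, -5, 5))  # well outside the hull
      p <- tangent_point_from(pivot, contour)
      expect_true(tangent_one_sided(pivot, contour, p))
    }
  })
})

test_that("landmarks land within 3 px of the analytic ground truth", {
  for (alpha in c(50, 65)) {
    f <- clean_frame(alpha = alpha)
    lm <- locate_landmarks(f$image, f$true_boxes)
    for (nm in names(f$true_landmarks)) {
      d <- sqrt(sum((lm[[nm]] - f$true_landmarks[[nm]])^2))
      expect_lt(d, 3)
    }
  }
})

test_that("missing structures abort landmark localization by name", {
  f <- render_frame(phantom_spec(visibility = c(lower_limb = 0),
                                 noise_sigma = 0))
  expect_error(locate_landmarks(f$image, f$true_boxes), "lower_limb")
  f2 <- render_frame(phantom_spec(visibility = c(labrum = 0),
                                  noise_sigma = 0))
  expect_error(locate_landmarks(f2$image, f2$true_boxes), "labrum")
})

test_that("labrum center is the centroid of a symmetric blob", {
  img <- matrix(10, 128, 128)
  yy <- matrix(rep(0:127, times = 128), 128); xx <- t(yy)
  img[(xx - 40)^2 + (yy - 60)^2 <= 49] <- 220
  box <- c(30, 50, 50, 70)
  m <- segment_structure(img, box)
  ctr <- colMeans(grafhip:::mask_pixels(m)) + box[1:2]
  expect_equal(unname(ctr), c(40, 60), tolerance = 0.05)
})

test_that("line-line angles are acute and match constructions", {
  v <- graf_line(c(0, 0), c(0, 1))
  expect_equal(angle_between(v, v), 0)
  hline <- graf_line(c(0, 0), c(1, 0))
  expect_equal(angle_between(v, hline), 90)
  l60 <- graf_line(c(5, 5), c(sin(pi / 3), cos(pi / 3)))
  expect_equal(angle_between(v, l60), 60, tolerance = 1e-9)
})

test_that("alpha/beta recovery and determinism on phantom frames", {
  f <- clean_frame(alpha = 65, beta = 55)
  r1 <- measure(f$image, f$true_boxes)
  expect_lt(abs(r1$alpha - 65), 2)
  expect_lt(abs(r1$beta - 55), 2)
  expect_equal(r1$graf_type, "I")
  expect_true(all(c(r1$alpha, r1$beta) >= 0 & c(r1$alpha, r1$beta) <= 90))

  r2 <- measure(f$image, f$true_boxes)
  expect_identical(r1[c("alpha", "beta", "graf_type")],
                   r2[c("alpha", "beta", "graf_type")])

  dysplastic <- clean_frame(alpha = 55)
  expect_equal(measure(dysplastic$image, dysplastic$true_boxes)$graf_type, "II")

  # the cartilage roof line passes through both of its defining landmarks
  lm <- r1$landmarks; cl <- r1$lines$cartilage_roof_line
  for (p in list(lm$bony_rim_point, lm$labrum_center)) {
    v <- p - cl$point
    dist <- abs(v[1] * cl$direction[2] - v[2] * cl$direction[1])
    expect_lt(dist, 0.5)
  }
})

test_that("Graf type flips exactly at the configured boundary", {
  expect_equal(classify_graf(61), "I")
  expect_equal(classify_graf(60), "I")     # boundary inclusive to type I
  expect_equal(classify_graf(59), "II")
  sweep <- vapply(seq(55, 65, by = 0.5), classify_graf, character(1))
  flips <- which(sweep[-1] != sweep[-length(sweep)])
  expect_equal(length(flips), 1)
  expect_equal(seq(55, 65, by = 0.5)[flips + 1], 60)
  expect_equal(classify_graf(58, boundary = 58), "I")
})
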