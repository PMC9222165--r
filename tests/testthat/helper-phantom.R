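# Shared fixtures: all synthetic, built in code at test time.

# A clean, noise-free default phantom frame.
clean_frame <- function(alpha = 60, beta = 55, tilt = 0, ...) {
  render_frame(phantom_spec(alpha_true = alpha, beta_true = beta,
                            ilium_tilt = tilt, noise_sigma = 0, ...))
}

true_box_of <- function(frame, structure) {
  i <- match(structure, STRUCTURES)
  tb <- frame$true_boxes
  c(tb$x_min[i], tb$y_min[i], tb$x_max[i], tb$y_max[i])
}

# Independent brute-force oracle for raw image moments: explicit double
# loop over columns i and rows j, never vectorized.
naive_moment <- function(V, p, q) {
  acc <- 0
  for (i in 0:(ncol(V) - 1))
    for (j in 0:(nrow(V) - 1))
      acc <- acc + i^p * j^q * V[j + 1, i + 1]
  acc
}

# Independent brute-force maximum-entropy threshold: recompute both class
# entropies from scratch for every candidate.
naive_kapur <- function(counts) {
  total <- sum(counts)
  best_t <- NA_integer_; best_psi <- -Inf
  for (t in 0:254) {
    lo <- counts[1:(t + 1)]; hi <- counts[(t + 2):256]
    w0 <- sum(lo) / total; w1 <- sum(hi) / total
    if (w0 <= 0 || w1 <= 0) next
    p0 <- lo[lo > 0] / sum(lo); p1 <- hi[hi > 0] / sum(hi)
    psi <- -sum(p0 * log(p0)) - sum(p1 * log(p1))
    if (psi > best_psi + 1e-12) { best_psi <- psi; best_t <- t }
  }
  best_t
}

# O(n^2) verification of the one-sided (tangent) property: every contour
# point must lie on the non-negative cross-product side of pivot -> p.
tangent_one_sided <- function(pivot, contour, p, eps = 1e-9) {
  v <- c(p[1] - pivot[1], p[2] - pivot[2])
  for (k in seq_len(nrow(contour))) {
    w <- c(contour[k, 1] - pivot[1], contour[k, 2] - pivot[2])
    if (v[1] * w[2] - v[2] * w[1] < -eps) return(FALSE)
  }
  TRUE
}

# A randomized sweep video in the study conditions: 9 frames across
# [-10, 10] degrees with a random sub-degree offset of the sweep center.
sweep_video <- function(seed, alpha = 60, beta = 55, noise_sigma = 0,
                        dropout = NULL) {
  offset <- with_test_seed(seed, stats::runif(1, -0.8, 0.8))
  traj <- seq(-10, 10, length.out = 9) + offset
  render_video(phantom_spec(alpha_true = alpha, beta_true = beta,
                            noise_sigma = noise_sigma, seed = seed),
               traj, dropout_schedule = dropout)
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}
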