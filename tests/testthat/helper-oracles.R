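# Independent oracles used to check the package's own geometry and
# statistics implementations. These deliberately use brute force /
# exhaustive enumeration, not the code paths they verify.

# Feret diameters by direct search: Fmax over all vertex pairs, Fmin as the
# minimum projection width over a fine grid of directions (0.1 deg steps).
feret_bruteforce <- function(pts) {
  d2 <- as.matrix(stats::dist(pts))
  fmax <- max(d2)
  angs <- seq(0, pi, by = 0.1 * pi / 180)
  fmin <- Inf
  for (a in angs) {
    proj <- pts[, 1] * cos(a) + pts[, 2] * sin(a)
    fmin <- min(fmin, max(proj) - min(proj))
  }
  c(fmax = fmax, fmin = fmin)
}

# Convex hull by gift wrapping (Jarvis march), counter-clockwise.
gift_wrap_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- if (length(hull) == 1) seq_len(n)[-p] else seq_len(n)
    best <- cand[1]
    for (q in cand) {
      if (q == p) next
      cr <- (pts[best, 1] - pts[p, 1]) * (pts[q, 2] - pts[p, 2]) -
            (pts[best, 2] - pts[p, 2]) * (pts[q, 1] - pts[p, 1])
      d_best <- sum((pts[best, ] - pts[p, ])^2)
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      if (best == p || cr < 0 || (abs(cr) < 1e-12 && d_q > d_best)) best <- q
    }
    if (best == start) break
    hull <- c(hull, best)
    if (length(hull) > n) stop("gift wrapping failed to close")
  }
  pts[hull, , drop = FALSE]
}

shoelace <- function(p) {
  n <- nrow(p)
  j <- c(n, seq_len(n - 1))
  abs(sum(p[j, 1] * p[, 2] - p[, 1] * p[j, 2])) / 2
}

# Exact two-sided Mann-Whitney p-value by enumerating all C(na+nb, na)
# assignments of the pooled values to group A.
mw_enumeration_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(a, b)
  mu <- na * length(b) / 2
  combos <- utils::combn(length(pooled), na)
  extreme <- 0
  for (k in seq_len(ncol(combos))) {
    xa <- pooled[combos[, k]]
    xb <- pooled[-combos[, k]]
    if (abs(u_stat(xa, xb) - mu) >= abs(u_obs - mu) - 1e-9) {
      extreme <- extreme + 1
    }
  }
  extreme / ncol(combos)
}

# Random convex polygon: convex hull of points on a noisy ellipse.
random_convex_polygon <- function(n = 12, rmin = 5, rmax = 40) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmin, rmax)
  pts <- cbind(r * cos(ang), r * sin(ang))
  idx <- grDevices::chull(pts)
  pts[idx, , drop = FALSE]
}

# Random star-shaped binary mask: radial function with a few harmonics.
random_star_mask <- function(size = 101) {
  c0 <- (size - 1) / 2
  k <- sample(2:5, 1)
  amp <- stats::runif(k, 0, 0.25)
  ph <- stats::runif(k, 0, 2 * pi)
  base <- stats::runif(1, size / 6, size / 3.2)
  xs <- matrix(rep(0:(size - 1), each = size), size, size) - c0
  ys <- matrix(rep(0:(size - 1), times = size), size, size) - c0
  th <- atan2(ys, xs)
  rad <- base * (1 + Reduce(`+`, lapply(seq_len(k), function(i)
    amp[i] * cos(i * th + ph[i]))))
  xs^2 + ys^2 <= rad^2
}

# Match measured cells to ground-truth rows by nearest centre; returns the
# truth row index for each measured record.
match_truth <- function(tab, truth) {
  vapply(seq_len(nrow(tab)), function(i) {
    which.min((truth$center_x_um - tab$centroid_x_um[i])^2 +
                (truth$center_y_um - tab$centroid_y_um[i])^2)
  }, integer(1))
}

# Noise-free, blur-free synthetic field plus the segmentation parameters
# used for ground-truth recovery checks.
noise_free_field <- function(seed = 1, ...) {
  generate_field(synthetic_field_spec(noise_sd = 0, psf_sigma_px = 0,
                                      seed = seed, ...))
}

recovery_params <- function() {
  segmentation_params(smoothing_sigma_px = 0)
}
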