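# Low-level planar geometry used by the morphometry operators.
# Conventions: points are n x 2 matrices of (x, y); pixel centres are
# 0-based; pixel [r, c] covers the square [c-1.5, c-0.5] x [r-1.5, r-0.5]
# shifted by +1, i.e. centre (c-1, r-1) with corners at +/- 0.5.

# Convex hull of a point set, counter-clockwise, as an m x 2 matrix.
convex_hull <- function(pts) {
  pts <- unique(round(pts, 9))
  if (nrow(pts) < 3) return(pts)
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  h <- pts[idx, , drop = FALSE]
  if (polygon_signed_area(h) < 0) h <- h[nrow(h):1, , drop = FALSE]
  h
}

# Signed area (shoelace); positive for counter-clockwise vertex order.
polygon_signed_area <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

polygon_area <- function(p) abs(polygon_signed_area(p))

# Maximum Feret diameter: the largest distance between two parallel tangent
# lines, attained by a pair of hull vertices (antipodal pair). The hull is
# small, so the exact all-pairs search over hull vertices is used.
hull_feret_max <- function(hull) {
  n <- nrow(hull)
  if (n == 1) return(0)
  d2 <- 0
  for (i in seq_len(n - 1)) {
    dx <- hull[(i + 1):n, 1] - hull[i, 1]
    dy <- hull[(i + 1):n, 2] - hull[i, 2]
    d2 <- max(d2, max(dx * dx + dy * dy))
  }
  sqrt(d2)
}

# Minimum Feret diameter (minimum width): for a convex polygon the minimum
# distance between parallel tangents is attained with one tangent flush with
# a hull edge, so the exact minimum is the smallest over edges of the
# farthest vertex distance from the edge line.
hull_feret_min <- function(hull) {
  n <- nrow(hull)
  if (n < 3) return(0)
  w <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- hull[j, 1] - hull[i, 1]
    ey <- hull[j, 2] - hull[i, 2]
    len <- sqrt(ex * ex + ey * ey)
    if (len < .Machine$double.eps) next
    # distance of all vertices from the line through edge (i, j)
    d <- abs((hull[, 1] - hull[i, 1]) * ey -
               (hull[, 2] - hull[i, 2]) * ex) / len
    w <- min(w, max(d))
  }
  w
}

# Linear indices -> (x, y) pixel-centre coordinates (0-based).
idx_to_xy <- function(idx, nrow_img) {
  r <- ((idx - 1L) %% nrow_img) + 1L
  c <- ((idx - 1L) %/% nrow_img) + 1L
  cbind(x = c - 1, y = r - 1)
}

# Boundary pixels of a mask given as linear indices: pixels with at least
# one 4-neighbour outside the mask (or on the image border).
boundary_idx <- function(idx, dim_img) {
  nr <- dim_img[1]; nc <- dim_img[2]
  m <- matrix(FALSE, nr, nc)
  m[idx] <- TRUE
  inner <- matrix(FALSE, nr, nc)
  inner[2:(nr - 1), 2:(nc - 1)] <-
    m[1:(nr - 2), 2:(nc - 1)] & m[3:nr, 2:(nc - 1)] &
    m[2:(nr - 1), 1:(nc - 2)] & m[2:(nr - 1), 3:nc]
  which(m & !inner)
}

# Pixel-corner point set of a mask (used for convex hulls): the four
# corners of every boundary pixel. Corner coordinates are pixel centres
# +/- 0.5 in each axis.
mask_corner_points <- function(idx, dim_img) {
  b <- boundary_idx(idx, dim_img)
  xy <- idx_to_xy(b, dim_img[1])
  rbind(cbind(xy[, 1] - 0.5, xy[, 2] - 0.5),
        cbind(xy[, 1] + 0.5, xy[, 2] - 0.5),
        cbind(xy[, 1] - 0.5, xy[, 2] + 0.5),
        cbind(xy[, 1] + 0.5, xy[, 2] + 0.5))
}

# Convex hull of a mask's pixel corners.
mask_hull <- function(idx, dim_img) {
  convex_hull(mask_corner_points(idx, dim_img))
}

# Convex hull of the centres of a mask's boundary pixels (the traced
# contour's vertices). Feret diameters are taken on this hull: the pixel
# centres of the boundary are an unbiased sample of the underlying contour,
# whereas pixel corners would inflate both diameters by ~1 px.
mask_center_hull <- function(idx, dim_img) {
  convex_hull(idx_to_xy(boundary_idx(idx, dim_img), dim_img[1]))
}
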