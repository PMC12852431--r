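# Synthetic Iba-1-like fluorescence fields with exhaustive ground truth.
# Every downstream stage (segmentation, morphometry, counting, statistics)
# is testable against planted cells without any image downloads.

#' Specification of a synthetic field
#'
#' Defaults describe a realistic Iba-1 field at the study's calibration:
#' about a dozen microglia per 0.1502 mm^2 field, soma semi-axes 3.0--5.5 um
#' (soma areas ~28--95 um^2), 3--6 primary processes of 15--40 um, dim
#' background with additive Gaussian noise and a ~1 px PSF blur.
#'
#' @param n_cells Number of planted cells (>= 0).
#' @param soma_axis_range Min/max soma semi-axis lengths (um).
#' @param branch_count_range Min/max primary branches per cell (integers).
#' @param branch_length_range Min/max total branch path length (um).
#' @param branch_width_px Odd positive branch thickness (px).
#' @param soma_peak_intensity,process_peak_intensity,background_level
#'   Rendering intensities on the 0--255 scale; must be strictly decreasing
#'   in this order.
#' @param noise_sd Additive Gaussian noise sd (intensity units, >= 0).
#' @param psf_sigma_px Gaussian blur sigma emulating the PSF (px, >= 0).
#' @param gain,offset Affine acquisition perturbation applied last
#'   (`gain > 0`).
#' @param width_px,height_px,microns_per_pixel Field geometry; defaults give
#'   the study's 0.1502 mm^2 field.
#' @param center_min_dist_um Minimum distance between soma centres (um).
#'   Microglia tile the tissue into largely non-overlapping territories; the
#'   default 55 um spacing keeps planted cells territorial, and each cell's
#'   branches are confined to a territory radius of half its
#'   nearest-neighbour distance.
#' @param allow_border Allow cells whose soma may touch the field border
#'   (default `FALSE`: whole cells, branches included, are kept inside).
#' @param centers_um Optional n x 2 matrix of forced soma centres (um);
#'   overrides random placement (and disables the spacing constraint).
#' @param seed Integer seed; fully determines placement, trees and noise.
#' @return An object of class `synthetic_field_spec`.
#' @export
synthetic_field_spec <- function(n_cells = 12L,
                                 soma_axis_range = c(3.0, 5.5),
                                 branch_count_range = c(3L, 6L),
                                 branch_length_range = c(15, 40),
                                 branch_width_px = 3L,
                                 soma_peak_intensity = 200,
                                 process_peak_intensity = 120,
                                 background_level = 20,
                                 noise_sd = 8,
                                 psf_sigma_px = 1,
                                 gain = 1, offset = 0,
                                 width_px = 1024L, height_px = 1024L,
                                 microns_per_pixel =
                                   default_field_geometry()$calibration$microns_per_pixel,
                                 center_min_dist_um = 55,
                                 allow_border = FALSE,
                                 centers_um = NULL,
                                 seed = 1L) {
  stopifnot(n_cells >= 0, diff(soma_axis_range) >= 0,
            diff(branch_count_range) >= 0, diff(branch_length_range) >= 0)
  if (branch_width_px < 1 || branch_width_px %% 2 == 0) {
    stop("branch_width_px must be an odd positive integer")
  }
  if (!(soma_peak_intensity > process_peak_intensity &&
        process_peak_intensity > background_level)) {
    stop("intensities must satisfy soma > process > background")
  }
  if (noise_sd < 0 || psf_sigma_px < 0) stop("noise/psf must be >= 0")
  if (gain <= 0) stop("gain must be positive")
  structure(list(n_cells = as.integer(n_cells),
                 soma_axis_range = soma_axis_range,
                 branch_count_range = as.integer(branch_count_range),
                 branch_length_range = branch_length_range,
                 branch_width_px = as.integer(branch_width_px),
                 soma_peak_intensity = soma_peak_intensity,
                 process_peak_intensity = process_peak_intensity,
                 background_level = background_level,
                 noise_sd = noise_sd, psf_sigma_px = psf_sigma_px,
                 gain = gain, offset = offset,
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 microns_per_pixel = microns_per_pixel,
                 center_min_dist_um = center_min_dist_um,
                 allow_border = allow_border, centers_um = centers_um,
                 seed = as.integer(seed)),
            class = "synthetic_field_spec")
}

# Pixels of a filled rotated ellipse, as linear indices into an nr x nc
# matrix. Centre and axes in pixel units, 0-based centre coordinates.
.ellipse_idx <- function(cx, cy, a, b, theta, nr, nc) {
  ext <- max(a, b)
  cs <- max(1L, floor(cx - ext)):min(nc, ceiling(cx + ext) + 1L)
  rs <- max(1L, floor(cy - ext)):min(nr, ceiling(cy + ext) + 1L)
  if (length(cs) == 0 || length(rs) == 0) return(integer(0))
  x <- rep(cs - 1, each = length(rs)) - cx
  y <- rep(rs - 1, times = length(cs)) - cy
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  rr <- rep(rs, times = length(cs))[inside]
  cc <- rep(cs, each = length(rs))[inside]
  (cc - 1L) * nr + rr
}

# Pull a branch vertex radially back inside the territory circle, outside
# the (slightly dilated) soma ellipse -- processes extend away from the
# soma, they do not wrap around it -- and clip it to the raster.
.confine <- function(q, center, radius_px, nr, nc, a = NULL, b = NULL,
                     theta = 0, soma_margin_px = 0) {
  d <- sqrt(sum((q - center)^2))
  if (d > radius_px && d > 0) q <- center + (q - center) * radius_px / d
  if (!is.null(a)) {
    ad <- a + soma_margin_px; bd <- b + soma_margin_px
    u <- (q[1] - center[1]) * cos(theta) + (q[2] - center[2]) * sin(theta)
    v <- -(q[1] - center[1]) * sin(theta) + (q[2] - center[2]) * cos(theta)
    f <- (u / ad)^2 + (v / bd)^2
    if (f < 1 && f > 0) q <- center + (q - center) / sqrt(f)
  }
  q[1] <- min(max(q[1], 1), nc - 2)
  q[2] <- min(max(q[2], 1), nr - 2)
  q
}

# Pixels within half-width of a segment (flat caps), as linear indices.
.segment_idx <- function(x0, y0, x1, y1, half_w, nr, nc) {
  cs <- max(1L, floor(min(x0, x1) - half_w)):
    min(nc, ceiling(max(x0, x1) + half_w) + 1L)
  rs <- max(1L, floor(min(y0, y1) - half_w)):
    min(nr, ceiling(max(y0, y1) + half_w) + 1L)
  x <- rep(cs - 1, each = length(rs))
  y <- rep(rs - 1, times = length(cs))
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  if (len2 == 0) {
    d2 <- (x - x0)^2 + (y - y0)^2
    inside <- d2 <= half_w^2
  } else {
    t <- ((x - x0) * dx + (y - y0) * dy) / len2
    inside <- t >= 0 & t <= 1 &
      ((x - (x0 + t * dx))^2 + (y - (y0 + t * dy))^2) <= half_w^2
  }
  rr <- rep(rs, times = length(cs))[inside]
  cc <- rep(cs, each = length(rs))[inside]
  (cc - 1L) * nr + rr
}

#' Generate a synthetic Iba-1-like field with ground truth
#'
#' Rendering order: paint the background level, composite somas as filled
#' ellipses at the soma peak intensity, composite branches (random trees of
#' line segments) at the process peak intensity, Gaussian-blur
#' (`psf_sigma_px`), add Gaussian noise (`noise_sd`), apply gain/offset, and
#' clip to `[0, 255]`. Somas and branches are composited by per-pixel
#' maximum, so soma interiors remain exactly at the soma peak before
#' blur/noise. Ground truth (continuous geometry, branch polylines, hull
#' area, mean soma intensity) is recorded before blur, noise and
#' gain/offset.
#'
#' @param spec A [synthetic_field_spec()].
#' @param metadata A [field_metadata()] attached to the rendered field.
#' @return A list of class `synthetic_field`: `field` (a [field_image()]),
#'   `truth` (data frame, one row per planted cell: centre, semi-axes,
#'   orientation, `soma_area_um2 = pi*a*b`, `feret_max_um = 2a`,
#'   `feret_min_um = 2b`, `fdr = a/b`, branch count and total length,
#'   `hull_area_um2`, `mean_soma_intensity`), `branches` (list of vertex
#'   matrices per cell), `soma_masks` (list of linear-index vectors) and
#'   `clip_fraction`.
#' @export
generate_field <- function(spec = synthetic_field_spec(),
                           metadata = field_metadata()) {
  stopifnot(inherits(spec, "synthetic_field_spec"))
  set.seed(spec$seed)
  nr <- spec$height_px; nc <- spec$width_px
  mpp <- spec$microns_per_pixel
  cal <- pixel_calibration(mpp)
  img <- matrix(spec$background_level, nr, nc)

  max_a_px <- spec$soma_axis_range[2] / mpp
  max_branch_px <- spec$branch_length_range[2] / mpp
  margin_px <- if (spec$allow_border) 0 else max_a_px + max_branch_px + 3

  # --- placement -----------------------------------------------------------
  n <- spec$n_cells
  centers <- matrix(numeric(0), 0, 2)
  axes <- matrix(numeric(0), 0, 2)
  thetas <- numeric(0)
  if (n > 0) {
    if (!is.null(spec$centers_um)) {
      if (nrow(spec$centers_um) != n) {
        stop("centers_um must have one row per cell")
      }
      centers <- spec$centers_um / mpp
      for (i in seq_len(n)) {
        ax <- sort(stats::runif(2, spec$soma_axis_range[1],
                                spec$soma_axis_range[2]),
                   decreasing = TRUE) / mpp
        axes <- rbind(axes, ax)
        thetas <- c(thetas, stats::runif(1, 0, pi))
      }
    } else {
      lo_x <- margin_px; hi_x <- nc - 1 - margin_px
      lo_y <- margin_px; hi_y <- nr - 1 - margin_px
      if (hi_x <= lo_x || hi_y <= lo_y) {
        stop("capacity error: raster too small for any cell (0 placeable)")
      }
      tries <- 0L
      while (nrow(centers) < n && tries < 300L * n) {
        tries <- tries + 1L
        cand <- c(stats::runif(1, lo_x, hi_x), stats::runif(1, lo_y, hi_y))
        ax <- sort(stats::runif(2, spec$soma_axis_range[1],
                                spec$soma_axis_range[2]),
                   decreasing = TRUE) / mpp
        if (nrow(centers) > 0) {
          d <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
          # territorial spacing (also guarantees soma non-overlap)
          if (any(d < max(spec$center_min_dist_um / mpp,
                          axes[, 1] + ax[1] + 4))) next
        }
        centers <- rbind(centers, cand)
        axes <- rbind(axes, ax)
        thetas <- c(thetas, stats::runif(1, 0, pi))
      }
      if (nrow(centers) < n) {
        stop(sprintf("capacity error: placed only %d of %d cells",
                     nrow(centers), n))
      }
    }
  }

  # --- somas ---------------------------------------------------------------
  soma_masks <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- .ellipse_idx(centers[i, 1], centers[i, 2], axes[i, 1],
                        axes[i, 2], thetas[i], nr, nc)
    soma_masks[[i]] <- idx
    img[idx] <- pmax(img[idx], spec$soma_peak_intensity)
  }

  # territory radius: half the nearest-neighbour centre distance (branches
  # of tiling microglia respect their neighbours), capped by the branch
  # length budget; single cells are unconstrained
  terr_px <- rep(max_a_px + max_branch_px + 2, n)
  if (n > 1) {
    dmat <- as.matrix(stats::dist(centers))
    diag(dmat) <- Inf
    terr_px <- pmin(apply(dmat, 1, min) / 2 - 1, terr_px)
  }

  # --- branches ------------------------------------------------------------
  half_w <- (spec$branch_width_px - 1) / 2 + 1e-9
  branches <- vector("list", n)
  total_len_um <- numeric(n)
  n_branches <- integer(n)
  for (i in seq_len(n)) {
    k <- sample(spec$branch_count_range[1]:spec$branch_count_range[2], 1)
    n_branches[i] <- k
    # primary processes radiate at roughly regular angular spacing (ramified
    # microglia spread their primaries around the soma)
    base_angles <- stats::runif(1, 0, 2 * pi) + 2 * pi * (0:(k - 1)) / k +
      stats::runif(k, -0.15, 0.15)
    verts <- list()
    for (bidx in seq_len(k)) {
      phi <- base_angles[bidx]
      # start on the soma ellipse boundary in direction phi
      ct <- cos(thetas[i]); st <- sin(thetas[i])
      du <- cos(phi - thetas[i]); dv <- sin(phi - thetas[i])
      rad <- 1 / sqrt((du / axes[i, 1])^2 + (dv / axes[i, 2])^2)
      p <- centers[i, ] + rad * c(cos(phi), sin(phi))
      len_px <- stats::runif(1, spec$branch_length_range[1],
                             spec$branch_length_range[2]) / mpp
      nseg <- sample(3:6, 1)
      seg <- len_px / nseg
      poly <- matrix(p, 1, 2)
      ang <- phi
      for (s in seq_len(nseg)) {
        ang <- ang + stats::rnorm(1, 0, 15 * pi / 180)
        q <- poly[nrow(poly), ] + seg * c(cos(ang), sin(ang))
        q <- .confine(q, centers[i, ], terr_px[i], nr, nc,
                      axes[i, 1], axes[i, 2], thetas[i], half_w + 1)
        poly <- rbind(poly, q)
      }
      verts[[length(verts) + 1]] <- poly
      # one optional bifurcation per branch
      if (stats::runif(1) < 0.3 && nseg >= 3) {
        j0 <- sample(2:(nseg - 1), 1)
        ang2 <- ang + sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.2)
        sub <- matrix(poly[j0, ], 1, 2)
        nsub <- sample(2:3, 1)
        for (s in seq_len(nsub)) {
          ang2 <- ang2 + stats::rnorm(1, 0, 15 * pi / 180)
          q <- sub[nrow(sub), ] + seg * c(cos(ang2), sin(ang2))
          q <- .confine(q, centers[i, ], terr_px[i], nr, nc,
                        axes[i, 1], axes[i, 2], thetas[i], half_w + 1)
          sub <- rbind(sub, q)
        }
        verts[[length(verts) + 1]] <- sub
      }
    }
    branches[[i]] <- verts
    seg_len <- 0
    for (poly in verts) {
      d <- diff(poly)
      seg_len <- seg_len + sum(sqrt(rowSums(d^2)))
      for (s in seq_len(nrow(poly) - 1)) {
        idx <- .segment_idx(poly[s, 1], poly[s, 2], poly[s + 1, 1],
                            poly[s + 1, 2], half_w, nr, nc)
        img[idx] <- pmax(img[idx], spec$process_peak_intensity)
      }
    }
    total_len_um[i] <- seg_len * mpp
  }

  # --- ground truth (pre blur/noise/gain) ----------------------------------
  truth <- data.frame(
    label = seq_len(n),
    center_x_um = if (n) centers[, 1] * mpp else numeric(0),
    center_y_um = if (n) centers[, 2] * mpp else numeric(0),
    a_um = if (n) axes[, 1] * mpp else numeric(0),
    b_um = if (n) axes[, 2] * mpp else numeric(0),
    theta = thetas,
    soma_area_um2 = if (n) pi * axes[, 1] * axes[, 2] * mpp^2 else numeric(0),
    feret_max_um = if (n) 2 * axes[, 1] * mpp else numeric(0),
    feret_min_um = if (n) 2 * axes[, 2] * mpp else numeric(0),
    fdr = if (n) axes[, 1] / axes[, 2] else numeric(0),
    n_branches = n_branches,
    branch_total_length_um = total_len_um,
    hull_area_um2 = numeric(n),
    mean_soma_intensity = rep(spec$soma_peak_intensity, n))
  for (i in seq_len(n)) {
    phi <- seq(0, 2 * pi, length.out = 181)[-181]
    ct <- cos(thetas[i]); st <- sin(thetas[i])
    ex <- centers[i, 1] + axes[i, 1] * cos(phi) * ct -
      axes[i, 2] * sin(phi) * st
    ey <- centers[i, 2] + axes[i, 1] * cos(phi) * st +
      axes[i, 2] * sin(phi) * ct
    pts <- cbind(ex, ey)
    for (poly in branches[[i]]) pts <- rbind(pts, poly)
    truth$hull_area_um2[i] <- polygon_area(convex_hull(pts)) * mpp^2
  }

  # --- optics, noise, acquisition ------------------------------------------
  if (spec$psf_sigma_px > 0) {
    img <- EBImage::gblur(img, sigma = spec$psf_sigma_px)
  }
  if (spec$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
  }
  img <- spec$gain * img + spec$offset
  clip_fraction <- mean(img < 0 | img > 255)
  img <- pmin(pmax(img, 0), 255)

  field <- field_image(img, cal, metadata)
  structure(list(field = field, truth = truth, branches = branches,
                 soma_masks = soma_masks, clip_fraction = clip_fraction,
                 spec = spec),
            class = "synthetic_field")
}

#' Apply an affine gain/offset acquisition perturbation
#'
#' `value' = gain * value + offset`, clipped to `[0, 255]`. The fraction of
#' pixels altered by clipping is reported alongside the image so invariance
#' tests can require a clip-free perturbation.
#'
#' @param field A [field_image()].
#' @param gain Multiplicative gain (> 0).
#' @param offset Additive offset (intensity units).
#' @return List with `field` (perturbed [field_image()]) and
#'   `clip_fraction`.
#' @export
apply_gain_offset <- function(field, gain, offset = 0) {
  stopifnot(inherits(field, "field_image"))
  if (gain <= 0) stop("gain must be positive")
  v <- gain * field$pixels + offset
  clip_fraction <- mean(v < 0 | v > 255)
  v <- pmin(pmax(v, 0), 255)
  list(field = field_image(v, field$calibration, field$metadata),
       clip_fraction = clip_fraction)
}
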