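# Per-cell morphometry: the five measurements taken for every microglial
# cell -- soma area, skeleton extent of the processes, arborization
# (convex-hull) territory, Feret's Diameter Ratio of the soma, and soma
# fluorescence intensity with cross-image normalization.

#' Feret diameters of a closed contour
#'
#' The maximum and minimum Feret diameters are the longest and shortest
#' distances between two parallel tangent lines to the contour. Both are
#' support-function quantities, so they are computed exactly on the convex
#' hull of the contour: the maximum as the largest antipodal vertex distance
#' (the rotating-calipers diameter) and the minimum as the smallest width
#' over directions normal to hull edges.
#'
#' @param contour An n x 2 matrix of (x, y) vertices (closed polygon, in
#'   pixel coordinates), with at least 3 non-collinear vertices.
#' @param microns_per_pixel Scale factor applied to both diameters
#'   (default 1, i.e. results in pixels).
#' @return Named numeric vector `c(feret_max, feret_min)`.
#' @export
feret_diameters <- function(contour, microns_per_pixel = 1) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3) stop("degenerate contour: need at least 3 vertices")
  hull <- convex_hull(contour)
  if (nrow(hull) < 3) stop("degenerate contour: vertices are collinear")
  c(feret_max = hull_feret_max(hull) * microns_per_pixel,
    feret_min = hull_feret_min(hull) * microns_per_pixel)
}

#' Feret's Diameter Ratio
#'
#' FDR = Fmax / Fmin, a soma-shape descriptor that is 1 for a perfect circle
#' and grows with elongation. FDR >= 1 by definition when the diameters come
#' from [feret_diameters()].
#'
#' @param feret_max,feret_min Maximum and minimum Feret diameters (same
#'   units); `feret_min` must be > 0.
#' @return The dimensionless ratio.
#' @export
feret_ratio <- function(feret_max, feret_min) {
  if (any(feret_min <= 0)) stop("feret_min must be positive")
  feret_max / feret_min
}

#' Classify soma morphology from the FDR
#'
#' Ramified microglia typically have FDR < 3; activated, amoeboid or
#' rod-shaped somas have FDR >= 3 (inclusive boundary).
#'
#' @param fdr Feret's Diameter Ratio, >= 1.
#' @return `"ramified"` or `"rod_amoeboid"` (vectorised).
#' @export
classify_morphology <- function(fdr) {
  if (any(fdr < 1)) stop("fdr must be >= 1")
  ifelse(fdr >= 3, "rod_amoeboid", "ramified")
}

# One pass of Zhang-Suen thinning (sub-iteration 1 or 2), vectorised over
# the whole (padded) matrix. m is a logical matrix with a 1-px FALSE border.
.zs_pass <- function(m, step) {
  nr <- nrow(m); nc <- ncol(m)
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  p  <- m[i, j]
  p2 <- m[i - 1, j];     p3 <- m[i - 1, j + 1]; p4 <- m[i, j + 1]
  p5 <- m[i + 1, j + 1]; p6 <- m[i + 1, j];     p7 <- m[i + 1, j - 1]
  p8 <- m[i, j - 1];     p9 <- m[i - 1, j - 1]
  b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
       (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
  if (step == 1L) {
    cond <- p & b >= 2 & b <= 6 & a == 1 &
      !(p2 & p4 & p6) & !(p4 & p6 & p8)
  } else {
    cond <- p & b >= 2 & b <= 6 & a == 1 &
      !(p2 & p4 & p8) & !(p2 & p6 & p8)
  }
  m[i, j] <- p & !cond
  m
}

#' Skeletonize a cell mask
#'
#' Reduces a binary cell mask (soma plus processes) to one-pixel-wide
#' centrelines by Zhang-Suen topology-preserving thinning, then reports the
#' skeleton extent two ways: as an area (skeleton pixel count times the
#' pixel area, in um^2) and as a path length (pixel count with diagonal-only
#' adjacencies weighted sqrt(2); a diagonal link that merely shortcuts an
#' orthogonal connection is not re-counted).
#'
#' @param mask Logical matrix (non-empty).
#' @param calibration A [pixel_calibration()].
#' @return List with `skeleton` (logical matrix, same shape as `mask`),
#'   `skeleton_area_um2` and `skeleton_length_um`.
#' @export
skeletonize_cell <- function(mask, calibration) {
  stopifnot(inherits(calibration, "pixel_calibration"))
  mask <- mask > 0
  if (!any(mask)) stop("cannot skeletonize an empty mask")
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(FALSE, nr + 2, nc + 2)
  m[2:(nr + 1), 2:(nc + 1)] <- mask
  repeat {
    before <- m
    m <- .zs_pass(m, 1L)
    m <- .zs_pass(m, 2L)
    if (identical(m, before)) break
  }
  skel <- m[2:(nr + 1), 2:(nc + 1)]
  mpp <- calibration$microns_per_pixel
  list(skeleton = skel,
       skeleton_area_um2 = sum(skel) * mpp^2,
       skeleton_length_um = .skeleton_length_px(skel) * mpp)
}

# Path length of a 1-px skeleton in pixel units: the pixel count, with
# diagonal-only adjacencies weighted sqrt(2) (a diagonal link that merely
# shortcuts an orthogonal connection is not re-counted).
.skeleton_length_px <- function(s) {
  nr <- nrow(s); nc <- ncol(s)
  m <- matrix(FALSE, nr + 2, nc + 2)
  m[2:(nr + 1), 2:(nc + 1)] <- s
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  p <- m[i, j]
  dr <- p & m[i + 1, j + 1] & !(m[i + 1, j] | m[i, j + 1])
  dl <- p & m[i + 1, j - 1] & !(m[i + 1, j] | m[i, j - 1])
  sum(s) + (sqrt(2) - 1) * (sum(dr) + sum(dl))
}

#' Arborization (convex-hull) area of a cell
#'
#' The arborization territory is the area of the convex hull enclosing the
#' whole cell (soma and processes). The hull is taken over the pixel-corner
#' point set of the mask and its area computed with the shoelace formula,
#' so it is always at least the mask's own pixel area.
#'
#' @param mask Logical matrix (non-empty).
#' @param calibration A [pixel_calibration()].
#' @return Hull area in um^2.
#' @export
arborization_area <- function(mask, calibration) {
  stopifnot(inherits(calibration, "pixel_calibration"))
  idx <- which(mask > 0)
  if (length(idx) == 0) stop("cannot compute the hull of an empty mask")
  hull <- mask_hull(idx, dim(mask))
  polygon_area(hull) * calibration$microns_per_pixel^2
}

#' Mean soma fluorescence intensity
#'
#' The arithmetic mean grayscale value (0--255) of all pixels within the
#' segmented soma area.
#'
#' @param field A [field_image()].
#' @param soma_mask Logical matrix the same shape as the field, or a vector
#'   of linear pixel indices.
#' @return Mean intensity in `[0, 255]`.
#' @export
soma_mean_intensity <- function(field, soma_mask) {
  stopifnot(inherits(field, "field_image"))
  idx <- if (is.matrix(soma_mask)) which(soma_mask > 0) else
    as.integer(soma_mask)
  if (length(idx) == 0) stop("soma mask is empty")
  if (max(idx) > length(field$pixels) || min(idx) < 1) {
    stop("soma mask lies outside the field")
  }
  mean(field$pixels[idx])
}

#' Fit the cross-image intensity normalization model
#'
#' Acquisition conditions (exposure, excitation, background) shift and scale
#' recorded intensities between images. The model estimates a robust
#' background level (median of pixels outside all cell masks, dilated to
#' avoid halo contamination) and a robust bright-pixel anchor (upper
#' quantile of pixels inside cell masks), and maps them affinely onto fixed
#' reference intensities. Applying the model to per-soma means makes
#' intensities comparable across images up to an affine acquisition change.
#'
#' @param field A [field_image()].
#' @param cell_labels Integer matrix of cell labels (0 = background), e.g.
#'   from [extract_cell_masks()].
#' @param target_background,target_anchor Reference intensities the
#'   background and anchor are mapped to (defaults 10 and 240).
#' @param fg_quantile Quantile of in-cell pixels used as the bright anchor
#'   (default 0.995).
#' @param dilate_px Dilation of the cell masks before taking background
#'   pixels (default 2 px).
#' @return An object of class `normalization_model` with fields
#'   `background_level`, `foreground_anchor`, `slope`, `intercept`.
#' @export
fit_normalization <- function(field, cell_labels, target_background = 10,
                              target_anchor = 240, fg_quantile = 0.995,
                              dilate_px = 2) {
  stopifnot(inherits(field, "field_image"))
  fg <- cell_labels > 0
  if (!any(fg)) stop("normalization infeasible: no foreground cells")
  dil <- EBImage::dilate(fg * 1, EBImage::makeBrush(2L * dilate_px + 1L,
                                                    "disc")) > 0.5
  bg_px <- field$pixels[!dil]
  if (length(bg_px) == 0) stop("normalization infeasible: no background")
  background_level <- stats::median(bg_px)
  foreground_anchor <- stats::quantile(field$pixels[fg], fg_quantile,
                                       names = FALSE)
  if (foreground_anchor <= background_level) {
    stop("normalization infeasible: foreground anchor not above background")
  }
  slope <- (target_anchor - target_background) /
    (foreground_anchor - background_level)
  structure(list(background_level = background_level,
                 foreground_anchor = foreground_anchor,
                 target_background = target_background,
                 target_anchor = target_anchor,
                 slope = slope,
                 intercept = target_background - slope * background_level),
            class = "normalization_model")
}

#' @export
print.normalization_model <- function(x, ...) {
  cat(sprintf(paste0("<normalization_model> background %.2f -> %.0f, ",
                     "anchor %.2f -> %.0f (slope %.4f)\n"),
              x$background_level, x$target_background, x$foreground_anchor,
              x$target_anchor, x$slope))
  invisible(x)
}

#' Normalize a soma mean intensity
#'
#' Applies the affine map of a [fit_normalization()] model and clips to the
#' 0--255 working scale.
#'
#' @param model A `normalization_model`.
#' @param mean_intensity_raw Raw mean soma intensity (vectorised).
#' @return Normalized intensity in `[0, 255]`.
#' @export
normalized_soma_intensity <- function(model, mean_intensity_raw) {
  stopifnot(inherits(model, "normalization_model"))
  pmin(pmax(model$slope * mean_intensity_raw + model$intercept, 0), 255)
}

#' Measure one cell
#'
#' Composes the per-cell operators: soma Feret diameters/FDR and morphology
#' class, skeleton extent and arborization hull of the full cell mask, and
#' raw plus normalized soma intensity. When measuring intensity, pixels
#' belonging to other cells' masks (dilated by `exclude_dilate_px`) are
#' ignored to avoid interference from neighbouring cells.
#'
#' @param field A [field_image()].
#' @param cell_labels Integer label matrix of full cells from
#'   [extract_cell_masks()].
#' @param soma A `soma_record` from [segment_somas()].
#' @param model Optional `normalization_model`; when `NULL` the normalized
#'   intensity is `NA`.
#' @param exclude_dilate_px Dilation of neighbouring-cell masks before
#'   exclusion (default 2 px).
#' @return An object of class `cell_morphometry` (a list extending the soma
#'   record with `skeleton_area_um2`, `skeleton_length_um`,
#'   `arborization_area_um2`, `morph_class`, intensities).
#' @export
measure_cell <- function(field, cell_labels, soma, model = NULL,
                         exclude_dilate_px = 2) {
  stopifnot(inherits(field, "field_image"), inherits(soma, "soma_record"))
  cal <- field$calibration
  dim_img <- dim(field$pixels)

  # soma shape: Feret diameters on the convex hull of the traced contour
  # (boundary pixel centres)
  hull <- if (!is.null(soma$contour) && nrow(soma$contour) >= 3)
    convex_hull(soma$contour) else mask_center_hull(soma$pixels, dim_img)
  fmax_px <- hull_feret_max(hull)
  fmin_px <- hull_feret_min(hull)
  fdr <- feret_ratio(fmax_px, fmin_px)

  # full-cell mask, cropped to its bounding box for the thinning loop
  cell_idx <- which(cell_labels == soma$label)
  if (length(cell_idx) == 0) cell_idx <- soma$pixels
  xy <- idx_to_xy(cell_idx, dim_img[1])
  r0 <- min(xy[, 2]) + 1L; r1 <- max(xy[, 2]) + 1L
  c0 <- min(xy[, 1]) + 1L; c1 <- max(xy[, 1]) + 1L
  crop <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
  crop[cbind(xy[, 2] + 1L - r0 + 1L, xy[, 1] + 1L - c0 + 1L)] <- TRUE
  skel <- skeletonize_cell(crop, cal)
  arb_um2 <- arborization_area(crop, cal)

  # intensity with neighbour exclusion
  soma_idx <- soma$pixels
  others <- cell_labels > 0 & cell_labels != soma$label
  if (any(others)) {
    ex <- EBImage::dilate(others * 1,
                          EBImage::makeBrush(2L * exclude_dilate_px + 1L,
                                             "disc")) > 0.5
    keep <- soma_idx[!ex[soma_idx]]
    if (length(keep) > 0) soma_idx <- keep
  }
  raw <- soma_mean_intensity(field, soma_idx)
  norm <- if (is.null(model)) NA_real_ else
    normalized_soma_intensity(model, raw)

  out <- soma
  out$feret_max_um <- fmax_px * cal$microns_per_pixel
  out$feret_min_um <- fmin_px * cal$microns_per_pixel
  out$fdr <- fdr
  out$morph_class <- classify_morphology(fdr)
  out$skeleton_area_um2 <- skel$skeleton_area_um2
  out$skeleton_length_um <- skel$skeleton_length_um
  out$arborization_area_um2 <- max(arb_um2, out$soma_area_um2)
  out$mean_intensity_raw <- raw
  out$mean_intensity_norm <- norm
  class(out) <- c("cell_morphometry", "soma_record")
  out
}

#' @export
as.data.frame.cell_morphometry <- function(x, ...) {
  data.frame(field_id = x$field_id, label = x$label,
             soma_area_um2 = x$soma_area_um2,
             centroid_x_um = x$centroid_x_um,
             centroid_y_um = x$centroid_y_um,
             feret_max_um = x$feret_max_um, feret_min_um = x$feret_min_um,
             fdr = x$fdr, morph_class = x$morph_class,
             skeleton_area_um2 = x$skeleton_area_um2,
             skeleton_length_um = x$skeleton_length_um,
             arborization_area_um2 = x$arborization_area_um2,
             mean_intensity_raw = x$mean_intensity_raw,
             mean_intensity_norm = x$mean_intensity_norm,
             touches_border = x$touches_border,
             stringsAsFactors = FALSE)
}

#' Measure every cell in a field
#'
#' Convenience wrapper: segments somas, extracts full-cell masks, fits the
#' intensity normalization, and measures every cell.
#'
#' @param field A [field_image()].
#' @param params A [segmentation_params()].
#' @return List with `cells` (list of `cell_morphometry`), `somas`,
#'   `cell_labels` and `normalization`.
#' @export
measure_field <- function(field, params = segmentation_params()) {
  somas <- segment_somas(field, params)
  if (length(somas) == 0) {
    return(list(cells = list(), somas = somas,
                cell_labels = matrix(0L, nrow(field$pixels),
                                     ncol(field$pixels)),
                normalization = NULL))
  }
  labels <- extract_cell_masks(field, somas, params)
  model <- tryCatch(fit_normalization(field, labels),
                    error = function(e) NULL)
  cells <- lapply(somas, function(s)
    measure_cell(field, labels, s, model))
  list(cells = cells, somas = somas, cell_labels = labels,
       normalization = model)
}
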