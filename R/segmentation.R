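# Soma detection and full-cell mask extraction. The recipe is smoothing ->
# global threshold -> morphological opening (erases thin processes) ->
# connected components -> physical-area filter, with every knob exposed in
# segmentation_params(). Process pixels are then assigned back to their
# soma by a deterministic nearest-seed geodesic propagation.

#' Segmentation parameters
#'
#' @param smoothing_sigma_px Gaussian pre-smoothing sigma (px, >= 0; the
#'   default 0 disables smoothing). The global Otsu threshold is already
#'   several noise standard deviations above background on typical fields;
#'   pre-smoothing spreads blur halos around cells into a continuum that
#'   biases the global threshold upward and can erase thin processes, so
#'   smoothing is reserved for unusually noisy material.
#' @param threshold_method `"otsu"` (global Otsu per field) or `"fixed"`.
#' @param threshold_level Fixed threshold on the 0--255 scale (used when
#'   `threshold_method = "fixed"`).
#' @param soma_opening_radius_px Disk radius (px) of the opening that erases
#'   processes while preserving somas; the default 3 px (about half a small
#'   soma radius at the default calibration) removes structures a few px
#'   wide.
#' @param min_soma_area_um2,max_soma_area_um2 Physical soma-area filter
#'   (inclusive bounds, um^2).
#' @param gap_closing_radius_px Disk radius (px) of the morphological
#'   closing used only when assigning process pixels to cells: the point
#'   spread and noise fragment thin processes at threshold, and closing
#'   bridges sub-resolution gaps so distal fragments stay connected to
#'   their cell (0 disables). The bridge is used for connectivity only;
#'   reported masks contain only thresholded foreground pixels.
#' @param border_policy `"exclude_touching"` drops somas touching the image
#'   border (the default for morphometry, where partial cells bias shape
#'   metrics); `"keep"` retains them (the default for counting).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma_px = 0,
                                threshold_method = c("otsu", "fixed"),
                                threshold_level = 50,
                                soma_opening_radius_px = 3L,
                                min_soma_area_um2 = 15,
                                max_soma_area_um2 = 300,
                                gap_closing_radius_px = 2L,
                                border_policy = c("exclude_touching",
                                                  "keep")) {
  threshold_method <- match.arg(threshold_method)
  border_policy <- match.arg(border_policy)
  if (smoothing_sigma_px < 0) stop("smoothing_sigma_px must be >= 0")
  if (soma_opening_radius_px < 1) stop("soma_opening_radius_px must be >= 1")
  if (gap_closing_radius_px < 0) stop("gap_closing_radius_px must be >= 0")
  if (min_soma_area_um2 <= 0 || max_soma_area_um2 <= min_soma_area_um2) {
    stop("soma area bounds must be positive and ordered")
  }
  structure(list(smoothing_sigma_px = smoothing_sigma_px,
                 threshold_method = threshold_method,
                 threshold_level = threshold_level,
                 soma_opening_radius_px = as.integer(soma_opening_radius_px),
                 min_soma_area_um2 = min_soma_area_um2,
                 max_soma_area_um2 = max_soma_area_um2,
                 gap_closing_radius_px = as.integer(gap_closing_radius_px),
                 border_policy = border_policy),
            class = "segmentation_params")
}

# 8-connected component labelling by flood fill. Returns an integer matrix;
# labels follow first-encounter (column-major) order of the components.
label_components <- function(mask) {
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  todo <- which(mask & lab == 0L)
  off <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  rowof <- function(i) ((i - 1L) %% nr) + 1L
  for (start in todo) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    lab[start] <- nxt
    frontier <- start
    while (length(frontier) > 0) {
      r <- rowof(frontier)
      cand <- c(frontier[r > 1L] - 1L, frontier[r < nr] + 1L,
                frontier - nr, frontier + nr,
                frontier[r > 1L] - nr - 1L, frontier[r > 1L] + nr - 1L,
                frontier[r < nr] - nr + 1L, frontier[r < nr] + nr + 1L)
      cand <- unique(cand[cand >= 1L & cand <= nr * nc])
      cand <- cand[mask[cand] & lab[cand] == 0L]
      lab[cand] <- nxt
      frontier <- cand
    }
  }
  lab
}

# Smooth + threshold a field; returns the logical foreground mask.
.foreground_mask <- function(field, params) {
  img <- field$pixels
  if (params$smoothing_sigma_px > 0) {
    img <- EBImage::gblur(img, sigma = params$smoothing_sigma_px)
  }
  thr <- if (params$threshold_method == "otsu") {
    EBImage::otsu(img / 255, range = c(0, 1), levels = 256L) * 255
  } else {
    params$threshold_level
  }
  img > thr
}

#' Detect microglial somas in a field
#'
#' Pipeline: optional Gaussian smoothing, global foreground threshold,
#' morphological opening with a disk to erase thin processes, 8-connected
#' component labelling, inclusive physical-area filter, and optional
#' exclusion of border-touching somas. Labels are assigned in raster-scan
#' order of the centroids (top-to-bottom, then left-to-right), so output is
#' deterministic for a fixed field and parameters.
#'
#' Geometry-heavy fields (Feret diameters, FDR, morphology class,
#' intensities) are populated later by [measure_cell()].
#'
#' @param field A [field_image()].
#' @param params A [segmentation_params()].
#' @return A list of `soma_record` objects (possibly empty), each with
#'   `label`, `pixels` (linear indices), `soma_area_um2`,
#'   `centroid_x_um`/`centroid_y_um`, `contour` (ordered boundary polygon in
#'   0-based pixel-centre coordinates), `touches_border`, `field_id`.
#' @export
segment_somas <- function(field, params = segmentation_params()) {
  stopifnot(inherits(field, "field_image"),
            inherits(params, "segmentation_params"))
  fg <- .foreground_mask(field, params)
  if (!any(fg)) return(list())
  brush <- EBImage::makeBrush(2L * params$soma_opening_radius_px + 1L,
                              "disc")
  opened <- EBImage::opening(fg * 1, brush) > 0.5
  if (!any(opened)) return(list())
  lab <- label_components(opened)
  nr <- nrow(lab); nc <- ncol(lab)
  mpp <- field$calibration$microns_per_pixel
  recs <- list()
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k)
    area <- length(idx) * mpp^2
    if (area < params$min_soma_area_um2 || area > params$max_soma_area_um2) {
      next
    }
    xy <- idx_to_xy(idx, nr)
    touches <- any(xy[, 1] == 0 | xy[, 1] == nc - 1 |
                   xy[, 2] == 0 | xy[, 2] == nr - 1)
    if (touches && params$border_policy == "exclude_touching") next
    recs[[length(recs) + 1]] <- structure(
      list(label = NA_integer_, pixels = idx, soma_area_um2 = area,
           centroid_x_um = mean(xy[, 1]) * mpp,
           centroid_y_um = mean(xy[, 2]) * mpp,
           contour = .trace_contour(idx, c(nr, nc)),
           touches_border = touches,
           field_id = field$metadata$field_id),
      class = "soma_record")
  }
  if (length(recs) == 0) return(recs)
  cy <- vapply(recs, function(r) r$centroid_y_um, numeric(1))
  cx <- vapply(recs, function(r) r$centroid_x_um, numeric(1))
  recs <- recs[order(cy, cx)]
  for (i in seq_along(recs)) recs[[i]]$label <- i
  recs
}

# Ordered boundary polygon of a mask component, 0-based pixel-centre (x, y).
.trace_contour <- function(idx, dim_img) {
  m <- matrix(0L, dim_img[1], dim_img[2])
  m[idx] <- 1L
  oc <- EBImage::ocontour(m)[[1]]
  # ocontour reports 0-based (dim1, dim2) = (row-1, col-1); convert to (x, y)
  cbind(x = oc[, 2], y = oc[, 1])
}

#' Assign process pixels to somas (full-cell masks)
#'
#' The thresholded foreground (without the opening that removed processes)
#' is partitioned among the detected somas by nearest-seed geodesic
#' propagation inside the foreground: each soma mask seeds its label, and
#' labels grow wavefront-by-wavefront through 8-connected foreground pixels.
#' On equidistant ridges the lowest label wins, making the partition
#' deterministic. Foreground components containing no soma (specks, debris)
#' stay unlabelled.
#'
#' @param field A [field_image()].
#' @param somas Soma records from [segment_somas()] on the same field.
#' @param params The [segmentation_params()] used for the somas.
#' @return Integer label matrix; 0 is background, positive values are soma
#'   labels. Every soma pixel keeps its own label.
#' @export
extract_cell_masks <- function(field, somas,
                               params = segmentation_params()) {
  stopifnot(inherits(field, "field_image"))
  nr <- nrow(field$pixels); nc <- ncol(field$pixels)
  lab <- matrix(0L, nr, nc)
  if (length(somas) == 0) return(lab)
  fg <- .foreground_mask(field, params)
  for (s in somas) {
    lab[s$pixels] <- s$label
    fg[s$pixels] <- TRUE  # somas always belong to the cell
  }
  # bridge sub-resolution gaps in thin processes (connectivity only)
  bridge <- fg
  if (params$gap_closing_radius_px > 0) {
    bridge <- EBImage::closing(
      fg * 1, EBImage::makeBrush(2L * params$gap_closing_radius_px + 1L,
                                 "disc")) > 0.5
    bridge <- bridge | fg
  }
  # propagate per bridged component (cropped to its bounding box):
  # components with no soma seed stay unlabelled
  comp <- label_components(bridge)
  for (k in seq_len(max(comp))) {
    cidx <- which(comp == k)
    if (!any(lab[cidx] > 0L)) next
    xy <- idx_to_xy(cidx, nr)
    r0 <- min(xy[, 2]) + 1L; r1 <- max(xy[, 2]) + 1L
    c0 <- min(xy[, 1]) + 1L; c1 <- max(xy[, 1]) + 1L
    lab[r0:r1, c0:c1] <- .propagate_labels(
      bridge[r0:r1, c0:c1, drop = FALSE],
      lab[r0:r1, c0:c1, drop = FALSE])
  }
  lab[!fg] <- 0L  # the bridge is connectivity-only
  storage.mode(lab) <- "integer"
  lab
}

# Synchronous wavefront growth of seed labels through a foreground mask;
# 8-connected, lowest label wins on equidistant ridges.
.propagate_labels <- function(fg, lab) {
  nr <- nrow(fg); nc <- ncol(fg)
  big <- max(lab) + 1L
  cur <- matrix(big, nr, nc)
  cur[lab > 0L] <- lab[lab > 0L]
  shift <- function(m, dr, dc) {
    out <- matrix(big, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
    out
  }
  repeat {
    cand <- pmin(shift(cur, 1, 0), shift(cur, -1, 0),
                 shift(cur, 0, 1), shift(cur, 0, -1),
                 shift(cur, 1, 1), shift(cur, 1, -1),
                 shift(cur, -1, 1), shift(cur, -1, -1))
    take <- fg & cur == big & cand < big
    if (!any(take)) break
    cur[take] <- cand[take]
  }
  cur[cur == big | !fg] <- 0L
  cur
}

#' Filter soma records by physical area
#'
#' Keeps records whose soma area lies within the inclusive bounds; input
#' order is preserved.
#'
#' @param records List of `soma_record`s.
#' @param min_soma_area_um2,max_soma_area_um2 Inclusive bounds (um^2),
#'   ordered.
#' @return The filtered list.
#' @export
filter_by_area <- function(records, min_soma_area_um2, max_soma_area_um2) {
  if (min_soma_area_um2 > max_soma_area_um2) {
    stop("area bounds must be ordered")
  }
  Filter(function(r) r$soma_area_um2 >= min_soma_area_um2 &&
           r$soma_area_um2 <= max_soma_area_um2, records)
}

#' @export
print.soma_record <- function(x, ...) {
  cat(sprintf("<soma_record> label %s, area %.1f um2, centroid (%.1f, %.1f) um\n",
              x$label, x$soma_area_um2, x$centroid_x_um, x$centroid_y_um))
  invisible(x)
}
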