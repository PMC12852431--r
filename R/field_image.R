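#' @keywords internal
"_PACKAGE"

# Enumerations shared across the package. Zones are ordered from the optic
# disc outward: 1 = proximal, 2 = intermediate, 3 = peripheral.
.groups    <- c("WT", "APP")
.ages      <- c(6L, 9L, 12L, 15L, 17L, 20L)
.layers    <- c("OS", "OPL", "IPL", "NFL_GCL")
.quadrants <- c("nasal", "temporal", "superior", "inferior")
.zones     <- 1:3

#' Pixel calibration
#'
#' Physical size of one pixel. All morphometric outputs are expressed in
#' micrometres (lengths) and square micrometres (areas) through this factor.
#'
#' @param microns_per_pixel Pixel pitch in micrometres per pixel; must be > 0.
#' @return An object of class `pixel_calibration`.
#' @export
pixel_calibration <- function(microns_per_pixel) {
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1 ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0) {
    stop("microns_per_pixel must be a single positive number")
  }
  structure(list(microns_per_pixel = as.numeric(microns_per_pixel)),
            class = "pixel_calibration")
}

#' Default field geometry
#'
#' The study design samples fields of 0.1502 mm^2. The raster size is a
#' package convention (the acquisition frame is not part of the data model);
#' the pixel pitch is derived so that
#' `width_px * height_px * microns_per_pixel^2 / 1e6 = 0.1502` exactly.
#'
#' @param width_px,height_px Raster size in pixels.
#' @param field_area_mm2 Target physical field area in mm^2.
#' @return List with `width_px`, `height_px` and a [pixel_calibration()].
#' @export
default_field_geometry <- function(width_px = 1024L, height_px = 1024L,
                                   field_area_mm2 = 0.1502) {
  mpp <- sqrt(field_area_mm2 * 1e6 / (width_px * height_px))
  list(width_px = as.integer(width_px), height_px = as.integer(height_px),
       calibration = pixel_calibration(mpp))
}

#' Physical field area in mm^2
#'
#' @param width_px,height_px Raster size in pixels.
#' @param calibration A [pixel_calibration()].
#' @return Field area in mm^2.
#' @export
field_area_mm2 <- function(width_px, height_px, calibration) {
  stopifnot(inherits(calibration, "pixel_calibration"))
  width_px * height_px * calibration$microns_per_pixel^2 / 1e6
}

#' Field metadata
#'
#' Study metadata attached to one imaged field: genotype group, age, retinal
#' layer, retinal quadrant and eccentricity zone (1 = proximal to the optic
#' disc, 3 = peripheral).
#'
#' @param group `"WT"` or `"APP"`.
#' @param age_months One of 6, 9, 12, 15, 17, 20.
#' @param layer One of `"OS"`, `"OPL"`, `"IPL"`, `"NFL_GCL"`.
#' @param quadrant One of `"nasal"`, `"temporal"`, `"superior"`, `"inferior"`.
#' @param zone Eccentricity zone, integer 1, 2 or 3.
#' @param animal_id Opaque animal identifier.
#' @param field_id Opaque field identifier (defaults to a composite of the
#'   other fields).
#' @return An object of class `field_metadata`.
#' @export
field_metadata <- function(group = "WT", age_months = 6L, layer = "IPL",
                           quadrant = "nasal", zone = 1L,
                           animal_id = "animal1", field_id = NULL) {
  group <- match.arg(group, .groups)
  layer <- match.arg(layer, .layers)
  quadrant <- match.arg(quadrant, .quadrants)
  age_months <- as.integer(age_months)
  zone <- as.integer(zone)
  if (!age_months %in% .ages) {
    stop("age_months must be one of ", paste(.ages, collapse = ", "))
  }
  if (!zone %in% .zones) stop("zone must be 1, 2 or 3")
  if (is.null(field_id)) {
    field_id <- paste(animal_id, group, age_months, layer, quadrant, zone,
                      sep = "_")
  }
  structure(list(group = group, age_months = age_months, layer = layer,
                 quadrant = quadrant, zone = zone,
                 animal_id = as.character(animal_id),
                 field_id = as.character(field_id)),
            class = "field_metadata")
}

#' Calibrated fluorescence field
#'
#' One 2-D grayscale field on the 0--255 working intensity scale. Pixels are
#' stored as a numeric matrix with rows as image rows (origin top-left);
#' continuous pixel coordinates are 0-based pixel centres, so pixel
#' `[r, c]` (1-based matrix indices) has centre `(x, y) = (c - 1, r - 1)`.
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]`.
#' @param calibration A [pixel_calibration()].
#' @param metadata A [field_metadata()].
#' @return An object of class `field_image`.
#' @export
field_image <- function(pixels, calibration, metadata = field_metadata()) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie within [0, 255]")
  }
  stopifnot(inherits(calibration, "pixel_calibration"),
            inherits(metadata, "field_metadata"))
  structure(list(pixels = pixels,
                 width_px = ncol(pixels), height_px = nrow(pixels),
                 calibration = calibration, metadata = metadata),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image> %d x %d px, %.4f um/px (%.4f mm^2)\n",
              x$width_px, x$height_px, x$calibration$microns_per_pixel,
              field_area_mm2(x$width_px, x$height_px, x$calibration)))
  cat(sprintf("  %s | %s, %d mo, %s, %s, zone %d\n", x$metadata$field_id,
              x$metadata$group, x$metadata$age_months, x$metadata$layer,
              x$metadata$quadrant, x$metadata$zone))
  cat(sprintf("  intensity range [%.1f, %.1f]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Project a z-stack to a single plane
#'
#' Fields acquired as z-stacks (optical sections every few micrometres) are
#' collapsed to one plane before segmentation. Maximum-intensity projection
#' is the default because it preserves thin processes that appear in only
#' one section.
#'
#' @param stack A list of numeric matrices, all the same shape.
#' @param method `"max"` (default) or `"mean"`.
#' @return A single numeric matrix.
#' @export
project_zstack <- function(stack, method = c("max", "mean")) {
  method <- match.arg(method)
  if (is.matrix(stack)) stack <- list(stack)
  if (length(stack) < 1) stop("stack must contain at least one plane")
  dims <- lapply(stack, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all planes in the stack must have the same shape")
  }
  if (length(stack) == 1) return(stack[[1]])
  out <- stack[[1]]
  if (method == "max") {
    for (i in 2:length(stack)) out <- pmax(out, stack[[i]])
  } else {
    for (i in 2:length(stack)) out <- out + stack[[i]]
    out <- out / length(stack)
  }
  out
}

#' Load a calibrated field from a TIFF file
#'
#' Reads a single- or multi-plane grayscale TIFF (8- or 16-bit), collapses
#' stacks with [project_zstack()], and rescales intensities linearly to the
#' 0--255 working scale (so a 16-bit full-scale value 65535 maps to 255).
#'
#' @param path Path to the TIFF file.
#' @param calibration A [pixel_calibration()].
#' @param metadata A [field_metadata()].
#' @param projection Projection method for stacks, see [project_zstack()].
#' @return A [field_image()].
#' @export
load_field <- function(path, calibration, metadata = field_metadata(),
                       projection = "max") {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  planes <- tiff::readTIFF(path, all = TRUE)
  if (is.array(planes) && !is.list(planes)) planes <- list(planes)
  for (p in planes) {
    if (length(dim(p)) == 3) {
      stop("unsupported format: expected grayscale, got ", dim(p)[3],
           " channels")
    }
  }
  # readTIFF returns values scaled to [0, 1] regardless of bit depth, so a
  # single multiplication realises the linear 0-255 rescale for both depths.
  planes <- lapply(planes, function(p) p * 255)
  px <- project_zstack(planes, method = projection)
  field_image(px, calibration, metadata)
}

#' Write a field to an 8-bit grayscale TIFF
#'
#' @param field A [field_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "field_image"))
  tiff::writeTIFF(round(field$pixels) / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a labelled cell mask as a 16-bit TIFF
#'
#' @param labels Integer label matrix (0 = background).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

# Canonical per-cell table schema; units are carried in the column names.
.cell_table_columns <- c(
  "field_id", "label", "soma_area_um2", "centroid_x_um", "centroid_y_um",
  "feret_max_um", "feret_min_um", "fdr", "morph_class",
  "skeleton_area_um2", "skeleton_length_um", "arborization_area_um2",
  "mean_intensity_raw", "mean_intensity_norm", "touches_border"
)

#' Write the per-cell morphometry table
#'
#' One row per measured cell; units are embedded in the column names
#' (um2 = square micrometres, um = micrometres, intensities on the 0--255
#' grayscale, `fdr` dimensionless). Rows are ordered deterministically by
#' `(field_id, label)`.
#'
#' @param cells A data frame of per-cell measurements (see
#'   [as.data.frame.cell_morphometry()]), or a list of `cell_morphometry`
#'   records. An empty input writes a header-only file.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  df <- cells_to_table(cells)
  df <- df[order(df$field_id, df$label), , drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write cell table: ", path)
  invisible(path)
}

#' Read a per-cell morphometry table written by [write_cell_table()]
#'
#' @param path CSV path.
#' @return A data frame with the canonical per-cell columns.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("cannot read cell table: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Normalise list-of-records / data.frame input to the canonical schema.
cells_to_table <- function(cells) {
  if (is.data.frame(cells)) {
    missing <- setdiff(.cell_table_columns, names(cells))
    for (m in missing) cells[[m]] <- if (m %in% c("field_id", "morph_class"))
      character(0) else logical(0)
    return(cells[, .cell_table_columns, drop = FALSE])
  }
  if (length(cells) == 0) {
    df <- as.data.frame(
      stats::setNames(rep(list(numeric(0)), length(.cell_table_columns)),
                      .cell_table_columns))
    df$field_id <- character(0)
    df$morph_class <- character(0)
    df$touches_border <- logical(0)
    return(df)
  }
  do.call(rbind, lapply(cells, as.data.frame))
}
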