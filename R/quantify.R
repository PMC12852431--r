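# Per-field counting and density, and the study's systematic sampling plan
# (four retinal quadrants x three eccentricity zones per retina).

#' Count cells in one field
#'
#' Applies the counting border policy: by default border-touching cells are
#' kept, because a partial cell still occupies the counting frame even
#' though its shape metrics are biased.
#'
#' @param records List of `soma_record`s from one field (segmented with
#'   `border_policy = "keep"` so the flag is available).
#' @param border_policy `"keep"` (default) or `"exclude_touching"`.
#' @return Non-negative integer count.
#' @export
count_cells <- function(records, border_policy = c("keep",
                                                   "exclude_touching")) {
  border_policy <- match.arg(border_policy)
  if (length(records) == 0) return(0L)
  if (border_policy == "keep") return(length(records))
  sum(!vapply(records, function(r) isTRUE(r$touches_border), logical(1)))
}

#' Cell density
#'
#' @param n_cells Cell count (>= 0).
#' @param field_area_mm2 Field area in mm^2 (> 0).
#' @return Cells per mm^2.
#' @export
cell_density <- function(n_cells, field_area_mm2) {
  if (any(field_area_mm2 <= 0)) stop("field area must be positive")
  n_cells / field_area_mm2
}

#' Sampling plan
#'
#' The study design: each retina is sampled in four quadrants at three
#' increasing eccentricities from the optic disc, i.e. 12 fields per retina,
#' with six retinas per group and two groups per time point.
#'
#' @param quadrants Character vector of quadrants.
#' @param zones Integer vector of eccentricity zones.
#' @param retinas_per_group Retinas analysed per group (default 6).
#' @param groups Character vector of groups.
#' @return An object of class `sampling_plan`.
#' @export
sampling_plan <- function(quadrants = .quadrants, zones = .zones,
                          retinas_per_group = 6L,
                          groups = .groups) {
  if (length(quadrants) == 0 || length(zones) == 0) {
    stop("quadrants and zones must be non-empty")
  }
  if (retinas_per_group < 1) stop("retinas_per_group must be positive")
  structure(list(quadrants = quadrants, zones = as.integer(zones),
                 retinas_per_group = as.integer(retinas_per_group),
                 groups = groups),
            class = "sampling_plan")
}

#' Enumerate the field slots of a sampling plan
#'
#' Returns the (quadrant, zone) slots of one retina in fixed order
#' (quadrants nasal, temporal, superior, inferior; zones ascending) together
#' with the design totals.
#'
#' @param plan A [sampling_plan()].
#' @return List with `slots` (data frame of quadrant and zone),
#'   `fields_per_retina`, `fields_per_group` (per time point) and
#'   `fields_per_age` (all groups combined).
#' @export
enumerate_fields <- function(plan = sampling_plan()) {
  stopifnot(inherits(plan, "sampling_plan"))
  slots <- expand.grid(zone = plan$zones, quadrant = plan$quadrants,
                       stringsAsFactors = FALSE)[, c("quadrant", "zone")]
  slots <- slots[order(match(slots$quadrant, plan$quadrants), slots$zone), ]
  rownames(slots) <- NULL
  per_retina <- nrow(slots)
  list(slots = slots,
       fields_per_retina = per_retina,
       fields_per_group = per_retina * plan$retinas_per_group,
       fields_per_age = per_retina * plan$retinas_per_group *
         length(plan$groups))
}

# Morphometric variables carried by a full per-layer summary. OS and
# NFL_GCL fields carry counts only (those layers are counted, not measured).
.morph_vars <- c("soma_area_um2", "skeleton_area_um2",
                 "arborization_area_um2", "fdr", "mean_intensity_raw",
                 "mean_intensity_norm")

#' Summarize one field
#'
#' One row per field: metadata, cell count, density (count divided by the
#' physical field area) and per-cell medians of each morphometric variable.
#' For the OS and NFL_GCL layers only the count and density are reported;
#' for fields with no cells the medians are `NA`.
#'
#' @param field A [field_image()].
#' @param cells List of `cell_morphometry` records measured in the field
#'   (may be empty).
#' @param n_cells Optional externally supplied count (e.g. from a
#'   `border_policy = "keep"` segmentation); defaults to `length(cells)`.
#' @return A one-row data frame.
#' @export
summarize_field <- function(field, cells, n_cells = NULL) {
  stopifnot(inherits(field, "field_image"))
  md <- field$metadata
  if (is.null(n_cells)) n_cells <- length(cells)
  area <- field_area_mm2(field$width_px, field$height_px, field$calibration)
  out <- data.frame(field_id = md$field_id, animal_id = md$animal_id,
                    group = md$group, age_months = md$age_months,
                    layer = md$layer, quadrant = md$quadrant,
                    zone = md$zone, n_cells = as.integer(n_cells),
                    field_area_mm2 = area,
                    density_cells_per_mm2 = cell_density(n_cells, area),
                    stringsAsFactors = FALSE)
  full <- md$layer %in% c("OPL", "IPL")
  for (v in .morph_vars) {
    out[[paste0("median_", v)]] <-
      if (full && length(cells) > 0) {
        stats::median(vapply(cells, function(x) as.numeric(x[[v]]),
                             numeric(1)), na.rm = TRUE)
      } else NA_real_
  }
  out
}

#' Build the long-format study table from per-cell measurements
#'
#' Reshapes a per-cell table (from [write_cell_table()] /
#' [cells_to_table()]) into the long format consumed by
#' [run_study_contrasts()]: one row per (cell, variable).
#'
#' @param cell_table Per-cell data frame including `field_id` and the
#'   metadata columns `group`, `age_months`, `layer` (joined from the field
#'   summaries when absent).
#' @param field_table Optional per-field data frame used to attach metadata
#'   by `field_id`.
#' @return Data frame with columns `group`, `age_months` (named `age`),
#'   `layer`, `field_id`, `variable`, `value`.
#' @export
study_table <- function(cell_table, field_table = NULL) {
  if (!is.null(field_table)) {
    keep <- c("field_id", "group", "age_months", "layer")
    cell_table <- merge(cell_table, field_table[, keep], by = "field_id")
  }
  need <- c("group", "age_months", "layer")
  miss <- setdiff(need, names(cell_table))
  if (length(miss) > 0) {
    stop("study table schema error: missing column ", miss[1])
  }
  vars <- intersect(.morph_vars, names(cell_table))
  long <- do.call(rbind, lapply(vars, function(v) {
    data.frame(group = cell_table$group, age = cell_table$age_months,
               layer = cell_table$layer, field_id = cell_table$field_id,
               variable = v, value = cell_table[[v]],
               stringsAsFactors = FALSE)
  }))
  long[!is.na(long$value), , drop = FALSE]
}
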