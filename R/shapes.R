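#' Rasterize a simple filled shape
#'
#' Renders a filled binary mask for a circle, ellipse, rectangle or cross,
#' centred in a raster that contains the shape with the requested margin.
#' The continuous geometry (centre, axes, orientation) is attached so mask
#' measurements can be compared against analytic values.
#'
#' A pixel belongs to the mask when its centre lies inside the continuous
#' shape. Angles are in radians, measured counter-clockwise from the x axis.
#'
#' @param shape One of `"circle"`, `"ellipse"`, `"rectangle"`, `"cross"`.
#' @param r Circle radius (px).
#' @param a,b Ellipse semi-axes (px), `a` along the rotated x axis.
#' @param w,h Rectangle width and height (px).
#' @param arm_len,arm_w Cross arm length and arm width (px).
#' @param theta Rotation angle (radians) for ellipse and rectangle.
#' @param margin Blank margin around the shape, in px (>= 2).
#' @return A list with `mask` (logical matrix), `params` (the continuous
#'   geometry) and `center` (x, y pixel coordinates of the shape centre).
#' @examples
#' m <- render_shape_mask("circle", r = 10)
#' sum(m$mask) / (pi * 10^2)  # close to 1
#' @export
render_shape_mask <- function(shape = c("circle", "ellipse", "rectangle",
                                        "cross"),
                              r = NULL, a = NULL, b = NULL, w = NULL,
                              h = NULL, arm_len = NULL, arm_w = NULL,
                              theta = 0, margin = 2) {
  shape <- match.arg(shape)
  if (margin < 2) stop("margin must be at least 2 px")
  extent <- switch(shape,
    circle = {
      if (is.null(r) || r <= 0) stop("circle requires a positive radius r")
      r
    },
    ellipse = {
      if (is.null(a) || is.null(b) || a <= 0 || b <= 0)
        stop("ellipse requires positive semi-axes a and b")
      max(a, b)
    },
    rectangle = {
      if (is.null(w) || is.null(h) || w <= 0 || h <= 0)
        stop("rectangle requires positive w and h")
      sqrt(w^2 + h^2) / 2
    },
    cross = {
      if (is.null(arm_len) || is.null(arm_w) || arm_len <= 0 || arm_w <= 0)
        stop("cross requires positive arm_len and arm_w")
      arm_len / 2
    })
  side <- 2L * (ceiling(extent) + margin) + 1L
  cx <- cy <- (side - 1) / 2            # 0-based centre coordinate
  xs <- matrix(rep(0:(side - 1), each = side), side, side)   # x = col - 1
  ys <- matrix(rep(0:(side - 1), times = side), side, side)  # y = row - 1
  dx <- xs - cx; dy <- ys - cy
  ct <- cos(theta); st <- sin(theta)
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  mask <- switch(shape,
    circle    = dx^2 + dy^2 <= r^2,
    ellipse   = (u / a)^2 + (v / b)^2 <= 1,
    rectangle = abs(u) <= w / 2 & abs(v) <= h / 2,
    cross     = (abs(dx) <= arm_len / 2 & abs(dy) <= arm_w / 2) |
                (abs(dy) <= arm_len / 2 & abs(dx) <= arm_w / 2))
  if (any(mask[1, ]) || any(mask[side, ]) || any(mask[, 1]) ||
      any(mask[, side])) {
    stop("shape exceeds the raster")
  }
  params <- list(shape = shape, r = r, a = a, b = b, w = w, h = h,
                 arm_len = arm_len, arm_w = arm_w, theta = theta)
  list(mask = mask, params = params, center = c(x = cx, y = cy))
}
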