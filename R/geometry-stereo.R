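#' Camera intrinsics for a rectified stereo pair
#'
#' Bundles the pinhole parameters used for triangulation: focal length in
#' pixels, principal point, and the stereo baseline (distance between the
#' left and right camera centres) in centimetres.
#'
#' @param f_px focal length in pixels; must be positive.
#' @param cx,cy principal point (column, row) in pixels.
#' @param baseline_cm stereo baseline in cm; must be positive.
#' @return An object of class `camera_intrinsics`.
#' @examples
#' camera_intrinsics(1000, 960, 540, 11)
#' @export
camera_intrinsics <- function(f_px, cx, cy, baseline_cm) {
  if (!is.numeric(f_px) || f_px <= 0) {
    abort("focal length must be positive", "domain_error")
  }
  if (!is.numeric(baseline_cm) || baseline_cm <= 0) {
    abort("baseline must be positive", "domain_error")
  }
  structure(
    list(f = as.numeric(f_px), cx = as.numeric(cx), cy = as.numeric(cy),
         baseline = as.numeric(baseline_cm)),
    class = "camera_intrinsics"
  )
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera_intrinsics: f = %g px, c = (%g, %g) px, baseline = %g cm\n",
              x$f, x$cx, x$cy, x$baseline))
  invisible(x)
}

#' Read camera intrinsics from a JSON config
#'
#' Expects the keys `f_px`, `cx`, `cy`, `baseline_cm`.
#'
#' @param path path to a JSON file.
#' @return A [camera_intrinsics()] object.
#' @export
read_intrinsics <- function(path) {
  cfg <- read_config(path, required = c("f_px", "cx", "cy", "baseline_cm"))
  camera_intrinsics(cfg$f_px, cfg$cx, cfg$cy, cfg$baseline_cm)
}

#' Disparity of a matched pixel pair
#'
#' The disparity of a scene point observed in a rectified stereo pair is the
#' horizontal offset between its left- and right-image columns,
#' `d = u_left - u_right`. Both pixels must lie on the same rectified row
#' (the epipolar constraint); a configurable tolerance accommodates noisy
#' rectification.
#'
#' Pixels are `(u, v)` = (column, row), 0-based, origin top-left.
#'
#' @param left_pixel,right_pixel numeric `(u, v)` pixel coordinates.
#' @param epipolar_tol maximum allowed row difference in pixels (default 0).
#' @return Disparity in pixels. Negative disparities are returned as-is but
#'   are rejected by [triangulate()].
#' @examples
#' compute_disparity(c(210, 80), c(100, 80))  # 110
#' @export
compute_disparity <- function(left_pixel, right_pixel, epipolar_tol = 0) {
  if (abs(left_pixel[2] - right_pixel[2]) > epipolar_tol) {
    abort(sprintf("epipolar violation: rows differ by %g px (tolerance %g)",
                  abs(left_pixel[2] - right_pixel[2]), epipolar_tol),
          "epipolar_violation")
  }
  as.numeric(left_pixel[1] - right_pixel[1])
}

#' Block-matching correspondence search along the epipolar line
#'
#' Given a pixel in the left image, scans the same row of the right image for
#' the integer disparity in `0..search_range` minimising the sum of absolute
#' differences (SAD) over an odd square window. Ties are broken toward the
#' smallest disparity, so textureless patches match at disparity 0.
#'
#' @param left_image,right_image numeric matrices (rows x cols) of equal
#'   shape, values on any common scale.
#' @param left_pixel `(u, v)` pixel in the left image, 0-based.
#' @param search_range maximum disparity searched, in pixels.
#' @param window odd window side length in pixels (default 11).
#' @return The matching right-image pixel `(u, v)`.
#' @export
find_correspondence <- function(left_image, right_image, left_pixel,
                                search_range, window = 11L) {
  if (window %% 2L != 1L) abort("window must be odd", "domain_error")
  if (!all(dim(left_image) == dim(right_image))) {
    abort("left and right images must have the same shape", "format_error")
  }
  u <- as.integer(left_pixel[1]); v <- as.integer(left_pixel[2])
  half <- (window - 1L) %/% 2L
  nr <- nrow(left_image); nc <- ncol(left_image)
  # 0-based pixel (u, v) lives at matrix cell [v + 1, u + 1]
  rows <- (v - half):(v + half) + 1L
  cols <- (u - half):(u + half) + 1L
  if (min(rows) < 1L || max(rows) > nr || min(cols) < 1L || max(cols) > nc) {
    abort("matching window exceeds image bounds at left_pixel", "bounds_error")
  }
  ref <- left_image[rows, cols, drop = FALSE]
  best_d <- NA_integer_; best_cost <- Inf
  for (d in 0:as.integer(search_range)) {
    ccols <- cols - d
    if (min(ccols) < 1L) break
    cost <- sum(abs(ref - right_image[rows, ccols, drop = FALSE]))
    if (cost < best_cost) {  # strict: ties keep the smaller disparity
      best_cost <- cost
      best_d <- d
    }
  }
  if (is.na(best_d)) abort("no candidate window fits in the right image", "bounds_error")
  c(u = u - best_d, v = v)
}

#' Triangulate a 3D point from pixel position and disparity
#'
#' Standard rectified-stereo triangulation: depth is `z = f * b / d`, and the
#' lateral coordinates follow the pinhole model,
#' `x = (u - cx) z / f`, `y = (v - cy) z / f`. Units are centimetres
#' because the baseline is given in centimetres.
#'
#' @param pixel `(u, v)` left-image pixel, 0-based.
#' @param disparity disparity in pixels; must be strictly positive.
#' @param intrinsics a [camera_intrinsics()] object.
#' @return Numeric `(x, y, z)` in cm, optical-camera frame.
#' @examples
#' K <- camera_intrinsics(1000, 960, 540, 11)
#' triangulate(c(960, 540), 110, K)  # on the optical axis, 100 cm away
#' @export
triangulate <- function(pixel, disparity, intrinsics) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  if (disparity <= 0) {
    abort("non-positive disparity gives no finite depth", "degenerate_depth")
  }
  z <- intrinsics$f * intrinsics$baseline / disparity
  c(x = (pixel[1] - intrinsics$cx) * z / intrinsics$f,
    y = (pixel[2] - intrinsics$cy) * z / intrinsics$f,
    z = z)
}

#' Project an optical-frame 3D point back to the image
#'
#' Inverse of [triangulate()] for the pinhole part: `u = f x / z + cx`,
#' `v = f y / z + cy`. Used for round-trip checks and overlap detection.
#'
#' @param point `(x, y, z)` in cm with `z > 0`.
#' @param intrinsics a [camera_intrinsics()] object.
#' @return Pixel `(u, v)`, possibly fractional.
#' @export
project_to_image <- function(point, intrinsics) {
  if (point[3] <= 0) abort("point must have positive depth", "degenerate_depth")
  c(u = intrinsics$f * point[1] / point[3] + intrinsics$cx,
    v = intrinsics$f * point[2] / point[3] + intrinsics$cy)
}
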