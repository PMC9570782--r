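#' Imaging-sonar geometry
#'
#' Describes how a 2D imaging-sonar frame maps into the world: the
#' transducer's tilt and beam-spread angles, the physical footprint of one
#' sonar pixel, and the device position. The sonar image is treated as a
#' vertical fan slice: every pixel's 3D point shares the device's
#' y-coordinate, so the elevation ambiguity of a 2D sonar is accepted rather
#' than modelled.
#'
#' @param tilt transducer tilt angle in radians, in `[0, pi/2)`.
#' @param spread beam spreading angle in radians, non-negative.
#' @param pixel_w,pixel_h physical size of one sonar pixel in cm
#'   (width along the range axis, height along the depth axis).
#' @param device_position `(x, y, z)` of the transducer in world cm;
#'   the world origin convention puts the device at depth `d` so `y = 0`
#'   by default.
#' @param image_shape `(cols, rows)` of the sonar frame in pixels.
#' @return An object of class `sonar_geometry`.
#' @examples
#' sonar_geometry(tilt = deg2rad(20), spread = deg2rad(10),
#'                pixel_w = 630 / 1080, pixel_h = 600 / 1092,
#'                device_position = c(630, 0, 0), image_shape = c(1080, 1092))
#' @export
sonar_geometry <- function(tilt = 0, spread = 0, pixel_w, pixel_h,
                           device_position = c(0, 0, 0),
                           image_shape = NULL) {
  if (pixel_w <= 0 || pixel_h <= 0) abort("pixel size must be positive", "domain_error")
  if (tilt < 0 || tilt >= pi / 2) abort("tilt must lie in [0, pi/2)", "domain_error")
  if (spread < 0) abort("spread must be non-negative", "domain_error")
  structure(
    list(tilt = tilt, spread = spread, w = pixel_w, h = pixel_h,
         device_position = as.numeric(device_position),
         image_shape = if (!is.null(image_shape)) as.integer(image_shape)),
    class = "sonar_geometry"
  )
}

#' @export
print.sonar_geometry <- function(x, ...) {
  cat(sprintf(paste0("sonar_geometry: tilt %.3f rad, spread %.3f rad, ",
                     "pixel %.4g x %.4g cm, device at (%g, %g, %g)\n"),
              x$tilt, x$spread, x$w, x$h,
              x$device_position[1], x$device_position[2], x$device_position[3]))
  invisible(x)
}

#' Build sonar geometry from a JSON device config
#'
#' Config keys: `tilt_deg`, `spread_deg`, `pond_length_cm`, `pond_width_cm`,
#' `image_cols`, `image_rows`, `device_x_cm`, `device_depth_cm`. Angles are
#' given in degrees (the `_deg` suffix makes the unit explicit) and converted
#' to radians; pixel sizes are derived with [pixel_physical_size()].
#'
#' @param path path to a JSON file.
#' @return A [sonar_geometry()] object.
#' @export
read_sonar_geometry <- function(path) {
  cfg <- read_config(path, required = c(
    "tilt_deg", "spread_deg", "pond_length_cm", "pond_width_cm",
    "image_cols", "image_rows", "device_x_cm", "device_depth_cm"))
  px <- pixel_physical_size(c(cfg$pond_length_cm, cfg$pond_width_cm),
                            c(cfg$image_cols, cfg$image_rows))
  sonar_geometry(tilt = deg2rad(cfg$tilt_deg), spread = deg2rad(cfg$spread_deg),
                 pixel_w = px[1], pixel_h = px[2],
                 device_position = c(cfg$device_x_cm, 0, 0),
                 image_shape = c(cfg$image_cols, cfg$image_rows))
}

#' Spherical to Cartesian coordinates
#'
#' A sonar return at range `r`, azimuth `theta` and elevation `phi` has
#' Cartesian position `(r cos(theta) cos(phi), r sin(theta) cos(phi),
#' r sin(phi))`.
#'
#' @param r range, cm, non-negative.
#' @param azimuth,elevation angles in radians.
#' @return Numeric `(x, y, z)`.
#' @export
spherical_to_cartesian <- function(r, azimuth, elevation) {
  if (any(r < 0)) abort("range must be non-negative", "domain_error")
  c(x = r * cos(azimuth) * cos(elevation),
    y = r * sin(azimuth) * cos(elevation),
    z = r * sin(elevation))
}

#' Projection of a beam direction onto the sonar image plane
#'
#' The 2D sonar image discards elevation: a return at range `r` and azimuth
#' `theta` lands at plane coordinates `(r cos(theta), r sin(theta))`
#' regardless of its elevation angle. This is why target height cannot be
#' read off a single 2D sonar frame.
#'
#' @param r range, cm, non-negative.
#' @param azimuth azimuth angle, radians.
#' @return Numeric `(u, v)` plane coordinates in cm.
#' @export
project_to_sonar_plane <- function(r, azimuth) {
  if (any(r < 0)) abort("range must be non-negative", "domain_error")
  c(u = r * cos(azimuth), v = r * sin(azimuth))
}

#' Critical point of an acoustic beam in sonar-local coordinates
#'
#' The critical point is the shortest-range point at which a beam reflects
#' off the target. For a beam with critical range `r_cp` and azimuth
#' `theta_cp`, on a transducer tilted by `t` with spreading angle `s`, its
#' local position is
#' `x = r sqrt(1 - sin^2((t+s)/2) - sin^2(theta))`, `y = r sin(theta)`,
#' `z = r sin((t+s)/2)`.
#'
#' @param r_cp critical range, cm.
#' @param theta_cp beam azimuth, radians.
#' @param geometry a [sonar_geometry()] (supplies tilt and spread).
#' @return Numeric `(x, y, z)` in the sonar-local frame.
#' @export
critical_point_local <- function(r_cp, theta_cp, geometry) {
  stopifnot(inherits(geometry, "sonar_geometry"))
  half <- (geometry$tilt + geometry$spread) / 2
  radicand <- 1 - sin(half)^2 - sin(theta_cp)^2
  if (radicand < 0) {
    abort("tilt/spread and azimuth leave no feasible critical point (negative radicand)",
          "geometry_infeasible")
  }
  c(x = r_cp * sqrt(radicand), y = r_cp * sin(theta_cp), z = r_cp * sin(half))
}

#' Rotation matrix from roll/pitch/yaw Euler angles
#'
#' Composes `R = Rz(yaw) %*% Ry(pitch) %*% Rx(roll)`; this order is fixed
#' and no alternative Euler conventions are supported.
#'
#' @param roll,pitch,yaw angles in radians.
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @export
euler_rotation_matrix <- function(roll = 0, pitch = 0, yaw = 0) {
  cr <- cos(roll); sr <- sin(roll)
  cp <- cos(pitch); sp <- sin(pitch)
  cy <- cos(yaw); sy <- sin(yaw)
  rx <- matrix(c(1, 0, 0, 0, cr, sr, 0, -sr, cr), 3, 3)
  ry <- matrix(c(cp, 0, -sp, 0, 1, 0, sp, 0, cp), 3, 3)
  rz <- matrix(c(cy, sy, 0, -sy, cy, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

#' Sonar-local point to world coordinates
#'
#' `world = device_position + R %*% point`, with `R` either a rotation
#' matrix or roll/pitch/yaw angles passed as a length-3 vector
#' `(roll, pitch, yaw)`.
#'
#' @param point `(x, y, z)` in the sonar-local frame, cm.
#' @param rotation 3x3 rotation matrix or numeric `(roll, pitch, yaw)`.
#' @param geometry a [sonar_geometry()] (supplies the device position).
#' @return Numeric `(x, y, z)` in world cm.
#' @export
local_to_world <- function(point, rotation, geometry) {
  stopifnot(inherits(geometry, "sonar_geometry"))
  R <- if (is.matrix(rotation)) rotation else
    euler_rotation_matrix(rotation[1], rotation[2], rotation[3])
  out <- geometry$device_position + as.numeric(R %*% as.numeric(point))
  c(x = out[1], y = out[2], z = out[3])
}

#' World 3D position of a sonar pixel
#'
#' Under the vertical-fan-slice model, pixel `(u, v)` (0-based, origin
#' top-left) maps to `(x_S - u w, y_S, v h)`: columns run against the world
#' x-axis away from the device, rows run down with depth, and every pixel
#' shares the device's y-coordinate.
#'
#' @param pixel `(u, v)` sonar pixel, 0-based.
#' @param geometry a [sonar_geometry()] with `image_shape` set.
#' @return Numeric `(x, y, z)` in world cm.
#' @export
sonar_pixel_to_3d <- function(pixel, geometry) {
  stopifnot(inherits(geometry, "sonar_geometry"))
  u <- pixel[1]; v <- pixel[2]
  if (!is.null(geometry$image_shape)) {
    if (u < 0 || v < 0 || u > geometry$image_shape[1] || v > geometry$image_shape[2]) {
      abort(sprintf("pixel (%g, %g) outside sonar image bounds", u, v), "bounds_error")
    }
  }
  dp <- geometry$device_position
  c(x = dp[1] - u * geometry$w, y = dp[2], z = v * geometry$h)
}

#' Inverse of [sonar_pixel_to_3d()]: world point to sonar pixel
#'
#' `u = (x_S - x) / w`, `v = z / h`. Fractional pixels are returned; callers
#' round as needed.
#'
#' @param point `(x, y, z)` world cm.
#' @param geometry a [sonar_geometry()].
#' @return Numeric `(u, v)`, possibly fractional.
#' @export
world_to_sonar_pixel <- function(point, geometry) {
  stopifnot(inherits(geometry, "sonar_geometry"))
  c(u = (geometry$device_position[1] - point[1]) / geometry$w,
    v = point[3] / geometry$h)
}

#' Physical footprint of one sonar pixel
#'
#' Divides the imaged pond extent by the image shape:
#' `w = length_cm / cols`, `h = width_cm / rows`. For the reference setup of
#' a 630 cm pond length imaged over 1080 columns this gives 0.583 cm.
#'
#' @param pond_extent `(length_cm, width_cm)` of the imaged area.
#' @param image_shape `(cols, rows)` of the sonar frame.
#' @return Numeric `(w, h)` in cm.
#' @examples
#' pixel_physical_size(c(630, 600), c(1080, 1092))
#' @export
pixel_physical_size <- function(pond_extent, image_shape) {
  if (any(pond_extent <= 0) || any(image_shape <= 0)) {
    abort("pond extent and image shape must be positive", "domain_error")
  }
  c(w = pond_extent[1] / image_shape[1], h = pond_extent[2] / image_shape[2])
}
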