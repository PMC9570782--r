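#' Rigid transform between the sonar and optical 3D frames
#'
#' A rotation matrix plus translation vector mapping sonar-frame points into
#' the optical-camera frame: `p_O = R %*% p_S + T`.
#'
#' @param R 3x3 rotation matrix; must be orthonormal with determinant +1.
#' @param T length-3 translation in cm.
#' @param check validate orthonormality (default TRUE).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(R, T = c(0, 0, 0), check = TRUE) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3L, 3L))) abort("R must be 3x3", "domain_error")
  if (check) {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6) {
      abort("R is not a proper rotation (orthonormal, det +1)", "domain_error")
    }
  }
  structure(list(R = R, T = as.numeric(T)), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\nR =\n")
  print(round(x$R, 6))
  cat("T =", paste(round(x$T, 4), collapse = ", "), "cm\n")
  invisible(x)
}

#' Matched 3D point sets from one calibration frame
#'
#' Pairs the sonar-frame and optical-frame 3D positions of the same physical
#' markers (typically four: A, B, C, D) observed in one synchronized frame.
#'
#' @param sonar_points,optical_points n x 3 matrices of corresponding points
#'   (equal row counts, n >= 3 recommended per frame).
#' @param frame_id optional identifier.
#' @return An object of class `matched_point_set`.
#' @export
matched_point_set <- function(sonar_points, optical_points, frame_id = NA) {
  s <- as_point_matrix(sonar_points)
  o <- as_point_matrix(optical_points)
  if (nrow(s) != nrow(o)) {
    abort("sonar and optical point sets must have equal length", "format_error")
  }
  if (nrow(s) < 1L) abort("a matched point set cannot be empty", "empty_input")
  structure(list(sonar = s, optical = o, frame_id = frame_id),
            class = "matched_point_set")
}

as_match_list <- function(matches) {
  if (inherits(matches, "matched_point_set")) return(list(matches))
  if (!is.list(matches) || !all(vapply(matches, inherits, TRUE, "matched_point_set"))) {
    abort("matches must be a matched_point_set or a list of them", "format_error")
  }
  matches
}

stack_matches <- function(matches) {
  matches <- as_match_list(matches)
  if (!length(matches)) abort("no matched points", "empty_input")
  list(sonar = do.call(rbind, lapply(matches, `[[`, "sonar")),
       optical = do.call(rbind, lapply(matches, `[[`, "optical")))
}

#' Estimate the sonar-to-optical rigid transform from matched markers
#'
#' Solves for the rotation and translation minimising the mean squared
#' residual `mean ||p_O - (R p_S + T)||^2` over all marker correspondences,
#' pooled across calibration frames. The solution is the closed-form
#' orthogonal-Procrustes/Kabsch estimate: subtract centroids, take the SVD
#' of the cross-covariance, and correct a possible reflection so that
#' `det(R) = +1`. With `allow_scale = TRUE` a similarity transform is
#' estimated instead (one isotropic scale factor); a full 12-dof affine fit
#' is deliberately not offered.
#'
#' @param matches a [matched_point_set()] or list of them.
#' @param allow_scale estimate an isotropic scale as well (default FALSE).
#' @return A [rigid_transform()]; when `allow_scale` is TRUE it carries a
#'   `scale` element and `R` is the scaled rotation applied as `s R p + T`.
#' @examples
#' scn <- gen_calibration_scene(n_frames = 3, noise_sd = 0, seed = 1)
#' fit <- solve_transform(scn$matches)
#' fusion_loss(fit, scn$matches)  # ~0 on noiseless markers
#' @export
solve_transform <- function(matches, allow_scale = FALSE) {
  pooled <- stack_matches(matches)
  s <- pooled$sonar; o <- pooled$optical
  if (nrow(s) < 3L) abort("need at least 3 matched points", "insufficient_data")
  cs <- colMeans(s); co <- colMeans(o)
  sc <- sweep(s, 2, cs); oc <- sweep(o, 2, co)
  sv <- svd(crossprod(sc, oc))  # 3x3 cross-covariance H = Sc' Oc
  if (sv$d[2] < max(sv$d[1], 1) * 1e-10) {
    abort("marker configuration is collinear or degenerate; rotation unidentifiable",
          "rank_deficient")
  }
  # R = V S U' with S correcting a reflection
  sgn <- sign(det(sv$v %*% t(sv$u)))
  S <- diag(c(1, 1, sgn))
  R <- sv$v %*% S %*% t(sv$u)
  scale <- 1
  if (allow_scale) {
    scale <- sum(sv$d * c(1, 1, sgn)) / sum(sc^2)
  }
  out <- rigid_transform(R, co - scale * as.numeric(R %*% cs), check = TRUE)
  if (allow_scale) {
    out$R <- scale * out$R
    out$scale <- scale
  }
  out
}

#' Mean squared registration residual
#'
#' `mean ||p_O - (R p_S + T)||^2` over every marker in every frame, in cm^2.
#' This is the quantity [solve_transform()] minimises.
#'
#' @param transform a [rigid_transform()].
#' @param matches a [matched_point_set()] or list of them.
#' @return Scalar loss in cm^2.
#' @export
fusion_loss <- function(transform, matches) {
  pooled <- stack_matches(matches)
  if (nrow(pooled$sonar) == 0L) abort("no matched points", "empty_input")
  pred <- apply_transform(pooled$sonar, transform)
  mean(rowSums((pooled$optical - pred)^2))
}

#' Apply a rigid transform to points
#'
#' @param points a point `(x, y, z)` or n x 3 matrix.
#' @param transform a [rigid_transform()].
#' @return Points in the target frame, same shape as the input.
#' @export
apply_transform <- function(points, transform) {
  p <- as_point_matrix(points)
  out <- p %*% t(transform$R)
  out <- sweep(out, 2, transform$T, `+`)
  colnames(out) <- c("x", "y", "z")
  if (is.null(dim(points))) out[1, ] else out
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return The inverse transform.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$R)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$T), check = FALSE)
}

#' Detect the sonar/optical overlap region and its sonar bounding box
#'
#' Maps each sonar-frame 3D point into the optical frame with the calibrated
#' transform and keeps those that fall inside the optical camera's field of
#' view (positive depth and pinhole projection inside the optical image).
#' The kept points are then mapped back to sonar pixels by inverting the
#' pixel-to-world model (`u = (x_S - x)/w`, `v = z/h`) and the axis-aligned
#' bounding box over those pixels, `x_lu = (min u, min v)`,
#' `x_rb = (max u, max v)`, crops the sonar image to the jointly observed
#' area.
#'
#' @param sonar_points n x 3 matrix of sonar-frame world points.
#' @param transform the sonar-to-optical [rigid_transform()].
#' @param intrinsics optical [camera_intrinsics()].
#' @param image_shape `(cols, rows)` of the optical image.
#' @param geometry the [sonar_geometry()] used for the back-mapping.
#' @return An object of class `overlap_result` with elements `points`
#'   (kept sonar-frame points), `pixels` (their sonar pixel coordinates),
#'   `bbox` (list `x_lu`, `x_rb`, integer pixels) and `n`. When no point
#'   overlaps, `n` is 0 and `bbox` is NULL: an empty-overlap signal, not an
#'   error.
#' @export
detect_overlap <- function(sonar_points, transform, intrinsics, image_shape,
                           geometry) {
  pts <- as_point_matrix(sonar_points)
  if (nrow(pts) == 0L) abort("sonar point cloud is empty", "empty_input")
  po <- apply_transform(pts, transform)
  u <- intrinsics$f * po[, 1] / po[, 3] + intrinsics$cx
  v <- intrinsics$f * po[, 2] / po[, 3] + intrinsics$cy
  keep <- po[, 3] > 0 & u >= 0 & u < image_shape[1] & v >= 0 & v < image_shape[2]
  if (!any(keep)) {
    return(structure(list(points = pts[0, , drop = FALSE],
                          pixels = NULL, bbox = NULL, n = 0L),
                     class = "overlap_result"))
  }
  kept <- pts[keep, , drop = FALSE]
  su <- (geometry$device_position[1] - kept[, 1]) / geometry$w
  sv_ <- kept[, 3] / geometry$h
  clamp <- function(x, hi) pmin(pmax(round(x), 0), hi)
  shape <- geometry$image_shape %||% c(Inf, Inf)
  bbox <- list(
    x_lu = c(u = clamp(min(su), shape[1] - 1), v = clamp(min(sv_), shape[2] - 1)),
    x_rb = c(u = clamp(max(su), shape[1] - 1), v = clamp(max(sv_), shape[2] - 1)))
  structure(list(points = kept, pixels = cbind(u = su, v = sv_),
                 bbox = bbox, n = sum(keep)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  if (x$n == 0L) {
    cat("overlap_result: no overlapping points\n")
  } else {
    cat(sprintf("overlap_result: %d points, bbox (%g, %g) - (%g, %g)\n",
                x$n, x$bbox$x_lu[1], x$bbox$x_lu[2], x$bbox$x_rb[1], x$bbox$x_rb[2]))
  }
  invisible(x)
}

#' Build matched point sets from a marker correspondence table
#'
#' The table carries one row per marker per frame with columns `frame_id`,
#' `marker_label`, `sonar_u`, `sonar_v`, `left_u`, `left_v`, `right_u`,
#' `right_v` (pixel coordinates, 0-based). Sonar 3D points come from
#' [sonar_pixel_to_3d()]; optical 3D points from stereo disparity and
#' [triangulate()].
#'
#' @param markers data frame as above, or a CSV path.
#' @param geometry a [sonar_geometry()].
#' @param intrinsics a [camera_intrinsics()].
#' @param epipolar_tol passed to [compute_disparity()].
#' @return A list of [matched_point_set()], one per frame.
#' @export
markers_to_matches <- function(markers, geometry, intrinsics, epipolar_tol = 0) {
  if (is.character(markers)) {
    markers <- utils::read.csv(markers, stringsAsFactors = FALSE)
  }
  need <- c("frame_id", "sonar_u", "sonar_v", "left_u", "left_v", "right_u", "right_v")
  missing <- setdiff(need, names(markers))
  if (length(missing)) {
    abort(paste("marker table is missing columns:", paste(missing, collapse = ", ")),
          "format_error")
  }
  lapply(split(markers, markers$frame_id), function(fr) {
    s3d <- t(apply(fr[, c("sonar_u", "sonar_v")], 1, sonar_pixel_to_3d,
                   geometry = geometry))
    o3d <- t(mapply(function(lu, lv, ru, rv) {
      d <- compute_disparity(c(lu, lv), c(ru, rv), epipolar_tol = epipolar_tol)
      triangulate(c(lu, lv), d, intrinsics)
    }, fr$left_u, fr$left_v, fr$right_u, fr$right_v))
    matched_point_set(s3d, o3d, frame_id = fr$frame_id[1])
  })
}

#' Serialize a rigid transform to JSON
#' @param transform a [rigid_transform()].
#' @param path output file.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(
    list(R = transform$R, T = transform$T,
         scale = transform$scale %||% 1),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read a rigid transform from JSON written by [write_transform()]
#' @param path JSON file.
#' @return A [rigid_transform()].
#' @export
read_transform <- function(path) {
  obj <- jsonlite::fromJSON(path)
  tr <- rigid_transform(as.matrix(obj$R), obj$T,
                        check = is.null(obj$scale) || obj$scale == 1)
  if (!is.null(obj$scale) && obj$scale != 1) tr$scale <- obj$scale
  tr
}
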