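test_that("identity correspondences yield the identity transform", {
  set.seed(21)
  pts <- matrix(runif(12, 0, 100), 4, 3)
  fit <- solve_transform(matched_point_set(pts, pts))
  expect_equal(fit$R, diag(3), tolerance = 1e-12)
  expect_equal(fit$T, c(0, 0, 0), tolerance = 1e-10)
})

test_that("a known rigid transform is recovered to 1e-9 from noiseless markers", {
  set.seed(22)
  true <- rigid_transform(euler_rotation_matrix(yaw = deg2rad(30)), c(5, -2, 1))
  scn <- gen_calibration_scene(n_frames = 4, noise_sd = 0, transform = true, seed = 22)
  fit <- solve_transform(scn$matches)
  expect_lt(sqrt(sum((fit$R - true$R)^2)), 1e-9)   # Frobenius error
  expect_lt(sqrt(sum((fit$T - true$T)^2)), 1e-9)
})

test_that("noisy registration beats the generating transform in loss, residual near sigma", {
  sigma <- 0.5
  scn <- gen_calibration_scene(n_frames = 10, n_markers = 4, noise_sd = sigma, seed = 23)
  fit <- solve_transform(scn$matches)
  loss_fit <- fusion_loss(fit, scn$matches)
  loss_true <- fusion_loss(scn$transform, scn$matches)
  expect_lte(loss_fit, loss_true)
  # per-axis residual RMS: sqrt(loss / 3) estimates sigma
  expect_equal(sqrt(loss_fit / 3), sigma, tolerance = 0.25)
})

test_that("the solver is invariant to relabelling corresponding pairs", {
  scn <- gen_calibration_scene(n_frames = 2, n_markers = 6, noise_sd = 0.3, seed = 24)
  fit1 <- solve_transform(scn$matches)
  perm <- sample(6)
  shuffled <- lapply(scn$matches, function(m) {
    matched_point_set(m$sonar[perm, ], m$optical[perm, ], m$frame_id)
  })
  fit2 <- solve_transform(shuffled)
  expect_equal(fit1$R, fit2$R, tolerance = 1e-12)
  expect_equal(fit1$T, fit2$T, tolerance = 1e-12)
})

test_that("collinear markers raise a rank-deficiency error", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(solve_transform(matched_point_set(line, line + 1)),
               class = "rank_deficient")
})

test_that("fusion loss matches trivial cases and a naive loop oracle", {
  set.seed(25)
  pts <- matrix(runif(30, -50, 50), 10, 3)
  tr <- rigid_transform(euler_rotation_matrix(0.2, -0.1, 0.4), c(3, 4, 5))
  exact <- matched_point_set(pts, apply_transform(pts, tr))
  expect_equal(fusion_loss(tr, exact), 0, tolerance = 1e-20)
  shifted <- matched_point_set(pts, sweep(pts, 2, c(1, 0, 0), `+`))
  expect_equal(fusion_loss(rigid_transform(diag(3)), shifted), 1.0)
  noisy <- matched_point_set(pts, apply_transform(pts, tr) +
                                    matrix(rnorm(30), 10, 3))
  expect_equal(fusion_loss(tr, noisy), brute_force_fusion_loss(tr, noisy),
               tolerance = 1e-12)
  expect_error(fusion_loss(tr, list()), class = "empty_input")
})

test_that("apply/invert compose to the identity", {
  set.seed(26)
  tr <- rigid_transform(euler_rotation_matrix(0.5, 0.3, -0.8), c(10, -5, 2))
  pts <- matrix(runif(21, -100, 100), 7, 3)
  expect_equal(apply_transform(pts, rigid_transform(diag(3))), pts,
               ignore_attr = TRUE)
  round_trip <- apply_transform(apply_transform(pts, tr), invert_transform(tr))
  expect_equal(round_trip, pts, tolerance = 1e-12, ignore_attr = TRUE)
  # matrix-product oracle
  p1 <- as.numeric(tr$R %*% pts[1, ] + tr$T)
  expect_equal(unname(apply_transform(pts[1, ], tr)), p1)
})

test_that("similarity mode recovers an isotropic scale", {
  set.seed(27)
  pts <- matrix(runif(30, -50, 50), 10, 3)
  tr <- rigid_transform(euler_rotation_matrix(yaw = 0.7), c(1, 2, 3))
  scaled <- sweep(pts %*% t(tr$R) * 1.8, 2, tr$T, `+`)
  fit <- solve_transform(matched_point_set(pts, scaled), allow_scale = TRUE)
  expect_equal(fit$scale, 1.8, tolerance = 1e-9)
})

test_that("overlap detection keeps in-frustum points and boxes their sonar pixels", {
  geom <- sonar_geometry(pixel_w = 1, pixel_h = 1, device_position = c(100, 0, 0),
                         image_shape = c(100, 100))
  K <- camera_intrinsics(50, 50, 50, 11)
  grid <- expand.grid(u = seq(0, 99, by = 3), v = seq(0, 99, by = 3))
  pts <- t(apply(grid, 1, sonar_pixel_to_3d, geometry = geom))
  # camera 150 cm in front of the fan plane, looking back along +y
  tr <- rigid_transform(euler_rotation_matrix(roll = -pi / 2),
                        c(-50, -40, 150))
  ov <- detect_overlap(pts, tr, K, c(100, 100), geom)
  expect_gt(ov$n, 0)
  # exhaustive per-point oracle
  keep <- apply(pts, 1, function(p) {
    q <- as.numeric(tr$R %*% p + tr$T)
    if (q[3] <= 0) return(FALSE)
    u <- K$f * q[1] / q[3] + K$cx; v <- K$f * q[2] / q[3] + K$cy
    u >= 0 && u < 100 && v >= 0 && v < 100
  })
  expect_identical(ov$n, sum(keep))
  su <- (100 - pts[keep, 1]) / 1; sv <- pts[keep, 3] / 1
  expect_equal(unname(ov$bbox$x_lu), round(c(min(su), min(sv))))
  expect_equal(unname(ov$bbox$x_rb), round(c(max(su), max(sv))))
})

test_that("full overlap and single-point overlap produce tight boxes", {
  geom <- sonar_geometry(pixel_w = 1, pixel_h = 1, device_position = c(10, 0, 0),
                         image_shape = c(10, 10))
  K <- camera_intrinsics(5, 50, 50, 11)
  pts <- t(apply(expand.grid(u = 0:9, v = 0:9), 1, sonar_pixel_to_3d,
                 geometry = geom))
  # push everything far in front of the camera: all points project near centre
  tr <- rigid_transform(diag(3), c(0, 0, 1000))
  ov <- detect_overlap(pts, tr, K, c(100, 100), geom)
  expect_identical(ov$n, nrow(pts))
  expect_equal(unname(ov$bbox$x_lu), c(0, 0))
  expect_equal(unname(ov$bbox$x_rb), c(9, 9))
  single <- detect_overlap(pts[42, , drop = FALSE], tr, K, c(100, 100), geom)
  expect_identical(single$n, 1L)
  expect_equal(single$bbox$x_lu, single$bbox$x_rb)
})

test_that("no overlap is a signal, not an error", {
  geom <- sonar_geometry(pixel_w = 1, pixel_h = 1, device_position = c(10, 0, 0))
  K <- camera_intrinsics(5, 50, 50, 11)
  behind <- rigid_transform(diag(3), c(0, 0, -1000))
  ov <- detect_overlap(matrix(c(1, 2, 3), 1, 3), behind, K, c(100, 100), geom)
  expect_identical(ov$n, 0L)
  expect_null(ov$bbox)
})

test_that("marker CSV round-trips through geometry into a recoverable transform", {
  geom <- sonar_geometry(pixel_w = 630 / 1080, pixel_h = 600 / 1092,
                         device_position = c(630, 0, 0), image_shape = c(1080, 1092))
  K <- camera_intrinsics(1000, 960, 540, 11)
  true <- rigid_transform(euler_rotation_matrix(0.1, -0.05, 0.6), c(12, 3, 500))
  set.seed(28)
  rows <- do.call(rbind, lapply(1:3, function(fr) {
    do.call(rbind, lapply(1:4, function(mk) {
      spx <- c(runif(1, 100, 900), runif(1, 100, 900))
      s3d <- sonar_pixel_to_3d(spx, geom)
      o3d <- as.numeric(true$R %*% s3d + true$T)  # z stays positive: T_z = 500
      lp <- project_to_image(o3d, K)
      d <- K$f * K$baseline / o3d[3]
      data.frame(frame_id = fr, marker_label = LETTERS[mk],
                 sonar_u = spx[1], sonar_v = spx[2],
                 left_u = lp[1], left_v = lp[2],
                 right_u = lp[1] - d, right_v = lp[2])
    }))
  }))
  matches <- markers_to_matches(rows, geom, K)
  expect_length(matches, 3)
  # optical points were re-derived via disparity; they must match the
  # constructed 3D points, so the fit recovers a transform with low residual
  fit <- solve_transform(matches)
  expect_lt(fusion_loss(fit, matches), 1e-12)
})

test_that("transforms serialize to JSON and back", {
  tr <- rigid_transform(euler_rotation_matrix(0.3, 0.2, 0.1), c(1.5, -2.25, 0))
  path <- withr::local_tempfile(fileext = ".json")
  write_transform(tr, path)
  back <- read_transform(path)
  expect_equal(back$R, tr$R, tolerance = 1e-12)
  expect_equal(back$T, tr$T, tolerance = 1e-12)
})
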