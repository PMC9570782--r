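test_that("generators are bit-reproducible under a fixed seed", {
  a <- gen_population(n = 100, seed = 71)
  b <- gen_population(n = 100, seed = 71)
  expect_identical(a, b)
  fa <- gen_feeding_sequence(n_frames = 8, seed = 72)
  fb <- gen_feeding_sequence(n_frames = 8, seed = 72)
  expect_identical(fa, fb)
  ca <- gen_calibration_scene(seed = 73)
  cb <- gen_calibration_scene(seed = 73)
  expect_identical(ca, cb)
  ma <- gen_instance_masks(a$lengths[1:20], frame_shape = c(128, 128), seed = 74)
  mb <- gen_instance_masks(b$lengths[1:20], frame_shape = c(128, 128), seed = 74)
  expect_identical(ma, mb)
})

test_that("population weights follow the allometric law", {
  pop <- gen_population(n = 50, mean_length = 22, sd_length = 0.001,
                        a = 0.0269, b = 3, weight_noise_sd = 0, seed = 75)
  expect_equal(pop$weights, 0.0269 * pop$lengths^3, tolerance = 1e-12)
  big <- gen_population(n = 5000, mean_length = 22, sd_length = 2, seed = 76)
  expect_lt(abs(mean(big$lengths) - 22), 3 * 2 / sqrt(5000))
  expect_true(all(big$lengths > 0))
  expect_true(all(gen_population(n = 2000, mean_length = 1, sd_length = 3,
                                 seed = 77)$lengths > 0))  # hard truncation regime
})

test_that("contamination labels partition the observed set with the set fractions", {
  pop <- gen_population(n = 1000, seed = 78)
  cont <- contaminate_lengths(pop$lengths, 0.2, 0.1, seed = 79)
  expect_length(cont$observed, 1000)
  expect_identical(as.integer(table(cont$label)), c(700L, 200L, 100L))
  merged <- cont$label == "merged"
  expect_true(all(cont$observed[merged] >
                    apply(cont$merged_parents[merged, ], 1, max)))
  expect_error(contaminate_lengths(pop$lengths, 0.6, 0.5), class = "domain_error")
})

test_that("noiseless calibration scenes are exactly recoverable", {
  scn <- gen_calibration_scene(n_frames = 6, noise_sd = 0, seed = 80)
  fit <- solve_transform(scn$matches)
  expect_lt(max(abs(fit$R - scn$transform$R)), 1e-9)
  expect_lt(max(abs(fit$T - scn$transform$T)), 1e-9)
})

test_that("noisy scenes leave a residual RMS near the generator sigma", {
  sigma <- 1.5
  scn <- gen_calibration_scene(n_frames = 20, noise_sd = sigma, seed = 81)
  fit <- solve_transform(scn$matches)
  expect_equal(sqrt(fusion_loss(fit, scn$matches) / 3), sigma, tolerance = 0.2)
})

test_that("coplanar but non-collinear markers are solvable", {
  set.seed(82)
  tr <- rigid_transform(euler_rotation_matrix(0.2, 0.1, -0.4), c(5, 5, 5))
  s <- cbind(runif(4, 0, 100), runif(4, 0, 100), 0)  # z = 0 plane
  m <- matched_point_set(s, apply_transform(s, tr))
  fit <- solve_transform(m)
  expect_lt(max(abs(fit$R - tr$R)), 1e-9)
})

test_that("uncontaminated masks round-trip their drawn lengths within a pixel", {
  set.seed(83)
  lengths <- rnorm(30, 22, 2)
  inst <- gen_instance_masks(lengths, frame_shape = c(128, 128),
                             pixel_size = c(0.583, 0.549),
                             frac_merged = 0, frac_partial = 0, seed = 83)
  measured <- vapply(inst$masks, mask_length, 0, pixel_size = c(0.583, 0.549))
  expect_equal(measured, inst$gt_length, tolerance = 1e-9)
  # drawn length matches the intended length to within one pixel footprint
  expect_true(all(abs(inst$gt_length - inst$intended_length) <= 0.583 + 1e-9))
})

test_that("fish longer than the frame raise a placement error", {
  expect_error(gen_instance_masks(500, frame_shape = c(64, 64),
                                  pixel_size = c(0.5, 0.5),
                                  frac_merged = 0, frac_partial = 0, seed = 84),
               class = "placement_error")
})

test_that("the feeding generator inverts exactly through the quantity chain", {
  fs <- gen_feeding_sequence(n_frames = 14, count_noise = 0, seed = 85)
  gt <- ground_truth_detectors(fs)
  qs <- run_quantity_pipeline(fs$frames, fs$l_fish, fs$theta, fs$dx, fs$dy,
                              classify = gt$classify, segment = gt$segment)
  stored <- fs$frame_count[qs$estimates$frame_id]
  expect_equal(qs$estimates$n_fish, stored, tolerance = 1e-12)
})

test_that("fallback detectors reproduce the generator's gathering flags without noise", {
  fs <- gen_feeding_sequence(n_frames = 18, seed = 86)
  flags <- vapply(3:16, function(i) {
    classify_gathering_fallback(build_frame_stack(fs$frames, i))
  }, TRUE)
  expect_identical(flags, fs$gathering[3:16])
})

test_that("count bias grows smoothly with speckle noise", {
  bias_at <- function(s) {
    fs <- gen_feeding_sequence(n_frames = 14, count_noise = 0, speckle_sd = s,
                               seed = 87)
    qs <- run_quantity_pipeline(fs$frames, fs$l_fish, fs$theta, fs$dx, fs$dy)
    abs(qs$mean - fs$true_count) / fs$true_count
  }
  b <- vapply(c(0, 0.05, 0.15), bias_at, 0)
  expect_lt(b[1], 0.01)        # noiseless: near-exact recovery
  expect_gt(b[3], b[1])        # heavy speckle visibly degrades the estimate
  expect_lt(b[2], 0.5)         # mild speckle stays usable
})
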