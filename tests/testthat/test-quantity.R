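make_region <- function(values, mask = values > 0) {
  fish_region_frame(mask, values)
}

test_that("school density is the region-normalised mean pixel value", {
  vals <- matrix(0, 10, 10)
  vals[3:6, 3:6] <- 0.8
  expect_equal(fish_density(make_region(vals)), 1)  # saturated: all at g_max

  vals2 <- matrix(0, 10, 10)
  vals2[1, 1:4] <- c(0.9, 0.9, 0, 0)
  region <- fish_region_frame(matrix(c(rep(TRUE, 4), rep(FALSE, 96)), 10, 10,
                                     byrow = TRUE), vals2)
  expect_equal(fish_density(region), 0.5)  # half at g_max, half zero

  set.seed(61)
  vals3 <- matrix(runif(400), 20, 20)
  mask3 <- matrix(runif(400) < 0.3, 20, 20)
  mask3[1, 1] <- TRUE
  region3 <- fish_region_frame(mask3, vals3)
  g <- vals3[mask3]
  expect_equal(fish_density(region3), sum(g) / (max(g) * length(g)),
               tolerance = 1e-12)
  # fixed full-scale normalisation as the config alternative
  expect_equal(fish_density(region3, use_dtype_max = TRUE, dtype_max = 1),
               mean(g), tolerance = 1e-12)
})

test_that("area and depth follow the slant-beam projection", {
  vals <- matrix(0, 50, 50); vals[10:19, 11:20] <- 1  # 100 px, bottom row 19 (1-based)
  r <- make_region(vals)
  ad0 <- region_area_depth(r, 1, 1, 0)
  expect_equal(unname(ad0), c(100, 0))
  ad60 <- region_area_depth(r, 1, 1, deg2rad(60))
  expect_equal(ad60[["A"]], 50.0)
  # scalar oracle at theta = 20 deg, anisotropy 0.5
  vals2 <- matrix(0, 500, 50); vals2[398:401, 3] <- 1
  ad20 <- region_area_depth(make_region(vals2), 0.5, 0.5, deg2rad(20))
  expect_equal(ad20[["A"]], 4 * 0.25 * cos(deg2rad(20)))
  expect_equal(ad20[["d"]], 401 * 0.5 * sin(deg2rad(20)))
  expect_error(region_area_depth(r, 1, 1, pi / 2), class = "domain_error")
})

test_that("the cuboid fish volume is l^3 / 4", {
  expect_equal(fish_volume(2), 2)
  expect_equal(fish_volume(20), 2000)
  expect_equal(fish_volume(14), 8 * fish_volume(7))  # cubic scaling
  expect_error(fish_volume(0), class = "domain_error")
})

test_that("the count is volume times density over per-fish volume", {
  expect_equal(estimate_quantity(2000, 1, 2000), 1)
  expect_equal(estimate_quantity(5000, 0, 2000), 0)
  expect_equal(estimate_quantity(5000, 0.8, 2000), 2 * estimate_quantity(5000, 0.4, 2000))
  expect_error(estimate_quantity(1, 1, 0), class = "domain_error")
})

test_that("the count is invariant to uniform rescaling of region intensities", {
  set.seed(62)
  vals <- matrix(runif(2500, 0, 0.9), 50, 50)
  mask <- matrix(FALSE, 50, 50); mask[20:40, 10:30] <- TRUE
  n1 <- with(frame_quantity_exposed(fish_region_frame(mask, vals)), n_fish)
  n2 <- with(frame_quantity_exposed(fish_region_frame(mask, vals * 0.37)), n_fish)
  expect_equal(n1, n2, tolerance = 1e-12)
})

test_that("enlarging the region never decreases the count", {
  vals <- matrix(0.5, 40, 40)
  vals[25, 25] <- 1
  small <- matrix(FALSE, 40, 40); small[20:25, 20:25] <- TRUE
  big <- small; big[10:25, 10:25] <- TRUE  # same bottom row, same g_max
  n_small <- frame_quantity_exposed(fish_region_frame(small, vals))$n_fish
  n_big <- frame_quantity_exposed(fish_region_frame(big, vals))$n_fish
  expect_gte(n_big, n_small)
})

test_that("pipeline estimates equal the manual four-stage chain per frame", {
  fs <- gen_feeding_sequence(n_frames = 12, seed = 63)
  gt <- ground_truth_detectors(fs)
  qs <- run_quantity_pipeline(fs$frames, fs$l_fish, fs$theta, fs$dx, fs$dy,
                              classify = gt$classify, segment = gt$segment)
  for (row in seq_len(qs$n_gathering)) {
    i <- qs$estimates$frame_id[row]
    region <- fs$regions[[i]]
    delta <- fish_density(region)
    ad <- region_area_depth(region, fs$dx, fs$dy, fs$theta)
    manual <- estimate_quantity(ad[["A"]] * ad[["d"]], delta, fish_volume(fs$l_fish))
    expect_equal(qs$estimates$n_fish[row], manual, tolerance = 1e-12)
  }
})

test_that("an all-dispersing video yields the no-estimate signal", {
  fs <- gen_feeding_sequence(n_frames = 10, gathering_frac = 0, seed = 64)
  fs$gathering[] <- FALSE
  fs$regions <- vector("list", 10)
  gt <- ground_truth_detectors(fs)
  qs <- run_quantity_pipeline(fs$frames, fs$l_fish, fs$theta, fs$dx, fs$dy,
                              classify = gt$classify, segment = gt$segment)
  expect_identical(qs$n_gathering, 0L)
  expect_true(is.na(qs$mean))
})

test_that("summary confidence intervals nest and centre on the mean", {
  fs <- gen_feeding_sequence(n_frames = 24, seed = 65)
  qs <- run_quantity_pipeline(fs$frames, fs$l_fish, fs$theta, fs$dx, fs$dy)
  expect_equal(mean(qs$ci68), qs$mean)
  expect_equal(mean(qs$ci95), qs$mean)
  expect_lte(qs$ci95[1], qs$ci68[1])
  expect_gte(qs$ci95[2], qs$ci68[2])
})

test_that("two-mode allocation splits the sonar total proportionally", {
  single <- allocate_two_mode_counts(1234, c(blochii = 55))
  expect_equal(unname(single$counts), 1234)

  alloc <- allocate_two_mode_counts(1000, c(a = 55, b = 45))
  expect_equal(unname(alloc$counts), c(550, 450))

  expect_error(allocate_two_mode_counts(100, c(a = 0, b = 0)),
               class = "no_optical_detections")
})

test_that("integer allocation conserves the total by largest remainder", {
  set.seed(66)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    counts <- setNames(sample(1:40, k), letters[1:k])
    total <- sample(50:5000, 1)
    alloc <- allocate_two_mode_counts(total, counts, integer = TRUE)
    expect_equal(sum(alloc$counts), total)
    expect_true(all(alloc$counts >= 0))
    # each integer share is within 1 of the exact proportional share
    exact <- total * counts / sum(counts)
    expect_true(all(abs(alloc$counts - exact) < 1))
  }
})
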