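# Shared fixtures and independent oracles. Oracles are deliberately naive
# (loops, exhaustive searches) so they stay independent of the vectorised
# implementation paths they check.

# exhaustive all-pairs farthest-point length of a mask
brute_force_mask_length <- function(mask, pixel_size) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2) return(0)
  best <- 0
  for (i in seq_len(nrow(idx) - 1)) {
    for (j in (i + 1):nrow(idx)) {
      du <- (idx[j, 2] - idx[i, 2]) * pixel_size[1]
      dv <- (idx[j, 1] - idx[i, 1]) * pixel_size[2]
      best <- max(best, sqrt(du^2 + dv^2))
    }
  }
  best
}

# naive per-point summation of the registration loss
brute_force_fusion_loss <- function(transform, matches) {
  if (inherits(matches, "matched_point_set")) matches <- list(matches)
  total <- 0; n <- 0
  for (m in matches) {
    for (i in seq_len(nrow(m$sonar))) {
      pred <- as.numeric(transform$R %*% m$sonar[i, ] + transform$T)
      total <- total + sum((m$optical[i, ] - pred)^2)
      n <- n + 1
    }
  }
  total / n
}

# random small mask with at least min_px pixels
random_mask <- function(rows, cols, n_px) {
  m <- matrix(FALSE, rows, cols)
  m[sample.int(rows * cols, n_px)] <- TRUE
  m
}

# a symmetric 6-point sample whose ML fit has skewness 0 and kurtosis
# exactly 3: one third of the mass at +/-a, the rest at the centre
kurtosis3_sample <- function(a = 1, centre = 10) {
  centre + c(-a, 0, 0, 0, 0, a)
}

make_stack <- function(frame, n = 5) {
  build_frame_stack(rep(list(frame), n), 3)
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# single-frame quantity chain with fixed cage geometry
frame_quantity_exposed <- function(region) {
  fishsonar:::frame_quantity(region, l_fish = 20, theta = deg2rad(20),
                             dx = 1, dy = 1)
}
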