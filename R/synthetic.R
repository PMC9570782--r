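# Synthetic-data generators. Every pipeline input the package needs can be
# generated with known ground truth: calibration marker scenes, fish
# populations with allometric weights, sonar instance masks with
# merged/partial contamination, and net-cage feeding sequences. Defaults
# emulate the study conditions the package targets: a ~22 cm / ~286 g
# population for the length/weight pipeline and a ~2200-fish net cage with
# 20 cm fish and a 20 degree beam slant for the quantity pipeline.

#' Generate a calibration scene of matched sonar/optical markers
#'
#' Draws random sonar-frame marker positions over several frames, maps them
#' through a (given or random) rigid transform, and perturbs the optical
#' points with isotropic Gaussian noise. Returns both the matched point
#' sets and the generating transform so registration can be scored exactly.
#'
#' @param n_frames number of calibration frames (default 10).
#' @param n_markers markers per frame (default 4, like markers A-D).
#' @param noise_sd isotropic noise on the optical points, cm (default 0).
#' @param transform generating [rigid_transform()]; random when NULL.
#' @param box sonar-frame sampling box `(x, y, z)` extents in cm.
#' @param seed RNG seed.
#' @return List `matches` (list of [matched_point_set()]) and `transform`.
#' @export
gen_calibration_scene <- function(n_frames = 10L, n_markers = 4L,
                                  noise_sd = 0, transform = NULL,
                                  box = c(600, 600, 300), seed = NULL) {
  if (n_markers < 3L) abort("need at least 3 markers", "insufficient_data")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(transform)) {
    transform <- rigid_transform(
      euler_rotation_matrix(stats::runif(1, -pi / 4, pi / 4),
                            stats::runif(1, -pi / 4, pi / 4),
                            stats::runif(1, -pi, pi)),
      stats::runif(3, -50, 50))
  }
  matches <- lapply(seq_len(n_frames), function(fr) {
    s <- cbind(stats::runif(n_markers, 0, box[1]),
               stats::runif(n_markers, 0, box[2]),
               stats::runif(n_markers, 0, box[3]))
    o <- apply_transform(s, transform)
    if (noise_sd > 0) o <- o + matrix(stats::rnorm(3 * n_markers, 0, noise_sd),
                                      ncol = 3)
    matched_point_set(s, o, frame_id = fr)
  })
  list(matches = matches, transform = transform)
}

#' Generate a fish population with allometric weights
#'
#' Lengths are drawn from a normal distribution truncated at zero; weights
#' follow the allometric law `W = a L^b` with multiplicative lognormal
#' noise. A reference length-weight table (as measured manually on a
#' subsample) is returned alongside.
#'
#' @param n population size (>= 10).
#' @param mean_length,sd_length length distribution parameters, cm.
#' @param a,b allometric coefficients (defaults 0.0269 and 3 give ~286 g at
#'   22 cm).
#' @param weight_noise_sd sd of the lognormal weight noise (default 0.1).
#' @param table_rows rows subsampled into the reference table (default 200).
#' @param seed RNG seed.
#' @return List `lengths`, `weights`, `table` (data frame `length_cm`,
#'   `weight_g`).
#' @export
gen_population <- function(n = 2000L, mean_length = 21.98, sd_length = 2,
                           a = 0.0269, b = 3, weight_noise_sd = 0.1,
                           table_rows = 200L, seed = NULL) {
  if (n < 10L) abort("population size must be at least 10", "insufficient_data")
  if (!is.null(seed)) set.seed(seed)
  lengths <- stats::rnorm(n, mean_length, sd_length)
  while (any(lengths <= 0)) {  # truncate at zero by resampling
    bad <- lengths <= 0
    lengths[bad] <- stats::rnorm(sum(bad), mean_length, sd_length)
  }
  noise <- if (weight_noise_sd > 0) exp(stats::rnorm(n, 0, weight_noise_sd)) else 1
  weights <- a * lengths^b * noise
  idx <- sample.int(n, min(table_rows, n))
  list(lengths = lengths, weights = weights,
       table = data.frame(length_cm = lengths[idx], weight_g = weights[idx]))
}

#' Contaminate observed instance lengths with merged and partial instances
#'
#' Emulates instance segmentation on a crowded school: a fraction of the
#' observed instances are two fish merged into one (observed length = sum
#' of a random pair of true lengths) and a fraction are partial fish
#' truncated by occlusion or the frame edge (40-70% of the body removed,
#' i.e. 30-60% retained). The remaining instances observe a true length
#' unchanged.
#'
#' @param lengths true single-fish lengths.
#' @param frac_merged fraction of observed instances that are merged pairs
#'   (default 0.2).
#' @param frac_partial fraction that are truncated (default 0.1).
#' @param seed RNG seed.
#' @return List `observed` (lengths), `label` (factor: single / merged /
#'   partial).
#' @export
contaminate_lengths <- function(lengths, frac_merged = 0.2, frac_partial = 0.1,
                                seed = NULL) {
  if (frac_merged < 0 || frac_partial < 0 || frac_merged + frac_partial >= 1) {
    abort("contamination fractions must be non-negative and sum below 1", "domain_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(lengths)
  n_m <- round(frac_merged * n)
  n_p <- round(frac_partial * n)
  n_s <- n - n_m - n_p
  singles <- sample(lengths, n_s)
  par1 <- sample(lengths, n_m, replace = TRUE)
  par2 <- sample(lengths, n_m, replace = TRUE)
  merged <- par1 + par2
  partial <- sample(lengths, n_p, replace = TRUE) * stats::runif(n_p, 0.3, 0.6)
  obs <- c(singles, merged, partial)
  lab <- factor(rep(c("single", "merged", "partial"), c(n_s, n_m, n_p)),
                levels = c("single", "merged", "partial"))
  parents <- rbind(matrix(NA_real_, n_s, 2), cbind(par1, par2),
                   matrix(NA_real_, n_p, 2))
  perm <- sample.int(n)
  list(observed = obs[perm], label = lab[perm],
       merged_parents = parents[perm, , drop = FALSE])
}

# Rasterize a straight segment of physical length L at angle `angle`,
# anchored so the whole segment stays inside the frame. Endpoint offsets
# are rounded to whole pixels, so the achieved farthest-point length equals
# the drawn length to within one pixel footprint.
draw_segment_mask <- function(frame_shape, L, angle, pixel_size) {
  cols <- frame_shape[1]; rows <- frame_shape[2]
  du <- round(L * cos(angle) / pixel_size[1])
  dv <- round(L * sin(angle) / pixel_size[2])
  if (abs(du) > cols - 1L || abs(dv) > rows - 1L) {
    abort("fish is longer than the frame", "placement_error")
  }
  pick <- function(lo, hi) if (lo >= hi) lo else sample(seq(lo, hi), 1L)
  u0 <- pick(max(0L, -du), cols - 1L - max(0L, du))
  v0 <- pick(max(0L, -dv), rows - 1L - max(0L, dv))
  nstep <- max(abs(du), abs(dv)) * 2L + 1L
  t <- seq(0, 1, length.out = nstep)
  us <- round(u0 + t * du); vs <- round(v0 + t * dv)
  mask <- matrix(FALSE, rows, cols)
  mask[cbind(vs + 1L, us + 1L)] <- TRUE
  attr(mask, "gt_length") <- sqrt((du * pixel_size[1])^2 + (dv * pixel_size[2])^2)
  mask
}

#' Generate sonar instance masks with overlap contamination
#'
#' Renders each observed instance as a pixel segment in its own frame-sized
#' mask: single fish at their drawn length, merged instances as two fish
#' fused end to end (observed extent = sum of the parent lengths), partial
#' instances truncated to 30-60% of the parent length. The achieved
#' farthest-point length of every mask is returned as ground truth and
#' matches the intended length to within one pixel.
#'
#' @param lengths true single-fish lengths, cm.
#' @param frame_shape `(cols, rows)` of the sonar frame.
#' @param pixel_size `(w, h)` physical pixel size, cm.
#' @param frac_merged,frac_partial contamination fractions (defaults 0.2 /
#'   0.1).
#' @param seed RNG seed.
#' @return List `masks` (logical matrices), `label` (factor), `gt_length`
#'   (achieved farthest-point lengths, cm), `intended_length`.
#' @export
gen_instance_masks <- function(lengths, frame_shape = c(512L, 512L),
                               pixel_size = c(0.583, 0.549),
                               frac_merged = 0.2, frac_partial = 0.1,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cont <- contaminate_lengths(lengths, frac_merged, frac_partial)
  masks <- vector("list", length(cont$observed))
  gt <- numeric(length(cont$observed))
  for (i in seq_along(cont$observed)) {
    angle <- stats::runif(1, 0, pi)
    masks[[i]] <- draw_segment_mask(frame_shape, cont$observed[i], angle, pixel_size)
    gt[i] <- attr(masks[[i]], "gt_length")
    attr(masks[[i]], "gt_length") <- NULL
  }
  list(masks = masks, label = cont$label, gt_length = gt,
       intended_length = cont$observed, merged_parents = cont$merged_parents)
}

#' Generate a net-cage feeding sequence with known ground truth
#'
#' Produces a sonar video of gathering and dispersing frames. Each
#' gathering frame contains one bright prism-projected school region whose
#' pixel count, bottom row and intensities are constructed so that the
#' density / area / depth / volume chain recovers that frame's ground-truth
#' count exactly: the region's normalised mean intensity equals
#' `delta_true`, and the per-frame count stored as ground truth is computed
#' from the realised region through the same geometric model. Frame-to-
#' frame variation of the school extent is controlled by `count_noise`
#' (lognormal sd on the target volume), so per-frame counts scatter around
#' `true_count`. Dispersing frames contain only sparse dim specks. Echo
#' intensity falls off linearly with row (range) when `range_decay` is
#' positive, mimicking the blurring of distant fish; optional Gaussian
#' speckle noise is added last.
#'
#' @param n_frames total frames (>= 5); the first and last two are always
#'   dispersing so every interior frame has stack context.
#' @param frame_shape `(cols, rows)`.
#' @param true_count nominal fish count in the cage (default 2200).
#' @param l_fish average fish length, cm (default 20).
#' @param theta beam slant angle, radians (default 20 degrees).
#' @param dx,dy physical pixel size, cm (default 3).
#' @param delta_true school packing density (default 0.6).
#' @param gathering_frac probability an interior frame is gathering
#'   (default 0.6).
#' @param count_noise lognormal sd of the per-frame school volume
#'   (default 0.1).
#' @param range_decay linear intensity fall-off across rows, as a fraction
#'   of full scale at the bottom row (default 0; the exact-inversion
#'   guarantee holds only at 0).
#' @param speckle_sd additive Gaussian noise sd (default 0).
#' @param seed RNG seed.
#' @return List `frames`, `gathering` (logical flags), `regions`
#'   ([fish_region_frame()] or NULL per frame), `frame_count` (per-frame
#'   ground-truth count, NA for dispersing), `true_count`, and the geometry
#'   parameters (`l_fish`, `theta`, `dx`, `dy`, `delta_true`).
#' @export
gen_feeding_sequence <- function(n_frames = 24L, frame_shape = c(200L, 200L),
                                 true_count = 2200, l_fish = 20,
                                 theta = deg2rad(20), dx = 3, dy = 3,
                                 delta_true = 0.6, gathering_frac = 0.6,
                                 count_noise = 0.1, range_decay = 0,
                                 speckle_sd = 0, seed = NULL) {
  if (n_frames < 5L) abort("need at least 5 frames", "insufficient_data")
  if (!is.null(seed)) set.seed(seed)
  cols <- frame_shape[1]; rows <- frame_shape[2]
  flags <- rep(FALSE, n_frames)
  interior <- 3:(n_frames - 2L)
  flags[interior] <- stats::runif(length(interior)) < gathering_frac
  if (!any(flags)) flags[interior[ceiling(length(interior) / 2)]] <- TRUE
  v_fish <- fish_volume(l_fish)
  frames <- vector("list", n_frames)
  regions <- vector("list", n_frames)
  counts <- rep(NA_real_, n_frames)
  for (i in seq_len(n_frames)) {
    frame <- matrix(0, rows, cols)
    if (flags[i]) {
      v_target <- true_count * v_fish / delta_true *
        exp(stats::rnorm(1, 0, count_noise))
      y_max <- round(rows * stats::runif(1, 0.6, 0.8))  # bottom row, 1-based
      depth <- y_max * dy * sin(theta)
      npix <- max(30L, round(v_target / (dx * dy * cos(theta) * depth)))
      wc <- max(10L, ceiling(npix / (0.9 * y_max)))
      if (wc > cols - 4L) abort("school does not fit the frame", "placement_error")
      nfull <- npix %/% wc; rem <- npix %% wc
      c0 <- (cols - wc) %/% 2L
      mask <- matrix(FALSE, rows, cols)
      if (nfull > 0L) mask[(y_max - nfull + 1L):y_max, (c0 + 1L):(c0 + wc)] <- TRUE
      if (rem > 0L) mask[y_max - nfull, (c0 + 1L):(c0 + rem)] <- TRUE
      m <- sum(mask)
      fill <- if (m > 1L) (delta_true * m - 1) / (m - 1) else delta_true
      frame[mask] <- fill
      frame[y_max, c0 + 1L] <- 1  # one saturated pixel pins g_max
      # realised ground truth through the same geometric chain
      A <- m * dx * dy * cos(theta)
      counts[i] <- estimate_quantity(A * depth, delta_true, v_fish)
      regions[[i]] <- fish_region_frame(mask, frame, frame_id = i)
    } else {
      n_speck <- round(0.0015 * rows * cols)
      idx <- cbind(sample.int(rows, n_speck, replace = TRUE),
                   sample.int(cols, n_speck, replace = TRUE))
      frame[idx] <- stats::runif(n_speck, 0.2, 0.9)
    }
    if (range_decay > 0) {
      frame <- frame * (1 - range_decay * (seq_len(rows) - 1) / (rows - 1))
    }
    if (speckle_sd > 0) {
      frame <- pmin(pmax(frame + matrix(stats::rnorm(rows * cols, 0, speckle_sd),
                                        rows, cols), 0), 1)
    }
    frames[[i]] <- frame
  }
  list(frames = frames, gathering = flags, regions = regions,
       frame_count = counts, true_count = true_count,
       l_fish = l_fish, theta = theta, dx = dx, dy = dy,
       delta_true = delta_true)
}

#' Ground-truth detector callbacks for a generated feeding sequence
#'
#' Wraps the generator's stored flags and regions as detector callables
#' with the fallback signatures, for scoring the quantity pipeline against
#' a perfect front end.
#'
#' @param seq_data a [gen_feeding_sequence()] result.
#' @return List `classify`, `segment`.
#' @export
ground_truth_detectors <- function(seq_data) {
  list(
    classify = function(stack, ...) seq_data$gathering[stack$target_index],
    segment = function(stack, ...) seq_data$regions[[stack$target_index]]
  )
}
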