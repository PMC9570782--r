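# Net-cage fish-quantity estimation from gathering frames. During feeding
# the school converges near the surface into a compact mass; the sonar
# beam cuts it slantwise, and the school's volume is modelled as an
# irregular prism over the segmented fish region. The count follows from
# n = V * delta / V_fish.

#' School packing density from a segmented fish region
#'
#' `delta = sum(g(x), x in region) / (g_max * |region|)`: the mean region
#' pixel value normalised by the region maximum, a dimensionless proxy for
#' how densely the school packs the insonified volume. By default `g_max`
#' is the maximum pixel value within the region; set `use_dtype_max` to
#' normalise by `dtype_max` instead.
#'
#' @param region a [fish_region_frame()].
#' @param use_dtype_max normalise by a fixed full-scale value rather than
#'   the region maximum (default FALSE).
#' @param dtype_max full-scale pixel value used when `use_dtype_max` is TRUE
#'   (default 1, for frames normalised to `[0, 1]`).
#' @return Density in `[0, 1]`.
#' @export
fish_density <- function(region, use_dtype_max = FALSE, dtype_max = 1) {
  stopifnot(inherits(region, "fish_region_frame"))
  g <- region$values[region$mask]
  if (!length(g)) abort("fish region is empty", "empty_region")
  gmax <- if (use_dtype_max) dtype_max else max(g)
  if (gmax <= 0) abort("region has no positive pixel values", "empty_region")
  sum(g) / (gmax * length(g))
}

#' Sea-plane area and depth of the fish school
#'
#' With the sonar beam slanted at angle `theta` to the sea plane, a region
#' of `|F|` pixels of physical size `dx * dy` projects onto the sea plane
#' with area `A = |F| dx dy cos(theta)`, and the school reaches depth
#' `d = y_max dy sin(theta)`, where `y_max` counts rows from the top of the
#' frame down to the bottom row of the region (0-based bottom row index
#' plus 1).
#'
#' @param region a [fish_region_frame()].
#' @param dx,dy physical pixel sizes in cm.
#' @param theta beam slant angle in radians, `[0, pi/2)`.
#' @return Numeric `(A, d)`: area in cm^2 and depth in cm.
#' @export
region_area_depth <- function(region, dx, dy, theta) {
  stopifnot(inherits(region, "fish_region_frame"))
  if (theta < 0 || theta >= pi / 2) abort("theta must lie in [0, pi/2)", "domain_error")
  npix <- sum(region$mask)
  if (npix == 0L) abort("fish region is empty", "empty_region")
  y_max <- max(which(rowSums(region$mask) > 0))  # 1-based bottom row == 0-based + 1
  c(A = npix * dx * dy * cos(theta), d = y_max * dy * sin(theta))
}

#' Cuboid volume of a single fish
#'
#' A fish of average length `l` is modelled as occupying a cuboid of
#' `l x l/2 x l/2`, i.e. `V_fish = l^3 / 4` cm^3.
#'
#' @param l_fish average fish length in cm, positive.
#' @return Volume in cm^3.
#' @examples
#' fish_volume(20)  # 2000 cm^3
#' @export
fish_volume <- function(l_fish) {
  if (any(l_fish <= 0)) abort("fish length must be positive", "domain_error")
  l_fish * (l_fish / 2) * (l_fish / 2)
}

#' Fish count from school volume, density and per-fish volume
#'
#' `n_fish = V * delta / V_fish`, returned as a real number; rounding is a
#' presentation concern.
#'
#' @param V school volume in cm^3.
#' @param delta packing density in `[0, 1]`.
#' @param V_fish single-fish volume in cm^3, positive.
#' @return Estimated count.
#' @export
estimate_quantity <- function(V, delta, V_fish) {
  if (any(V_fish <= 0)) abort("per-fish volume must be positive", "domain_error")
  V * delta / V_fish
}

frame_quantity <- function(region, l_fish, theta, dx, dy, frame_id = NA, ...) {
  delta <- fish_density(region, ...)
  ad <- region_area_depth(region, dx, dy, theta)
  V <- ad[["A"]] * ad[["d"]]
  vf <- fish_volume(l_fish)
  list(frame_id = frame_id, n_fish = estimate_quantity(V, delta, vf),
       V = V, delta = delta, A = ad[["A"]], d_school = ad[["d"]])
}

#' Fish-quantity estimation over a feeding video
#'
#' For every frame with two context frames on each side: build the 5-frame
#' stack, classify it as gathering or dispersing, and for gathering frames
#' segment the fish region and chain density, prism area/depth, volume and
#' count. Per-frame estimates from the gathering frames are aggregated into
#' a mean, standard deviation, and normal-approximation 68% and 95%
#' confidence intervals (`mean +/- z sd`, z = 1 and 1.96).
#'
#' The classifier and segmenter are pluggable: any callables with the
#' fallback signatures ([classify_gathering_fallback()],
#' [segment_fish_region_fallback()]) may be passed, including ground-truth
#' callbacks from the synthetic generator.
#'
#' @param frames list of numeric frame matrices in temporal order (>= 5).
#' @param l_fish average fish length in cm.
#' @param theta beam slant angle in radians.
#' @param dx,dy physical pixel sizes in cm.
#' @param classify gathering classifier `function(stack) -> logical`.
#' @param segment region segmenter `function(stack) -> fish_region_frame or
#'   NULL`.
#' @param ... passed to [fish_density()].
#' @return An object of class `quantity_summary`: data frame `estimates`
#'   (one row per gathering frame with `n_fish`, `V`, `delta`, `A`,
#'   `d_school`), `mean`, `sd`, `ci68`, `ci95`, `n_gathering`. When no
#'   gathering frame is found the summary carries `n_gathering = 0` and NA
#'   statistics: the no-estimate signal.
#' @export
run_quantity_pipeline <- function(frames, l_fish, theta, dx, dy,
                                  classify = classify_gathering_fallback,
                                  segment = segment_fish_region_fallback,
                                  ...) {
  if (length(frames) < 5L) abort("need at least 5 frames", "insufficient_data")
  rows <- list()
  for (i in 3:(length(frames) - 2L)) {
    stack <- build_frame_stack(frames, i)
    if (!isTRUE(classify(stack))) next
    region <- segment(stack)
    if (is.null(region)) next
    rows[[length(rows) + 1L]] <-
      as.data.frame(frame_quantity(region, l_fish, theta, dx, dy,
                                   frame_id = i, ...))
  }
  if (!length(rows)) {
    return(structure(list(estimates = NULL, mean = NA_real_, sd = NA_real_,
                          ci68 = c(NA_real_, NA_real_), ci95 = c(NA_real_, NA_real_),
                          n_gathering = 0L),
                     class = "quantity_summary"))
  }
  est <- do.call(rbind, rows)
  m <- mean(est$n_fish)
  s <- stats::sd(est$n_fish)
  if (is.na(s)) s <- 0  # single gathering frame
  structure(list(estimates = est, mean = m, sd = s,
                 ci68 = c(m - s, m + s), ci95 = c(m - 1.96 * s, m + 1.96 * s),
                 n_gathering = nrow(est)),
            class = "quantity_summary")
}

#' @export
print.quantity_summary <- function(x, ...) {
  if (x$n_gathering == 0L) {
    cat("quantity_summary: no gathering frames found (no estimate)\n")
    return(invisible(x))
  }
  cat(sprintf("quantity_summary over %d gathering frame(s):\n", x$n_gathering))
  cat(sprintf("  mean %.2f fish, sd %.2f\n", x$mean, x$sd))
  cat(sprintf("  68%% CI [%.2f, %.2f], 95%% CI [%.2f, %.2f]\n",
              x$ci68[1], x$ci68[2], x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Allocate a sonar total count across species
#'
#' The sonar counts fish without species information; optical detections
#' carry species labels but only within the short optical range. The
#' two-mode allocation splits the sonar total in proportion to the optical
#' per-species counts: `C_i = C_sonar * c_i / c_total`. With
#' `integer = TRUE`, counts are rounded by the largest-remainder method so
#' they sum exactly to `C_sonar`.
#'
#' @param C_sonar total count from the sonar pipeline.
#' @param optical_counts named numeric vector of per-species optical
#'   detection counts; must sum to a positive total.
#' @param integer return integer counts (default FALSE).
#' @return An object of class `count_allocation`: `counts` (per species),
#'   `sonar_total`, `optical_counts`, `optical_total`.
#' @examples
#' allocate_two_mode_counts(1000, c(a = 55, b = 45))
#' @export
allocate_two_mode_counts <- function(C_sonar, optical_counts, integer = FALSE) {
  if (any(optical_counts < 0)) abort("optical counts must be non-negative", "domain_error")
  c_total <- sum(optical_counts)
  if (c_total <= 0) abort("no optical detections to allocate against", "no_optical_detections")
  shares <- C_sonar * optical_counts / c_total
  if (integer) {
    base <- floor(shares)
    short <- round(C_sonar) - sum(base)
    if (short > 0) {
      extra <- order(shares - base, decreasing = TRUE)[seq_len(short)]
      base[extra] <- base[extra] + 1
    }
    shares <- base
  }
  structure(list(counts = shares, sonar_total = C_sonar,
                 optical_counts = optical_counts, optical_total = c_total),
            class = "count_allocation")
}

#' @export
print.count_allocation <- function(x, ...) {
  cat(sprintf("count_allocation of sonar total %g across %d species:\n",
              x$sonar_total, length(x$counts)))
  print(x$counts)
  invisible(x)
}
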