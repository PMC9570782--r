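# Pluggable detector contracts. The production system would put trained
# networks behind these signatures (an instance segmenter for the length
# pipeline, a gathering-frame classifier and a fish-region segmenter for
# the quantity pipeline); the package ships deterministic classical
# fallbacks with the same signatures so every downstream stage is testable
# without trained weights. Any callable with a matching signature can be
# plugged in through the pipeline arguments or the CLI `detector` config
# key.

#' Five-frame stack around a target sonar frame
#'
#' The quantity pipeline classifies and segments the target frame together
#' with its two preceding and two succeeding frames, which carry the motion
#' cue that distinguishes a gathering school from a dispersing one.
#'
#' @param frames list of equally shaped numeric matrices in temporal order.
#' @param target_index 1-based index of the target frame; must leave two
#'   frames of context on each side.
#' @return An object of class `frame_stack`: list of the 5 frames plus the
#'   target index (the target is element 3).
#' @export
build_frame_stack <- function(frames, target_index) {
  n <- length(frames)
  if (target_index < 3L || target_index > n - 2L) {
    abort("target frame needs two context frames on each side", "bounds_error")
  }
  sel <- frames[(target_index - 2L):(target_index + 2L)]
  shp <- dim(sel[[1]])
  if (!all(vapply(sel, function(f) all(dim(f) == shp), TRUE))) {
    abort("stacked frames must share one shape", "format_error")
  }
  structure(list(frames = sel, target_index = target_index),
            class = "frame_stack")
}

target_frame <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  stack$frames[[3L]]
}

#' Threshold-based gathering-frame classifier (fallback detector)
#'
#' A gathering school produces one large bright blob; a dispersing school
#' leaves only sparse specks. The fallback classifies the target frame as
#' "gathering" when the fraction of pixels brighter than
#' `intensity_threshold * g_max` exceeds `area_threshold`, where `g_max` is
#' the frame's maximum pixel value. An all-zero frame is never gathering.
#'
#' @param stack a [build_frame_stack()] result.
#' @param intensity_threshold fraction of `g_max` in (0, 1); default 0.5.
#' @param area_threshold bright-area fraction in (0, 1); default 0.02.
#' @return TRUE iff classified as a gathering frame.
#' @export
classify_gathering_fallback <- function(stack, intensity_threshold = 0.5,
                                        area_threshold = 0.02) {
  if (intensity_threshold <= 0 || intensity_threshold >= 1 ||
      area_threshold <= 0 || area_threshold >= 1) {
    abort("thresholds must lie in (0, 1)", "domain_error")
  }
  frame <- target_frame(stack)
  gmax <- max(frame)
  if (gmax <= 0) return(FALSE)
  mean(frame > intensity_threshold * gmax) > area_threshold
}

#' Segmented fish region in one sonar frame
#'
#' Couples a boolean region mask with the source frame's pixel values; the
#' quantity pipeline reads density, area and depth off this object.
#'
#' @param mask logical matrix, TRUE on fish-region pixels.
#' @param values numeric matrix of the source frame, same shape.
#' @param frame_id optional identifier.
#' @return An object of class `fish_region_frame`.
#' @export
fish_region_frame <- function(mask, values, frame_id = NA) {
  if (!is.logical(mask)) mask <- mask > 0
  if (!all(dim(mask) == dim(values))) {
    abort("mask and values must share one shape", "format_error")
  }
  if (!any(mask)) abort("fish region is empty", "empty_region")
  structure(list(mask = mask, values = values, frame_id = frame_id),
            class = "fish_region_frame")
}

#' Threshold-and-morphology fish-region segmenter (fallback detector)
#'
#' Thresholds the target frame at `intensity_threshold * g_max`, discards
#' connected blobs smaller than `min_blob_px` (8-connectivity), applies a
#' 3x3 morphological closing, and returns the largest surviving connected
#' region.
#'
#' @param stack a [build_frame_stack()] result.
#' @param intensity_threshold fraction of `g_max` in (0, 1); default 0.5.
#' @param min_blob_px minimum blob size in pixels; default 25.
#' @return A [fish_region_frame()], or NULL when no blob survives (the
#'   empty-region signal).
#' @export
segment_fish_region_fallback <- function(stack, intensity_threshold = 0.5,
                                         min_blob_px = 25L) {
  if (intensity_threshold <= 0 || intensity_threshold >= 1) {
    abort("intensity_threshold must lie in (0, 1)", "domain_error")
  }
  frame <- target_frame(stack)
  gmax <- max(frame)
  if (gmax <= 0) return(NULL)
  bw <- frame > intensity_threshold * gmax
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_blob_px)
  if (!length(keep)) return(NULL)
  bw <- matrix(lab %in% keep, nrow(frame), ncol(frame))
  closed <- EBImage::closing(EBImage::Image(bw * 1), EBImage::makeBrush(3, "box"))
  lab2 <- EBImage::bwlabel(closed > 0)
  lab2 <- matrix(as.integer(lab2), nrow(frame), ncol(frame))
  sizes2 <- tabulate(lab2[lab2 > 0])
  if (!length(sizes2)) return(NULL)
  fish_region_frame(lab2 == which.max(sizes2), frame)
}

#' Read instance masks produced by an external detector
#'
#' Accepts either a labelled 8-bit PNG (pixel value = instance label, 0 =
#' background) or a directory of per-instance binary PNGs. Masks may come
#' from any external instance segmenter (e.g. a trained Mask R-CNN); this
#' reader only validates their geometry.
#'
#' @param path labelled PNG file or directory of binary PNGs.
#' @param frame_shape optional `(cols, rows)`; masks of any other shape
#'   raise a format error.
#' @return A list of logical matrices, one per instance; empty when the
#'   label image has no foreground.
#' @export
load_external_masks <- function(path, frame_shape = NULL) {
  check_shape <- function(m) {
    if (!is.null(frame_shape) &&
        !(ncol(m) == frame_shape[1] && nrow(m) == frame_shape[2])) {
      abort(sprintf("mask shape %d x %d does not match frame shape %d x %d",
                    ncol(m), nrow(m), frame_shape[1], frame_shape[2]),
            "format_error")
    }
    m
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    return(lapply(files, function(f) check_shape(png::readPNG(f) > 0)))
  }
  if (!file.exists(path)) abort(paste("no such mask file:", path), "empty_input")
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  check_shape(img)
  labels <- round(img * 255)
  ids <- sort(unique(labels[labels > 0]))
  lapply(ids, function(i) labels == i)
}

#' Accuracy from a 2x2 confusion matrix
#'
#' Fraction of correctly classified frames, `sum(diag) / sum`. Used to score
#' a gathering/dispersing classifier against annotated frames.
#'
#' @param confusion 2x2 matrix, rows = actual, columns = predicted.
#' @return Scalar accuracy in `[0, 1]`.
#' @examples
#' classification_accuracy(matrix(c(58, 3, 0, 113), 2, 2))
#' @export
classification_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (sum(confusion) <= 0) abort("confusion matrix is empty", "empty_input")
  sum(diag(confusion)) / sum(confusion)
}
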