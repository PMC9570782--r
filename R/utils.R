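# Internal helpers shared across modules.

# Classed error so callers can distinguish failure modes programmatically.
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fishsonar_error", "error")))
}

# All angles are radians internally; config files may carry degrees.

#' Convert degrees to radians
#' @param deg angle in degrees.
#' @return Angle in radians.
#' @export
deg2rad <- function(deg) deg * pi / 180

as_point_matrix <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 3L) {
      abort("a 3D point must have exactly 3 components", "domain_error")
    }
    points <- matrix(points, nrow = 1L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) {
    abort("point matrices must have 3 columns (x, y, z)", "domain_error")
  }
  storage.mode(points) <- "double"
  points
}

`%||%` <- function(a, b) if (is.null(a)) b else a
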