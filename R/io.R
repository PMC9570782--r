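# File I/O: frame sequences (PNG/TIFF), JSON configs, ASCII PLY point
# clouds. CSV tables go through base utils readers at the call sites.

#' Read an ordered grayscale frame sequence
#'
#' Reads every PNG/TIFF in a directory in lexicographic filename order
#' (zero-padded numeric names give temporal order). Multi-channel images
#' are reduced to grayscale by channel averaging; all frames are returned
#' as numeric matrices on the `[0, 1]` scale used throughout the package.
#' Non-image files are skipped with a warning; frames of differing shapes
#' raise a format error, and an empty directory an empty-input error.
#'
#' @param path directory containing the frames.
#' @return List of numeric matrices in temporal order.
#' @export
read_frames <- function(path) {
  if (!dir.exists(path)) abort(paste("no such directory:", path), "empty_input")
  files <- sort(list.files(path, full.names = TRUE))
  files <- files[!dir.exists(files)]
  frames <- list()
  for (f in files) {
    ext <- tolower(tools::file_ext(f))
    img <- switch(ext,
                  png = png::readPNG(f),
                  tif = , tiff = tiff::readTIFF(f),
                  {
                    warning("skipping non-image file: ", basename(f))
                    NULL
                  })
    if (is.null(img)) next
    if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
    frames[[length(frames) + 1L]] <- img
  }
  if (!length(frames)) abort("no image frames found", "empty_input")
  shp <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) all(dim(f) == shp), TRUE))) {
    abort("frames have mixed shapes", "format_error")
  }
  frames
}

#' Write a frame sequence as zero-padded PNGs
#' @param frames list of numeric matrices in `[0, 1]`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_frames <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(frames)) {
    png::writePNG(pmin(pmax(frames[[i]], 0), 1),
                  file.path(dir, sprintf("%04d.png", i - 1L)))
  }
  invisible(dir)
}

#' Write 3D points as an ASCII PLY file
#'
#' @param points n x 3 matrix (cm); must be non-empty.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_point_cloud <- function(points, path) {
  p <- as_point_matrix(points)
  if (nrow(p) == 0L) abort("point cloud is empty", "empty_input")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(p)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  utils::write.table(format(p, scientific = FALSE, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASCII PLY point cloud written by [write_point_cloud()]
#' @param path PLY file.
#' @return n x 3 numeric matrix.
#' @export
read_point_cloud <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  if (is.na(end)) abort("not a PLY file (no end_header)", "format_error")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  body <- lines[(end + 1L):(end + nv)]
  m <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
  colnames(m) <- c("x", "y", "z")
  m
}

#' Read and validate a JSON config
#'
#' @param path JSON file.
#' @param required character vector of keys that must be present; a missing
#'   key raises a config error naming it.
#' @return Named list.
#' @export
read_config <- function(path, required = character()) {
  if (!file.exists(path)) abort(paste("no such config file:", path), "config_error")
  cfg <- jsonlite::fromJSON(path)
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    abort(paste("config is missing required key(s):", paste(missing, collapse = ", ")),
          "config_error")
  }
  cfg
}
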