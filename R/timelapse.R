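#' Calibrated multi-channel time-lapse container
#'
#' @param frames numeric or integer array with dimensions T x C x Y x X
#'   (frames, channels, rows, columns). Rendered stacks hold 16-bit counts
#'   (0..65535); analyses operate on floating-point copies.
#' @param channel_names character vector of length C.
#' @param pixel_size um per pixel (> 0).
#' @param frame_interval seconds between frames (> 0).
#' @param axis_annotation optional animal-pole angle, degrees (0 = "up",
#'   increasing clockwise).
#'
#' @return An object of class `oo_timelapse`.
#' @examples
#' tl <- timelapse(array(0L, c(2, 1, 8, 8)), "ooplasm", 1, 60)
#' dim(tl$frames)
#' @export
timelapse <- function(frames, channel_names, pixel_size = 1.0,
                      frame_interval = 60, axis_annotation = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 4L)
    stop("'frames' must be a T x C x Y x X array")
  if (any(dim(frames) < 1L)) stop("all dimensions must be >= 1")
  if (length(channel_names) != dim(frames)[2])
    stop("length(channel_names) must equal the channel dimension")
  stopifnot_scalar(pixel_size, "pixel_size")
  stopifnot_scalar(frame_interval, "frame_interval")
  structure(list(frames = frames,
                 channel_names = as.character(channel_names),
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 axis_annotation = axis_annotation),
            class = "oo_timelapse")
}

#' @export
print.oo_timelapse <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("oo_timelapse: %d frame(s), %d channel(s), %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  pixel %g um, interval %g s; channels: %s\n",
              x$pixel_size, x$frame_interval,
              paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' Extract one channel of one frame as a matrix
#'
#' @param tl an `oo_timelapse`.
#' @param frame frame index (1-based).
#' @param channel channel name or index.
#' @return A Y x X numeric matrix (double).
#' @export
tl_frame <- function(tl, frame, channel) {
  if (!inherits(tl, "oo_timelapse")) stop("'tl' must be an oo_timelapse")
  if (is.character(channel)) {
    channel <- match(channel, tl$channel_names)
    if (is.na(channel)) stop("unknown channel name")
  }
  d <- dim(tl$frames)
  if (frame < 1 || frame > d[1]) stop("frame index out of range")
  m <- tl$frames[frame, channel, , ]
  storage.mode(m) <- "double"
  m
}

#' Measurement line with a perpendicular averaging width
#'
#' @param p1,p2 numeric length-2 endpoints (x, y) in micrometres; must be
#'   distinct.
#' @param width averaging width in pixels (odd, >= 1).
#' @return An object of class `oo_line_spec`.
#' @export
line_spec <- function(p1, p2, width = 1L) {
  if (length(p1) != 2 || length(p2) != 2 || all(p1 == p2))
    stop("endpoints must be two distinct (x, y) points")
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L) stop("'width' must be odd and >= 1")
  structure(list(p1 = as.numeric(p1), p2 = as.numeric(p2), width = width),
            class = "oo_line_spec")
}

#' Write a time-lapse to multi-page TIFF plus a JSON sidecar
#'
#' Pages are stored frame-major (all channels of frame 1, then frame 2, ...)
#' as 16-bit grayscale. Calibration and channel names go to a sidecar
#' `<basename>.json` next to the TIFF, keeping the image file dialect-free.
#' Lossless for integer data in 0..65535.
#'
#' @param tl an `oo_timelapse` with finite pixel values in 0..65535.
#' @param path output TIFF path (".tif" appended when missing).
#' @return Invisibly, the TIFF path.
#' @seealso [read_timelapse()]
#' @export
write_timelapse <- function(tl, path) {
  if (!inherits(tl, "oo_timelapse")) stop("'tl' must be an oo_timelapse")
  if (any(!is.finite(tl$frames)))
    stop("pixel values must be finite")
  if (min(tl$frames) < 0 || max(tl$frames) > 65535)
    stop("pixel values must lie in 0..65535 for 16-bit storage")
  if (!grepl("\\.tiff?$", path)) path <- paste0(path, ".tif")
  d <- dim(tl$frames)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[1])) for (c in seq_len(d[2])) {
    m <- tl$frames[t, c, , ]
    storage.mode(m) <- "double"
    pages[[k]] <- m / 65535
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = TRUE)
  sidecar <- sub("\\.tiff?$", ".json", path)
  jsonlite::write_json(
    list(shape = d, channel_names = tl$channel_names,
         pixel_size = tl$pixel_size, frame_interval = tl$frame_interval,
         axis_annotation = tl$axis_annotation),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read a time-lapse written by [write_timelapse()]
#'
#' When the JSON sidecar is missing the stack is read as a single-channel
#' series with default calibration (1.0 um/pixel, 60 s/frame) and a warning
#' is emitted. A sidecar whose recorded shape disagrees with the TIFF is an
#' error rather than silently partial data.
#'
#' @param path TIFF path.
#' @return An `oo_timelapse` with integer 16-bit counts.
#' @export
read_timelapse <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("unreadable TIFF: ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- sub("\\.tiff?$", ".json", path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    d <- as.integer(meta$shape)
    if (length(d) != 4L || d[1] * d[2] != length(pages) ||
        any(dim(pages[[1]]) != d[3:4]))
      stop("sidecar shape disagrees with TIFF contents")
    channel_names <- meta$channel_names
    pixel_size <- meta$pixel_size
    frame_interval <- meta$frame_interval
    axis_annotation <- meta$axis_annotation
    if (is.null(axis_annotation) || length(axis_annotation) == 0)
      axis_annotation <- NULL
  } else {
    warning("no JSON sidecar found; assuming one channel, 1.0 um/pixel, 60 s")
    d <- c(length(pages), 1L, dim(pages[[1]]))
    channel_names <- "channel1"
    pixel_size <- 1.0
    frame_interval <- 60
    axis_annotation <- NULL
  }
  frames <- array(0L, dim = d)
  k <- 1L
  for (t in seq_len(d[1])) for (c in seq_len(d[2])) {
    m <- pages[[k]]
    if (length(dim(m)) == 3L) m <- m[, , 1]  # tolerate grayscale-as-RGB
    frames[t, c, , ] <- as.integer(round(m * 65535))
    k <- k + 1L
  }
  timelapse(frames, channel_names, pixel_size, frame_interval,
            axis_annotation)
}

#' Write ground-truth tables to headered CSV files
#'
#' One file per table, named `<prefix>_<table>.csv`.
#'
#' @param truth an `oo_truth` object from [generate_timelapse()] or
#'   [generate_contraction_series()].
#' @param prefix output path prefix.
#' @return Invisibly, the written paths.
#' @export
write_ground_truth <- function(truth, prefix) {
  if (!inherits(truth, "oo_truth")) stop("'truth' must be an oo_truth")
  out <- character(0)
  for (nm in c("granule_tracks", "fusion_events", "aster_tracks",
               "true_velocities")) {
    if (is.null(truth[[nm]])) next
    f <- paste0(prefix, "_", nm, ".csv")
    utils::write.csv(truth[[nm]], f, row.names = FALSE)
    out <- c(out, f)
  }
  invisible(out)
}
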