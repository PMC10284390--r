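#' Detect microtubule asters as multi-scale Laplacian-of-Gaussian blobs
#'
#' Scale-normalized LoG responses are computed over a small sigma ladder,
#' maximized over scale, and local maxima above a relative threshold are
#' kept with non-maximum suppression at a minimum separation of
#' `min_sigma`. The threshold is relative to the strongest response, so
#' detections are invariant to a constant intensity rescaling.
#'
#' @param frame Y x X numeric matrix (microtubule channel).
#' @param min_sigma,max_sigma blob scale range, um (capped so the
#'   Gaussian kernel fits inside the frame).
#' @param n_scales number of sigmas in the ladder.
#' @param threshold relative response threshold in (0, 1). An absolute
#'   floor of 1e-3 of the frame's dynamic range is applied as well, so a
#'   featureless frame yields no detections while detections remain
#'   invariant to intensity rescaling.
#' @param pixel_size um per pixel.
#' @param mask optional logical matrix restricting detections to the
#'   oocyte; the exterior is flattened to the interior median before
#'   filtering, so the oocyte boundary (a strong LoG edge otherwise)
#'   cannot register as a blob.
#' @return Data frame with `x`, `y` (um), `sigma` (um) and `response`;
#'   zero rows when nothing is found.
#' @export
detect_asters <- function(frame, min_sigma = 4, max_sigma = 10,
                          n_scales = 3, threshold = 0.3, pixel_size = 1,
                          mask = NULL) {
  if (!is.matrix(frame)) stop("'frame' must be a matrix")
  m <- normalize01(frame)
  if (!is.null(mask)) m[!mask] <- median(m[mask])
  smax <- pixel_size * (min(dim(m)) - 1) / 8  # kernel must fit the frame
  sigmas <- unique(pmin(seq(min_sigma, max_sigma, length.out = n_scales),
                        smax))
  lap <- matrix(0, 3, 3)
  lap[2, ] <- lap[, 2] <- 1; lap[2, 2] <- -4
  best <- matrix(-Inf, nrow(m), ncol(m))
  best_s <- matrix(sigmas[1], nrow(m), ncol(m))
  for (s in sigmas) {
    g <- EBImage::imageData(EBImage::gblur(EBImage::Image(m),
                                           sigma = s / pixel_size))
    resp <- -(s / pixel_size)^2 *
      EBImage::imageData(EBImage::filter2(EBImage::Image(g), lap))
    upd <- resp > best
    best[upd] <- resp[upd]
    best_s[upd] <- s
  }
  if (!is.null(mask)) best[!mask] <- -Inf
  floor_abs <- max(1e-3 * diff(range(m)), 1e-9)
  rmax <- max(best)
  if (!is.finite(rmax) || rmax <= floor_abs)
    return(data.frame(x = numeric(), y = numeric(), sigma = numeric(),
                      response = numeric()))
  sep <- max(1L, round(min_sigma / pixel_size))
  brush <- EBImage::makeBrush(2L * sep + 1L, shape = "disc")
  fin_min <- min(best[is.finite(best)])
  bestf <- best; bestf[!is.finite(bestf)] <- fin_min
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(bestf - fin_min),
                                            brush)) + fin_min
  peaks <- which(best >= dil - 1e-12 & best >= threshold * rmax &
                   best > floor_abs)
  if (!length(peaks))
    return(data.frame(x = numeric(), y = numeric(), sigma = numeric(),
                      response = numeric()))
  nr <- nrow(m)
  i <- (peaks - 1L) %% nr + 1L
  j <- (peaks - 1L) %/% nr + 1L
  # collapse plateau peaks closer than the suppression radius
  ord <- order(-best[peaks])
  keep <- logical(length(peaks))
  for (k in ord) {
    if (any(keep & (i - i[k])^2 + (j - j[k])^2 < sep^2)) next
    keep[k] <- TRUE
  }
  data.frame(x = (j[keep] - 0.5) * pixel_size,
             y = (i[keep] - 0.5) * pixel_size,
             sigma = best_s[peaks][keep],
             response = best[peaks][keep])
}

#' Aster counts (and density) over a time-lapse
#'
#' Runs [detect_asters()] with fixed parameters on every frame. The
#' relative response threshold is applied against the strongest response
#' of the whole series, not per frame, so frames recorded before any
#' aster has formed yield zero detections instead of normalizing the
#' threshold to their own noise. When a per-frame oocyte area is
#' supplied the aster density is reported per 1e5 um^2, which makes
#' counts comparable between oocytes of different size.
#'
#' @param tl an `oo_timelapse`.
#' @param channel channel name or index (default "microtubule").
#' @param oocyte_area optional numeric vector (um^2), one value per frame
#'   or a single value recycled.
#' @param threshold relative response threshold, as in [detect_asters()],
#'   applied against the series-wide maximum response.
#' @param ... passed to [detect_asters()] (fixed across frames); pass
#'   `mask =` the oocyte mask to keep the oocyte boundary out of the
#'   detections.
#' @return An `oo_aster_table` data frame: `frame`, `time_s`, `count`,
#'   `density` (per 1e5 um^2; NA without area), plus a `spots` attribute
#'   holding the per-frame detections.
#' @export
aster_counts <- function(tl, channel = "microtubule", oocyte_area = NULL,
                         threshold = 0.3, ...) {
  if (!inherits(tl, "oo_timelapse")) stop("'tl' must be an oo_timelapse")
  nT <- dim(tl$frames)[1]
  if (!is.null(oocyte_area)) {
    if (length(oocyte_area) == 1L) oocyte_area <- rep(oocyte_area, nT)
    if (length(oocyte_area) != nT) stop("area series length mismatch")
  }
  spots <- vector("list", nT)
  for (t in seq_len(nT)) {
    spots[[t]] <- detect_asters(tl_frame(tl, t, channel),
                                pixel_size = tl$pixel_size,
                                threshold = 0, ...)
  }
  rmax <- max(c(0, vapply(spots, function(s)
    if (nrow(s)) max(s$response) else 0, numeric(1))))
  counts <- integer(nT)
  for (t in seq_len(nT)) {
    sp <- spots[[t]][spots[[t]]$response >= threshold * rmax, ,
                     drop = FALSE]
    spots[[t]] <- sp
    counts[t] <- nrow(sp)
  }
  out <- data.frame(
    frame = seq_len(nT), time_s = (seq_len(nT) - 1) * tl$frame_interval,
    count = counts,
    density = if (is.null(oocyte_area)) NA_real_
              else counts / oocyte_area * 1e5
  )
  attr(out, "spots") <- spots
  class(out) <- c("oo_aster_table", "data.frame")
  out
}

#' Temporal maximum-intensity projection with time-of-maximum map
#'
#' Per-pixel maximum over the chosen frame range plus the frame index at
#' which each pixel attains it - the quantitative counterpart of a
#' temporal color-coded projection used to outline contracting microtubule
#' structures.
#'
#' @param tl an `oo_timelapse`.
#' @param channel channel name or index.
#' @param range frame range (default all frames).
#' @return List with `projection` (matrix) and `tmax` (frame-of-maximum,
#'   integer matrix, indices within `range`'s original frame numbering).
#' @export
temporal_projection <- function(tl, channel, range = NULL) {
  if (!inherits(tl, "oo_timelapse")) stop("'tl' must be an oo_timelapse")
  nT <- dim(tl$frames)[1]
  if (is.null(range)) range <- seq_len(nT)
  if (length(range) < 1 || min(range) < 1 || max(range) > nT)
    stop("empty or out-of-bounds range")
  proj <- tl_frame(tl, range[1], channel)
  tmax <- matrix(range[1], nrow(proj), ncol(proj))
  for (t in range[-1]) {
    fr <- tl_frame(tl, t, channel)
    upd <- fr > proj
    proj[upd] <- fr[upd]
    tmax[upd] <- t
  }
  list(projection = proj, tmax = tmax)
}
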