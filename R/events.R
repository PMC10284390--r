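#' Histogram of fusion (merge) events over time
#'
#' Bins the merge events of a track set by time. An optional granule
#' subsample emulates scoring fusions on a random subset of 10-20 granules
#' per oocyte: only merges whose surviving or absorbed track belongs to
#' the subsample are counted.
#'
#' @param tracks an `oo_track_set`.
#' @param bin_minutes histogram bin width, minutes (default 10).
#' @param subsample optional number of tracks to sample (seeded by
#'   `seed`); NULL counts all merges.
#' @param seed RNG seed for the subsample.
#' @return List with `breaks_min`, `counts`, and `total`.
#' @export
fusion_histogram <- function(tracks, bin_minutes = 10, subsample = NULL,
                             seed = 1L) {
  if (!inherits(tracks, "oo_track_set")) stop("'tracks' must be an oo_track_set")
  if (bin_minutes <= 0) stop("'bin_minutes' must be > 0")
  mg <- tracks$merges
  if (!is.null(subsample)) {
    ids <- sort(unique(tracks$tracks$track))
    if (subsample < length(ids)) {
      pick <- with_seed(seed, sample(ids, subsample))
      mg <- mg[mg$incoming %in% pick | mg$survivor %in% pick, , drop = FALSE]
    }
  }
  t_min <- (mg$frame - 1) * tracks$frame_interval / 60
  n_frames <- max(tracks$tracks$frame)
  t_max <- (n_frames - 1) * tracks$frame_interval / 60
  breaks <- seq(0, ceiling(t_max / bin_minutes) * bin_minutes + bin_minutes,
                by = bin_minutes)
  counts <- if (nrow(mg)) tabulate(findInterval(t_min, breaks,
                                                rightmost.closed = TRUE),
                                   nbins = length(breaks) - 1L)
            else integer(length(breaks) - 1L)
  list(breaks_min = breaks, counts = counts, total = sum(counts))
}

#' Mean granule cross-sectional area per frame and its fold change
#'
#' The per-frame mean 2D area of segmented granules, and the area factor:
#' final mean area over first mean area. After an expected
#' `fusion_rounds_mean` pairwise-fusion rounds with 3D volume
#' conservation, the factor approaches `2^(2 * rounds / 3)` - the
#' calibrated default of 1.5 rounds doubles the mean area.
#'
#' @param x an `oo_track_set`, or a list of `oo_label_frame`s.
#' @return List with `frame`, `mean_area` (um^2, NA where a frame has no
#'   granules), and `area_factor` (last finite / first finite).
#' @export
mean_area_series <- function(x) {
  if (inherits(x, "oo_track_set")) {
    tr <- x$tracks
    frames <- sort(unique(tr$frame))
    mean_area <- vapply(frames, function(f)
      mean(tr$area[tr$frame == f]), numeric(1))
  } else if (is.list(x)) {
    frames <- seq_along(x)
    mean_area <- vapply(x, function(lf) {
      st <- label_stats(if (inherits(lf, "oo_label_frame")) lf$labels else lf,
                        if (inherits(lf, "oo_label_frame")) lf$pixel_size else 1)
      if (nrow(st)) mean(st$area) else NA_real_
    }, numeric(1))
  } else stop("'x' must be an oo_track_set or a list of label frames")
  fin <- which(is.finite(mean_area))
  if (!length(fin)) stop("no frame contains granules")
  list(frame = frames, mean_area = mean_area,
       area_factor = mean_area[fin[length(fin)]] / mean_area[fin[1]])
}

#' Cortical granule depletion ratio upon egg activation
#'
#' Percentage of pre-activation granules that underwent exocytosis, i.e.
#' have no overlapping granule in the post-activation frame. Overlap means
#' any shared pixel; no registration is applied, matching the comparison
#' of the last frame before and the first frame after activation of an
#' immobilized egg.
#'
#' @param pre,post `oo_label_frame`s (cortical class) of the same field of
#'   view.
#' @return Depletion ratio in percent (0-100).
#' @export
depletion_ratio <- function(pre, post) {
  lp <- if (inherits(pre, "oo_label_frame")) pre$labels else pre
  la <- if (inherits(post, "oo_label_frame")) post$labels else post
  if (!identical(dim(lp), dim(la))) stop("fields of view differ")
  n_pre <- max(lp)
  if (n_pre < 1L) stop("empty pre-activation granule set")
  surviving <- unique(lp[lp > 0L & la > 0L])
  100 * (n_pre - length(surviving)) / n_pre
}

#' K+ vesicle counts per frame
#'
#' @param label_frames list of `oo_label_frame`s (kplus class) or integer
#'   label matrices.
#' @return Data frame with `frame` and `count`.
#' @export
k_vesicle_counts <- function(label_frames) {
  counts <- vapply(label_frames, function(lf) {
    l <- if (inherits(lf, "oo_label_frame")) lf$labels else lf
    length(unique(l[l > 0L]))
  }, integer(1))
  data.frame(frame = seq_along(label_frames), count = counts)
}

#' Chorion elevation ratio from a brightfield frame
#'
#' Detects the two roughly concentric circular boundaries (chorion and
#' oocyte) by edge detection followed by radial Hough-style voting: edge
#' pixels vote for their distance to the common center (estimated as the
#' edge centroid, refined once), and the two strongest, well-separated
#' radius peaks give the chorion and oocyte radii. The ratio is outer
#' diameter / inner diameter - the standard chorion elevation measure.
#'
#' @param frame Y x X numeric matrix (brightfield).
#' @param pixel_size um per pixel.
#' @param edge_quantile quantile of the gradient magnitude above which a
#'   pixel is an edge (default 0.95).
#' @param min_separation_um minimum radius separation of the two peaks.
#' @return List with `ratio`, `r_inner`, `r_outer` (um) and `center`.
#' @export
chorion_ratio <- function(frame, pixel_size = 1, edge_quantile = 0.95,
                          min_separation_um = 5) {
  m <- normalize01(frame)
  gx <- m[, c(2:ncol(m), ncol(m))] - m[, c(1, 1:(ncol(m) - 1))]
  gy <- m[c(2:nrow(m), nrow(m)), ] - m[c(1, 1:(nrow(m) - 1)), ]
  mag <- sqrt(gx^2 + gy^2)
  thr <- stats::quantile(mag[mag > 0], edge_quantile)
  idx <- which(mag >= thr)
  if (length(idx) < 20) stop("fewer than two circles found")
  nr <- nrow(m)
  i <- (idx - 1L) %% nr + 1L
  j <- (idx - 1L) %/% nr + 1L
  x <- (j - 0.5) * pixel_size; y <- (i - 0.5) * pixel_size
  ctr <- c(mean(x), mean(y))
  for (it in 1:2) {  # one refinement pass of the common center
    r <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
    w <- 1 / pmax(r, 1)  # balance the vote between the two circles
    ctr <- c(sum(x * w) / sum(w), sum(y * w) / sum(w))
  }
  r <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
  bw <- pixel_size
  h <- tabulate(floor(r / bw) + 1L)
  hs <- stats::filter(h, rep(1 / 3, 3), sides = 2)
  hs[is.na(hs)] <- 0
  p1 <- which.max(hs)
  sep <- ceiling(min_separation_um / bw)
  h2 <- hs
  h2[max(1, p1 - sep):min(length(h2), p1 + sep)] <- 0
  if (max(h2) <= 0 || max(h2) < 0.1 * max(hs)) {
    # a single radius peak: either the chorion sits on the oocyte
    # (elevation ratio 1) or there is only one circle in the frame
    r1 <- (p1 - 0.5) * bw
    if (stats::sd(r[abs(r - r1) <= 3 * bw]) <= 1.5 * bw &&
        mean(abs(r - r1) <= 3 * bw) > 0.9)
      return(list(ratio = 1.0, r_inner = r1, r_outer = r1, center = ctr))
    stop("fewer than two circles found")
  }
  p2 <- which.max(h2)
  # refine each radius as the mean edge distance near its peak; the
  # window spans both gradient edges of a ring so the estimate centers
  # on the ring rather than one of its sides
  refine <- function(p) {
    sel <- abs(r - (p - 0.5) * bw) <= 3 * bw
    mean(r[sel])
  }
  r_in <- refine(min(p1, p2)); r_out <- refine(max(p1, p2))
  list(ratio = r_out / r_in, r_inner = r_in, r_outer = r_out, center = ctr)
}
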