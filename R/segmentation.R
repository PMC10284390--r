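#' Segment the oocyte outline from a single channel
#'
#' Smooths the channel, applies a global Otsu threshold, keeps the largest
#' connected component and fills its holes (granules are dark in the
#' ooplasm channel, so the interior is full of holes before filling).
#'
#' @param frame Y x X numeric matrix with interior/exterior contrast
#'   (typically the ooplasm channel).
#' @param pixel_size um per pixel.
#' @param smooth_sigma Gaussian smoothing sigma, um.
#' @return Logical Y x X mask of the oocyte (simply connected).
#' @export
segment_oocyte <- function(frame, pixel_size = 1, smooth_sigma = 2) {
  if (!is.matrix(frame)) stop("'frame' must be a matrix")
  m <- normalize01(frame)
  if (max(m) <= 0) stop("no foreground found")
  if (smooth_sigma > 0)
    m <- EBImage::imageData(EBImage::gblur(EBImage::Image(m),
                                           sigma = smooth_sigma / pixel_size))
  thr <- EBImage::otsu(EBImage::Image(m))
  bw <- m > thr
  if (!any(bw)) stop("no foreground found")
  lab <- EBImage::bwlabel(EBImage::Image(bw))
  tab <- tabulate(lab[lab > 0])
  big <- which.max(tab)
  mask <- EBImage::imageData(lab) == big
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  mask
}

normalize01 <- function(m) {
  storage.mode(m) <- "double"
  mx <- max(m)
  if (mx > 1) m / 65535 else m
}

#' Segment granules of one class from a multi-channel frame
#'
#' Classical pipeline replacing interactive ML segmentation: Gaussian
#' smoothing, a global threshold (Otsu by default, overridable), a
#' distance-transform watershed to split touching granules, and a minimum
#' area filter. Yolk granules are the Lysotracker-positive blobs; cortical
#' granules are the blobs dark in BOTH the ooplasm and Lysotracker
#' channels, restricted to the oocyte mask eroded by 2 um (the cortex rim
#' blurs into the exterior, and an unclipped mask produces a spurious Cg
#' depletion next to the cortex). K+ and Rab11 classes are bright puncta in
#' their own channel.
#'
#' @param channels named list of Y x X matrices; yolk needs `lysotracker`,
#'   cortical needs `ooplasm` and `lysotracker`, kplus/rab11 need the
#'   channel of the same name. Use [tl_frame()] to pull channels from an
#'   `oo_timelapse`.
#' @param class one of `"yolk"`, `"cortical"`, `"kplus"`, `"rab11"`.
#' @param pixel_size um per pixel.
#' @param oocyte_mask optional logical mask; computed from the ooplasm (or,
#'   failing that, the target) channel when missing.
#' @param threshold optional numeric threshold(s) in [0, 1] overriding Otsu;
#'   for cortical a length-2 vector (ooplasm, lysotracker).
#' @param min_area minimum granule area, um^2 (defaults: yolk 20,
#'   cortical 3, kplus 3, rab11 1).
#' @param smooth_sigma Gaussian smoothing sigma, um.
#' @param frame_index stored in the result for bookkeeping.
#' @return An `oo_label_frame`: list with integer `labels` (background 0),
#'   `class`, `frame_index`, `pixel_size`.
#' @export
segment_granules <- function(channels, class = c("yolk", "cortical",
                                                 "kplus", "rab11"),
                             pixel_size = 1, oocyte_mask = NULL,
                             threshold = NULL, min_area = NULL,
                             smooth_sigma = 1, frame_index = 1L) {
  class <- match.arg(class)
  if (!is.list(channels) || is.null(names(channels)))
    stop("'channels' must be a named list of matrices")
  need <- switch(class, yolk = "lysotracker",
                 cortical = c("ooplasm", "lysotracker"),
                 kplus = "kplus", rab11 = "rab11")
  missing_ch <- setdiff(need, names(channels))
  if (length(missing_ch))
    stop("missing channel(s): ", paste(missing_ch, collapse = ", "))
  if (is.null(min_area))
    min_area <- switch(class, yolk = 20, cortical = 3, kplus = 3, rab11 = 1)

  smooth <- function(m) {
    if (smooth_sigma > 0)
      EBImage::imageData(EBImage::gblur(EBImage::Image(m),
                                        sigma = smooth_sigma / pixel_size))
    else m
  }
  otsu_in <- function(m, mask) {
    v <- m[mask]
    if (!length(v)) stop("empty oocyte mask")
    EBImage::otsu(EBImage::Image(matrix(clamp(v, 0, 1))))
  }

  if (is.null(oocyte_mask)) {
    src <- if ("ooplasm" %in% names(channels)) channels$ooplasm
           else channels[[need[1]]]
    oocyte_mask <- segment_oocyte(src, pixel_size)
  }
  if (!any(oocyte_mask)) stop("empty oocyte mask")

  if (class == "cortical") {
    oo <- smooth(normalize01(channels$ooplasm))
    ly <- smooth(normalize01(channels$lysotracker))
    if (is.null(threshold)) {
      thr_o <- otsu_in(oo, oocyte_mask)
      thr_l <- otsu_in(ly, oocyte_mask)
    } else {
      if (length(threshold) == 1L) threshold <- rep(threshold, 2)
      thr_o <- threshold[1]; thr_l <- threshold[2]
    }
    rim <- max(1L, round(2 / pixel_size))  # 2 um erosion of the rim
    core <- EBImage::imageData(EBImage::erode(
      EBImage::Image(oocyte_mask * 1),
      EBImage::makeBrush(2L * rim + 1L, shape = "disc"))) > 0
    # the dark membrane boundaries of yolk granules are Lysotracker- and
    # ooplasm-negative too; excluding the dilated yolk neighborhood keeps
    # inter-yolk membrane slivers out of the cortical class
    halo <- max(1L, round(2 / pixel_size))
    near_yolk <- EBImage::imageData(EBImage::dilate(
      EBImage::Image((ly > thr_l) * 1),
      EBImage::makeBrush(2L * halo + 1L, shape = "disc"))) > 0
    bw <- (oo < thr_o) & (ly < thr_l) & core & !near_yolk
  } else {
    tgt <- switch(class, yolk = "lysotracker", kplus = "kplus",
                  rab11 = "rab11")
    m <- smooth(normalize01(channels[[tgt]]))
    thr <- if (is.null(threshold)) otsu_in(m, oocyte_mask) else threshold[1]
    bw <- (m > thr) & oocyte_mask
  }

  labels <- split_and_filter(bw, pixel_size, min_area)
  structure(list(labels = labels, class = class,
                 frame_index = as.integer(frame_index),
                 pixel_size = pixel_size),
            class = "oo_label_frame")
}

# Distance-transform watershed split followed by a minimum-area filter,
# with sequential relabeling.
split_and_filter <- function(bw, pixel_size, min_area, suppress = 1.2) {
  zero <- matrix(0L, nrow(bw), ncol(bw))
  if (!any(bw)) return(zero)
  # fill noise holes so they do not crater the distance transform
  bw <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bw * 1))) > 0
  d <- EBImage::gblur(EBImage::distmap(EBImage::Image(bw * 1)), sigma = 1)
  d[!bw] <- 0
  dm <- EBImage::imageData(d)
  # seeds: local maxima of the distance map under scale-adaptive
  # non-maximum suppression - a peak of distance value v (granule radius
  # ~v) absorbs weaker maxima within suppress * v, so noise maxima inside
  # large granules vanish while touching small granules, whose centers
  # are at least one radius apart, keep separate seeds
  mx <- EBImage::imageData(EBImage::dilate(d, EBImage::makeBrush(3, "box")))
  rmin <- max(1, 0.5 * sqrt(min_area / pi) / pixel_size)
  cand <- which(dm >= mx - 1e-9 & dm >= rmin)
  if (!length(cand)) return(zero)
  nr <- nrow(bw)
  ci <- (cand - 1L) %% nr + 1L
  cj <- (cand - 1L) %/% nr + 1L
  cv <- dm[cand]
  ord <- order(-cv, cand)
  ki <- kj <- kv <- numeric(0)
  for (k in ord) {
    if (length(ki) &&
        any((ki - ci[k])^2 + (kj - cj[k])^2 < (suppress * kv)^2)) next
    ki <- c(ki, ci[k]); kj <- c(kj, cj[k]); kv <- c(kv, cv[k])
  }
  seeds <- zero
  seeds[cbind(ki, kj)] <- seq_along(ki)
  lab <- EBImage::imageData(EBImage::propagate(d, EBImage::Image(seeds),
                                               mask = bw))
  storage.mode(lab) <- "integer"
  # small components can miss the seed floor entirely; keep them as
  # objects of their own rather than dropping them
  cc <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
  storage.mode(cc) <- "integer"
  seeded <- unique(cc[lab > 0L])
  orphan <- cc > 0L & !(cc %in% seeded)
  if (any(orphan)) {
    shift <- max(lab)
    lab[orphan] <- cc[orphan] + shift
  }
  areas <- tabulate(lab[lab > 0]) * pixel_size^2
  keep <- which(areas >= min_area)
  if (!length(keep)) return(zero)
  remap <- integer(max(lab))
  remap[keep] <- seq_along(keep)
  out <- zero
  nz <- lab > 0
  out[nz] <- remap[lab[nz]]
  out
}

#' @export
print.oo_label_frame <- function(x, ...) {
  cat(sprintf("oo_label_frame (%s): %d object(s), frame %d\n",
              x$class, max(x$labels), x$frame_index))
  invisible(x)
}

# per-label area (um^2) and centroid (um) of a label matrix
label_stats <- function(labels, pixel_size) {
  idx <- which(labels > 0)
  if (!length(idx))
    return(data.frame(label = integer(), area = numeric(),
                      x = numeric(), y = numeric()))
  l <- labels[idx]
  nr <- nrow(labels)
  i <- (idx - 1L) %% nr + 1L
  j <- (idx - 1L) %/% nr + 1L
  n <- tapply(rep(1, length(l)), l, sum)
  cx <- (tapply(j, l, mean) - 0.5) * pixel_size
  cy <- (tapply(i, l, mean) - 0.5) * pixel_size
  data.frame(label = as.integer(names(n)), area = as.numeric(n) * pixel_size^2,
             x = as.numeric(cx), y = as.numeric(cy))
}
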