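#' Link label frames over time and record merges
#'
#' Frame-to-frame linking by maximal pixel overlap: each label of frame t
#' links to the label of frame t+1 it overlaps most (granules are large and
#' slow relative to the frame interval, so overlap linking is more robust
#' than centroid matching). Ties are broken by the larger overlap area,
#' then the smaller track id. A label receiving two or more links is a
#' merge (fusion) event; the track with the larger overlap survives. A
#' label with no incoming link starts a new track; a track with no outgoing
#' link ends.
#'
#' @param label_frames list of `oo_label_frame`s (or integer matrices) of
#'   the same class and shape, in temporal order (>= 2 frames).
#' @param pixel_size um per pixel (taken from the first `oo_label_frame`
#'   when available).
#' @param frame_interval seconds between frames (used downstream for event
#'   timing).
#' @return An `oo_track_set`: list with `tracks`
#'   (track, frame, label, x, y, area) and `merges`
#'   (frame, incoming, survivor) - one row per track absorbed in a merge,
#'   so a k-way merge contributes k-1 rows (pairwise fusion counting).
#' @export
track_labels <- function(label_frames, pixel_size = NULL,
                         frame_interval = 60) {
  if (length(label_frames) < 2L) stop("need >= 2 frames")
  mats <- lapply(label_frames, function(f) {
    if (inherits(f, "oo_label_frame")) f$labels else f
  })
  if (is.null(pixel_size)) {
    pixel_size <- if (inherits(label_frames[[1]], "oo_label_frame"))
      label_frames[[1]]$pixel_size else 1
  }
  cls <- vapply(label_frames, function(f)
    if (inherits(f, "oo_label_frame")) f$class else NA_character_,
    character(1))
  if (length(unique(stats::na.omit(cls))) > 1L)
    stop("label frames mix classes")
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
    stop("label frames differ in shape")

  n_frames <- length(mats)
  tracks <- vector("list", n_frames)
  merges <- list()
  next_track <- 1L

  st <- label_stats(mats[[1]], pixel_size)
  map <- integer(0)  # current frame: label -> track id
  if (nrow(st)) {
    map <- seq.int(next_track, next_track + nrow(st) - 1L)
    names(map) <- st$label
    next_track <- next_track + nrow(st)
  }
  tracks[[1]] <- data.frame(track = unname(map[as.character(st$label)]),
                            frame = 1L, label = st$label,
                            x = st$x, y = st$y, area = st$area)

  for (f in 2L:n_frames) {
    prev <- mats[[f - 1L]]; cur <- mats[[f]]
    both <- prev > 0L & cur > 0L
    links <- data.frame(from = integer(), to = integer(), ov = integer())
    if (any(both)) {
      tab <- table(prev[both], cur[both])
      from_lab <- as.integer(rownames(tab))
      to_lab <- as.integer(colnames(tab))
      # outgoing link of each previous label: maximal overlap target
      for (r in seq_along(from_lab)) {
        ov <- tab[r, ]
        best <- max(ov)
        if (best == 0) next
        cand <- which(ov == best)
        links <- rbind(links, data.frame(from = from_lab[r],
                                         to = to_lab[cand[1]],
                                         ov = as.integer(best)))
      }
    }
    st <- label_stats(cur, pixel_size)
    new_map <- integer(nrow(st))
    names(new_map) <- st$label
    for (r in seq_len(nrow(st))) {
      lab <- st$label[r]
      inc <- links[links$to == lab, , drop = FALSE]
      if (nrow(inc) == 0L) {
        new_map[r] <- next_track
        next_track <- next_track + 1L
      } else {
        inc$track <- unname(map[as.character(inc$from)])
        # survivor: larger overlap, then smaller track id
        inc <- inc[order(-inc$ov, inc$track), , drop = FALSE]
        new_map[r] <- inc$track[1]
        if (nrow(inc) > 1L) {
          merges[[length(merges) + 1L]] <- data.frame(
            frame = f, incoming = inc$track[-1], survivor = inc$track[1])
        }
      }
    }
    tracks[[f]] <- data.frame(track = unname(new_map[as.character(st$label)]),
                              frame = f, label = st$label,
                              x = st$x, y = st$y, area = st$area)
    map <- new_map
  }

  structure(list(
    tracks = do.call(rbind, tracks),
    merges = if (length(merges)) do.call(rbind, merges)
             else data.frame(frame = integer(), incoming = integer(),
                             survivor = integer()),
    pixel_size = pixel_size, frame_interval = frame_interval
  ), class = "oo_track_set")
}

#' @export
print.oo_track_set <- function(x, ...) {
  cat(sprintf("oo_track_set: %d track(s) over %d frame(s), %d merge(s)\n",
              length(unique(x$tracks$track)), max(x$tracks$frame),
              nrow(x$merges)))
  invisible(x)
}
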