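#' Build a width-averaged kymograph along a line or circumferential arc
#'
#' Each kymograph cell (position, time) is the mean of `width` bilinear
#' samples taken perpendicular to the line (or radially, for arcs) at that
#' position. Positions are spaced one pixel apart along the line/arc.
#'
#' @param tl an `oo_timelapse`.
#' @param channel channel name or index.
#' @param line an [line_spec()] for a straight line, or for an arc a list
#'   `list(center = c(x, y), radius = r, theta = c(from, to))` (radians,
#'   angle convention: 0 = animal pole, clockwise positive; positions run
#'   along arc length `radius * theta`).
#' @param width_px overrides the line's averaging width (odd, >= 1).
#' @return An `oo_kymograph`: list with `matrix` (positions x frames),
#'   `um_per_row`, `s_per_col`, and the sampling description.
#' @export
build_kymograph <- function(tl, channel, line, width_px = NULL) {
  if (!inherits(tl, "oo_timelapse")) stop("'tl' must be an oo_timelapse")
  px <- tl$pixel_size
  d <- dim(tl$frames)
  is_arc <- is.list(line) && !inherits(line, "oo_line_spec")

  if (is_arc) {
    if (!all(c("center", "radius", "theta") %in% names(line)))
      stop("arc must be list(center=, radius=, theta=)")
    width <- if (is.null(width_px)) 1L else as.integer(width_px)
    arc_len <- line$radius * abs(diff(line$theta))
    n_pos <- max(2L, floor(arc_len / px))
    th <- seq(line$theta[1], line$theta[2], length.out = n_pos)
    u <- angle_unit(th)
    base_x <- line$center[1] + u[, "x"] * line$radius
    base_y <- line$center[2] + u[, "y"] * line$radius
    # averaging offsets are radial
    nx <- u[, "x"]; ny <- u[, "y"]
    um_per_row <- arc_len / (n_pos - 1)
  } else {
    if (!inherits(line, "oo_line_spec")) stop("'line' must be a line_spec or arc")
    width <- if (is.null(width_px)) line$width else as.integer(width_px)
    v <- line$p2 - line$p1
    len <- sqrt(sum(v^2))
    n_pos <- max(2L, floor(len / px))
    tt <- seq(0, 1, length.out = n_pos)
    base_x <- line$p1[1] + v[1] * tt
    base_y <- line$p1[2] + v[2] * tt
    # perpendicular unit vector
    nx <- rep(-v[2] / len, n_pos); ny <- rep(v[1] / len, n_pos)
    um_per_row <- len / (n_pos - 1)
  }
  if (width < 1L || width %% 2L == 0L) stop("width must be odd and >= 1")
  fov_x <- d[4] * px; fov_y <- d[3] * px
  offs <- (seq_len(width) - (width + 1) / 2) * px
  sx <- outer(base_x, offs, function(b, o) b + nx * o)
  sy <- outer(base_y, offs, function(b, o) b + ny * o)
  if (min(sx) < -px || max(sx) > fov_x + px ||
      min(sy) < -px || max(sy) > fov_y + px)
    stop("line exits the image")

  mat <- matrix(NA_real_, n_pos, d[1])
  for (t in seq_len(d[1])) {
    fr <- tl_frame(tl, t, channel)
    vals <- matrix(bilinear(fr, as.vector(sx), as.vector(sy), px),
                   n_pos, width)
    mat[, t] <- rowMeans(vals)
  }
  structure(list(matrix = mat, um_per_row = um_per_row,
                 s_per_col = tl$frame_interval,
                 line = line, width = width, is_arc = is_arc),
            class = "oo_kymograph")
}

#' @export
print.oo_kymograph <- function(x, ...) {
  cat(sprintf("oo_kymograph: %d positions x %d frames (%.3g um/row, %g s/col)\n",
              nrow(x$matrix), ncol(x$matrix), x$um_per_row, x$s_per_col))
  invisible(x)
}

#' Extract a velocity from a kymograph by per-column feature localization
#'
#' Automates the manual line fits done on kymographs: in `edge` mode the
#' per-column interface position is located by the half-maximum crossing
#' (robust to intensity scaling) and a least-squares line is fitted; in
#' `ridge` mode the per-column intensity maximum is located and a robust
#' repeated-median (Siegel) line is fitted. The slope is converted to
#' um/min. Sign convention: positive = towards larger positions along the
#' line; orient the line so that outward/animal-pole-ward is positive.
#'
#' @param k an `oo_kymograph`.
#' @param roi optional `list(rows = range, cols = range)` sub-rectangle
#'   (indices); defaults to the whole kymograph.
#' @param mode `"edge"` or `"ridge"`.
#' @return An `oo_velocity`: list with `speed` (um/min), `fit_quality`
#'   (R^2 of the line fit in [0, 1]), `support` (positions um and frames
#'   used), and the per-column feature `positions`.
#' @export
extract_slope <- function(k, roi = NULL, mode = c("edge", "ridge")) {
  mode <- match.arg(mode)
  if (!inherits(k, "oo_kymograph")) stop("'k' must be an oo_kymograph")
  m <- k$matrix
  rows <- seq_len(nrow(m)); cols <- seq_len(ncol(m))
  if (!is.null(roi)) {
    if (!is.null(roi$rows)) rows <- roi$rows
    if (!is.null(roi$cols)) cols <- roi$cols
    if (min(rows) < 1 || max(rows) > nrow(m) ||
        min(cols) < 1 || max(cols) > ncol(m))
      stop("roi outside the kymograph")
  }
  sub <- m[rows, cols, drop = FALSE]
  pos_um <- (rows - 1) * k$um_per_row
  t_min <- (cols - 1) * k$s_per_col / 60

  feat <- rep(NA_real_, ncol(sub))
  for (c in seq_len(ncol(sub))) {
    prof <- sub[, c]
    if (all(!is.finite(prof)) || max(prof) == min(prof)) next
    if (mode == "ridge") {
      feat[c] <- pos_um[which.max(prof)]
    } else {
      half <- (max(prof) + min(prof)) / 2
      above <- prof >= half
      cr <- which(above[-1] != above[-length(above)])
      if (!length(cr)) next
      i <- cr[1]
      # linear interpolation of the crossing position
      f <- (half - prof[i]) / (prof[i + 1] - prof[i])
      feat[c] <- pos_um[i] + f * (pos_um[i + 1] - pos_um[i])
    }
  }
  ok <- is.finite(feat)
  if (mean(ok) < 0.5) stop("feature absent in > 50% of columns")
  x <- t_min[ok]; y <- feat[ok]
  if (mode == "ridge") {
    fit <- repeated_median_fit(x, y)
    pred <- fit$intercept + fit$slope * x
    ss_res <- sum((y - pred)^2); ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot == 0) 1 else clamp(1 - ss_res / ss_tot, 0, 1)
    speed <- fit$slope
  } else {
    fit <- stats::lm(y ~ x)
    speed <- unname(coef(fit)[2])
    r2 <- if (stats::var(y) == 0) 1 else summary(fit)$r.squared
  }
  structure(list(speed = speed, fit_quality = r2,
                 support = list(positions_um = range(y), frames = range(cols)),
                 positions = data.frame(t_min = x, pos_um = y)),
            class = "oo_velocity")
}

#' @export
print.oo_velocity <- function(x, ...) {
  cat(sprintf("velocity %.3g um/min (R^2 = %.3f)\n", x$speed, x$fit_quality))
  invisible(x)
}

#' Flow-speed profile along a kymograph from tracked trajectories
#'
#' Each trajectory (a feature entering the kymograph at a known position
#' and frame range) contributes one ridge-mode slope, plotted at its
#' normalized start position along the line (0 = line start, typically the
#' animal pole; 1 = line end).
#'
#' @param k an `oo_kymograph` (typically along the AV axis).
#' @param trajectories data frame with columns `position_um` (start
#'   position along the line), `frame_start`, `frame_end`, and optionally
#'   `window_um` (half-width of the position band searched; default 15).
#' @return Data frame with `norm_position`, `speed_um_min`, `fit_quality`.
#' @export
flow_profile <- function(k, trajectories) {
  if (!inherits(k, "oo_kymograph")) stop("'k' must be an oo_kymograph")
  if (nrow(trajectories) < 1) stop("need >= 1 trajectory")
  line_len <- (nrow(k$matrix) - 1) * k$um_per_row
  win <- if ("window_um" %in% names(trajectories)) trajectories$window_um
         else rep(15, nrow(trajectories))
  out <- lapply(seq_len(nrow(trajectories)), function(i) {
    p0 <- trajectories$position_um[i]
    if (p0 < 0 || p0 > line_len) stop("trajectory outside kymograph")
    # follow the ridge column by column inside a moving window
    cols <- trajectories$frame_start[i]:trajectories$frame_end[i]
    if (min(cols) < 1 || max(cols) > ncol(k$matrix))
      stop("trajectory outside kymograph")
    pos <- p0
    xs <- numeric(0); ys <- numeric(0)
    for (c in cols) {
      r0 <- max(1, floor((pos - win[i]) / k$um_per_row) + 1)
      r1 <- min(nrow(k$matrix), ceiling((pos + win[i]) / k$um_per_row) + 1)
      prof <- k$matrix[r0:r1, c]
      ridge <- (r0 - 1 + which.max(prof) - 1) * k$um_per_row
      xs <- c(xs, (c - 1) * k$s_per_col / 60)
      ys <- c(ys, ridge)
      pos <- ridge
    }
    fit <- repeated_median_fit(xs, ys)
    pred <- fit$intercept + fit$slope * xs
    ss_tot <- sum((ys - mean(ys))^2)
    r2 <- if (ss_tot == 0) 1 else clamp(1 - sum((ys - pred)^2) / ss_tot, 0, 1)
    data.frame(norm_position = p0 / line_len, speed_um_min = fit$slope,
               fit_quality = r2)
  })
  do.call(rbind, out)
}

#' Wave speed from an onset-front kymograph
#'
#' For a circumferential kymograph of aster formation, the onset time at
#' each arc position is the first frame whose intensity exceeds the
#' threshold; a least-squares line fitted to onset time versus arc
#' position gives the front speed as the inverse slope.
#'
#' @param k an `oo_kymograph` (circumferential arc).
#' @param threshold onset threshold; default halfway between the kymograph
#'   minimum and maximum.
#' @param min_fraction minimum fraction of positions that must show an
#'   onset (default 0.5); otherwise an error.
#' @return Speed in um/min. `Inf` (with a warning) when onset is
#'   simultaneous everywhere - the degenerate infinite-speed front.
#' @export
wave_speed <- function(k, threshold = NULL, min_fraction = 0.5) {
  if (!inherits(k, "oo_kymograph")) stop("'k' must be an oo_kymograph")
  m <- k$matrix
  if (is.null(threshold)) threshold <- (max(m) + min(m)) / 2
  onset <- apply(m, 1, function(row) {
    w <- which(row >= threshold)
    if (length(w)) w[1] else NA_integer_
  })
  ok <- !is.na(onset)
  if (mean(ok) < min_fraction) stop("no onset front detected")
  pos <- (which(ok) - 1) * k$um_per_row
  t_min <- (onset[ok] - 1) * k$s_per_col / 60
  if (stats::var(t_min) == 0) {
    warning("simultaneous onset everywhere; returning Inf")
    return(Inf)
  }
  fit <- stats::lm(t_min ~ pos)
  slope <- unname(coef(fit)[2])  # min per um
  if (slope == 0) {
    warning("flat onset fit; returning Inf")
    return(Inf)
  }
  abs(1 / slope)
}
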