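#' Fit oocyte geometry: center of mass and per-angle radius
#'
#' The oocyte radius is measured along 72 rays at 5 degree increments from
#' the mask center of mass; the per-angle radius R(theta), rather than a
#' single mean radius, later normalizes each pixel's radial position.
#'
#' @param mask logical oocyte mask (from [segment_oocyte()]).
#' @param pixel_size um per pixel.
#' @param animal_pole_angle angle of the animal pole, degrees (0 = "up",
#'   clockwise positive); stored for downstream arc conventions.
#' @return An `oo_geometry`: list with `center` (x, y um),
#'   `radius_by_angle` (72 values, um, at `angles_deg`), and
#'   `animal_pole_angle`.
#' @export
fit_geometry <- function(mask, pixel_size = 1, animal_pole_angle = 0) {
  if (!any(mask)) stop("empty mask")
  idx <- which(mask)
  nr <- nrow(mask)
  i <- (idx - 1L) %% nr + 1L
  j <- (idx - 1L) %/% nr + 1L
  center <- c(x = (mean(j) - 0.5) * pixel_size,
              y = (mean(i) - 0.5) * pixel_size)
  angles <- seq(0, 355, by = 5) * pi / 180
  rmax <- max(nrow(mask), ncol(mask)) * pixel_size
  steps <- seq(0, rmax, by = pixel_size / 2)
  radius <- vapply(angles, function(th) {
    u <- angle_unit(th)
    x <- center[1] + u[, "x"] * steps
    y <- center[2] + u[, "y"] * steps
    jj <- floor(x / pixel_size) + 1L
    ii <- floor(y / pixel_size) + 1L
    ok <- jj >= 1 & jj <= ncol(mask) & ii >= 1 & ii <= nrow(mask)
    inside <- logical(length(steps))
    inside[ok] <- mask[cbind(ii[ok], jj[ok])]
    if (!inside[1]) return(NA_real_)
    steps[max(which(inside))]
  }, numeric(1))
  if (any(is.na(radius)) || any(radius <= 0))
    stop("ray missed the mask boundary (mask not star-shaped around center)")
  structure(list(center = center, radius_by_angle = radius,
                 angles_deg = seq(0, 355, by = 5),
                 animal_pole_angle = animal_pole_angle),
            class = "oo_geometry")
}

#' @export
print.oo_geometry <- function(x, ...) {
  cat(sprintf("oo_geometry: center (%.1f, %.1f) um, R = %.1f +- %.1f um\n",
              x$center[1], x$center[2], mean(x$radius_by_angle),
              stats::sd(x$radius_by_angle)))
  invisible(x)
}

# R(theta) linearly interpolated (periodic) at arbitrary angles (radians).
geometry_radius_at <- function(geometry, theta) {
  ang <- geometry$angles_deg * pi / 180
  r <- geometry$radius_by_angle
  # periodic wrap: append the first node at 2*pi
  stats::approx(c(ang, 2 * pi), c(r, r[1]),
                xout = theta %% (2 * pi), rule = 2)$y
}

# normalized radius r/R(theta) of micrometre points (x, y)
normalized_radius <- function(geometry, x, y) {
  ctr <- geometry$center
  d <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
  th <- point_angle(x, y, ctr)
  d / geometry_radius_at(geometry, th)
}

#' Phase-fraction profile over the normalized oocyte radius
#'
#' Every pixel of the ooplasm, yolk and cortical phase masks is assigned a
#' normalized radius r/R(theta) using its own angle's oocyte radius, and
#' binned. Within each bin the three phase counts are normalized to the
#' total phase (their sum), giving per-bin fractions that sum to 1. Bins
#' with zero occupancy report NA fractions rather than 0, so an empty bin
#' is never mistaken for depletion.
#'
#' @param phases named list of logical masks `ooplasm`, `yolk`, `cortical`
#'   (same shape). Non-listed pixels (exterior, GV) are ignored.
#' @param geometry an `oo_geometry` from [fit_geometry()].
#' @param n_bins number of equal bins on [0, 1] (default 20).
#' @param pixel_size um per pixel.
#' @return An `oo_phase_profile`: list with `edges` (length n_bins + 1),
#'   `fraction` (n_bins x 3 matrix, columns ooplasm/yolk/cortical) and
#'   `occupancy` (total phase pixels per bin). Pixels with r/R > 1 (border
#'   effects) land in the last bin.
#' @export
phase_fractions <- function(phases, geometry, n_bins = 20, pixel_size = 1) {
  need <- c("ooplasm", "yolk", "cortical")
  if (!all(need %in% names(phases)))
    stop("'phases' must contain ooplasm, yolk and cortical masks")
  if (n_bins < 2) stop("'n_bins' must be >= 2")
  d <- dim(phases[[need[1]]])
  counts <- matrix(0, n_bins, 3, dimnames = list(NULL, need))
  total_px <- 0L
  for (k in seq_along(need)) {
    m <- phases[[need[k]]]
    if (!identical(dim(m), d)) stop("phase masks differ in shape")
    idx <- which(m)
    total_px <- total_px + length(idx)
    if (!length(idx)) next
    nr <- d[1]
    i <- (idx - 1L) %% nr + 1L
    j <- (idx - 1L) %/% nr + 1L
    x <- (j - 0.5) * pixel_size
    y <- (i - 0.5) * pixel_size
    rn <- normalized_radius(geometry, x, y)
    bin <- clamp(floor(rn * n_bins) + 1L, 1L, n_bins)
    counts[, k] <- counts[, k] + tabulate(bin, nbins = n_bins)
  }
  if (total_px == 0L) stop("all-background input")
  occupancy <- rowSums(counts)
  fraction <- counts / occupancy  # NaN where occupancy == 0
  fraction[occupancy == 0, ] <- NA_real_
  structure(list(edges = seq(0, 1, length.out = n_bins + 1),
                 fraction = fraction, occupancy = occupancy),
            class = "oo_phase_profile")
}

#' Per-bin change between two phase profiles
#'
#' @param profile_a,profile_b `oo_phase_profile`s with identical binning;
#'   the result is `profile_b - profile_a` per phase per bin.
#' @return Matrix of per-bin fraction changes (NA where either profile has
#'   an empty bin).
#' @export
delta_phase <- function(profile_a, profile_b) {
  if (!inherits(profile_a, "oo_phase_profile") ||
      !inherits(profile_b, "oo_phase_profile"))
    stop("inputs must be oo_phase_profile objects")
  if (!isTRUE(all.equal(profile_a$edges, profile_b$edges)))
    stop("binning mismatch")
  profile_b$fraction - profile_a$fraction
}

#' Radial histogram and surface density of granules
#'
#' Granule centroids are binned by normalized radius (bin width 0.05), and
#' the surface density is the summed granule area divided by the imaging
#' plane (oocyte cross-section) area.
#'
#' @param label_frame an `oo_label_frame` (typically cortical class).
#' @param geometry an `oo_geometry`.
#' @param bin_width normalized-radius bin width (default 0.05).
#' @param plane_area imaging-plane area in um^2; defaults to the polygon
#'   area implied by the fitted R(theta).
#' @return An `oo_density_profile`: list with `breaks`, `counts`,
#'   `surface_density` (dimensionless area fraction in [0, 1]) and the
#'   per-granule `radii` (normalized).
#' @export
radial_histogram <- function(label_frame, geometry, bin_width = 0.05,
                             plane_area = NULL) {
  if (!inherits(label_frame, "oo_label_frame"))
    stop("'label_frame' must be an oo_label_frame")
  px <- label_frame$pixel_size
  st <- label_stats(label_frame$labels, px)
  if (is.null(plane_area)) {
    th <- geometry$angles_deg * pi / 180
    r <- geometry$radius_by_angle
    plane_area <- 0.5 * sum(r^2 * (2 * pi / length(th)))
  }
  breaks <- seq(0, ceiling(1.2 / bin_width) * bin_width, by = bin_width)
  if (nrow(st) == 0)
    return(structure(list(breaks = breaks,
                          counts = integer(length(breaks) - 1L),
                          surface_density = 0, radii = numeric(0)),
                     class = "oo_density_profile"))
  rn <- normalized_radius(geometry, st$x, st$y)
  rn <- clamp(rn, 0, max(breaks) - 1e-9)
  counts <- tabulate(floor(rn / bin_width) + 1L, nbins = length(breaks) - 1L)
  structure(list(breaks = breaks, counts = counts,
                 surface_density = clamp(sum(st$area) / plane_area, 0, 1),
                 radii = rn),
            class = "oo_density_profile")
}

#' Mean intensity of a region of interest over time, with normalization
#'
#' Covers the fixed-ROI intensity measurements (square ROIs in the GV or
#' oocyte center, brightfield attenuation) and band profiles along a
#' measurement line (AV-axis or circumferential scans). Normalization
#' modes: `none`; `to_first` (divide by the first frame's value);
#' `to_reference_frame` (divide by the value at `reference_frame`);
#' `to_AP_value` (profiles: divide by the value at the first position, the
#' animal pole); `subtract_baseline_then_peak` (profiles: subtract the
#' profile at `reference_frame`, then divide by the maximum - used for the
#' nucleoplasm redistribution after GV breakdown).
#'
#' @param tl an `oo_timelapse`.
#' @param channel channel name or index.
#' @param roi either `c(x0, y0, x1, y1)` in um (rectangle; mean per frame)
#'   or an [line_spec()] (band profile: mean across the width, per position
#'   and frame).
#' @param normalization one of the modes above.
#' @param reference_frame frame index for the reference modes.
#' @return For a rectangle: numeric series, one value per frame. For a
#'   line: matrix positions x frames with attribute `positions_um`.
#' @export
roi_intensity <- function(tl, channel, roi,
                          normalization = c("none", "to_first",
                                            "to_reference_frame",
                                            "to_AP_value",
                                            "subtract_baseline_then_peak"),
                          reference_frame = 1L) {
  normalization <- match.arg(normalization)
  if (!inherits(tl, "oo_timelapse")) stop("'tl' must be an oo_timelapse")
  nT <- dim(tl$frames)[1]
  px <- tl$pixel_size

  if (inherits(roi, "oo_line_spec")) {
    k <- build_kymograph(tl, channel, roi)
    prof <- k$matrix  # positions x frames
    out <- switch(normalization,
      none = prof,
      to_first = prof / prof[, 1],
      to_reference_frame = prof / prof[, reference_frame],
      to_AP_value = sweep(prof, 2, prof[1, ], "/"),
      subtract_baseline_then_peak = {
        d <- prof - prof[, reference_frame]
        d / max(d)
      })
    attr(out, "positions_um") <- (seq_len(nrow(prof)) - 0.5) * k$um_per_row
    return(out)
  }

  if (length(roi) != 4) stop("rectangle roi must be c(x0, y0, x1, y1)")
  j0 <- floor(roi[1] / px) + 1L; j1 <- ceiling(roi[3] / px)
  i0 <- floor(roi[2] / px) + 1L; i1 <- ceiling(roi[4] / px)
  d <- dim(tl$frames)
  if (j0 < 1 || i0 < 1 || j1 > d[4] || i1 > d[3] || j0 > j1 || i0 > i1)
    stop("ROI outside the frame or empty")
  series <- vapply(seq_len(nT), function(t)
    mean(tl_frame(tl, t, channel)[i0:i1, j0:j1]), numeric(1))
  switch(normalization,
         none = series,
         to_first = series / series[1],
         to_reference_frame = series / series[reference_frame],
         to_AP_value = stop("to_AP_value applies to line profiles"),
         subtract_baseline_then_peak = {
           s <- series - series[reference_frame]
           s / max(s)
         })
}

#' Voxel-count volume of a binary 3D stack
#'
#' Volume as the voxel count times `pixel_size^2 * z_step`, the way oocyte
#' volume is measured from segmented, binarized Z stacks.
#'
#' @param stack 3D logical/0-1 array (Y x X x Z) or list of binary slices.
#' @param pixel_size um per pixel in-plane.
#' @param z_step um between slices.
#' @return Volume in um^3.
#' @export
voxel_volume <- function(stack, pixel_size, z_step) {
  stopifnot_scalar(pixel_size, "pixel_size")
  stopifnot_scalar(z_step, "z_step")
  if (is.list(stack)) {
    total <- 0
    for (s in stack) {
      v <- as.vector(s)
      if (!all(v %in% c(0, 1, TRUE, FALSE))) stop("stack must be binary")
      total <- total + sum(v != 0)
    }
  } else {
    v <- as.vector(stack)
    if (!all(v %in% c(0, 1, TRUE, FALSE))) stop("stack must be binary")
    total <- sum(v != 0)
  }
  total * pixel_size^2 * z_step
}

#' Binary voxel stacks of the synthetic oocyte and its germinal vesicle
#'
#' Digitizes the scene's spheres (oocyte and GV) on a voxel grid, slice by
#' slice, for the voxel-count volume pipeline. A voxel belongs to a sphere
#' when its center lies inside.
#'
#' @param params an [scene_params()].
#' @param voxel_size um per voxel in-plane (slices are spaced `z_step` um).
#' @param z_step um between slices (default equal to `voxel_size`).
#' @return List with binary arrays `oocyte` and `gv` (Y x X x Z) and the
#'   calibration used.
#' @export
scene_volume_stacks <- function(params, voxel_size = 2, z_step = voxel_size) {
  if (!inherits(params, "oo_scene_params"))
    stop("'params' must be created by scene_params()")
  R <- params$oocyte_diameter / 2
  gr <- params$gv_diameter / 2
  side <- ceiling(2 * R / voxel_size) + 2L
  nz <- ceiling(2 * R / z_step) + 2L
  ctr <- side * voxel_size / 2
  zc <- nz * z_step / 2
  # GV tangent to the animal pole along the z axis of the stack
  gz <- zc - (R - gr)
  xs <- ((seq_len(side) - 0.5) * voxel_size - ctr)^2
  oo <- array(FALSE, c(side, side, nz))
  gv <- array(FALSE, c(side, side, nz))
  plane <- outer(xs, xs, "+")
  for (k in seq_len(nz)) {
    z <- (k - 0.5) * z_step
    r2 <- R^2 - (z - zc)^2
    if (r2 > 0) oo[, , k] <- plane <= r2
    g2 <- gr^2 - (z - gz)^2
    if (g2 > 0) gv[, , k] <- plane <= g2
  }
  list(oocyte = oo, gv = gv, voxel_size = voxel_size, z_step = z_step)
}
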