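#' Render a synthetic scene into a multi-channel frame
#'
#' Channel semantics follow the imaging: the ooplasm channel is bright
#' interior signal with both yolk and cortical granules dark; Lysotracker
#' marks yolk granules bright while cortical granules stay dark in both
#' channels (which is how Cgs are identified); the microtubule channel is a
#' diffuse background plus Gaussian aster spots; Rab11 and K+ channels show
#' small bright puncta; the brightfield proxy attenuates with local yolk
#' coverage. The clean image is blurred with a Gaussian PSF and corrupted
#' with photon (Poisson) plus additive read noise per `params$noise_model`;
#' the oocyte exterior sits at background level.
#'
#' Rendering is seeded from `(params$seed, state$frame)`, so rendering the
#' same state twice gives identical images.
#'
#' @param state an `oo_scene`.
#' @param params an [scene_params()]; defaults to the scene's own.
#' @return Integer array C x Y x X of 16-bit counts, with channel names
#'   `r paste(scene_channels(), collapse = ", ")` on the first dimension.
#' @export
render_frame <- function(state, params = state$params) {
  if (!inherits(state, "oo_scene")) stop("'state' must be an oo_scene")
  px <- params$pixel_size
  side <- scene_side_px(params)
  if (side < 8L)
    stop("pixel_size incompatible with field of view (image would be empty)")
  ctr <- state$center; R <- state$radius
  xs <- (pixel_centers_x(side, px) - ctr[1])^2
  ys <- (pixel_centers_y(side, px) - ctr[2])^2
  inside <- outer(ys, xs, "+") <= R^2

  g <- state$granules[state$granules$alive, , drop = FALSE]
  yolk <- g[g$kind == "yolk", , drop = FALSE]
  cg <- g[g$kind == "cortical", , drop = FALSE]
  kp <- g[g$kind == "kplus", , drop = FALSE]
  rb <- g[g$kind == "rab11", , drop = FALSE]

  blank <- matrix(0.02, side, side)

  ch <- list()
  # ooplasm (Clip170-like): granules excluded from the signal
  m <- blank; m[inside] <- 0.55
  if (state$gv_present)
    m <- paint_disk(m, state$gv_center[1], state$gv_center[2],
                    state$gv_radius, 0.50, px)
  for (i in seq_len(nrow(yolk)))
    m <- paint_disk(m, yolk$x[i], yolk$y[i], yolk$radius[i], 0.06, px)
  for (i in seq_len(nrow(cg)))
    m <- paint_disk(m, cg$x[i], cg$y[i], cg$radius[i], 0.06, px)
  ch$ooplasm <- m

  # Lysotracker: yolk bright with a dark membrane rim (the dye marks the
  # acidic lumen, not the bounding membrane), cortical dark. Rims are
  # painted after all lumina so that touching granules stay separated by
  # an intensity valley, as they are in the real images.
  m <- blank; m[inside] <- 0.10
  if (state$gv_present)
    m <- paint_disk(m, state$gv_center[1], state$gv_center[2],
                    state$gv_radius, 0.05, px)
  for (i in seq_len(nrow(yolk)))
    m <- paint_disk(m, yolk$x[i], yolk$y[i], yolk$radius[i], 0.60, px)
  for (i in seq_len(nrow(yolk)))
    m <- paint_ring(m, yolk$x[i], yolk$y[i], yolk$radius[i],
                    yolk$radius[i] + 1.6, 0.03, px)
  for (i in seq_len(nrow(cg)))
    m <- paint_disk(m, cg$x[i], cg$y[i], cg$radius[i], 0.03, px)
  ch$lysotracker <- m

  # microtubules: background + Gaussian asters
  m <- blank; m[inside] <- 0.12
  ast <- aster_positions(state)
  for (i in seq_len(nrow(ast)))
    m <- add_gaussian_spot(m, ast$x[i], ast$y[i], ast$amplitude[i],
                           ast$sigma[i], px)
  ch$microtubule <- clamp(m, 0, 1)

  # Rab11 / K+ puncta
  m <- blank; m[inside] <- 0.05
  for (i in seq_len(nrow(rb)))
    m <- paint_disk(m, rb$x[i], rb$y[i], rb$radius[i], 0.70, px)
  ch$rab11 <- m
  m <- blank; m[inside] <- 0.05
  for (i in seq_len(nrow(kp)))
    m <- paint_disk(m, kp$x[i], kp$y[i], kp$radius[i], 0.70, px)
  ch$kplus <- m

  # brightfield proxy: attenuation where yolk sits
  m <- matrix(0.80, side, side)
  for (i in seq_len(nrow(yolk)))
    m <- paint_disk(m, yolk$x[i], yolk$y[i], yolk$radius[i], 0.35, px)
  ch$brightfield <- m

  nm <- params$noise_model
  out <- array(0L, dim = c(length(ch), side, side))
  with_seed(params$seed + 104729 * (state$frame %% 10000) + 13, {
    for (k in seq_along(ch)) {
      m <- ch[[k]]
      if (params$psf_sigma > 0)
        m <- EBImage::imageData(EBImage::gblur(EBImage::Image(m),
                                               sigma = params$psf_sigma / px))
      if (nm$photon_rate > 0) {
        v <- rpois(length(m), clamp(m, 0, 1) * nm$photon_rate)
        if (nm$read_sigma > 0) v <- v + rnorm(length(m), 0, nm$read_sigma)
        m <- matrix(v / nm$photon_rate, side, side)
      }
      out[k, , ] <- to_uint16(m)
    }
  })
  dimnames(out) <- list(scene_channels(), NULL, NULL)
  out
}

#' Generate a synthetic maturation time-lapse with ground truth
#'
#' Drives [init_scene()], [step_scene()] and [render_frame()] for
#' `params$n_frames` frames at `params$frame_interval`, recording the
#' ground-truth tables used as test oracles: per-frame granule tracks,
#' fusion events, aster tracks and the prescribed speeds.
#'
#' @param params an [scene_params()] object.
#' @return A list with `timelapse` (an `oo_timelapse`) and `truth` (an
#'   `oo_truth` with `granule_tracks`, `fusion_events`, `aster_tracks`,
#'   `true_velocities`). Speeds are signed: radially inward negative,
#'   outward positive.
#' @examples
#' \donttest{
#' p <- scene_params(oocyte_diameter = 120, gv_diameter = 30, n_yolk = 8,
#'                   n_cg = 16, yolk_radius_range = c(4, 7),
#'                   cg_radius_range = c(1.5, 3), n_frames = 4,
#'                   gvbd_time = 60)
#' run <- generate_timelapse(p)
#' dim(run$timelapse$frames)
#' }
#' @export
generate_timelapse <- function(params) {
  state <- init_scene(params)
  side <- scene_side_px(params)
  chn <- scene_channels()
  frames <- array(0L, dim = c(params$n_frames, length(chn), side, side))
  tracks <- vector("list", params$n_frames)
  asters <- vector("list", params$n_frames)
  for (f in seq_len(params$n_frames)) {
    tracks[[f]] <- scene_track_rows(state)
    ap <- aster_positions(state)
    asters[[f]] <- if (nrow(ap)) data.frame(frame = state$frame, id = ap$id,
                                            x = ap$x, y = ap$y)
                   else data.frame(frame = integer(), id = integer(),
                                   x = numeric(), y = numeric())
    frames[f, , , ] <- render_frame(state, params)
    if (f < params$n_frames) state <- step_scene(state, params$frame_interval)
  }
  truth <- structure(list(
    granule_tracks = do.call(rbind, tracks),
    fusion_events = state$fusion_events,
    aster_tracks = do.call(rbind, asters),
    true_velocities = data.frame(
      process = c("yolk_compaction", "cg_outward", "aster_drift",
                  "aster_wave"),
      speed_um_min = c(-params$compaction_speed, params$cg_outward_speed,
                       params$aster_drift_speed, params$aster_wave_speed)
    ),
    domain_map = NULL,
    geometry = list(center = state$center, radius = state$radius,
                    gv_center = state$gv_center, gv_radius = state$gv_radius)
  ), class = "oo_truth")
  list(
    timelapse = timelapse(frames, chn, params$pixel_size,
                          params$frame_interval, axis_annotation = 0),
    truth = truth
  )
}

#' @export
print.oo_truth <- function(x, ...) {
  cat("Ground truth tables:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.data.frame(v)) cat(sprintf("  %s: %d rows\n", nm, nrow(v)))
    else if (is.matrix(v)) cat(sprintf("  %s: %d x %d\n", nm, nrow(v), ncol(v)))
  }
  invisible(x)
}
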