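#' Parameters of a synthetic oocyte maturation scene
#'
#' Bundles the geometry, kinematics, population sizes and imaging model of a
#' synthetic stage III/IV oocyte time-lapse. Defaults reproduce the imaged
#' biology: a 600 um oocyte whose germinal vesicle (GV) occupies 1.5% of the
#' oocyte volume (diameter 148 um), yolk granules (Yg) that fuse with 3D
#' volume conservation at an expected 1.5 pairwise-fusion rounds per granule
#' (so the mean cross-sectional area doubles, 2^(2*1.5/3) = 2), centripetal
#' Yg compaction and outward cortical granule (Cg) advection at 0.3 um/min,
#' and an animal-to-vegetal microtubule aster-formation wave.
#'
#' @param oocyte_diameter oocyte diameter, um.
#' @param gv_diameter GV diameter, um; must be smaller than the oocyte.
#'   The default 148 um makes the GV 1.5% of a 600 um oocyte's volume.
#' @param pixel_size image calibration, um per pixel.
#' @param frame_interval time between frames, seconds.
#' @param n_frames number of frames in a generated time-lapse.
#' @param n_yolk,n_cg number of yolk / cortical granules.
#' @param yolk_radius_range,cg_radius_range granule radius ranges, um
#'   (length-2, increasing).
#' @param fusion_rounds_mean expected pairwise-fusion rounds per Yg over the
#'   post-GVBD part of the run (dimensionless).
#' @param gvbd_time time of germinal vesicle breakdown, seconds from the
#'   first frame; fusion, compaction, aster and K+ dynamics start here.
#' @param compaction_speed inward Yg advection speed, um/min.
#' @param cg_outward_speed outward Cg advection speed, um/min.
#' @param aster_wave_speed speed of the aster-formation front along the
#'   aster nucleation circumference (at 0.75 oocyte radius), um/min.
#' @param aster_drift_speed outward radial drift of asters (and Rab11
#'   puncta), um/min.
#' @param aster_density_peak peak aster density, count per 1e5 um^2 of
#'   oocyte cross-section.
#' @param aster_sigma Gaussian sigma of a rendered aster, um.
#' @param aster_lifetime mean aster lifetime, minutes.
#' @param n_rab11 number of Rab11-positive puncta.
#' @param k_appear_rate K+ vesicle appearance rate after GVBD, count/min.
#' @param noise_model list with `photon_rate` (expected photon count at
#'   unit intensity; 0 disables photon noise) and `read_sigma` (additive
#'   Gaussian read noise, photon counts).
#' @param psf_sigma Gaussian point-spread sigma, um; 0 disables blurring.
#' @param field_size side of the square surface patch used by
#'   [generate_contraction_series()], um.
#' @param seed integer seed; identical parameters and seed give
#'   bit-identical frames and tables.
#'
#' @return An object of class `oo_scene_params` (a validated list).
#' @seealso [init_scene()], [generate_timelapse()],
#'   [generate_contraction_series()]
#' @examples
#' p <- scene_params(oocyte_diameter = 150, n_yolk = 20, n_cg = 40,
#'                   yolk_radius_range = c(4, 8), cg_radius_range = c(1.5, 3),
#'                   n_frames = 10)
#' p$gv_diameter / p$oocyte_diameter
#' @export
scene_params <- function(oocyte_diameter = 600,
                         gv_diameter = 148,
                         pixel_size = 1.0,
                         frame_interval = 60,
                         n_frames = 60,
                         n_yolk = 300,
                         n_cg = 600,
                         yolk_radius_range = c(8, 20),
                         cg_radius_range = c(2, 5),
                         fusion_rounds_mean = 1.5,
                         gvbd_time = 600,
                         compaction_speed = 0.3,
                         cg_outward_speed = 0.3,
                         aster_wave_speed = 20,
                         aster_drift_speed = 0.5,
                         aster_density_peak = 8,
                         aster_sigma = 6,
                         aster_lifetime = 20,
                         n_rab11 = 150,
                         k_appear_rate = 4,
                         noise_model = list(photon_rate = 200, read_sigma = 2),
                         psf_sigma = 1.0,
                         field_size = 200,
                         seed = 1L) {
  # gv_diameter default is tied to oocyte_diameter = 600; scale it if the
  # caller shrinks the oocyte but leaves the GV at its default.
  stopifnot_scalar(oocyte_diameter, "oocyte_diameter")
  stopifnot_scalar(gv_diameter, "gv_diameter")
  stopifnot_scalar(pixel_size, "pixel_size")
  stopifnot_scalar(frame_interval, "frame_interval")
  stopifnot_scalar(n_frames, "n_frames")
  stopifnot_scalar(psf_sigma, "psf_sigma", positive = FALSE)
  stopifnot_scalar(field_size, "field_size")
  for (nm in c("fusion_rounds_mean", "compaction_speed", "cg_outward_speed",
               "aster_wave_speed", "aster_drift_speed", "aster_density_peak",
               "k_appear_rate", "gvbd_time")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("'%s' must be a finite non-negative scalar", nm), call. = FALSE)
  }
  for (nm in c("n_yolk", "n_cg", "n_rab11")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v))
      stop(sprintf("'%s' must be a non-negative integer", nm), call. = FALSE)
  }
  if (gv_diameter >= oocyte_diameter)
    stop("'gv_diameter' must be smaller than 'oocyte_diameter'")
  for (nm in c("yolk_radius_range", "cg_radius_range")) {
    v <- get(nm)
    if (length(v) != 2L || any(!is.finite(v)) || any(v <= 0) || v[1] >= v[2])
      stop(sprintf("'%s' must be an increasing positive length-2 range", nm),
           call. = FALSE)
  }
  if (!is.list(noise_model) ||
      !all(c("photon_rate", "read_sigma") %in% names(noise_model)))
    stop("'noise_model' must be list(photon_rate=, read_sigma=)")
  if (noise_model$photon_rate < 0 || noise_model$read_sigma < 0)
    stop("noise_model rates must be non-negative")
  if (n_frames < 1) stop("'n_frames' must be >= 1")

  p <- list(
    oocyte_diameter = oocyte_diameter, gv_diameter = gv_diameter,
    pixel_size = pixel_size, frame_interval = frame_interval,
    n_frames = as.integer(n_frames), n_yolk = as.integer(n_yolk),
    n_cg = as.integer(n_cg), yolk_radius_range = as.numeric(yolk_radius_range),
    cg_radius_range = as.numeric(cg_radius_range),
    fusion_rounds_mean = fusion_rounds_mean, gvbd_time = gvbd_time,
    compaction_speed = compaction_speed, cg_outward_speed = cg_outward_speed,
    aster_wave_speed = aster_wave_speed, aster_drift_speed = aster_drift_speed,
    aster_density_peak = aster_density_peak, aster_sigma = aster_sigma,
    aster_lifetime = aster_lifetime, n_rab11 = as.integer(n_rab11),
    k_appear_rate = k_appear_rate, noise_model = noise_model,
    psf_sigma = psf_sigma, field_size = field_size, seed = as.integer(seed)
  )
  class(p) <- "oo_scene_params"
  p
}

#' @export
print.oo_scene_params <- function(x, ...) {
  cat("Synthetic oocyte scene parameters\n")
  cat(sprintf("  oocyte %g um, GV %g um (volume fraction %.2f%%)\n",
              x$oocyte_diameter, x$gv_diameter,
              100 * (x$gv_diameter / x$oocyte_diameter)^3))
  cat(sprintf("  %d Yg (%g-%g um), %d Cg (%g-%g um), %d frames @ %g s\n",
              x$n_yolk, x$yolk_radius_range[1], x$yolk_radius_range[2],
              x$n_cg, x$cg_radius_range[1], x$cg_radius_range[2],
              x$n_frames, x$frame_interval))
  cat(sprintf("  fusion rounds %g, GVBD at %g s, seed %d\n",
              x$fusion_rounds_mean, x$gvbd_time, x$seed))
  invisible(x)
}

# image side (pixels) for a scene: oocyte plus a 1/15 margin, even size
scene_side_px <- function(params) {
  2L * as.integer(ceiling(params$oocyte_diameter * (16 / 15) /
                            (2 * params$pixel_size)))
}

# channel order used by all rendered stacks
scene_channels <- function() {
  c("ooplasm", "lysotracker", "microtubule", "rab11", "kplus", "brightfield")
}
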