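#' Generate a synthetic contracting-network series with ground truth
#'
#' Emulates the temporal evolution of a microtubule network on a square
#' surface patch that contracts either locally (towards `n_foci`
#' attractors, as in control oocytes where many small asters form) or
#' globally (towards a single attractor, the large-scale contraction mode
#' seen under dynein inhibition). A speckled network texture is seeded
#' uniformly, every speckle is assigned to its nearest attractor, and each
#' frame renders the speckles at positions interpolated towards that
#' attractor. The ground-truth `domain_map` labels every initial network
#' pixel with its attractor basin - the exact Voronoi partition that
#' [contraction_domains()] should recover.
#'
#' @param params an [scene_params()]; uses `field_size`, `pixel_size`,
#'   `n_frames`, `frame_interval`, `psf_sigma`, `noise_model`, `seed`.
#' @param mode `"local"` (n_foci attractors) or `"global"` (one attractor).
#' @param n_foci number of attractors in local mode (>= 1; ignored in
#'   global mode). Perfect squares are laid out on a regular grid, other
#'   counts on a truncated grid. An error is raised when foci would be
#'   closer than the minimum resolvable spacing.
#' @param speckle_density fraction of patch pixels seeded with network
#'   speckles.
#' @return A list with `timelapse` (single "network" channel) and `truth`
#'   (an `oo_truth` whose `domain_map` is the label image of attractor
#'   basins over the initial network mask, and `foci` the attractor table).
#' @examples
#' p <- scene_params(field_size = 60, n_frames = 6,
#'                   noise_model = list(photon_rate = 0, read_sigma = 0),
#'                   psf_sigma = 0)
#' run <- generate_contraction_series(p, mode = "global")
#' max(run$truth$domain_map)
#' @export
generate_contraction_series <- function(params, mode = c("local", "global"),
                                        n_foci = 9,
                                        speckle_density = 0.10) {
  if (!inherits(params, "oo_scene_params"))
    stop("'params' must be created by scene_params()")
  mode <- match.arg(mode)
  L <- params$field_size
  px <- params$pixel_size
  side <- as.integer(round(L / px))
  if (side < 8L) stop("field too small for the pixel size")
  if (mode == "global") n_foci <- 1L
  if (n_foci < 1) stop("'n_foci' must be >= 1")

  foci <- contraction_foci(n_foci, L)
  min_spacing <- max(6 * params$psf_sigma, 12 * px)
  if (n_foci > 1) {
    dmin <- min(stats::dist(foci))
    if (dmin < min_spacing)
      stop(sprintf("n_foci = %d exceeds what a %g um patch can separate",
                   n_foci, L))
  }

  res <- with_seed(params$seed + 7919, {
    n_pts <- max(1L, round(speckle_density * side^2))
    pts <- cbind(runif(n_pts, 0, L), runif(n_pts, 0, L))
    # attractor basin of each speckle = nearest focus
    d2 <- vapply(seq_len(nrow(foci)), function(k)
      (pts[, 1] - foci[k, 1])^2 + (pts[, 2] - foci[k, 2])^2,
      numeric(n_pts))
    basin <- if (nrow(foci) == 1L) rep(1L, n_pts)
             else max.col(-d2, ties.method = "first")

    nT <- params$n_frames
    frames <- array(0L, dim = c(nT, 1L, side, side))
    nm <- params$noise_model
    for (t in seq_len(nT)) {
      s <- if (nT == 1L) 1 else 0.05 + 0.95 * (1 - (t - 1) / (nT - 1))
      cx <- foci[basin, 1] + (pts[, 1] - foci[basin, 1]) * s
      cy <- foci[basin, 2] + (pts[, 2] - foci[basin, 2]) * s
      j <- clamp(ceiling(cx / px), 1, side)
      i <- clamp(ceiling(cy / px), 1, side)
      cnt <- matrix(tabulate((j - 1L) * side + i, nbins = side * side),
                    side, side)
      m <- clamp(0.05 + 0.30 * cnt, 0, 1)
      if (params$psf_sigma > 0)
        m <- EBImage::imageData(EBImage::gblur(EBImage::Image(m),
                                               sigma = params$psf_sigma / px))
      if (nm$photon_rate > 0) {
        v <- rpois(length(m), clamp(m, 0, 1) * nm$photon_rate)
        if (nm$read_sigma > 0) v <- v + rnorm(length(m), 0, nm$read_sigma)
        m <- matrix(v / nm$photon_rate, side, side)
      }
      frames[t, 1L, , ] <- to_uint16(m)
    }

    # ground-truth domain map over the initial network mask
    dmap <- matrix(0L, side, side)
    j <- clamp(ceiling(pts[, 1] / px), 1, side)
    i <- clamp(ceiling(pts[, 2] / px), 1, side)
    # a pixel holding speckles from several basins takes the first-placed one
    lin <- (j - 1L) * side + i
    keep <- !duplicated(lin)
    dmap[lin[keep]] <- basin[keep]
    list(frames = frames, dmap = dmap)
  })

  truth <- structure(list(
    granule_tracks = NULL, fusion_events = NULL, aster_tracks = NULL,
    true_velocities = NULL,
    domain_map = res$dmap,
    foci = data.frame(id = seq_len(nrow(foci)),
                      x = foci[, 1], y = foci[, 2]),
    mode = mode, field_size = L
  ), class = "oo_truth")
  list(
    timelapse = timelapse(res$frames, "network", px, params$frame_interval),
    truth = truth
  )
}

# Regular (possibly truncated) grid of attractors in a square of side L.
contraction_foci <- function(n, L) {
  if (n == 1L) return(cbind(L / 2, L / 2))
  g <- ceiling(sqrt(n))
  rows <- ceiling(n / g)
  xs <- (seq_len(g) - 0.5) / g * L
  ys <- (seq_len(rows) - 0.5) / rows * L
  grid <- expand.grid(x = xs, y = ys)
  as.matrix(grid[seq_len(n), , drop = FALSE])
}
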