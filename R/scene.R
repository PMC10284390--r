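#' Initialize a synthetic oocyte scene
#'
#' Builds the initial (stage III) state of a synthetic oocyte: a disk of the
#' configured diameter with the germinal vesicle placed tangent to the
#' animal-pole interior, `n_yolk` yolk granules and `n_cg` cortical granules
#' packed without pairwise overlap exceeding 10% of the smaller radius and
#' none intersecting the GV, Rab11 puncta scattered through the ooplasm, and
#' a pre-computed aster nucleation schedule for the animal-to-vegetal wave.
#'
#' Granules are seeded largest-first by rejection sampling and the packing is
#' then tightened by deterministic pairwise push-apart relaxation; at the
#' default ~75% areal coverage rejection sampling alone cannot terminate. If
#' relaxation cannot satisfy the overlap bound the density is infeasible and
#' an error is raised.
#'
#' @param params an [scene_params()] object.
#' @return An object of class `oo_scene`: a list carrying `params`, `time`
#'   (s), `frame`, oocyte geometry (`center`, `radius`, `gv_center`,
#'   `gv_radius`, `gv_present`), a `granules` data frame
#'   (id, kind, x, y, radius, alive, parent1, parent2), an `asters` schedule,
#'   accumulated `fusion_events`, and the RNG state used to continue the
#'   simulation deterministically.
#' @examples
#' p <- scene_params(oocyte_diameter = 120, gv_diameter = 30, n_yolk = 10,
#'                   n_cg = 20, yolk_radius_range = c(4, 7),
#'                   cg_radius_range = c(1.5, 3), n_frames = 5)
#' sc <- init_scene(p)
#' nrow(sc$granules[sc$granules$kind == "yolk", ])
#' @export
init_scene <- function(params) {
  if (!inherits(params, "oo_scene_params"))
    stop("'params' must be created by scene_params()")
  side_um <- scene_side_px(params) * params$pixel_size
  center <- c(side_um / 2, side_um / 2)
  R <- params$oocyte_diameter / 2
  gv_r <- params$gv_diameter / 2
  gv_center <- center + c(0, -(R - gv_r))  # tangent to the animal pole (up)

  state <- with_seed(params$seed, {
    ry <- sort(runif(params$n_yolk, params$yolk_radius_range[1],
                     params$yolk_radius_range[2]), decreasing = TRUE)
    rc <- sort(runif(params$n_cg, params$cg_radius_range[1],
                     params$cg_radius_range[2]), decreasing = TRUE)
    radii <- c(ry, rc)
    kind <- c(rep("yolk", params$n_yolk), rep("cortical", params$n_cg))
    # required center separation: overlap of up to 10% of the smaller
    # radius is tolerated, except between two cortical granules, which
    # start dispersed in between the yolk granules with a clear gap
    need <- outer(radii, radii, "+") - 0.1 * outer(radii, radii, pmin)
    cc <- kind == "cortical"
    need[cc, cc] <- outer(radii[cc], radii[cc], "+") + 0.9
    diag(need) <- 0
    pos <- pack_granules(radii, center, R, gv_center, gv_r, need)

    gr <- data.frame(
      id = seq_along(radii), kind = kind,
      x = pos[, 1], y = pos[, 2], radius = radii,
      alive = rep(TRUE, length(radii)),
      parent1 = rep(NA_integer_, length(radii)),
      parent2 = rep(NA_integer_, length(radii)),
      stringsAsFactors = FALSE
    )
    next_id <- length(radii) + 1L

    if (params$n_rab11 > 0) {
      rb <- place_sparse(params$n_rab11, center, R - 8, gv_center, gv_r,
                         min_sep = 8)
      gr <- rbind(gr, data.frame(
        id = next_id + seq_len(params$n_rab11) - 1L, kind = "rab11",
        x = rb[, 1], y = rb[, 2], radius = 1.5,
        alive = TRUE, parent1 = NA_integer_, parent2 = NA_integer_
      ))
      next_id <- next_id + params$n_rab11
    }

    asters <- schedule_asters(params, center, R)

    st <- list(
      params = params, time = 0, frame = 1L,
      center = center, radius = R,
      gv_center = gv_center, gv_radius = gv_r, gv_present = TRUE,
      granules = gr, asters = asters,
      fusion_events = data.frame(frame = integer(), parent1 = integer(),
                                 parent2 = integer(), child = integer()),
      next_id = next_id
    )
    st$rng_state <- get(".Random.seed", envir = globalenv())
    st
  })
  class(state) <- "oo_scene"
  state
}

#' @export
print.oo_scene <- function(x, ...) {
  g <- x$granules[x$granules$alive, ]
  cat(sprintf("Synthetic oocyte scene at t = %g s (frame %d)\n", x$time, x$frame))
  cat(sprintf("  oocyte R = %g um; GV %s\n", x$radius,
              if (x$gv_present) "intact" else "broken down"))
  print(table(g$kind))
  invisible(x)
}

# Largest-first rejection seeding + push-apart relaxation.
pack_granules <- function(radii, center, R, gv_center, gv_r, need = NULL,
                          attempts = 120L, maxit = 600L, tol = 0.05) {
  n <- length(radii)
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  if (is.null(need)) {
    need <- outer(radii, radii, "+") - 0.1 * outer(radii, radii, pmin)
    diag(need) <- 0
  }
  # 3 um cortex clearance: granules start clear of the rim that granule
  # segmentation erodes away
  R <- R - 3
  px <- numeric(n); py <- numeric(n)
  for (i in seq_len(n)) {
    r <- radii[i]
    best <- NULL; best_v <- Inf
    for (a in seq_len(attempts)) {
      rr <- max(R - r, 0) * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
      cx <- center[1] + rr * sin(th); cy <- center[2] - rr * cos(th)
      v_gv <- (gv_r + r) - sqrt(sum((c(cx, cy) - gv_center)^2))
      v_pk <- 0
      if (i > 1L) {
        d <- sqrt((px[seq_len(i - 1L)] - cx)^2 + (py[seq_len(i - 1L)] - cy)^2)
        v_pk <- max(need[seq_len(i - 1L), i] - d)
      }
      v <- max(v_gv, v_pk, 0)
      if (v < best_v) { best_v <- v; best <- c(cx, cy) }
      if (v <= 0) break
    }
    px[i] <- best[1]; py[i] <- best[2]
  }
  pos <- relax_positions(cbind(px, py), radii, center, R, gv_center, gv_r,
                         need = need, maxit = maxit)
  viol <- packing_violation(pos, radii, gv_center, gv_r, need)
  if (viol > tol)
    stop(sprintf(paste0("packing failure: residual overlap %.2f um exceeds ",
                        "tolerance; granule density is infeasible"), viol))
  pos
}

# Maximum remaining pairwise/GV overlap violation (um).
packing_violation <- function(pos, radii, gv_center = NULL, gv_r = 0,
                              need = NULL) {
  n <- nrow(pos)
  v <- 0
  if (n > 1L) {
    d <- as.matrix(stats::dist(pos))
    if (is.null(need)) {
      need <- outer(radii, radii, "+") - 0.1 * outer(radii, radii, pmin)
      diag(need) <- 0
    }
    v <- max(need - d)
  }
  if (!is.null(gv_center)) {
    dg <- sqrt((pos[, 1] - gv_center[1])^2 + (pos[, 2] - gv_center[2])^2)
    v <- max(v, max(gv_r + radii - dg, 0))
  }
  max(v, 0)
}

# Iterative pairwise push-apart; keeps granules inside the oocyte and
# outside the GV (when gv_r > 0). Deterministic.
relax_positions <- function(pos, radii, center, R, gv_center = NULL, gv_r = 0,
                            need = NULL, maxit = 200L, tol = 0.02,
                            factor = 1.05) {
  n <- nrow(pos)
  if (n == 0L) return(pos)
  if (is.null(need)) {
    need <- outer(radii, radii, "+") - 0.1 * outer(radii, radii, pmin)
    diag(need) <- 0
  }
  for (it in seq_len(maxit)) {
    d <- as.matrix(stats::dist(pos))
    over <- need - d
    over[lower.tri(over, diag = TRUE)] <- -1
    idx <- which(over > 0, arr.ind = TRUE)
    moved <- FALSE
    if (nrow(idx) > 0) {
      moved <- TRUE
      i <- idx[, 1]; j <- idx[, 2]
      dx <- pos[j, 1] - pos[i, 1]; dy <- pos[j, 2] - pos[i, 2]
      dd <- pmax(d[idx], 1e-9)
      push <- factor * over[idx] / 2
      ux <- dx / dd; uy <- dy / dd
      # coincident centers: push along a fixed direction
      zero <- dd < 1e-8
      if (any(zero)) { ux[zero] <- 1; uy[zero] <- 0 }
      ids <- c(i, j)
      vx <- c(-ux * push, ux * push)
      vy <- c(-uy * push, uy * push)
      sx <- rowsum(vx, ids); sy <- rowsum(vy, ids)
      k <- as.integer(rownames(sx))
      pos[k, 1] <- pos[k, 1] + sx[, 1]
      pos[k, 2] <- pos[k, 2] + sy[, 1]
    }
    # GV exclusion
    if (!is.null(gv_center) && gv_r > 0) {
      dg <- sqrt((pos[, 1] - gv_center[1])^2 + (pos[, 2] - gv_center[2])^2)
      bad <- dg < gv_r + radii
      if (any(bad)) {
        moved <- TRUE
        dgb <- pmax(dg[bad], 1e-9)
        f <- (gv_r + radii[bad]) / dgb
        pos[bad, 1] <- gv_center[1] + (pos[bad, 1] - gv_center[1]) * f
        pos[bad, 2] <- gv_center[2] + (pos[bad, 2] - gv_center[2]) * f
      }
    }
    # cortex clamp
    dc <- sqrt((pos[, 1] - center[1])^2 + (pos[, 2] - center[2])^2)
    out <- dc > R - radii
    if (any(out)) {
      dcb <- pmax(dc[out], 1e-9)
      f <- (R - radii[out]) / dcb
      pos[out, 1] <- center[1] + (pos[out, 1] - center[1]) * f
      pos[out, 2] <- center[2] + (pos[out, 2] - center[2]) * f
    }
    if (!moved) break
    if (it %% 20L == 0L &&
        packing_violation(pos, radii, gv_center, gv_r, need) <= tol) break
  }
  pos
}

# Sparse point placement with a minimum separation (rejection only).
place_sparse <- function(n, center, R, gv_center, gv_r, min_sep,
                         attempts = 400L) {
  px <- numeric(n); py <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(attempts)) {
      rr <- R * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
      cx <- center[1] + rr * sin(th); cy <- center[2] - rr * cos(th)
      if (sqrt(sum((c(cx, cy) - gv_center)^2)) < gv_r + min_sep) next
      if (i > 1L) {
        d2 <- (px[seq_len(i - 1L)] - cx)^2 + (py[seq_len(i - 1L)] - cy)^2
        if (min(d2) < min_sep^2) next
      }
      px[i] <- cx; py[i] <- cy; placed <- TRUE; break
    }
    if (!placed) stop("packing failure: cannot place sparse puncta")
  }
  cbind(px, py)
}

# Aster nucleation schedule. The formation front starts at the animal pole
# at GVBD and travels symmetrically towards the vegetal pole along the
# nucleation circumference (0.75 R) at aster_wave_speed. Angular slots keep
# a minimum arc gap of 3 sigma so rendered asters stay resolvable.
schedule_asters <- function(params, center, R) {
  r_wave <- 0.75 * R
  area <- pi * R^2
  peak <- params$aster_density_peak * area / 1e5
  t_wave <- pi * r_wave / max(params$aster_wave_speed, 1e-9)  # min, AP to VP
  life_mean <- 1.35 * params$aster_lifetime
  n_total <- round(peak * max(1, t_wave / max(life_mean, 1e-9)))
  empty <- data.frame(id = integer(), theta = numeric(), spawn_r = numeric(),
                      spawn_t = numeric(), death_t = numeric(),
                      amplitude = numeric(), sigma = numeric())
  if (n_total < 1 || params$aster_density_peak == 0) return(empty)
  min_gap <- 3 * params$aster_sigma / r_wave  # radians
  thetas <- numeric(0)
  for (k in seq_len(n_total)) {
    for (a in 1:300) {
      th <- runif(1, 0, 2 * pi)
      if (length(thetas) == 0) { thetas <- th; break }
      gap <- abs((thetas - th + pi) %% (2 * pi) - pi)
      if (min(gap) >= min_gap) { thetas <- c(thetas, th); break }
    }
  }
  n <- length(thetas)
  arc <- r_wave * pmin(thetas, 2 * pi - thetas)
  spawn_t <- params$gvbd_time + 60 * arc / max(params$aster_wave_speed, 1e-9)
  life <- 60 * params$aster_lifetime * runif(n, 0.7, 2.0)
  data.frame(
    id = seq_len(n), theta = thetas,
    spawn_r = R * runif(n, 0.70, 0.80),
    spawn_t = spawn_t, death_t = spawn_t + life,
    amplitude = 0.5 * runif(n, 0.8, 1.2), sigma = params$aster_sigma
  )
}

# Radius of the granule arising from a volume-conserving pairwise fusion.
fusion_child_radius <- function(r1, r2) (r1^3 + r2^3)^(1 / 3)

#' Advance a synthetic scene by one time step
#'
#' Applies the post-GVBD dynamics: yolk granules advect towards the oocyte
#' center at `compaction_speed` and contacting pairs fuse with 3D volume
#' conservation (child radius `(r1^3 + r2^3)^(1/3)`, placed at the
#' volume-weighted centroid); cortical granules and Rab11 puncta advect
#' outward; K+ vesicles appear and fuse; scheduled asters activate with the
#' animal-to-vegetal wave and drift outward. Before `gvbd_time` the scene is
#' static. Granules clamp at the cortex rather than exit. The per-pair
#' fusion probability is re-calibrated every step against the count schedule
#' `n(t) = n0 * 2^(-fusion_rounds_mean * tau)`, `tau` the fraction of the
#' post-GVBD run elapsed, so the expected number of fusion rounds per
#' granule over the run equals `fusion_rounds_mean`.
#'
#' @param state an `oo_scene` from [init_scene()] or a previous step.
#' @param dt time step, seconds (> 0).
#' @return The advanced `oo_scene`; fusion events are appended to
#'   `state$fusion_events` with the frame index of the new state.
#' @export
step_scene <- function(state, dt) {
  if (!inherits(state, "oo_scene")) stop("'state' must be an oo_scene")
  stopifnot_scalar(dt, "dt")
  p <- state$params
  t0 <- state$time; t1 <- t0 + dt
  eff_dt <- max(0, t1 - max(t0, p$gvbd_time))  # seconds of post-GVBD motion

  # restore the scene RNG stream
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
  })
  assign(".Random.seed", state$rng_state, envir = globalenv())

  g <- state$granules
  ctr <- state$center; R <- state$radius
  new_frame <- state$frame + 1L

  if (eff_dt > 0) {
    # yolk: inward advection
    iy <- which(g$alive & g$kind == "yolk")
    if (length(iy)) {
      step_um <- p$compaction_speed * eff_dt / 60
      dx <- ctr[1] - g$x[iy]; dy <- ctr[2] - g$y[iy]
      d <- sqrt(dx^2 + dy^2)
      f <- pmin(step_um / pmax(d, 1e-9), 1)
      g$x[iy] <- g$x[iy] + dx * f
      g$y[iy] <- g$y[iy] + dy * f
    }
    # cortical + rab11: outward advection, clamped 3 um inside the cortex
    for (kk in c("cortical", "rab11")) {
      ik <- which(g$alive & g$kind == kk)
      if (!length(ik)) next
      sp <- if (kk == "cortical") p$cg_outward_speed else p$aster_drift_speed
      step_um <- sp * eff_dt / 60
      dx <- g$x[ik] - ctr[1]; dy <- g$y[ik] - ctr[2]
      d <- pmax(sqrt(dx^2 + dy^2), 1e-9)
      dmax <- R - g$radius[ik] - 3
      dnew <- pmin(d + step_um, dmax)
      g$x[ik] <- ctr[1] + dx / d * dnew
      g$y[ik] <- ctr[2] + dy / d * dnew
    }
    # cortical granules travel through the ooplasm in between the yolk
    # granules, not through them: slide any Cg that ends up inside a
    # yolk granule out along their line of centers
    ic <- which(g$alive & g$kind == "cortical")
    iy0 <- which(g$alive & g$kind == "yolk")
    if (length(ic) && length(iy0)) {
      for (pass in 1:3) {
        dxm <- outer(g$x[ic], g$x[iy0], "-")
        dym <- outer(g$y[ic], g$y[iy0], "-")
        dm <- sqrt(dxm^2 + dym^2)
        needm <- outer(g$radius[ic], g$radius[iy0], "+") -
          0.1 * outer(g$radius[ic], g$radius[iy0], pmin)
        ov <- needm - dm
        worst <- max.col(ov, ties.method = "first")
        sel <- ov[cbind(seq_along(ic), worst)] > 0
        if (!any(sel)) break
        j <- worst[sel]
        dd <- pmax(dm[cbind(which(sel), j)], 1e-9)
        push <- needm[cbind(which(sel), j)] - dd
        g$x[ic[sel]] <- g$x[ic[sel]] + dxm[cbind(which(sel), j)] / dd * push
        g$y[ic[sel]] <- g$y[ic[sel]] + dym[cbind(which(sel), j)] / dd * push
      }
      # keep them inside the oocyte
      dx <- g$x[ic] - ctr[1]; dy <- g$y[ic] - ctr[2]
      d <- pmax(sqrt(dx^2 + dy^2), 1e-9)
      dmax <- R - g$radius[ic] - 3
      f <- pmin(dmax / d, 1)
      g$x[ic] <- ctr[1] + dx * f
      g$y[ic] <- ctr[2] + dy * f
    }
    # K+ vesicles: appearance ...
    n_new <- rpois(1, p$k_appear_rate * eff_dt / 60)
    if (n_new > 0) {
      kp <- place_sparse(n_new, ctr, R - 6,
                         gv_center = ctr, gv_r = 0, min_sep = 6)
      ex <- which(g$alive & g$kind == "kplus")
      # nudge new vesicles off existing ones (sparse; rejection vs existing)
      g <- rbind(g, data.frame(
        id = state$next_id + seq_len(n_new) - 1L, kind = "kplus",
        x = kp[, 1], y = kp[, 2], radius = 2,
        alive = TRUE, parent1 = NA_integer_, parent2 = NA_integer_
      ))
      state$next_id <- state$next_id + n_new
    }
    # ... and fusion of contacting K+ pairs (volume conserving, unrecorded)
    ik <- which(g$alive & g$kind == "kplus")
    if (length(ik) > 1) {
      d <- as.matrix(stats::dist(cbind(g$x[ik], g$y[ik])))
      # near-contact pairs fuse too: vesicles from different appearance
      # batches can land within a pixel of touching
      need <- outer(g$radius[ik], g$radius[ik], "+") + 1.5
      touch <- which(d < need & upper.tri(d), arr.ind = TRUE)
      used <- integer(0)
      for (rix in seq_len(nrow(touch))) {
        a <- ik[touch[rix, 1]]; b <- ik[touch[rix, 2]]
        if (a %in% used || b %in% used) next
        used <- c(used, a, b)
        w <- g$radius[c(a, b)]^3
        g$x[a] <- sum(g$x[c(a, b)] * w) / sum(w)
        g$y[a] <- sum(g$y[c(a, b)] * w) / sum(w)
        g$radius[a] <- fusion_child_radius(g$radius[a], g$radius[b])
        g$alive[b] <- FALSE
      }
    }

    # yolk fusion against the count schedule
    run_end <- (p$n_frames - 1) * p$frame_interval
    if (run_end > p$gvbd_time && p$fusion_rounds_mean > 0) {
      iy <- which(g$alive & g$kind == "yolk")
      n0 <- p$n_yolk
      tau <- clamp((min(t1, run_end) - p$gvbd_time) /
                     (run_end - p$gvbd_time), 0, 1)
      n_target <- n0 * 2^(-p$fusion_rounds_mean * tau)
      deficit <- length(iy) - n_target
      if (deficit > 0 && length(iy) > 1) {
        d <- as.matrix(stats::dist(cbind(g$x[iy], g$y[iy])))
        need <- outer(g$radius[iy], g$radius[iy], "+")
        touch <- which(d < need & upper.tri(d), arr.ind = TRUE)
        if (nrow(touch) > 0) {
          prob <- min(1, deficit / nrow(touch))
          # ascending (min id) processing order
          pid <- pmin(g$id[iy][touch[, 1]], g$id[iy][touch[, 2]])
          touch <- touch[order(pid), , drop = FALSE]
          fused <- integer(0)
          for (rix in seq_len(nrow(touch))) {
            a <- iy[touch[rix, 1]]; b <- iy[touch[rix, 2]]
            if (a %in% fused || b %in% fused) next
            if (runif(1) > prob) next
            fused <- c(fused, a, b)
            w <- g$radius[c(a, b)]^3
            child <- data.frame(
              id = state$next_id, kind = "yolk",
              x = sum(g$x[c(a, b)] * w) / sum(w),
              y = sum(g$y[c(a, b)] * w) / sum(w),
              radius = fusion_child_radius(g$radius[a], g$radius[b]),
              alive = TRUE, parent1 = g$id[a], parent2 = g$id[b]
            )
            g$alive[c(a, b)] <- FALSE
            g <- rbind(g, child)
            state$fusion_events <- rbind(state$fusion_events, data.frame(
              frame = new_frame, parent1 = child$parent1,
              parent2 = child$parent2, child = child$id
            ))
            state$next_id <- state$next_id + 1L
          }
        }
      }
    }

    # Advection is prescribed, not force-balanced: granule overlaps
    # created by compaction are mostly resolved by fusion itself (a fused
    # child frees ~21% of the pair's area). Only pathological overlaps -
    # deeper than 25% of the smaller radius, mostly fusion children
    # landing on a neighbor - are pushed back to that depth; the
    # corrections are small and rare enough to leave the prescribed
    # speeds the analyses must recover intact.
    iy <- which(g$alive & g$kind == "yolk")
    if (length(iy) > 1) {
      need <- outer(g$radius[iy], g$radius[iy], "+") -
        0.25 * outer(g$radius[iy], g$radius[iy], pmin)
      diag(need) <- 0
      pos <- relax_positions(cbind(g$x[iy], g$y[iy]), g$radius[iy], ctr, R,
                             need = need, maxit = 4L)
      g$x[iy] <- pos[, 1]; g$y[iy] <- pos[, 2]
    }
  }

  state$granules <- g
  state$time <- t1
  state$frame <- new_frame
  state$gv_present <- t1 <= p$gvbd_time
  state$rng_state <- get(".Random.seed", envir = globalenv())
  state
}

# Live aster positions at scene time t (outward drift after spawn).
aster_positions <- function(state) {
  a <- state$asters
  if (nrow(a) == 0) return(a[0, c("id", "theta")])
  t <- state$time
  live <- a$spawn_t <= t & t < a$death_t
  a <- a[live, , drop = FALSE]
  if (nrow(a) == 0)
    return(data.frame(id = integer(), x = numeric(), y = numeric(),
                      amplitude = numeric(), sigma = numeric()))
  drift <- state$params$aster_drift_speed * (t - a$spawn_t) / 60
  rad <- pmin(a$spawn_r + drift, state$radius - 2 * a$sigma)
  u <- angle_unit(a$theta)
  data.frame(id = a$id,
             x = state$center[1] + u[, "x"] * rad,
             y = state$center[2] + u[, "y"] * rad,
             amplitude = a$amplitude, sigma = a$sigma)
}

# Ground-truth table rows for the current frame.
scene_track_rows <- function(state) {
  g <- state$granules[state$granules$alive, , drop = FALSE]
  if (nrow(g) == 0)
    return(data.frame(frame = integer(), id = integer(), kind = character(),
                      x = numeric(), y = numeric(), radius = numeric()))
  data.frame(frame = state$frame, id = g$id, kind = g$kind,
             x = g$x, y = g$y, radius = g$radius)
}
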